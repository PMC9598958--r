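#' Convert raw counts to log2(TPM + 1)
#'
#' Per sample, counts are divided by gene length, scaled so the column sums
#' to one million (TPM), and transformed to log2(TPM + 1).
#'
#' @param counts non-negative count matrix (genes x samples).
#' @param lengths positive gene lengths in bp, aligned with rows of `counts`.
#' @return matrix of log2(TPM + 1) values, same dimnames as `counts`.
#' @export
counts_to_logtpm <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  log2(tpm + 1)
}

#' Filter genes by expression, chromosome and cis-probe support
#'
#' Keeps protein-coding genes expressed at or above `min_value` in at least
#' half of the samples (rounded up for odd sample counts), not on a
#' blocklisted chromosome, and with at least one cis probe.
#'
#' @param expr expression matrix (genes x samples, log2 scale).
#' @param genes gene data frame with `gene_id`, `chrom` and (optionally)
#'   `gene_type`.
#' @param cis_counts named vector of cis-probe counts per gene.
#' @param min_value expression threshold (inclusive).
#' @param blocklist chromosomes to exclude (sex chromosomes by default).
#' @return list with `keep` (gene ids) and `report` (gene_id, reason for
#'   every dropped gene).
#' @export
filter_genes <- function(expr, genes, cis_counts,
                         min_value = 1,
                         blocklist = c("chrX", "chrY", "X", "Y")) {
  n <- ncol(expr)
  need <- ceiling(n / 2)
  ids <- rownames(expr)
  gi <- genes[match(ids, genes$gene_id), , drop = FALSE]
  coding <- if ("gene_type" %in% names(gi)) {
    is.na(gi$gene_type) | gi$gene_type == "protein_coding"
  } else rep(TRUE, length(ids))
  expressed <- rowSums(expr >= min_value) >= need
  autosomal <- !(gi$chrom %in% blocklist)
  has_probe <- !is.na(cis_counts[ids]) & cis_counts[ids] >= 1
  keep <- coding & expressed & autosomal & has_probe
  reason <- character(0); dropped <- character(0)
  add <- function(mask, why) {
    dropped <<- c(dropped, ids[mask]); reason <<- c(reason, rep(why, sum(mask)))
  }
  add(!coding, "not_protein_coding")
  add(coding & !expressed, "low_expression")
  add(coding & expressed & !autosomal, "blocklisted_chromosome")
  add(coding & expressed & autosomal & !has_probe, "no_cis_probes")
  list(keep = ids[keep],
       report = data.frame(gene_id = dropped, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Filter and impute methylation probes
#'
#' Probes missing in more than `max_missing` of the samples are removed;
#' remaining missing entries are imputed with the probe's median over
#' available samples (even counts: mean of the two central values).
#'
#' @param beta beta-value matrix (probes x samples) in `[0,1]` with `NA`s.
#' @param max_missing maximum tolerated missing fraction (exclusive bound:
#'   a probe missing in exactly this fraction is kept).
#' @return list with `beta` (complete matrix) and `report` (probe_id, reason
#'   for dropped probes).
#' @export
filter_impute_probes <- function(beta, max_missing = 0.10) {
  ok <- !is.na(beta)
  if (any(beta[ok] < 0 | beta[ok] > 1)) stop("beta values must lie in [0, 1]")
  frac <- rowMeans(!ok)
  drop <- frac > max_missing
  report <- data.frame(probe_id = rownames(beta)[drop],
                       reason = rep("missing_gt_threshold", sum(drop)),
                       stringsAsFactors = FALSE)
  beta <- beta[!drop, , drop = FALSE]
  nas <- which(is.na(beta), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    med <- apply(beta, 1, median, na.rm = TRUE)
    beta[nas] <- med[nas[, "row"]]
  }
  list(beta = beta, report = report)
}
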