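#' Min-max normalized coefficient importance for one gene
#'
#' Absolute refit coefficients of a gene's cis probes are min-max scaled
#' within the gene (zero coefficients take part in the min/max pool, so the
#' minimum is 0 whenever any probe was shrunk out), rounded to one decimal
#' (halves away from zero), and zero-coefficient probes are dropped after
#' scaling. A probe is `effective` when its raw coefficient is nonzero and
#' `important` when its normalized value rounds to 1.0; ties at the maximum
#' all count as important.
#'
#' @param fit a `gene_fit` (see [cross_validate()]).
#' @return data frame with one row per effective probe: `gene_id`,
#'   `probe_id`, `raw_coefficient`, `sign`, `normalized`, `effective`,
#'   `important`. Zero rows when every coefficient is zero.
#' @export
normalize_coefficients <- function(fit) {
  b <- fit$coefficients
  ab <- abs(b)
  mx <- max(ab); mn <- min(ab)
  if (mx == 0) {
    return(data.frame(gene_id = character(), probe_id = character(),
                      raw_coefficient = numeric(), sign = character(),
                      normalized = numeric(), effective = logical(),
                      important = logical(), stringsAsFactors = FALSE))
  }
  scaled <- if (mx > mn) (ab - mn) / (mx - mn) else rep(1, length(ab))
  nrm <- round_half_up(scaled, 1)
  keep <- ab > 0
  data.frame(gene_id = fit$gene_id, probe_id = names(b)[keep],
             raw_coefficient = unname(b[keep]),
             sign = ifelse(b[keep] < 0, "negative", "positive"),
             normalized = unname(nrm[keep]),
             effective = TRUE,
             important = unname(nrm[keep] == 1),
             stringsAsFactors = FALSE)
}

#' Importance records for a fitted gene set
#'
#' Applies [normalize_coefficients()] to every fit and joins the probe
#' annotations (signed TSS distance, CGI relation, gene component).
#'
#' @param fit_set a [fit_gene_set()] result.
#' @param pairs annotated (gene, probe) table from [annotate_probes()].
#' @return data frame of importance records, one row per effective probe per
#'   gene.
#' @export
importance_table <- function(fit_set, pairs) {
  recs <- do.call(rbind, lapply(fit_set$fits, normalize_coefficients))
  if (is.null(recs) || nrow(recs) == 0) {
    recs <- data.frame(gene_id = character(), probe_id = character(),
                       raw_coefficient = numeric(), sign = character(),
                       normalized = numeric(), effective = logical(),
                       important = logical(), stringsAsFactors = FALSE)
  }
  rownames(recs) <- NULL
  key <- paste(recs$gene_id, recs$probe_id)
  pkey <- paste(pairs$gene_id, pairs$probe_id)
  m <- match(key, pkey)
  recs$signed_distance <- pairs$signed_distance[m]
  recs$cgi_relation <- pairs$cgi_relation[m]
  recs$component <- pairs$component[m]
  recs
}

percent_summary <- function(eff, imp) {
  ifelse(eff > 0, 100 * imp / eff, NA_real_)
}

#' Percentage of important probes by distance from TSS
#'
#' Bins effective probes by signed TSS distance and, per bin and coefficient
#' sign, reports the percentage of important probes among effective ones.
#' Bins without effective probes are omitted (an empty bin has no defined
#' percentage).
#'
#' @param records importance records from [importance_table()].
#' @param bin_width bin width in bp.
#' @param range `c(lower, upper)` signed-distance range in bp.
#' @param by_sign split by coefficient sign (default) or pool both signs.
#' @return data frame with `bin_start`, `bin_mid`, `sign`, `n_effective`,
#'   `n_important`, `percent`.
#' @export
distance_profile <- function(records, bin_width = 1000, range = c(-1e6, 1e6),
                             by_sign = TRUE) {
  r <- records[records$signed_distance >= range[1] &
               records$signed_distance <= range[2], , drop = FALSE]
  bin <- floor((r$signed_distance - range[1]) / bin_width)
  grp <- if (by_sign) list(bin = bin, sign = r$sign) else list(bin = bin)
  agg <- aggregate(cbind(n_effective = r$effective,
                         n_important = r$important), by = grp, FUN = sum)
  agg$bin_start <- range[1] + agg$bin * bin_width
  agg$bin_mid <- agg$bin_start + bin_width / 2
  if (!by_sign) agg$sign <- "both"
  agg$percent <- percent_summary(agg$n_effective, agg$n_important)
  agg <- agg[agg$n_effective > 0, c("bin_start", "bin_mid", "sign",
                                    "n_effective", "n_important", "percent")]
  agg[order(agg$bin_start, agg$sign), , drop = FALSE]
}

#' Percentage of important probes by CGI relation or gene component
#'
#' @param records importance records from [importance_table()].
#' @param key grouping column: `"cgi_relation"` or `"component"`.
#' @param window optional signed-distance window filter, e.g.
#'   `c(-2000, 7000)`.
#' @param genes optional gene subset (e.g. genes with cross-validated
#'   R^2 above 0.3).
#' @param by_sign split by coefficient sign.
#' @return data frame with `category`, `sign`, `n_effective`, `n_important`,
#'   `percent`.
#' @export
region_profile <- function(records, key = c("cgi_relation", "component"),
                           window = NULL, genes = NULL, by_sign = TRUE) {
  key <- match.arg(key)
  valid <- list(cgi_relation = c("island", "shore", "shelf", "open_sea"),
                component = c("first_exon", "first_intron", "other_exon",
                              "other_intron", "intergenic"))[[key]]
  if (!all(records[[key]] %in% valid))
    stop("unknown ", key, " category: ",
         paste(setdiff(records[[key]], valid), collapse = ", "))
  r <- records
  if (!is.null(window)) {
    r <- r[r$signed_distance >= window[1] & r$signed_distance <= window[2], ,
           drop = FALSE]
  }
  if (!is.null(genes)) r <- r[r$gene_id %in% genes, , drop = FALSE]
  grp <- if (by_sign) list(category = r[[key]], sign = r$sign)
         else list(category = r[[key]])
  agg <- aggregate(cbind(n_effective = r$effective,
                         n_important = r$important), by = grp, FUN = sum)
  if (!by_sign) agg$sign <- "both"
  agg$percent <- percent_summary(agg$n_effective, agg$n_important)
  agg[order(agg$category, agg$sign),
      c("category", "sign", "n_effective", "n_important", "percent")]
}

#' Logistic regression of importance on CGI relation
#'
#' Models the probability that an effective probe is important as a function
#' of its CGI relation, with the open sea as the reference level, by pooled
#' probe-level maximum likelihood. Reports Wald p-values. Perfect separation
#' is flagged rather than an error.
#'
#' @param records importance records from [importance_table()].
#' @return data frame with `term`, `estimate`, `std_error`, `p_value` and a
#'   `separation` attribute (TRUE when the fit did not converge or blew up).
#' @export
region_logistic <- function(records) {
  rel <- factor(records$cgi_relation,
                levels = c("open_sea", "island", "shore", "shelf"))
  rel <- droplevels(rel)
  if (nlevels(rel) < 2) stop("need at least two CGI categories")
  y <- as.integer(records$important)
  if (length(unique(y)) < 2) stop("need both outcomes present")
  fit <- suppressWarnings(glm(y ~ rel, family = binomial()))
  sm <- summary(fit)$coefficients
  terms <- sub("^rel", "", rownames(sm))
  out <- data.frame(term = terms, estimate = sm[, "Estimate"],
                    std_error = sm[, "Std. Error"],
                    p_value = sm[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "separation") <- !fit$converged || any(abs(sm[, "Estimate"]) > 15)
  out
}
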