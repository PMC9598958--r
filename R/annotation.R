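#' Read gene models from a GTF file
#'
#' Parses gene/transcript/exon features via `rtracklayer` and converts the
#' 1-based inclusive GTF coordinates to the package's internal 0-based
#' half-open convention. Exons are returned in 5'-to-3' order within each
#' transcript.
#'
#' @param path GTF file.
#' @return list with `genes` (gene_id, chrom, strand, gene_type) and `exons`
#'   (gene_id, transcript_id, chrom, strand, start, end, exon_number).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  exons <- data.frame(
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  )
  # 5' order: ascending start on +, descending on -
  ord <- order(exons$gene_id, exons$transcript_id,
               ifelse(exons$strand == "+", 1, -1) * exons$start)
  exons <- exons[ord, , drop = FALSE]
  exons$exon_number <- stats::ave(seq_len(nrow(exons)),
                                  exons$transcript_id, FUN = seq_along)
  rownames(exons) <- NULL
  gtype <- if (!is.null(gr$gene_type)) gr$gene_type else rep(NA_character_, length(gr))
  gn <- gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = gn$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gn)),
    strand = as.character(GenomicRanges::strand(gn)),
    gene_type = if (!is.null(gn$gene_type)) gn$gene_type else NA_character_,
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons)
}

#' Read CpG-island intervals from a BED file
#'
#' @param path BED file (0-based half-open, as BED defines).
#' @return data frame with `chrom`, `start`, `end` in the internal 0-based
#'   half-open convention.
#' @export
read_cgi_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a probe manifest
#'
#' @param path tab-separated file with columns `probe_id`, `chrom`, `pos`.
#' @return data frame with those columns.
#' @export
read_probe_manifest <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(df)))
  df
}

#' Select the TSS of a gene
#'
#' The TSS is the strand-aware 5' start of the transcript with the largest
#' summed exon length. Ties go to the transcript with the more 5' start,
#' then to the lexicographically smaller transcript id.
#'
#' @param exons exon data frame of one gene (0-based half-open, with
#'   `transcript_id`, `strand`, `start`, `end`).
#' @param gene_id gene name used in error messages.
#' @return list with `tss` (0-based coordinate of the first transcribed
#'   base) and `transcript_id` of the selected transcript.
#' @export
select_tss <- function(exons, gene_id = "gene") {
  if (nrow(exons) == 0) stop("gene ", gene_id, " has no transcripts")
  strand <- exons$strand[1]
  sums <- tapply(exons$end - exons$start, exons$transcript_id, sum)
  starts <- if (strand == "+") {
    tapply(exons$start, exons$transcript_id, min)
  } else {
    -(tapply(exons$end, exons$transcript_id, max) - 1L)
  }
  tx <- names(sums)
  ord <- order(-sums, starts[tx], tx)
  win <- tx[ord[1]]
  list(tss = as.integer(abs(starts[[win]])), transcript_id = win)
}

#' Add TSS coordinates to a gene table
#'
#' Applies [select_tss()] to every gene.
#'
#' @param genes gene data frame (`gene_id` at minimum).
#' @param exons exon data frame covering the same genes.
#' @return `genes` with `tss` and `tss_transcript` columns appended.
#' @export
add_tss <- function(genes, exons) {
  ex_by_gene <- split(exons, exons$gene_id)
  sel <- lapply(genes$gene_id, function(g) {
    e <- ex_by_gene[[g]]
    if (is.null(e)) stop("gene ", g, " has no transcripts")
    select_tss(e, g)
  })
  genes$tss <- vapply(sel, `[[`, integer(1), "tss")
  genes$tss_transcript <- vapply(sel, `[[`, character(1), "transcript_id")
  genes
}

#' Collect cis probes for every gene
#'
#' Pairs each gene with every same-chromosome probe within `window_bp` of its
#' TSS (boundary inclusive). The signed distance is `pos - tss` on the plus
#' strand and is negated on the minus strand, so negative always means
#' upstream of the gene.
#'
#' @param genes gene data frame with `tss` (see [add_tss()]).
#' @param probes probe manifest (`probe_id`, `chrom`, `pos`).
#' @param window_bp window half-width in bp.
#' @return data frame with `gene_id`, `probe_id`, `signed_distance`. A probe
#'   may appear under several genes.
#' @export
collect_cis_probes <- function(genes, probes, window_bp = 1e6) {
  if (nrow(genes) == 0 || nrow(probes) == 0) {
    return(data.frame(gene_id = character(), probe_id = character(),
                      signed_distance = integer(), stringsAsFactors = FALSE))
  }
  lev <- union(unique(genes$chrom), unique(probes$chrom))
  win <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lev),
    IRanges::IRanges(start = genes$tss - window_bp + 1L,
                     end = genes$tss + window_bp + 1L)) # 1-based inclusive span
  pr <- GenomicRanges::GRanges(
    factor(probes$chrom, levels = lev),
    IRanges::IRanges(start = probes$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(win, pr)
  gi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  d <- probes$pos[pi] - genes$tss[gi]
  d <- ifelse(genes$strand[gi] == "-", -d, d)
  out <- data.frame(gene_id = genes$gene_id[gi], probe_id = probes$probe_id[pi],
                    signed_distance = as.integer(d), stringsAsFactors = FALSE)
  out[abs(out$signed_distance) <= window_bp, , drop = FALSE]
}

#' Annotate probes with their CpG-island relation
#'
#' A probe inside an island is `island`; otherwise its distance to the
#' nearest island edge (in bases, so an adjacent base is 1 bp away) puts it
#' in `shore` (1-2000), `shelf` (2001-4000) or `open_sea` (farther, or no
#' island on the chromosome).
#'
#' @param probes probe manifest (`probe_id`, `chrom`, `pos`).
#' @param cgi CpG-island intervals (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return character vector of categories, aligned with `probes` rows.
#' @export
annotate_cgi_relation <- function(probes, cgi) {
  out <- rep("open_sea", nrow(probes))
  if (nrow(cgi) == 0 || nrow(probes) == 0) return(out)
  lev <- union(unique(probes$chrom), unique(cgi$chrom))
  pr <- GenomicRanges::GRanges(factor(probes$chrom, levels = lev),
                               IRanges::IRanges(probes$pos + 1L, width = 1L))
  is <- GenomicRanges::GRanges(factor(cgi$chrom, levels = lev),
                               IRanges::IRanges(cgi$start + 1L, cgi$end))
  ov <- GenomicRanges::countOverlaps(pr, is) > 0
  out[ov] <- "island"
  nn <- GenomicRanges::distanceToNearest(pr, is)
  qi <- S4Vectors::queryHits(nn)
  # GRanges distance counts intervening bases; the edge-to-probe gap is one more
  gap <- S4Vectors::mcols(nn)$distance + 1L
  lab <- ifelse(gap <= 2000, "shore", ifelse(gap <= 4000, "shelf", "open_sea"))
  keep <- !ov[qi]
  out[qi[keep]] <- lab[keep]
  out
}

# component of one position against 5'-ordered exons of one transcript
component_of <- function(pos, ex_start, ex_end) {
  lo <- min(ex_start); hi <- max(ex_end)
  if (pos < lo || pos >= hi) return("intergenic")
  k <- length(ex_start)
  hit <- which(pos >= ex_start & pos < ex_end)
  if (length(hit)) return(if (hit[1] == 1) "first_exon" else "other_exon")
  for (j in seq_len(k - 1)) {
    glo <- min(ex_end[j], ex_end[j + 1])
    ghi <- max(ex_start[j], ex_start[j + 1])
    if (pos >= glo && pos < ghi)
      return(if (j == 1) "first_intron" else "other_intron")
  }
  "intergenic"
}

#' Annotate a probe position with its gene component
#'
#' Classification is against the TSS-selected transcript: the 5'-most exon
#' and intron are `first_exon` / `first_intron`, remaining exonic and
#' intronic bases are `other_exon` / `other_intron`, and positions outside
#' the transcript span are `intergenic`.
#'
#' @param pos probe position(s), 0-based.
#' @param exons exon data frame of the selected transcript, with
#'   `exon_number` in 5' order.
#' @return character vector of component labels.
#' @export
annotate_component <- function(pos, exons) {
  e <- exons[order(exons$exon_number), , drop = FALSE]
  vapply(pos, component_of, character(1), ex_start = e$start, ex_end = e$end)
}

#' Build the annotated cis-probe table
#'
#' Runs TSS selection, cis-probe collection, CGI-relation and gene-component
#' annotation over a whole genome.
#'
#' @param genes gene data frame (`gene_id`, `chrom`, `strand`).
#' @param exons exon data frame.
#' @param cgi CpG-island data frame.
#' @param probes probe manifest.
#' @param window_bp cis window half-width in bp.
#' @return list with `genes` (TSS added) and `pairs`: one row per (gene,
#'   probe) pairing with `signed_distance`, `cgi_relation` and `component`.
#' @export
annotate_probes <- function(genes, exons, cgi, probes, window_bp = 1e6) {
  genes <- add_tss(genes, exons)
  pairs <- collect_cis_probes(genes, probes, window_bp)
  pos <- probes$pos[match(pairs$probe_id, probes$probe_id)]
  rel <- annotate_cgi_relation(probes, cgi)
  pairs$cgi_relation <- rel[match(pairs$probe_id, probes$probe_id)]
  pairs$component <- rep(NA_character_, nrow(pairs))
  ex_by_tx <- split(exons, exons$transcript_id)
  for (g in unique(pairs$gene_id)) {
    sel <- pairs$gene_id == g
    tx <- genes$tss_transcript[genes$gene_id == g]
    pairs$component[sel] <- annotate_component(pos[sel], ex_by_tx[[tx]])
  }
  list(genes = genes, pairs = pairs)
}
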