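#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults describe a
#' tumor-cohort-sized study: 300 samples, 200 genes, a Poisson mean of 30
#' CpG probes per gene inside the megabase cis window, 30% of genes with a
#' planted methylation effect concentrated between 2 kb upstream and 7 kb
#' downstream of the TSS, and a subset of causal genes whose expression
#' shifts the hazard of death.
#'
#' Methylation beta values are drawn from a two-mode Beta mixture: most
#' probes have a per-probe mean (low- or high-methylation mode) fixed across
#' samples with Beta-distributed jitter, while causal probes vary from
#' patient to patient between the two modes, emulating regulatory CpGs whose
#' methylation state differs across tumors.
#'
#' @param n_samples number of samples (columns of both matrices).
#' @param n_genes number of genes.
#' @param probes_per_gene Poisson mean of the per-gene probe count (min 5).
#' @param window_bp cis window half-width around the TSS, in bp.
#' @param causal_fraction fraction of genes with planted methylation effects.
#' @param causal_probes_per_gene number of causal probes per causal gene.
#' @param effect_region signed bp interval relative to the TSS (negative =
#'   upstream) in which causal probes are placed.
#' @param negative_effect_prob probability a planted effect is negative.
#' @param effect_size_range absolute effect-size range (log2 expression units
#'   per unit beta).
#' @param noise_sd residual standard deviation of expression.
#' @param missing_rate per-entry missingness probability for beta values.
#' @param survival_linked_fraction fraction of causal genes whose expression
#'   shifts the hazard.
#' @param hazard_ratio multiplicative hazard per unit z-score of each
#'   survival-linked gene's expression.
#' @param censor_rate administrative censoring fraction.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @param chrom_bp optional fixed chromosome length in bp; by default
#'   chromosomes are sized to fit the genes and their windows.
#' @param genes_per_chrom genes placed per synthetic chromosome.
#' @return an object of class `cismeth_config` (a validated list).
#' @export
sim_config <- function(n_samples = 300,
                       n_genes = 200,
                       probes_per_gene = 30,
                       window_bp = 1e6,
                       causal_fraction = 0.3,
                       causal_probes_per_gene = 1,
                       effect_region = c(-2000, 7000),
                       negative_effect_prob = 0.8,
                       effect_size_range = c(1, 3),
                       noise_sd = 0.5,
                       missing_rate = 0.02,
                       survival_linked_fraction = 0.1,
                       hazard_ratio = 2,
                       censor_rate = 0.3,
                       seed = 1,
                       chrom_bp = NULL,
                       genes_per_chrom = 25) {
  cfg <- list(
    n_samples = n_samples, n_genes = n_genes,
    probes_per_gene = probes_per_gene, window_bp = window_bp,
    causal_fraction = causal_fraction,
    causal_probes_per_gene = causal_probes_per_gene,
    effect_region = effect_region,
    negative_effect_prob = negative_effect_prob,
    effect_size_range = effect_size_range, noise_sd = noise_sd,
    missing_rate = missing_rate,
    survival_linked_fraction = survival_linked_fraction,
    hazard_ratio = hazard_ratio, censor_rate = censor_rate,
    seed = seed, chrom_bp = chrom_bp, genes_per_chrom = genes_per_chrom
  )
  fracs <- c("causal_fraction", "negative_effect_prob", "missing_rate",
             "survival_linked_fraction", "censor_rate")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop(f, " must be a single value in [0, 1]")
  }
  if (n_samples < 0 || n_genes < 0) stop("counts must be non-negative")
  if (probes_per_gene <= 0 || genes_per_chrom <= 0) stop("counts must be positive")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (length(effect_region) != 2 || effect_region[1] >= effect_region[2])
    stop("effect_region must be an increasing interval")
  if (abs(effect_region[1]) > window_bp || abs(effect_region[2]) > window_bp)
    stop("effect_region must lie inside the cis window")
  if (length(effect_size_range) != 2 || any(effect_size_range <= 0) ||
      effect_size_range[1] > effect_size_range[2])
    stop("effect_size_range must be a positive increasing interval")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  # probes are placed up to window_bp from each TSS; the chromosome must
  # accommodate the full window on both sides of every gene
  spacing <- 2 * window_bp + 200000
  needed <- 2 * (window_bp + 100000) +
    (min(genes_per_chrom, max(n_genes, 1)) - 1) * spacing
  if (!is.null(chrom_bp) && chrom_bp < needed)
    stop("cis window (", window_bp, " bp) does not fit on a chromosome of ",
         chrom_bp, " bp; need at least ", needed, " bp")
  structure(cfg, class = "cismeth_config")
}

# maps a signed-distance interval [a, b) (5'->3' along the gene) to a
# 0-based half-open genomic interval
signed_to_genomic <- function(tss, strand, a, b) {
  if (strand == "+") c(tss + a, tss + b) else c(tss - b + 1, tss - a + 1)
}

# truth-side CGI labelling: direct scan over all islands of the chromosome,
# deliberately independent of annotate_cgi_relation()
truth_cgi <- function(pos, cgi) {
  if (nrow(cgi) == 0) return("open_sea")
  inside <- pos >= cgi$start & pos < cgi$end
  if (any(inside)) return("island")
  gap <- min(ifelse(pos < cgi$start, cgi$start - pos, pos - (cgi$end - 1)))
  if (gap <= 2000) "shore" else if (gap <= 4000) "shelf" else "open_sea"
}

# truth-side component labelling against the 5'-ordered exons of one
# transcript (starts/ends 0-based half-open, already in 5'->3' order)
truth_component <- function(pos, ex_start, ex_end) {
  span <- range(c(ex_start, ex_end))
  if (pos < span[1] || pos >= span[2]) return("intergenic")
  k <- length(ex_start)
  for (j in seq_len(k)) {
    if (pos >= ex_start[j] && pos < ex_end[j])
      return(if (j == 1) "first_exon" else "other_exon")
  }
  for (j in seq_len(k - 1)) {
    # genomic gap between 5' exon j and exon j+1 (either strand order)
    lo <- min(ex_end[j], ex_end[j + 1])
    hi <- max(ex_start[j], ex_start[j + 1])
    if (pos >= lo && pos < hi)
      return(if (j == 1) "first_intron" else "other_intron")
  }
  "intergenic" # unreachable for well-formed transcripts
}

#' Simulate gene models, CpG islands and a probe manifest
#'
#' Genes are placed on synthetic chromosomes far enough apart that their cis
#' windows do not overlap; each has a multi-exon transcript on a random
#' strand (and often a shorter second transcript, so TSS selection is
#' exercised). CpG islands are placed at promoters and at distal positions so
#' island, shore, shelf and open-sea probes all occur. Probe positions are
#' drawn around the TSS with density decaying with distance; causal genes get
#' their causal probes placed inside `effect_region`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cismeth_genome`: a list with data frames
#'   `genes` (gene_id, chrom, strand, gene_type, length, base_expr),
#'   `exons` (0-based half-open, 5'-ordered with `exon_number`),
#'   `cgi`, `probes` (probe_id, chrom, pos), and `truth`
#'   (per-gene causal/survival flags, planted effects, per-probe true
#'   distance, CGI relation and component). All coordinates are 0-based
#'   half-open.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "cismeth_config"))
  set.seed(derive_seed(config$seed, "genome"))
  ng <- config$n_genes
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (ng == 0) {
    g <- list(
      genes = empty(gene_id = character(), chrom = character(),
                    strand = character(), gene_type = character(),
                    length = integer(), base_expr = numeric()),
      exons = empty(gene_id = character(), transcript_id = character(),
                    chrom = character(), strand = character(),
                    start = integer(), end = integer(), exon_number = integer()),
      cgi = empty(chrom = character(), start = integer(), end = integer()),
      probes = empty(probe_id = character(), chrom = character(), pos = integer()),
      truth = list(
        genes = empty(gene_id = character(), causal = logical(),
                      survival_linked = logical(), base_expr = numeric()),
        effects = empty(gene_id = character(), probe_id = character(),
                        effect = numeric(), distance = integer()),
        probes = empty(probe_id = character(), gene_id = character(),
                       true_distance = integer(), true_cgi_relation = character(),
                       true_component = character())
      ),
      config = config
    )
    class(g) <- "cismeth_genome"
    return(g)
  }

  spacing <- 2 * config$window_bp + 200000
  gpc <- config$genes_per_chrom
  chrom_idx <- ((seq_len(ng) - 1) %/% gpc) + 1
  pos_idx <- ((seq_len(ng) - 1) %% gpc)
  anchor <- config$window_bp + 100000 + pos_idx * spacing

  gene_id <- sprintf("G%04d", seq_len(ng))
  chrom <- sprintf("chrS%d", chrom_idx)
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  n_causal <- ceiling(config$causal_fraction * ng)
  causal_ids <- if (n_causal > 0) sample(gene_id, n_causal) else character()
  n_linked <- ceiling(config$survival_linked_fraction * n_causal)
  linked_ids <- if (n_linked > 0) sample(causal_ids, n_linked) else character()

  exons_l <- vector("list", ng)
  cgi_l <- list()
  probes_l <- vector("list", ng)
  tprobes_l <- vector("list", ng)
  effects_l <- vector("list", ng)
  glen <- integer(ng)
  base_expr <- runif(ng, 6, 10)

  pid0 <- 0L
  for (i in seq_len(ng)) {
    tss <- anchor[i]; st <- strand[i]
    k <- sample(3:6, 1)
    elen <- sample(120:400, k, replace = TRUE)
    ilen <- sample(400:2500, k - 1, replace = TRUE)
    glen[i] <- sum(elen)
    # 5'-ordered signed offsets of exon starts
    off <- cumsum(c(0, head(elen, -1) + ilen))
    ex <- t(vapply(seq_len(k), function(j)
      signed_to_genomic(tss, st, off[j], off[j] + elen[j]), numeric(2)))
    tx1 <- sprintf("%s.t1", gene_id[i])
    exdf <- data.frame(gene_id = gene_id[i], transcript_id = tx1,
                       chrom = chrom[i], strand = st,
                       start = as.integer(ex[, 1]), end = as.integer(ex[, 2]),
                       exon_number = seq_len(k), stringsAsFactors = FALSE)
    if (k >= 3 && runif(1) < 0.6) { # shorter isoform: exons 2..k
      tx2 <- sprintf("%s.t2", gene_id[i])
      exdf2 <- exdf[-1, ]
      exdf2$transcript_id <- tx2
      exdf2$exon_number <- seq_len(k - 1)
      exdf <- rbind(exdf, exdf2)
    }
    exons_l[[i]] <- exdf

    # CpG islands: promoter, distal downstream, distal upstream
    isl <- list()
    if (runif(1) < 0.6) isl <- c(isl, list(signed_to_genomic(tss, st, -500, 800)))
    if (runif(1) < 0.5) isl <- c(isl, list(signed_to_genomic(tss, st, 19600, 20400)))
    if (runif(1) < 0.3) isl <- c(isl, list(signed_to_genomic(tss, st, -30500, -29800)))
    if (length(isl)) {
      im <- do.call(rbind, isl)
      cgi_l[[length(cgi_l) + 1]] <- data.frame(
        chrom = chrom[i], start = as.integer(im[, 1]), end = as.integer(im[, 2]),
        stringsAsFactors = FALSE)
    }

    # probe distances: causal probes forced into the effect region, two
    # promoter-region probes for every gene (arrays are promoter-dense),
    # the rest decaying around the TSS with a uniform far tail
    is_causal <- gene_id[i] %in% causal_ids
    m <- max(5L, rpois(1, config$probes_per_gene))
    n_forced <- if (is_causal) config$causal_probes_per_gene else 0L
    m <- max(m, n_forced + 2L)
    d_causal <- if (n_forced > 0)
      as.integer(round(runif(n_forced, config$effect_region[1], config$effect_region[2])))
    else integer()
    d_prom <- as.integer(round(runif(2, config$effect_region[1], config$effect_region[2])))
    n_rest <- m - n_forced - 2L
    n_near <- floor(0.6 * n_rest)
    d_near <- as.integer(round(rnorm(n_near, 0, 8000)))
    d_far <- as.integer(round(runif(n_rest - n_near, -config$window_bp, config$window_bp)))
    d <- c(d_causal, d_prom, pmax(pmin(c(d_near, d_far), config$window_bp), -config$window_bp))
    pos <- if (st == "+") tss + d else tss - d
    probe_id <- sprintf("cg%08d", pid0 + seq_along(d))
    pid0 <- pid0 + length(d)
    probes_l[[i]] <- data.frame(probe_id = probe_id, chrom = chrom[i],
                                pos = as.integer(pos), stringsAsFactors = FALSE)
    tprobes_l[[i]] <- data.frame(probe_id = probe_id, gene_id = gene_id[i],
                                 true_distance = d, stringsAsFactors = FALSE)
    if (n_forced > 0) {
      mag <- runif(n_forced, config$effect_size_range[1], config$effect_size_range[2])
      sgn <- ifelse(runif(n_forced) < config$negative_effect_prob, -1, 1)
      effects_l[[i]] <- data.frame(gene_id = gene_id[i],
                                   probe_id = probe_id[seq_len(n_forced)],
                                   effect = sgn * mag, distance = d_causal,
                                   stringsAsFactors = FALSE)
    }
  }

  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      gene_type = "protein_coding", length = glen,
                      base_expr = base_expr, stringsAsFactors = FALSE)
  exons <- do.call(rbind, exons_l)
  cgi <- if (length(cgi_l)) do.call(rbind, cgi_l) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  cgi <- cgi[order(cgi$chrom, cgi$start), , drop = FALSE]
  rownames(cgi) <- NULL
  probes <- do.call(rbind, probes_l)
  tprobes <- do.call(rbind, tprobes_l)

  # truth annotations via the direct per-probe scans above
  tprobes$true_cgi_relation <- vapply(seq_len(nrow(tprobes)), function(r) {
    ch <- probes$chrom[r]
    truth_cgi(probes$pos[r], cgi[cgi$chrom == ch, , drop = FALSE])
  }, character(1))
  tx1 <- exons[grepl("\\.t1$", exons$transcript_id), , drop = FALSE]
  tx1_by_gene <- split(tx1, tx1$gene_id)
  tprobes$true_component <- vapply(seq_len(nrow(tprobes)), function(r) {
    e <- tx1_by_gene[[tprobes$gene_id[r]]]
    e <- e[order(e$exon_number), ]
    truth_component(probes$pos[r], e$start, e$end)
  }, character(1))

  truth <- list(
    genes = data.frame(gene_id = gene_id, causal = gene_id %in% causal_ids,
                       survival_linked = gene_id %in% linked_ids,
                       base_expr = base_expr, stringsAsFactors = FALSE),
    effects = if (length(effects_l)) do.call(rbind, effects_l) else
      data.frame(gene_id = character(), probe_id = character(),
                 effect = numeric(), distance = integer(),
                 stringsAsFactors = FALSE),
    probes = tprobes
  )
  rownames(truth$effects) <- NULL

  g <- list(genes = genes, exons = exons, cgi = cgi, probes = probes,
            truth = truth, config = config)
  class(g) <- "cismeth_genome"
  g
}

#' Simulate methylation beta values and expression
#'
#' Beta values are bimodal in `[0,1]`: ordinary probes keep a fixed per-probe
#' mean with Beta jitter across samples, causal probes switch between low and
#' high methylation modes from sample to sample. Expression of a causal gene
#' is its baseline plus the planted linear combination of its causal probes'
#' beta values plus Gaussian noise; other genes are independent of
#' methylation. Missing beta entries are then inserted at `missing_rate`
#' (expression is computed from the complete values).
#'
#' @param genome a [simulate_genome()] result.
#' @param config the same [sim_config()] object.
#' @return list with `beta` (probes x samples, may contain `NA`) and
#'   `expr` (genes x samples, log2 expression scale).
#' @export
simulate_methylation_expression <- function(genome, config) {
  stopifnot(inherits(genome, "cismeth_genome"))
  set.seed(derive_seed(config$seed, "meth"))
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  np <- nrow(genome$probes)
  causal_probes <- unique(genome$truth$effects$probe_id)

  beta <- matrix(NA_real_, np, n, dimnames = list(genome$probes$probe_id, samples))
  if (np > 0 && n > 0) {
    mu <- ifelse(runif(np) < 0.5, rbeta(np, 2, 8), rbeta(np, 8, 2))
    for (r in seq_len(np)) {
      if (genome$probes$probe_id[r] %in% causal_probes) {
        hi <- runif(n) < 0.5 # patient-variable regulatory CpG
        beta[r, ] <- ifelse(hi, rbeta(n, 10, 2), rbeta(n, 2, 10))
      } else {
        beta[r, ] <- rbeta(n, 6 * mu[r], 6 * (1 - mu[r]))
      }
    }
  }

  ng <- nrow(genome$genes)
  expr <- matrix(0, ng, n, dimnames = list(genome$genes$gene_id, samples))
  eff <- genome$truth$effects
  for (i in seq_len(ng)) {
    gid <- genome$genes$gene_id[i]
    y <- rep(genome$genes$base_expr[i], n)
    ge <- eff[eff$gene_id == gid, , drop = FALSE]
    if (nrow(ge) > 0)
      y <- y + as.numeric(crossprod(beta[ge$probe_id, , drop = FALSE], ge$effect))
    expr[i, ] <- y + rnorm(n, 0, config$noise_sd)
  }

  if (config$missing_rate > 0 && np > 0 && n > 0) {
    miss <- matrix(runif(np * n) < config$missing_rate, np, n)
    beta[miss] <- NA_real_
  }
  list(beta = beta, expr = expr)
}

#' Simulate survival records
#'
#' Event times are exponential with log-hazard equal to
#' `log(hazard_ratio)` times the z-scored expression of each survival-linked
#' gene, summed over linked genes. Administrative censoring truncates the
#' longest `censor_rate` fraction of follow-up.
#'
#' @param expr expression matrix (genes x samples).
#' @param genome a [simulate_genome()] result (for the linked-gene truth).
#' @param config the same [sim_config()] object.
#' @return data frame with columns `sample`, `time` (> 0), `event` (0/1).
#' @export
simulate_survival <- function(expr, genome, config) {
  set.seed(derive_seed(config$seed, "surv"))
  n <- ncol(expr)
  if (n == 0) {
    return(data.frame(sample = character(), time = numeric(),
                      event = integer(), stringsAsFactors = FALSE))
  }
  linked <- genome$truth$genes$gene_id[genome$truth$genes$survival_linked]
  linked <- intersect(linked, rownames(expr))
  eta <- rep(0, n)
  if (length(linked) > 0 && config$hazard_ratio != 1) {
    z <- t(apply(expr[linked, , drop = FALSE], 1, function(v) (v - mean(v)) / sd(v)))
    eta <- log(config$hazard_ratio) * colSums(z)
  }
  h0 <- log(2) / 36 # baseline median time 36 (arbitrary time units)
  time <- rexp(n) / (h0 * exp(eta))
  if (config$censor_rate > 0) {
    cq <- quantile(time, probs = 1 - config$censor_rate, names = FALSE)
    event <- as.integer(time <= cq)
    time <- pmin(time, cq)
  } else {
    event <- rep(1L, n)
  }
  data.frame(sample = colnames(expr), time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a complete study
#'
#' Runs [simulate_genome()], [simulate_methylation_expression()] and
#' [simulate_survival()] under a single seed.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cismeth_sim`: list with `genome`, `beta`,
#'   `expr`, `clinical`, `truth` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  me <- simulate_methylation_expression(genome, config)
  clinical <- simulate_survival(me$expr, genome, config)
  out <- list(genome = genome, beta = me$beta, expr = me$expr,
              clinical = clinical, truth = genome$truth, config = config)
  class(out) <- "cismeth_sim"
  out
}

#' Write a simulated study to disk
#'
#' Emits `genes.gtf`, `cgi.bed`, `probes.tsv`, `beta.tsv`, `expression.tsv`,
#' `clinical.tsv`, `gene_lengths.tsv` and `truth.json`. GTF is written
#' 1-based inclusive, BED 0-based half-open, matching the conventions of
#' those formats.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cismeth_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(sim$genome, file.path(dir, "genes.gtf"))
  cgi <- sim$genome$cgi
  bed <- data.frame(cgi$chrom, cgi$start, cgi$end)
  write.table(bed, file.path(dir, "cgi.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv(sim$genome$probes, file.path(dir, "probes.tsv"))
  write_matrix_tsv(sim$beta, file.path(dir, "beta.tsv"), "probe_id")
  write_matrix_tsv(sim$expr, file.path(dir, "expression.tsv"), "gene_id")
  write_tsv(sim$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(sim$genome$genes[, c("gene_id", "length")],
            file.path(dir, "gene_lengths.tsv"))
  jsonlite::write_json(
    list(genes = sim$truth$genes, effects = sim$truth$effects,
         probes = sim$truth$probes),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA)
  invisible(dir)
}

# GTF emitter: gene, transcript and exon features with gene_id,
# transcript_id and gene_type attributes (1-based inclusive coordinates)
write_gtf <- function(genome, path) {
  ex <- genome$exons
  lines <- character(0)
  for (gid in genome$genes$gene_id) {
    ge <- ex[ex$gene_id == gid, , drop = FALSE]
    gi <- genome$genes[genome$genes$gene_id == gid, ]
    attr_g <- sprintf('gene_id "%s"; gene_type "%s";', gid, gi$gene_type)
    lines <- c(lines, paste(gi$chrom, "sim", "gene", min(ge$start) + 1,
                            max(ge$end), ".", gi$strand, ".", attr_g, sep = "\t"))
    for (tx in unique(ge$transcript_id)) {
      te <- ge[ge$transcript_id == tx, , drop = FALSE]
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
                        gid, tx, gi$gene_type)
      lines <- c(lines, paste(gi$chrom, "sim", "transcript", min(te$start) + 1,
                              max(te$end), ".", gi$strand, ".", attr_t, sep = "\t"))
      for (r in seq_len(nrow(te))) {
        lines <- c(lines, paste(gi$chrom, "sim", "exon", te$start[r] + 1,
                                te$end[r], ".", gi$strand, ".", attr_t, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
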