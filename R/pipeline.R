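#' Compare full-window and restricted-window fits
#'
#' Pairs per-gene cross-validated metrics from two fits of the same genes
#' (typically the full megabase window against the promoter-proximal
#' 2 kb-upstream/7 kb-downstream window) and reports the Pearson correlation
#' of each metric across genes.
#'
#' @param full metrics data frame of the full-window fit (from
#'   [fit_gene_set()]).
#' @param restricted metrics data frame of the restricted-window fit.
#' @return list with `paired` (per-gene metrics side by side) and
#'   `correlations` (metric, pearson_r, p_value).
#' @export
compare_windows <- function(full, restricted) {
  shared <- intersect(full$gene_id, restricted$gene_id)
  if (length(shared) < 3)
    stop("need at least 3 shared genes to correlate metrics")
  f <- full[match(shared, full$gene_id), ]
  r <- restricted[match(shared, restricted$gene_id), ]
  mets <- c("mse", "rmse", "mae", "r2")
  paired <- data.frame(gene_id = shared, stringsAsFactors = FALSE)
  for (m in mets) {
    paired[[paste0(m, "_full")]] <- f[[m]]
    paired[[paste0(m, "_restricted")]] <- r[[m]]
  }
  cors <- do.call(rbind, lapply(mets, function(m) {
    ct <- cor.test(f[[m]], r[[m]], method = "pearson")
    data.frame(metric = m, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  }))
  list(paired = paired, correlations = cors)
}

read_study_inputs <- function(input_dir) {
  gm <- read_gene_models(file.path(input_dir, "genes.gtf"))
  lengths <- read_tsv(file.path(input_dir, "gene_lengths.tsv"))
  gm$genes$length <- lengths$length[match(gm$genes$gene_id, lengths$gene_id)]
  list(
    genes = gm$genes, exons = gm$exons,
    cgi = read_cgi_bed(file.path(input_dir, "cgi.bed")),
    probes = read_probe_manifest(file.path(input_dir, "probes.tsv")),
    beta = read_matrix_tsv(file.path(input_dir, "beta.tsv")),
    expr = read_matrix_tsv(file.path(input_dir, "expression.tsv")),
    clinical = read_tsv(file.path(input_dir, "clinical.tsv"))
  )
}

#' Run the full analysis pipeline
#'
#' Annotates probes, preprocesses both matrices, fits the per-gene penalized
#' regressions on the full cis window and on the restricted
#' promoter-proximal window, scores probe importance, scans survival, calls
#' MASA genes and tests the methylation-by-survival association. Every
#' intermediate table is written to `out_dir` together with a manifest
#' recording the configuration, input checksums and package version.
#'
#' @param sim a [simulate_dataset()] result, or `NULL` when reading from
#'   `input_dir`.
#' @param input_dir directory holding `genes.gtf`, `cgi.bed`, `probes.tsv`,
#'   `beta.tsv`, `expression.tsv`, `clinical.tsv`, `gene_lengths.tsv`
#'   (see [write_simulation()]); ignored when `sim` is given.
#' @param out_dir output directory (created).
#' @param window_bp cis window half-width in bp.
#' @param restricted_window signed-distance window of the restricted refit.
#' @param alpha_grid mixing weights; the default fixes a global elastic net
#'   at `alpha = 0.1`, `seq(0, 1, 0.1)` selects alpha per gene.
#' @param n_folds cross-validation folds.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @param r2_threshold R^2 threshold for methylation-affected genes.
#' @param p_threshold log-rank p threshold for survival-associated genes.
#' @param max_missing probe missingness bound for [filter_impute_probes()].
#' @param expression_scale `"log2tpm"` when the expression matrix is already
#'   log2(TPM+1); `"counts"` to apply [counts_to_logtpm()] first.
#' @param blocklist chromosomes whose genes are excluded.
#' @param min_prop minimum group proportion for the survival cutpoint scan.
#' @return (invisibly) list with all stage results: `annotation`, `beta`,
#'   `expr`, `filter_report`, `fit_full`, `fit_restricted`, `records`,
#'   `profiles`, `logistic`, `survival`, `masa`, `association`,
#'   `window_comparison`, `manifest`.
#' @export
run_pipeline <- function(sim = NULL, input_dir = NULL, out_dir,
                         window_bp = 1e6, restricted_window = c(-2000, 7000),
                         alpha_grid = 0.1, n_folds = 5, seed = 1,
                         r2_threshold = 0.3, p_threshold = 0.05,
                         max_missing = 0.10,
                         expression_scale = c("log2tpm", "counts"),
                         blocklist = c("chrX", "chrY", "X", "Y"),
                         min_prop = 0.1) {
  expression_scale <- match.arg(expression_scale)
  stage <- "inputs"
  res <- tryCatch({
    inputs <- if (!is.null(sim)) {
      stopifnot(inherits(sim, "cismeth_sim"))
      list(genes = sim$genome$genes, exons = sim$genome$exons,
           cgi = sim$genome$cgi, probes = sim$genome$probes,
           beta = sim$beta, expr = sim$expr, clinical = sim$clinical)
    } else {
      read_study_inputs(input_dir)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

    stage <- "annotate"
    ann <- annotate_probes(inputs$genes, inputs$exons, inputs$cgi,
                           inputs$probes, window_bp)

    stage <- "preprocess"
    expr <- inputs$expr
    if (expression_scale == "counts")
      expr <- counts_to_logtpm(expr, inputs$genes$length[
        match(rownames(expr), inputs$genes$gene_id)])
    pf <- filter_impute_probes(inputs$beta, max_missing)
    pairs <- ann$pairs[ann$pairs$probe_id %in% rownames(pf$beta), ,
                       drop = FALSE]
    cis_counts <- table(pairs$gene_id)
    gf <- filter_genes(expr, inputs$genes,
                       setNames(as.integer(cis_counts), names(cis_counts)),
                       blocklist = blocklist)
    expr <- expr[gf$keep, , drop = FALSE]
    pairs <- pairs[pairs$gene_id %in% gf$keep, , drop = FALSE]
    common <- intersect(colnames(pf$beta), colnames(expr))
    beta <- pf$beta[, common, drop = FALSE]
    expr <- expr[, common, drop = FALSE]

    stage <- "fit"
    fit_full <- fit_gene_set(beta, expr, pairs, alpha_grid = alpha_grid,
                             n_folds = n_folds, seed = seed)
    fit_restr <- fit_gene_set(beta, expr, pairs, alpha_grid = alpha_grid,
                              n_folds = n_folds, seed = seed,
                              window = restricted_window)

    stage <- "importance"
    records <- importance_table(fit_full, pairs)
    affected <- fit_full$metrics$gene_id[
      !is.na(fit_full$metrics$r2) & fit_full$metrics$r2 > r2_threshold]
    profiles <- list(
      distance_full = distance_profile(records, 1000, c(-window_bp, window_bp)),
      distance_zoom = distance_profile(records, 1000, c(-25000, 25000)),
      cgi = region_profile(records, "cgi_relation"),
      cgi_window = region_profile(records, "cgi_relation",
                                  window = restricted_window),
      component = region_profile(records, "component"),
      cgi_high_r2 = if (length(affected) >= 1)
        region_profile(records, "cgi_relation", genes = affected) else NULL
    )
    logistic <- if (sum(records$important) > 0 &&
                    sum(!records$important) > 0 &&
                    length(unique(records$cgi_relation)) >= 2)
      region_logistic(records) else NULL

    stage <- "survival"
    surv <- survival_scan(expr, inputs$clinical, min_prop = min_prop)

    stage <- "masa"
    masa <- call_masa(fit_full$metrics, surv, r2_threshold, p_threshold)
    assoc <- if (all(rowSums(association_table(masa)) > 0) &&
                 all(colSums(association_table(masa)) > 0))
      association_test(masa) else NULL

    stage <- "compare"
    cmp <- if (length(intersect(fit_full$metrics$gene_id,
                                fit_restr$metrics$gene_id)) >= 3)
      compare_windows(fit_full$metrics, fit_restr$metrics) else NULL

    list(annotation = ann, beta = beta, expr = expr,
         filter_report = list(genes = gf$report, probes = pf$report),
         fit_full = fit_full, fit_restricted = fit_restr,
         records = records, profiles = profiles, logistic = logistic,
         survival = surv, masa = masa, association = assoc,
         window_comparison = cmp)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  write_pipeline_outputs(res, out_dir,
                         config = list(window_bp = window_bp,
                                       restricted_window = restricted_window,
                                       alpha_grid = alpha_grid,
                                       n_folds = n_folds, seed = seed,
                                       r2_threshold = r2_threshold,
                                       p_threshold = p_threshold,
                                       max_missing = max_missing,
                                       expression_scale = expression_scale,
                                       min_prop = min_prop),
                         input_dir = input_dir)
  invisible(res)
}

association_table <- function(masa) {
  t(vapply(c(TRUE, FALSE), function(a)
    vapply(c(TRUE, FALSE), function(s)
      sum(masa$methylation_affected == a & masa$survival_associated == s),
      numeric(1)), numeric(2)))
}

write_pipeline_outputs <- function(res, out_dir, config, input_dir = NULL) {
  write_tsv(res$annotation$pairs, file.path(out_dir, "annotated_probes.tsv"))
  write_tsv(res$fit_full$metrics, file.path(out_dir, "metrics_full.tsv"))
  write_tsv(res$fit_restricted$metrics,
            file.path(out_dir, "metrics_restricted.tsv"))
  write_tsv(res$fit_full$coefficients,
            file.path(out_dir, "coefficients_full.tsv"))
  write_tsv(res$records, file.path(out_dir, "importance_records.tsv"))
  for (nm in names(res$profiles)) {
    if (!is.null(res$profiles[[nm]]))
      write_tsv(res$profiles[[nm]],
                file.path(out_dir, paste0("profile_", nm, ".tsv")))
  }
  if (!is.null(res$logistic))
    write_tsv(res$logistic, file.path(out_dir, "cgi_logistic.tsv"))
  write_tsv(res$survival, file.path(out_dir, "survival_scan.tsv"))
  write_tsv(res$masa, file.path(out_dir, "masa.tsv"))
  if (!is.null(res$association)) {
    a <- res$association
    jsonlite::write_json(list(chi2 = a$chi2, p = a$p, or = a$or,
                              ci_low = a$ci_low, ci_high = a$ci_high,
                              haldane = a$haldane),
                         file.path(out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$window_comparison)) {
    write_tsv(res$window_comparison$paired,
              file.path(out_dir, "window_paired_metrics.tsv"))
    write_tsv(res$window_comparison$correlations,
              file.path(out_dir, "window_correlations.tsv"))
  }
  checksums <- if (!is.null(input_dir)) {
    fl <- list.files(input_dir, full.names = TRUE)
    as.list(tools::md5sum(fl))
  } else NULL
  summary <- list(
    n_genes_fit = nrow(res$fit_full$metrics),
    n_genes_dropped = nrow(res$filter_report$genes),
    n_probes_dropped = nrow(res$filter_report$probes),
    median_cv_r2 = median(res$fit_full$metrics$r2),
    n_methylation_affected = sum(res$masa$methylation_affected),
    n_survival_associated = sum(res$masa$survival_associated),
    n_masa = sum(res$masa$masa)
  )
  manifest <- list(config = config, input_checksums = checksums,
                   package_version = as.character(packageVersion("cismeth")),
                   r_version = R.version.string, summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
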