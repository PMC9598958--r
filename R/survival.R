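#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test: at every distinct event time the
#' observed events in one group are compared with their hypergeometric
#' expectation given the risk sets, tied event times pooled into one risk-set
#' evaluation. The chi-square statistic is `U^2 / V` with one degree of
#' freedom, where `U` is the summed observed-minus-expected and `V` the
#' summed hypergeometric variance.
#'
#' @param group logical or 0/1 vector of group membership.
#' @param time survival or censoring times (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @return list with `U`, `V`, `statistic` (chi-square), `z`
#'   (`U/sqrt(V)`, the standardized statistic) and `p`.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.logical(group)
  if (length(unique(group)) < 2) stop("both groups must be non-empty")
  stopifnot(length(time) == length(group), length(event) == length(group),
            all(time > 0), all(event %in% c(0, 1)))
  ev_times <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in ev_times) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    U <- U + (d1 - d * n1 / n)
    if (n > 1) V <- V + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  if (V == 0) {
    warning("no usable events; log-rank p set to 1")
    return(list(U = U, V = 0, statistic = 0, z = 0, p = 1))
  }
  chi <- U^2 / V
  list(U = U, V = V, statistic = chi, z = U / sqrt(V),
       p = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Expression cutoff by maximally selected log-rank statistics
#'
#' Evaluates the standardized log-rank statistic at every candidate cutpoint
#' (midpoints between sorted unique expression values) whose low/high split
#' leaves at least `min_prop` of the samples on each side, and returns the
#' cutpoint maximizing the absolute standardized statistic. The scan is
#' exhaustive by construction. No multiplicity correction is applied to the
#' p-value at the selected cutpoint, which is therefore anti-conservative;
#' see the package vignette.
#'
#' @param expr expression values, one per sample.
#' @param time survival or censoring times.
#' @param event event indicators.
#' @param min_prop minimum fraction of samples per group (default 10%).
#' @param min_events minimum number of events required (default 20).
#' @return list with `cutoff`, `statistic` (the maximal `|z|`), `logrank`
#'   (the [logrank_test()] at the selected cutoff) and `scan` (data frame of
#'   every evaluated cutpoint and its `|z|`).
#' @export
maxstat_cutoff <- function(expr, time, event, min_prop = 0.1,
                           min_events = 20) {
  n <- length(expr)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event) < min_events)
    stop("need at least ", min_events, " events for cutpoint selection")
  u <- sort(unique(expr))
  if (length(u) < 2) stop("expression is constant; no cutpoint exists")
  cand <- (u[-1] + u[-length(u)]) / 2
  lo <- vapply(cand, function(c) sum(expr <= c), integer(1))
  m <- ceiling(min_prop * n)
  ok <- lo >= m & (n - lo) >= m
  if (!any(ok)) stop("no cutpoint keeps ", min_prop, " of samples per group")
  cand <- cand[ok]
  z <- vapply(cand, function(c) {
    abs(logrank_test(expr > c, time, event)$z)
  }, numeric(1))
  best <- which.max(z)
  list(cutoff = cand[best], statistic = z[best],
       logrank = logrank_test(expr > cand[best], time, event),
       scan = data.frame(cutpoint = cand, abs_z = z))
}

#' Survival scan over genes
#'
#' For every gene, picks the maximally selected expression cutoff and tests
#' the low/high split with the log-rank test. A Benjamini-Hochberg adjusted
#' p-value column is emitted for reference; the MASA definition itself uses
#' the raw p-values.
#'
#' @param expr expression matrix (genes x samples).
#' @param clinical data frame with `sample`, `time`, `event`.
#' @param min_prop minimum group proportion for the cutpoint scan.
#' @return data frame with `gene_id`, `cutoff`, `statistic`, `logrank_p`,
#'   `logrank_p_bh`.
#' @export
survival_scan <- function(expr, clinical, min_prop = 0.1) {
  idx <- match(colnames(expr), clinical$sample)
  if (anyNA(idx)) stop("clinical records missing for some samples")
  time <- clinical$time[idx]; event <- clinical$event[idx]
  rows <- lapply(rownames(expr), function(g) {
    ms <- maxstat_cutoff(expr[g, ], time, event, min_prop = min_prop)
    data.frame(gene_id = g, cutoff = ms$cutoff, statistic = ms$statistic,
               logrank_p = ms$logrank$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$logrank_p_bh <- stats::p.adjust(out$logrank_p, method = "BH")
  out
}

#' Call methylation-affected, survival-associated (MASA) genes
#'
#' A gene is methylation-affected when its cross-validated R^2 is strictly
#' above `r2_threshold` and survival-associated when its log-rank p-value is
#' at or below `p_threshold`; MASA genes are the intersection.
#'
#' @param metrics per-gene metrics (needs `gene_id`, `r2`), e.g. from
#'   [fit_gene_set()].
#' @param surv per-gene survival results from [survival_scan()].
#' @param r2_threshold R^2 threshold (strict inequality).
#' @param p_threshold log-rank p threshold (inclusive).
#' @return data frame with `gene_id`, `r2`, `cutoff`, `logrank_p`,
#'   `methylation_affected`, `survival_associated`, `masa`; genes present in
#'   only one input are excluded and listed in the `excluded` attribute.
#' @export
call_masa <- function(metrics, surv, r2_threshold = 0.3, p_threshold = 0.05) {
  shared <- intersect(metrics$gene_id, surv$gene_id)
  excluded <- setdiff(union(metrics$gene_id, surv$gene_id), shared)
  m <- metrics[match(shared, metrics$gene_id), ]
  s <- surv[match(shared, surv$gene_id), ]
  out <- data.frame(
    gene_id = shared, r2 = m$r2, cutoff = s$cutoff, logrank_p = s$logrank_p,
    methylation_affected = m$r2 > r2_threshold,
    survival_associated = s$logrank_p <= p_threshold,
    stringsAsFactors = FALSE)
  out$masa <- out$methylation_affected & out$survival_associated
  attr(out, "excluded") <- excluded
  out
}

#' Association between methylation effect and survival association
#'
#' Pearson chi-square test (no continuity correction) on the 2x2 table of
#' methylation-affected by survival-associated gene status, with the odds
#' ratio and its Woolf (log-scale normal) 95% confidence interval. A zero
#' cell triggers the Haldane 0.5 correction for the OR and CI only, flagged
#' in the result. The chi-square reference distribution is asymptotic; with
#' few genes per cell the p-value is approximate.
#'
#' @param masa MASA table from [call_masa()], or a 2x2 matrix
#'   `[affected, not] x [associated, not]` with the (affected, associated)
#'   cell first.
#' @return list with `table`, `chi2`, `p`, `or`, `ci_low`, `ci_high`,
#'   `haldane`.
#' @export
association_test <- function(masa) {
  tab <- if (is.matrix(masa)) masa else {
    table(factor(masa$methylation_affected, levels = c(TRUE, FALSE)),
          factor(masa$survival_associated, levels = c(TRUE, FALSE)))
  }
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all marginals of the 2x2 table must be positive")
  # the small-expected-count advisory is silenced: the Pearson statistic is
  # reported as-is and the chi-square approximation caveat is documented
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  haldane <- any(tab == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(table = tab, chi2 = unname(chi$statistic), p = chi$p.value,
       or = or, ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se), haldane = haldane)
}
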