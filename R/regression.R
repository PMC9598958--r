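#' Prediction error and explanatory power
#'
#' Mean squared error, its square root, mean absolute error and the
#' coefficient of determination `R^2 = 1 - RSS/TSS` (total sum of squares
#' about the mean of `y_real`).
#'
#' @param y_real observed values.
#' @param y_pred predicted values, same length (>= 2).
#' @return list with `mse`, `rmse`, `mae`, `r2` and `r2_defined` (FALSE when
#'   `y_real` is constant, in which case `r2` is `NA`).
#' @export
score_predictions <- function(y_real, y_pred) {
  if (length(y_real) != length(y_pred)) stop("lengths differ")
  if (length(y_real) < 2) stop("need at least 2 observations")
  err <- y_real - y_pred
  mse <- mean(err^2)
  tss <- sum((y_real - mean(y_real))^2)
  r2_defined <- tss > 0
  list(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
       r2 = if (r2_defined) 1 - sum(err^2) / tss else NA_real_,
       r2_defined = r2_defined)
}

# The package states the elastic-net objective as
#   (1/2N) RSS + lambda * alpha * ||b||_1 + lambda * (1 - alpha) / 2 * ||b||_2^2
# with penalties applied to internally standardized coefficients. glmnet's
# gaussian path applies the L2 part scaled by 1/sd(y) (population sd); this
# maps a textbook (alpha, lambda) onto the glmnet parametrization solving
# the same problem.
to_glmnet_spec <- function(alpha, lambda, y) {
  sy <- sqrt(mean((y - mean(y))^2))
  l1 <- lambda * alpha
  l2 <- lambda * (1 - alpha)
  lambda_g <- l1 + l2 * sy
  alpha_g <- if (lambda_g > 0) l1 / lambda_g else 1
  list(alpha = alpha_g, lambda = lambda_g)
}

# and the inverse, for reporting a glmnet-scale selection on the stated scale
from_glmnet_spec <- function(alpha_g, lambda_g, y) {
  sy <- sqrt(mean((y - mean(y))^2))
  l1 <- lambda_g * alpha_g
  l2 <- if (sy > 0) lambda_g * (1 - alpha_g) / sy else 0
  lambda <- l1 + l2
  alpha <- if (lambda > 0) l1 / lambda else alpha_g
  list(alpha = alpha, lambda = lambda)
}

# glmnet requires >= 2 columns; a zero-variance dummy column is penalty-inert
pad_single_column <- function(X) {
  if (ncol(X) >= 2) return(list(X = X, padded = FALSE))
  list(X = cbind(X, `.pad` = 0), padded = TRUE)
}

#' Fit an elastic net at a fixed penalty
#'
#' Minimizes `(1/2N) RSS + lambda*alpha*||b||_1 +
#' lambda*(1-alpha)/2*||b||_2^2` with an unpenalized intercept. Features are
#' standardized internally; coefficients are returned on the original data
#' scale. `alpha = 1` is the lasso, `alpha = 0` ridge regression.
#'
#' @param X predictor matrix (samples x probes), no missing values.
#' @param y response vector aligned with rows of `X`.
#' @param alpha L1/L2 mixing weight in `[0,1]`.
#' @param lambda penalty strength `>= 0`.
#' @return list with `intercept` and `coefficients` (named by column).
#' @export
fit_penalized <- function(X, y, alpha, lambda) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  cn <- colnames(X)
  if (var(y) == 0) {
    return(list(intercept = mean(y),
                coefficients = setNames(rep(0, ncol(X)), cn)))
  }
  pad <- pad_single_column(X)
  gs <- to_glmnet_spec(alpha, lambda, y)
  path <- if (gs$lambda > 0) gs$lambda * c(10, 1) else c(0.01, 0)
  fit <- glmnet::glmnet(pad$X, y, alpha = gs$alpha, lambda = path,
                        standardize = TRUE, thresh = 1e-14, maxit = 1e6)
  # the target lambda is the last path entry, so no interpolation is needed
  cf <- as.numeric(coef(fit)[, length(path)])
  b <- cf[-1]
  if (pad$padded) b <- b[-length(b)]
  list(intercept = cf[1], coefficients = setNames(b, cn))
}

#' Cross-validated elastic-net model selection for one gene
#'
#' For each mixing weight in `alpha_grid`, a 100-point log-spaced lambda path
#' (down to 1e-3 of the largest useful lambda) is evaluated by k-fold
#' cross-validation on shared folds; the (alpha, lambda) pair minimizing the
#' cross-validated MSE wins, with ties broken toward larger lambda and then
#' larger alpha (the sparser model). Held-out predictions are pooled across
#' folds to compute the reported metrics, and the winning penalty is refit on
#' all samples for the final coefficients.
#'
#' @param X predictor matrix (samples x probes).
#' @param y response vector.
#' @param alpha_grid mixing weights to try; the default reproduces a global
#'   elastic net at `alpha = 0.1`, `seq(0, 1, 0.1)` searches the full grid.
#' @param n_folds number of folds (n must be at least `2 * n_folds`).
#' @param seed seed for fold assignment (ignored when `foldid` is given).
#' @param foldid optional explicit fold assignment, reused across the grid.
#' @param gene_id identifier stored in the result.
#' @return object of class `gene_fit`: intercept, named `coefficients`,
#'   selected `alpha`/`lambda` (in the parametrization of the search grid),
#'   the equivalent `alpha_obj`/`lambda_obj` on the textbook objective scale
#'   used by [fit_penalized()], `cv_metrics` (pooled held-out
#'   mse/rmse/mae/r2), `n`, `p`.
#' @export
cross_validate <- function(X, y, alpha_grid = 0.1, n_folds = 5, seed = 1,
                           foldid = NULL, gene_id = NA_character_) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("rows of X must align with y")
  if (n < 2 * n_folds) stop("need at least ", 2 * n_folds, " samples for ",
                            n_folds, "-fold cross-validation")
  if (is.null(foldid)) {
    set.seed(derive_seed(seed, "folds"))
    foldid <- sample(rep(seq_len(n_folds), length.out = n))
  }
  pad <- pad_single_column(X)
  best <- NULL
  for (a in sort(alpha_grid)) {
    cv <- glmnet::cv.glmnet(pad$X, y, alpha = a, foldid = foldid,
                            keep = TRUE, nlambda = 100,
                            lambda.min.ratio = 1e-3, standardize = TRUE,
                            thresh = 1e-10)
    i <- which(cv$cvm == min(cv$cvm))
    i <- i[which.max(cv$lambda[i])] # tie: larger lambda
    cand <- list(alpha = a, lambda = cv$lambda[i], cvm = cv$cvm[i],
                 pred = cv$fit.preval[, i], fit = cv$glmnet.fit)
    if (is.null(best) || cand$cvm < best$cvm ||
        (cand$cvm == best$cvm && (cand$lambda > best$lambda ||
          (cand$lambda == best$lambda && cand$alpha > best$alpha)))) {
      best <- cand
    }
  }
  metrics <- score_predictions(y, best$pred)
  cf <- as.numeric(coef(best$fit, s = best$lambda, exact = TRUE,
                        x = pad$X, y = y, alpha = best$alpha, thresh = 1e-10))
  b <- cf[-1]
  if (pad$padded) b <- b[-length(b)]
  spec <- from_glmnet_spec(best$alpha, best$lambda, y)
  structure(list(
    gene_id = gene_id, intercept = cf[1],
    coefficients = setNames(b, colnames(X)),
    # selected penalty in the software parametrization the grid is defined on
    alpha = best$alpha, lambda = best$lambda,
    # and on the stated objective scale, so fit_penalized() reproduces it
    alpha_obj = spec$alpha, lambda_obj = spec$lambda,
    cv_metrics = metrics, foldid = foldid,
    n = n, p = ncol(X)
  ), class = "gene_fit")
}

#' Fit penalized models for a set of genes
#'
#' Runs [cross_validate()] per gene on its cis probes, optionally restricted
#' to a signed-distance window around the TSS. Fold assignment is built once
#' from the seed and shared by every gene, so per-gene comparisons between
#' runs are paired.
#'
#' @param beta complete beta matrix (probes x samples).
#' @param expr expression matrix (genes x samples), same samples.
#' @param pairs annotated (gene, probe) table from [annotate_probes()].
#' @param alpha_grid mixing weights (default: global elastic net at 0.1).
#' @param n_folds folds for cross-validation.
#' @param seed seed for fold assignment.
#' @param window optional `c(lower, upper)` signed-distance filter in bp,
#'   e.g. `c(-2000, 7000)` for the promoter-proximal refit.
#' @return list of class `gene_fit_set`: `fits` (named `gene_fit` list),
#'   `metrics` (one row per gene), `coefficients` (gene_id, probe_id,
#'   coefficient), `skipped` (genes without usable probes), `window`.
#' @export
fit_gene_set <- function(beta, expr, pairs, alpha_grid = 0.1, n_folds = 5,
                         seed = 1, window = NULL) {
  stopifnot(identical(colnames(beta), colnames(expr)))
  if (!is.null(window)) {
    pairs <- pairs[pairs$signed_distance >= window[1] &
                   pairs$signed_distance <= window[2], , drop = FALSE]
  }
  pairs <- pairs[pairs$probe_id %in% rownames(beta), , drop = FALSE]
  set.seed(derive_seed(seed, "folds"))
  foldid <- sample(rep(seq_len(n_folds), length.out = ncol(beta)))
  genes <- intersect(rownames(expr), unique(pairs$gene_id))
  skipped <- setdiff(rownames(expr), genes)
  fits <- vector("list", length(genes))
  names(fits) <- genes
  probes_by_gene <- split(pairs$probe_id, pairs$gene_id)
  for (g in genes) {
    pr <- probes_by_gene[[g]]
    X <- t(beta[pr, , drop = FALSE])
    fits[[g]] <- cross_validate(X, expr[g, ], alpha_grid = alpha_grid,
                                n_folds = n_folds, foldid = foldid,
                                gene_id = g)
  }
  metrics <- do.call(rbind, lapply(fits, function(f) data.frame(
    gene_id = f$gene_id, alpha = f$alpha, lambda = f$lambda,
    mse = f$cv_metrics$mse, rmse = f$cv_metrics$rmse,
    mae = f$cv_metrics$mae, r2 = f$cv_metrics$r2,
    n = f$n, p = f$p, stringsAsFactors = FALSE)))
  rownames(metrics) <- NULL
  coefs <- do.call(rbind, lapply(fits, function(f) data.frame(
    gene_id = f$gene_id, probe_id = names(f$coefficients),
    coefficient = unname(f$coefficients), stringsAsFactors = FALSE)))
  rownames(coefs) <- NULL
  structure(list(fits = fits, metrics = metrics, coefficients = coefs,
                 skipped = data.frame(gene_id = skipped,
                                      reason = rep("no_probes_in_window",
                                                   length(skipped)),
                                      stringsAsFactors = FALSE),
                 window = window),
            class = "gene_fit_set")
}
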