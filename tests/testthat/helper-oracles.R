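# Independent oracle implementations used across test files. These are
# deliberately naive (brute force, closed form) and share no code with the
# package internals they check.

# ridge solution in closed form on 1/N-standardized predictors,
# back-transformed to the original scale
oracle_ridge <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(scale(X, center = TRUE, scale = FALSE)^2))
  Xs <- scale(X, center = xm, scale = xs)
  yc <- y - mean(y)
  bs <- solve(crossprod(Xs) + n * lambda * diag(p), crossprod(Xs, yc))
  b <- unname(as.numeric(bs) / xs)
  list(intercept = mean(y) - sum(b * xm), coefficients = b)
}

# worst violation of the elastic-net stationarity conditions at a proposed
# solution, evaluated in standardized coordinates
oracle_kkt_violation <- function(X, y, alpha, lambda, b_orig) {
  n <- nrow(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(scale(X, center = TRUE, scale = FALSE)^2))
  Xs <- scale(X, center = xm, scale = xs)
  b <- b_orig * xs
  r <- (y - mean(y)) - Xs %*% b
  g <- as.numeric(crossprod(Xs, r)) / n - lambda * (1 - alpha) * b
  max(ifelse(b == 0, pmax(abs(g) - lambda * alpha, 0),
             abs(g - lambda * alpha * sign(b))))
}

# value of the penalized objective (1/2N)RSS + lam*a*|b|_1 + lam*(1-a)/2*|b|_2^2
# with penalties on standardized coefficients
oracle_objective <- function(X, y, alpha, lambda, intercept, b_orig) {
  n <- nrow(X)
  xs <- sqrt(colMeans(scale(X, center = TRUE, scale = FALSE)^2))
  b <- b_orig * xs
  rss <- sum((y - intercept - X %*% b_orig)^2)
  rss / (2 * n) + lambda * alpha * sum(abs(b)) +
    lambda * (1 - alpha) / 2 * sum(b^2)
}

# CGI banding by scanning every island (no interval machinery)
oracle_cgi <- function(pos, cgi_chrom_df) {
  if (nrow(cgi_chrom_df) == 0) return("open_sea")
  gaps <- vapply(seq_len(nrow(cgi_chrom_df)), function(i) {
    s <- cgi_chrom_df$start[i]; e <- cgi_chrom_df$end[i]
    if (pos >= s && pos < e) 0L
    else if (pos < s) s - pos
    else pos - (e - 1L)
  }, integer(1))
  g <- min(gaps)
  if (g == 0) "island"
  else if (g <= 2000) "shore"
  else if (g <= 4000) "shelf"
  else "open_sea"
}

# gene-component labelling by painting every base of the transcript span
oracle_component <- function(pos, exons) {
  e <- exons[order(exons$exon_number), , drop = FALSE]
  span <- c(min(e$start), max(e$end))
  if (pos < span[1] || pos >= span[2]) return("intergenic")
  paint <- rep("other_intron", span[2] - span[1])
  k <- nrow(e)
  # paint introns first (in 5' order), then exons on top
  ord5 <- seq_len(k)
  for (j in seq_len(k - 1)) {
    glo <- min(e$end[j], e$end[j + 1]); ghi <- max(e$start[j], e$start[j + 1])
    if (ghi > glo) {
      paint[(glo - span[1] + 1):(ghi - span[1])] <-
        if (j == 1) "first_intron" else "other_intron"
    }
  }
  for (j in ord5) {
    paint[(e$start[j] - span[1] + 1):(e$end[j] - span[1])] <-
      if (j == 1) "first_exon" else "other_exon"
  }
  paint[pos - span[1] + 1]
}

# small simulated study reused by several files
tiny_sim <- function(seed = 7, n_samples = 60, n_genes = 12, ...) {
  simulate_dataset(sim_config(n_samples = n_samples, n_genes = n_genes,
                              probes_per_gene = 10, seed = seed, ...))
}
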