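fake_fit <- function(coefs, gene_id = "g") {
  structure(list(gene_id = gene_id,
                 coefficients = setNames(coefs, paste0("p", seq_along(coefs)))),
            class = "gene_fit")
}

fake_records <- function(n_eff, n_imp, cgi = "open_sea", sign = "negative",
                         distance = 0, gene_id = "g", component = "intergenic") {
  stopifnot(n_imp <= n_eff)
  data.frame(gene_id = gene_id,
             probe_id = paste0(cgi, sign, distance, seq_len(n_eff)),
             raw_coefficient = ifelse(sign == "negative", -1, 1),
             sign = sign,
             normalized = c(rep(1, n_imp), rep(0.5, n_eff - n_imp)),
             effective = TRUE,
             important = seq_len(n_eff) <= n_imp,
             signed_distance = distance, cgi_relation = cgi,
             component = component, stringsAsFactors = FALSE)
}

test_that("min-max normalization matches hand-worked examples", {
  out <- normalize_coefficients(fake_fit(c(0, 2, -4)))
  # zero coefficient joins the pool (min 0) but is dropped from the rows
  expect_equal(out$probe_id, c("p2", "p3"))
  expect_equal(out$normalized, c(0.5, 1.0))
  expect_equal(out$sign, c("positive", "negative"))
  expect_equal(out$important, c(FALSE, TRUE))
  expect_true(all(out$effective))

  # a single nonzero coefficient is its gene's most important probe
  one <- normalize_coefficients(fake_fit(c(0, 0, 3)))
  expect_equal(one$probe_id, "p3")
  expect_equal(one$normalized, 1.0)
  expect_true(one$important)

  # equal nonzero magnitudes: max == min > 0, everything scales to 1
  eq <- normalize_coefficients(fake_fit(c(2, -2)))
  expect_equal(eq$normalized, c(1, 1))
  expect_true(all(eq$important))

  # all-zero gene contributes no records
  expect_equal(nrow(normalize_coefficients(fake_fit(c(0, 0)))), 0)
})

test_that("importance rounds halves away from zero at one decimal", {
  near <- normalize_coefficients(fake_fit(c(0, 0.96, 1)))
  expect_equal(near$normalized, c(1.0, 1.0))
  expect_true(all(near$important))
  far <- normalize_coefficients(fake_fit(c(0, 0.94, 1)))
  expect_equal(far$normalized, c(0.9, 1.0))
  expect_equal(far$important, c(FALSE, TRUE))
  # 0.95 scaled rounds up, not to even
  half <- normalize_coefficients(fake_fit(c(0, 0.95, 1)))
  expect_equal(half$normalized[1], 1.0)
})

test_that("importance_table joins annotations and recounts the fit", {
  sim <- tiny_sim(seed = 81, n_genes = 8, missing_rate = 0)
  ann <- annotate_probes(sim$genome$genes, sim$genome$exons, sim$genome$cgi,
                         sim$genome$probes, sim$config$window_bp)
  fs <- fit_gene_set(sim$beta, sim$expr, ann$pairs, seed = 5)
  recs <- importance_table(fs, ann$pairs)
  # every record corresponds to a nonzero coefficient of the fit
  key <- paste(fs$coefficients$gene_id, fs$coefficients$probe_id)
  nz <- fs$coefficients[fs$coefficients$coefficient != 0, ]
  expect_setequal(paste(recs$gene_id, recs$probe_id),
                  paste(nz$gene_id, nz$probe_id))
  expect_equal(recs$raw_coefficient,
               nz$coefficient[match(paste(recs$gene_id, recs$probe_id),
                                    paste(nz$gene_id, nz$probe_id))])
  # every gene with a nonzero coefficient has at least one important probe
  imp_by_gene <- tapply(recs$important, recs$gene_id, any)
  expect_true(all(imp_by_gene))
  expect_true(all(recs$normalized >= 0 & recs$normalized <= 1))
  # joined annotation agrees with the pairs table
  m <- match(paste(recs$gene_id, recs$probe_id),
             paste(ann$pairs$gene_id, ann$pairs$probe_id))
  expect_false(anyNA(m))
  expect_equal(recs$signed_distance, ann$pairs$signed_distance[m])
  expect_equal(recs$cgi_relation, ann$pairs$cgi_relation[m])
})

test_that("distance_profile bins, percentages and empty-bin omission", {
  recs <- rbind(fake_records(4, 1, distance = -1500),
                fake_records(2, 2, distance = 250),
                fake_records(3, 0, distance = 250, sign = "positive"),
                fake_records(5, 2, distance = 10500))
  prof <- distance_profile(recs, bin_width = 1000, range = c(-2000, 12000))
  # bins: [-2000,-1000) neg, [0,1000) neg and pos, [10000,11000) neg
  expect_equal(nrow(prof), 4)
  expect_equal(prof$bin_start, c(-2000, 0, 0, 10000))
  expect_equal(prof$bin_mid, prof$bin_start + 500)
  expect_equal(prof$percent[prof$bin_start == -2000], 25)
  neg0 <- prof$percent[prof$bin_start == 0 & prof$sign == "negative"]
  pos0 <- prof$percent[prof$bin_start == 0 & prof$sign == "positive"]
  expect_equal(neg0, 100)
  expect_equal(pos0, 0)
  expect_equal(prof$n_effective[prof$bin_start == 10000], 5)
  expect_equal(prof$percent[prof$bin_start == 10000], 40)
  # pooling signs merges the two bin-0 rows
  pooled <- distance_profile(recs, 1000, c(-2000, 12000), by_sign = FALSE)
  expect_equal(pooled$n_effective[pooled$bin_start == 0], 5)
  expect_equal(pooled$percent[pooled$bin_start == 0], 40)
  # the range filter drops out-of-range records entirely
  narrow <- distance_profile(recs, 1000, c(-2000, 2000))
  expect_equal(sum(narrow$n_effective), 9)
})

test_that("distance_profile is invariant to translating bins with the records", {
  recs <- fake_records(6, 3, distance = 730)
  a <- distance_profile(recs, 500, c(-1000, 1000))
  shifted <- recs; shifted$signed_distance <- shifted$signed_distance + 5000
  b <- distance_profile(shifted, 500, c(4000, 6000))
  expect_equal(b$bin_start - 5000, a$bin_start)
  expect_equal(b$percent, a$percent)
  expect_equal(b$n_effective, a$n_effective)
})

test_that("region_profile partitions effective probes and validates categories", {
  recs <- rbind(fake_records(10, 8, cgi = "island"),
                fake_records(10, 2, cgi = "open_sea"),
                fake_records(4, 1, cgi = "shore", sign = "positive"))
  prof <- region_profile(recs, "cgi_relation")
  expect_equal(sum(prof$n_effective), nrow(recs))
  expect_equal(prof$percent[prof$category == "island"], 80)
  expect_equal(prof$percent[prof$category == "open_sea"], 20)
  expect_equal(prof$percent[prof$category == "shore"], 25)
  bad <- recs; bad$cgi_relation[1] <- "lagoon"
  expect_error(region_profile(bad, "cgi_relation"), "lagoon")

  comp <- rbind(fake_records(5, 5, component = "first_exon"),
                fake_records(5, 0, component = "other_intron"))
  pc <- region_profile(comp, "component")
  expect_equal(pc$percent[pc$category == "first_exon"], 100)
  expect_equal(pc$percent[pc$category == "other_intron"], 0)

  # window and gene filters subset before counting
  recs$signed_distance <- rep(c(-5000, 100), length.out = nrow(recs))
  w <- region_profile(recs, "cgi_relation", window = c(-2000, 7000))
  expect_equal(sum(w$n_effective), sum(recs$signed_distance >= -2000))
  recs$gene_id <- rep(c("g1", "g2"), length.out = nrow(recs))
  gsub <- region_profile(recs, "cgi_relation", genes = "g1")
  expect_equal(sum(gsub$n_effective), sum(recs$gene_id == "g1"))
})

test_that("region_logistic recovers the closed-form two-level log odds", {
  recs <- rbind(fake_records(10, 9, cgi = "island"),
                fake_records(10, 1, cgi = "open_sea"))
  fit <- region_logistic(recs)
  # reference open_sea: intercept log(1/9), island log odds ratio log(81)
  expect_equal(fit$estimate[fit$term == "(Intercept)"], log(1 / 9),
               tolerance = 1e-6)
  expect_equal(fit$estimate[fit$term == "island"], log(81), tolerance = 1e-6)
  expect_false(attr(fit, "separation"))

  # doubling every count keeps the estimates and shrinks the p-value
  dbl <- region_logistic(rbind(recs, transform(
    recs, probe_id = paste0(probe_id, "b"))))
  expect_equal(dbl$estimate, fit$estimate, tolerance = 1e-6)
  expect_lt(dbl$p_value[dbl$term == "island"],
            fit$p_value[fit$term == "island"])
})

test_that("region_logistic under a null and under separation", {
  set.seed(82)
  n <- 400
  recs <- fake_records(n, 0)
  recs$cgi_relation <- sample(c("island", "open_sea"), n, TRUE)
  recs$important <- runif(n) < 0.3
  fit <- region_logistic(recs)
  expect_lt(abs(fit$estimate[fit$term == "island"]), 0.5)
  expect_gt(fit$p_value[fit$term == "island"], 0.01)

  sep <- rbind(fake_records(10, 10, cgi = "island"),
               fake_records(10, 0, cgi = "open_sea"))
  fs <- region_logistic(sep)
  expect_true(attr(fs, "separation"))

  expect_error(region_logistic(fake_records(10, 5)), "two CGI categories")
  expect_error(region_logistic(rbind(fake_records(5, 5, cgi = "island"),
                                     fake_records(5, 5))), "both outcomes")
})
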