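make_exons <- function(tx, strand, ivs) {
  do.call(rbind, lapply(seq_along(ivs), function(j) data.frame(
    gene_id = "g", transcript_id = tx, chrom = "chr1", strand = strand,
    start = ivs[[j]][1], end = ivs[[j]][2], exon_number = j,
    stringsAsFactors = FALSE)))
}

test_that("select_tss picks the strand-aware start of the longest-exon transcript", {
  one <- make_exons("t1", "+", list(c(100, 200), c(300, 500)))
  expect_equal(select_tss(one)$tss, 100)

  # exon sums 400 vs 600: the longer transcript wins
  two <- rbind(make_exons("t1", "+", list(c(100, 500))),
               make_exons("t2", "+", list(c(50, 450), c(600, 800))))
  sel <- select_tss(two)
  expect_equal(sel$transcript_id, "t2")
  expect_equal(sel$tss, 50)

  # minus strand: TSS is the last covered base (0-based)
  neg <- make_exons("t1", "-", list(c(100, 500)))
  expect_equal(select_tss(neg)$tss, 499)

  # tie in exon sum: more 5' start, then transcript id
  tie <- rbind(make_exons("tB", "+", list(c(200, 300))),
               make_exons("tA", "+", list(c(200, 300))))
  expect_equal(select_tss(tie)$transcript_id, "tA")
  tie2 <- rbind(make_exons("tB", "+", list(c(100, 200))),
                make_exons("tA", "+", list(c(150, 250))))
  expect_equal(select_tss(tie2)$transcript_id, "tB")

  expect_error(select_tss(one[0, ], "gX"), "gX")
})

test_that("collect_cis_probes matches a brute-force scan and sign convention", {
  set.seed(31)
  genes <- data.frame(
    gene_id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"), tss = c(2000000L, 2500000L, 1000000L),
    stringsAsFactors = FALSE)
  probes <- data.frame(
    probe_id = sprintf("p%04d", 1:1000),
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = sample.int(4000000L, 1000), stringsAsFactors = FALSE)
  w <- 800000
  got <- collect_cis_probes(genes, probes, w)
  # brute force over all pairs
  exp_rows <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(probes))) {
    if (genes$chrom[i] == probes$chrom[j] &&
        abs(probes$pos[j] - genes$tss[i]) <= w) {
      d <- probes$pos[j] - genes$tss[i]
      if (genes$strand[i] == "-") d <- -d
      exp_rows[[length(exp_rows) + 1]] <-
        data.frame(gene_id = genes$gene_id[i], probe_id = probes$probe_id[j],
                   signed_distance = d, stringsAsFactors = FALSE)
    }
  }
  want <- do.call(rbind, exp_rows)
  key <- function(df) sort(paste(df$gene_id, df$probe_id, df$signed_distance))
  expect_equal(key(got), key(want))

  # sign convention and boundary inclusion
  p2 <- data.frame(probe_id = c("x", "y"), chrom = "chr1",
                   pos = c(2000000L, 1997500L), stringsAsFactors = FALSE)
  got2 <- collect_cis_probes(genes[1, ], p2, 1e6)
  expect_equal(got2$signed_distance[got2$probe_id == "x"], 0L)
  expect_equal(got2$signed_distance[got2$probe_id == "y"], -2500L)
  # minus-strand gene: a probe left of the TSS is downstream (positive)
  got3 <- collect_cis_probes(genes[2, ], data.frame(
    probe_id = "z", chrom = "chr1", pos = 2499000L), 1e6)
  expect_equal(got3$signed_distance, 1000L)
})

test_that("CGI banding follows the island/shore/shelf/open-sea distances", {
  cgi <- data.frame(chrom = "chr1", start = 10000L, end = 11000L,
                    stringsAsFactors = FALSE)
  at <- function(pos) annotate_cgi_relation(
    data.frame(probe_id = "p", chrom = "chr1", pos = pos), cgi)
  expect_equal(at(10500), "island")
  expect_equal(at(10999), "island")
  expect_equal(at(11000), "shore")      # adjacent base, 1 bp gap
  expect_equal(at(11000 - 1 + 1500), "shore")   # 1500 bp gap
  expect_equal(at(11000 - 1 + 2000), "shore")   # boundary of the shore band
  expect_equal(at(11000 - 1 + 3000), "shelf")   # 3000 bp gap
  expect_equal(at(11000 - 1 + 4000), "shelf")
  expect_equal(at(11000 - 1 + 5000), "open_sea")
  expect_equal(at(10000 - 1500), "shore")       # upstream side
})

test_that("CGI banding agrees with a brute-force scan on random probes", {
  set.seed(32)
  cgi <- data.frame(
    chrom = rep(c("chr1", "chr2"), c(6, 4)),
    start = c(sort(sample.int(90000, 6)) * 10L, sort(sample.int(90000, 4)) * 10L),
    stringsAsFactors = FALSE)
  cgi$end <- cgi$start + sample(200:2000, 10)
  probes <- data.frame(probe_id = sprintf("p%03d", 1:500),
                       chrom = sample(c("chr1", "chr2", "chr3"), 500, TRUE),
                       pos = sample.int(1000000L, 500),
                       stringsAsFactors = FALSE)
  got <- annotate_cgi_relation(probes, cgi)
  want <- vapply(seq_len(500), function(i)
    oracle_cgi(probes$pos[i], cgi[cgi$chrom == probes$chrom[i], , drop = FALSE]),
    character(1))
  expect_equal(got, want)
})

test_that("gene components classify exons, introns and flanks correctly", {
  ex <- make_exons("t1", "+", list(c(1000, 1200), c(1500, 1700), c(2000, 2300)))
  expect_equal(annotate_component(1100, ex), "first_exon")
  expect_equal(annotate_component(1300, ex), "first_intron")
  expect_equal(annotate_component(1600, ex), "other_exon")
  expect_equal(annotate_component(1800, ex), "other_intron")
  expect_equal(annotate_component(500, ex), "intergenic")
  expect_equal(annotate_component(2500, ex), "intergenic")
  # single-exon transcript has no introns
  ex1 <- make_exons("t1", "+", list(c(1000, 1200)))
  expect_equal(annotate_component(c(1100, 1250), ex1),
               c("first_exon", "intergenic"))
})

test_that("component labels match a painted-array oracle on random positions", {
  set.seed(33)
  for (strand in c("+", "-")) {
    k <- 4
    elen <- sample(100:300, k); ilen <- sample(200:900, k - 1)
    off <- cumsum(c(0, head(elen, -1) + ilen))
    tss <- 50000
    ivs <- lapply(seq_len(k), function(j) {
      if (strand == "+") c(tss + off[j], tss + off[j] + elen[j])
      else c(tss - off[j] - elen[j] + 1, tss - off[j] + 1)
    })
    ex <- make_exons("t1", strand, ivs)
    span <- c(min(ex$start) - 500, max(ex$end) + 500)
    pos <- sample(span[1]:span[2], 200)
    got <- annotate_component(pos, ex)
    want <- vapply(pos, oracle_component, character(1), exons = ex)
    expect_equal(got, want)
  }
})

test_that("reverse-complementing the locus preserves distances and labels", {
  sim <- tiny_sim(seed = 41, n_genes = 8)
  g <- sim$genome
  ann <- annotate_probes(g$genes, g$exons, g$cgi, g$probes,
                         sim$config$window_bp)
  M <- max(g$probes$pos, g$exons$end, g$cgi$end) + 1000
  mirror_iv <- function(s, e) c(M - e, M - s)
  g2 <- g
  g2$genes$strand <- ifelse(g$genes$strand == "+", "-", "+")
  g2$exons$strand <- ifelse(g$exons$strand == "+", "-", "+")
  ivs <- t(mapply(mirror_iv, g$exons$start, g$exons$end))
  g2$exons$start <- ivs[, 1]; g2$exons$end <- ivs[, 2]
  ivc <- t(mapply(mirror_iv, g$cgi$start, g$cgi$end))
  g2$cgi$start <- ivc[, 1]; g2$cgi$end <- ivc[, 2]
  g2$probes$pos <- M - 1 - g$probes$pos
  ann2 <- annotate_probes(g2$genes, g2$exons, g2$cgi, g2$probes,
                          sim$config$window_bp)
  key <- function(p) order(p$gene_id, p$probe_id)
  a <- ann$pairs[key(ann$pairs), ]; b <- ann2$pairs[key(ann2$pairs), ]
  expect_equal(a$signed_distance, b$signed_distance)
  expect_equal(a$cgi_relation, b$cgi_relation)
  expect_equal(a$component, b$component)
})

test_that("flipping strand alone negates every signed distance", {
  sim <- tiny_sim(seed = 42, n_genes = 6)
  g <- sim$genome
  genes <- add_tss(g$genes, g$exons)
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  a <- collect_cis_probes(genes, g$probes, 1e6)
  b <- collect_cis_probes(flipped, g$probes, 1e6)
  key <- function(p) order(p$gene_id, p$probe_id)
  expect_equal(a$signed_distance[key(a)], -b$signed_distance[key(b)])
})

test_that("GTF and BED round-trip through the readers", {
  sim <- tiny_sim(seed = 43, n_genes = 6)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  gm <- read_gene_models(file.path(dir, "genes.gtf"))
  expect_setequal(gm$genes$gene_id, sim$genome$genes$gene_id)
  key <- function(e) e[order(e$transcript_id, e$exon_number),
                       c("transcript_id", "start", "end", "exon_number")]
  got <- key(gm$exons); want <- key(sim$genome$exons)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  cgi <- read_cgi_bed(file.path(dir, "cgi.bed"))
  expect_equal(cgi$start, sim$genome$cgi$start)
  expect_equal(cgi$end, sim$genome$cgi$end)
  pm <- read_probe_manifest(file.path(dir, "probes.tsv"))
  expect_equal(pm, sim$genome$probes)
})
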