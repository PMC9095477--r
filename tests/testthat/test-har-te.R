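.mkHars <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  names(gr) <- df$id
  mcols(gr)$source <- df$source
  mcols(gr)$group <- df$group
  gr
}

test_that("unique-HAR construction merges across sources with provenance and group sets", {
  hars <- .mkHars(data.frame(
    id = c("h1", "h2", "h3", "h4"),
    chrom = c("chrA", "chrA", "chrA", "chrB"),
    start = c(100, 150, 500, 100), end = c(200, 250, 600, 150),
    source = c("s1", "s2", "s1", "s2"),
    group = c("vHAR", "pHAR", "mHAR", "pHAR")))
  u <- buildUniqueHars(hars)
  expect_equal(length(u), 3)
  g1 <- mcols(u)$group_set[start(u) == 100 & as.character(seqnames(u)) == "chrA"]
  expect_equal(g1, "vHAR,pHAR")
  ## disjoint inputs: unique count = total count
  far <- .mkHars(data.frame(id = paste0("x", 1:3), chrom = "chrA",
                            start = c(1, 1000, 2000), end = c(10, 1010, 2010),
                            source = "s1", group = "vHAR"))
  expect_equal(length(buildUniqueHars(far)), 3)
  expect_error(buildUniqueHars(.mkHars(data.frame(
    id = "b", chrom = "chrA", start = 1, end = 10, source = "s1",
    group = "zHAR"))), "group")
  ## random multi-source fixture vs per-base union with member back-assignment
  set.seed(13)
  rnd <- randomGRanges(120, maxPos = 2000, maxW = 60)
  names(rnd) <- sprintf("r%03d", seq_along(rnd))
  mcols(rnd)$source <- sample(paste0("s", 1:7), 120, replace = TRUE)
  mcols(rnd)$group <- sample(c("vHAR", "mHAR", "pHAR"), 120, replace = TRUE)
  u2 <- buildUniqueHars(rnd)
  o <- oracleMerge(rnd)
  expect_equal(start(u2), o$start)
  expect_equal(end(u2), o$end)
  for (k in seq_along(u2)) {
    members <- unlist(mcols(u2)$members[k])
    inside <- names(rnd)[intervalsOverlap(rnd, rep(u2[k], length(rnd)))]
    expect_setequal(members, inside)
  }
  ## summary fractions equal direct computation
  sm <- attr(u2, "summary")
  for (g in c("vHAR", "mHAR", "pHAR")) {
    frac <- mean(grepl(g, mcols(u2)$group_set))
    expect_equal(sm$fraction[sm$group == g], frac)
  }
})

test_that("nORF-HAR association includes the window boundary and reduces to overlap at window 0", {
  sp <- GRanges("chrA", IRanges(10000, 11000), strand = "+")
  names(sp) <- "n1"
  ## gap = HAR start - span end - 1, so gap == 500 means start 11501
  hars <- GRanges("chrA", IRanges(c(11501, 11502, 10500),
                                  width = c(100, 100, 10)))
  names(hars) <- c("gap_eq", "gap_over", "inside")
  a <- associateNorfHar(sp, hars, window = 500)
  expect_setequal(a$feature_id, c("gap_eq", "inside"))
  expect_equal(a$relation[a$feature_id == "inside"], "overlap")
  expect_equal(a$distance[a$feature_id == "inside"], 0)
  expect_equal(a$distance[a$feature_id == "gap_eq"], 500)
  ## monotone in window
  a2 <- associateNorfHar(sp, hars, window = 501)
  expect_true(all(paste(a$norf_id, a$feature_id) %in%
                    paste(a2$norf_id, a2$feature_id)))
  ## window 0 equals the pure-overlap oracle on random fixtures
  set.seed(17)
  spans <- randomGRanges(50, maxPos = 2000, maxW = 100)
  names(spans) <- sprintf("n%02d", 1:50)
  feats <- randomGRanges(50, maxPos = 2000, maxW = 100)
  names(feats) <- sprintf("f%02d", 1:50)
  a0 <- associateNorfHar(spans, feats, window = 0)
  for (i in seq_along(spans)) for (j in seq_along(feats)) {
    expected <- oracleOverlap(spans[i], feats[j])
    got <- any(a0$norf_id == names(spans)[i] & a0$feature_id == names(feats)[j])
    expect_identical(got, expected)
  }
})

test_that("upstream TE association is strand-aware and never overlaps the nORF", {
  plus <- GRanges("chrA", IRanges(10000, 11000), strand = "+")
  names(plus) <- "nP"
  tes <- GRanges("chrA", IRanges(c(8500, 9500, 11500), c(9500, 10100, 11800)))
  names(tes) <- c("up_ok", "straddle", "downstream")
  a <- associateNorfTe(plus, tes, upstreamWindow = 2000)
  expect_identical(a$feature_id, "up_ok")   # straddler touches the nORF
  ## minus-strand mirror: reflect all coordinates around 21000
  minus <- GRanges("chrA", IRanges(21000 - 11000, 21000 - 10000), strand = "-")
  names(minus) <- "nM"
  tes_m <- GRanges("chrA", IRanges(21000 - c(9500, 10100, 11800),
                                   21000 - c(8500, 9500, 11500)))
  names(tes_m) <- c("up_ok", "straddle", "downstream")
  am <- associateNorfTe(minus, tes_m, upstreamWindow = 2000)
  expect_identical(am$feature_id, "up_ok")
  expect_error(associateNorfTe(GRanges("chrA", IRanges(1, 10), strand = "*"),
                               tes), "unstranded")
  ## exhaustive output invariant: no pair overlaps its nORF
  set.seed(19)
  spans <- randomGRanges(40, maxPos = 40000, maxW = 500)
  strand(spans) <- sample(c("+", "-"), 40, replace = TRUE)
  names(spans) <- sprintf("n%02d", 1:40)
  feats <- randomGRanges(80, maxPos = 40000, maxW = 400)
  names(feats) <- sprintf("t%02d", 1:80)
  aa <- associateNorfTe(spans, feats)
  if (nrow(aa)) {
    for (k in seq_len(nrow(aa)))
      expect_false(oracleOverlap(spans[aa$norf_id[k]], feats[aa$feature_id[k]]))
  }
})

test_that("DE designation uses transcript spans (introns included) and matches a brute-force oracle", {
  ex <- GRangesList(de_tx = GRanges("chrA", IRanges(c(1000, 3000), c(1200, 3200)),
                                    strand = "+"))
  mcols(ex) <- DataFrame(gene_id = "g", biotype = "retained_intron")
  de_tx <- TranscriptSet(ex)
  feats <- GRanges("chrA", IRanges(c(2000, 5000), c(2100, 5100)))
  names(feats) <- c("intronic", "far")
  r <- designateDeFeatures(feats, de_tx)
  expect_true(mcols(r)$de[1])     # HAR inside the intron is still flagged
  expect_false(mcols(r)$de[2])
  rx <- designateDeFeatures(feats, de_tx, exonLevel = TRUE)
  expect_false(mcols(rx)$de[1])   # exon-level mode excludes the intron
  set.seed(23)
  f2 <- randomGRanges(60, maxPos = 5000, maxW = 200)
  names(f2) <- sprintf("f%02d", 1:60)
  spans <- featureSpans(de_tx)
  r2 <- designateDeFeatures(f2, de_tx)
  for (i in seq_along(f2))
    expect_identical(mcols(r2)$de[i], oracleOverlap(f2[i], spans))
})

test_that("correlation screen applies the dual magnitude+significance gate on both statistics", {
  x <- seq_len(10)
  m <- rbind(nA = x, tA = 2 * x + 1, tB = c(x[1:9], -50))
  colnames(m) <- sprintf("s%02d", 1:10)
  oe <- OrfExperiment(m - min(m), unit = "TPM")
  pairs <- data.frame(norf_id = c("nA", "nA"), te_id = c("tA", "tB"))
  r <- correlatePairs(oe, pairs)
  expect_equal(r$pearson_r[1], 1)
  expect_equal(r$spearman_rho[1], 1)
  expect_true(r$significant[1])
  ## brute-force agreement with cor() on random pairs
  set.seed(29)
  rm_ <- matrix(rnorm(200), 10, 20, dimnames = list(sprintf("v%02d", 1:10), NULL))
  colnames(rm_) <- sprintf("s%02d", 1:20)
  oe2 <- OrfExperiment(rm_ - min(rm_), unit = "TPM")
  pr <- data.frame(norf_id = rownames(rm_)[1:5], te_id = rownames(rm_)[6:10])
  rr <- correlatePairs(oe2, pr)
  for (k in 1:5) {
    expect_equal(rr$pearson_r[k], cor(rm_[k, ], rm_[k + 5, ]), tolerance = 1e-10)
    expect_equal(rr$spearman_rho[k],
                 cor(rm_[k, ], rm_[k + 5, ], method = "spearman"),
                 tolerance = 1e-10)
    ct <- cor.test(rm_[k, ], rm_[k + 5, ])
    expect_equal(rr$pearson_p[k], ct$p.value, tolerance = 1e-10)
  }
  ## a strong but sub-0.5 correlation is not significant regardless of p
  set.seed(31)
  u <- rnorm(2000); v <- 0.45 * u + rnorm(2000) * sqrt(1 - 0.45^2)
  big <- OrfExperiment(rbind(a = u, b = v) + 10, unit = "TPM")
  colnames(big) <- sprintf("s%04d", 1:2000)
  rb <- correlatePairs(big, data.frame(norf_id = "a", te_id = "b"))
  expect_lt(rb$pearson_p, 1e-9)
  expect_false(rb$significant)
  ## zero variance: undefined, not significant
  zv <- OrfExperiment(rbind(a = rep(1, 10), b = x) * 1.0, unit = "TPM")
  rz <- correlatePairs(zv, data.frame(norf_id = "a", te_id = "b"))
  expect_true(is.na(rz$pearson_r))
  expect_false(rz$significant)
})

test_that("chi-square presence test matches the closed form with star labels", {
  r <- chisqPresence(rep(c(TRUE, FALSE), each = 10), rep(c("g1", "g2"), 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$stars, "N.S.")
  ## 10/10 present vs 0/10: statistic 20 on 1 df
  r2 <- chisqPresence(c(rep(TRUE, 10), rep(FALSE, 10)),
                      rep(c("g1", "g2"), each = 10))
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df, 1)
  expect_equal(r2$stars, "***")
  ## random tables vs stats::chisq.test without continuity correction
  set.seed(37)
  for (i in 1:50) {
    pres <- runif(30) < 0.5
    grp <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (length(unique(grp)) < 2 || length(unique(pres)) < 2) next
    got <- chisqPresence(pres, grp)
    ref <- suppressWarnings(chisq.test(table(factor(pres, c(FALSE, TRUE)), grp),
                                       correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(chisqPresence(c(TRUE, FALSE), c("a", "a")), "groups")
})
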