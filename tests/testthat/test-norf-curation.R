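test_that("countsToTpm normalizes every column to one million", {
  m <- matrix(c(10, 90), 2, 1, dimnames = list(c("A", "B"), "s1"))
  oe <- OrfExperiment(m, lengths = c(100, 900))
  tpm <- assay(countsToTpm(oe))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))   # equal rates by symmetry
  ## single feature
  one <- OrfExperiment(matrix(7, 1, 1, dimnames = list("A", "s1")), lengths = 50)
  expect_equal(unname(assay(countsToTpm(one))[1, 1]), 1e6)
  ## random matrix: columns sum to 1e6
  set.seed(1)
  r <- OrfExperiment(matrix(rpois(100, 40), 20, 5), lengths = sample(100:900, 20))
  expect_equal(unname(colSums(assay(countsToTpm(r)))), rep(1e6, 5),
               tolerance = 1e-6)
  ## errors
  z <- OrfExperiment(matrix(0, 2, 2), lengths = c(10, 10))
  expect_error(countsToTpm(z), "all-zero")
  expect_error(countsToTpm(OrfExperiment(m)), "length")
})

test_that("lowNoiseFilter applies the strict median-of-cORF-SD rule within equal bins", {
  ## one bin, cORF SDs {1,2,3} (median 2), nORF SDs {1.5, 2.0, 2.5}:
  ## expected flags {TRUE, FALSE, FALSE} by direct median arithmetic
  ## rows with exact sample SD: scale a centered unit-SD vector
  base <- scale(seq_len(11))[, 1]
  base <- base / sd(base)
  m <- rbind(c1 = 50 + 1 * base, c2 = 50 + 2 * base, c3 = 50 + 3 * base,
             n1 = 50 + 1.5 * base, n2 = 50 + 2.0 * base, n3 = 50 + 2.5 * base)
  res <- lowNoiseFilter(m, isCanonical = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                        Q = 1)
  expect_equal(unname(res$low_noise[4:6]), c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(res$low_noise[1:3])))
  expect_equal(unname(res$bin_median_corf_sd[4]), 2)
  ## all ORFs identical SD: zero flagged (strict inequality)
  m2 <- rbind(a = 1 + base, b = 2 + base, x = 3 + base, y = 4 + base)
  r2 <- lowNoiseFilter(m2, c(TRUE, TRUE, FALSE, FALSE), Q = 1)
  expect_false(any(r2$low_noise, na.rm = TRUE))
  ## Q=4 on 8 ORFs: bin sizes {2,2,2,2}
  m3 <- matrix(rep(1:8, each = 3) + rnorm(24, 0, 0.01), 8, 3, byrow = TRUE)
  rownames(m3) <- letters[1:8]
  r3 <- lowNoiseFilter(m3, rep(c(TRUE, FALSE), 4), Q = 4)
  expect_equal(as.vector(table(r3$bin)), rep(2L, 4))
  ## errors / warnings
  expect_error(lowNoiseFilter(m3, rep(TRUE, 8), Q = 9), "exceeds")
  expect_warning(lowNoiseFilter(m3[, , drop = FALSE],
                                c(TRUE, rep(FALSE, 7)), Q = 2), "no canonical")
})

test_that("lowNoiseFilter is invariant to sample order and recovers planted noise strata", {
  ids <- sprintf("n%02d", 1:30)
  sim <- generateRiboseqCounts(11, ids, nCorfs = 150, nSamples = 50)
  tpm <- countsToTpm(sim$counts)
  canon <- rowData(sim$counts)$is_canonical
  res <- lowNoiseFilter(tpm, canon, Q = 9)
  ## permuting samples changes nothing
  perm <- assay(tpm)[, sample(ncol(tpm))]
  res2 <- lowNoiseFilter(perm, canon, Q = 9)
  expect_identical(res$low_noise, res2$low_noise)
  ## planted multiplier 0.5 vs 2.0: sensitivity and specificity >= 0.9
  got <- res$low_noise[match(sim$truth$orf_id, res$orf_id)]
  expect_gte(mean(got[sim$truth$low_noise], na.rm = TRUE), 0.9)
  expect_gte(mean(!got[!sim$truth$low_noise], na.rm = TRUE), 0.9)
})

test_that("generateRiboseqCounts honors multiplier 0 and mean-matched grids", {
  plan <- setNames(c(0, 0.5, 2), c("nA", "nB", "nC"))
  sim <- generateRiboseqCounts(5, names(plan), nCorfs = 10, nSamples = 8,
                               noisePlan = plan)
  m <- assay(sim$counts)
  expect_equal(length(unique(m["nA", ])), 1L)   # constant counts
  sim2 <- generateRiboseqCounts(5, names(plan), nCorfs = 10, nSamples = 8,
                                noisePlan = plan)
  expect_identical(m, assay(sim2$counts))       # same seed, same matrix
  expect_error(generateRiboseqCounts(5, "x", nSamples = 1), ">= 2")
})

test_that("classifyNorfFrame projects codon phase through spliced coordinates", {
  ts <- tinyTranscripts()
  ## txA CDS: exonic chain (111-200, 301-380), + strand
  norfs <- tinyNorfSet(list(
    inframe = GRanges("chrA", IRanges(123, 143), strand = "+"),  # offset 12 nt
    shifted = GRanges("chrA", IRanges(124, 144), strand = "+"),  # offset 13 nt
    intronic = GRanges("chrA", IRanges(221, 260), strand = "+"), # inside intron
    outside = GRanges("chrA", IRanges(5001, 5100), strand = "+"),
    antisense_cds = GRanges("chrA", IRanges(123, 143), strand = "-")))
  cls <- norfFrameClass(classifyNorfFrame(norfs, ts))
  expect_equal(unname(cls["inframe"]), "in_frame_cds")
  expect_equal(unname(cls["shifted"]), "alt_frame_cds")
  expect_equal(unname(cls["intronic"]), "non_cds")
  expect_equal(unname(cls["outside"]), "intergenic")
  expect_equal(unname(cls["antisense_cds"]), "non_cds")  # CDS overlap needs same strand
})

test_that("frame classification agrees with the per-base projection oracle on spliced chains", {
  ts <- generateAnnotation(301, nGenes = 30)
  ns <- generateNorfs(302, ts, nNorfs = 30,
                      mix = c(hosted = 0.2, cds = 0.6, intergenic = 0.2))
  cls <- norfFrameClass(classifyNorfFrame(ns, ts))
  md <- mcols(ns@exons)
  cds_idx <- which(md$planted_kind == "cds")
  expect_gt(length(cds_idx), 5)
  for (i in cds_idx) {
    host <- md$host_transcript[i]
    rel <- oracleFrameRelation(ns@exons[[i]], ts@cds[[host]],
                               as.character(strand(ns@exons[[i]]))[1])
    expect_equal(unname(cls[i]),
                 if (rel == "in") "in_frame_cds" else "alt_frame_cds",
                 info = names(cls)[i])
    ## and the generator's planted frame agrees too
    expect_equal(unname(cls[i]), md$planted_frame[i])
  }
})

test_that("in-frame removal honors the category exception list exhaustively", {
  cats <- orfCategories()
  one <- GRanges("chrA", IRanges(1, 30), strand = "+")
  for (cat in cats) for (fc in frameClasses()) {
    ns <- tinyNorfSet(list(x = one), categories = cat)
    norfFrameClass(ns) <- c(x = fc)
    kept <- length(applyInframeRemoval(ns)) == 1L
    if (fc == "in_frame_cds" &&
        !(cat %in% c("readthrough", "extended", "uORF", "truncated"))) {
      expect_false(kept, info = paste(cat, fc))
    } else {
      expect_true(kept, info = paste(cat, fc))
    }
  }
  ns <- tinyNorfSet(list(x = one), categories = "internal")
  expect_error(applyInframeRemoval(ns), "frame_class")
})

test_that("deduplication keeps the lexicographically smallest id and matches the set oracle", {
  ch1 <- GRanges("chrA", IRanges(c(1, 101), c(50, 150)), strand = "+")
  ch2 <- GRanges("chrA", IRanges(c(1, 101), c(50, 151)), strand = "+")
  ns <- tinyNorfSet(list(b = ch1, a = ch1, c = ch2))
  dd <- deduplicateNorfs(ns)
  expect_setequal(norfIds(dd), c("a", "c"))
  expect_equal(as.character(mcols(dd@exons)$aliases[["a"]]), "b")
  ## random set with planted duplicates vs brute-force set-of-chains size
  set.seed(9)
  chains <- replicate(12, {
    pos <- sort(sample.int(500, 2))
    GRanges("chrA", IRanges(c(pos[1], pos[1] + 100 + pos[2]), width = 30),
            strand = sample(c("+", "-"), 1))
  })
  idx <- sample(12, 30, replace = TRUE)
  ns2 <- tinyNorfSet(setNames(lapply(idx, function(i) chains[[i]]),
                              sprintf("d%02d", 1:30)))
  key <- vapply(idx, function(i)
    paste(as.character(strand(chains[[i]]))[1],
          paste(start(chains[[i]]), end(chains[[i]]), collapse = ","),
          sep = "|"), "")
  expect_equal(length(deduplicateNorfs(ns2)), length(unique(key)))
})
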