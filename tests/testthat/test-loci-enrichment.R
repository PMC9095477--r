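.mkSnps <- function(rsid, pos, p, chrom = "chrS1", maf = 0.3, hwe = 0.5) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos, p = p, maf = maf,
             hwe_p = hwe, stringsAsFactors = FALSE)
}

test_that("SNP QC removes strictly sub-threshold MAF and HWE", {
  s <- .mkSnps(c("a", "b", "c", "d"), 1:4 * 100, 0.5,
               maf = c(0.05, 0.049, 0.3, 0.3),
               hwe = c(0.5, 0.5, 1e-5, 1e-4))
  out <- snpQc(s)
  expect_setequal(out$rsid, c("a", "d"))   # boundaries kept (strict <)
})

test_that("stratification yields nested subsets", {
  set.seed(43)
  s <- .mkSnps(sprintf("r%03d", 1:200), 1:200 * 50, 10^-runif(200, 0, 8))
  st <- stratifySnps(s)
  expect_equal(length(st), 6)
  for (k in 2:6)
    expect_true(all(st[[k]]$rsid %in% st[[k - 1]]$rsid))
  expect_true(all(st[["1e-02"]]$p < 1e-2))
  ## p = 5e-3 falls only in the 1e-2 stratum
  s2 <- .mkSnps("x", 100, 5e-3)
  st2 <- stratifySnps(s2)
  expect_equal(nrow(st2[["1e-02"]]), 1)
  expect_equal(nrow(st2[["1e-03"]]), 0)
})

test_that("greedy LD clumping follows p order and the r2/window rules", {
  ## A(p=1e-8), B(p=1e-6, r2=0.5, 100 kb apart) -> one clump indexed by A
  s <- .mkSnps(c("A", "B"), c(1e6, 1.1e6), c(1e-8, 1e-6))
  r2 <- data.frame(rsid_a = "A", rsid_b = "B", r2 = 0.5)
  cl <- ldClump(s, r2)
  expect_equal(length(unique(cl$clump)), 1)
  expect_equal(unique(cl$index_rsid), "A")
  ## r2 below threshold: two clumps
  r2lo <- data.frame(rsid_a = "A", rsid_b = "B", r2 = 0.05)
  expect_equal(length(unique(ldClump(s, r2lo)$clump)), 2)
  ## asymmetric r2 is rejected
  bad <- data.frame(rsid_a = c("A", "B"), rsid_b = c("B", "A"), r2 = c(0.5, 0.7))
  expect_error(ldClump(s, bad), "asymmetric")
  ## random block fixture vs a brute-force greedy oracle
  g <- generateGwas(47, nSnps = 300, blockSize = 6,
                    causalLoci = GRanges("chrS1", IRanges(1e6, 2e6)))
  snps <- snpQc(g$snps)
  cl2 <- ldClump(snps, g$r2)
  ## invariant: every QC SNP with p < 1e-4 is in exactly one clump
  low <- snps$rsid[snps$p < 1e-4]
  expect_setequal(intersect(cl2$rsid, low), low)
  expect_false(anyDuplicated(cl2$rsid) > 0)
  ## index p is minimal within each clump
  for (k in unique(cl2$clump)) {
    sub <- cl2[cl2$clump == k, ]
    expect_equal(sub$rsid[which.min(sub$p)], unique(sub$index_rsid))
  }
  ## brute-force greedy oracle reproduces the index set
  lk <- new.env()
  for (i in seq_len(nrow(g$r2))) {
    k1 <- paste(g$r2$rsid_a[i], g$r2$rsid_b[i]); assign(k1, g$r2$r2[i], lk)
    k2 <- paste(g$r2$rsid_b[i], g$r2$rsid_a[i]); assign(k2, g$r2$r2[i], lk)
  }
  getr2 <- function(a, b) if (exists(paste(a, b), lk)) get(paste(a, b), lk) else 0
  o <- snps[order(snps$p, snps$pos, snps$rsid), ]
  assigned <- character(); oracle_idx <- character()
  for (i in seq_len(nrow(o))) {
    if (o$rsid[i] %in% assigned || o$p[i] >= 1e-4) next
    oracle_idx <- c(oracle_idx, o$rsid[i])
    assigned <- c(assigned, o$rsid[i])
    for (j in seq_len(nrow(o))) {
      if (o$rsid[j] %in% assigned) next
      if (o$chrom[j] == o$chrom[i] && abs(o$pos[j] - o$pos[i]) <= 3e6 &&
          getr2(o$rsid[i], o$rsid[j]) >= 0.1)
        assigned <- c(assigned, o$rsid[j])
    }
  }
  expect_setequal(cl2$index_rsid[cl2$is_index], oracle_idx)
})

test_that("MHC collapse keeps the most median index (lower median on even counts)", {
  mk <- function(pos) {
    n <- length(pos)
    data.frame(clump = seq_len(n), index_rsid = sprintf("i%d", seq_len(n)),
               rsid = sprintf("i%d", seq_len(n)), chrom = "chr6", pos = pos,
               p = 1e-8, is_index = TRUE, stringsAsFactors = FALSE)
  }
  inside <- 28477797 + c(1e5, 2e5, 3e5)
  out3 <- mhcCollapse(mk(inside))
  expect_equal(out3$pos, inside[2])
  four <- 28477797 + c(1e5, 2e5, 3e5, 4e5)
  out4 <- mhcCollapse(mk(four))
  expect_equal(out4$pos, four[2])          # lower median
  ## 0 or 1 MHC clump, or indices outside the region: identity
  expect_identical(mhcCollapse(mk(1e6)), mk(1e6))
  outside <- mk(c(1e6, 2e6))
  expect_identical(mhcCollapse(outside), outside)
  ## non-MHC clumps survive alongside the median one
  mixed <- rbind(mk(inside), transform(mk(1e6), clump = 9, index_rsid = "z",
                                       rsid = "z"))
  kept <- mhcCollapse(mixed)
  expect_setequal(kept$pos, c(inside[2], 1e6))
})

test_that("locus definition spans linked SNPs with strict r2 > 0.5 within 250 kb", {
  idx <- .mkSnps("I", 1e6, 1e-8)
  others <- .mkSnps(c("L1", "L2", "far", "weak"),
                    c(1e6 - 1e5, 1e6 + 1e5, 1e6 + 3e5, 1e6 + 5e4),
                    0.01)
  snps <- rbind(idx, others)
  r2 <- data.frame(rsid_a = "I", rsid_b = c("L1", "L2", "far", "weak"),
                   r2 = c(0.8, 0.9, 0.9, 0.5))
  loci <- defineLoci(idx, snps, r2)
  expect_equal(start(loci), 9e5)
  expect_equal(end(loci), 1.1e6)           # 200 kb span + 1 base
  expect_equal(width(loci), 2e5 + 1)
  expect_equal(mcols(loci)$n_snps, 3)      # index + L1 + L2; r2 == 0.5 excluded
  ## no linked SNPs: single-base locus
  solo <- defineLoci(idx, idx, data.frame(rsid_a = character(),
                                          rsid_b = character(), r2 = numeric()))
  expect_equal(width(solo), 1)
})

test_that("interval enrichment is calibrated, deterministic and detects planted co-location", {
  set.seed(53)
  reference <- GRanges("chrS1", IRanges(seq(1e4, 2e6, by = 4e4), width = 500))
  names(reference) <- sprintf("n%03d", seq_along(reference))
  loci <- GRanges("chrS1", IRanges(seq(1e4, 4e5, by = 1e5), width = 3e4))
  ## targets == reference: statistic equals its own null, p = 1
  r_all <- intervalEnrichment(reference, reference, loci, nPerm = 200, seed = 1)
  expect_equal(r_all$empirical_p, 1)
  ## loci covering everything: p = 1
  whole <- GRanges("chrS1", IRanges(1, 3e6))
  r_whole <- intervalEnrichment(reference[1:5], reference, whole,
                                nPerm = 200, seed = 1)
  expect_equal(r_whole$empirical_p, 1)
  ## determinism under a fixed seed
  a <- intervalEnrichment(reference[1:10], reference, loci, nPerm = 300, seed = 9)
  b <- intervalEnrichment(reference[1:10], reference, loci, nPerm = 300, seed = 9)
  expect_identical(a$empirical_p, b$empirical_p)
  expect_identical(a$null, b$null)
  ## planted co-location: all targets inside loci, reference mostly outside
  inside <- reference[IRanges::overlapsAny(reference, loci)]
  r_pl <- intervalEnrichment(inside, reference, loci, nPerm = 1000, seed = 3)
  expect_lte(r_pl$empirical_p, 0.01)
  ## sex-chromosome guard
  sexy <- c(reference[1:5], GRanges("chrSY", IRanges(1, 100)))
  names(sexy) <- c(names(reference[1:5]), "ny")
  expect_message(intervalEnrichment(sexy, c(reference, sexy[6]), loci,
                                    nPerm = 100, seed = 1), "sex")
})

test_that("family-wise corrected p is never below the empirical p and respects the round structure", {
  set.seed(59)
  reference <- GRanges("chrS1", IRanges(seq(1e4, 2e6, by = 4e4), width = 500))
  names(reference) <- sprintf("n%03d", seq_along(reference))
  loci <- list(s1 = GRanges("chrS1", IRanges(c(1e4, 2e5), width = 5e4)),
               s2 = GRanges("chrS1", IRanges(c(1e4, 2e5, 4e5), width = 5e4)))
  sets <- list(t1 = reference[1:8], t2 = reference[20:27])
  fam <- enrichLociFamily(sets, reference, loci, nPerm = 400, seed = 7)
  expect_equal(nrow(fam), 4)
  expect_true(all(fam$corrected_p >= fam$empirical_p))
  expect_true(all(fam$empirical_p > 0 & fam$empirical_p <= 1))
  fam2 <- enrichLociFamily(sets, reference, loci, nPerm = 400, seed = 7)
  expect_identical(fam$empirical_p, fam2$empirical_p)
  expect_identical(fam$corrected_p, fam2$corrected_p)
})
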