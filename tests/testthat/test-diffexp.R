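test_that("TMM factors behave analytically and match edgeR within 1e-8", {
  set.seed(21)
  base <- matrix(rnbinom(180, mu = 60, size = 5), 30, 6,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
  ## identical columns: all factors 1
  same <- base[, rep(1, 4)]
  colnames(same) <- paste0("c", 1:4)
  expect_equal(tmmFactors(same)$factor, rep(1, 4))
  ## doubling one column is absorbed by library size
  dbl <- cbind(base[, 1, drop = FALSE] * 2L, base[, 1, drop = FALSE])
  colnames(dbl) <- c("a", "b")
  expect_equal(tmmFactors(dbl)$factor, c(1, 1), tolerance = 1e-12)
  ## independent reference implementation of the published formula
  skip_if_not_installed("edgeR")
  f_ref <- edgeR::calcNormFactors(base, method = "TMM")
  expect_equal(unname(tmmFactors(base)$factor), unname(f_ref),
               tolerance = 1e-8)
  ## scaling one sample leaves M and A unchanged; only the precision
  ## weights shift, so factors are invariant up to that second-order term
  sc <- base; sc[, 3] <- sc[, 3] * 5L
  expect_equal(tmmFactors(sc)$factor, tmmFactors(base)$factor,
               tolerance = 0.02)
  ## geometric mean is 1
  expect_equal(exp(mean(log(tmmFactors(base)$factor))), 1, tolerance = 1e-9)
  expect_error(tmmFactors(cbind(base, z = 0L)), "all-zero")
})

test_that("log-CPM applies log2(1e6 x count / effective library + 0.5)", {
  m <- matrix(c(0, 10, 100, 5), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  f <- tmmFactors(m + 1)  # any valid factor table
  lc <- assay(logCpm(m, f))
  eff <- f$eff_lib_size
  expect_equal(lc["a", "s1"], log2(0 + 0.5))            # zero count -> -1
  expect_equal(lc["b", "s1"], log2(1e6 * 10 / eff[1] + 0.5))
  ## count equal to 1e-6 of the effective library gives log2(1.5)
  m2 <- matrix(c(eff[1] * 1e-6, 1), 2, 1, dimnames = list(c("x", "y"), "s1"))
  lc2 <- assay(logCpm(m2, f[1, , drop = FALSE]))
  expect_equal(lc2["x", 1], log2(1.5), tolerance = 1e-9)
})

test_that("random-intercept REML reduces to OLS for singleton groups and matches lme4", {
  set.seed(31)
  n <- 40
  X <- cbind(`(Intercept)` = 1, x = rnorm(n), d = rep(0:1, n / 2))
  ## singleton groups: estimates equal OLS
  y <- as.vector(X %*% c(1, 0.3, 0.8) + rnorm(n))
  f <- fitRandomIntercept(y, X, group = seq_len(n), coef = "d")
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(f$effect, unname(coef(ols)[3]), tolerance = 1e-8)
  ## grouped data: agree with lme4 REML
  skip_if_not_installed("lme4")
  g <- factor(rep(1:20, each = 2))
  y2 <- as.vector(X %*% c(1, 0.3, 0.8)) + rnorm(20, 0, 0.5)[g] + rnorm(n, 0, 0.6)
  f2 <- fitRandomIntercept(y2, X, g, coef = "d")
  m <- lme4::lmer(y2 ~ X[, 2] + X[, 3] + (1 | g), REML = TRUE)
  expect_equal(f2$effect, unname(lme4::fixef(m)[3]), tolerance = 1e-5)
  expect_equal(f2$se, coef(summary(m))[3, 2], tolerance = 1e-4)
  ## singular design errors with the aliased column named
  Xs <- cbind(X, d2 = X[, "d"])
  expect_error(fitRandomIntercept(y2, Xs, g), "aliased.*d2")
})

test_that("mixed-model fixed effect is recovered without bias on planted data", {
  ## planted log2 fold change 1.0, n = 200 samples, intercept SD 0.3;
  ## mean estimate over replicates must sit within 0.05 of truth
  set.seed(41)
  n <- 200; reps <- 100   # scaled from the illustrative 200 reps; same bound
  g <- factor(rep(seq_len(n / 2), each = 2))
  d <- rep(0:1, n / 2)
  X <- cbind(`(Intercept)` = 1, d = d)
  est <- replicate(reps, {
    y <- 2 + d * 1.0 + rnorm(nlevels(g), 0, 0.3)[g] + rnorm(n, 0, 0.8)
    fitRandomIntercept(y, X, g, coef = "d")$effect
  })
  expect_lt(abs(mean(est) - 1.0), 0.05)
})

test_that("BH adjustment equals its brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  ## brute force, direct from the step-up definition
  bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    vapply(seq_len(m), function(k) {
      i <- which(o == k)  # rank of p[k]
      min(1, min(m * p[o][seq(i, m)] / seq(i, m)))
    }, 0)
  }
  set.seed(51)
  for (r in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_equal(bhAdjust(p), bruteBH(p))
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
  }
  ## NA propagation: excluded from m
  p <- c(0.01, NA, 0.04)
  q <- bhAdjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bhAdjust(c(0.01, 0.04)))
})

test_that("Fisher two-tailed p sums hypergeometric probabilities at fixed margins", {
  expect_equal(fisherEnrichment(1, 1, 1, 1)$odds_ratio, 1)
  expect_equal(fisherEnrichment(1, 1, 1, 1)$p, 1)
  expect_equal(fisherEnrichment(2, 0, 0, 2)$p, 1 / 3)  # 3-table enumeration
  expect_error(fisherEnrichment(0, 0, 3, 4), "margin")
  ## random small tables vs full enumeration and fisher.test
  enumP <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    xs <- max(0, c1 - r2):min(r1, c1)
    pr <- vapply(xs, function(x) dhyper(x, r1, r2, c1), 0)
    obs <- dhyper(a, r1, r2, c1)
    sum(pr[pr <= obs * (1 + 1e-12)])
  }
  set.seed(61)
  for (r in 1:100) {
    t_ <- rpois(4, 5) + 1
    got <- fisherEnrichment(t_[1], t_[2], t_[3], t_[4])
    expect_equal(got$p, enumP(t_[1], t_[2], t_[3], t_[4]))
    ft <- fisher.test(matrix(t_, 2, byrow = TRUE))
    expect_equal(got$p, ft$p.value, tolerance = 1e-6)
  }
})

test_that("DE nORF mapping inherits transcript direction and is monotone in the threshold", {
  de <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   effect = c(1, -2, 0.5), se = 1,
                   p = c(0.001, 0.002, 0.2), q = c(0.01, 0.02, 0.4),
                   direction = c("up", "down", "up"))
  matches <- data.frame(norf_id = c("nA", "nA", "nB"),
                        transcript_id = c("t1", "t2", "t3"),
                        match_class = "contained", biotype = "lincRNA")
  r <- deNorfs(de, matches, qThreshold = 0.05)
  expect_equal(r$norfs$direction[r$norfs$norf_id == "nA"], "both")
  expect_equal(r$summary$n_de_transcripts, 2)
  r2 <- deNorfs(de, matches, qThreshold = 0.5)
  expect_gte(nrow(r2$norfs), nrow(r$norfs))
  expect_true("nB" %in% r2$norfs$norf_id)
  ## no transcript below threshold: empty table
  r0 <- deNorfs(de, matches, qThreshold = 1e-6)
  expect_equal(nrow(r0$norfs), 0)
  ## two conditions: intersection reported
  r3 <- deNorfs(list(A = de, B = de), matches, 0.05)
  expect_equal(r3$intersection, "nA")
})

test_that("sex QC flags metadata mislabels via XIST clustering", {
  set.seed(71)
  n <- 20
  sex <- rep(c("M", "F"), each = n / 2)
  m <- rbind(XIST = ifelse(sex == "F", 8, 0) + rnorm(n, 0, 0.2),
             chrY1 = ifelse(sex == "M", 6, 0) + rnorm(n, 0, 0.2),
             chrY2 = ifelse(sex == "M", 5, 0) + rnorm(n, 0, 0.2))
  colnames(m) <- sprintf("s%02d", 1:n)
  oe <- OrfExperiment(m - min(m), colData = DataFrame(sex = sex), unit = "TPM")
  r <- sexQc(oe, chrYFeatureIds = c("chrY1", "chrY2"), xistId = "XIST")
  expect_false(any(r$flagged))
  ## relabel one male as female: exactly that sample flagged
  sex2 <- sex; sex2[2] <- "F"
  r2 <- sexQc(oe, chrYFeatureIds = c("chrY1", "chrY2"), xistId = "XIST",
              sex = sex2)
  expect_identical(which(r2$flagged), 2L)
  ## constant XIST: degenerate clustering, warning, nothing flagged
  m3 <- m; m3["XIST", ] <- 1
  oe3 <- OrfExperiment(m3 - min(m3), colData = DataFrame(sex = sex), unit = "TPM")
  expect_warning(r3 <- sexQc(oe3, c("chrY1", "chrY2"), "XIST"), "constant")
  expect_false(any(r3$flagged))
})
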