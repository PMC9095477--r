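## Normalization and per-transcript differential expression: TMM scaling
## factors, log2(CPM + 0.5), a random-intercept linear mixed model fitted by
## profiled REML with a Wald t test, Benjamini-Hochberg FDR control, the
## mapping of DE transcripts onto DE nORFs, the Fisher sanity check, and the
## chrY/XIST sex-metadata QC.

#' Trimmed mean of M-values normalization factors
#'
#' Implements the published TMM scheme: the reference sample is the one whose
#' upper-quartile of library-size-normalized counts is closest to the mean
#' upper-quartile; per sample, log2 expression ratios (M) and average log2
#' abundances (A) against the reference are computed over features positive
#' in both, doubly trimmed (30% on M, 5% on A by default), and the factor is
#' 2 to the precision-weighted mean of the surviving M values. Factors are
#' rescaled to geometric mean 1, so effective library size = library size x
#' factor.
#'
#' @param counts Numeric matrix of raw counts (features x samples) or an
#'   [OrfExperiment] with unit `"count"`.
#' @param refSample Optional reference column (index or name); default
#'   automatic as above.
#' @param logratioTrim,absTrim Trim fractions for M and A.
#' @param aCutoff Lower A cutoff.
#' @return `data.frame` with one row per sample: `sample_id`, `lib_size`,
#'   `factor`, `eff_lib_size`.
#' @export
tmmFactors <- function(counts, refSample = NULL, logratioTrim = 0.3,
                       absTrim = 0.05, aCutoff = -1e10) {
  x <- if (is(counts, "OrfExperiment")) assay(counts) else as.matrix(counts)
  if (ncol(x) < 2L) stop("at least 2 samples required")
  lib <- colSums(x)
  if (any(lib == 0)) stop("sample(s) with all-zero counts: ",
                          paste(colnames(x)[lib == 0], collapse = ", "))
  f75 <- apply(x, 2L, stats::quantile, probs = 0.75) / lib
  ref <- if (!is.null(refSample)) {
    if (is.character(refSample)) match(refSample, colnames(x)) else refSample
  } else if (stats::median(f75) < 1e-20) {
    which.max(colSums(sqrt(x)))
  } else which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(i)
    .tmmPair(x[, i], x[, ref], lib[i], lib[ref],
             logratioTrim, absTrim, aCutoff), 0)
  f <- f / exp(mean(log(f)))
  data.frame(sample_id = colnames(x), lib_size = lib, factor = f,
             eff_lib_size = lib * f, row.names = colnames(x),
             stringsAsFactors = FALSE)
}

.tmmPair <- function(obs, ref, nO, nR, logratioTrim, absTrim, aCutoff) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > aCutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * absTrim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' log2 counts per million with a prior count
#'
#' `log2(1e6 * count / effective_library_size + prior)`, with effective
#' library sizes from [tmmFactors()].
#'
#' @param counts Count matrix or [OrfExperiment] (unit `"count"`).
#' @param factors Normalization table from [tmmFactors()]; default computed.
#' @param prior Prior count added inside the log (default 0.5).
#' @return An `OrfExperiment` with unit `"logCPM"`.
#' @export
logCpm <- function(counts, factors = tmmFactors(counts), prior = 0.5) {
  x <- if (is(counts, "OrfExperiment")) assay(counts) else as.matrix(counts)
  eff <- factors$eff_lib_size[match(colnames(x), factors$sample_id)]
  if (any(eff <= 0) || anyNA(eff)) stop("effective library sizes must be positive")
  val <- log2(sweep(x, 2L, eff, "/") * 1e6 + prior)
  cd <- if (is(counts, "OrfExperiment")) colData(counts) else NULL
  OrfExperiment(val, colData = cd, unit = "logCPM")
}

## ---------------------------------------------------------------------------
## Random-intercept linear mixed model (profiled REML)
## ---------------------------------------------------------------------------

#' Fit a linear model with one random intercept per individual
#'
#' Fits `y = X beta + b[group] + e`, `b ~ N(0, sigma_b^2)`, by REML: the
#' variance ratio `lambda = sigma_b^2 / sigma_e^2` is profiled out with a 1-D
#' optimization, exploiting the block-diagonal marginal covariance
#' `V = I + lambda Z Z'`. The coefficient of interest is tested with a Wald t
#' statistic on `n - rank(X) - 1` residual degrees of freedom. When every
#' group has a single sample the estimates reduce exactly to ordinary least
#' squares.
#'
#' @param y Numeric response vector (e.g. one transcript's log-CPM values).
#' @param X Design matrix (with intercept), full rank.
#' @param group Factor (or coercible) of individual ids along `y`.
#' @param coef Column of `X` to test (name or index); default the last.
#' @return List: `effect`, `se`, `t`, `df`, `p`, `lambda` (variance ratio),
#'   `sigma2` (residual variance), `converged`, `ols_fallback`.
#' @export
fitRandomIntercept <- function(y, X, group, coef = ncol(X)) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(group) == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("singular design; aliased column(s): ", paste(aliased, collapse = ", "))
  }
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  p <- ncol(X)
  ng <- as.vector(table(group))
  ## sufficient statistics: only the per-group shrinkage weights depend on
  ## lambda, so the crossproducts are computed once
  XtX0 <- crossprod(X); Xty0 <- crossprod(X, y); yty0 <- sum(y * y)
  SX <- rowsum(X, group); Sy <- as.vector(rowsum(y, group))
  ## crossproducts under V^-1 = blockdiag(I - c_i J), c_i = lambda/(1+n_i*lambda)
  .gls <- function(lambda) {
    ci <- lambda / (1 + ng * lambda)
    XtX <- XtX0 - crossprod(SX, ci * SX)
    Xty <- Xty0 - crossprod(SX, ci * Sy)
    yty <- yty0 - sum(ci * Sy * Sy)
    ch <- chol(XtX)
    beta <- backsolve(ch, forwardsolve(t(ch), Xty))
    rss <- yty - sum(Xty * beta)
    list(beta = beta, rss = max(rss, 1e-300), XtX = XtX, chol = ch)
  }
  .negREML <- function(loglambda) {
    lambda <- exp(loglambda)
    fit <- .gls(lambda)
    sigma2 <- fit$rss / (n - p)
    logdetV <- sum(log(1 + ng * lambda))
    logdetXtX <- 2 * sum(log(diag(fit$chol)))
    (n - p) * log(sigma2) + logdetV + logdetXtX
  }
  res <- tryCatch({
    opt <- stats::optimize(.negREML, interval = c(-14, 14))
    lam <- exp(opt$minimum)
    if (.negREML(-30) <= opt$objective) lam <- 0   # boundary: no group variance
    list(lambda = lam, converged = TRUE)
  }, error = function(e) list(lambda = 0, converged = FALSE))
  fit <- .gls(res$lambda)
  sigma2 <- fit$rss / (n - p)
  covb <- chol2inv(fit$chol) * sigma2
  k <- if (is.character(coef)) match(coef, colnames(X)) else coef
  if (is.na(k)) stop("coefficient '", coef, "' not found in design")
  eff <- fit$beta[k]
  se <- sqrt(covb[k, k])
  df <- n - p - 1
  tval <- eff / se
  list(effect = eff, se = se, t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df),
       lambda = res$lambda, sigma2 = sigma2,
       converged = res$converged, ols_fallback = !res$converged)
}

#' Per-transcript mixed-model differential expression
#'
#' Fits [fitRandomIntercept()] to every row of a log-CPM matrix with a design
#' built from sample metadata, tests the diagnosis contrast, and controls the
#' FDR with [bhAdjust()]. Rows with zero variance are skipped and reported in
#' the `skipped` attribute.
#'
#' @param x [OrfExperiment] with unit `"logCPM"` (rows = transcripts).
#' @param design Model formula evaluated on `colData(x)` (or a data frame
#'   passed as `data`); must include the diagnosis term.
#' @param coef Name of the design-matrix column to test
#'   (e.g. `"diagnosiscase_A"`).
#' @param group Vector of individual ids along samples; default
#'   `colData(x)$individual_id`.
#' @param data Optional data frame overriding `colData(x)`.
#' @return `data.frame`: `transcript_id`, `effect` (log2 scale), `se`, `p`,
#'   `q` (BH-adjusted), `direction` (`up`/`down`). Attribute `skipped` lists
#'   zero-variance transcripts.
#' @export
fitMixedModels <- function(x, design, coef, group = NULL, data = NULL) {
  stopifnot(is(x, "OrfExperiment"))
  if (expressionUnit(x) != "logCPM")
    stop("fitMixedModels expects unit 'logCPM'")
  if (is.null(data)) data <- as.data.frame(colData(x))
  if (is.null(group)) group <- data$individual_id
  X <- stats::model.matrix(design, data = data)
  m <- assay(x)
  zerovar <- apply(m, 1L, function(v) stats::var(v) == 0)
  rows <- which(!zerovar)
  out <- data.frame(
    transcript_id = rownames(m)[rows],
    effect = NA_real_, se = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE)
  for (r in seq_along(rows)) {
    f <- fitRandomIntercept(m[rows[r], ], X, group, coef = coef)
    out$effect[r] <- f$effect; out$se[r] <- f$se; out$p[r] <- f$p
  }
  out$q <- bhAdjust(out$p)
  out$direction <- ifelse(out$effect >= 0, "up", "down")
  attr(out, "skipped") <- rownames(m)[zerovar]
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1, where `m` counts
#' the non-missing p-values. `NA` inputs propagate and are excluded from `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  pv <- p[ok]
  stopifnot(all(pv >= 0 & pv <= 1))
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m * pv[o] / (m:1)))
  q[ok][o] <- adj
  q
}

#' Map differentially expressed transcripts onto DE nORFs
#'
#' DE transcripts are those with `q < qThreshold`; a DE nORF is any nORF
#' matched (via [matchNorfs()]) to at least one DE transcript, inheriting the
#' transcript's direction. An nORF matched to both an up- and a
#' down-regulated transcript is reported with direction `both`. With several
#' conditions the cross-condition intersection of DE nORF ids is reported.
#'
#' @param deResults A `data.frame` from [fitMixedModels()] or a named list of
#'   them (one per condition).
#' @param matches Match table from [matchNorfs()].
#' @param qThreshold FDR threshold (default 0.05).
#' @return List: `norfs` (condition, norf_id, direction), `summary`
#'   (condition, n_de_transcripts, n_up, n_down, n_de_with_norf, n_de_norfs),
#'   `intersection` (nORF ids DE in every condition).
#' @export
deNorfs <- function(deResults, matches, qThreshold = 0.05) {
  if (is.data.frame(deResults)) deResults <- list(condition = deResults)
  norf_rows <- list(); summ_rows <- list()
  for (cond in names(deResults)) {
    de <- deResults[[cond]]
    sig <- de[!is.na(de$q) & de$q < qThreshold, , drop = FALSE]
    hit <- matches[matches$transcript_id %in% sig$transcript_id, , drop = FALSE]
    dir_tx <- stats::setNames(sig$direction, sig$transcript_id)
    if (nrow(hit)) {
      dirs <- tapply(dir_tx[hit$transcript_id], hit$norf_id,
                     function(d) if (length(unique(d)) > 1L) "both" else d[1])
      norf_rows[[cond]] <- data.frame(
        condition = cond, norf_id = names(dirs), direction = unname(dirs),
        stringsAsFactors = FALSE)
    }
    n_norf <- if (nrow(hit)) length(unique(hit$norf_id)) else 0L
    summ_rows[[cond]] <- data.frame(
      condition = cond,
      n_de_transcripts = nrow(sig),
      n_up = sum(sig$direction == "up"),
      n_down = sum(sig$direction == "down"),
      n_de_with_norf = length(unique(hit$transcript_id)),
      n_de_norfs = n_norf,
      stringsAsFactors = FALSE)
  }
  norfs <- if (length(norf_rows)) {
    do.call(rbind, norf_rows)
  } else {
    data.frame(condition = character(), norf_id = character(),
               direction = character(), stringsAsFactors = FALSE)
  }
  rownames(norfs) <- NULL
  sets <- lapply(names(deResults), function(cond)
    norfs$norf_id[norfs$condition == cond])
  inter <- if (length(sets)) sort(Reduce(intersect, sets)) else character()
  list(norfs = norfs, summary = do.call(rbind, summ_rows), intersection = inter)
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Odds ratio is the sample cross-product ratio `(a d) / (b c)` (infinite or
#' zero on empty off-diagonal cells). The two-tailed p-value sums the
#' hypergeometric probabilities, at fixed margins, of every table whose
#' probability does not exceed the observed table's (relative tolerance
#' 1e-12).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return List: `odds_ratio`, `p`.
#' @examples
#' fisherEnrichment(2, 0, 0, 2)$p  # 1/3
#' @export
fisherEnrichment <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("zero margin: test undefined")
  or <- (a * d) / (b * c)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
  list(odds_ratio = or, p = p)
}

#' Sex-metadata QC from chrY expression and XIST clustering
#'
#' Reports mean chrY feature expression per sample, single-linkage clusters
#' XIST expression into two groups, assigns each cluster the majority sex of
#' its members' metadata, and flags samples whose cluster-majority sex
#' disagrees with their own metadata label. Constant XIST expression makes
#' the clustering degenerate: a warning is raised and nothing is flagged.
#'
#' @param x [OrfExperiment] (any unit).
#' @param sex Character vector of metadata sex labels along samples; default
#'   `colData(x)$sex`.
#' @param chrYFeatureIds Feature ids on chrY (non-empty).
#' @param xistId Feature id of XIST; if absent, a chrY-only report is
#'   returned with a warning.
#' @return `data.frame`: `sample_id`, `mean_chrY`, `xist`, `cluster`,
#'   `metadata_sex`, `cluster_sex`, `flagged`.
#' @export
sexQc <- function(x, chrYFeatureIds, xistId = "XIST", sex = colData(x)$sex) {
  stopifnot(is(x, "OrfExperiment"), length(chrYFeatureIds) > 0)
  m <- assay(x)
  ychr <- intersect(chrYFeatureIds, rownames(m))
  if (!length(ychr)) stop("none of chrYFeatureIds present in the matrix")
  mean_y <- colMeans(m[ychr, , drop = FALSE])
  out <- data.frame(sample_id = colnames(m), mean_chrY = mean_y,
                    xist = NA_real_, cluster = NA_integer_,
                    metadata_sex = as.character(sex),
                    cluster_sex = NA_character_, flagged = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!xistId %in% rownames(m)) {
    warning("XIST feature '", xistId, "' absent; chrY-only report")
    return(out)
  }
  xist <- m[xistId, ]
  out$xist <- xist
  if (stats::var(xist) == 0) {
    warning("constant XIST expression; clustering degenerate, nothing flagged")
    return(out)
  }
  hc <- stats::hclust(stats::dist(xist), method = "single")
  cl <- stats::cutree(hc, k = 2)
  out$cluster <- cl
  for (k in 1:2) {
    tab <- table(out$metadata_sex[cl == k])
    top <- names(tab)[tab == max(tab)]
    out$cluster_sex[cl == k] <- if (length(top) == 1L) top else NA_character_
  }
  out$flagged <- !is.na(out$cluster_sex) & out$cluster_sex != out$metadata_sex
  out
}
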