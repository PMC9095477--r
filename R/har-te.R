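## HAR/TE work: merging multi-source HAR compilations with provenance,
## windowed nORF-HAR association, strand-aware upstream nORF-TE association,
## DE designation by DE-transcript span overlap, dual Pearson/Spearman
## expression-correlation screening, and chi-square presence tests.

.HAR_GROUPS <- c("vHAR", "mHAR", "pHAR")

#' Merge multi-source HAR lists into unique HARs
#'
#' Overlapping (or bookended) HARs from all sources are merged into unique
#' HARs; each merged interval keeps its member records and the set of
#' conservation groups they carry (vHAR = conserved in vertebrates, mHAR =
#' mammals, pHAR = non-human primates). A unique HAR containing members of
#' several groups counts toward each, so per-group fractions may exceed 100%
#' in total.
#'
#' @param hars A named `GRanges` with `mcols()` columns `source` and `group`
#'   (each group one of vHAR/mHAR/pHAR), or a list of such `GRanges` (one per
#'   source) which is concatenated first.
#' @return A `GRanges` of unique HARs with `mcols()`: `members`
#'   (CharacterList), `sources` (CharacterList), `group_set` (comma-collapsed
#'   sorted group subset). Attribute `summary` holds the unique count and
#'   per-group fractions.
#' @export
buildUniqueHars <- function(hars) {
  if (is.list(hars) && !is(hars, "GRanges"))
    hars <- do.call(c, unname(hars))
  stopifnot(is(hars, "GRanges"))
  md <- mcols(hars)
  if (is.null(md$group) || is.null(md$source))
    stop("HAR input needs 'source' and 'group' metadata columns")
  bad <- !(md$group %in% .HAR_GROUPS)
  if (any(bad))
    stop("unknown conservation group label(s): ",
         paste(unique(md$group[bad]), collapse = ", "))
  merged <- mergeIntervals(hars)
  rev <- mcols(merged)$revmap
  mcols(merged)$sources <- IRanges::extractList(md$source, rev)
  grp <- IRanges::extractList(md$group, rev)
  mcols(merged)$group_set <- vapply(grp, function(g)
    paste(intersect(.HAR_GROUPS, unique(g)), collapse = ","), "")
  names(merged) <- paste0("uHAR_", seq_along(merged))
  n <- length(merged)
  frac <- vapply(.HAR_GROUPS, function(g)
    mean(vapply(grp, function(gs) g %in% gs, TRUE)), 0)
  attr(merged, "summary") <- data.frame(
    n_unique = n, group = .HAR_GROUPS, fraction = frac,
    stringsAsFactors = FALSE)
  merged
}

#' Associate nORFs with HARs within a window
#'
#' A HAR is associated with an nORF iff it overlaps the nORF span extended by
#' `window` bases on both sides (gap exactly equal to the window still
#' associates; `window = 0` degenerates to pure overlap, so abutting
#' intervals do not pair). Relation is `overlap` when the HAR intersects the span
#' itself, otherwise `within_window`; the signed distance is 0 on overlap,
#' negative for HARs left of the span, positive for HARs right of it.
#' Strand-agnostic.
#'
#' @param norfs A [NorfSet] (or a `GRanges` of spans).
#' @param hars `GRanges` of (unique) HARs.
#' @param window Window size in bases (default 100 kb; the sensitivity
#'   analysis uses 1 kb).
#' @return `data.frame`: `norf_id`, `feature_id`, `relation`, `distance`.
#' @export
associateNorfHar <- function(norfs, hars, window = 100000) {
  stopifnot(window >= 0)
  sp <- if (is(norfs, "NorfSet")) featureSpans(norfs) else norfs
  ## gap == window associates; window 0 degenerates to pure overlap
  hits <- findOverlaps(sp, hars, maxgap = if (window > 0) window else -1L,
                       ignore.strand = TRUE)
  qi <- queryHits(hits); sj <- subjectHits(hits)
  ov <- intervalsOverlap(sp[qi], hars[sj])
  gap <- intervalDistance(sp[qi], hars[sj])
  sign <- ifelse(end(hars)[sj] < start(sp)[qi], -1, 1)
  fid <- if (!is.null(names(hars))) names(hars)[sj] else as.character(sj)
  out <- data.frame(
    norf_id = names(sp)[qi], feature_id = fid,
    relation = ifelse(ov, "overlap", "within_window"),
    distance = ifelse(ov, 0, sign * gap),
    stringsAsFactors = FALSE)
  out[order(out$norf_id, out$feature_id), , drop = FALSE]
}

#' Associate nORFs with TEs in the 2 kb upstream window
#'
#' The upstream window is strand-aware: the 2 kb immediately before the nORF
#' span start on the plus strand, immediately after the span end on the minus
#' strand. A TE is associated iff it overlaps the window and does not overlap
#' the nORF span itself. Unstranded nORFs are an error unless
#' `strandAware = FALSE`, in which case the window is taken left of the span.
#'
#' @param norfs A [NorfSet] (or a stranded `GRanges` of spans).
#' @param tes `GRanges` of TEs.
#' @param upstreamWindow Window size in bases (default 2000).
#' @param strandAware Use the nORF strand to orient the window.
#' @return `data.frame`: `norf_id`, `feature_id`, `relation` (`upstream`),
#'   `distance` (signed gap from span, negative upstream on plus strand).
#' @export
associateNorfTe <- function(norfs, tes, upstreamWindow = 2000,
                            strandAware = TRUE) {
  sp <- if (is(norfs, "NorfSet")) featureSpans(norfs) else norfs
  str <- as.character(strand(sp))
  if (strandAware && any(str == "*"))
    stop("unstranded nORF(s): upstream window undefined")
  minus <- strandAware & str == "-"
  win_start <- ifelse(minus, end(sp) + 1L,
                      pmax(1L, start(sp) - upstreamWindow))
  win_end <- ifelse(minus, end(sp) + upstreamWindow, start(sp) - 1L)
  ok <- win_end >= win_start
  win <- GRanges(seqnames(sp)[ok], IRanges(win_start[ok], win_end[ok]))
  names(win) <- names(sp)[ok]
  hits <- findOverlaps(win, tes, ignore.strand = TRUE)
  qi <- queryHits(hits); sj <- subjectHits(hits)
  sp_q <- sp[match(names(win)[qi], names(sp))]
  keep <- !intervalsOverlap(sp_q, tes[sj])
  qi <- qi[keep]; sj <- sj[keep]; sp_q <- sp_q[keep]
  gap <- intervalDistance(sp_q, tes[sj])
  sign <- ifelse(end(tes)[sj] < start(sp_q), -1, 1)
  fid <- if (!is.null(names(tes))) names(tes)[sj] else as.character(sj)
  out <- data.frame(
    norf_id = names(win)[qi], feature_id = fid,
    relation = rep_len("upstream", length(qi)), distance = sign * gap,
    stringsAsFactors = FALSE)
  out[order(out$norf_id, out$feature_id), , drop = FALSE]
}

#' Designate DE HARs / DE TEs by DE-transcript overlap
#'
#' A feature is flagged DE iff it overlaps the genomic span (start to end,
#' introns included) of at least one differentially expressed transcript;
#' set `exonLevel = TRUE` to require overlap with the exon union instead.
#'
#' @param features `GRanges` of HARs or TEs.
#' @param deTranscripts A [TranscriptSet] (already subset to DE transcripts)
#'   or a `GRanges`/`GRangesList` of DE transcript structures.
#' @param exonLevel Overlap against exons rather than spans.
#' @return The `features` with a logical `de` metadata column; attribute
#'   `n_de_transcripts_with_feature` counts DE transcripts containing at
#'   least one feature.
#' @export
designateDeFeatures <- function(features, deTranscripts, exonLevel = FALSE) {
  target <- if (is(deTranscripts, "TranscriptSet")) {
    if (exonLevel) unlist(txExons(deTranscripts), use.names = FALSE)
    else featureSpans(deTranscripts)
  } else if (is(deTranscripts, "GRangesList")) {
    if (exonLevel) unlist(deTranscripts, use.names = FALSE)
    else .spansOf(deTranscripts)
  } else deTranscripts
  mcols(features)$de <- IRanges::overlapsAny(features, target,
                                             ignore.strand = TRUE)
  attr(features, "n_de_transcripts_with_feature") <-
    sum(IRanges::overlapsAny(target, features, ignore.strand = TRUE))
  features
}

## Pearson r with t-transform p; Spearman = Pearson on average ranks.
.corT <- function(u, v) {
  n <- length(u)
  r <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  r <- max(-1, min(1, r))
  tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

#' Screen DE nORF / DE TE pairs for correlated expression
#'
#' For each candidate pair, Pearson and Spearman correlations of the two
#' features' expression across samples are computed (Spearman as Pearson on
#' average ranks; both p-values via the t transform on n-2 df). A pair is
#' significant iff |r| > 0.5 AND |rho| > 0.5 AND both p < 0.05. Pairs
#' involving a zero-variance vector are reported with `NA` correlations and
#' `significant = FALSE`.
#'
#' @param x [OrfExperiment] holding normalized expression for both nORFs and
#'   TEs (TE expression is typically inherited from the containing DE
#'   transcript).
#' @param pairs `data.frame` with columns `norf_id`, `te_id` naming rows of
#'   `x`.
#' @param rMin Magnitude gate (default 0.5).
#' @param pMax Significance gate (default 0.05).
#' @return `data.frame`: `norf_id`, `te_id`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `significant`.
#' @export
correlatePairs <- function(x, pairs, rMin = 0.5, pMax = 0.05) {
  m <- if (is(x, "OrfExperiment")) assay(x) else as.matrix(x)
  if (ncol(m) < 4L) stop("need n >= 4 samples")
  out <- data.frame(pairs[c("norf_id", "te_id")],
                    pearson_r = NA_real_, pearson_p = NA_real_,
                    spearman_rho = NA_real_, spearman_p = NA_real_,
                    significant = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    u <- m[pairs$norf_id[i], ]; v <- m[pairs$te_id[i], ]
    if (stats::var(u) == 0 || stats::var(v) == 0) next
    pe <- .corT(u, v)
    sp <- .corT(rank(u), rank(v))
    out$pearson_r[i] <- pe$r; out$pearson_p[i] <- pe$p
    out$spearman_rho[i] <- sp$r; out$spearman_p[i] <- sp$p
    out$significant[i] <- abs(pe$r) > rMin && abs(sp$r) > rMin &&
      pe$p < pMax && sp$p < pMax
  }
  out
}

#' Chi-square test of presence/absence across metadata groups
#'
#' Pearson chi-square (no continuity correction) on the presence x group
#' contingency table, with `(r-1)(c-1)` degrees of freedom, plus the
#' conventional star label (`*` < 0.05, `**` < 0.01, `***` < 0.001).
#'
#' @param presence Logical (or yes/no) vector, one entry per sample.
#' @param groups Group label per sample (>= 2 non-empty groups).
#' @return List: `statistic`, `df`, `p`, `stars`.
#' @export
chisqPresence <- function(presence, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  presence <- factor(as.logical(presence), levels = c(FALSE, TRUE))
  tab <- table(presence, groups)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use <- rowSums(tab) > 0
  stat <- sum((tab[use, ] - exp_tab[use, ])^2 / exp_tab[use, ])
  df <- (sum(use) - 1) * (ncol(tab) - 1)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "N.S."
  list(statistic = stat, df = df, p = p, stars = stars)
}
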