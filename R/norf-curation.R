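## nORF database construction: TPM conversion of Ribo-seq counts, the
## quantile-binned low-noise filter against canonical-ORF baselines,
## frame-relative classification against annotated CDS, the in-frame removal
## rule with its category exceptions, and exon-chain deduplication.

#' Convert raw counts to transcripts per million
#'
#' Per sample, each feature's count is divided by its length to give a read
#' rate, and rates are rescaled so that every column sums to one million:
#' `TPM_i = 1e6 * (count_i / length_i) / sum_j (count_j / length_j)`.
#'
#' @param x An [OrfExperiment] with unit `"count"` and feature lengths in
#'   `rowData(x)$length` (or supplied via `lengths`).
#' @param lengths Optional numeric vector of feature lengths overriding
#'   `rowData(x)$length`.
#' @return An `OrfExperiment` with unit `"TPM"`.
#' @examples
#' m <- matrix(c(10, 90), 2, 1, dimnames = list(c("A", "B"), "s1"))
#' oe <- OrfExperiment(m, lengths = c(100, 900))
#' SummarizedExperiment::assay(countsToTpm(oe))  # both 5e5
#' @export
countsToTpm <- function(x, lengths = NULL) {
  stopifnot(is(x, "OrfExperiment"))
  if (expressionUnit(x) != "count")
    stop("countsToTpm expects unit 'count', got '", expressionUnit(x), "'")
  if (is.null(lengths)) lengths <- rowData(x)$length
  if (is.null(lengths) || anyNA(lengths))
    stop("feature lengths are required (rowData(x)$length or `lengths`)")
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  counts <- assay(x)
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero column(s): TPM undefined for sample(s) ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  OrfExperiment(tpm, colData = colData(x), lengths = lengths, unit = "TPM")
}

#' Quantile-binned low-noise filter for non-canonical ORFs
#'
#' All ORFs (canonical and non-canonical together) are sorted by mean
#' expression and cut into `Q` contiguous quantile bins of (near-)equal
#' occupancy, so that each bin holds ORFs of similar mean. Within each bin,
#' the median standard deviation of the canonical ORFs sets the noise
#' baseline; a non-canonical ORF is flagged low-noise iff its SD is strictly
#' below that bin's baseline. Bins containing no canonical ORF flag nothing
#' (their non-canonical members get `NA`) and are reported via the
#' `bins_without_corf` attribute.
#'
#' Ties in mean are broken by ORF id, so the flagged set is invariant to
#' input order. SD is the sample standard deviation (n-1 denominator).
#'
#' @param x An [OrfExperiment] (unit `"TPM"`) or a numeric matrix, ORFs x
#'   samples; at least two samples.
#' @param isCanonical Logical vector along rows: `TRUE` for canonical ORFs.
#' @param Q Number of quantile bins. Defaults to 4000, capped (with a
#'   warning) at the number of ORFs for small inputs; an explicitly supplied
#'   `Q` larger than the number of ORFs is an error.
#' @return A [S4Vectors::DataFrame] with one row per input ORF, in input
#'   order: `orf_id`, `mean`, `sd`, `bin`, `bin_median_corf_sd`, `low_noise`
#'   (`NA` for canonical ORFs and for bins without canonical members).
#'   Attribute `bins_without_corf` lists offending bin indices.
#' @export
lowNoiseFilter <- function(x, isCanonical, Q = 4000) {
  m <- if (is(x, "OrfExperiment")) assay(x) else as.matrix(x)
  n <- nrow(m)
  if (ncol(m) < 2L) stop("at least 2 samples required (SD undefined)")
  if (length(isCanonical) != n) stop("isCanonical must match rows")
  q_given <- !missing(Q)
  if (Q > n) {
    if (q_given) stop("Q (", Q, ") exceeds the number of ORFs (", n, ")")
    warning("Q = ", Q, " capped at n = ", n, " ORFs")
    Q <- n
  }
  if (Q < 1L) stop("Q must be >= 1")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  ord <- order(mu, ids)
  bin <- integer(n)
  bin[ord] <- as.integer(ceiling(seq_len(n) * Q / n))
  med <- rep(NA_real_, Q)
  for (b in unique(bin[isCanonical])) med[b] <- stats::median(sdv[isCanonical & bin == b])
  empty <- sort(setdiff(unique(bin), unique(bin[isCanonical])))
  if (length(empty))
    warning(length(empty), " bin(s) contain no canonical ORF; their nORFs are unflagged")
  binmed <- med[bin]
  low <- ifelse(isCanonical, NA, sdv < binmed)
  res <- DataFrame(orf_id = ids, mean = mu, sd = sdv, bin = bin,
                   bin_median_corf_sd = binmed, low_noise = low)
  attr(res, "bins_without_corf") <- empty
  res
}

## ---------------------------------------------------------------------------
## Frame classification
## ---------------------------------------------------------------------------

## Spliced (exonic-base) index of genomic positions within a sorted exon
## chain, 0-based in translation order (reversed on the minus strand).
## Positions outside the chain return NA.
.splicedIndex <- function(exons, strand, pos) {
  w <- width(exons)
  if (strand == "-") {
    before <- rev(cumsum(rev(w))) - w        # spliced bases 3' of each exon
    idx <- rep(NA_real_, length(pos))
    for (j in seq_along(exons))
      idx <- ifelse(pos >= start(exons)[j] & pos <= end(exons)[j],
                    before[j] + (end(exons)[j] - pos), idx)
  } else {
    before <- cumsum(w) - w
    idx <- rep(NA_real_, length(pos))
    for (j in seq_along(exons))
      idx <- ifelse(pos >= start(exons)[j] & pos <= end(exons)[j],
                    before[j] + (pos - start(exons)[j]), idx)
  }
  idx
}

## Frame relation of one nORF chain to one CDS chain on the same strand:
## "none" (no shared exonic base), "in" (reading frames align on every shared
## segment), or "alt".
.frameRelation <- function(norf_ex, cds_ex, strand) {
  ## pairwise exon clipping (plain arithmetic; both chains are short)
  ns <- start(norf_ex); ne <- end(norf_ex)
  cs <- start(cds_ex); ce <- end(cds_ex)
  i <- rep(seq_along(ns), each = length(cs))
  j <- rep(seq_along(cs), times = length(ns))
  lo <- pmax(ns[i], cs[j]); hi <- pmin(ne[i], ce[j])
  anchor <- lo[lo <= hi]    # offset is constant within a shared segment
  if (!length(anchor)) return("none")
  ni <- .splicedIndex(norf_ex, strand, anchor)
  ci <- .splicedIndex(cds_ex, strand, anchor)
  off <- (ci - ni) %% 3
  if (all(off == 0)) "in" else "alt"
}

#' Classify nORFs by reading frame relative to annotated CDS
#'
#' Each nORF's codon positions are projected through shared exonic bases
#' (spliced coordinates, not genomic distance) onto every overlapping
#' same-strand CDS. The nORF is `in_frame_cds` if its reading frame aligns
#' with at least one such CDS on every shared segment; `alt_frame_cds` if it
#' shares exonic bases with a same-strand CDS but always frame-shifted;
#' `non_cds` if it overlaps a transcript span but no same-strand CDS
#' exonic base; `intergenic` otherwise. nORFs whose spliced length is not a
#' multiple of 3 are classified from the first overlapping codon, with a
#' warning.
#'
#' @param norfs A [NorfSet].
#' @param reference A [TranscriptSet] carrying CDS for protein-coding
#'   transcripts.
#' @return The `NorfSet` with `frame_class` filled in (see [frameClasses()]).
#' @export
classifyNorfFrame <- function(norfs, reference) {
  stopifnot(is(norfs, "NorfSet"), is(reference, "TranscriptSet"))
  nsp <- featureSpans(norfs)
  tsp <- featureSpans(reference)
  cds_ids <- names(reference@cds)
  cds_sp <- tsp[names(tsp) %in% cds_ids]
  lens <- sum(width(norfs@exons))
  if (any(lens %% 3 != 0))
    warning(sum(lens %% 3 != 0),
            " nORF(s) with length not a multiple of 3; classifying on first overlapping codon")
  tx_hits <- findOverlaps(nsp, tsp, ignore.strand = TRUE)
  cds_hits <- findOverlaps(nsp, cds_sp, ignore.strand = FALSE)
  cls <- rep("intergenic", length(norfs))
  has_tx <- unique(queryHits(tx_hits))
  cls[has_tx] <- "non_cds"
  nstrand <- as.character(strand(nsp))
  for (i in unique(queryHits(cds_hits))) {
    rel <- "none"
    for (j in subjectHits(cds_hits)[queryHits(cds_hits) == i]) {
      id <- names(cds_sp)[j]
      r <- .frameRelation(norfs@exons[[i]], reference@cds[[id]], nstrand[i])
      if (r == "in") { rel <- "in"; break }
      if (r == "alt") rel <- "alt"
    }
    if (rel == "in") cls[i] <- "in_frame_cds"
    else if (rel == "alt") cls[i] <- "alt_frame_cds"
  }
  norfFrameClass(norfs) <- stats::setNames(cls, norfIds(norfs))
  norfs
}

#' Remove in-frame nORFs, honouring the category exceptions
#'
#' nORFs classified `in_frame_cds` are removed unless their upstream category
#' is one of the exception labels (readthrough, extended, uORF, truncated) —
#' those annotations describe legitimate in-frame variants of the canonical
#' ORF and are retained. All non-in-frame nORFs pass unconditionally.
#'
#' @param norfs A [NorfSet] with `frame_class` populated (see
#'   [classifyNorfFrame()]).
#' @param exceptions Category labels exempt from removal.
#' @return The filtered `NorfSet`.
#' @export
applyInframeRemoval <- function(norfs,
                                exceptions = c("readthrough", "extended",
                                               "uORF", "truncated")) {
  stopifnot(is(norfs, "NorfSet"))
  fc <- norfFrameClass(norfs)
  if (anyNA(fc)) stop("frame_class missing; run classifyNorfFrame() first")
  cat <- norfCategory(norfs)
  keep <- !(fc == "in_frame_cds" & !(cat %in% exceptions))
  norfs[which(keep)]
}

#' Collapse nORFs with identical exon chains
#'
#' nORFs with the same chromosome, strand and exact exon chain are collapsed
#' to a single record. The survivor is the lexicographically smallest id;
#' the ids of collapsed duplicates are recorded in an `aliases` metadata
#' column.
#'
#' @param norfs A [NorfSet].
#' @return A `NorfSet` of unique chains with `mcols()$aliases`
#'   (`CharacterList`) naming each survivor's duplicates.
#' @export
deduplicateNorfs <- function(norfs) {
  stopifnot(is(norfs, "NorfSet"))
  exl <- norfs@exons
  key <- vapply(seq_along(exl), function(i) {
    ex <- exl[[i]]
    paste(as.character(seqnames(ex))[1], as.character(strand(ex))[1],
          paste(start(ex), end(ex), sep = "-", collapse = ","), sep = "|")
  }, "")
  ids <- names(exl)
  groups <- split(ids, key)
  survivors <- sort(vapply(groups, min, ""))
  aliases <- lapply(groups, function(g) sort(setdiff(g, min(g))))
  names(aliases) <- vapply(groups, min, "")
  out <- norfs[match(survivors, ids)]
  md <- mcols(out@exons)
  md$aliases <- IRanges::CharacterList(aliases[survivors])
  mcols(out@exons) <- md
  out
}
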