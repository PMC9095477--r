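## Which annotated/assembled transcripts contain nORFs: the TPM expression
## filter, pseudoautosomal-region removal, intron-chain ("=") equality,
## exon-boundary containment, and the non-protein-coding biotype rule.

#' Retain transcripts expressed above a TPM threshold in enough samples
#'
#' A transcript is kept iff its TPM is strictly greater than `tpmMin` in at
#' least `ceiling(sampleFrac * n_samples)` samples (default: TPM > 0.1 in at
#' least 10% of samples).
#'
#' @param x An [OrfExperiment] with unit `"TPM"` (or a numeric matrix).
#' @param tpmMin Strict lower TPM bound.
#' @param sampleFrac Minimum fraction of samples required.
#' @return Character vector of retained feature ids.
#' @export
expressionFilter <- function(x, tpmMin = 0.1, sampleFrac = 0.10) {
  m <- if (is(x, "OrfExperiment")) {
    if (expressionUnit(x) != "TPM")
      stop("expressionFilter expects unit 'TPM'")
    assay(x)
  } else as.matrix(x)
  stopifnot(sampleFrac >= 0, sampleFrac <= 1)
  if (!length(m)) return(character())
  need <- ceiling(sampleFrac * ncol(m))
  rownames(m)[rowSums(m > tpmMin) >= need]
}

#' Remove transcripts from pseudoautosomal regions
#'
#' Drops transcripts whose genomic span overlaps a supplied PAR interval, or
#' whose id carries the PAR suffix tag (`_PAR_Y`), regardless of coordinates.
#'
#' @param transcripts A [TranscriptSet].
#' @param parRegions `GRanges` of PAR intervals (may be empty).
#' @param parSuffix Regular expression matched against transcript ids.
#' @return The filtered `TranscriptSet`.
#' @export
removeParFeatures <- function(transcripts, parRegions = GRanges(),
                              parSuffix = "_PAR_Y$") {
  stopifnot(is(transcripts, "TranscriptSet"))
  sp <- featureSpans(transcripts)
  drop <- grepl(parSuffix, names(sp))
  if (length(parRegions))
    drop <- drop | IRanges::overlapsAny(sp, parRegions, ignore.strand = TRUE)
  transcripts[which(!drop)]
}

.junctions <- function(ex) {
  ## ordered intron coordinate pairs (donor, acceptor) of a sorted chain
  if (length(ex) < 2L) return(matrix(numeric(0), ncol = 2))
  cbind(end(ex)[-length(ex)], start(ex)[-1])
}

## plain-vector chain representation (chrom, strand, exon starts/ends),
## used so the matching loops avoid per-pair S4 dispatch
.chainsOf <- function(grl) {
  sp <- .spansOf(grl)
  list(chrom = as.character(seqnames(sp)),
       strand = as.character(strand(sp)),
       s = as.list(start(grl)), e = as.list(end(grl)))
}

.chainContained <- function(ns, ne, ts, te) {
  for (i in seq_along(ns)) {
    ov <- which(ts <= ne[i] & te >= ns[i])
    cov <- if (length(ov))
      sum(pmin(te[ov], ne[i]) - pmax(ts[ov], ns[i]) + 1) else 0
    if (cov < ne[i] - ns[i] + 1) return(FALSE)
  }
  nn <- length(ns)
  if (nn < 2L) return(TRUE)
  if (length(ts) < 2L) return(FALSE)
  jn_d <- ne[-nn]; jn_a <- ns[-1]
  jt_d <- te[-length(te)]; jt_a <- ts[-1]
  all(vapply(seq_along(jn_d), function(k)
    any(jt_d == jn_d[k] & jt_a == jn_a[k]), TRUE))
}

.chainIntronsEqual <- function(ns, ne, ts, te) {
  if (length(ns) < 2L || length(ts) < 2L) return(FALSE)
  length(ns) == length(ts) &&
    all(ne[-length(ne)] == te[-length(te)]) && all(ns[-1] == ts[-1])
}

#' Intron-chain equality (transcript class "=")
#'
#' Two multi-exon chains are "=" iff their ordered intron lists (junction
#' coordinate pairs) are identical on the same chromosome and strand;
#' terminal exon ends are free to differ. Single-exon chains never match by
#' this rule (they are handled by containment).
#'
#' @param a,b `GRanges` exon chains, sorted by position.
#' @return Logical scalar.
#' @export
intronChainEqual <- function(a, b) {
  if (is.unsorted(start(a)) || is.unsorted(start(b)))
    stop("exon chains must be sorted by start position")
  if (length(a) < 2L || length(b) < 2L) return(FALSE)
  if (as.character(seqnames(a))[1] != as.character(seqnames(b))[1]) return(FALSE)
  if (as.character(strand(a))[1] != as.character(strand(b))[1]) return(FALSE)
  .chainIntronsEqual(start(a), end(a), start(b), end(b))
}

#' Is an nORF's exon chain contained in a transcript's?
#'
#' `TRUE` iff every nORF exon base is covered by the transcript's exon union
#' and every nORF splice junction exists in the transcript's junction set.
#' Terminal nORF exon ends may lie anywhere inside a transcript exon.
#'
#' @param norfExons,txExons `GRanges` exon chains (same chromosome/strand
#'   comparison is the caller's responsibility; mismatches simply return
#'   `FALSE`).
#' @return Logical scalar.
#' @export
norfContainedIn <- function(norfExons, txExons) {
  if (as.character(seqnames(norfExons))[1] != as.character(seqnames(txExons))[1])
    return(FALSE)
  .chainContained(start(norfExons), end(norfExons),
                  start(txExons), end(txExons))
}

#' Match nORFs to retained non-protein-coding transcripts
#'
#' For every nORF and every expression-retained transcript on the same
#' chromosome and strand, a match is recorded iff the nORF is contained in
#' the transcript (see [norfContainedIn()]) and the transcript's biotype is
#' not `protein_coding`. The match class is `intron_chain_equal` when the two
#' chains share an identical intron chain, otherwise `contained`. Transcripts
#' with missing biotype are treated as non-protein-coding and flagged in the
#' `missing_biotype` attribute. One nORF may match many transcripts; output
#' order is by (norf_id, transcript_id), independent of input order.
#'
#' @param norfs A [NorfSet].
#' @param transcripts A [TranscriptSet].
#' @param retainedIds Transcript ids that passed [expressionFilter()];
#'   default all.
#' @return `data.frame` with columns `norf_id`, `transcript_id`,
#'   `match_class`, `biotype`.
#' @export
matchNorfs <- function(norfs, transcripts, retainedIds = txIds(transcripts)) {
  stopifnot(is(norfs, "NorfSet"), is(transcripts, "TranscriptSet"))
  keep <- txIds(transcripts) %in% retainedIds
  tx <- transcripts[which(keep)]
  bt <- txBiotype(tx)
  non_coding <- is.na(bt) | !(bt %in% c("protein_coding", "protein-coding"))
  tx_sp <- featureSpans(tx)
  n_sp <- featureSpans(norfs)
  hits <- findOverlaps(n_sp, tx_sp, ignore.strand = FALSE)
  nc <- .chainsOf(norfs@exons); tc <- .chainsOf(tx@exons)
  rows <- list()
  for (k in seq_along(hits)) {
    i <- queryHits(hits)[k]; j <- subjectHits(hits)[k]
    if (!non_coding[j]) next
    if (nc$chrom[i] != tc$chrom[j]) next
    if (!.chainContained(nc$s[[i]], nc$e[[i]], tc$s[[j]], tc$e[[j]])) next
    eq <- nc$strand[i] == tc$strand[j] &&
      .chainIntronsEqual(nc$s[[i]], nc$e[[i]], tc$s[[j]], tc$e[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      norf_id = norfIds(norfs)[i], transcript_id = txIds(tx)[j],
      match_class = if (eq) "intron_chain_equal" else "contained",
      biotype = unname(bt[j]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(norf_id = character(), transcript_id = character(),
               match_class = character(), biotype = character(),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$norf_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_biotype") <- txIds(tx)[is.na(bt)]
  out
}

#' Biotype composition of nORF-containing transcripts
#'
#' Summarizes a match table into the percentage of matched transcripts per
#' biotype (each transcript counted once).
#'
#' @param matches Match table from [matchNorfs()].
#' @return `data.frame` with `biotype`, `n_transcripts`, `percent`.
#' @export
biotypeComposition <- function(matches) {
  u <- unique(matches[c("transcript_id", "biotype")])
  tab <- table(u$biotype, useNA = "ifany")
  data.frame(biotype = names(tab), n_transcripts = as.integer(tab),
             percent = 100 * as.integer(tab) / max(1L, sum(tab)),
             stringsAsFactors = FALSE)
}
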