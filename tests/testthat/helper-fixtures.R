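## Shared fixtures and independent oracles, all built in code.

library(GenomicRanges)
library(IRanges)
library(S4Vectors)
suppressPackageStartupMessages(library(SummarizedExperiment))

## --- per-base bitmap oracles ------------------------------------------------

## base-set of a GRanges, keyed by chromosome
.bitmapOf <- function(gr) {
  out <- list()
  for (i in seq_along(gr)) {
    ch <- as.character(seqnames(gr))[i]
    out[[ch]] <- union(out[[ch]], start(gr)[i]:end(gr)[i])
  }
  lapply(out, sort)
}

## brute-force merged intervals from the per-base bitmap
oracleMerge <- function(gr) {
  bm <- .bitmapOf(gr)
  rows <- list()
  for (ch in sort(names(bm))) {
    b <- bm[[ch]]
    brk <- c(0, which(diff(b) > 1), length(b))
    for (k in seq_len(length(brk) - 1)) {
      seg <- b[(brk[k] + 1):brk[k + 1]]
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, start = min(seg),
                                             end = max(seg))
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$chrom, df$start), , drop = FALSE]
}

oracleOverlap <- function(a, b) {
  if (as.character(seqnames(a)) != as.character(seqnames(b))) return(FALSE)
  length(intersect(start(a):end(a), start(b):end(b))) > 0
}

oracleDistance <- function(a, b) {
  if (as.character(seqnames(a)) != as.character(seqnames(b))) return(Inf)
  if (oracleOverlap(a, b)) return(0)
  ba <- start(a):end(a); bb <- start(b):end(b)
  min(abs(outer(ba, bb, "-"))) - 1
}

randomGRanges <- function(n, chroms = c("chrA", "chrB"), maxPos = 3000,
                          maxW = 120) {
  GRanges(sample(chroms, n, replace = TRUE),
          IRanges(sample.int(maxPos, n, replace = TRUE),
                  width = sample.int(maxW, n, replace = TRUE)))
}

## --- tiny hand-built annotation + nORFs for matching/classification --------

## plus-strand two-exon transcript, CDS starting at spliced position 11
tinyTranscripts <- function() {
  ex <- GRangesList(
    txA = GRanges("chrA", IRanges(c(101, 301), c(200, 400)), strand = "+"),
    txB = GRanges("chrA", IRanges(c(1001, 1301), c(1100, 1400)), strand = "+"),
    txC = GRanges("chrB", IRanges(2001, 2600), strand = "-"))
  mcols(ex) <- DataFrame(gene_id = c("gA", "gB", "gC"),
                         biotype = c("protein_coding", "retained_intron",
                                     "lincRNA"))
  cds <- GRangesList(
    txA = GRanges("chrA", IRanges(c(111, 301), c(200, 380)), strand = "+"))
  TranscriptSet(ex, cds = cds)
}

tinyNorfSet <- function(chains, categories = "non_coding") {
  NorfSet(GRangesList(chains), category = categories)
}

## brute-force per-base frame-projection oracle: spliced codon phase of every
## shared genomic base of an nORF chain vs a CDS chain (same strand)
oracleFrameRelation <- function(norf, cds, strand) {
  splice <- function(gr) {
    pos <- unlist(lapply(seq_along(gr), function(i) start(gr)[i]:end(gr)[i]))
    pos <- sort(pos)
    if (strand == "-") pos <- rev(pos)
    setNames(seq_along(pos) - 1L, pos)   # 0-based spliced index by position
  }
  ni <- splice(norf); ci <- splice(cds)
  shared <- intersect(names(ni), names(ci))
  if (!length(shared)) return("none")
  off <- (ci[shared] - ni[shared]) %% 3
  if (all(off == 0)) "in" else "alt"
}
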