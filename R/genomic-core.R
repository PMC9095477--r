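## Coordinate conventions: all in-memory intervals are GRanges (1-based,
## closed), the Bioconductor convention. GTF I/O is 1-based closed on disk
## (no shift); BED I/O is 0-based half-open on disk and converted by the
## readers/writers. Chromosome names are normalized to carry a "chr" prefix.

#' @importFrom GenomicRanges reduce shift findOverlaps
#' @importFrom GenomeInfoDb seqnames seqlevels
#' @importFrom rtracklayer import export
NULL

#' Normalize chromosome names to the chr-prefixed form
#'
#' @param x Character vector of chromosome names.
#' @return Character vector with a `chr` prefix added where missing.
#' @export
normalizeChrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

.renameChroms <- function(gr) {
  sl <- seqlevels(gr)
  GenomeInfoDb::seqlevels(gr) <- stats::setNames(normalizeChrom(sl), sl)
  gr
}

## ---------------------------------------------------------------------------
## GTF
## ---------------------------------------------------------------------------

#' Read and write transcript annotation in GTF format
#'
#' `readGtf()` parses a GTF file (Ensembl/GENCODE attribute dialect, with
#' `transcript_id` and `gene_id` attributes; biotype read from a `biotype`,
#' `transcript_biotype` or `transcript_type` attribute) into a
#' [TranscriptSet]. Exons are grouped by transcript and sorted; chromosome
#' names are normalized to a `chr` prefix. `writeGtf()` writes a
#' `TranscriptSet` back out with deterministic ordering, so that
#' `readGtf(writeGtf(x))` reproduces coordinates exactly.
#'
#' @param path File path.
#' @param x A [TranscriptSet].
#' @return `readGtf` returns a `TranscriptSet`; `writeGtf` returns `path`
#'   invisibly.
#' @export
readGtf <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- .renameChroms(gr)
  md <- mcols(gr)
  if (is.null(md$transcript_id) || is.null(md$gene_id))
    stop("GTF must carry transcript_id and gene_id attributes")
  bt_col <- intersect(c("biotype", "transcript_biotype", "transcript_type"),
                      colnames(md))[1]
  is_exon <- md$type == "exon"
  is_cds <- md$type == "CDS"
  if (!any(is_exon)) stop("GTF contains no exon features")
  ex <- gr[is_exon]
  exl <- GenomicRanges::split(granges(ex), mcols(ex)$transcript_id)
  exl <- GRangesList(lapply(exl, GenomicRanges::sort))
  ids <- names(exl)
  first <- match(ids, mcols(ex)$transcript_id)
  md_tx <- DataFrame(
    gene_id = mcols(ex)$gene_id[first],
    biotype = if (!is.na(bt_col)) as.character(mcols(ex)[[bt_col]][first])
              else NA_character_
  )
  mcols(exl) <- md_tx
  cdsl <- GRangesList()
  if (any(is_cds)) {
    cds <- gr[is_cds]
    keep <- mcols(cds)$transcript_id %in% ids
    cds <- cds[keep]
    cdsl <- GenomicRanges::split(granges(cds), mcols(cds)$transcript_id)
    cdsl <- GRangesList(lapply(cdsl, GenomicRanges::sort))
  }
  ## validation: exon outside declared transcript bounds
  if (any(md$type == "transcript")) {
    txf <- gr[md$type == "transcript"]
    tx_ids <- mcols(txf)$transcript_id
    hit <- match(ids, tx_ids)
    sp <- .spansOf(exl)
    bad <- !is.na(hit) &
      (start(sp) < start(txf)[hit] | end(sp) > end(txf)[hit])
    if (any(bad))
      stop("exon outside declared transcript bounds for: ",
           paste(ids[bad], collapse = ", "))
  }
  TranscriptSet(exl, cds = cdsl)
}

#' @rdname readGtf
#' @export
writeGtf <- function(x, path) {
  stopifnot(is(x, "TranscriptSet"))
  ids <- sort(txIds(x))
  rows <- lapply(ids, function(id) {
    ex <- x@exons[[id]]
    gid <- mcols(x@exons)$gene_id[match(id, names(x@exons))]
    bt <- mcols(x@exons)$biotype[match(id, names(x@exons))]
    feat <- granges(ex)
    mc <- DataFrame(source = "norfscan", type = rep("exon", length(feat)),
                    phase = NA_integer_)
    if (id %in% names(x@cds)) {
      cd <- granges(x@cds[[id]])
      ## GTF frame column: bases to skip to the next codon start
      ord <- if (as.character(strand(x@cds[[id]]))[1] == "-")
        rev(seq_along(cd)) else seq_along(cd)
      before <- cumsum(width(cd)[ord]) - width(cd)[ord]
      ph <- integer(length(cd))
      ph[ord] <- (3L - before %% 3L) %% 3L
      feat <- c(feat, cd)
      mc <- rbind(mc, DataFrame(source = "norfscan",
                                type = rep("CDS", length(cd)), phase = ph))
    }
    mc$transcript_id <- id
    mc$gene_id <- gid
    mc$biotype <- bt
    mcols(feat) <- mc
    feat
  })
  out <- unlist(GRangesList(rows), use.names = FALSE)
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED
## ---------------------------------------------------------------------------

#' Read and write nORF exon chains in BED12 format
#'
#' BED12 blocks become exon chains; the on-disk 0-based half-open coordinates
#' are converted to the in-memory 1-based closed convention. An optional 13th
#' column carries the ORF category label (see [orfCategories()]); categories
#' may instead be supplied separately.
#'
#' @param path File path.
#' @param categories Optional named character vector (names are nORF ids)
#'   overriding any category column in the file.
#' @param x A [NorfSet].
#' @return `readNorfBed` returns a [NorfSet]; `writeNorfBed` returns `path`
#'   invisibly.
#' @export
readNorfBed <- function(path, categories = NULL) {
  stopifnot(file.exists(path))
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  extra <- if (length(first) >= 13L) c(category = "character") else character()
  gr <- rtracklayer::import(path, format = "bed", extraCols = extra)
  gr <- .renameChroms(gr)
  if (is.null(gr$name) || anyDuplicated(gr$name))
    stop("BED12 nORF file must carry unique names")
  exl <- GRangesList(lapply(seq_along(gr), function(i) {
    bl <- if (!is.null(gr$blocks)) gr$blocks[[i]] else IRanges(1L, width(gr)[i])
    GRanges(seqnames(gr)[i], IRanges::shift(bl, start(gr)[i] - 1L),
            strand = strand(gr)[i])
  }))
  names(exl) <- gr$name
  cat_vec <- if (!is.null(categories)) {
    unname(categories[gr$name])
  } else if (!is.null(gr$category)) gr$category else NA_character_
  NorfSet(exl, category = cat_vec)
}

#' @rdname readNorfBed
#' @export
writeNorfBed <- function(x, path) {
  stopifnot(is(x, "NorfSet"))
  exl <- x@exons
  sp <- .spansOf(exl)
  starts <- start(sp) - 1L                       # to 0-based half-open
  lines <- vapply(seq_along(exl), function(i) {
    ex <- exl[[i]]
    sizes <- paste0(paste(width(ex), collapse = ","), ",")
    offs <- paste0(paste(start(ex) - start(sp)[i], collapse = ","), ",")
    paste(as.character(seqnames(sp))[i], starts[i], end(sp)[i],
          names(exl)[i], 0L, as.character(strand(sp))[i],
          starts[i], end(sp)[i], "0,0,0", length(ex), sizes, offs,
          mcols(exl)$category[i], sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write feature intervals (HARs, TEs) in BED6 plus extra columns
#'
#' HAR files carry `source` and `group` columns (group is one of vHAR, mHAR,
#' pHAR); TE files carry `family`, `te_class` and `clade`. `extraCols` names
#' the columns after the six standard BED fields, in file order.
#'
#' @param path File path.
#' @param extraCols Named character vector of column types, as for
#'   [rtracklayer::import].
#' @param gr A `GRanges` whose `mcols()` contain the extra columns.
#' @return `readFeatureBed` returns a `GRanges` (named by the BED name field);
#'   `writeFeatureBed` returns `path` invisibly.
#' @export
readFeatureBed <- function(path, extraCols = character()) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "bed", extraCols = extraCols)
  gr <- .renameChroms(gr)
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' @rdname readFeatureBed
#' @export
writeFeatureBed <- function(gr, path) {
  md <- mcols(gr)
  extra <- md[, setdiff(colnames(md), c("name", "score", "revmap")), drop = FALSE]
  for (cn in colnames(extra))    # collapse list columns (e.g. provenance)
    if (is(extra[[cn]], "List") || is.list(extra[[cn]]))
      extra[[cn]] <- vapply(extra[[cn]], paste, "", collapse = ",")
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = if (!is.null(names(gr))) names(gr) else ".",
    score = if ("score" %in% colnames(md)) md$score else 0L,
    strand = as.character(strand(gr)),
    check.names = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  if (ncol(extra)) df <- cbind(df, as.data.frame(extra))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Interval arithmetic
## ---------------------------------------------------------------------------

#' Merge intervals, keeping member provenance
#'
#' Overlapping and bookended (distance-0) intervals are merged,
#' strand-agnostically. Each merged interval records the indices (`revmap`)
#' and names (`members`) of its contributing inputs, so multi-source feature
#' lists (e.g. HAR compilations) keep their provenance through merging.
#' Merging is idempotent and preserves the base-pair union of the input.
#'
#' @param gr A `GRanges` (optionally named).
#' @return A sorted, pairwise-disjoint `GRanges` with `mcols()` columns
#'   `revmap` (IntegerList) and `members` (CharacterList).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 16), c(20, 30)))
#' mergeIntervals(gr)   # one interval 11-30 with both members
#' @export
mergeIntervals <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  gr0 <- granges(gr)
  GenomeInfoDb::seqlevels(gr0) <- sort(GenomeInfoDb::seqlevels(gr0))
  merged <- reduce(gr0, with.revmap = TRUE, ignore.strand = TRUE,
                   min.gapwidth = 1L)
  nm <- if (!is.null(names(gr))) names(gr) else as.character(seq_along(gr))
  mcols(merged)$members <- IRanges::extractList(nm, mcols(merged)$revmap)
  merged
}

#' Pairwise overlap and distance between intervals
#'
#' Element-wise comparison of two equal-length `GRanges` (or length-1
#' recycled). Intervals on different chromosomes never overlap and are at
#' infinite distance; abutting intervals do not overlap and are at distance 0;
#' overlapping intervals are at distance 0. Strand is ignored.
#'
#' @param a,b `GRanges` of equal length (or either of length 1).
#' @return `intervalsOverlap`: logical vector. `intervalDistance`: numeric
#'   vector of gap sizes in bases (`Inf` across chromosomes).
#' @export
intervalsOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
}

#' @rdname intervalsOverlap
#' @export
intervalDistance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  gap <- pmax(pmax(start(a), start(b)) - pmin(end(a), end(b)) - 1L, 0L)
  ifelse(same, gap, Inf)
}

## ---------------------------------------------------------------------------
## Plain TSV helpers (deterministic column order)
## ---------------------------------------------------------------------------

#' Read and write tab-separated tables and expression matrices
#'
#' `writeTsv`/`readTsv` are thin, deterministic wrappers around base table
#' I/O (tab separator, header row, no quoting, no row names).
#' `writeExpressionTsv`/`readExpressionTsv` store an [OrfExperiment] assay as
#' a TSV with a leading `feature_id` column, preserving the unit tag via
#' a `lengths`/metadata sidecar-free convention (unit supplied on read).
#'
#' @param df Data frame to write.
#' @param path File path.
#' @param x An `OrfExperiment`.
#' @param unit Unit tag for the matrix being read.
#' @param colData Optional sample metadata to attach on read.
#' @return Readers return a `data.frame` / `OrfExperiment`; writers return
#'   `path` invisibly.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname writeTsv
#' @export
writeExpressionTsv <- function(x, path) {
  stopifnot(is(x, "OrfExperiment"))
  df <- data.frame(feature_id = rownames(x), assay(x), check.names = FALSE)
  if ("length" %in% colnames(rowData(x)))
    df <- cbind(df[1], length = rowData(x)$length, df[-1])
  writeTsv(df, path)
}

#' @rdname writeTsv
#' @export
readExpressionTsv <- function(path, unit = "count", colData = NULL) {
  df <- readTsv(path)
  lengths <- if ("length" %in% colnames(df)) df$length else NULL
  keep <- setdiff(colnames(df), c("feature_id", "length"))
  m <- as.matrix(df[keep])
  rownames(m) <- df$feature_id
  OrfExperiment(m, colData = colData, lengths = lengths, unit = unit)
}
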