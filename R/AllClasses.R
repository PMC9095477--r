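#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges ranges width start end
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand granges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData rowData<-
NULL

.ORF_CATEGORIES <- c(
  "canonical", "truncated", "extended", "uORF", "overlapping_uORF",
  "internal", "external", "polycistronic", "readthrough", "non_coding"
)

.FRAME_CLASSES <- c("in_frame_cds", "alt_frame_cds", "non_cds", "intergenic")

.EXPRESSION_UNITS <- c("count", "TPM", "logCPM")

#' Closed vocabularies used across the package
#'
#' `orfCategories()` returns the upstream ORF category labels (canonical,
#' truncated, extended, uORF, overlapping uORF, internal, external,
#' polycistronic, readthrough, non-coding). `frameClasses()` returns the
#' frame classification vocabulary assigned by [classifyNorfFrame()].
#'
#' @return Character vector of allowed labels.
#' @export
orfCategories <- function() .ORF_CATEGORIES

#' @rdname orfCategories
#' @export
frameClasses <- function() .FRAME_CLASSES

## ---------------------------------------------------------------------------
## TranscriptSet
## ---------------------------------------------------------------------------

#' Set of transcript models
#'
#' Holds per-transcript exon chains as a [GenomicRanges::GRangesList] (names
#' are transcript ids; `mcols()` carries `gene_id` and `biotype`), plus an
#' optional CDS chain per protein-coding transcript. Exons within a transcript
#' must be sorted and pairwise disjoint; any CDS must lie inside its
#' transcript's exon union.
#'
#' @slot exons `GRangesList`, one element per transcript.
#' @slot cds `GRangesList`, named subset of `exons` carrying coding chains.
#'
#' @export
setClass("TranscriptSet", representation(exons = "GRangesList", cds = "GRangesList"))

## Vectorized chain check: within every element of a GRangesList, exons must
## be on one chromosome, sorted by start, and pairwise disjoint.
.chainsWellFormed <- function(grl) {
  u <- unlist(grl, use.names = FALSE)
  if (!length(u)) return(TRUE)
  grp <- rep(seq_along(grl), S4Vectors::elementNROWS(grl))
  n <- length(u)
  if (n < 2L) return(TRUE)
  same <- grp[-1] == grp[-n]
  ch <- as.character(seqnames(u))
  all(ch[-1][same] == ch[-n][same]) &&
    all(start(u)[-1][same] > end(u)[-n][same])
}

.validTranscriptSet <- function(object) {
  msg <- character()
  ex <- object@exons
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    msg <- c(msg, "exons must be a named GRangesList with unique transcript ids")
  md <- mcols(ex)
  if (!all(c("gene_id", "biotype") %in% colnames(md)))
    msg <- c(msg, "mcols(exons) must contain gene_id and biotype")
  if (!.chainsWellFormed(ex))
    msg <- c(msg, "each transcript's exons must be on one chromosome, sorted and pairwise disjoint")
  cds <- object@cds
  if (length(cds)) {
    if (!all(names(cds) %in% names(ex)))
      msg <- c(msg, "cds names must be a subset of exon names")
    else {
      uc <- unlist(cds, use.names = TRUE)
      ue <- unlist(ex[names(cds)], use.names = TRUE)
      hits <- findOverlaps(uc, ue, type = "within", ignore.strand = TRUE)
      ok <- logical(length(uc))
      same_tx <- names(uc)[queryHits(hits)] == names(ue)[subjectHits(hits)]
      ok[queryHits(hits)[same_tx]] <- TRUE
      ## pieces not inside a single exon may still be covered by the union
      for (q in which(!ok)) {
        id <- names(uc)[q]
        ok[q] <- sum(width(GenomicRanges::setdiff(granges(uc[q]),
                                                  granges(ex[[id]])))) == 0
      }
      if (!all(ok)) msg <- c(msg, "cds chains must be contained in the exon union")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("TranscriptSet", .validTranscriptSet)

#' Construct a TranscriptSet
#'
#' @param exons Named `GRangesList` of exon chains with `mcols()` columns
#'   `gene_id` and `biotype`.
#' @param cds Optional named `GRangesList` of CDS chains (names must be a
#'   subset of `names(exons)`).
#' @return A `TranscriptSet`.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chrS1", IRanges::IRanges(101, 200), "+"))
#' S4Vectors::mcols(ex) <- S4Vectors::DataFrame(gene_id = "g1", biotype = "lincRNA")
#' TranscriptSet(ex)
#' @export
TranscriptSet <- function(exons, cds = GRangesList()) {
  md <- mcols(exons)
  nm <- names(exons)
  exons <- GenomicRanges::sort(GRangesList(exons))
  names(exons) <- nm
  if (is.null(md$gene_id)) md$gene_id <- names(exons)
  if (is.null(md$biotype)) md$biotype <- NA_character_
  mcols(exons) <- md
  new("TranscriptSet", exons = exons, cds = GRangesList(cds))
}

## ---------------------------------------------------------------------------
## NorfSet
## ---------------------------------------------------------------------------

#' Set of novel open reading frames (nORFs)
#'
#' An nORF is a stranded exon chain plus an upstream category label (see
#' [orfCategories()]) and, after [classifyNorfFrame()], a frame classification
#' relative to annotated CDS. Stored as a `GRangesList` with `mcols()` columns
#' `category`, `frame_class` and optionally `aa_sequence`.
#'
#' @slot exons `GRangesList`, one element per nORF.
#' @export
setClass("NorfSet", representation(exons = "GRangesList"))

.validNorfSet <- function(object) {
  msg <- character()
  ex <- object@exons
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    msg <- c(msg, "exons must be a named GRangesList with unique nORF ids")
  md <- mcols(ex)
  if (!"category" %in% colnames(md))
    msg <- c(msg, "mcols(exons) must contain a category column")
  else {
    bad <- !is.na(md$category) & !(md$category %in% .ORF_CATEGORIES)
    if (any(bad))
      msg <- c(msg, paste0("unknown category label(s): ",
                           paste(unique(md$category[bad]), collapse = ", ")))
  }
  if ("frame_class" %in% colnames(md)) {
    bad <- !is.na(md$frame_class) & !(md$frame_class %in% .FRAME_CLASSES)
    if (any(bad)) msg <- c(msg, "frame_class outside the allowed vocabulary")
  }
  if (!.chainsWellFormed(ex))
    msg <- c(msg, "each nORF's exons must be on one chromosome, sorted and pairwise disjoint")
  if (length(msg)) msg else TRUE
}
setValidity("NorfSet", .validNorfSet)

#' Construct a NorfSet
#'
#' @param exons Named `GRangesList` of nORF exon chains.
#' @param category Character vector of category labels (recycled), one of
#'   [orfCategories()]; may also already be present in `mcols(exons)`.
#' @return A `NorfSet`.
#' @export
NorfSet <- function(exons, category = NULL) {
  md <- mcols(exons)
  nm <- names(exons)
  exons <- GenomicRanges::sort(GRangesList(exons))
  names(exons) <- nm
  if (!is.null(category)) md$category <- rep_len(category, length(exons))
  if (is.null(md$category)) md$category <- NA_character_
  if (is.null(md$frame_class)) md$frame_class <- NA_character_
  mcols(exons) <- md
  new("NorfSet", exons = exons)
}

## ---------------------------------------------------------------------------
## OrfExperiment
## ---------------------------------------------------------------------------

#' Expression matrix with a tagged unit
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] whose
#' single assay holds non-negative raw counts or TPM (or log-CPM, which may be
#' negative), tagged by a `unit` slot. Feature lengths (needed for TPM
#' conversion) live in `rowData(x)$length`; sample metadata (diagnosis,
#' individual id, sex, covariates) lives in `colData(x)`.
#'
#' @slot unit One of `"count"`, `"TPM"`, `"logCPM"`.
#' @export
setClass("OrfExperiment", contains = "SummarizedExperiment",
         representation(unit = "character"))

.validOrfExperiment <- function(object) {
  msg <- character()
  if (length(object@unit) != 1L || !(object@unit %in% .EXPRESSION_UNITS))
    msg <- c(msg, paste0("unit must be one of: ", paste(.EXPRESSION_UNITS, collapse = ", ")))
  v <- assay(object)
  if (object@unit != "logCPM" && length(v) && min(v) < 0)
    msg <- c(msg, "count/TPM values must be non-negative")
  if ("length" %in% colnames(rowData(object))) {
    len <- rowData(object)$length
    if (any(!is.na(len) & len <= 0)) msg <- c(msg, "feature lengths must be positive")
  }
  if (length(msg)) msg else TRUE
}
setValidity("OrfExperiment", .validOrfExperiment)

#' Construct an OrfExperiment
#'
#' @param values Numeric matrix, features x samples, with dimnames.
#' @param colData Data frame / DataFrame of per-sample metadata (one row per
#'   column of `values`); typically carries `diagnosis`, `individual_id`, `sex`
#'   and covariate columns.
#' @param lengths Optional numeric vector of feature lengths (bases), recycled
#'   against rows; stored in `rowData(x)$length`.
#' @param unit Unit tag, one of `"count"`, `"TPM"`, `"logCPM"`.
#' @return An `OrfExperiment`.
#' @examples
#' m <- matrix(rpois(20, 10), 4, 5,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' oe <- OrfExperiment(m, lengths = c(300, 300, 900, 1200))
#' expressionUnit(oe)
#' @export
OrfExperiment <- function(values, colData = NULL, lengths = NULL, unit = "count") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(colData)) colData <- DataFrame(row.names = colnames(values))
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(lengths)) rd$length <- rep_len(lengths, nrow(values))
  se <- SummarizedExperiment(assays = list(values = values),
                             colData = as(colData, "DataFrame"), rowData = rd)
  new("OrfExperiment", se, unit = unit)
}
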