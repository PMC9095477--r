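#' Accessors for TranscriptSet, NorfSet and OrfExperiment
#'
#' `txIds`/`norfIds` return feature identifiers; `txExons`/`norfExons` the
#' exon-chain `GRangesList`; `txCds` the CDS chains; `txBiotype`, `txGeneId`,
#' `norfCategory`, `norfFrameClass` the per-feature annotation columns;
#' `featureSpans` the genomic span (first exon start to last exon end) of each
#' feature as a `GRanges`; `expressionUnit` the unit tag of an
#' `OrfExperiment`.
#'
#' @param x A `TranscriptSet`, `NorfSet` or `OrfExperiment`.
#' @param value Replacement value.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @rdname accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))
#' @rdname accessors
#' @export
setGeneric("txCds", function(x) standardGeneric("txCds"))
#' @rdname accessors
#' @export
setGeneric("txBiotype", function(x) standardGeneric("txBiotype"))
#' @rdname accessors
#' @export
setGeneric("txGeneId", function(x) standardGeneric("txGeneId"))
#' @rdname accessors
#' @export
setGeneric("norfIds", function(x) standardGeneric("norfIds"))
#' @rdname accessors
#' @export
setGeneric("norfExons", function(x) standardGeneric("norfExons"))
#' @rdname accessors
#' @export
setGeneric("norfCategory", function(x) standardGeneric("norfCategory"))
#' @rdname accessors
#' @export
setGeneric("norfFrameClass", function(x) standardGeneric("norfFrameClass"))
#' @rdname accessors
#' @export
setGeneric("norfFrameClass<-", function(x, value) standardGeneric("norfFrameClass<-"))
#' @rdname accessors
#' @export
setGeneric("featureSpans", function(x) standardGeneric("featureSpans"))
#' @rdname accessors
#' @export
setGeneric("expressionUnit", function(x) standardGeneric("expressionUnit"))

.spansOf <- function(grl) {
  sp <- unlist(range(grl), use.names = FALSE)
  names(sp) <- names(grl)
  mcols(sp) <- mcols(grl)
  sp
}

setMethod("txIds", "TranscriptSet", function(x) names(x@exons))
setMethod("txExons", "TranscriptSet", function(x) x@exons)
setMethod("txCds", "TranscriptSet", function(x) x@cds)
setMethod("txBiotype", "TranscriptSet", function(x)
  stats::setNames(mcols(x@exons)$biotype, names(x@exons)))
setMethod("txGeneId", "TranscriptSet", function(x)
  stats::setNames(mcols(x@exons)$gene_id, names(x@exons)))
setMethod("featureSpans", "TranscriptSet", function(x) .spansOf(x@exons))

setMethod("norfIds", "NorfSet", function(x) names(x@exons))
setMethod("norfExons", "NorfSet", function(x) x@exons)
setMethod("norfCategory", "NorfSet", function(x)
  stats::setNames(mcols(x@exons)$category, names(x@exons)))
setMethod("norfFrameClass", "NorfSet", function(x)
  stats::setNames(mcols(x@exons)$frame_class, names(x@exons)))
setReplaceMethod("norfFrameClass", "NorfSet", function(x, value) {
  md <- mcols(x@exons)
  md$frame_class <- unname(value[names(x@exons)])
  mcols(x@exons) <- md
  validObject(x)
  x
})
setMethod("featureSpans", "NorfSet", function(x) .spansOf(x@exons))

setMethod("expressionUnit", "OrfExperiment", function(x) x@unit)

#' @rdname accessors
#' @param i,j,drop Subsetting indices as for `GRangesList`.
#' @export
setMethod("[", c("TranscriptSet", "ANY"), function(x, i, j, ..., drop = FALSE) {
  ex <- x@exons[i]
  new("TranscriptSet", exons = ex, cds = x@cds[names(x@cds) %in% names(ex)])
})

#' @rdname accessors
#' @export
setMethod("[", c("NorfSet", "ANY"), function(x, i, j, ..., drop = FALSE) {
  new("NorfSet", exons = x@exons[i])
})

setMethod("length", "TranscriptSet", function(x) length(x@exons))
setMethod("length", "NorfSet", function(x) length(x@exons))

setMethod("show", "TranscriptSet", function(object) {
  bt <- table(mcols(object@exons)$biotype, useNA = "ifany")
  cat("TranscriptSet with", length(object@exons), "transcripts (",
      length(object@cds), "with CDS )\n")
  cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = ", "), "\n")
})

setMethod("show", "NorfSet", function(object) {
  ct <- table(mcols(object@exons)$category, useNA = "ifany")
  cat("NorfSet with", length(object@exons), "nORFs\n")
  cat("  categories:", paste(names(ct), ct, sep = ":", collapse = ", "), "\n")
  fc <- mcols(object@exons)$frame_class
  if (any(!is.na(fc))) {
    ft <- table(fc, useNA = "ifany")
    cat("  frame classes:", paste(names(ft), ft, sep = ":", collapse = ", "), "\n")
  }
})

setMethod("show", "OrfExperiment", function(object) {
  cat("OrfExperiment [", object@unit, "]: ", nrow(object), " features x ",
      ncol(object), " samples\n", sep = "")
  callNextMethod()
})
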