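## Accessor generics and show methods.

#' @name accessors
#' @title Accessors for Repertoire and VSegmentSlice objects
#' @description Read-only access to sample metadata, the clonotype table,
#'   the total UMI depth and the clonotype count.
#' @param x a \code{\linkS4class{Repertoire}} or
#'   \code{\linkS4class{VSegmentSlice}}
#' @return \code{clonotypes()} a data.frame; \code{umiTotal()} and
#'   \code{nClonotypes()} integers; the metadata accessors single strings.
NULL

#' @rdname accessors
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("donorId", function(x) standardGeneric("donorId"))
#' @rdname accessors
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))
#' @rdname accessors
#' @export
setGeneric("cellSubset", function(x) standardGeneric("cellSubset"))
#' @rdname accessors
#' @export
setGeneric("vSegment", function(x) standardGeneric("vSegment"))
#' @rdname accessors
#' @export
setGeneric("umiTotal", function(x) standardGeneric("umiTotal"))
#' @rdname accessors
#' @export
setGeneric("nClonotypes", function(x) standardGeneric("nClonotypes"))
#' @rdname accessors
#' @export
setGeneric("downsampledTo", function(x) standardGeneric("downsampledTo"))

#' @rdname accessors
setMethod("clonotypes", "Repertoire", function(x) x@clonotypes)
#' @rdname accessors
setMethod("clonotypes", "VSegmentSlice", function(x) x@clonotypes)
#' @rdname accessors
setMethod("sampleId", "Repertoire", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "VSegmentSlice", function(x) x@sampleId)
#' @rdname accessors
setMethod("donorId", "Repertoire", function(x) x@donorId)
#' @rdname accessors
setMethod("cohort", "Repertoire", function(x) x@cohort)
#' @rdname accessors
setMethod("cohort", "VSegmentSlice", function(x) x@cohort)
#' @rdname accessors
setMethod("cellSubset", "Repertoire", function(x) x@cellSubset)
#' @rdname accessors
setMethod("cellSubset", "VSegmentSlice", function(x) x@cellSubset)
#' @rdname accessors
setMethod("vSegment", "VSegmentSlice", function(x) x@vSegment)
#' @rdname accessors
setMethod("umiTotal", "Repertoire",
          function(x) sum(x@clonotypes$umi_count))
#' @rdname accessors
setMethod("umiTotal", "VSegmentSlice",
          function(x) sum(x@clonotypes$umi_count))
#' @rdname accessors
setMethod("nClonotypes", "Repertoire", function(x) nrow(x@clonotypes))
#' @rdname accessors
setMethod("nClonotypes", "VSegmentSlice", function(x) nrow(x@clonotypes))
#' @rdname accessors
setMethod("downsampledTo", "VSegmentSlice", function(x) x@downsampledTo)

setMethod("show", "Repertoire", function(object) {
  cat("Repertoire", object@sampleId,
      sprintf("(donor %s, cohort %s, subset %s)\n",
              object@donorId, object@cohort, object@cellSubset))
  cat(" ", nrow(object@clonotypes), "clonotypes,",
      sum(object@clonotypes$umi_count), "UMIs,",
      length(unique(object@clonotypes$v_segment)), "V segments\n")
})

setMethod("show", "VSegmentSlice", function(object) {
  cat("VSegmentSlice", object@vSegment, "of", object@sampleId,
      sprintf("(%s/%s)\n", object@cohort, object@cellSubset))
  cat(" ", nrow(object@clonotypes), "clonotypes,",
      sum(object@clonotypes$umi_count), "UMIs")
  if (!is.na(object@downsampledTo))
    cat(", downsampled to", object@downsampledTo,
        "(seed", object@seedUsed, ")")
  cat("\n")
})

setMethod("show", "GermlineSet", function(object) {
  cat("GermlineSet:", length(object@vGenes), "TRBV,",
      length(object@dGenes), "TRBD,", length(object@jGenes), "TRBJ\n")
})

#' @rdname accessors
#' @export
setGeneric("vGenes", function(x) standardGeneric("vGenes"))
#' @rdname accessors
#' @export
setGeneric("dGenes", function(x) standardGeneric("dGenes"))
#' @rdname accessors
#' @export
setGeneric("jGenes", function(x) standardGeneric("jGenes"))
#' @rdname accessors
setMethod("vGenes", "GermlineSet", function(x) x@vGenes)
#' @rdname accessors
setMethod("dGenes", "GermlineSet", function(x) x@dGenes)
#' @rdname accessors
setMethod("jGenes", "GermlineSet", function(x) x@jGenes)
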