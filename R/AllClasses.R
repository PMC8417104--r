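## Core S4 containers.
##
## Clonotype tables are carried as plain data.frames with a fixed column
## contract (see .CLONOTYPE_COLS); the S4 classes wrap them with sample
## metadata and enforce the invariants every downstream metric relies on.

.CLONOTYPE_COLS <- c("cdr3_nt", "cdr3_aa", "v_segment", "j_segment",
                     "umi_count", "frequency")
.CLONOTYPE_OPT  <- c("v_end", "d_len", "j_start", "true_insertions")

#' Repertoire: one sample's clonotype set plus metadata
#'
#' A \code{Repertoire} holds the distinct TCR-beta clonotypes observed in
#' one sorted-subset sample. Clonotypes are keyed by the
#' (CDR3 nucleotide sequence, V segment, J segment) triple; abundance is
#' the number of UMI-labelled cDNA molecules. Rows are kept sorted by
#' descending UMI count with ties broken by CDR3 nucleotide sequence, so
#' any "top N" selection is deterministic.
#'
#' @slot sampleId sample identifier, unique within a study
#' @slot donorId donor identifier
#' @slot cohort cohort label (the study contrasts \code{XLA}, \code{young},
#'   \code{old})
#' @slot cellSubset sorted T-cell subset label (e.g. \code{nCD4},
#'   \code{mCD4}, \code{RTE}, \code{mnCD4}, \code{nTreg})
#' @slot clonotypes data.frame with columns \code{cdr3_nt},
#'   \code{cdr3_aa}, \code{v_segment}, \code{j_segment}, \code{umi_count},
#'   \code{frequency}, and optional junction-annotation columns
#'   \code{v_end}, \code{d_len}, \code{j_start}, \code{true_insertions}
#'
#' @aliases Repertoire-class
#' @exportClass Repertoire
setClass("Repertoire",
  representation(sampleId = "character", donorId = "character",
                 cohort = "character", cellSubset = "character",
                 clonotypes = "data.frame"))

.validClonotypeDF <- function(df, requireSorted = TRUE) {
  miss <- setdiff(.CLONOTYPE_COLS, names(df))
  if (length(miss))
    return(paste("missing clonotype columns:", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(is.na(df$umi_count)) || any(df$umi_count < 1) ||
      any(df$umi_count != round(df$umi_count)))
    return("umi_count must be positive integers")
  if (any(grepl("[^ACGT]", df$cdr3_nt)))
    return("cdr3_nt must contain only A/C/G/T")
  if (any(nchar(df$cdr3_nt) < 9L))
    return("cdr3_nt shorter than 9 nt")
  key <- paste(df$cdr3_nt, df$v_segment, df$j_segment, sep = "|")
  if (anyDuplicated(key))
    return("duplicate (cdr3_nt, v_segment, j_segment) triples")
  tot <- sum(df$umi_count)
  if (max(abs(df$frequency - df$umi_count / tot)) > 1e-9)
    return("frequency inconsistent with umi_count / total")
  if (requireSorted) {
    o <- order(-df$umi_count, df$cdr3_nt)
    if (!identical(o, seq_len(nrow(df))))
      return("clonotypes not sorted by descending umi_count, cdr3_nt")
  }
  TRUE
}

setValidity("Repertoire", function(object) {
  for (s in c("sampleId", "donorId", "cohort", "cellSubset")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || !nzchar(v))
      return(paste(s, "must be a single non-empty string"))
  }
  .validClonotypeDF(object@clonotypes)
})

#' VSegmentSlice: a repertoire restricted to one TRBV segment
#'
#' Diversity, convergence and CDR3 features are all evaluated per V
#' segment to remove V-dependent composition effects; the slice records
#' whether (and at which depth and seed) it has been downsampled.
#'
#' @slot sampleId,cohort,cellSubset parent sample metadata
#' @slot vSegment the TRBV segment the slice is restricted to
#' @slot clonotypes clonotype data.frame (same contract as
#'   \code{\linkS4class{Repertoire}})
#' @slot downsampledTo UMI depth the slice was downsampled to, or
#'   \code{NA} if it holds the full slice
#' @slot seedUsed RNG seed used for downsampling, or \code{NA}
#'
#' @aliases VSegmentSlice-class
#' @exportClass VSegmentSlice
setClass("VSegmentSlice",
  representation(sampleId = "character", cohort = "character",
                 cellSubset = "character", vSegment = "character",
                 clonotypes = "data.frame",
                 downsampledTo = "integer", seedUsed = "integer"))

setValidity("VSegmentSlice", function(object) {
  ok <- .validClonotypeDF(object@clonotypes, requireSorted = FALSE)
  if (!isTRUE(ok)) return(ok)
  if (nrow(object@clonotypes) &&
      length(unique(object@clonotypes$v_segment)) != 1L)
    return("slice mixes V segments")
  if (!is.na(object@downsampledTo) &&
      sum(object@clonotypes$umi_count) != object@downsampledTo)
    return("depth does not equal downsampledTo")
  TRUE
})

#' GermlineSet: synthetic germline segments for V(D)J simulation
#'
#' V entries hold the 3' end of the V gene starting at the conserved
#' cysteine codon (the CDR3 start); J entries hold the 5' head of the J
#' gene up to and including the conserved phenylalanine codon (the CDR3
#' end). Usage vectors give the segment-draw probabilities of the
#' simulator.
#'
#' @slot vGenes,dGenes,jGenes named character vectors of A/C/G/T sequences
#' @slot vUsage,jUsage named probability vectors over vGenes / jGenes
#'
#' @aliases GermlineSet-class
#' @exportClass GermlineSet
setClass("GermlineSet",
  representation(vGenes = "character", dGenes = "character",
                 jGenes = "character",
                 vUsage = "numeric", jUsage = "numeric"))

setValidity("GermlineSet", function(object) {
  seqs <- c(object@vGenes, object@dGenes, object@jGenes)
  if (any(grepl("[^ACGT]", seqs))) return("germline sequences must be A/C/G/T")
  if (!identical(names(object@vUsage), names(object@vGenes)))
    return("vUsage names must match vGenes")
  if (!identical(names(object@jUsage), names(object@jGenes)))
    return("jUsage names must match jGenes")
  if (abs(sum(object@vUsage) - 1) > 1e-9 || abs(sum(object@jUsage) - 1) > 1e-9)
    return("usage vectors must sum to 1")
  if (any(object@vUsage < 0) || any(object@jUsage < 0))
    return("usage probabilities must be nonnegative")
  TRUE
})

## ---- constructors ----------------------------------------------------

## Normalize a clonotype data.frame: fill cdr3_aa, recompute frequencies,
## sort by (-umi, cdr3_nt). Internal; used by every public constructor.
.finalizeClonotypes <- function(df) {
  if (nrow(df) == 0L) {
    df <- data.frame(cdr3_nt = character(), cdr3_aa = character(),
                     v_segment = character(), j_segment = character(),
                     umi_count = integer(), frequency = numeric(),
                     stringsAsFactors = FALSE)
    return(df)
  }
  if (is.null(df$cdr3_aa) || anyNA(df$cdr3_aa))
    df$cdr3_aa <- translateCdr3(df$cdr3_nt)
  df$umi_count <- as.integer(df$umi_count)
  df$frequency <- df$umi_count / sum(df$umi_count)
  df <- df[order(-df$umi_count, df$cdr3_nt), , drop = FALSE]
  rownames(df) <- NULL
  keep <- c(.CLONOTYPE_COLS, intersect(.CLONOTYPE_OPT, names(df)))
  df[, keep, drop = FALSE]
}

#' Construct a Repertoire
#'
#' @param clonotypes data.frame with at least \code{cdr3_nt},
#'   \code{v_segment}, \code{j_segment}, \code{umi_count};
#'   \code{cdr3_aa} is translated and \code{frequency} recomputed.
#' @param sampleId,donorId,cohort,cellSubset sample metadata strings
#' @param mergeDuplicates merge rows sharing a (cdr3_nt, V, J) triple by
#'   summing their counts (with a warning) instead of failing validity
#' @return a validated \code{\linkS4class{Repertoire}}
#' @export
Repertoire <- function(clonotypes, sampleId, donorId = sampleId,
                       cohort = "unknown", cellSubset = "unknown",
                       mergeDuplicates = FALSE) {
  df <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  if (mergeDuplicates && nrow(df)) {
    key <- paste(df$cdr3_nt, df$v_segment, df$j_segment, sep = "|")
    if (anyDuplicated(key)) {
      warning(sum(duplicated(key)),
              " duplicate (cdr3_nt, V, J) rows merged by summing counts")
      agg <- rowsum(df$umi_count, key)
      first <- df[!duplicated(key), , drop = FALSE]
      first$umi_count <- as.integer(agg[paste(first$cdr3_nt, first$v_segment,
                                              first$j_segment, sep = "|"), 1])
      df <- first
    }
  }
  methods::new("Repertoire", sampleId = sampleId, donorId = donorId,
               cohort = cohort, cellSubset = cellSubset,
               clonotypes = .finalizeClonotypes(df))
}

## Internal VSegmentSlice constructor.
.newSlice <- function(df, sampleId, cohort, cellSubset, vSegment,
                      downsampledTo = NA_integer_, seedUsed = NA_integer_) {
  df$frequency <- df$umi_count / sum(df$umi_count)
  rownames(df) <- NULL
  methods::new("VSegmentSlice", sampleId = sampleId, cohort = cohort,
               cellSubset = cellSubset, vSegment = vSegment,
               clonotypes = df,
               downsampledTo = as.integer(downsampledTo),
               seedUsed = as.integer(seedUsed))
}
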