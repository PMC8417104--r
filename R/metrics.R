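## Repertoire-level statistics: seeded UMI downsampling, Chao1 richness,
## normalized Shannon-Wiener evenness, convergence, public-clonotype
## sharing.

#' Insufficient-coverage condition
#'
#' Signalled (as an error of class \code{insufficientCoverage}) when a
#' sample or V-segment slice does not hold enough UMIs for the requested
#' equal-depth analysis. The pipeline catches it and records the sample as
#' excluded from that analysis rather than dropping it silently.
#'
#' @param msg message text
#' @keywords internal
.insufficientCoverage <- function(msg) {
  stop(structure(class = c("insufficientCoverage", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## Multivariate-hypergeometric draw of n UMIs without replacement from
## integer counts; returns the downsampled count vector.
.hyperDownsample <- function(counts, n) {
  idx <- rep.int(seq_along(counts), counts)
  take <- sample(idx, n)
  tabulate(take, nbins = length(counts))
}

#' Downsample to a fixed number of UMIs
#'
#' Samples \code{n} UMIs without replacement from the multiset of all
#' UMI-labelled molecules (a multivariate hypergeometric draw over
#' clonotypes); clonotypes reduced to zero are dropped. Equal-depth
#' downsampling is the normalization behind all diversity, convergence
#' and publicity comparisons, removing the dependence of richness
#' estimates on sequencing depth.
#'
#' @param x a \code{\linkS4class{VSegmentSlice}} or
#'   \code{\linkS4class{Repertoire}}
#' @param n target UMI count; if the object holds fewer UMIs an
#'   \code{insufficientCoverage} error is signalled
#' @param seed RNG seed making the draw reproducible
#' @return an object of the same class at depth exactly \code{n}
#' @export
setGeneric("downsampleUmis",
           function(x, n, seed = NULL) standardGeneric("downsampleUmis"))

.downsampleDF <- function(df, n, seed) {
  depth <- sum(df$umi_count)
  if (depth < n)
    .insufficientCoverage(sprintf(
      "insufficient coverage: %d UMIs available, %d requested", depth, n))
  if (depth == n) return(df)
  newCounts <- withSeed(seed, .hyperDownsample(df$umi_count, n))
  df$umi_count <- as.integer(newCounts)
  df <- df[df$umi_count > 0L, , drop = FALSE]
  df$frequency <- df$umi_count / n
  df
}

#' @rdname downsampleUmis
setMethod("downsampleUmis", "VSegmentSlice", function(x, n, seed = NULL) {
  df <- .downsampleDF(clonotypes(x), n, seed)
  .newSlice(df, sampleId(x), cohort(x), cellSubset(x), vSegment(x),
            downsampledTo = n,
            seedUsed = if (is.null(seed)) NA_integer_ else seed)
})

#' @rdname downsampleUmis
setMethod("downsampleUmis", "Repertoire", function(x, n, seed = NULL) {
  df <- .downsampleDF(clonotypes(x), n, seed)
  methods::initialize(x, clonotypes = .finalizeClonotypes(df))
})

#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: \eqn{S_{obs} + f_1 (f_1 - 1) / (2 (f_2 + 1))},
#' where \eqn{f_1} and \eqn{f_2} are the numbers of clonotypes observed
#' exactly once and twice. Estimates total repertoire richness from the
#' rare tail; the bias-corrected form stays defined when no doubletons
#' are observed.
#'
#' @param counts positive integer clonotype counts (or an object with
#'   clonotypes)
#' @return the Chao1 estimate (always \eqn{\ge S_{obs}})
#' @export
chao1 <- function(counts) {
  counts <- .asCounts(counts)
  if (!length(counts)) stop("empty count vector", call. = FALSE)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Normalized Shannon-Wiener index (Pielou evenness)
#'
#' Shannon entropy of the clonotype frequency distribution divided by its
#' maximum \eqn{\ln S_{obs}}: \eqn{H / \ln S_{obs} \in (0, 1]}. Measures
#' the evenness of the clone-size distribution; its complement is
#' clonality.
#'
#' @param counts positive integer clonotype counts (at least two distinct
#'   clonotypes)
#' @return evenness in (0, 1]
#' @export
shannonWienerNormalized <- function(counts) {
  counts <- .asCounts(counts)
  if (length(counts) < 2L)
    stop("evenness undefined for fewer than 2 clonotypes", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(length(counts))
}

.asCounts <- function(x) {
  if (methods::is(x, "Repertoire") || methods::is(x, "VSegmentSlice"))
    x <- clonotypes(x)$umi_count
  stopifnot(is.numeric(x), all(x >= 1), all(x == round(x)))
  x
}

#' Convergent-recombination index
#'
#' The relative number of distinct nucleotide sequence variants per
#' amino-acid CDR3 sequence: (number of distinct \code{cdr3_nt}
#' clonotypes) / (number of distinct \code{cdr3_aa} sequences) within the
#' slice. Always \eqn{\ge 1}; equal to 1 exactly when translation is
#' injective on the slice.
#'
#' @param x a \code{\linkS4class{VSegmentSlice}},
#'   \code{\linkS4class{Repertoire}} or clonotype data.frame whose
#'   clonotypes are all functional
#' @return the convergence ratio
#' @export
convergence <- function(x) {
  df <- if (is.data.frame(x)) x else clonotypes(x)
  if (!nrow(df)) stop("empty slice", call. = FALSE)
  if (any(grepl("[*_]", df$cdr3_aa)))
    stop("convergence requires functional clonotypes only", call. = FALSE)
  length(unique(df$cdr3_nt)) / length(unique(df$cdr3_aa))
}

#' Diversity metrics for one slice
#'
#' Convenience wrapper evaluating observed richness, Chao1, normalized
#' Shannon-Wiener and convergence on one (optionally downsampled) slice.
#'
#' @param slice a \code{\linkS4class{VSegmentSlice}}
#' @return one-row data.frame: sample_id, v_segment, n_umi, observed,
#'   chao1, shannon_norm, convergence
#' @export
diversityMetrics <- function(slice) {
  counts <- clonotypes(slice)$umi_count
  data.frame(sample_id = sampleId(slice), v_segment = vSegment(slice),
             n_umi = sum(counts), observed = length(counts),
             chao1 = chao1(counts),
             shannon_norm = shannonWienerNormalized(counts),
             convergence = convergence(slice),
             stringsAsFactors = FALSE)
}

#' Shared public clonotypes between two samples
#'
#' Downsamples each whole repertoire to \code{equalUmi} UMIs (with a
#' per-sample seed, so the comparison is symmetric), takes each sample's
#' \code{topN} most abundant clonotypes after downsampling (ties broken by
#' CDR3 nucleotide sequence), collapses each side to its set of distinct
#' CDR3 amino-acid sequences, and returns the size of the intersection --
#' the number of public amino-acid clonotypes shared by the pair.
#'
#' @param repA,repB \code{\linkS4class{Repertoire}} objects
#' @param topN number of most-abundant clonotypes considered per sample
#' @param equalUmi common UMI depth both samples are downsampled to;
#'   samples below it signal \code{insufficientCoverage}
#' @param seed master seed; each sample's downsampling seed is derived
#'   from \code{seed} and its \code{sampleId} only, making the result
#'   symmetric in (A, B)
#' @return integer count of shared amino-acid CDR3 sequences
#' @export
pairwisePublicity <- function(repA, repB, topN, equalUmi, seed = 1L) {
  topAA <- function(r) {
    d <- downsampleUmis(r, equalUmi, seed = deriveSeed(seed, sampleId(r),
                                                       "publicity"))
    df <- clonotypes(d)            # already sorted (-umi, cdr3_nt)
    unique(df$cdr3_aa[seq_len(min(topN, nrow(df)))])
  }
  length(intersect(topAA(repA), topAA(repB)))
}
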