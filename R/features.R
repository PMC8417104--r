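## Abundance-weighted CDR3 physicochemical and structural features:
## central-region interaction strength, side-chain volume, charge, CDR3
## length, added (non-templated) nucleotides, within-stratum Z-scoring.

#' Residue scales used by the CDR3 features
#'
#' \code{strong}: the hydrophobic and aromatic residues F, I, L, M, V, W,
#' Y, whose presence in the CDR3 centre is associated with stronger
#' peptide-MHC contact. \code{charged}: D, E, K, R (histidine excluded --
#' mostly uncharged at physiological pH). \code{volume}: amino-acid
#' residue volumes in cubic Angstroms (Zamyatnin, 1972, Prog Biophys Mol
#' Biol 24:107-123), covering all 20 standard residues.
#'
#' @return list with elements \code{strong}, \code{charged} (character
#'   vectors) and \code{volume} (named numeric vector)
#' @export
residueScales <- function() {
  list(
    strong = c("F", "I", "L", "M", "V", "W", "Y"),
    charged = c("D", "E", "K", "R"),
    volume = c(A = 88.6,  R = 173.4, N = 114.1, D = 111.1, C = 108.5,
               Q = 143.8, E = 138.4, G = 60.1,  H = 153.2, I = 166.7,
               L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
               S = 89.0,  T = 116.1, W = 227.8, Y = 193.6, V = 140.0))
}

#' Central region of a CDR3
#'
#' The \code{k} residues in the middle of the CDR3 loop, the positions
#' with the highest probability of contacting the peptide-MHC complex.
#' The window starts at 0-based offset \code{floor((L - k) / 2)}, so
#' even-parity ties resolve toward the N-terminus. Sequences shorter than
#' \code{k} return \code{NA} (the clonotype is excluded from
#' central-region features; length/insertion features still use it).
#'
#' @param cdr3aa character vector of functional amino-acid CDR3s
#' @param k window width (default 5)
#' @return character vector of \code{k}-residue windows (or \code{NA})
#' @export
centralRegion <- function(cdr3aa, k = 5L) {
  L <- nchar(cdr3aa)
  off <- floor((L - k) / 2)
  out <- substr(cdr3aa, off + 1L, off + k)
  out[L < k] <- NA_character_
  out
}

.centralFraction <- function(cdr3aa, set, k = 5L) {
  win <- centralRegion(cdr3aa, k)
  vapply(strsplit(win, NULL), function(ch) {
    if (length(ch) == 0L || anyNA(ch)) return(NA_real_)
    mean(ch %in% set)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Central-region CDR3 features of single clonotypes
#'
#' \code{clonotypeStrength}: fraction of the central \code{k} residues
#' that are strongly interacting (hydrophobic/aromatic).
#' \code{clonotypeVolume}: mean residue volume over the central window in
#' cubic Angstroms. \code{clonotypeCharge}: fraction of central residues
#' that are charged. All return \code{NA} for CDR3s shorter than
#' \code{k}.
#'
#' @param cdr3aa character vector of functional amino-acid CDR3s
#' @param scales residue scales, see \code{\link{residueScales}}
#' @param k central window width
#' @return numeric vector
#' @export
clonotypeStrength <- function(cdr3aa, scales = residueScales(), k = 5L)
  .centralFraction(cdr3aa, scales$strong, k)

#' @rdname clonotypeStrength
#' @export
clonotypeCharge <- function(cdr3aa, scales = residueScales(), k = 5L)
  .centralFraction(cdr3aa, scales$charged, k)

#' @rdname clonotypeStrength
#' @export
clonotypeVolume <- function(cdr3aa, scales = residueScales(), k = 5L) {
  win <- centralRegion(cdr3aa, k)
  vapply(strsplit(win, NULL), function(ch) {
    if (length(ch) == 0L || anyNA(ch)) return(NA_real_)
    mean(scales$volume[ch])
  }, numeric(1), USE.NAMES = FALSE)
}

## Longest substring of any D gene occurring in `mid`, counted only when
## >= 3 nt (shorter matches are indistinguishable from chance).
.bestDMatch <- function(mid, dGenes) {
  L <- nchar(mid)
  if (L < 3L) return(0L)
  best <- 0L
  for (d in dGenes) {
    dl <- nchar(d)
    for (len in seq(min(L, dl), 3L)) {
      found <- FALSE
      for (s in seq_len(dl - len + 1L)) {
        if (grepl(substr(d, s, s + len - 1L), mid, fixed = TRUE)) {
          found <- TRUE; break
        }
      }
      if (found) { if (len > best) best <- len; break }
    }
    if (best >= min(L, dl)) break
  }
  best
}

#' Number of added (non-templated) nucleotides in a CDR3
#'
#' Estimates the number of random nucleotides inserted at the V-D and D-J
#' junctions. When junction annotation is present (columns \code{v_end},
#' \code{d_len}, \code{j_start}, as recorded by the simulator or an
#' upstream aligner) the count is exact:
#' \code{(j_start - v_end) - d_len}. Otherwise it is inferred by germline
#' matching: the V match is the longest prefix of the CDR3 agreeing with
#' the germline V tail, the J match the longest suffix agreeing with the
#' germline J head (matches are maximized in that order), and the D match
#' the longest substring of any D gene found in the remaining middle,
#' counted only when at least 3 nt. Negative remainders (overlapping
#' chance matches) clamp to 0.
#'
#' @param clonotypes clonotype data.frame (or Repertoire/VSegmentSlice)
#' @param germline a \code{\linkS4class{GermlineSet}} providing the V
#'   tails, D genes and J heads
#' @return integer vector of added-nucleotide counts
#' @export
addedNucleotides <- function(clonotypes, germline) {
  df <- if (is.data.frame(clonotypes)) clonotypes else clonotypes(clonotypes)
  n <- nrow(df)
  out <- integer(n)
  hasAnn <- all(c("v_end", "d_len", "j_start") %in% names(df))
  ann <- if (hasAnn) !is.na(df$v_end) & !is.na(df$d_len) & !is.na(df$j_start)
         else rep(FALSE, n)
  out[ann] <- (df$j_start[ann] - df$v_end[ann]) - df$d_len[ann]
  todo <- which(!ann)
  if (length(todo)) {
    missingV <- setdiff(unique(df$v_segment[todo]), names(germline@vGenes))
    missingJ <- setdiff(unique(df$j_segment[todo]), names(germline@jGenes))
    if (length(missingV) || length(missingJ))
      stop("germline lacks segment(s): ",
           paste(c(missingV, missingJ), collapse = ", "), call. = FALSE)
    revJ <- .reverseString(unname(germline@jGenes))
    names(revJ) <- names(germline@jGenes)
    for (i in todo) {
      nt <- df$cdr3_nt[i]
      L <- nchar(nt)
      vm <- .lcpLength(nt, germline@vGenes[[df$v_segment[i]]])
      jm <- .lcpLength(.reverseString(nt), revJ[[df$j_segment[i]]])
      jm <- min(jm, L - vm)      # V match has priority on overlap
      mid <- substr(nt, vm + 1L, L - jm)
      dm <- .bestDMatch(mid, germline@dGenes)
      out[i] <- max(L - vm - jm - dm, 0L)
    }
  }
  out[out < 0L] <- 0L
  out
}

#' Abundance-weighted mean of a per-clonotype feature
#'
#' \eqn{\sum_i w_i x_i / \sum_i w_i} with \eqn{w_i} the clonotype's UMI
#' count (or 1 for unweighted). Clonotypes whose feature value is
#' \code{NA} (e.g. CDR3 too short for the central window) contribute to
#' neither sum. Equivalent to expanding every clonotype into its
#' individual UMI-labelled molecules and taking a plain mean.
#'
#' @param slice a \code{\linkS4class{VSegmentSlice}} (or Repertoire)
#' @param values numeric vector of per-clonotype feature values, aligned
#'   with the clonotype rows
#' @param weighting \code{"umi"} or \code{"unweighted"}
#' @return the weighted mean, or \code{NA} if every clonotype is excluded
#' @export
weightedFeature <- function(slice, values,
                            weighting = c("umi", "unweighted")) {
  weighting <- match.arg(weighting)
  df <- if (is.data.frame(slice)) slice else clonotypes(slice)
  stopifnot(length(values) == nrow(df))
  w <- if (weighting == "umi") df$umi_count else rep(1, nrow(df))
  ok <- !is.na(values)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * values[ok]) / sum(w[ok])
}

.FEATURES <- c("strength", "volume", "charge", "cdr3_len", "added_nt",
               "shannon_norm", "chao1", "convergence")

#' Per-clonotype feature values for a slice
#'
#' @param slice a \code{\linkS4class{VSegmentSlice}}
#' @param germline germline set for added-nucleotide inference (may be
#'   omitted when junction annotation is present)
#' @param scales residue scales
#' @return data.frame of per-clonotype values: strength, volume, charge,
#'   cdr3_len, added_nt
#' @export
clonotypeFeatures <- function(slice, germline = NULL,
                              scales = residueScales()) {
  df <- if (is.data.frame(slice)) slice else clonotypes(slice)
  addedNt <- if (is.null(germline) &&
                 !all(c("v_end", "d_len", "j_start") %in% names(df)))
    rep(NA_integer_, nrow(df))
  else addedNucleotides(df, germline)
  data.frame(strength = clonotypeStrength(df$cdr3_aa, scales),
             volume = clonotypeVolume(df$cdr3_aa, scales),
             charge = clonotypeCharge(df$cdr3_aa, scales),
             cdr3_len = nchar(df$cdr3_aa),
             added_nt = addedNt)
}

#' Z-score features within (subset, V segment, feature) strata
#'
#' To remove the dependence of feature values on the V segment, every
#' feature is standardized across samples within its (cell subset, V
#' segment) stratum: \eqn{z = (x - \bar x) / \sigma} with the population
#' standard deviation. Degenerate strata (zero variance) map to all-zero
#' z-values; strata with a single sample are dropped with a warning. Raw
#' values are retained alongside.
#'
#' @param records feature data.frame with columns \code{sample_id},
#'   \code{subset}, \code{v_segment}, \code{feature}, \code{raw_value}
#' @return the same data.frame with a \code{z_value} column
#' @export
zscoreWithinStratum <- function(records) {
  need <- c("sample_id", "subset", "v_segment", "feature", "raw_value")
  stopifnot(all(need %in% names(records)))
  key <- interaction(records$subset, records$v_segment, records$feature,
                     drop = TRUE)
  sizes <- table(key)
  single <- names(sizes)[sizes == 1L]
  if (length(single)) {
    warning(length(single),
            " stratum/strata with a single sample dropped from z-scoring")
    keep <- !(as.character(key) %in% single)
    records <- records[keep, , drop = FALSE]
    key <- droplevels(key[keep])
  }
  z <- stats::ave(records$raw_value, key, FUN = function(x) {
    s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))  # population sd
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  records$z_value <- z
  rownames(records) <- NULL
  records
}

#' Aggregate z-scored features over V segments
#'
#' \code{pooled_segments} keeps one observation per (sample, V segment)
#' -- the unit used for group testing, mirroring per-segment panel
#' pooling. \code{mean_over_segments} averages each sample's z-values
#' over its retained segments, giving one value per (sample, feature) --
#' the input for PCA.
#'
#' @param records z-scored feature data.frame
#'   (\code{\link{zscoreWithinStratum}} output)
#' @param mode \code{"pooled_segments"} or \code{"mean_over_segments"}
#' @return a feature data.frame
#' @export
aggregateSampleFeatures <- function(records,
                                    mode = c("pooled_segments",
                                             "mean_over_segments")) {
  mode <- match.arg(mode)
  stopifnot("z_value" %in% names(records))
  if (mode == "pooled_segments") return(records)
  agg <- stats::aggregate(z_value ~ sample_id + subset + feature,
                          data = records, FUN = mean)
  meta <- unique(records[, intersect(c("sample_id", "donor_id", "cohort"),
                                     names(records)), drop = FALSE])
  merge(agg, meta, by = "sample_id", sort = TRUE)
}
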