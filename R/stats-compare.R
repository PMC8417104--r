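## Rank-based inference implemented from the defining formulas:
## Kruskal-Wallis omnibus, Dunn pairwise post-hoc, Benjamini-Hochberg
## step-up adjustment, Wilcoxon rank-sum (exact for small untied samples),
## and SVD-based PCA. Tail probabilities come from the standard
## chi-square / normal routines.

.midranks <- function(x) rank(x, ties.method = "average")

## Sum of (t^3 - t) over tie groups of the pooled sample.
.tieTerm <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank-sum test
#'
#' Midranks the pooled data and computes
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - (N+1)/2)^2}
#' divided by the tie-correction factor
#' \eqn{1 - \sum_g (t_g^3 - t_g) / (N^3 - N)}; the p-value is the upper
#' chi-square tail with \eqn{k - 1} degrees of freedom. Used to compare
#' the medians of three or more cohorts.
#'
#' @param groups list of numeric vectors, one per group (each nonempty)
#' @return list with \code{H}, \code{p}, \code{df}, and per-group mean
#'   ranks \code{meanRanks}
#' @export
kruskalWallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- .midranks(pooled)
  g <- rep(seq_along(groups), lengths(groups))
  meanRanks <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) *
    sum(lengths(groups) * (meanRanks - (N + 1) / 2)^2)
  corr <- 1 - .tieTerm(pooled) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  k <- length(groups)
  p <- if (H == 0) 1 else stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  list(H = H, p = p, df = k - 1L,
       meanRanks = as.numeric(meanRanks))
}

#' Dunn pairwise post-hoc comparisons
#'
#' For every pair of groups, on the midranks of the pooled data:
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left[\frac{N(N+1)}{12} -
#'    \frac{\sum_g(t_g^3 - t_g)}{12(N-1)}\right]
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with two-sided p-values from the standard normal. Raw p-values are
#' returned; apply \code{\link{benjaminiHochberg}} across the family.
#'
#' @param groups named (or unnamed) list of numeric vectors
#' @return data.frame with columns \code{group_i}, \code{group_j},
#'   \code{z}, \code{p_raw}
#' @export
dunnPairwise <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L))
  nms <- names(groups)
  if (is.null(nms)) nms <- as.character(seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- .midranks(pooled)
  g <- rep(seq_along(groups), lengths(groups))
  meanRanks <- tapply(r, g, mean)
  n <- lengths(groups)
  varCore <- N * (N + 1) / 12 - .tieTerm(pooled) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(varCore * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (meanRanks[i] - meanRanks[j]) / se else 0
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(group_i = nms[pairs[1, ]], group_j = nms[pairs[2, ]],
             z = res[1, ], p_raw = pmin(res[2, ], 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted \eqn{p_{(i)} = \min_{j \ge i} (m \, p_{(j)} / j)}, capped at
#' 1 and returned in the input order. Controls the false discovery rate
#' across a family of tests; rejecting adjusted p-values below
#' \eqn{\alpha} reproduces the classic step-up rejection set.
#'
#' @param pRaw numeric vector of raw p-values in [0, 1]
#' @return adjusted p-values in input order
#' @export
benjaminiHochberg <- function(pRaw) {
  stopifnot(is.numeric(pRaw))
  if (any(is.na(pRaw) | pRaw < 0 | pRaw > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pRaw)
  if (m == 0L) return(numeric(0))
  o <- order(pRaw)
  adj <- rev(cummin(rev(m * pRaw[o] / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided test of a location shift between two samples. When the
#' pooled sample size is at most \code{exactLimit} and there are no ties,
#' the null distribution of the rank sum is enumerated exactly over all
#' \eqn{\binom{N}{n_a}} rank assignments and
#' \eqn{p = \min(1, 2\min(P(W \le w), P(W \ge w)))}. Otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b numeric vectors (both nonempty)
#' @param exactLimit largest pooled size for exact enumeration
#' @return list with \code{W} (rank sum of \code{a}), \code{p}, and
#'   \code{method} (\code{"exact"} or \code{"normal"})
#' @export
wilcoxonRankSum <- function(a, b, exactLimit = 12L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  pooled <- c(a, b)
  N <- length(pooled)
  na <- length(a)
  r <- .midranks(pooled)
  W <- sum(r[seq_len(na)])
  ties <- anyDuplicated(pooled) > 0L
  if (length(unique(pooled)) == 1L)
    return(list(W = W, p = 1, method = "degenerate"))
  if (N <= exactLimit && !ties) {
    sums <- utils::combn(N, na, FUN = function(idx) sum(idx))
    pLe <- mean(sums <= W)
    pGe <- mean(sums >= W)
    p <- min(1, 2 * min(pLe, pGe))
    return(list(W = W, p = p, method = "exact"))
  }
  nb <- N - na
  mu <- na * (N + 1) / 2
  sigma2 <- na * nb / 12 * ((N + 1) - .tieTerm(pooled) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(W = W, p = 1, method = "normal"))
  d <- W - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)   # continuity correction
  list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Principal component analysis of a feature matrix
#'
#' Column-centers (and unit-scales, if \code{standardize}) the samples x
#' characteristics matrix and decomposes it by SVD. Scores are
#' \eqn{U D}, loadings the right singular vectors, explained-variance
#' fractions \eqn{d_i^2 / \sum d^2}. Sign convention: each loading
#' column's largest-magnitude entry is made positive, so results are
#' deterministic across platforms.
#'
#' @param x numeric matrix, samples in rows, characteristics in columns,
#'   no missing values
#' @param standardize divide each column by its (sample) standard
#'   deviation; constant columns are dropped with a warning
#' @return list with \code{scores}, \code{loadings},
#'   \code{varianceFraction}, \code{center}, \code{scale}
#' @export
pcaFeatures <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  scl <- rep(1, ncol(x))
  if (standardize) {
    scl <- apply(xc, 2, stats::sd)
    const <- scl == 0 | is.na(scl)
    if (any(const)) {
      warning(sum(const), " constant column(s) dropped from PCA")
      xc <- xc[, !const, drop = FALSE]
      ctr <- ctr[!const]
      scl <- scl[!const]
      if (ncol(xc) < 2L) stop("fewer than 2 varying columns", call. = FALSE)
    }
    xc <- sweep(xc, 2, scl, "/")
  }
  if (all(xc == 0)) stop("rank-0 matrix: no variation to decompose",
                         call. = FALSE)
  sv <- svd(xc)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(sv$u %*% diag(sv$d, nrow = length(sv$d)), 2, flip, "*")
  k <- length(sv$d)
  dimnames(loadings) <- list(colnames(xc), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(xc), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings,
       varianceFraction = sv$d^2 / sum(sv$d^2),
       center = ctr, scale = scl)
}

#' Group tests for every feature of a study
#'
#' For each (subset, feature), splits the chosen observation units by
#' cohort and runs either the Kruskal-Wallis omnibus followed by Dunn
#' pairwise comparisons with Benjamini-Hochberg adjustment (3+ cohorts),
#' or the Wilcoxon rank-sum test (2 cohorts). Adjustment is applied
#' within each feature's family of pairwise comparisons.
#'
#' @param records z-scored feature data.frame with columns
#'   \code{sample_id}, \code{cohort}, \code{subset}, \code{feature},
#'   \code{z_value}
#' @param value which column to test (default \code{"z_value"})
#' @return data.frame: subset, feature, test, group_i, group_j, n_i, n_j,
#'   statistic, z, p_raw, p_adj (omnibus rows carry H and its p)
#' @export
compareCohorts <- function(records, value = "z_value") {
  stopifnot(all(c("cohort", "subset", "feature", value) %in% names(records)))
  out <- list()
  for (ss in unique(records$subset)) {
    sub <- records[records$subset == ss, , drop = FALSE]
    for (ft in unique(sub$feature)) {
      d <- sub[sub$feature == ft, , drop = FALSE]
      groups <- split(d[[value]], d$cohort)
      groups <- groups[lengths(groups) > 0L]
      if (length(groups) < 2L) next
      n <- lengths(groups)
      if (length(groups) >= 3L) {
        kw <- kruskalWallis(groups)
        dn <- dunnPairwise(groups)
        dn$p_adj <- benjaminiHochberg(dn$p_raw)
        rows <- data.frame(subset = ss, feature = ft, test = "dunn",
                           group_i = dn$group_i, group_j = dn$group_j,
                           n_i = as.integer(n[dn$group_i]),
                           n_j = as.integer(n[dn$group_j]),
                           statistic = kw$H, z = dn$z,
                           p_raw = dn$p_raw, p_adj = dn$p_adj,
                           kw_p = kw$p, stringsAsFactors = FALSE)
      } else {
        wt <- wilcoxonRankSum(groups[[1]], groups[[2]])
        rows <- data.frame(subset = ss, feature = ft, test = "wilcoxon",
                           group_i = names(groups)[1],
                           group_j = names(groups)[2],
                           n_i = n[[1]], n_j = n[[2]],
                           statistic = wt$W, z = NA_real_,
                           p_raw = wt$p, p_adj = wt$p, kw_p = NA_real_,
                           stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- rows
    }
  }
  if (!length(out))
    return(data.frame(subset = character(), feature = character(),
                      test = character(), group_i = character(),
                      group_j = character(), n_i = integer(),
                      n_j = integer(), statistic = numeric(), z = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      kw_p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
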