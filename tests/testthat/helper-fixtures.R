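## Small in-code fixtures shared across test files.

## A valid clonotype row set from explicit counts; nt sequences are
## distinct, in-frame and stop-free unless `nt` is supplied.
makeClonotypes <- function(counts, v = "TRBV9", j = "TRBJ2-7", nt = NULL) {
  n <- length(counts)
  if (is.null(nt)) {
    codons <- c("GCC", "AGC", "ACC", "GGG", "CTG", "TAT", "CAG", "GAA",
                "TTC", "ATG")
    nt <- vapply(seq_len(n), function(i) {
      idx <- 1 + ((i - 1 + seq_len(4)) %% length(codons))
      paste0("TGCGCCAGCAGC", paste(codons[idx], collapse = ""), "TTC")
    }, character(1))
  }
  data.frame(cdr3_nt = nt,
             v_segment = rep_len(v, n), j_segment = rep_len(j, n),
             umi_count = as.integer(counts), stringsAsFactors = FALSE)
}

makeTestRepertoire <- function(counts, sampleId = "s1", cohort = "young",
                               cellSubset = "nTreg", ...) {
  Repertoire(makeClonotypes(counts, ...), sampleId = sampleId,
             cohort = cohort, cellSubset = cellSubset)
}

## Independent midrank implementation for cross-checks: rank by counting,
## never via rank().
bruteMidranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

## Independent brute-force Kruskal-Wallis H and Dunn z values built on
## bruteMidranks; mirrors the defining formulas line by line.
bruteKWDunn <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- bruteMidranks(pooled)
  g <- rep(seq_along(groups), lengths(groups))
  Rbar <- vapply(seq_along(groups), function(i) mean(r[g == i]), numeric(1))
  n <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  tie <- sum(sapply(unique(pooled), function(v) {
    t <- sum(pooled == v); t^3 - t
  }))
  H <- H / (1 - tie / (N^3 - N))
  varCore <- N * (N + 1) / 12 - tie / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  z <- apply(pairs, 2, function(ij)
    (Rbar[ij[1]] - Rbar[ij[2]]) /
      sqrt(varCore * (1 / n[ij[1]] + 1 / n[ij[2]])))
  list(H = H, z = z)
}
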