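test_that("Kruskal-Wallis H matches hand computation and degenerate cases", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)                    # rank means 2, 5, 8
  expect_equal(kw$df, 2L)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))
  same <- kruskalWallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(41)
  g <- list(rnorm(6), rnorm(8), rnorm(5))
  h0 <- kruskalWallis(g)$H
  expect_equal(kruskalWallis(lapply(g, exp))$H, h0)
  expect_equal(kruskalWallis(lapply(g, function(x) x^3 + 10))$H, h0)
})

test_that("Kruskal-Wallis agrees with the reference implementation under ties", {
  set.seed(43)
  for (i in 1:100) {
    g <- lapply(sample(3:5, sample(3:4, 1), replace = TRUE),
                function(n) sample(1:6, n, replace = TRUE))  # heavy ties
    if (length(unique(unlist(g))) < 2) next
    kw <- kruskalWallis(g)
    ref <- kruskal.test(unlist(g), factor(rep(seq_along(g), lengths(g))))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Dunn z values behave under symmetry, ordering and no-tie reduction", {
  ## mirrored layout: outer-pair z values are antisymmetric
  g <- list(c(1, 2), c(5, 6), c(9, 10))
  dz <- dunnPairwise(g)
  z13 <- dz$z[dz$group_i == "1" & dz$group_j == "3"]
  z12 <- dz$z[dz$group_i == "1" & dz$group_j == "2"]
  z23 <- dz$z[dz$group_i == "2" & dz$group_j == "3"]
  expect_equal(z12, z23)            # mirrored spacing
  ## extreme pair carries the largest |z|
  g2 <- list(c(1, 2, 3), c(4.5, 5, 5.5), c(7, 8, 9))
  dz2 <- dunnPairwise(g2)
  expect_equal(which.max(abs(dz2$z)),
               which(dz2$group_i == "1" & dz2$group_j == "3"))
  ## without ties the tie term vanishes: equal to untied closed form
  set.seed(47)
  x <- list(runif(4), runif(5), runif(3))
  N <- 12
  pooled <- unlist(x)
  r <- rank(pooled)
  gidx <- rep(1:3, lengths(x))
  z12hand <- (mean(r[gidx == 1]) - mean(r[gidx == 2])) /
    sqrt(N * (N + 1) / 12 * (1 / 4 + 1 / 5))
  dz3 <- dunnPairwise(x)
  expect_equal(dz3$z[dz3$group_i == "1" & dz3$group_j == "2"], z12hand,
               tolerance = 1e-12)
})

test_that("KW and Dunn match an independent brute-force midrank computation", {
  set.seed(53)
  for (i in 1:100) {
    g <- lapply(sample(3:6, 3, replace = TRUE),
                function(n) sample(seq(0, 5, 0.5), n, replace = TRUE))
    if (length(unique(unlist(g))) < 2) next
    brute <- bruteKWDunn(g)
    expect_equal(kruskalWallis(g)$H, brute$H, tolerance = 1e-10)
    expect_equal(dunnPairwise(g)$z, unname(brute$z), tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg reproduces the step-up rule", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjaminiHochberg(0.37), 0.37)   # m = 1 unchanged
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(59)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    adj <- benjaminiHochberg(p)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    ## rejection set identity with the classic step-up procedure
    alpha <- 0.2
    m <- length(p)
    o <- order(p)
    k <- which(p[o] <= alpha * seq_len(m) / m)
    stepUp <- if (length(k)) o[seq_len(max(k))] else integer(0)
    expect_setequal(which(adj <= alpha), stepUp)
  }
})

test_that("Wilcoxon rank-sum: exact enumeration, degenerate and approximate branches", {
  w <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(w$p, 1 / 3)            # 2/6 of all rank assignments
  expect_equal(w$method, "exact")
  expect_equal(wilcoxonRankSum(c(3, 1, 2), c(1, 2, 3))$p, 1,
               tolerance = 0.05)      # identical multisets
  expect_equal(wilcoxonRankSum(rep(4, 3), rep(4, 5))$p, 1)
  ## exact branch matches the reference exact test on untied data
  set.seed(61)
  for (i in 1:30) {
    a <- sample(seq(0, 100, 0.25), 6)
    b <- sample(setdiff(seq(0.05, 100, 0.3), a), 6)
    p <- wilcoxonRankSum(a, b)$p
    expect_equal(p, wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  ## normal approximation tracks the exact p within 0.02 at n = (6, 6)
  set.seed(67)
  for (i in 1:50) {
    a <- rnorm(6); b <- rnorm(6)
    pe <- wilcoxonRankSum(a, b)$p
    pa <- wilcoxonRankSum(a, b, exactLimit = 0L)$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("PCA decomposes, reconstructs and orders variance", {
  set.seed(71)
  ## two perfectly correlated features: PC1 holds all variance
  x <- rnorm(10)
  m <- cbind(f1 = x, f2 = 2 * x + 5)
  pc <- pcaFeatures(m, standardize = TRUE)
  expect_equal(pc$varianceFraction[1], 1)
  expect_equal(sum(pc$varianceFraction), 1)
  ## general matrix: variance fractions sum to 1, loadings orthonormal,
  ## scores reconstruct the standardized matrix
  m2 <- matrix(rnorm(9 * 5), 9, 5,
               dimnames = list(paste0("s", 1:9), paste0("f", 1:5)))
  pc2 <- pcaFeatures(m2, standardize = TRUE)
  expect_equal(sum(pc2$varianceFraction), 1, tolerance = 1e-9)
  expect_equal(crossprod(pc2$loadings), diag(ncol(m2)), tolerance = 1e-9,
               ignore_attr = TRUE)
  std <- scale(m2)
  expect_lt(max(abs(pc2$scores %*% t(pc2$loadings) - std)), 1e-9)
  ## agreement with the reference implementation up to sign
  pr <- prcomp(m2, center = TRUE, scale. = TRUE)
  expect_equal(abs(unname(pc2$scores[, 1:4])), abs(unname(pr$x[, 1:4])),
               tolerance = 1e-9)
  expect_equal(pc2$varianceFraction,
               pr$sdev^2 / sum(pr$sdev^2), tolerance = 1e-9)
  ## sign convention: dominant loading entries are positive
  expect_true(all(apply(pc2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  ## degenerate input errors
  expect_error(pcaFeatures(matrix(1, 3, 3), standardize = FALSE), "rank-0")
})

test_that("cohort comparison dispatches KW/Dunn for 3 groups, Wilcoxon for 2", {
  set.seed(73)
  rec <- expand.grid(sample_id = paste0("s", 1:12),
                     v_segment = "TRBV9", feature = c("strength", "chao1"),
                     stringsAsFactors = FALSE)
  rec$subset <- "nTreg"
  rec$cohort <- rep(rep(c("XLA", "young", "old"), each = 4), 2)
  rec$z_value <- rnorm(nrow(rec)) + 2 * (rec$cohort == "XLA") *
    (rec$feature == "strength")
  res <- compareCohorts(rec)
  expect_setequal(unique(res$test), "dunn")
  expect_equal(nrow(res), 6L)  # 2 features x 3 pairs
  ## BH is applied within each feature family of 3 comparisons
  for (ft in unique(res$feature)) {
    sub <- res[res$feature == ft, ]
    expect_equal(sub$p_adj, benjaminiHochberg(sub$p_raw))
  }
  two <- rec[rec$cohort != "old", ]
  res2 <- compareCohorts(two)
  expect_setequal(unique(res2$test), "wilcoxon")
})
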