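test_that("default germline set is deterministic and properly framed", {
  g1 <- defaultGermlineSet(1L)
  g2 <- defaultGermlineSet(1L)
  expect_identical(vGenes(g1), vGenes(g2))
  expect_identical(jGenes(g1), jGenes(g2))
  expect_gte(length(vGenes(g1)), 12L)
  expect_gte(length(jGenes(g1)), 13L)
  ## every V tail opens with a cysteine codon and translates cleanly
  expect_true(all(substr(vGenes(g1), 1, 3) %in% c("TGT", "TGC")))
  expect_true(all(grepl("^C", translateCdr3(vGenes(g1)))))
  ## every J head carries the conserved phenylalanine codon
  expect_true(all(grepl("TT[TC]", jGenes(g1))))
  ## uniform default usage
  expect_equal(unname(g1@vUsage), rep(1 / length(vGenes(g1)),
                                      length(vGenes(g1))))
})

test_that("degenerate recombination (no insertions, no trimming) is pure V+D+J", {
  g <- defaultGermlineSet()
  cfg <- cohortConfig(insertionMeanVD = 0, insertionMeanDJ = 0,
                      vTrimMax = 0L, dTrimMax = 0L, jTrimMax = 0L)
  cl <- recombineClonotypes(g, cfg, n = 50L, seed = 2L)
  expect_true(all(cl$true_insertions == 0L))
  for (i in seq_len(nrow(cl))) {
    d <- substr(cl$cdr3_nt[i], cl$v_end[i] + 1L, cl$v_end[i] + cl$d_len[i])
    expect_equal(cl$cdr3_nt[i],
                 paste0(vGenes(g)[[cl$v_segment[i]]], d,
                        jGenes(g)[[cl$j_segment[i]]]))
    expect_true(d %in% dGenes(g))
  }
})

test_that("recombined clonotypes are in-frame and stop-free", {
  g <- defaultGermlineSet()
  cl <- recombineClonotypes(g, cohortConfig(), n = 2000L, seed = 4L)
  expect_true(all(nchar(cl$cdr3_nt) %% 3L == 0L))
  expect_false(any(grepl("[*_]", cl$cdr3_aa)))
  expect_equal(translateCdr3(cl$cdr3_nt), cl$cdr3_aa)
  ## junction bookkeeping is internally consistent
  expect_true(all(cl$v_end + (cl$true_insertions + cl$d_len) +
                    (nchar(cl$cdr3_nt) - cl$j_start) == nchar(cl$cdr3_nt)))
})

test_that("insertion counts match an independent junction simulation", {
  ## Independent oracle: re-simulate the generative recipe from scratch
  ## (geometric insertion draws + the productive-junction acceptance rule)
  ## and compare mean accepted insertion totals. The acceptance rule is
  ## part of the model: conditioning on stop-free junctions shifts the
  ## raw geometric mean slightly, and both routes must agree on that.
  g <- defaultGermlineSet()
  cfg <- cohortConfig(insertionMeanVD = 4, insertionMeanDJ = 4,
                      vTrimMax = 0L, dTrimMax = 0L, jTrimMax = 0L,
                      strengthBias = 0)
  cl <- recombineClonotypes(g, cfg, n = 10000L, seed = 6L)

  oracle <- local({
    set.seed(60)
    gcode <- Biostrings::GENETIC_CODE
    sense <- setdiff(names(gcode), c("TAA", "TAG", "TGA"))
    insert <- function(n) {
      if (n == 0) return("")
      substr(paste(sample(sense, ceiling(n / 3), TRUE), collapse = ""), 1, n)
    }
    kept <- numeric(0)
    while (length(kept) < 10000) {
      v <- sample(vGenes(g), 1); d <- sample(dGenes(g), 1)
      j <- sample(jGenes(g), 1)
      n1 <- rgeom(1, 1 / 5); n2 <- rgeom(1, 1 / 5)
      nt <- paste0(v, insert(n1), d, insert(n2), j)
      if (nchar(nt) %% 3 != 0) next
      cods <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
      if (any(gcode[cods] == "*")) next
      kept <- c(kept, n1 + n2)
    }
    kept
  })
  seTot <- sqrt(var(cl$true_insertions) / 10000 + var(oracle) / 10000)
  expect_lt(abs(mean(cl$true_insertions) - mean(oracle)), 3 * seTot)
})

test_that("biased insertion codons raise central strong-residue content monotonically", {
  g <- defaultGermlineSet()
  means <- vapply(c(0, 1, 2), function(b) {
    cfg <- cohortConfig(strengthBias = b)
    cl <- recombineClonotypes(g, cfg, n = 10000L, seed = 8L)
    mean(clonotypeStrength(cl$cdr3_aa), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("generated repertoires conserve depth and are seed-reproducible", {
  g <- defaultGermlineSet()
  cfg <- cohortConfig(nClonotypes = 300L, totalUmi = 1000L)
  r1 <- generateRepertoire(g, cfg, "s1", seed = 12L)
  expect_equal(umiTotal(r1), 1000L)
  expect_equal(nClonotypes(r1), 300L)
  expect_true(all(clonotypes(r1)$umi_count >= 1L))
  ## byte-identical written tables across runs with one seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeClonotypeTable(r1, f1, "airr")
  writeClonotypeTable(generateRepertoire(g, cfg, "s1", seed = 12L),
                      f2, "airr")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("lognormal sigma -> 0 gives near-uniform clone sizes", {
  g <- defaultGermlineSet()
  cfg <- cohortConfig(nClonotypes = 100L, totalUmi = 1050L,
                      cloneSizeModel = list(type = "lognormal",
                                            meanlog = 0, sdlog = 1e-9))
  r <- generateRepertoire(g, cfg, "u1", seed = 3L)
  expect_true(all(abs(clonotypes(r)$umi_count - 10.5) <= 1))
})

test_that("zero convergence rate keeps translation (almost) injective", {
  ## With no programmed convergence, amino-acid collisions can still arise
  ## naturally (independent rearrangements converging by chance at the
  ## junction) -- the phenomenon the convergence statistic exists for.
  ## Direct counting across seeds: collisions must be rare, isolated
  ## events, never deficits (nt variants >= aa variants always).
  g <- defaultGermlineSet()
  cfg <- cohortConfig(nClonotypes = 500L, totalUmi = 1500L,
                      convergenceRate = 0)
  collisions <- vapply(1:20, function(s) {
    df <- clonotypes(generateRepertoire(g, cfg, "c0", seed = s))
    nNt <- length(unique(df$cdr3_nt))
    nAa <- length(unique(df$cdr3_aa))
    expect_gte(nNt, nAa)
    nNt - nAa
  }, integer(1))
  expect_lte(max(collisions), 3L)      # never more than ~0.5% of clones
  expect_lt(mean(collisions), 0.5)     # on average well under 1 per sample
  expect_gte(sum(collisions == 0L), 10L)  # equality is the typical outcome
})

test_that("raising the convergence rate raises the convergence statistic", {
  g <- defaultGermlineSet()
  base <- cohortConfig(nClonotypes = 400L, totalUmi = 1200L,
                       convergenceRate = 0)
  conv <- repfeat:::.overrideConfig(base, list(convergenceRate = 0.15))
  wins <- 0L
  for (s in 1:20) {
    a <- generateRepertoire(g, base, "a", seed = s)
    b <- generateRepertoire(g, conv, "b", seed = s + 1000L)
    if (convergence(clonotypes(b)) > convergence(clonotypes(a)))
      wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("cohort generation honours overrides and rejects unknown fields", {
  g <- defaultGermlineSet()
  base <- cohortConfig(nSamples = 2L, nClonotypes = 300L, totalUmi = 900L,
                       seed = 21L)
  reps <- generateCohorts(base, list(A = list(), B = list(nClonotypes = 150L)),
                          g)
  expect_equal(length(reps), 4L)
  expect_setequal(vapply(reps, cohort, character(1)), c("A", "B"))
  nA <- vapply(reps[grepl("^A", names(reps))], nClonotypes, integer(1))
  nB <- vapply(reps[grepl("^B", names(reps))], nClonotypes, integer(1))
  expect_true(all(nB < min(nA)))
  expect_error(generateCohorts(base, list(A = list(bogusKnob = 1)), g),
               "bogusKnob")
})
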