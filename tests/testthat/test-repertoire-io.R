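test_that("mixcr tables parse with normalized frequencies and segment names", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cloneCount\tnSeqCDR3\taaSeqCDR3\tallVHitsWithScore\tbestJHit",
               "6\tTGCGCCAGCAGCCTGGGGTATTTC\tCASSLGYF\tTRBV9*00(1290.1),TRBV9-2*00(800)\tTRBJ2-7*01",
               "3\tTGCGCCAGCAGCGGGTATGAGTTC\tCASSGYEF\tTRBV12-3*01\tTRBJ2-1*01",
               "1\tTGCGCCAGCAGCTATTATGCGTTC\tCASSYYAF\tTRBV28*00(500)\tTRBJ1-1*01"), f)
  r <- readClonotypeTable(f, "mixcr", sampleId = "m1")
  df <- clonotypes(r)
  expect_equal(df$frequency, c(0.6, 0.3, 0.1))
  expect_equal(df$umi_count, c(6L, 3L, 1L))
  expect_setequal(df$v_segment, c("TRBV9", "TRBV12-3", "TRBV28"))
  expect_false(any(grepl("[*(,]", df$v_segment)))
})

test_that("airr tables parse with allele suffixes stripped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("duplicate_count\tjunction\tjunction_aa\tv_call\tj_call",
               "5\tTGCGCCAGCAGCCTGGGGTATTTC\tCASSLGYF\tTRBV12-3*01\tTRBJ2-7*01"), f)
  r <- readClonotypeTable(f, "airr")
  expect_equal(clonotypes(r)$v_segment, "TRBV12-3")
  expect_equal(clonotypes(r)$j_segment, "TRBJ2-7")
})

test_that("duplicate (cdr3_nt, V, J) rows merge by summing counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  nt <- "TGCGCCAGCAGCCTGGGGTATTTC"
  writeLines(c("duplicate_count\tjunction\tjunction_aa\tv_call\tj_call",
               paste("2", nt, "CASSLGYF", "TRBV9*01", "TRBJ2-7*01", sep = "\t"),
               paste("3", nt, "CASSLGYF", "TRBV9*02", "TRBJ2-7*01", sep = "\t")),
             f)
  expect_warning(r <- readClonotypeTable(f, "airr"), "merged")
  expect_equal(nClonotypes(r), 1L)
  expect_equal(clonotypes(r)$umi_count, 5L)
})

test_that("format errors name the missing column and bad-count line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction\tjunction_aa\tv_call\tj_call",
               "TGCGCCAGCAGCCTGGGGTATTTC\tCASSLGYF\tTRBV9\tTRBJ2-7"), f)
  expect_error(readClonotypeTable(f, "airr"), "duplicate_count")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("duplicate_count\tjunction\tjunction_aa\tv_call\tj_call",
               "2.5\tTGCGCCAGCAGCCTGGGGTATTTC\tCASSLGYF\tTRBV9\tTRBJ2-7"), f2)
  expect_error(readClonotypeTable(f2, "airr"), "line 2")
})

test_that("zero-count rows are dropped, not kept", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("duplicate_count\tjunction\tjunction_aa\tv_call\tj_call",
               "0\tTGCGCCAGCAGCGGGTATGAGTTC\tCASSGYEF\tTRBV9\tTRBJ2-1",
               "4\tTGCGCCAGCAGCCTGGGGTATTTC\tCASSLGYF\tTRBV9\tTRBJ2-7"), f)
  expect_message(r <- readClonotypeTable(f, "airr"), "zero or missing")
  expect_equal(nClonotypes(r), 1L)
})

test_that("write/read round-trips both dialects and empty repertoires", {
  g <- defaultGermlineSet()
  r <- generateRepertoire(g, cohortConfig(nClonotypes = 200L,
                                          totalUmi = 600L), "rt1",
                          cohort = "young", cellSubset = "nTreg", seed = 5L)
  for (dialect in c("mixcr", "airr")) {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeClonotypeTable(r, f, dialect)
    r2 <- readClonotypeTable(f, dialect, sampleId = "rt1",
                             cohort = "young", cellSubset = "nTreg")
    expect_equal(clonotypes(r2)[, c("cdr3_nt", "cdr3_aa", "v_segment",
                                    "j_segment", "umi_count", "frequency")],
                 clonotypes(r)[, c("cdr3_nt", "cdr3_aa", "v_segment",
                                   "j_segment", "umi_count", "frequency")])
  }
  ## annotation columns survive the AIRR round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  writeClonotypeTable(r, f, "airr")
  r3 <- readClonotypeTable(f, "airr")
  expect_equal(clonotypes(r3)$true_insertions, clonotypes(r)$true_insertions)
  ## empty repertoire: header-only file, empty on re-read
  e <- methods::new("Repertoire", sampleId = "e", donorId = "e",
                    cohort = "c", cellSubset = "s",
                    clonotypes = repfeat:::.finalizeClonotypes(
                      data.frame(cdr3_nt = character())))
  fe <- withr::local_tempfile(fileext = ".tsv")
  writeClonotypeTable(e, fe, "airr")
  expect_equal(length(readLines(fe)), 1L)
  expect_equal(nClonotypes(readClonotypeTable(fe, "airr")), 0L)
})

test_that("repeated writes are byte-identical", {
  g <- defaultGermlineSet()
  r <- generateRepertoire(g, cohortConfig(nClonotypes = 1000L,
                                          totalUmi = 3000L), "det1",
                          seed = 9L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeClonotypeTable(r, f1, "airr")
  writeClonotypeTable(r, f2, "airr")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("filterFunctional removes stops/frameshifts and renormalizes", {
  df <- makeClonotypes(c(5L, 5L))
  df$cdr3_nt[1] <- "TGCGCCAGCAGCTGAGGGTATTTC"  # internal TGA stop
  r <- Repertoire(df, "f1")
  ff <- filterFunctional(r)
  expect_equal(nClonotypes(ff), 1L)
  expect_false(any(grepl("[*_]", clonotypes(ff)$cdr3_aa)))
  expect_equal(clonotypes(ff)$frequency, 1.0)

  ## hand renormalization: 10 clonotypes, 3 nonfunctional (counts 1,2,3)
  ## of total 20; the count-7 survivor must get frequency 7/14 = 0.5
  df2 <- makeClonotypes(c(7L, 1L, 2L, 3L, 1L, 1L, 1L, 1L, 1L, 2L))
  df2$cdr3_nt[2] <- "TGCGCCAGCAGCTAGGGGTATTTC"   # stop
  df2$cdr3_nt[3] <- "TGCGCCAGCAGCTGAGCGTATTTC"   # stop
  df2$cdr3_nt[4] <- "TGCGCCAGCAGCCTGGGGTATTTCA"  # frameshift (25 nt)
  r2 <- Repertoire(df2, "f2")
  ff2 <- filterFunctional(r2)
  expect_equal(nClonotypes(ff2), 7L)
  expect_equal(sum(clonotypes(ff2)$frequency), 1)
  expect_equal(clonotypes(ff2)$frequency[clonotypes(ff2)$umi_count == 7L], 0.5)

  ## identity on clean repertoires; idempotent in general
  clean <- makeTestRepertoire(c(3L, 2L))
  expect_equal(clonotypes(filterFunctional(clean)), clonotypes(clean))
  expect_equal(clonotypes(filterFunctional(ff2)), clonotypes(ff2))
  ## everything nonfunctional is an error
  df3 <- makeClonotypes(2L)
  df3$cdr3_nt <- "TGCGCCAGCAGCTGAGGGTATTTC"
  expect_error(filterFunctional(Repertoire(df3, "f3")), "functional")
})

test_that("abundant-V selection uses intersection-over-samples semantics", {
  r1 <- Repertoire(rbind(makeClonotypes(c(60L, 40L), v = "TRBV9"),
                         makeClonotypes(30L, v = "TRBV30",
                                        nt = "TGCGCCAGCAGCAAACCCTATTTC")),
                   "a1")
  r2 <- Repertoire(rbind(makeClonotypes(c(50L, 50L), v = "TRBV9"),
                         makeClonotypes(5L, v = "TRBV30",
                                        nt = "TGCGCCAGCAGCAAACCCTATTTC")),
                   "a2")
  expect_equal(selectAbundantVSegments(list(r1, r2), minUmi = 20L), "TRBV9")
  ## minUmi = 1 keeps every segment present in every sample
  expect_setequal(selectAbundantVSegments(list(r1, r2), minUmi = 1L),
                  c("TRBV9", "TRBV30"))
  ## ordering is by total abundance, descending
  sel <- selectAbundantVSegments(list(r1, r2), minUmi = 1L)
  expect_equal(sel[1], "TRBV9")
  expect_error(selectAbundantVSegments(list(), 1L))
})

test_that("V slicing partitions the repertoire and conserves UMIs", {
  g <- defaultGermlineSet()
  r <- generateRepertoire(g, cohortConfig(nClonotypes = 500L,
                                          totalUmi = 5000L), "p1", seed = 3L)
  vs <- unique(clonotypes(r)$v_segment)
  slices <- lapply(vs, function(v) sliceByV(r, v))
  expect_equal(sum(vapply(slices, umiTotal, numeric(1))), umiTotal(r))
  expect_equal(sum(vapply(slices, nClonotypes, integer(1))), nClonotypes(r))
  expect_setequal(unlist(lapply(slices, function(s) clonotypes(s)$cdr3_nt)),
                  clonotypes(r)$cdr3_nt)
  expect_error(sliceByV(r, "TRBV99"), "TRBV99")
})

test_that("manifests round-trip through TSV and YAML", {
  d <- withr::local_tempdir()
  r <- makeTestRepertoire(c(3L, 2L))
  writeClonotypeTable(r, file.path(d, "s1.tsv"), "airr")
  man <- data.frame(sample_id = "s1", donor_id = "d1", cohort = "young",
                    subset = "nTreg", file_path = "s1.tsv", dialect = "airr",
                    stringsAsFactors = FALSE)
  tsv <- file.path(d, "manifest.tsv")
  utils::write.table(man, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readManifest(tsv)$sample_id, "s1")
  yamlPath <- file.path(d, "manifest.yaml")
  yaml::write_yaml(list(samples = list(as.list(man[1, ]))), yamlPath)
  expect_equal(readManifest(yamlPath)$cohort, "young")
  reps <- loadStudy(tsv)
  expect_equal(sampleId(reps[["s1"]]), "s1")
  expect_equal(cohort(reps[["s1"]]), "young")
})
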