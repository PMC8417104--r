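## End-to-end orchestration: load -> functional filter -> abundant-V
## selection -> equal-depth downsampling -> diversity/convergence ->
## weighted CDR3 features -> Z-scores -> cohort tests -> publicity -> PCA,
## with full exclusion bookkeeping and per-(sample, analysis) sub-seeds.

#' Pipeline configuration
#'
#' Depth parameters may be single numbers or named per-subset vectors
#' (names = subset labels); unnamed values apply to every subset. The
#' defaults mirror a full-scale study (1,000 UMIs per V segment for
#' diversity; 13,000 top clonotypes at 23,000 common UMIs for publicity)
#' and are meant to be overridden for desk-scale synthetic runs.
#'
#' @param manifest path to a study manifest (TSV or YAML), see
#'   \code{\link{readManifest}}
#' @param outDir output directory (created if absent)
#' @param minUmi per-sample UMI threshold for a V segment to enter the
#'   per-segment analyses
#' @param diversityDepth UMI depth per V slice for diversity/convergence
#' @param publicityEqualUmi common whole-sample UMI depth for publicity
#' @param publicityTopN number of most-abundant clonotypes compared
#' @param weighting \code{"umi"} or \code{"unweighted"} feature weighting
#' @param zscore standardize features within (subset, V, feature) strata
#' @param germline optional \code{\linkS4class{GermlineSet}} enabling
#'   added-nucleotide inference when tables lack junction annotation
#' @param seed master seed; all per-sample/per-analysis seeds derive
#'   from it
#' @return a validated config list (class \code{pipelineConfig})
#' @export
pipelineConfig <- function(manifest, outDir, minUmi = 1000L,
                           diversityDepth = 1000L,
                           publicityEqualUmi = 23000L,
                           publicityTopN = 13000L,
                           weighting = c("umi", "unweighted"),
                           zscore = TRUE, germline = NULL, seed = 1L) {
  cfg <- list(manifest = manifest, outDir = outDir,
              minUmi = minUmi, diversityDepth = diversityDepth,
              publicityEqualUmi = publicityEqualUmi,
              publicityTopN = publicityTopN,
              weighting = match.arg(weighting), zscore = isTRUE(zscore),
              germline = germline, seed = as.integer(seed))
  stopifnot(all(unlist(cfg[c("minUmi", "diversityDepth",
                             "publicityEqualUmi", "publicityTopN")]) > 0))
  class(cfg) <- "pipelineConfig"
  cfg
}

.depthFor <- function(depth, subset) {
  if (is.null(names(depth))) return(as.integer(depth[1]))
  if (subset %in% names(depth)) return(as.integer(depth[[subset]]))
  if ("" %in% names(depth)) return(as.integer(depth[[which(names(depth) == "")[1]]]))
  stop("no depth configured for subset ", subset, call. = FALSE)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  path
}

#' Run the full repertoire-comparison pipeline
#'
#' Executes every stage deterministically from the master seed and writes
#' tidy TSV outputs plus a machine-readable JSON run report to
#' \code{config$outDir}: \code{metrics.tsv} (per sample x V diversity and
#' convergence at equal depth), \code{features.tsv} (raw and z-scored
#' abundance-weighted CDR3 features), \code{tests.tsv} (Kruskal-Wallis /
#' Dunn / Benjamini-Hochberg or Wilcoxon results), \code{publicity.tsv}
#' (pairwise shared public clonotypes per subset), \code{pca_scores.tsv},
#' \code{pca_loadings.tsv}, \code{pca_variance.tsv}, and
#' \code{report.json}. No sample is dropped silently: every sample
#' appears per analysis as included or excluded with a reason
#' (insufficient coverage being the canonical one).
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return the run report, invisibly: a list with per-stage counts, the
#'   exclusion table, seeds, and the output file inventory
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  man <- readManifest(config$manifest)
  if (length(unique(man$cohort)) < 2L)
    stop("pipeline requires at least 2 cohorts", call. = FALSE)
  reps <- loadStudy(man)
  reps <- lapply(reps, filterFunctional)
  exclusions <- data.frame(analysis = character(), sample_id = character(),
                           v_segment = character(), reason = character(),
                           stringsAsFactors = FALSE)
  exclude <- function(analysis, sid, v, reason) {
    exclusions <<- rbind(exclusions, data.frame(
      analysis = analysis, sample_id = sid, v_segment = v, reason = reason,
      stringsAsFactors = FALSE))
  }

  subsets <- unique(man$subset)
  metricRows <- list(); featRows <- list(); pubRows <- list()
  abundantV <- list()

  for (ss in subsets) {
    ssIds <- man$sample_id[man$subset == ss]
    ssReps <- reps[ssIds]
    minU <- .depthFor(config$minUmi, ss)
    vSel <- selectAbundantVSegments(ssReps, minU)
    abundantV[[ss]] <- vSel
    divDepth <- .depthFor(config$diversityDepth, ss)

    for (sid in ssIds) {
      r <- ssReps[[sid]]
      for (v in vSel) {
        sl <- sliceByV(r, v)
        ## diversity + convergence at equal depth
        ds <- tryCatch(
          downsampleUmis(sl, divDepth,
                         seed = deriveSeed(config$seed, sid, v, "diversity")),
          insufficientCoverage = function(e) {
            exclude("diversity", sid, v, conditionMessage(e)); NULL
          })
        if (!is.null(ds)) {
          dm <- diversityMetrics(ds)
          for (mt in c("chao1", "shannon_norm", "convergence")) {
            metricRows[[length(metricRows) + 1L]] <- data.frame(
              sample_id = sid, donor_id = donorId(r), cohort = cohort(r),
              subset = ss, v_segment = v, metric = mt, value = dm[[mt]],
              n_umi = dm$n_umi,
              seed = deriveSeed(config$seed, sid, v, "diversity"),
              stringsAsFactors = FALSE)
          }
        }
        ## abundance-weighted CDR3 features on the full slice
        cf <- clonotypeFeatures(sl, germline = config$germline)
        for (ft in colnames(cf)) {
          val <- weightedFeature(sl, cf[[ft]], weighting = config$weighting)
          if (is.na(val)) { exclude("features", sid, v,
                                    paste("no usable clonotypes for", ft))
                            next }
          featRows[[length(featRows) + 1L]] <- data.frame(
            sample_id = sid, donor_id = donorId(r), cohort = cohort(r),
            subset = ss, v_segment = v, feature = ft, raw_value = val,
            n_umi_used = umiTotal(sl), n_clonotypes_used = nClonotypes(sl),
            stringsAsFactors = FALSE)
        }
      }
    }

    ## pairwise publicity on whole samples
    pubUmi <- .depthFor(config$publicityEqualUmi, ss)
    topN <- .depthFor(config$publicityTopN, ss)
    deep <- vapply(ssReps, function(r) umiTotal(r) >= pubUmi, logical(1))
    for (sid in ssIds[!deep])
      exclude("publicity", sid, NA_character_,
              sprintf("insufficient coverage: %d UMIs available, %d requested",
                      umiTotal(ssReps[[sid]]), pubUmi))
    okIds <- ssIds[deep]
    if (length(okIds) >= 2L) {
      prs <- utils::combn(okIds, 2)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b <- prs[2, k]
        pubRows[[length(pubRows) + 1L]] <- data.frame(
          subset = ss, sample_a = a, sample_b = b,
          cohort_a = cohort(ssReps[[a]]), cohort_b = cohort(ssReps[[b]]),
          shared = pairwisePublicity(ssReps[[a]], ssReps[[b]],
                                     topN = topN, equalUmi = pubUmi,
                                     seed = config$seed),
          equal_umi = pubUmi, top_n = topN, stringsAsFactors = FALSE)
      }
    }
  }

  metrics <- if (length(metricRows)) do.call(rbind, metricRows) else
    data.frame()
  feats <- if (length(featRows)) do.call(rbind, featRows) else data.frame()

  ## fold the equal-depth diversity metrics into the feature table
  if (nrow(metrics)) {
    mFeat <- data.frame(sample_id = metrics$sample_id,
                        donor_id = metrics$donor_id,
                        cohort = metrics$cohort, subset = metrics$subset,
                        v_segment = metrics$v_segment,
                        feature = metrics$metric, raw_value = metrics$value,
                        n_umi_used = metrics$n_umi,
                        n_clonotypes_used = NA_integer_,
                        stringsAsFactors = FALSE)
    feats <- rbind(feats, mFeat)
  }

  if (config$zscore && nrow(feats)) {
    feats <- zscoreWithinStratum(feats)
  } else if (nrow(feats)) {
    feats$z_value <- feats$raw_value
  }

  tests <- if (nrow(feats)) compareCohorts(feats) else data.frame()

  ## PCA per subset on per-sample mean z-scores
  pcaScores <- list(); pcaLoad <- list(); pcaVar <- list()
  if (nrow(feats)) {
    agg <- aggregateSampleFeatures(feats, "mean_over_segments")
    for (ss in unique(agg$subset)) {
      a <- agg[agg$subset == ss, , drop = FALSE]
      wide <- stats::reshape(a[, c("sample_id", "feature", "z_value")],
                             idvar = "sample_id", timevar = "feature",
                             direction = "wide")
      rn <- wide$sample_id
      mat <- as.matrix(wide[, -1, drop = FALSE])
      colnames(mat) <- sub("^z_value\\.", "", colnames(mat))
      rownames(mat) <- rn
      ## impute missing strata at the column mean (logged as exclusions)
      if (anyNA(mat)) {
        nas <- which(is.na(mat), arr.ind = TRUE)
        for (i in seq_len(nrow(nas)))
          exclude("pca", rn[nas[i, 1]], colnames(mat)[nas[i, 2]],
                  "missing feature imputed at column mean")
        for (jj in unique(nas[, 2]))
          mat[is.na(mat[, jj]), jj] <- mean(mat[, jj], na.rm = TRUE)
      }
      if (nrow(mat) < 2L || ncol(mat) < 2L) next
      pc <- tryCatch(pcaFeatures(mat, standardize = TRUE),
                     error = function(e) NULL)
      if (is.null(pc)) next
      sc <- data.frame(subset = ss, sample_id = rownames(pc$scores),
                       pc$scores[, seq_len(min(5L, ncol(pc$scores))),
                                 drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
      meta <- unique(a[, c("sample_id", "cohort")])
      pcaScores[[ss]] <- merge(sc, meta, by = "sample_id", sort = TRUE)
      pcaLoad[[ss]] <- data.frame(subset = ss,
                                  feature = rownames(pc$loadings),
                                  pc$loadings[, seq_len(min(5L,
                                    ncol(pc$loadings))), drop = FALSE],
                                  stringsAsFactors = FALSE, row.names = NULL)
      pcaVar[[ss]] <- data.frame(subset = ss,
                                 component = paste0("PC",
                                   seq_along(pc$varianceFraction)),
                                 variance_fraction = pc$varianceFraction,
                                 stringsAsFactors = FALSE)
    }
  }

  publicity <- if (length(pubRows)) do.call(rbind, pubRows) else data.frame()

  files <- c(
    metrics = .writeTSV(metrics, file.path(config$outDir, "metrics.tsv")),
    features = .writeTSV(feats, file.path(config$outDir, "features.tsv")),
    tests = .writeTSV(tests, file.path(config$outDir, "tests.tsv")),
    publicity = .writeTSV(publicity,
                          file.path(config$outDir, "publicity.tsv")),
    exclusions = .writeTSV(exclusions,
                           file.path(config$outDir, "exclusions.tsv")))
  if (length(pcaScores)) {
    files <- c(files,
      pca_scores = .writeTSV(do.call(rbind, c(pcaScores,
        list(make.row.names = FALSE))),
        file.path(config$outDir, "pca_scores.tsv")),
      pca_loadings = .writeTSV(do.call(rbind, c(pcaLoad,
        list(make.row.names = FALSE))),
        file.path(config$outDir, "pca_loadings.tsv")),
      pca_variance = .writeTSV(do.call(rbind, c(pcaVar,
        list(make.row.names = FALSE))),
        file.path(config$outDir, "pca_variance.tsv")))
  }

  report <- list(
    n_samples = nrow(man),
    subsets = as.list(vapply(subsets, function(ss)
      sum(man$subset == ss), integer(1))),
    abundant_v_segments = abundantV,
    stage_counts = list(metrics = nrow(metrics), features = nrow(feats),
                        tests = nrow(tests), publicity = nrow(publicity)),
    exclusions = exclusions,
    master_seed = config$seed,
    config = list(minUmi = config$minUmi,
                  diversityDepth = config$diversityDepth,
                  publicityEqualUmi = config$publicityEqualUmi,
                  publicityTopN = config$publicityTopN,
                  weighting = config$weighting, zscore = config$zscore),
    files = as.list(stats::setNames(basename(unlist(files)), names(files))))
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$tables <- list(metrics = metrics, features = feats, tests = tests,
                        publicity = publicity,
                        pca_scores = if (length(pcaScores))
                          do.call(rbind, c(pcaScores,
                            list(make.row.names = FALSE))) else NULL,
                        pca_variance = if (length(pcaVar))
                          do.call(rbind, c(pcaVar,
                            list(make.row.names = FALSE))) else NULL)
  invisible(report)
}

## ---- synthetic fixture studies ---------------------------------------

#' Cohort effect presets for fixture studies
#'
#' \code{null}: three cohorts (young, old, XLA) at identical parameters,
#' for calibration runs. \code{xla_like}: the XLA cohort gets the
#' directional alterations the analysis is meant to detect -- fewer
#' distinct clonotypes (lower diversity / higher clonality), a raised
#' convergence rate, shorter junctional insertions (shorter CDR3s, fewer
#' added nucleotides) and a raised strong-residue codon bias.
#'
#' @param preset \code{"null"} or \code{"xla_like"}
#' @return named list of per-cohort config overrides
#' @export
fixtureEffects <- function(preset = c("null", "xla_like")) {
  preset <- match.arg(preset)
  xla <- if (preset == "null") list() else
    list(nClonotypes = 600L, convergenceRate = 0.2,
         insertionMeanVD = 2, insertionMeanDJ = 2, strengthBias = 2)
  list(young = list(), old = list(), XLA = xla)
}

#' Generate a complete synthetic fixture study on disk
#'
#' Simulates three labelled cohorts with \code{\link{generateCohorts}},
#' writes one AIRR TSV per sample (with ground-truth junction annotation
#' columns), a study manifest, and a ground-truth JSON of the true
#' generative parameters per cohort.
#'
#' @param preset \code{"null"} or \code{"xla_like"}, see
#'   \code{\link{fixtureEffects}}
#' @param seed master seed
#' @param dir output directory
#' @param base base \code{\link{cohortConfig}}; its \code{seed} is
#'   replaced by \code{seed}
#' @param cellSubset subset label for all samples
#' @return list: \code{manifest} (path), \code{dir}, \code{groundTruth}
#'   (path), \code{germline}
#' @export
makeFixtureStudy <- function(preset = c("null", "xla_like"), seed = 1L,
                             dir = tempfile("fixture"),
                             base = cohortConfig(),
                             cellSubset = "nTreg") {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base$seed <- as.integer(seed)
  germline <- defaultGermlineSet()
  effects <- fixtureEffects(preset)
  reps <- generateCohorts(base, effects, germline, cellSubset = cellSubset)
  rows <- lapply(reps, function(r) {
    f <- paste0(sampleId(r), ".tsv")
    writeClonotypeTable(r, file.path(dir, f), dialect = "airr")
    data.frame(sample_id = sampleId(r), donor_id = donorId(r),
               cohort = cohort(r), subset = cellSubset(r),
               file_path = f, dialect = "airr", stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.tsv")
  .writeTSV(man, manifestPath)
  truth <- list(preset = preset, seed = as.integer(seed),
                base = unclass(base),
                effects = effects,
                samples = man$sample_id)
  gtPath <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, gtPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(manifest = manifestPath, dir = dir, groundTruth = gtPath,
       germline = germline)
}

#' Desk-scale pipeline configuration for fixture studies
#'
#' Depths matched to the fixture generator's default sample size (5,000
#' UMIs over 12 V segments): 250-UMI V slices for diversity, publicity on
#' the top 500 clonotypes at 3,000 common UMIs.
#'
#' @param manifest manifest path (from \code{\link{makeFixtureStudy}})
#' @param outDir output directory
#' @param seed master seed
#' @return a \code{\link{pipelineConfig}}
#' @export
fixturePipelineConfig <- function(manifest, outDir, seed = 1L) {
  pipelineConfig(manifest, outDir, minUmi = 250L, diversityDepth = 250L,
                 publicityEqualUmi = 3000L, publicityTopN = 500L,
                 seed = seed)
}
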