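## Reading/writing clonotype tables (MiXCR-flavour and AIRR Rearrangement
## TSV), functional filtering, abundant-V selection and V slicing.

.DIALECTS <- c("mixcr", "airr")

.dialectCols <- function(dialect) {
  switch(dialect,
    mixcr = list(count = c("cloneCount", "count"),
                 nt = "nSeqCDR3", aa = "aaSeqCDR3",
                 v = c("bestVHit", "allVHitsWithScore"),
                 j = c("bestJHit", "allJHitsWithScore")),
    airr  = list(count = "duplicate_count",
                 nt = "junction", aa = "junction_aa",
                 v = "v_call", j = "j_call"))
}

.pickCol <- function(tab, candidates, path) {
  hit <- intersect(candidates, names(tab))
  if (!length(hit))
    stop("clonotype table ", path, " lacks required column ",
         paste(candidates, collapse = " or "), call. = FALSE)
  hit[1]
}

#' Read a clonotype table into a Repertoire
#'
#' Parses a tab-separated clonotype table in either the MiXCR export
#' flavour (\code{cloneCount}/\code{count}, \code{nSeqCDR3},
#' \code{aaSeqCDR3}, \code{bestVHit}/\code{allVHitsWithScore}, ...) or the
#' AIRR Rearrangement flavour (\code{duplicate_count}, \code{junction},
#' \code{junction_aa}, \code{v_call}, \code{j_call}). V/J calls are
#' normalized to the segment level: allele suffixes after \code{*} are
#' stripped and composite hit lists truncated at the first comma (best hit
#' kept). Frequencies are recomputed from UMI counts. Rows with zero or
#' missing counts are dropped (with a message); rows whose count is not a
#' positive integer raise an error naming the offending line. Rows sharing
#' a (cdr3_nt, V, J) triple are merged by summing counts, with a warning.
#'
#' @param path path to the TSV file
#' @param dialect \code{"mixcr"} or \code{"airr"}
#' @param sampleId,donorId,cohort,cellSubset sample metadata
#' @return a validated \code{\linkS4class{Repertoire}}
#' @export
readClonotypeTable <- function(path, dialect = c("mixcr", "airr"),
                               sampleId = tools::file_path_sans_ext(basename(path)),
                               donorId = sampleId, cohort = "unknown",
                               cellSubset = "unknown") {
  dialect <- match.arg(dialect)
  cols <- .dialectCols(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  countCol <- .pickCol(tab, cols$count, path)
  ntCol <- .pickCol(tab, cols$nt, path)
  vCol <- .pickCol(tab, cols$v, path)
  jCol <- .pickCol(tab, cols$j, path)
  aaCol <- intersect(cols$aa, names(tab))

  rawCount <- trimws(tab[[countCol]])
  num <- suppressWarnings(as.numeric(rawCount))
  blank <- is.na(num) & (is.na(rawCount) | rawCount == "")
  badRows <- which(!blank & (is.na(num) | num < 0 | num != round(num)))
  if (length(badRows))
    stop("count '", rawCount[badRows[1]], "' on line ", badRows[1] + 1L,
         " of ", path, " is not a positive integer", call. = FALSE)
  drop <- blank | num == 0
  if (any(drop))
    message("dropping ", sum(drop), " rows with zero or missing count in ",
            basename(path))
  tab <- tab[!drop, , drop = FALSE]
  num <- num[!drop]

  df <- data.frame(
    cdr3_nt = toupper(trimws(tab[[ntCol]])),
    cdr3_aa = if (length(aaCol)) trimws(tab[[aaCol[1]]]) else NA_character_,
    v_segment = normalizeSegment(trimws(tab[[vCol]])),
    j_segment = normalizeSegment(trimws(tab[[jCol]])),
    umi_count = as.integer(num),
    stringsAsFactors = FALSE)
  for (opt in .CLONOTYPE_OPT)
    if (opt %in% names(tab))
      df[[opt]] <- suppressWarnings(as.integer(tab[[opt]]))
  Repertoire(df, sampleId = sampleId, donorId = donorId, cohort = cohort,
             cellSubset = cellSubset, mergeDuplicates = TRUE)
}

#' Write a Repertoire as a clonotype TSV
#'
#' Writes the table in the requested dialect so that
#' \code{readClonotypeTable(writeClonotypeTable(r))} round-trips all
#' fields. Output is deterministic: repeated writes of the same object are
#' byte-identical.
#'
#' @param repertoire a \code{\linkS4class{Repertoire}}
#' @param path output file path
#' @param dialect \code{"mixcr"} or \code{"airr"}
#' @return invisibly, \code{path}
#' @export
writeClonotypeTable <- function(repertoire, path,
                                dialect = c("mixcr", "airr")) {
  dialect <- match.arg(dialect)
  df <- clonotypes(repertoire)
  out <- switch(dialect,
    mixcr = data.frame(cloneCount = df$umi_count,
                       cloneFraction = df$frequency,
                       nSeqCDR3 = df$cdr3_nt, aaSeqCDR3 = df$cdr3_aa,
                       bestVHit = df$v_segment, bestJHit = df$j_segment,
                       stringsAsFactors = FALSE),
    airr  = data.frame(duplicate_count = df$umi_count,
                       junction = df$cdr3_nt, junction_aa = df$cdr3_aa,
                       v_call = df$v_segment, j_call = df$j_segment,
                       stringsAsFactors = FALSE))
  for (opt in intersect(.CLONOTYPE_OPT, names(df))) out[[opt]] <- df[[opt]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Remove nonfunctional clonotypes
#'
#' Drops clonotypes whose CDR3 amino-acid sequence contains a stop
#' (\code{*}) or frameshift (\code{_}) marker, or whose nucleotide length
#' is not a multiple of three, then renormalizes frequencies over the
#' survivors. Amino-acid-level analyses (convergence, publicity,
#' physicochemical features) require translatable CDR3s; the filter is
#' applied uniformly before all downstream metrics. Idempotent.
#'
#' @param repertoire a \code{\linkS4class{Repertoire}}
#' @return the filtered \code{Repertoire}
#' @export
filterFunctional <- function(repertoire) {
  df <- clonotypes(repertoire)
  keep <- !grepl("[*_]", df$cdr3_aa) & nchar(df$cdr3_nt) %% 3L == 0L &
    nzchar(df$cdr3_aa)
  if (!any(keep))
    stop("no functional clonotypes left in sample ", sampleId(repertoire),
         call. = FALSE)
  if (all(keep)) return(repertoire)
  methods::initialize(repertoire,
                      clonotypes = .finalizeClonotypes(df[keep, , drop = FALSE]))
}

#' Select V segments abundantly covered in every sample
#'
#' Returns the TRBV segments whose summed UMI count reaches \code{minUmi}
#' in \emph{every} repertoire of the collection (all sharing one subset),
#' ordered by total abundance across samples, descending. Restricting the
#' per-segment analyses to these segments avoids bias from segments that
#' are poorly covered in some individuals.
#'
#' @param repertoires list of \code{\linkS4class{Repertoire}} objects of
#'   one cell subset
#' @param minUmi minimum per-sample UMI count for a segment to qualify
#' @return character vector of TRBV names
#' @export
selectAbundantVSegments <- function(repertoires, minUmi) {
  stopifnot(length(repertoires) >= 1L, minUmi >= 1)
  perSample <- lapply(repertoires, function(r) {
    df <- clonotypes(r)
    tapply(df$umi_count, df$v_segment, sum)
  })
  allV <- unique(unlist(lapply(perSample, names)))
  counts <- vapply(perSample, function(u) {
    out <- stats::setNames(numeric(length(allV)), allV)
    out[names(u)] <- u
    out
  }, numeric(length(allV)))
  counts <- matrix(counts, nrow = length(allV),
                   dimnames = list(allV, NULL))
  ok <- rowSums(counts >= minUmi) == length(repertoires)
  tot <- rowSums(counts)
  names(sort(tot[ok], decreasing = TRUE))
}

#' Restrict a repertoire to one TRBV segment
#'
#' @param repertoire a \code{\linkS4class{Repertoire}}
#' @param v a TRBV segment name present in the repertoire
#' @return a \code{\linkS4class{VSegmentSlice}} holding exactly the
#'   clonotypes with that V call; UMI totals conserved
#' @export
sliceByV <- function(repertoire, v) {
  df <- clonotypes(repertoire)
  sel <- df$v_segment == v
  if (!any(sel))
    stop("V segment ", v, " absent from sample ", sampleId(repertoire),
         call. = FALSE)
  .newSlice(df[sel, , drop = FALSE], sampleId(repertoire),
            cohort(repertoire), cellSubset(repertoire), v)
}

## ---- study manifests -------------------------------------------------

.MANIFEST_COLS <- c("sample_id", "donor_id", "cohort", "subset",
                    "file_path", "dialect")

#' Read a study manifest
#'
#' A manifest lists one row per sample: \code{sample_id}, \code{donor_id},
#' \code{cohort}, \code{subset}, \code{file_path} (relative paths resolved
#' against the manifest's directory), \code{dialect} (\code{mixcr} or
#' \code{airr}). TSV and YAML (a list of records under \code{samples})
#' are accepted.
#'
#' @param path manifest file (.tsv/.txt or .yaml/.yml)
#' @return data.frame of manifest rows with absolute file paths
#' @export
readManifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  man <- if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    rows <- if (!is.null(y$samples)) y$samples else y
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[.MANIFEST_COLS], stringsAsFactors = FALSE)))
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  miss <- setdiff(.MANIFEST_COLS, names(man))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$sample_id))
    stop("duplicate sample_id in manifest", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", man$file_path)
  man$file_path[rel] <- file.path(dirname(path), man$file_path[rel])
  bad <- !file.exists(man$file_path)
  if (any(bad))
    stop("manifest file(s) not found: ",
         paste(man$file_path[bad], collapse = ", "), call. = FALSE)
  if (!all(man$dialect %in% .DIALECTS))
    stop("manifest dialect must be one of: ",
         paste(.DIALECTS, collapse = ", "), call. = FALSE)
  man
}

#' Load every sample of a study manifest
#'
#' @param manifest path to a manifest file, or a data.frame as returned by
#'   \code{\link{readManifest}}
#' @return named list of \code{\linkS4class{Repertoire}} objects
#' @export
loadStudy <- function(manifest) {
  man <- if (is.character(manifest)) readManifest(manifest) else manifest
  reps <- lapply(seq_len(nrow(man)), function(i)
    readClonotypeTable(man$file_path[i], dialect = man$dialect[i],
                       sampleId = man$sample_id[i], donorId = man$donor_id[i],
                       cohort = man$cohort[i], cellSubset = man$subset[i]))
  stats::setNames(reps, man$sample_id)
}
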