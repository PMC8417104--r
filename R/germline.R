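## Synthetic TRB germline segments for the repertoire simulator.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.allCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.senseCodons <- function() setdiff(.allCodons(), .STOP_CODONS)

#' Bundled synthetic germline segment set
#'
#' Returns a deterministic set of synthetic TRB germline fragments: 12
#' TRBV 3' tails (each starting at a conserved cysteine codon, TGT/TGC,
#' and continuing in frame without stops), 2 TRBD genes and 13 TRBJ 5'
#' heads (in frame, ending at a conserved phenylalanine codon, TTT/TTC).
#' The sequences are generated, not real IMGT alleles: they reproduce the
#' structural constraints junctional simulation needs (framing anchors,
#' realistic lengths) and nothing else. Default segment usage is uniform.
#'
#' @param seed integer; the same seed always yields the same set
#' @return a \code{\linkS4class{GermlineSet}}
#' @export
defaultGermlineSet <- function(seed = 1L) {
  vNames <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-2", "TRBV7-2", "TRBV9",
              "TRBV11-2", "TRBV12-3", "TRBV15", "TRBV19", "TRBV20-1",
              "TRBV28")
  jNames <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))
  ## one codon per residue: germline segments carry no internal synonymy,
  ## mirroring the amino-acid-distinct 3' ends of real TRBV genes
  aaCodon <- c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
               "AAA", "CTT", "ATG", "AAT", "CCT", "CAA", "CGT", "TCT",
               "ACT", "GTT", "TGG", "TAT")
  withSeed(seed, {
    repeat {
      vTails <- vapply(seq_along(vNames), function(i) {
        ## conserved Cys, then the canonical alanine-serine-serine motif,
        ## then 2-4 segment-specific codons
        extra <- sample(aaCodon, sample(2:4, 1), replace = TRUE)
        paste0(sample(c("TGT", "TGC"), 1), "GCCAGCAGC",
               paste(extra, collapse = ""))
      }, character(1))
      if (!anyDuplicated(translateCdr3(vTails))) break
    }
    ## TRBD genes are short and G-rich; codon-aligned lengths keep the
    ## untrimmed, insertion-free junction satisfiable in frame
    dSeqs <- vapply(c(12L, 15L), function(n) {
      paste(sample(c("G", "G", "G", "A", "C", "T"), n, replace = TRUE),
            collapse = "")
    }, character(1))
    jHeads <- vapply(seq_along(jNames), function(i) {
      body <- sample(aaCodon, sample(4:6, 1), replace = TRUE)
      paste0(paste(body, collapse = ""), sample(c("TTT", "TTC"), 1))
    }, character(1))
    methods::new("GermlineSet",
                 vGenes = stats::setNames(vTails, vNames),
                 dGenes = stats::setNames(dSeqs, c("TRBD1", "TRBD2")),
                 jGenes = stats::setNames(jHeads, jNames),
                 vUsage = stats::setNames(rep(1 / length(vNames),
                                              length(vNames)), vNames),
                 jUsage = stats::setNames(rep(1 / length(jNames),
                                              length(jNames)), jNames))
  })
}

#' Replace the usage vectors of a germline set
#'
#' @param germline a \code{\linkS4class{GermlineSet}}
#' @param vUsage,jUsage optional (possibly unnormalized) nonnegative
#'   weights, either named or in gene order; missing means keep current
#' @return the updated \code{GermlineSet}
#' @export
setUsage <- function(germline, vUsage = NULL, jUsage = NULL) {
  fix <- function(u, genes) {
    if (is.null(names(u))) names(u) <- names(genes)
    u <- u[names(genes)]
    stopifnot(!anyNA(u), all(u >= 0), sum(u) > 0)
    u / sum(u)
  }
  if (!is.null(vUsage)) germline@vUsage <- fix(vUsage, germline@vGenes)
  if (!is.null(jUsage)) germline@jUsage <- fix(jUsage, germline@jGenes)
  methods::validObject(germline)
  germline
}
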