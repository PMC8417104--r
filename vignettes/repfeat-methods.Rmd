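---
title: "Methods: repertoire metrics, CDR3 features and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire metrics, CDR3 features and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repfeat)
```

## Scope and data model

`repfeat` compares TCR-β repertoires of sorted T-cell subsets between
donor cohorts. The unit of data is the **clonotype**: a distinct
rearrangement keyed by its CDR3 nucleotide sequence plus V and J
segment calls, quantified by the number of UMI-labelled cDNA molecules
(PCR-bias-free abundance). A **Repertoire** is one sample's clonotype
set plus metadata (donor, cohort, cell subset); V/J calls are
normalized to the segment level (allele suffixes stripped, composite
hit lists truncated to the best hit) because all analyses are
segment-level. Clonotypes are kept sorted by descending UMI count with
ties broken lexicographically on the nucleotide sequence, so every
"top N" selection is deterministic.

Nonfunctional clonotypes (stop codon, frameshift, length not a
multiple of three) are removed before **all** downstream metrics and
frequencies renormalized. Amino-acid-level analyses require this;
applying the same filter before diversity estimation keeps one
consistent clonotype universe. Whether the original analyses excluded
nonfunctional clonotypes from diversity estimation is not decidable
from the available description; we chose uniformity and note that the
alternative (diversity on all clonotypes) changes slices by only the
small nonfunctional fraction. Similarly, diversity is computed on
nucleotide-level clonotypes — the native clonotype definition — rather
than on amino-acid classes; the two differ by the (small) convergence
factor.

## Equal-depth normalization

Every diversity-type comparison is preceded by downsampling to a fixed
number of UMIs — a multivariate hypergeometric draw without
replacement over clonotypes, seeded per (sample, V segment, analysis)
so the whole pipeline is reproducible from one master seed. Samples or
slices that do not reach the target depth raise a typed
`insufficientCoverage` condition; the pipeline converts it into an
exclusion record rather than dropping the sample silently, and the run
report accounts for every input sample in every analysis.

Sub-seeds are derived by a polynomial hash of the master seed and
string labels, folded modulo 2³¹−1. Deriving publicity seeds from the
sample identifier only (not from the pair) makes the pairwise
publicity statistic exactly symmetric.

## Metrics

- **Chao1** (bias-corrected): S_obs + f₁(f₁−1)/(2(f₂+1)). The
  bias-corrected variant is used so that slices with no doubletons
  (f₂ = 0) remain defined; the variant choice was otherwise open.
- **Normalized Shannon–Wiener**: H/ln S_obs with
  H = −Σ pᵢ ln pᵢ — Pielou evenness, the convention common in
  repertoire analysis. It is undefined for fewer than two clonotypes
  (an error, not a silent 0).
- **Convergence**: distinct-nucleotide count divided by
  distinct-amino-acid count within an equal-depth V slice. This equals
  the mean number of nucleotide variants per amino-acid clonotype.
- **Publicity**: both whole samples are downsampled to a common depth,
  each side reduced to its top-N clonotypes and collapsed to distinct
  amino-acid CDR3s, and the intersection counted. Matching is on the
  amino-acid sequence alone (not amino acid + V), and sharing is
  counted raw (unweighted) — the natural reading of a shared-clonotype
  count.

## CDR3 features

Physicochemical features are evaluated on the **central five residues**
of the CDR3 (window at 0-based offset ⌊(L−5)/2⌋, resolving even-length
ties toward the N-terminus), the loop positions with the highest
contact probability with peptide–MHC. Strength is the fraction of
strongly interacting residues {F, I, L, M, V, W, Y}; charge the
fraction of {D, E, K, R} (histidine excluded: mostly uncharged at
physiological pH); volume the mean of a published residue-volume scale
(Zamyatnin 1972, Å³) over the window — a mean-scale operationalization
of "bulky amino acids", chosen because no explicit bulky set is
standard. CDR3s shorter than five residues are excluded from
central-window features only; they still count for length, insertion
and diversity analyses. CDR3 length and added nucleotides are
whole-CDR3 features.

**Added nucleotides** (non-templated junction insertions) use the
recorded junction annotation when present (exact:
(j_start − v_end) − d_len). Without annotation they are inferred by
germline matching: longest CDR3 prefix agreeing with the germline V
tail, then longest suffix agreeing with the J head, then the longest
D-gene substring (≥ 3 nt, shorter matches being indistinguishable from
chance) in the remaining middle; chance overlaps can make the estimate
exceed the remainder, which clamps at zero. Because trimming removes
nucleotides from the junction-facing ends, the retained V is a prefix
of the stored V tail and the retained J a suffix of the stored J head;
the matcher follows that orientation. On simulated ground truth with
mean 4+4 insertions the estimator's mean absolute error is ≈ 1 nt
(chance matches extending into the insertion account for it); the test
suite enforces ≤ 1.5 nt.

Per-slice feature values are **abundance-weighted means**
(Σwᵢxᵢ/Σwᵢ, wᵢ = UMI count), equivalent to expanding clonotypes into
per-molecule rows and averaging; an unweighted mode exists. Weighted
values are invariant to row order and to a common count rescaling.

## Standardization and inference

To remove V-segment composition effects, every feature is turned into
Z-scores across samples within its (cell subset, V segment, feature)
stratum, using the **population** standard deviation; zero-variance
strata map to all-zero scores and singleton strata are dropped with a
warning (deterministic, bounded behaviour). Z-scoring is idempotent up
to 1e-9.

Group testing treats the pooled per-(sample × V segment) observations
as test units, mirroring per-segment panel pooling; a per-sample
aggregated mode (`mean_over_segments`) exists for sensitivity analysis
and feeds the PCA. Under the synthetic generator the per-V slices of a
sample are independent clonotype sets, so pooling does not inflate the
null; with real data the pooled mode inherits whatever within-donor
correlation the biology induces, which is why both modes are exposed.

The Kruskal–Wallis H (with tie correction), Dunn pairwise z values
(pooled-midrank variance with tie term), Benjamini–Hochberg step-up
adjustment and the exact/approximate Wilcoxon rank-sum test are
implemented from their defining formulas; chi-square and normal tail
probabilities come from R's standard routines. All tests are
two-sided. The Wilcoxon test enumerates the exact rank-sum null for
pooled sizes ≤ 12 without ties and otherwise uses the normal
approximation with tie-corrected variance and continuity correction;
the continuity-corrected approximation is conservative at very small
sizes (its exact size at 8 + 8 is 0.038), so null-calibration checks
are run at two-cohort sizes of 10 + 13, where its exact size is 0.042.
Benjamini–Hochberg adjustment is applied within each feature's family
of pairwise comparisons, matching per-panel adjustment; adjusted
p-values reproduce the classic step-up rejection set at any level.

PCA column-centers (and unit-scales by default) the samples ×
characteristics matrix and decomposes it by SVD; scores are UD,
loadings V, and each loading column's largest-magnitude entry is made
positive so signs are platform-independent. Constant columns are
dropped with a warning; missing strata in the pipeline's PCA input are
imputed at the column mean and logged as exclusions. The default PCA
input is the per-sample mean Z-score of every available feature within
a subset (8 features at desk scale; with several subsets the
characteristic set grows accordingly — the "23 characteristics" of a
full multi-subset study are whatever the feature table provides, since
no canonical enumeration exists).

## The synthetic-repertoire generator

The generator reproduces the statistical structure the metrics
consume, not T-cell biology: no thymic selection, no pMHC specificity.
One clonotype is V-tail + N1 + D + N2 + J-head with

- V, D, J drawn from usage distributions over a bundled
  **synthetic** germline (12 TRBV tails opening at the conserved Cys
  codon, 2 TRBD genes, 13 TRBJ heads ending at the conserved Phe
  codon; deterministic, generated, explicitly not IMGT sequences).
  Germline codons are drawn from a one-codon-per-residue alphabet and
  V tails are pairwise distinct at the amino-acid level, as real TRBV
  3' ends are — otherwise germline-internal synonymy would inflate
  convergence artifactually.
- Uniform exonuclease trimming within configured bounds (defaults 3 nt
  for V, 3 nt per D side, 4 nt for J);
- Geometric numbers of inserted nucleotides at each junction (default
  mean 4 + 4), drawn as codon strings truncated to length, with an
  optional logit bias toward codons of strongly interacting residues
  (`strengthBias`, default 0);
- Rejection of out-of-frame or stop-containing junctions (the
  productive-rearrangement filter). This conditioning slightly lowers
  the realized insertion mean relative to the raw geometric mean
  (longer junctions have more stop opportunities) — a property of the
  model, shared by the independent junction simulation used as the
  test oracle.
- With probability `convergenceRate` a new clonotype synonymously
  recodes an existing amino-acid CDR3 (same amino acids and V/J,
  different nucleotides) — convergent recombination implemented
  literally, so the convergence statistic's expectation is
  1/(1 − rate). Rare *natural* convergence events also occur
  (independent junctions encoding one amino-acid sequence), as they do
  in real repertoires.
- Clone sizes from a lognormal (default meanlog 0, sdlog 1) or
  power-law model, apportioned to exactly `totalUmi` molecules by
  largest-remainder rounding with a one-UMI floor — depth is conserved
  exactly.

Every simulated clonotype retains its true junction structure
(`v_end`, `d_len`, `j_start`, `true_insertions`), which survives the
AIRR round trip, enabling estimator-recovery tests against ground
truth.

What the generator does **not** emulate: germline allelic variation,
position-dependent trimming/insertion profiles (an IGoR-class model),
selection-driven amino-acid preferences, cross-sample donor structure
beyond cohort labels, or sequencing error. Passing tests therefore
demonstrate correctness of the statistical machinery and
detectability of injected effects under a clean generative model —
not performance on real sequencing artefacts.

## Fixture studies and effect sizes

`makeFixtureStudy()` writes a three-cohort study (young, old, XLA; 8
samples per cohort by default) of AIRR tables plus manifest and
ground-truth JSON. Desk-scale defaults — 1,500 clonotypes over 5,000
UMIs per sample, 12 uniformly used V segments — are sized so that the
full pipeline runs in seconds; the matching
`fixturePipelineConfig()` uses 250-UMI V slices for diversity and
publicity on the top 500 clonotypes at 3,000 common UMIs. (Full-scale
defaults of `pipelineConfig()` — 1,000-UMI diversity slices, 13,000
top clonotypes at 23,000 common UMIs — correspond to real study
depths.)

The `xla_like` preset injects the directional alterations the analysis
must detect: clonotypes per sample 1,500 → 600 (lower richness and
evenness at equal depth), convergence rate 0.02 → 0.2, insertion means
4 → 2 nt per junction (shorter CDR3s, fewer added nucleotides), and
insertion-codon strength bias 0 → 2. Effect sizes were set, as fixture
design, to move each abundance-weighted feature by roughly one
between-sample standard deviation — the magnitude of a prominently
significant effect at cohort sizes of 6–10. The strength bias in
particular acts only on the (shortened) non-templated insertions, a
few nucleotides of the 15-nt central window, so a per-codon logit
shift of 2 (odds ratio ≈ 7) is what yields a ≈ 1 SD shift in the
weighted central strength; smaller biases are diluted below
detectability by the templated majority of the window.

Acceptance-level checks run this design at 20 seeds: every injected
direction must be flagged (Dunn adjusted p < 0.05, correct sign) in at
least 90% of seeds, and on matched identical-parameter null studies at
most 10% of features may be flagged. Type-I calibration of the rank
tests uses 10,000 null simulations each.

## Numerical and degenerate-input conventions

- Frequencies are recomputed from counts on every construction; sums
  are validated to 1e-6 (1e-9 per clonotype).
- Duplicate (CDR3 nt, V, J) rows in input tables merge by summing
  counts with a warning; zero/missing-count rows are dropped with a
  message; malformed counts are row-level errors naming the line.
- `chao1` of an empty vector, `convergence` of an empty slice, and
  evenness of a single clonotype are errors, not NA.
- Kruskal–Wallis returns H = 0, p = 1 for fully tied data (tie
  correction factor ≤ 0); Wilcoxon returns p = 1 for degenerate pooled
  data.
- All randomness flows through explicit seeds; reruns of a pipeline
  configuration are byte-identical, including the JSON run report
  (file inventory stored as relative names).

## Known limitations

- The added-nucleotide estimator underestimates insertions by the
  expected chance-match overlap (≈ 0.5–1 nt at default settings); use
  annotated tables when junction calls are available.
- Pooled-segment test units assume approximate independence of per-V
  values within a sample; real repertoires may violate this (see
  above).
- The volume scale operationalizes "bulkiness" as a mean residue
  volume; fraction-of-bulky-set variants would need only a different
  residue scale but are not provided.
- Publicity depends on both `topN` and the common depth; values are
  comparable only within one configuration.
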