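# repfeat

Comparative analysis of TCR-β (T-cell receptor beta-chain) repertoires
across donor cohorts and sorted T-cell subsets, with a seeded V(D)J
recombination simulator for synthetic validation studies.

## The scientific problem

High-throughput TCR-β sequencing of sorted T-cell subsets (naïve and
memory CD4⁺/CD8⁺ cells, recent thymic emigrants, naïve regulatory T
cells, …) yields per-sample clonotype tables: distinct CDR3
rearrangements with UMI-based abundances. Comparing such repertoires
between cohorts — for example patients with a primary immunodeficiency
versus young and elderly healthy donors — requires a battery of
statistics that are all sensitive to sequencing depth and V-segment
composition, so the whole analysis is organised around equal-depth
downsampling and per-V-segment standardization:

- **Diversity.** Richness via the bias-corrected Chao1 estimator,
  S_obs + f₁(f₁−1)/(2(f₂+1)), where f₁ and f₂ count clonotypes seen
  once and twice; evenness via the normalized Shannon–Wiener index
  H/ln S_obs (Pielou evenness, the complement of clonality). Both are
  computed on V-segment slices downsampled to a common number of UMIs.
- **Convergence.** Convergent recombination, quantified as the number
  of distinct CDR3 nucleotide variants per distinct CDR3 amino-acid
  sequence (≥ 1, with 1 = injective translation).
- **Publicity.** The number of CDR3 amino-acid sequences shared by a
  pair of samples among their top-N most abundant clonotypes, after
  downsampling both to the same UMI count.
- **CDR3 physicochemical features.** Abundance-weighted means of
  per-clonotype values over the five middle residues of the CDR3 loop
  (the positions most likely to contact peptide–MHC): interaction
  strength (fraction of F, I, L, M, V, W, Y), mean residue volume (Å³),
  charged-residue fraction (D, E, K, R); plus whole-CDR3 length and the
  estimated number of non-templated nucleotides added at the V–D and
  D–J junctions.
- **Inference.** Features are turned into Z-scores within each (cell
  subset, V segment) stratum, compared across cohorts with the
  Kruskal–Wallis test followed by Dunn pairwise comparisons under
  Benjamini–Hochberg adjustment (Wilcoxon rank-sum for two cohorts),
  and summarized by PCA over the repertoire characteristics. The rank
  tests, the adjustment and the PCA are implemented from their defining
  formulas and cross-checked against reference implementations in the
  test suite.

Because real patient data cannot ship with a package, `repfeat`
includes a first-class synthetic-repertoire module: a seeded V(D)J
recombination simulator with controllable clone-size distribution, V/J
usage, junctional insertions and trimming, nucleotide-level convergence
and residue-composition bias, which generates AIRR-format studies with
per-clonotype ground truth for estimator-recovery and power testing.

## Worked example

Simulate a three-cohort study (8 samples each of young healthy, old
healthy, and a B-cell-deficient-like cohort with reduced diversity,
raised convergence, shortened junctions and raised CDR3 strength), then
run the full pipeline:

```r
library(repfeat)

fx  <- makeFixtureStudy("xla_like", seed = 1, dir = "demo_study")
cfg <- fixturePipelineConfig(fx$manifest, "demo_study/out", seed = 1)
rep <- runPipeline(cfg)

tests <- read.delim("demo_study/out/tests.tsv")
subset(tests, group_i == "XLA" & group_j == "young" &
       feature %in% c("shannon_norm", "convergence", "cdr3_len",
                      "added_nt", "strength"))[, c("feature", "z", "p_adj")]
```

```
      feature      z    p_adj
     strength   6.39 2.50e-10
     cdr3_len -10.24 1.96e-24
     added_nt -10.50 1.34e-25
 shannon_norm  -9.07 1.79e-19
  convergence  10.88 2.12e-27
```

Each row is a Dunn comparison of XLA versus young on Z-scored
per-(sample × V segment) values: the altered cohort shows higher CDR3
interaction strength and convergence (positive z) and lower evenness,
CDR3 length and added nucleotides (negative z), all far below the 0.05
adjusted-significance level. The underlying equal-depth metrics are in
`metrics.tsv`; for example mean per-slice Chao1 drops from ≈ 151 (young)
to ≈ 54 (XLA) and mean convergence rises from ≈ 1.02 to ≈ 1.22 at this
seed — the injected convergence rate of 0.2 corresponds to an expected
nt/aa ratio of 1/(1 − 0.2) = 1.25.

Lower-level entry points mirror the analysis stages:
`readClonotypeTable()` / `writeClonotypeTable()` (MiXCR-flavour and
AIRR TSV), `filterFunctional()`, `selectAbundantVSegments()`,
`sliceByV()`, `downsampleUmis()`, `chao1()`,
`shannonWienerNormalized()`, `convergence()`, `pairwisePublicity()`,
`clonotypeStrength()`/`clonotypeVolume()`/`clonotypeCharge()`,
`addedNucleotides()`, `weightedFeature()`, `zscoreWithinStratum()`,
`kruskalWallis()`, `dunnPairwise()`, `benjaminiHochberg()`,
`wilcoxonRankSum()`, `pcaFeatures()`. A thin command-line front end is
installed at `exec/repfeat.R` (`simulate` and `run` subcommands).

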