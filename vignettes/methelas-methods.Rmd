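---
title: "Models and design decisions in methelas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in methelas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

methelas implements two analysis tracks — whole-genome bisulfite methylome
contrasts for aging/Dnmt3a studies, and fasting–refeeding elasticity
scoring — together with a simulator that generates every input with known
ground truth. This vignette records the models, the parameters that matter,
and the design decisions taken where the underlying procedures were
underspecified, so that results are interpretable and reproducible.

## Coordinate and data conventions

All internal coordinates are 0-based half-open; conversion to and from
1-based formats (Bismark coverage) happens only inside the readers and
writers, so off-by-one drift cannot accumulate. CpGs are represented by the
position of the C on the forward strand; inputs reporting both strands can
be collapsed by the reader (`collapse_strands = TRUE`), which sums counts
at positions differing by one. The methylation-percent column of coverage
files is never trusted: counts are authoritative and the level is
recomputed as `meth / (meth + unmeth)`, undefined at zero coverage.

## The methylome simulator

The simulator emulates the count structure of post-bisulfite
adaptor-tagging (PBAT) sequencing of a 2×2 design (genotype WT/Tg × age
young/old):

* **CpG positions** follow exponential inter-CpG gaps (default mean 100 bp,
  roughly the genome-wide CpG density in mouse). Planted differentially
  methylated regions span a fixed number of consecutive CpGs (default 15)
  laid down at half the background spacing, reflecting the CpG-dense
  regulatory context (islands, shores, enhancers) where DMRs concentrate in
  real data. Fixing the CpG count rather than the bp width makes caller
  recall independent of local density.
* **Baseline methylation** of each CpG is a Beta(2, 2) draw shared by all
  samples, giving the broad unimodal methylation landscape of a
  whole-genome average without the bimodality of CpG islands; the shape is
  configurable (`baseline_beta`).
* **Effects** act on the proportion scale and are clipped to [0, 1]: old
  samples shift by `+age_effect` inside planted age-hyper regions and
  `-age_effect` inside age-hypo regions (default 0.3); Tg samples shift by
  `tg_effect_in_hyper` (0.15), `tg_effect_in_hypo` (0.03) and
  `tg_effect_background` (0.01). The defaults encode the qualitative
  asymmetry the aging analysis is meant to recover — the genotype effect is
  stronger where methylation rises with age. Because no quantitative effect
  sizes are published for these shifts, the defaults are scenario
  parameters chosen once as plausible for a strong overexpression model,
  not empirical estimates.
* **Counts** are Poisson totals (default mean coverage 20×) with
  beta-binomial methylated counts. The dispersion `rho` (default 0.05)
  interpolates between the binomial (`rho = 0`, a testable limit) and
  increasingly overdispersed counts, matching the extra-binomial variation
  of real bisulfite libraries.
* **Randomness** derives from one global seed through named sub-streams
  (per chromosome, per sample, per stage), so enlarging a design adds
  samples without perturbing existing ones, and identical seeds give
  byte-identical outputs.

What the simulator does **not** emulate: bisulfite conversion failure,
mapping bias, copy-number and SNP confounders, strand asymmetry,
methylation bimodality, and spatial correlation of methylation beyond the
planted regions. Passing tests on simulated data therefore demonstrate the
correctness and statistical behavior of the algorithms under the stated
model, not performance on any particular real library.

For the fasting–refeeding track, tissue masses are state means with
multiplicative lognormal noise (`cv` on the log scale, default 0.05 ≈ 5%
biological variation); the refed mean interpolates between fasted and fed
by the elasticity parameter `rho in [0, 1]`. MIAMI probes get Gaussian
log-ratio noise on both channels with a class-dependent shift on the
methylation-sensitive (HpaII) channel only.

## Descriptive layer

Windows tile each chromosome from 0 with step = size by default; the
sliding step is exposed but disjoint tiling is the default because the
window step of the summarized analyses is not stated and disjoint windows
keep values independent. The trailing partial window is kept. Sex
chromosomes are excluded by default, the standard convention for
methylome analyses of mixed-sex designs. Window and feature values are
unweighted means of the per-site levels of retained CpGs ("averaging the
methylation levels of CG sites"), not coverage-weighted means; a
`min_sites` threshold (default 1, since no per-window site minimum is
published) controls when a cell is reported missing.

PCA drops regions with any missing value (complete-case) before a
centered, unscaled decomposition — the simplest defensible policy;
imputation is out of scope. Hierarchical clustering offers Euclidean
distance (sample trees) and correlation distance with complete linkage
(DMR z-score heatmaps). Row z-scores use the sample (n−1) standard
deviation. Zero-spread rows are an error by default or dropped with a
warning (`on_zero_spread = "drop"`), because a constant row has no
z-score.

## The DMR caller

The caller follows the metilene recipe — gap-limited pre-segmentation,
recursive binary segmentation, per-region two-sample tests — without
claiming bit-compatibility:

* **Site inclusion:** a CpG enters the contrast when its level is defined
  in all samples of each group (`min_present` relaxes this). This stricter
  rule replaces metilene's internal missing-value imputation, which is not
  documented in enough detail to reproduce.
* **Pre-segmentation:** chromosomes split where adjacent informative CpGs
  are more than `max_cpg_gap_bp` apart (default 300 bp, metilene's
  default); candidate regions need `min_cpgs` sites (default 10, likewise).
* **Segmentation objective:** the contiguous block (length ≥ `min_cpgs`)
  maximizing the absolute mean per-site difference; recursion descends into
  the best block and its flanks until no sub-block improves on its parent,
  with leftmost tie-breaking. Because a minimum-length argmax shrinks a
  true region to its strongest core under noise, each emitted block is
  boundary-refined: extended over adjacent CpGs whose per-site difference
  shares the block's sign, up to the pre-segment edge. Refined candidates
  can overlap; after filtering, overlapping calls are resolved by keeping
  the region with the smaller KS p (then larger |difference|, then
  leftmost), so the final call set is always disjoint.
* **Tests:** metilene-based workflows filter on metilene's "2D KS"
  p-value, a statistic that is awkward to audit outside that tool.
  This package substitutes a standard two-sample Kolmogorov–Smirnov test on
  the pooled per-site per-sample values plus a Mann–Whitney U test on
  per-site group means, and records both — preserving the filtering
  semantics (p-threshold plus effect-size threshold) with an auditable
  statistic. This divergence is deliberate and documented here.
* **Exact mode:** `p_method = "exact"` enumerates all C(nA+nB, nA)
  assignments of samples to groups and reports permutation p-values of the
  KS statistic and the absolute rank-sum deviation. With 4 vs 4 samples the
  smallest achievable exact p is 1/70 ≈ 0.014, which can never satisfy a
  p < 0.01 filter — an inherent property of exact small-sample inference,
  and the reason the asymptotic p-values (as in metilene itself) are the
  calling default while the exact mode serves validation.
* **Filters:** `p_KS < p` and `|mean difference| > delta`, with the two
  published pairs exposed as presets: tibialis anterior (0.01, 0.20) and
  gastrocnemius (0.05, 0.10); thresholds are absolute values on the
  proportion scale (20% ⇔ 0.20), applied to both directions.
  Benjamini–Hochberg q-values are computed across all tested candidates for
  transparency but do not participate in the published-filter mode, which
  filters on the raw p.
* **DMRG:** the nearest gene (gap distance; 0 when overlapping the gene
  body) with deterministic tie-breaking by gene start then id.

## Aging contrasts

Age-DMRs come from the old-WT vs young-WT contrast and partition by sign
into hyper and hypo sets. The Dnmt3a-sensitivity statistic works on the
methylation-proportion scale — per region, the young-Tg minus young-WT mean
level — because that is the scale of the published heatmaps and of the
"methylation difference" thresholds; no logit transform is applied, keeping
deltas bounded in [−1, 1]. The two per-region delta distributions (hyper vs
hypo sets) are compared by a Wilcoxon rank test, chosen because region
deltas are bounded and non-normal; the test choice is implementation
plumbing rather than a field convention. Old-Tg samples
are carried through matrices and heatmaps but excluded from the sensitivity
statistic, which concerns young animals only.

## MIAMI classification

Probes are classified on the linear HpaII between-sample signal ratio with
the published thresholds: below 0.714 hypomethylated, above 1.3
hypermethylated (strict inequalities; the asymmetry of the pair is
reproduced verbatim since no rationale is published). Whether an MspI-ratio
constraint should gate calls is not documented for the protocol; an optional
`mspi_band` implements that copy-number guard but is off by default, so the
default behavior asserts only what is documented. Note that classifying on
the HpaII ratio alone means noise on the MspI (copy-number) channel
propagates into the call; with the default simulation noise this produces a
small, quantifiable misclassification rate around the thresholds, which the
tests measure as classification/truth agreement rather than asserting
perfect recovery.

## ElaS

The Tissue Elasticity Score is evaluated exactly as its spreadsheet
definition, including two oddities that are reproduced deliberately:

1. `X` and `Y` are already percentages of the form
   `value/mean(fasted)×100 − 100`, yet the formula subtracts a further 100
   from both. The printed formula is what produced the published figures,
   so the verbatim form is the default; the arguably intended reading (no
   second subtraction) is available behind `corrected = TRUE` and is off by
   default.
2. The final condition applies `ABS()` to `Y − 100` but not to `A`; this is
   kept as printed.

Consequences of the verbatim form: scores are shifted far negative for
realistic tissue-mass ratios and only orderings and differences are
interpretable — which is how they are used (the score is monotone in the
restoration fraction, verified by simulation in the test suite). When
`max(Y − 100, A) = 0` the division is undefined; the score is reported as 0
with a `degenerate` flag rather than raising, so batch runs complete, and
flagged scores are excluded from summaries. Group summaries are mean ± SE
with a two-tailed unpaired Student's t test between genotypes, the
published comparison; the SE of a single refed mouse is reported missing.

The gene-responsiveness summaries (induction = fasted/fed mean ratio;
restoration = 1 − |refed − fed| / |fasted − fed|) are this package's own
descriptive metrics for fed/fasted/refed expression panels; restoration is
flagged undefined when fasted and fed means coincide.

## Pipeline and reproducibility

`validate_config()` schema-checks a YAML scenario, rejects unknown keys and
out-of-order stages, and fills the tissue-mode presets (coverage ≥ 10 reads
with the 0.01/0.20 filters for tibialis anterior; ≥ 5 reads with 0.05/0.10
for gastrocnemius). `run_pipeline()` executes simulate → methylome → dmr →
aging → miami → elas, writes every output as plain text, and records a JSON
manifest with the seed, per-stage wall-clock and md5 checksums; a failing
stage is recorded in the manifest before the error propagates. Because all
outputs are uncompressed text written deterministically, checksums are
plain file md5 and reruns with the same config and seed are byte-identical.

## Problem sizes and numerical choices

The test suite and the acceptance script work at desk scale, chosen to give
stable Monte-Carlo margins: genomes of 1–2 Mb (≈ 10,000–20,000 CpGs) at
20× coverage with 4 mice per group; 50–70 planted regions of 15 CpGs; 10–20
replicate simulations for stochastic checks; 8 mice per feeding state.
Segmentation tie-breaks and the 1e-12 tolerance on the improvement test
make the caller deterministic; permutation p-values use a 1e-12 slack when
comparing statistics to protect against floating-point ties.

## Known limitations

* The KS/MWU region tests are a documented stand-in for metilene's exact
  statistic; absolute DMR counts on real data will differ from a metilene
  run even where the filtering semantics match.
* Site inclusion requires full per-group coverage by default, which is
  conservative at low depth.
* The simulator's independence assumptions (between CpGs, between samples)
  understate the spatial and biological correlation of real methylomes, so
  simulated false-positive rates are optimistic relative to real data.
* The reported decline of methylation in old Tg muscle relative to young
  Tg muscle (a possible technical artifact) has no defined statistic and is
  not modeled.
* Epigenetic-clock age prediction, DEG calling, and enrichment analyses are
  out of scope; DEG lists are consumed as plain tables.
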