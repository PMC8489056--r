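---
title: "Reference-gene stability analysis with refstab: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability analysis with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR reports a quantification cycle Cq per well: the PCR cycle at which
fluorescence crosses a threshold. Cq is a log2-scale abundance measure —
one cycle less means roughly twice as much starting template — and it mixes
three things: the gene's true expression, the amount of RNA/cDNA loaded for
that sample, and technical noise. Normalization against reference genes is
how the loading term is removed, which is exactly why an unstable
"reference" is so damaging. `refstab` implements the four standard
stability diagnostics, a consensus, and the quantification workflow that
follows the choice.

## Data model

The unit of analysis is a gene × sample matrix of technical-replicate-
collapsed Cq values (`cq_matrix`), with sample metadata assigning each
biological sample to a group (a developmental stage, a sex × stage class, a
cultivar treatment — the package attaches no meaning to the label beyond
grouping).

Choices made at this layer:

* **Technical replicates are averaged arithmetically.** Cq is already a log
  quantity; a geometric mean of Cq would average on the wrong scale.
* **Replicate disagreement is flagged, never deleted.** A cell whose
  replicate range exceeds `outlier_range` (default 0.5 cycles, the usual
  rule of thumb for SYBR triplicates) keeps its mean but carries a flag, so
  a rerun from the same file reproduces the same matrix.
* **Missing Cq ("Undetermined") is never imputed.** Each algorithm receives
  the complete-case submatrix for its gene panel; imputation would
  manufacture stability. Fewer than three surviving samples is an error,
  not a silent degenerate result.

## The four algorithms

**Comparative ΔCq.** For every ordered gene pair, the per-sample difference
ΔCq = Cq_j − Cq_k; its sample SD (n−1 denominator, as everywhere in the
package) measures how much that pair's relative expression moves; gene j's
score is the mean of its G−1 pair SDs. Differencing removes anything shared
per sample, so the score is exactly invariant to loading.

**geNorm.** Cq is first transformed to relative quantities
q = E^(Cq_min − Cq) with E the amplification factor (default 2, i.e. 100%
efficiency), anchoring each gene's best sample at q = 1. M_j is the mean
over partners of SD(log2 q_j/q_k). Two reporting modes exist because the
field uses both: `genorm_m_values()` computes one M per gene on the full
panel (the only way a published table can show *distinct* values for the
top two genes), and `genorm_stepwise_ranking()` re-computes M after
excluding the worst gene, repeatedly, until two genes remain — those two
are mutually indistinguishable by construction and are reported jointly
with rank 1.5 (the same average-rank convention the consensus uses). Genes
with full-panel M above 1.5 are flagged unusable, the conventional ceiling.
`pairwise_variation_curve()` builds normalization factors NF_n (per-sample
geometric means of the top-n genes' quantities) and
V(n/n+1) = SD(log2 NF_n/NF_{n+1}); the optimal panel size is the smallest n
with V < 0.15, falling back to all genes when no n qualifies. The 0.15
cutoff is the community default and a *guideline*; the curve itself is
always reported.

**NormFinder.** A variance-components view on sample-centered log2
expression x = −Cq. Centering each sample over genes removes loading;
centering each gene's group means across groups leaves the gene × group
interaction deviations d_ig. Per gene and group an intragroup variance is
estimated with a correction undoing the contraction that centering over a
finite panel of G genes induces (the estimate is floored at zero, as
negative variances are meaningless), a common intergroup variance γ² is
estimated from the spread of the d_ig, each deviation is shrunk by
γ²/(γ² + σ²_ig/n_g), and the stability value is
SV = mean_g(|d̃_ig| + √(σ²_ig/n_g)). With a single group the deviations
disappear and SV reduces to the per-gene residual SD. Because every step is
invariant to per-gene affine recodings, working on −Cq is equivalent to
working on any 2^(±ΔCq) quantity transform — the package states this rather
than guessing which transform a given spreadsheet used. G ≥ 3 genes and
n_g ≥ 2 per group are hard requirements of the estimator.

**BestKeeper.** Deliberately *not* loading-invariant: the BestKeeper index
is the per-sample geometric mean of all candidates' raw Cq, and each gene
is judged by its Pearson r against that index (plus raw-Cq descriptives: a
good reference should co-vary with total input). Dispersion defaults to the
mean absolute deviation from the mean — BestKeeper's published "SD (± Cq)"
is an average deviation — with the sample SD available via
`dispersion_mode = "sd"`; both are returned. Genes with dispersion above
1 cycle are flagged inconsistent but never auto-excluded. A zero-variance
gene has no defined r and is reported as missing with a flag, ranked last.

**Consensus.** The four rankings are combined by the unweighted geometric
mean of ranks, ties as average ranks. The well-known web aggregator
publishes numbers that cannot be reproduced from its own printed ranks
under any plain geometric mean, so `refstab` implements the documented,
reproducible rule and leaves any reweighting to the reader.

## Quantification

`ddcq_fold_change()` implements Livak 2^(−ΔΔCq): ΔCq = target − reference
per sample, calibrated against a sample, a group (mean ΔCq over its
samples) or an explicit ΔCq. Multi-gene references are aggregated as the
arithmetic mean of Cq — identically the log2 of the geometric mean of
quantities, the aggregation geNorm recommends. A shared-calibrator mode
scales several targets to the first target's calibrator ΔCq, the
convention used when two genes are plotted against one gene's level in one
stage. The default assumes 100% efficiency; per-gene efficiencies from
`fit_standard_curve()` can be fed into the geNorm transform, and the
standard-curve module reports E% = (10^(−1/slope) − 1) × 100 from the
regression of mean Cq per dilution level on log10 amount (per-level
averaging is the default; pooled replicate regression is a flag — published
work rarely states which was used, and on balanced designs the slope is
identical). Between-run correction divides each plate's quantities by that
plate's calibrator geometric mean relative to all plates, with factors
renormalized to unit geometric mean so the correction is label-invariant.

## The simulator, and what passing tests mean

`generate_cq_dataset()` draws
Cq = μ_i + L_s + δ_ig + η_is + plate_p + ε_isr with independent normal
components: gene-specific group effects δ (SD τ_i — expression that truly
changes across stages, which is what stability algorithms punish),
sample-level noise η (SD σ_i), shared loading L (SD 0.5 cycles by default —
a realistic spread for column-purified RNA batches), technical noise ε (SD
0.1 cycles, typical for SYBR triplicates) and optional plate shifts. The
default panel mirrors the stage-structured design the package was built
around: 7 genes × 8 stage/sex groups × 3 biological × 3 technical
replicates, true instabilities √(τ² + σ²) spanning 0.1–1.0 cycles, split
evenly between the two components. All randomness flows from one seed
through a private stream, so generation never perturbs the caller's RNG.

What the simulator does *not* emulate: amplification-curve shape,
inhibition, heavy-tailed or correlated noise, gradual primer degradation,
and genuinely non-normal group effects. Recovery results on simulated data
therefore validate the algorithms' arithmetic and their documented
sensitivity profiles (loading invisible to ΔCq/geNorm/NormFinder, visible
to BestKeeper), not robustness to pathological chemistry.

Two statistical facts shaped the test design and are worth knowing when
interpreting any stability table. First, the pairwise methods score each
gene through its partners, so the scores of two very stable genes differ
only marginally when the panel also contains noisy genes — their relative
order is the least reliable part of any ranking. Second, with K groups the
*realized* spread of a gene's group effects fluctuates around τ with
relative SD ≈ 1/√(2(K−1)) (~27% at K = 8), so methods measure the realized,
not the parametric, instability; recovery tests are framed as high
fixed-seed success rates or median errors, not certainties.

## Problem sizes and numerics

The validation experiments run 100 simulated datasets of the default
24-sample design per claim, 20–50 datasets for the slower property checks,
and n = 200 samples for the single-group NormFinder consistency check —
sizes at which the sampling distributions of the metrics are tight enough
for meaningful assertions while the whole suite stays interactive. Ties in
every ranking break deterministically by input order; SDs use the n−1
denominator throughout; log ratios are base 2; variance estimates are
floored at zero; ORF coordinates are 0-based half-open internally and
1-based in human-readable reports.

## Known limitations

* NormFinder's exact SV combination rule is not printed in most applied
  papers; `refstab` follows the Andersen-style decomposition described
  above and validates it by recovery, so small numeric differences from any
  particular binary's output are expected.
* BestKeeper's regression-on-index diagnostics and the original
  spreadsheet layouts are out of scope; only the index correlations and
  descriptives are computed.
* The consensus is the documented unweighted geometric mean; aggregators
  with hidden weights will disagree.
* Instrument-native exports (RDML and vendor formats) are not parsed; the
  package reads plain long/wide CSV.
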