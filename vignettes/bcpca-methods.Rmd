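---
title: "Models and methods behind bcpca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bcpca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcpca)
```

This vignette explains the statistical models the package implements, the
assumptions behind them, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the procedure was genuinely open.

## The measurement model

A pooled BC-PCA screen couples the in vivo abundance of one binary protein
complex to the competitive growth of one barcoded strain: the two proteins
are fused to complementary DHFR fragments, and the reconstituted enzyme
confers methotrexate (MTX) resistance in proportion to complex abundance.
Each strain carries two independent barcodes (UP-tag and DOWN-tag) whose
array fluorescence measures strain abundance after selection. The package
treats relative log2 barcode abundance as directly proportional to relative
log2 complex abundance. This identity-on-log2 transfer function is a
modeling decision: the assay literature establishes monotonicity and an
approximately linear relationship over the useful dynamic range, but no
exact functional form, and every downstream inference consumes only
relative changes, for which the identity is the natural neutral choice.

## Differential calling

Raw fluorescence is quantile-normalized and then log2-transformed.
Normalization is performed separately for UP-tags and DOWN-tags, which are
PCR-amplified as separate pools, and separately within each selection
regime, whose intensity distributions differ systematically. Ties receive
the mean of the per-rank means they span (the deterministic convention of
`limma::normalizeQuantiles`). Quantile normalization assumes the columns
are exchangeable draws from a common distribution; two consequences matter
in practice. First, genuine signal in a minority of treatment columns is
mildly compressed, most strongly for strains at the extremes of the
intensity distribution, where the per-rank means are dominated by control
columns. Second, data that are already on a common scale (for example a
noiseless simulation) do not need it, and `bcpca_calls(..., normalize =
FALSE)` skips it; the package's exact round-trip verification uses that
path so that the calling logic itself can be checked against planted truth
without rank-compression artifacts.

The contrast is fixed at treatment mean minus control mean (two treatment
and six control replicates in the emulated design) — no covariates, because
the procedure being implemented is a plain two-group comparison. The test
statistic is an empirical-Bayes moderated t: per-tag residual variances
$s_g^2$ with $d_g$ degrees of freedom are shrunk toward a prior $s_0^2$
with $d_0$ prior degrees of freedom,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated statistic is referred to a t distribution on $d_0 + d_g$
degrees of freedom. The hyperparameters are fitted by moment matching on
the log residual variances (the scaled-F hierarchical model): the excess
spread of $\log s_g^2$ beyond its sampling spread determines $d_0$ through
the inverse trigamma function, and $s_0^2$ follows from the mean. When the
observed spread does not exceed the sampling spread, $d_0 = \infty$ and
$s_0^2$ is the arithmetic mean of the variances (the moment estimator in
that limit). Two limits pin the implementation down: $d_0 = 0$ must
reproduce the ordinary pooled t exactly, and $d_0 = \infty$ must use the
common variance for every tag; both are tested, and the full fit is
cross-checked against an independent implementation of the same model.
Rows with zero residual variance are decided by the contrast alone (p = 1
for a zero contrast, p = 0 otherwise), which makes noiseless data behave
sensibly instead of producing 0/0.

P-values are converted to q-values by Benjamini–Hochberg step-up within
each tag class. The dual-tag call requires *both* tags to pass
`|log2R| > 0.25` and `q < 0.05` with matching signs; all four inequalities
are strict, exactly as the thresholds are stated. A complex with tags
moving in opposite directions is `unchanged` no matter how significant.

Tag artifacts are handled in two passes, both using the identical
normalization, contrast and threshold machinery on the non-selective
(−MTX) arrays: strains called dynamic without selection respond to the
condition through the fusion itself and are excluded for that condition;
and any PCA fragment (protein × fusion side) occurring **more than once**
among a condition's excluded strains taints every complex carrying it,
which are excluded "by association". Exclusion takes precedence over
calling, so an excluded strain is never reported accumulated or depleted.

Missing intensities are not imputed — import fails loudly. Barcodes not
detected across replicates should be removed before analysis, which is how
the assay's own bookkeeping treats them.

## Hubs and the conservative ratio

Hubs are proteins with at least 10 distinct interaction partners; a
homodimer self-edge contributes one partner (the protein itself). Per
strain, the **conservative log2 ratio** is whichever tag ratio is closest
to zero (ties resolve to the UP-tag), a deliberately cautious single-number
summary. Directional bias of a hub in a condition compares the
conservative ratios of hub-incident complexes against all remaining
complexes with a two-sided Mann–Whitney U test — exact enumeration when
both groups have at most eight observations and no ties, otherwise the
normal approximation with continuity and tie corrections — and BH
correction is applied jointly across all hub × condition tests, the most
conservative reading of an uncorrected-family ambiguity.

## Rewiring null models

The question the topology analysis asks: are the observed dynamic edges
arranged as if a few proteins changed availability (protein-centric), or
as if individual interactions were modulated independently
(interaction-specific)? The two samplers hold the observed numbers of
accumulated, depleted and unchanged interactions fixed:

* **Node-based.** Directions alternate, starting with accumulated. A
  uniformly random protein is proposed to have *all* of its interactions
  change in the current direction; the proposal is accepted only if the
  resulting count of that direction's labels would not exceed its quota.
  Relabeling may flip edges previously assigned the other direction — the
  most recent assignment wins — in which case sampling of the deficient
  direction resumes; the loop ends when both quotas are met exactly.
  Because flips make the process path-dependent, it can cycle on dense
  graphs with large quotas; each attempt therefore has a bounded proposal
  budget and the sampler restarts from scratch, raising an error (never
  silently truncating) if a retry budget of attempts is exhausted. Note a
  structural feasibility constraint: whole-node moves can only realize
  label counts reachable without ever exceeding the quota, so, for
  example, a quota of one on a graph whose minimum degree is two is
  unsatisfiable and correctly errors.
* **Edge-based.** The required labels are assigned uniformly at random to
  still-static edges.
* **Mixtures.** `round(fraction × quota)` labels per direction from the
  node-based phase, the remainder edge-based, so final counts always equal
  the quotas exactly.

For each candidate fraction, 1,000 simulated labelings (200 in the
package's own desk-scale checks; the parameter is `n_sims`) yield a null
distribution of the metric — largest same-direction component size, or
subgraph density $2|E|/(|V|(|V|-1))$ with $|V|$ the nodes incident to at
least one such edge — separately for accumulated and depleted subnetworks.
The observed metric is placed on the empirical percentile scale (linear
interpolation between order statistics at plotting positions
$(i-\tfrac12)/n$); a fraction is *consistent* when the observation falls
within the 5th–95th percentile band for both directions, and the best
fraction minimizes the larger of the two departures $|percentile - 50|$,
with ties resolved toward the smaller fraction for determinism. Fewer than
50 dynamic edges triggers a warning: the bands become unstable, which is
why conditions with little rewiring are not informative for this analysis.
Conventions fixed where the procedure was open: self-edges count toward
$|E|$ and their node toward $|V|$; a single-node subgraph has density 0;
the alternation starts with "accumulated".

## Mass-action prediction

Treating each binary complex as an isolated equilibrium with total protein
concentrations $C_1, C_2$ and dissociation constant $K_d$, the complex
concentration is the physically admissible root of
$K_d = (C_1 - C)(C_2 - C)/C$:

$$C = \tfrac12\left(C_1 + C_2 + K_d - \sqrt{(C_1 + C_2 + K_d)^2 - 4 C_1 C_2}\right),$$

evaluated in the rationalized form $2C_1C_2/(S + \sqrt{S^2 - 4C_1C_2})$
to avoid cancellation; as $K_d \to 0$ it tends to $\min(C_1, C_2)$, which
is also provided as the explicit tight-binding approximation. $K_d$ is
modeled as $\max(C_1, C_2)/20$, a scale-free choice placing every complex
in a moderately strong binding regime. Resting concentrations are used in
ppm as-is — only ratios matter downstream. Predictions for a condition
scale each protein by its mRNA ratio $R_i$ at a chosen timepoint (4 h
after the carbon-source shift is the default, where mRNA and complex
changes correspond best) and re-evaluate the closed form; the prediction
is $\log_2(C_{cond}/C_{ref})$.

Choices worth stating: $K_d$ is held at its reference value in the
perturbed condition, because a binding constant is a property of the
complex, not of expression levels (a `recompute_kd` flag exposes the other
reading, which only matters for large fold changes); homodimers are
evaluated with $C_1 = C_2$ and the same closed form with no stoichiometric
factor; missing abundances fall back to the genomewide median ppm and
missing expression to $R = 1$, with fallback counts recorded; and strains
whose tag ratios disagree by more than 1 log2 unit (strictly) are excluded
from model-data comparisons as barcode artifacts.

Direction accuracy summarizes the predictor qualitatively: for a grid of
minimum predicted effect sizes, the fraction of predicted-accumulated
complexes actually called accumulated (and likewise depleted), optionally
restricted to significant calls (used when stratifying by hub
concertedness), with bootstrap confidence bands over complexes.

## Variance partitioning under measurement error

An observed model-to-data correlation understates a model's intrinsic
explanatory power because both the expression input and the barcode
readout are noisy. For two equally noisy measurements of an ideal signal
$X$,

$$\rho(X+\varepsilon_1, X+\varepsilon_2) = \frac{\sigma_X^2}{\sigma_X^2 + \sigma_\varepsilon^2} = \rho(X, X+\varepsilon)^2,$$

so the *unsquared* correlation between a replicate pair already estimates
the squared signal-versus-measurement correlation — the variance-explained
ceiling that experimental error alone imposes. Inverting the identity
gives the noise to inject to emulate an observed replicate correlation:
$\sigma_\varepsilon = \sigma_X\sqrt{1/\rho - 1}$.

"Noise-added" replicates are built in three steps: calibrated Gaussian
noise on the log2 expression ratios (spread taken as the standard
deviation of the reference expression vector); the mass-action model maps
noisy expression to predicted complex ratios; and two independent Gaussian
terms on the output calibrated to the biological-replicate and
between-tag correlations (spread taken as the standard deviation of the
predicted vector). The two output components are combined as independent
Gaussians — the correlations are measured separately and no dependence
between them is identifiable from them. With 100 replicates, all
$\binom{100}{2} = 4950$ unordered pairwise correlations form the
$\rho^2_{exp}$ distribution; each is paired with a bootstrap resample (over
complexes) of the observed model-to-data squared correlation
$\rho^2_{total}$, and the intrinsic variance explained is

$$\rho^2_{mod} = \frac{1}{1/\rho^2_{total} - 1/\rho^2_{exp} + 1},$$

reported as a full distribution with median and 5th/95th percentiles.
Bootstrap pairs that land above the experimental ceiling are clipped to it
with a warning — at small sample sizes this is expected sampling noise,
not an error. All correlations are Pearson on log2 scales. Parameter
recovery is the operative validation: with model error injected so that
the true $\rho^2_{mod}$ is 0.6 on 1,000 synthetic complexes, the median
estimate lands within a few hundredths of 0.6.

## The synthetic-study generator

`synthetic_spec()` fixes the study conditions; one master seed drives
deterministic per-stage substreams, so an identical spec reproduces the
study bit for bit. The defaults emulate the design being modeled:
duplicate treatment arrays against six control replicates, in both
selective and non-selective media; a network of 800 interactions among 400
proteins with eight planted hubs of at least ten partners (hubs are wired
to each other first, then topped up with random partners — only the
degree threshold matters to the analysis, not a specific degree law);
2% homodimer self-edges among filler edges; log-normal resting abundances
(log10-ppm mean 1.3, sd 1.0, the spread of genomewide proteome
compilations); 20 proteins perturbed with log2 changes drawn uniformly
from [−2, 2] and 10 interaction-specific shifts applied directly to
complex levels (capped at the limiting partner's concentration so ground
truth never violates the physical bound); and log2-scale Gaussian noise of
0.1 for tags and replicates and 0.2 for expression, consistent with the
high replicate correlations such arrays achieve. Protein-centric effects
are propagated to complex levels *through the mass-action model*, so the
generator is the exact inverse of the inference chain; interaction-specific
effects are direct log2 shifts because the downstream analysis only ever
sees the resulting ratio. Expression is reported at two timepoints with
independent noise so the replicate correlation needed by the variance
partition can be estimated, and a configurable fraction of genes can be
set missing to exercise the R = 1 fallback.

What the generator does **not** emulate: probe-level microarray physics,
growth-curve kinetics (the growth-to-intensity map is identity on log2),
correlated or heavy-tailed noise, competition between complexes sharing a
protein, and condition-specific interactions absent from the reference
network. Passing tests on synthetic data therefore demonstrate that the
inference chain is internally correct and invertible under the stated
noise model — not that real arrays satisfy that model.

## Problem sizes and reproducibility

The package's own verification runs at desk scale, chosen so the full
suite completes in well under a minute of compute per module: networks of
150–1,000 edges, 100 noise-added replicates (4,950 pairwise estimates),
200 topology simulations per grid point, and 10,000 random triples for the
closed-form-versus-bisection check. Every stochastic step accepts a seed;
`run_pipeline()` derives per-stage substreams from one master seed and
writes a manifest, and rerunning with the same inputs and seed reproduces
byte-identical outputs.

## Known limitations

The moderated-t hyperparameters are fitted per contrast, not jointly
across conditions sharing a control; with many conditions a joint fit
would gain a little stability. The node-based sampler's flip semantics are
one of several readings of "the most recent assignment takes precedence";
the chosen reading terminates and respects both quotas, but percentile
bands on real data could shift slightly under another reading. Quantile
normalization compresses signal at the extremes of the intensity
distribution when treatment columns are few. And the mass-action model
deliberately ignores localization, post-translational modification, and
competition — deviations between its predictions and observed complex
changes are the interesting biology, which is exactly what the variance
partition quantifies.
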