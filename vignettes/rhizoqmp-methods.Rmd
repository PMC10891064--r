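---
title: "Methods: quantitative profiling, turnover, network ecology and SynCom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative profiling, turnover, network ecology and SynCom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoqmp)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data validation does and does not
establish.

## Spike-in calibration (QMP)

Relative microbiome profiling (RMP) normalizes each sample to its read
total, so any statement about abundance is conditional on the total load —
which in root compartments changes by more than an order of magnitude over
plant development. Quantitative profiling adds synthetic DNA standards of
known copy number to each sample before PCR; because spikes and community
DNA pass through the same amplification and sequencing, the reads-per-copy
rate cancels and

$$A_{ij} = c_{ij}\,\frac{\sum_k S_k}{\sum_k s_{kj}}\,\frac{1}{m_j}$$

estimates taxon $i$'s 16S copies per gram of fresh sample $j$ ($c$ taxon
reads, $S$ spike copies added, $s$ spike reads, $m$ mass in grams).

Two choices here were open:

* **Pooled spike ratio.** We sum copies and reads over all spikes rather
  than calibrating each spike separately. The pooled ratio is the maximum
  likelihood estimator under proportional sampling, tolerates dropout of
  low-concentration spikes, and needs no regression. Per-spike
  copies/read ratios are still computed as diagnostics
  (`spike_diagnostics()`); a coefficient of variation above 0.5 within a
  sample triggers a warning, since discordant spikes indicate
  amplification bias. A multi-point per-spike regression would be the
  natural extension and can be layered on the same diagnostics table.
* **Zero spike reads.** A sample with no spike reads has no calibration;
  it is excluded with a warning, never silently.

The taxonomic filters run before any normalization: features whose
kingdom is not Bacteria are dropped in all samples (this removes
chloroplast/host signal and unassigned kingdoms), and
Bradyrhizobiaceae-affiliated features are zeroed in endosphere samples
only — inside the root the nodule symbiont dominates reads without
reflecting the resident community. Rarefaction (single draw without
replacement, default 1030 reads, shallower samples dropped with a report)
applies only to the RMP branch; QMP analyses use unrarefied calibrated
profiles.

## Diversity and temporal turnover

Shannon diversity uses the natural logarithm (configurable via `base`).
Bray-Curtis dissimilarity is computed on copies per gram for QMP — so
load differences contribute to $\beta$-diversity — and on proportions for
RMP; no transformation is applied by default (a log option would damp
load effects and is deliberately left to the caller). PCoA is classical
MDS on $-D^2/2$; negative eigenvalues are reported, not corrected, and
axis variance is expressed relative to the sum of positive eigenvalues.

PERMANOVA is the one-factor form computed from squared distances:
$SS_{total} = \sum_{i<j} d_{ij}^2 / n$, within-group sums analogously per
group, $R^2 = SS_{among}/SS_{total}$, and the p-value from free
permutation of sample labels, $(1 + \#\{F^* \ge F\})/(B+1)$. Permutation
is unrestricted by default; the field design would also support
block-restricted permutation by replicate, which can be imposed by
permuting within strata before calling, but the free test is the default
because the package cannot know which stratification is meaningful for a
given user. The implementation is checked against `vegan::adonis2` in the
test suite but does not call it.

Two regressions summarize temporal dynamics:

* **Time decay:** Bray-Curtis distance of all within-treatment pairs
  against their day difference $\Delta d > 0$; the OLS slope is the
  turnover rate (d⁻¹).
* **Divergence:** Bray-Curtis distance of every treatment sample to every
  same-day control sample, against day; the slope measures how fast a
  treatment's community drifts away from the control.

Both are fit per (treatment, compartment) stratum; when the supplied
samples span several compartments the functions insist on an explicit
`compartment` argument rather than silently pooling.

**Uncertainty for distance regressions.** Pairs that share a sample are
correlated, so the textbook OLS standard error on $n(n-1)/2$ pairs is far
too small — in our simulations its nominal 95% interval covered a planted
slope in as little as 8% of runs. The package therefore keeps the OLS
point estimate (the field's standard summary) but derives the slope's
standard error, p-value and confidence bounds from a sample-level
bootstrap: whole samples are resampled with replacement (independently
for the two sides of a divergence fit), pairs are reweighted by the
product of their endpoints' multiplicities, and the weighted regression
is refit (`n_boot = 199` by default). Measured coverage of the planted
slope is ~85–92% — imperfect, because residual slope bias from the
dissimilarity's absolute-value kernel cannot be removed entirely, but an
order of magnitude closer to nominal than the pair-level formula.

The QMP/RMP disagreement report (`scale_trend_disagreement()`) fits each
feature's stage-mean trend on both scales and reports the share of
features whose trend direction flips — the quantity that summarizes how
badly compositional data would misrepresent load dynamics in a given
dataset.

## Differential load

The differential procedure deliberately mirrors a stage-paired design:
abundances are averaged per (treatment, stage) over replicates, the
treatment and control stage-mean vectors (length 8 under the default
design) are compared by a two-sided paired Wilcoxon signed-rank test, and
calls require both `p < 0.05` and fold change above 1.5 (below 1/1.5 for
decreases), with strict inequalities. Raw p-values are used: with eight
pairs the exact two-sided floor is $2/2^8 \approx 0.0078$, so an FDR
correction over hundreds of features would leave no attainable calls —
the fold-change gate takes the role of controlling practical relevance.

Numerical choices:

* Zero differences are dropped before ranking (classical convention);
  ties get average ranks. For $n \le 12$ retained pairs the null
  distribution is enumerated exactly over all $2^n$ sign assignments of
  the observed ranks; beyond that a tie-corrected normal approximation
  with continuity correction is used (it matches
  `wilcox.test(..., exact = FALSE, correct = TRUE)`).
* The fold change is the ratio of grand means of the stage means. Zeros
  are replaced by half the smallest nonzero stage mean in the comparison,
  which keeps the ratio finite and exactly reciprocal under swapping the
  two groups.
* Core-taxon selection (> 0.1% relative abundance in at least one
  sample) is strict at the boundary; a feature at exactly 0.1% is not
  core.

## Co-occurrence networks

Networks are built on core features' absolute abundances: tie-aware
Spearman correlations with two-sided p from the t approximation on
$n - 2$ df; BH-FDR over the family of all testable feature pairs (the
upper triangle, excluding pairs involving constant features); an edge
requires $|\rho| > 0.8$ *and* adjusted $p < 0.05$. Whether FDR runs
before or after the $\rho$ gate does not change the edge set, but it
changes the family size; the full-triangle family is the conservative
reading and the one implemented.

Modules ("ecological clusters") come from Louvain-type greedy modularity
maximization on the unweighted edge set, run under a fixed seed and
relabeled `module1, module2, ...` by descending size. Node roles use
within-module degree z-scores and among-module connectivity,

$$Z_i = \frac{\kappa_i - \bar\kappa_{m(i)}}{\sigma_{\kappa,m(i)}},
\qquad P_i = 1 - \sum_s \left(\frac{k_{is}}{k_i}\right)^2,$$

with module hubs at $Z_i > 2.5$, connectors at $P_i > 0.62$, network hubs
at both. Conventions for degenerate cases are explicit: a module whose
within-degrees have zero variance yields $Z_i = 0$ for its members, and
isolated nodes are peripheral with $Z_i = P_i = 0$.

Average degree ($2E/N$) is computed over the full core node set including
isolated nodes, so that complexity comparisons across treatments or stage
groups (D1–D14, D28–D42, D60–D72, plus pooled) use a fixed denominator.
Robustness is the expected fraction of surviving nodes in the largest
connected component after removing a uniformly random
$\lfloor fN \rfloor$ of the nodes (default $f = 0.5$), estimated by Monte
Carlo with mean and sd reported. This LCC-under-random-removal definition
is a documented stand-in for the robustness statistic of the wider
literature, whose exact formula varies between papers; comparisons should
be made within, not across, definitions.

## SynCom design

ASVs of a module are matched against cultured isolates by pairwise 16S
identity. Alignment is semi-global (free end gaps) with match +2,
mismatch −1, affine gaps (open 2, extend 0.5), and identity is the share
of identical columns among aligned columns excluding terminal gaps — a
deliberate, documented substitute for a local-alignment search: amplicon
and isolate sequences cover comparable regions, and end-gap-free identity
is insensitive to small length differences. The matching rule is strict:
a strain qualifies only above 95% identity, each ASV keeps its single
best strain (ties broken lexicographically by strain ID, which makes
plans order-invariant), each genus contributes one strain (highest
identity), and strains whose source ASV belongs to an excluded family —
Bradyrhizobiaceae by default, to avoid nodulation-driven growth effects —
are removed and reported.

A module qualifies as treatment-enriched when Dunn's post hoc comparison
(after a tie-corrected Kruskal-Wallis across treatments, on the 8
per-stage mean loads per treatment) is significant against the control
after FDR and the stage-mean ratio exceeds 1. `run_qmp_pipeline()` chains
the whole path and selects the qualifying module with the largest ratio.

## The synthetic-data generator

The generator is first-class, tested code: it is the source of ground
truth for every validation in the package. Per sample and ASV,

$$A = L_{g}(d)\; w \; M \; E \; \varepsilon$$

with $L_g$ a per-phylum logistic load curve, $w$ a lognormal ASV weight,
$M$ a lognormal latent factor shared by all members of a module within a
sample, $E$ the planted treatment-by-module multiplier, and $\varepsilon$
feature-level lognormal noise. Sequencing draws `depth` reads per sample
from a multinomial over ASVs (weighted by copies × mass) and spikes
(weighted by copies added); spike totals are sized so that the expected
spike read share equals `spike_fraction` at the median community size,
and are spread over 12 standards at two-fold concentration steps.

Default conditions emulate the field design this pipeline targets: four
treatments (Control, -N, -P, -K), stages at days 1, 4, 7, 14, 28, 42, 60,
72 post germination, carrying capacities summing to ~2.6 × 10¹⁰ copies
g⁻¹ with early loads of ~5 × 10⁹ (the observed rhizosphere scale), a
late-blooming Bacteroidetes group (logistic midpoint day 55), three
planted modules of 25 ASVs among 300, and a 3× enrichment of module 2
under -N. Six replicates per treatment-stage keep desk-scale runtimes;
the corresponding field design had nine samples per treatment-stage.

Noise levels were fixed analytically, from two constraints, before any
recovery test was run: the module factor must dominate feature noise
strongly enough that within-module Spearman correlations exceed the 0.8
edge threshold with margin (σ_mod = 0.5, σ_disp = 0.15 gives ~0.9), and
per-stage means over six replicates must be stable enough that a planted
3× effect yields a consistent Wilcoxon sign pattern. The combined
replicate CV for module members is ~55%, a realistic field-scale
variability; the feature-specific component alone is smaller than typical
because the shared module factor carries most of the variance.

The drift generators used for turnover validation are separate and
minimal: composition shifts linearly between two feature blocks so that
the expected Bray-Curtis distance is exactly `rate × Δday`
(`simulate_drift_profiles`), and a divergence variant perturbs the
(always positive) per-feature shift by mean-one lognormal noise so the
expected distance to control stays exactly linear in day
(`simulate_divergence_profiles`). Per-feature abundance noise is kept
mild in the drift generator because the absolute value inside Bray-Curtis
otherwise attenuates the slope — a measured, documented effect that also
cautions against interpreting small empirical turnover slopes without a
noise model.

What the generator does *not* emulate: phylogenetic signal in sequences
(ASV references are i.i.d. uniform, so matching tests identity handling
only), chimeras and PCR bias, overdispersed sequencing beyond the
multinomial, spatial/plot structure, and compositional interactions
between taxa. Passing recovery tests therefore demonstrates correctness
of the estimators and decision rules under the stated generative model,
not robustness to every artifact of real amplicon data.

## Problem sizes and determinism

The test suite and acceptance script run at deliberately modest sizes:
192–384 samples, 300 ASVs, depths of 10⁴–5 × 10⁴ reads, 500 (PERMANOVA, 199 permutations each) and 2000 (Kruskal-Wallis)
null simulations, 50 brute-force role graphs, and an
exhaustive 252-subset robustness enumeration. Every stochastic step takes
an explicit seed (`withr::with_seed`, so the caller's RNG state is never
clobbered), and the acceptance script derives all sub-seeds from its
`--seed` argument.

## Known limitations

* The spike calibration assumes spikes and community amplify with equal
  efficiency; systematic primer bias between spike and template is
  invisible to the pooled ratio (the per-spike CV diagnostic catches only
  dosage-dependent discordance).
* Bootstrap confidence intervals for turnover slopes are approximate
  (~85–92% measured coverage at nominal 95%).
* Louvain modularity has a resolution limit; very small planted modules
  may merge. Module labels are stable only under a fixed seed.
* Identity-based isolate matching cannot separate strains whose 16S
  differ by less than the mutation scale of interest; the >95% rule is a
  genus-scale heuristic, as in common practice.
* The robustness statistic is one of several definitions in use;
  cross-study comparisons of its absolute value are not meaningful.
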