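---
title: "Methods: paired RNA/DNA dormancy analysis and tidal-creek oxygen metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired RNA/DNA dormancy analysis and tidal-creek oxygen metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltmarsh)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices, and the limits of what its tests can
show. No empirical number is stated here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The activity ratio and dormancy classification

The observable is a pair of count matrices over the same taxa and
biological samples: 16S rRNA gene reads (DNA, the *total* community) and
16S rRNA reads (RNA, a proxy for the *potentially active* community —
ribosome content indicates capacity for protein synthesis, not
necessarily division). For taxon $i$ in a sample the activity ratio is

$$ r_i = \frac{\mathrm{RNA}_i}{\mathrm{DNA}_i + 1}, $$

and a detected taxon is dormant when $r_i \le \theta$ with $\theta = 1$
by default. Choices embedded here, and why:

* **The +1 sits on the gene denominator only.** A sequence present in a
  sample's RNA must come from an organism present in the total community;
  a zero gene count is treated as a sequencing miss, and the +1 both
  encodes that assumption and keeps RNA-only taxa finite (an RNA-only
  taxon is active, which is the intended reading). The *order-level
  display* ratio (`order_activity()`) instead uses
  $(\sum \mathrm{RNA}+1)/(\sum \mathrm{DNA}+1)$ — a deliberate,
  visualization-only deviation so $\log_{10}$ stays finite for orders
  absent from one molecule.
* **Boundary is dormant.** $r = \theta$ exactly classifies dormant;
  activity requires strict excess.
* **Depth normalization before the ratio.** Each library (column, per
  molecule) is scaled to a common size (the mean library size) before the
  +1; otherwise a deeper RNA than DNA library inflates every ratio
  mechanically. A raw-count mode (`normalize = FALSE`) exists for
  exact-reproduction attempts against externally computed tables. Whether
  the original analyses used raw, relative or rarefied counts is not
  stated in our sources; both modes are provided and the tests exercise
  both.
* **Richness-based proportion.** The dormant proportion is the fraction
  of *detected* taxa classified dormant — every detected taxon counts
  once, undetected taxa (zero in both molecules) are excluded from
  numerator and denominator. An abundance-weighted variant
  (`weighted = TRUE`) is provided but is not the default, since "per cent
  of dormant taxa" is a statement about taxa, not reads.
* **Threshold sweep.** `threshold_sweep()` evaluates the proportion over
  $\theta = 1..50$; curves are non-decreasing in $\theta$ by construction
  and the tests assert it. Because ratios scale with relative library
  depth, sweep positions are only meaningful on normalized tables.

Known limitation: per-taxon ribosome copy number varies across lineages,
so a single global threshold misclassifies taxa whose resting ribosome
content is unusually high or low. No correction is attempted; the sweep
is the sensitivity analysis for this.

## Diversity

Shannon diversity is $H = -\sum p_i \log_2 p_i$ (bits; the base is an
argument). Rarefaction subsamples each library to a fixed depth without
replacement (multivariate hypergeometric), dropping — never up-sampling —
libraries below the depth. `mean_rarefied_shannon()` averages $H$ over
independent restarts at a fixed depth; the optional depth-step curve
variant was considered and rejected as out of scope, fixed-depth restarts
being the interpretation we adopt of restart-based rarefaction. The
abundant-active census (`abundant_active_taxa()`) takes, per comparison
group, taxa with at least `min_count` (default 100) RNA reads summed
within the group whose mean ratio exceeds $\theta$; summing within the
group (rather than per sample or across the whole dataset) is our
reading of an ambiguous filter, and the alternative scopes are one
argument away.

## Beta diversity and inference

* **Bray-Curtis** on relative abundances by default
  ($d = \sum|x_i-y_i| / \sum(x_i+y_i)$, bounded [0,1]).
* **Weighted UniFrac** accumulates per-branch subtree mass differences
  weighted by branch length, in one postorder pass; the normalized
  variant (default) divides by the abundance-weighted root-to-tip depth
  sum of the two samples so distances lie in [0,1]. Tests check both
  variants against an exhaustive per-branch brute-force oracle on random
  coalescent trees and against an independent implementation.
* **PCoA** double-centres the squared distances and eigendecomposes;
  coordinates come from positive eigenvalues, negative eigenvalues are
  reported, and axis variance fractions are relative to the positive
  total.
* **PERMANOVA** is single-factor: $F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(N-a)}$
  with $SS$ from squared distances, a permutation null under full random
  relabelling, and the add-one p-value $p = (\#\{F^\ast \ge F\}+1)/(B+1)$,
  never exactly zero. Factors (treatment, habitat, month) are tested in
  separate single-factor runs; permutations are unrestricted (no strata).
  Consequence worth knowing: when a *different* strong factor structures
  the distances (habitat, in these data), unrestricted permutation makes
  the test of an orthogonal factor conservative — rejection rates fall
  below the nominal level rather than above it. The test suite therefore
  measures type-I calibration within a single habitat, where sample
  labels are exchangeable under the null, and measures power on the full
  design.
* **Kruskal-Wallis** per taxon (tie-corrected, chi-square reference;
  constant rows return $H=0, p=1$), with Bonferroni and
  Benjamini-Hochberg adjustment via the standard step-up.

## The community simulator

`simulate_paired_community()` generates the statistical structure the
dormancy analysis assumes, with truth labels:

* **Rank abundance**: lognormal ($\sigma_{\log} = 1$), shared by both
  molecules.
* **Per-sample overdispersion**: one Dirichlet draw per sample
  (concentration 1000) perturbs the community, and *both* molecules are
  multinomial on that same perturbed community — the RNA additionally
  reweighted by activity. Sharing the draw keeps the per-taxon ratio free
  of spurious between-molecule noise; real paired extractions from one
  homogenized core motivate it.
* **Activity multipliers**: dormant taxa draw from a truncated lognormal
  on (0, 0.5], active taxa from 1.4 plus a Gamma tail. Because a
  sequencer returns a fixed number of RNA reads, only *relative* activity
  is observable; the generator therefore calibrates the
  abundance-weighted mean multiplier to 1, which makes a taxon's expected
  ratio equal its multiplier and the $\theta=1$ classifier consistent
  with the truth labels. Two consequences are worth stating. First, the
  fewer taxa are active, the higher their apparent ratios — the
  high-ratio bloom taxa in enriched samples are a structural consequence
  of fixed sequencing depth, not an extra assumption. Second, a *fully*
  active community calibrates to ratios near 1 and the classifier's
  false-positive rate is accordingly large; the tests assert that
  boundary clustering rather than pretending the classifier is clean in
  a regime it cannot distinguish.
* **Enrichment as activity reassignment**: under `treatment =
  "enriched"`, all but `bloom_fraction` (default 0.1) of the active taxa
  are reassigned to dormancy and the remaining bloom absorbs the
  community's activity (`bloom_boost`, then recalibration). The DNA table
  is treatment-invariant *by construction* — the central observation
  (active community shifts, total community does not) is a generator
  property the pipeline must recover, not a number copied in. Defaults
  (45% base dormancy; enriched effective dormancy ≈ 95%) are scenario
  constants chosen for realism.
* `simulate_experiment()` adds the factorial design: a per-habitat
  lognormal tilt of base abundances (habitat structures the *total*
  community), monthly lognormal jitter of reference-arm active
  multipliers (seasonality of the *active* community, suppressed in the
  enriched arm, which is spatiotemporally homogenized), order-level
  taxonomy with bloom taxa placed in the bloom-forming orders
  (Desulfobacterales, Oscillatoriales), and a random coalescent tree for
  UniFrac.

What the generator does **not** emulate: chimeras, primer/copy-number
bias, relic DNA, spatial autocorrelation within a transect, and
compositional effects of true abundance change under enrichment (the
enriched arm changes activity only). Passing recovery tests therefore
shows the *pipeline* is consistent, not that the biological threshold
$\theta = 1$ is correct for field data.

Recovery accuracy depends on depth: at $5\times10^4$ reads per library
the dormant proportion is recovered within ±0.05 of truth (tested over
20 seeds at $p \in \{0.45, 0.90\}$); at $10^4$ reads rare active taxa
lose reads to sampling, their ratios shrink toward 0 through the +1, and
estimated dormancy biases a few points high. The analysis scripts use
$10^4$ for speed and show exactly that bias; the same effect operates on
real libraries, which is one reason the threshold sweep matters.

## The creek oxygen model

Forward (simulator) and inverse (estimator) share one mass balance for a
well-mixed control volume per unit creek length:

$$ \frac{d(VC)}{dt} = \mathrm{NEM} + Q_{adv}\,C_b + F_{gas}. $$

* **Geometry**: trapezoidal cross-section; wetted volume
  $V(h) = w_0 h + s h^2$ and width $w(h) = w_0 + 2sh$, both
  non-decreasing in depth (defaults $w_0 = 4$ m, $s = 2$).
* **Water balance**: $Q_{adv} = dV/dt$ by centred finite differences
  (one-sided at the ends, step = the series step). Freshwater, porewater
  and platform-drainage fluxes are ~1% each of the tidal flux and are
  excluded.
* **Boundary concentration** $C_b$ is the measured in-creek concentration
  — a single sonde cannot distinguish inflowing from resident water, so
  the control volume is treated as well mixed and the advective term
  reduces to $C\,dV/dt$. The forward simulator uses the same convention
  (flood water is returning ebb water), so forward-inverse consistency is
  exact up to discretization; an upstream/downstream two-sensor mode is
  left as a stub. With this convention the estimator algebraically
  reduces to $\mathrm{NEM} = V\,dC/dt - F_{gas}$, but it is computed as
  the full three-term balance so the discrete budget closes identically
  (tested to $10^{-12}$).
* **Solubility**: the combined-fit solubility polynomial in scaled
  temperature (checked against its published value at T = 10 °C, S = 35
  to 5 decimal places), converted to mmol m⁻³ with the one-atmosphere
  EOS-80 density.
* **Gas exchange**: $F_{gas} = k\,(C_{sat}-C)\,w(h)$ with
  $k = k_{600}\,(Sc/600)^{-1/2}$. Registered $k_{600}$ parameterizations:
  additive wind + current (default; quadratic wind term 0.266 cm h⁻¹ per
  (m s⁻¹)², surface-renewal current term $16.4\sqrt{v/h}$ cm h⁻¹),
  current-only, and wind-only. The exact coefficients are configuration
  — the contract every registered model must satisfy (and the tests
  check) is monotonicity in wind at fixed current and in current at
  fixed wind; single-driver variants are smaller in magnitude than the
  combined model, which is checked directionally only.
* **Windows**: high tides are local depth maxima separated by ≥ 6 h
  (semidiurnal); NEM is summarised as mean ± s.d. over 60 minutes centred
  on each maximum, windows truncated by the series boundary are dropped
  with a warning, and windows whose peak depth exceeds the platform
  flooding elevation are flagged. `apply_bias_correction()` subtracts a
  constant (default 0.35 mmol O₂ m⁻¹ min⁻¹) from flagged windows only —
  the hook for peak-tide drainage bias. Bubble injection is not
  modelled.

The creek simulator integrates the same balance forward (Euler, 1-minute
internal step) under a spring-neap-modulated sinusoidal tide (period
12.4 h; a 6-day run yields 12 high tides, the spring-neap phase chosen
so only the biggest tides flood the platform), a daylight half-sine
gross production (peak 1.2 mmol O₂ m⁻¹ min⁻¹) and constant respiration
(0.5), with Gaussian observation noise applied to the emitted saturation
series only. Noise-free, the inverse recovers the prescribed NEM with
RMSE well under 5% of its range across gas-exchange strengths 0-3x
default, and halving the sensor step changes the recovery by under 1%.
With realistic noise the 10-minute derivative is noise-dominated —
which is precisely why the analysis aggregates over the hour of high
tide, where the window means recover the truth closely (the `analysis/`
drivers print both numbers).

## Problem sizes and reproducibility

Test and acceptance runs use deliberately desk-scale conditions: 50-200
taxa, 10-72 samples, library depths $10^3$-$5\times10^4$, 999-10,000
permutations, 50 replicate experiments for PERMANOVA power and 600
single-habitat replicates for its type-I rate (the calibration band is
tight, so the rate is estimated with more replicates than the power
check needs). Every stochastic path takes an explicit integer seed and
is bit-reproducible under it; the acceptance script derives all its
sub-seeds from one `--seed` argument.
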