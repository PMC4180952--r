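---
title: "Methods: simulating and analyzing cell-cycle transcription under arrest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing cell-cycle transcription under arrest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscarrest)
```

# Scope

`oscarrest` studies a single question end to end: when the budding-yeast cell
cycle is arrested — by persistent mitotic CDK activity, by cyclin loss, or by
a checkpoint — which periodically transcribed genes keep oscillating, and how
do the rest halt? The package simulates synchronized-population expression
time courses with known ground truth, calls periodic genes by a conservative
multi-algorithm consensus, classifies per-gene arrest behaviors, aligns
conditions at the 50%-budded anchor, and tests transcription-factor regulons
for overrepresentation in behavior clusters.

# The generative model

## Single cells and populations

A gene's single-cell expression over the cycle is a circular pulse

$$f(\theta) = b + a\,e^{\kappa(\cos 2\pi(\theta - \phi) - 1)},$$

with baseline $b \ge 0$ (expression units), amplitude $a \ge 0$, peak phase
$\phi \in [0,1)$ (cycle fraction) and concentration $\kappa \ge 0$
(dimensionless sharpness; $\kappa = 0$ is flat, $\kappa \approx 5$ is a
pulse covering roughly a quarter of the cycle). $a = 0$ defines a
constitutive gene.

An elutriation-synchronized population starts with phase
$\Theta_0 \sim$ wrapped normal$(\theta_0, \sigma_0)$ and progresses at
$1/p$ cycles per minute ($p$ = period, minutes). Synchrony decays: the phase
sd at time $t$ is

$$\sigma(t) = \sqrt{\sigma_0^2 + (c\,t/p)^2},$$

with $c$ the dispersion gain per elapsed cycle. The bulk signal is
$E[f(\Theta_t)]$, evaluated by a deterministic midpoint quadrature over
$[0,1)$ (256 nodes by default; the wrapped-normal density sums 11 integer
wraps, accurate for $\sigma \le 1$). Because the phase distribution spreads,
bulk amplitude damps cycle by cycle while single cells keep oscillating —
the defining artifact of synchronized-population experiments. With
$\sigma_0 = c = 0$ the code takes an exact branch and the bulk trace equals
the single-cell profile.

## Defaults and why

* `period = 100` min: a realistic cycle length for elutriated daughter cells
  in these experimental designs (sampled 20 min / 300–360 min, or 18 min /
  360 min, giving 3–3.6 observable cycles).
* `initial_sd = 0.05`, `dispersion_rate = 0.08` per cycle: chosen once,
  qualitatively, so that simulated budding curves rise sharply in cycle one
  and bulk oscillations remain visible but clearly damped through the third
  cycle, matching published budding-index and heat-map behavior for this
  class of experiment. The source study does not quantify synchrony loss, so
  these two numbers are the package's stated world; they were fixed before
  the acceptance measurements and not revisited.
* `bud_phase = 0.25`: bud emergence at late G1/S.
* `noise_cv = 0.1`: multiplicative lognormal measurement noise with mean 1
  (`exp(N(-cv²/2, cv))`), the standard positive-data, constant-CV model for
  array intensities.
* Regulon panel: 20% SBF, 20% MBF, 20% SFF, 10% Swi5/Ace2, 30% constitutive;
  peak phases 0.15 / 0.20 / 0.55 / 0.80 with ±0.05 jitter; baselines and
  amplitudes lognormal (periodic genes swing several-fold). The proportions
  are a free modeling choice recorded in the config.

## Arrest programs

Each regulon carries one program per condition, anchored to the gene's own
first peak (time $t_{peak} = ((\phi - \theta_0) \bmod 1)\,p$), not to a
global clock:

| program | trajectory |
|---|---|
| `continue` | population-mean profile unchanged |
| `repress_after_first_peak` | profile until $t_1 = t_{peak} + p/4$, then exponential decay to $b$ with half-life $p/4$ |
| `persistent_high` | profile until $t_{peak}$, then held at the single-cell plateau $b + a$ |
| `off` | $b$ throughout |
| `one_cycle_then_repress` | as repression but starting one full period later |

The condition map encodes the observed biology: under persistent mitotic CDK
("CDK on"), SBF targets are repressed after one pulse, SFF targets plateau
(positive feedback with mitotic CDK), Swi5/Ace2 targets are never induced
(nuclear exclusion), and the MBF branch continues. The replication checkpoint
holds MBF targets persistently high; the spindle checkpoint allows MBF one
extra cycle before repression. Removing Rad53 signaling during the
replication checkpoint restores SBF/MBF cycling. "CDK off" leaves the whole
network free-running.

## Budding curves

Within the first cycle the budded fraction is
$\Phi((\theta_0 + t/p - \theta_{bud})/\sigma(t))$. Arrested cells keep their
bud, so arrest curves are held at their running maximum; cycling (WT)
populations lose the bud at division, so the WT curve is the wrapped-normal
probability of phase mod 1 falling in $[\theta_{bud}, 1)$. The 50% crossing
(`t50_budded`, linear interpolation between bracketing samples) is the
cross-condition alignment anchor.

# Periodicity calling

Three deliberately different statistics score each gene:

1. **Lomb–Scargle maximum power** over a period grid (default 40–240 min in
   10-min steps), computed from the actual sampling times; missing points
   are simply absent, never imputed. Constant series have zero power.
2. **Maximum lagged autocorrelation**: Pearson correlation of the series
   with itself at lags matching the period grid. Lags are capped at half the
   series length — longer lags leave too few overlapping points and their
   noisy correlations would inflate the permutation null.
3. **Maximum rank-template concordance**: Kendall's $\tau_b$ against a bank
   of cosine templates over the period grid × 16 phases, each paired with an
   amplitude-damped variant (half-life 1.5 periods) because a
   desynchronizing population's genuine oscillation shrinks late in the
   course. Rank-based, hence invariant to monotone distortions of scale.
   Inside the permutation test the statistic adds a `1e-9`-weighted
   continuous key (maximum Pearson correlation against the same bank) so
   that discrete-$\tau$ ties between observed and permuted series cannot
   make the p-value conservative; the key never reorders distinct $\tau$
   values.

Calibration is by seeded time-order permutation with the add-one convention
$p = (1 + \#[\text{perm} \ge \text{obs}])/(n_{perm}+1)$ (default
$n_{perm} = 999$; $p \ge 1/(n_{perm}+1)$ by construction; per-gene seeds are
derived deterministically from the global seed and gene index, and one
permutation stream is shared by the three statistics). Each algorithm's
p-values get Benjamini–Hochberg adjustment across genes, and the
high-confidence periodic set is the **intersection** of the three
significant sets at per-algorithm FDR $\alpha = 0.05$ — conservative by
design: per-branch FDR is the controllable knob, and dropping an algorithm
can only grow the set.

`estimate_period_phase` takes the grid argmax of Lomb–Scargle power (ties
broken toward the shorter period), refines the period by a continuous
1-D maximization between the bracketing grid points (an on-grid noiseless
period is recovered essentially exactly, which a three-point parabola would
not achieve), and reports the first peak time in $[0, p)$ from a
least-squares cosine fit. A boundary argmax is returned unrefined and
flagged.

# Behavior classification

Features are computed on the post-first-cycle window $t > 1.25\,p_{WT}$ (the
margin skips the shared first pulse that every condition exhibits):

* `post_window_q`: the median of the three algorithms' raw permutation
  p-values on the windowed series — the gene is "still oscillating" when at
  least two of the three scorers reject at $\alpha$ individually. This is a
  per-gene phenotype call, so per-comparison calibration is the appropriate
  control; applying across-gene BH here lets the weakest branch
  (autocorrelation on a ~12-point window) collapse the step-up and was
  measured to halve sensitivity. Across-gene FDR control belongs to the
  discovery module and stays there. The windowed period grid is targeted at
  $[0.6, 1.6] \times p_{WT}$: the scientific question is whether the gene
  still oscillates at roughly the WT period.
* `first_cycle_peak_ratio`: first-cycle maximum over the series floor — did
  the gene pulse at all?
* `late_mean_ratio`: mean of the last quarter over the first-cycle maximum —
  where did it settle?
* `late_slope_sign`: sign of the late linear trend, 0 when the relative
  change over the late window is below `slope_tol`.

The label rule, applied in order: **oscillating** if `post_window_q ≤ alpha`;
else **low_flat** if there was never a first-cycle pulse
(`first_cycle_peak_ratio < 2`); else **persistent_high** if
`late_mean_ratio ≥ 0.6` with non-negative late slope; else **repressed** if
`late_mean_ratio ≤ 0.3`; else **damped**. The no-pulse check precedes the
persistence check deliberately: a flat-at-baseline gene has
`late_mean_ratio ≈ 1` and would otherwise masquerade as persistently high.
All thresholds (0.05, 2, 0.6, 0.3, `slope_tol = 0.2`, window start 1.25,
late fraction 0.25) are config-exposed defaults validated by simulation —
the reference analysis classifies qualitatively from heat maps, so there are
no published numbers to inherit. Measured on the default 500-gene CDK-on
scenario, 94% of genes recover their generative program's label and every
regulon's modal label matches its program.

Replicate concordance is the squared Pearson correlation of all
(gene, time) pairs on `log2(x + 1)` (variance stabilization; the source
study does not state its scale). Period comparisons report medians and the
median absolute per-gene difference over shared genes — robust to occasional
estimator boundary failures.

# Enrichment

One-sided hypergeometric tail $P(X \ge k)$ per (TF, cluster) pair, computed
as a log-sum-exp over log densities; the universe is the set of genes in the
expression matrix (the conditioning implicit in clustering measured genes),
never the genome. Annotation targets outside the universe are dropped with a
logged count. BH is applied jointly across all pairs. Annotations come from
a user GMT file; the pipeline also writes the generator's own regulon
membership as a clearly-labeled synthetic GMT for self-contained demos.

# Determinism and numerics

* Every stochastic step is seeded; a config + seed reproduces all result
  tables byte for byte (the provenance log carries the only timestamp).
* Expression matrices are written with 10 significant digits (round trips
  are faithful to <1e-9 relative); derived report tables use 6.
* Quadrature: 256 midpoint nodes by default, 11 wrapped-normal wraps;
  exact branches for $\sigma = 0$, $a = 0$, $\kappa = 0$.
* Degenerate series (constant, zero-variance segments, all-tied ranks)
  score 0 rather than erroring; permutation p-values for constant series
  are exactly 1.
* Ties in the power argmax resolve toward the shorter period; equal peak
  times order lexicographically by gene id; genes without estimates trail
  the heat-map ordering in a sorted "uncalled" block.

# What a green test does and does not establish

The generator emulates the statistical structure the analysis assumes:
smooth pulse profiles, Gaussian phase spread growing with time,
condition-independent noise, arrest programs that are exact members of the
classifier's label vocabulary. Real microarray time courses add probe-level
artifacts, regulon heterogeneity, partial arrests, and biological replicate
variation that this world does not contain. Green acceptance tests therefore
establish that the pipeline's statistics are calibrated (uniform null
p-values, FDR-controlled consensus), that its estimators recover known
truth at realistic noise (periods to half a sampling interval, behavior
labels at ~90%), and that its set arithmetic reproduces the published
fractions — not that the pipeline would reproduce the genome-scale gene
counts of the original microarray experiments, which depend on the deposited
data and unpublished algorithm settings.

# Known limitations

* Bulk signal only; no single-cell trajectories and no network ODEs — arrest
  programs are phenomenological.
* The wrapped-normal quadrature degrades for $\sigma(t) > 1$ (far beyond any
  plausible time course).
* Autocorrelation has intrinsically low power on short post-arrest windows;
  the classifier compensates by majority voting, the discovery module does
  not (by design).
* The `persistent_high` plateau joins the mean profile discontinuously at
  the first peak when desynchronization has already eroded the bulk peak;
  the step is below noise scale for realistic parameters.
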