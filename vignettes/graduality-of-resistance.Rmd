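---
title: "Modelling the graduality of acquired drug resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the graduality of acquired drug resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradres)
```

## The question

When a tumor cell population acquires resistance to a targeted inhibitor,
did rare fully resistant cells pre-exist and simply expand, did tolerant
cells convert to resistance in a single heritable hit (a mutation or an
epigenetic switch), or did fitness under drug improve gradually through
many small heritable steps? The three hypotheses leave different
fingerprints in cheap, classical assays:

* **clonogenic colony sizes** — a single-hit transition predicts a bimodal
  size distribution (small tolerant colonies, large resistant ones) whose
  resistant mode grows more frequent with longer drug exposure; gradual
  adaptation predicts a homogeneous shift of the whole distribution;
* **limiting dilution** — under single-hit kinetics the fraction of wells
  with no robust colony decays exponentially in the number of seeded
  cells, giving the frequency of resistance-initiating cells (RICs);
* **clone tracing** — if resistant clones pre-exist, the same barcodes
  expand in independent replicate cultures of the same drug.

`gradres` implements the quantitative machinery for all three readouts,
plus the synthetic data needed to exercise them offline.

## The lattice colony-growth model

Cells occupy single sites of a 2D square lattice (the surface of a culture
dish). Each cell carries a step index $k \in \{0, \dots, n\}$ and divides
per update round with probability

$$p(k) = p_{\text{init}} + k\,\frac{p_{\max} - p_{\text{init}}}{n},$$

so the $n$ (epi)mutational steps are fractional increments of the single
tolerant-to-resistant transition: $p(0) = p_{\text{init}}$ and
$p(n) = p_{\max}$ exactly. At each division, each daughter independently
gains one step with probability $\mu$ (per daughter, per division; both
post-division cells count as daughters — the main ambiguity in this
convention is documented here once and used consistently). Optional
extensions: a per-update death probability, bidirectional steps
($\pm 1$ with equal odds, floored at 0 and capped at $n$), and per-step
fitness increments drawn from a truncated normal
($\text{sd} = \texttt{effect\_sd} \times$ mean increment) instead of fixed
increments.

Space limits growth: a cell can divide only if an empty site lies in its
Moore neighbourhood, or one cell away — in which case the intervening cell
is pushed one site outward into an empty neighbour of its own and the
daughter takes its place. Daughter site and displacement direction are
drawn uniformly among the admissible options. Updates are asynchronous:
every living cell acts once per round, in a freshly randomized order;
daughters born during a round first act in the next round. The Moore
(8-neighbour) neighbourhood is the default because diagonal placements are
part of the intended geometry; a von Neumann variant is available.

Two structural invariants are asserted on every simulation: the colony
bounding box grows by at most 4 sites per round (daughter plus
displacement extend the reach by at most 2 sites on each side), and
populations never exceed $2^t$ after $t$ rounds without death. Lattices
are sized automatically from the bounding-box bound ($4t + 5$ per side) so
a colony can never touch the boundary; forcing a smaller lattice raises an
error instead of silently distorting growth.

`updates_per_day` defaults to 2, so $p = 1$ corresponds to a minimum cell
cycle of about 12 h. The clonogenic phase defaults to 7 days (14 rounds),
matching the one-week colony readout of the graduality assay; the generic
10-day clonogenic protocol corresponds to 20 rounds.

### The two-phase assay

The experiment the model reproduces has two phases: weeks of drug exposure
in bulk culture (pre-incubation), then re-plating at clonogenic density
and one week of colony growth. `simulate_preincubation()` models the first
phase well-mixed — the culture is dense and repeatedly re-plated, so
colony-level spatial competition is not the relevant constraint — tracking
only the population distribution over step indices, with random
down-sampling to `n_cells` whenever the population exceeds a ceiling
(mimicking re-plating). `run_colony_cohort()` then draws each colony's
founder step from that distribution and grows it spatially.

Because fully resistant colonies vary widely in size, the maximal division
probability is drawn *per colony* by resampling observed resistant colony
sizes and inverting them through the calibration map (below); the initial
probability is calibrated from the tolerant median only, assuming little
variability among tolerant cells. The pre-incubation phase, which is
shared by all colonies, uses the reference $p_{\max}$ obtained from the
resistant median; the step index, i.e. the *fraction* of the transition
achieved, is what carries over into each colony's own scale. The
interaction between a shared bulk phase and per-colony growth ceilings is
genuinely underdetermined by the assays; this is the minimal consistent
interpretation and is fixed here once.

## Calibration

`build_rate_size_map()` simulates mutation-free colonies across a grid of
division probabilities and records mean final sizes, smoothed by isotonic
regression (`stats::isoreg`) so the map is monotone and invertible by
linear interpolation. Monte-Carlo noise is the only reason raw means could
dip; isotonic smoothing removes it without a parametric assumption.
Inversion clamps targets above the map's maximum to the largest grid
probability with a warning. Tolerant/resistant reference samples then give
`p_init`, the reference `p_max`, and the per-colony `p_max` sampler
(empirical resampling, no parametric fit).

A single observed colony size is an imprecise rate estimate: at the
7-day design, 87% of single-size inversions at a true rate of 0.6 land
within ±0.1; at the 10-day design, ~95%. Cohort-level calibration uses
medians and is much tighter (±0.05 on `p_init` in the recovery tests).

## Model selection on the (μ, n) grid

For each candidate (mutation probability, step count) the package
simulates the full two-phase assay and compares simulated to observed
colony sizes with the Kullback–Leibler divergence

$$D(P_{\text{obs}} \,\|\, Q_{\text{sim}}) = \sum_i P_i \ln \frac{P_i}{Q_i}$$

on shared log2-spaced bins (colony sizes span orders of magnitude), with a
Laplace pseudocount of 1 per bin so divergences stay finite. The direction
penalizes models that assign little probability where data actually fall.
Multi-timepoint fits average the divergence across timepoints without
weighting. `best_fit_region()` reports all grid cells within a relative
tolerance (default 10%) of the minimum.

At the scale used in the tests (2,000 simulated colonies per grid cell,
grids of 4 mutation probabilities × 6 step counts, 20 replicate
recoveries), a cohort generated at $n = 30$, $\mu = 0.05$ is recovered as
the grid argmin, and the single-step model $n = 1$ fits worst at every
mutation probability by a wide margin. The mechanism is worth spelling
out: under $n = 1$, any cell that jumps during pre-incubation is fully
resistant and its lineage takes over the well-mixed culture, so the
simulated size distribution becomes strongly bimodal — unlike the
homogeneous shift produced by many small steps.

## The mixture-null KS test

The single-hit hypothesis implies that an intermediate-timepoint size
sample is a mixture of the tolerant and fully resistant reference
distributions. `ks_mixture_test()` fits the mixing fraction by minimizing
the Kolmogorov–Smirnov distance between the observed sample and
$\alpha F_{\text{tol}} + (1-\alpha) F_{\text{res}}$ over an $\alpha$ grid
(step 0.01), then computes a parametric-bootstrap p-value: bootstrap
samples of the observed size are drawn from the *fitted* mixture and the
KS distance re-minimized for each, because the null is composite. The
statistic is rank-based, so any common monotone rescaling of all three
samples leaves the result unchanged. Measured over 1,000 null replicates
the empirical type-I rate at nominal 0.05 is ≈0.05–0.06, and power
against a unimodal sample midway (log scale) between the reference modes
is essentially 1 at 200 colonies.

## Limiting dilution

Under single-hit kinetics, a well seeded with $d$ cells is negative with
probability $(1 - f)^d$, so $\ln(\text{fraction negative})$ is linear in
$d$ through the origin with slope $\ln(1 - f)$. The fit is ordinary least
squares (zero intercept by default; a free-intercept option is reported
when the two disagree by more than 10%), dose levels with zero negative
wells are dropped with a warning (log undefined; a +0.5 continuity option
exists), and the frequency estimate is

$$\text{cells per RIC} = \frac{1}{1 - e^{\text{slope}}}, \qquad
\text{error} = \frac{\text{se}_{\text{slope}}\, e^{\text{slope}}}
{(1 - e^{\text{slope}})^2}.$$

One numerical choice matters for error calibration: the variance of
$\ln \hat p$ grows steeply with dose ($\approx (1-p)/(pn)$) while the
least-squares weights concentrate on high doses, so the conventional
residual-based slope error understates the slope's sampling variability
by about a factor of 2 at this design. The default standard error
therefore propagates the per-level binomial variance through the
least-squares weights; with it, the delta-method error matches the
empirical SD of the estimates (ratio ≈ 1.0–1.2 at the 400-cell top
density design). The residual-based error remains available as
`se_method = "residual"`.

## Dose–response

Viability normalization subtracts mean empty-well luminescence and scales
by the DMSO mean; the four-parameter curve
$y = b + (100 - b)/(1 + (x/\mathrm{IC}_{50})^k)$ is fitted by bounded
Levenberg–Marquardt least squares on linear concentration, exactly in the
form the assay reports. Initialization is deterministic
($b_0 = $ smallest observed viability, $\mathrm{IC}_{50,0} = $ the dose
nearest half-way between 100 and $b_0$, $k_0 = 1$) with bounds
$b \in [0, 100]$, $k \in (0, 10]$, $\mathrm{IC}_{50} \in (0, 10^4 \times$
max dose$]$, so the fit is a pure function of the data. Flat plates leave
IC50 unidentifiable; the fit then reports `converged = FALSE` or an
at-bound flag rather than failing silently. Noiseless plates are
recovered to better than $10^{-6}$ relative error; at 10% multiplicative
noise the mean IC50 bias stays below 5% over 200 plates.

## Barcode clone tracing

Frequencies are computed per sample before any filtering. The enrichment
threshold is the largest entry of the element-wise mean of the baseline
frequency vectors — the most abundant clone before selection — and
enrichment is strict (`frequency > threshold`). Shannon diversity
$H = -\sum f_i \ln f_i$ is reported in nats (the base is a documented
convention, not a data property). Replicate structure is summarized by
pairwise Spearman correlation over the union of enriched barcodes, and by
agglomerative clustering (complete linkage, Euclidean distance on log10
pseudo-frequencies, pseudocount 0.5 reads) of barcodes and samples.

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical structure each analysis relies
on: lognormal (or mixture-of-lognormal) colony sizes rounded to whole
cells; binomial negative-well counts under single-hit kinetics at the
assay's plate design (top density 400 cells/well, five two-fold
dilutions, 10 wells per level); barcode populations in which a fixed
per-condition clone set expands with per-replicate lognormal growth
factors before multinomial sequencing at fixed depth; luminescence with
multiplicative normal noise over a sigmoid plus plate background. The
defaults are the study conditions: quadruplicate cultures with two
baseline aliquots, RIC frequency 1/500 (inside the observed 1:338–1:660
band), a 7-day clonogenic phase after up to 3 weeks of exposure.

Three defaults deserve justification. The lognormal family for colony
sizes is a modelling choice — the empirical distribution family is not
reported — chosen because colony sizes are positive, right-skewed and
span orders of magnitude. The baseline barcode abundance spread
(`baseline_sdlog = 0.4`) reflects a clone population expanded from a
bottleneck for a fixed period: spreads much wider than this are
inconsistent with the design property that a ~20-fold expansion lifts a
typical clone above the most abundant baseline clone, which is what makes
the baseline-max threshold rule a sensible detector in the first place.
The dose–response truth includes a `scale` parameter (luminescence at
100% viability) because raw plate signal needs one; it cancels exactly in
normalization.

What the generators deliberately omit: sequencing error and barcode
collision models (counts only), library bottlenecks and puromycin
selection, nutrient or drug gradients, cell migration, 3D growth, and any
pharmacokinetics — drug identity enters only through parameter values.
Passing tests therefore demonstrate that the *inference machinery* is
correct and calibrated under the stated generative assumptions, not that
real assays satisfy those assumptions.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the analyses at desk scale:
2,000 simulated colonies per grid cell (the original analysis used many
more), 20 replicate grid recoveries, 400 null replicates for test
calibration, 200 simulated plates for the frequency and IC50 recoveries,
50 synthetic clone-tracing experiments. These sizes were chosen so the
whole suite runs in minutes on one core while keeping Monte-Carlo error
well below the margins being tested.

Conventions fixed once and used everywhere: colony sizes are integers
≥ 1 (rounded half-up); histograms use log2 bins with edges
$0.5, 1, 2, 4, \dots$ spanning both compared samples and Laplace
pseudocount 1; the KL direction is observed‖simulated; the mixture
$\alpha$ grid step is 0.01 and its bootstrap p-value uses the
$(1 + \#\{D^* \ge D\})/(1 + B)$ convention; enrichment is strictly
greater-than; all randomness flows through explicit seeds (one seeded
generator per call, never hidden global state) and every simulation is
bit-reproducible given its seed.

## Known limitations

* The pre-incubation phase is non-spatial by default; a fully spatial
  pre-incubation would require simulating millions of cells on a torus
  and is out of scope at desk scale.
* The KL grid ranks models; it is not a posterior, and no
  likelihood-based uncertainty is attached to the best-fit region beyond
  the relative-tolerance band.
* The mixture test conditions on the finite reference samples; very small
  references make the null itself noisy.
* With `effect_sd > 0` the well-mixed pre-incubation still tracks step
  counts only (increment variability is a colony-phase refinement).

## A short worked example

```{r example, eval = FALSE}
# calibrate from mutation-free reference cohorts
map <- build_rate_size_map(14, reps = 200, seed = 1)
tol <- simulate_fixed_rate_cohort(rep(0.3, 300), 14, seed = 2)
set.seed(3); res <- simulate_fixed_rate_cohort(runif(300, 0.8, 0.97), 14)
cal <- calibrate_cohort(tol, res, map)

# simulate an observed 3-week cohort under gradual adaptation, then ask
# the grid which (mu, n) explains it
par_true <- simulation_params(p_init = cal$p_init, p_max = cal$p_max_ref,
                              n_steps = 30, mu = 0.05)
obs <- run_colony_cohort(par_true, 3, 2000, cal$p_max_sampler, seed = 4)
grid <- sweep_parameter_grid(obs, 3, c(0.005, 0.01, 0.05, 0.1),
                             c(1, 3, 10, 30, 100, 300), cal,
                             reps = 2000, seed = 5)
best_fit_region(grid)

# and whether a tolerant/resistant mixture could explain it instead
ks_mixture_test(obs, tol, res, n_boot = 1000, seed = 6)
```
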