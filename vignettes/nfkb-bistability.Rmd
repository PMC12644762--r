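---
title: "A bistable NF-kB circuit model of breast-cancer subtype plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable NF-kB circuit model of breast-cancer subtype plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`nfkbgrn` implements a mass-action model of the transcriptional circuit in
which the NF-kB heterodimer (p65:p50) activates the EMT transcription
factors TWIST1, SLUG and SIP1 and both of its own subunit genes. The
positive feedback through p50 and p65 makes the circuit bistable: a
low-NF-kB attractor whose expression levels correspond to the HER2-positive
breast-cancer phenotype and a high-NF-kB attractor corresponding to the
triple-negative (TNBC) phenotype, separated by a saddle-type unstable
stationary state.

Each gene X is modelled by a three-step activation scheme on molecule
counts, with two copies of every gene:

* binding/unbinding of the dimer at the regulatory region,
  `NFKB + N0_X <-> N1_X` (rates `kon_X`, `koff_X`);
* transcription from the bound gene, `N1_X -> N1_X + RNA_X` (`ktx_X`),
  plus constitutive synthesis `0 -> RNA_X` (`kbasal_X`) and decay
  `RNA_X -> 0` (`kdR_X`);
* for the translated subunits p50 and p65, translation
  `RNA_X -> RNA_X + P_X` (`ktl_X`) and protein decay (`kdP_X`).

`P_p50 + P_p65 <-> NFKB` closes the loop. The law of mass action gives both
the deterministic ODE system (`ode_rhs()`, `jacobian()`) and the stochastic
jump process (`ssa()`, `tau_leap()`). The five constraints
`N0_X + N1_X = 2` are exact conservation laws; they produce two null
Jacobian eigenvalues in the nine-species dynamical core (the p50/p65/NFKB
feedback loop — the three EMT targets are feed-forward and do not
influence the core dynamics).

The target genes are tracked at RNA level only by default, matching the
reported protein species (p50, p65, NF-kB); `grn_params(translate_targets
= TRUE)` adds generic target proteins.

## The calibrated parameter set

The default `grn_params()` values were calibrated in two layers.

**Stationary structure.** The three stationary states under wild-type and
p65-degradation-perturbed conditions pin down all rate *ratios*. At
stationarity the model implies, for each translated gene, `P_X =
(ktl_X/kdP_X) RNA_X`; a dimer balance `NFKB = (ka/kd) P_p50 P_p65`; and a
saturating RNA response `RNA_X = (2 ktx_X/kdR_X) N/(K_X + N) + kbasal_X /
kdR_X` with `K_X = koff_X/kon_X` and `N` the stationary dimer count. The
reference molecule numbers this package targets (see
`reference_states()` inside the test suite, or the README) satisfy these
relations to better than one part in 10^4, and the three-point fit of each
saturating response is exact, which fixes `Kd = kd/ka = 637143.5`,
`ktl/kdP = 311.29` (p50) and `856.09` (p65), and the per-gene
`(ktx/kdR, koff/kon, kbasal/kdR)` triples. Everything a deterministic
analysis sees — all three states, their shifts under p65-degradation
scaling, basin distances, fold bifurcations — follows from these ratios
alone, with no further freedom.

**Time scales.** Seven absolute rates (RNA and protein turnover of the two
subunits, two promoter binding scales, the dimerisation scale) are not
constrained by stationarity. They were chosen so that

* the leading Jacobian eigenvalues match the hour-scale relaxation of the
  circuit: the saddle's unstable eigenvalue `+2.5e-3 / min`, the weakest
  stable modes `-5.9e-3 / min` (HER2) and `-3.2e-3 / min` (TNBC);
* stochastic cells starting at the HER2 state undergo rare, irreversible,
  fluctuation-driven transitions to the TNBC basin, with the experimentally
  motivated sensitivity to p65 degradation (below);
* tau-leaping at `epsilon = 1e-3` remains desk-scale (roughly 0.1-0.4 ms of
  CPU per model minute per cell).

These three requirements pull against each other: fast turnover favours the
eigenvalue targets but averages away the transcriptional-bursting noise
that drives basin escape, and fast dimer exchange shrinks the feasible leap
size. The shipped compromise (`kdR = 0.3/min`, protein half-lives of 9-22
minutes, promoter dwell times of seconds, slow dimer exchange) reproduces
the eigenvalues within 2% and produces heavy-tailed wild-type first-passage
times with a mean around 60 model-days. The wild-type transition window is
thus compressed relative to a multi-year tumour history; transition claims
at long horizons are validated as monotone-trend properties on scaled
horizons, while the perturbed-degradation claims (below) are reproduced at
full ensemble size.

## Attractor geometry and perturbation scans

`find_stationary_states()` enumerates roots of the ODE system by damped
Newton iteration on the conservation-reduced system from log-uniform
multistarts (default 200; roots deduplicated at relative distance 1e-4)
and classifies them via the core-subsystem eigenstructure: the two stable
states show seven negative and two null eigenvalues, the middle state one
positive eigenvalue.

`scan_degradation()` rescales the p65 protein degradation rate — mimicking
FBXW2-type mutations or targeted protein degradation — and reports the
per-species percentage shifts of all three states plus the Euclidean
distances from each stable state to the saddle in the (p50, p65) protein
plane, the model's measure of attractor-basin size. Lowering degradation
by 2.5% raises HER2-state p65 by ~6.7% and shrinks the HER2-to-saddle
distance by ~19.8%; raising it by 5% grows that distance by ~47% while
shrinking the TNBC-to-saddle distance by ~53%. The basins disappear
entirely at factors ~0.915 (HER2) and ~1.07 (TNBC) — the bistable regime
is only a few percent wide in these parameter directions, which is why
small degradation changes reshape transition kinetics so strongly, and why
the parameter-recovery experiment in the test suite perturbs rates by 5%
(larger perturbations leave the bistable regime and land on the
calibration objective's penalty plateau).

## Stochastic simulation

`tau_leap()` implements Poisson tau-leaping with the species-based
bounded-relative-change step selection (control parameter `epsilon`,
default 1e-3; `g_i` equal to the highest order among reactions consuming
species i), falling back to exact SSA steps when the selected leap is
shorter than 10 expected reaction waiting times, and rejecting/halving
candidate leaps that would drive any count negative. `ssa()` provides the
exact reference; the test suite checks distributional agreement on small
networks where exact simulation is affordable. Propensities use the
falling-factorial stochastic convention; gene-copy conservation is exact
by construction of the stoichiometry and is asserted along trajectories.
All randomness flows through R's RNG, so a seed fixes a trajectory
bitwise; ensemble cell i uses `base_seed + i`.

## Basin assignment and first passages

The basin boundary (separatrix) is the stable manifold of the saddle. The
package's fast classifier linearises it: the normal is the left eigenvector
of the saddle Jacobian associated with the positive eigenvalue, applied to
the full state when available and to its (p50, p65) projection otherwise.
Against the relaxation oracle (integrate the ODE to convergence, label by
the attained attractor) the linearised classifier agrees on over 95% of
points sampled over the biologically covered plane; a naive chord through
the two stable states misclassifies roughly a quarter of that plane because
the separatrix curves strongly.
`separatrix_normal()` still reports the saddle anchor and the HER2-to-TNBC
chord direction for phase-plane plotting.

`detect_transition()` and `first_passage_ensemble()` report the first time
a trajectory's basin label flips and stays flipped for a dwell window
(default 10 model-days; transitions here are two-state-like, so results
are insensitive to the dwell choice over 1-10 days). The online
first-passage sampler avoids storing year-scale trajectories.

With the default parameters: wild-type cells cross HER2 -> TNBC at random
times (roughly two thirds of an ensemble within 10-11 model-weeks), and no
TNBC-started cell has been observed to cross back; at 2.5% lower p65
degradation all 120 cells of the standard ensemble cross within two weeks
(comfortably inside a 30-day window); at 5% higher degradation no crossing
is observed over the probed horizons. The ordering — lower degradation
accelerates, higher degradation blocks — mirrors the basin-size changes
above.

## The quasi-potential landscape

`build_landscape()` launches many short (default 30 model-minute)
tau-leaping simulations from a uniform grid over the (p50, p65) protein
plane — intervals (0, 1.8e5) x (0, 6e5), the remaining species at their
conditional quasi-equilibrium — bins the visited states, and reports
`U = -ln(P + pseudocount)`. Because 30 minutes is short relative to the
circuit's hour-scale relaxation, endpoint-only occupancy at the desk-scale
default of 1e4 simulations is dominated by bin-level sampling noise at
100x100 bins; the full-path accumulation option (all recorded states enter
the occupancy) together with the small moving-average smoother in
`landscape_minima()` resolves the two wells reliably at that scale. The
wells sit inside the HER2 and TNBC basins respectively; at growing
simulation counts the well minima approach the ODE stable states.

## Calibration utilities

`ddct_fold()`/`fold_to_molecules()`/`qpcr_to_targets()` convert triplicate
Ct tables into absolute RNA-count targets via the delta-delta-Ct method and
per-cell reference abundances. `steady_state_objective()` scores a
parameter set by the squared log-ratio between model stationary RNA counts
and the targets at both stable states simultaneously (log scale, because
targets span orders of magnitude), with a penalty when bistability is
lost; `fit_parameters()` wraps seeded multistart Nelder-Mead over
log-parameters. Self-consistency (targets generated from the model refit
to objective < 1e-8) and parameter recovery within the bistable regime are
exercised in the test suite.

`simulate_dhmeq_recovery()` models transient NF-kB inhibition: during
treatment all NF-kB-DNA binding is disabled (`kon = 0`; an alternative
mode instead empties the dimer pool at release). After release the
deterministic system relaxes back; RNA levels are reported at chosen times.
Two caveats are inherent to this circuit and worth knowing: (i) recovery
time courses are governed by the shared NF-kB feedback, so the model cannot
produce gene-specific recovery differences between subtypes (the EMT
targets are driven identically in both subtypes up to their stationary
scale); (ii) with the calibrated fast protein turnover, treatments much
longer than about an hour collapse the protein state into the HER2 basin,
so a TNBC cell loses its subtype identity — recovery experiments should
use short treatment durations (the default examples use 30-120 minutes).

## Cohort correlations

`cohort_ensemble()` produces labelled single-cell trajectories;
`sample_simulated_cohort()` draws one recorded moment from each of n
distinct cells (optionally restricted to moments carrying a given basin
label), and `repeated_correlation()` repeats the draw (default 100 times),
computes the Spearman correlation between p50 and p65 RNA per subtype set
(17 HER2-labelled and 34 TNBC-labelled pairs by default) and averages over
the sets whose correlation p-value falls below 5e-3.

Two properties of this procedure deserve emphasis. First, the raw
moment-to-moment RNA correlation in this model is modest (about 0.3 across
HER2-basin moments and about 0.1 across TNBC-basin moments — short-lived
transcripts carry mostly intrinsic noise), and TNBC < HER2 robustly: the
TNBC basin is more symmetric, while HER2-basin excursions stretch along
the correlated direction toward the saddle. Second, the p-value filter is
a truncation: when the underlying correlation is modest, only draws whose
sample correlation exceeds the significance boundary (≈0.64 at n = 17,
≈0.47 at n = 34) are accepted, so accepted-set means sit just above those
boundaries. Both effects are visible in the reported summaries and should
be kept in mind when comparing against cohort data analysed with the same
filter. The desk-scale ensemble stops each cell after a post-transition
residence window (default ~14 days, i.e. tens of TNBC-basin correlation
times), which bounds the several-fold more expensive TNBC-side simulation;
with that window the TNBC-labelled moments cover both the basin-entry
corridor and the basin core.

`synth_qpcr()`, `synth_cohort()` (Gaussian copula with log-normal or
negative-binomial marginals and an exact latent-correlation inversion for
the target Spearman rho) and `synth_transition_trajectory()` generate
study-shaped inputs with known ground truth, so every pipeline stage is
testable without external data; the copula generator also reproduces
bulk-scale (rho ~ 0.6) and single-cell-scale (rho ~ 0.16-0.19,
negative-binomial counts) comparison cohorts.

## Numerical choices and limitations

* Deterministic integration: `deSolve::lsoda` with the analytic Jacobian;
  transient negative excursions are clamped at zero.
* Root finding: damped Newton with step halving, nonnegativity projection,
  and gene occupancies capped at the copy number; failure to converge from
  a start is simply discarded.
* Null-eigenvalue threshold: `|lambda| < 1e-9 max|lambda|`, separating the
  two conservation zeros cleanly from the slowest genuine mode.
* Tau-leaping records at fixed intervals and never leaps across a
  recording point; Poisson variates use an inversion/rejection sampler on
  R's uniform stream (statistically exact, chosen because the leap means
  change every step).
* The wild-type first-passage distribution is heavy-tailed; quantitative
  statements about its mean at full 120-cell, multi-year scale are outside
  the desk-scale test envelope and are asserted only as trends.
* The synthetic-data generators emulate study-shaped inputs (triplicate Ct
  tables, copula cohorts, switching trajectories) but not full
  transcriptomes, batch effects, or measurement noise beyond Gaussian Ct
  jitter and count dispersion — passing tests demonstrate pipeline
  correctness, not biological validity on real cohorts.

## Reproducing the headline analyses

```{r, eval = FALSE}
library(nfkbgrn)
net <- build_network(grn_params())
rep <- find_stationary_states(net)
rep$states

# attractor geometry under p65-degradation perturbations
degradation_report(grn_params(), factors = c(0.975, 1.05))

# transitions at 2.5% lower p65 degradation: 120 cells, 30-day window
assay <- perturbed_transition_assay(grn_params(), 0.975, n_cells = 120)
assay$fraction_transitioned

# quasi-potential landscape
ls <- build_landscape(net, n_sims = 1e4, accumulate = "path")
landscape_minima(ls)
```

`scripts/acceptance.R` (repository root) reruns the full pipeline from
scratch and writes the headline numbers as JSON; see the README.
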