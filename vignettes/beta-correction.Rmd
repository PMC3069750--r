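---
title: "Cross-validated beta correction for classical density modification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated beta correction for classical density modification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classical density modification (DM) improves a crystallographic electron-density
map by alternating two steps: impose expected real-space features (a flat
disordered-solvent region, a protein-like density histogram) on the current
map, then recombine the modified map's phases with the original experimental
phase probabilities. The recombination needs an error model for the modified
phases, and that error model is estimated from the agreement between the
observed amplitudes |Fo| and the modified-map amplitudes |Fc|.

The catch: the modified map was *derived from* the observations, so |Fc|
agrees with |Fo| far better than the map's genuine quality warrants. The
Luzzati error parameter D, refined against that agreement, is inflated; the
model phases are trusted too much; the combined figures of merit (FOM) race
towards one while the true phase quality barely moves. The failure is easiest
to see with the identity ("null") modification: the modified map equals the
experimental map, |Fc| matches |Fo| essentially perfectly, and after a few
cycles every reflection claims a FOM of one even though nothing improved.

`betadm` implements a cross-validation estimate of this artificial covariance
inflation — a single multiplicative factor beta — inside a complete but
minimal classical DM loop, together with the statistics needed to measure the
resulting calibration.

## The model

For acentric reflections the observed amplitude given a model amplitude is
Rice distributed,

    P(|Fo|; D|Fc|, sigmaDelta^2),

with per-resolution-bin Luzzati D in [0, 1.2] and residual variance
sigmaDelta^2, both refined by bounded maximum likelihood (`refine_luzzati`).
Experimental phase information enters as Hendrickson–Lattman (HL)
coefficients, exp(A cos phi + B sin phi + C cos 2phi + D sin 2phi). The model
phase contributes a term X cos(phi - phi_c) with

    X = 2 D_eff |Fo| |Fc| / sigmaDelta_eff^2,

so phase combination is a coefficient addition in HL space
(`combine_phases`), with centroid phase and FOM evaluated by quadrature.

The beta correction scales the model covariance after each cycle's D
refinement:

    D_eff = beta * D,
    sigmaDelta_eff^2 = sigmaDelta^2 + (1 - beta^2) D^2 <|Fc|^2>,

the variance recomputed so the per-bin second moment of the observations is
preserved — the self-consistent bivariate-Gaussian reading of a scaled
covariance term. beta = 1 is exactly the uncorrected model.

beta itself is estimated by cross-validation (`estimate_beta`): a free set
(5% of reflections by default) is excluded completely from five cycles of DM
— no observed amplitude, no experimental phase, zero coefficient on the
first cycle and a model-only `D_eff Fc` fill afterwards — and beta is the
ratio of the free-set to working-set covariance between |Fo| and |Fc| from
the final cycle. A model genuinely independent of the observations gives
beta near one; a model that has memorized its observations gives a working
covariance far above the free one, hence beta well below one. Production DM
then restarts from the initial experimental map and runs (20 cycles by
default) on all reflections with beta fixed.

## Covariance conventions

Two numerical choices in the beta ratio deserve a note.

* **Per-(bin, set) second-moment scaling.** Free reflections are absent from
  map synthesis, so their |Fc| are systematically small; a raw cross moment
  would measure that scale rather than the free-set correlation the ratio is
  defined on. |Fc| is therefore scaled onto the |Fo| second moment within
  each resolution bin and each set before the mean-centred cross moments are
  pooled. The ratio is then invariant to any global positive rescaling of
  the model amplitudes.
* **Unbiased pooled normalization.** Cross moments are pooled over bins and
  divided by the summed (n_b - 1); with ~10 free reflections per bin the
  naive 1/n normalization biases beta low by several percent.

Mean-centring is done within each resolution bin so that resolution trends
in the amplitudes do not masquerade as correlation. Inside the Luzzati
refinement the per-bin scale is the square root of the second-moment ratio,
never the cross-moment regression scale — the latter would absorb D itself
and make the refinement degenerate.

When the free-set covariance is non-positive (the pure null-modification
limit, where free |Fc| are exactly zero), the returned beta is clamped to a
1e-6 floor so downstream likelihoods stay defined; the raw ratio and both
covariances are kept in the `beta_estimate` object.

## The toy-crystal generator

The package ships its own ground-truth generator instead of depending on
deposited data:

```{r}
library(betadm)
ds <- simulate_toy_dataset(kappa = 1, seed = 5)
ds$refl
ds$phases
```

* **Crystal**: point atoms with Gaussian B-factor falloff, placed uniformly
  in an orthogonal P1 cell (default 60 atoms, 22 Å cell, 2.2 Å resolution,
  about 2100 unique acentric reflections). P1 keeps every reflection
  acentric and avoids all space-group bookkeeping; the correction is
  symmetry-agnostic at this level. Centric reflections, anomalous signal and
  non-orthogonal cells are deliberately absent.
* **Amplitudes**: |Fo| = |F_true| (1 + eps), eps ~ N(0, 0.05) by default.
* **Experimental phases**: per-reflection phase errors drawn from a von
  Mises(0, kappa) distribution. The von Mises form matches the unimodal HL
  density exactly, so the simulated HL coefficients (A, B) = kappa
  (cos phi, sin phi) are self-consistent and the stored FOM
  I1(kappa)/I0(kappa) equals the expected cosine of the simulated error:
  the synthetic "experimental phasing" is calibrated by construction. A
  `kappa_reported` argument can miscalibrate it deliberately, mimicking the
  overconfidence of real phasing programs; the magnitude of that effect in
  real pipelines is not something the toy can tell you.

What the toy does *not* emulate: resolution-dependent phase quality,
correlated amplitude errors, heavy-atom substructure artifacts, genuine
solvent (the "solvent" of a uniform point-atom crystal is the interstitial
volume), and bimodal (C, D != 0) experimental distributions. Passing tests
on these ensembles demonstrate the mechanics and direction of the bias
correction, not its quantitative behaviour on real SAD data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `solvent_fraction` | 0.5 | fraction of the cell flattened each cycle; a user parameter, not estimated |
| `mask_radius` | 8 Å | Wang sphere radius for the local-density solvent score |
| `n_bins` | ~n/150, max 12 | resolution bins for D refinement; at least 50 reflections per bin, tails merged |
| `mode` | `"2mfodfc"` | next-cycle map coefficients; `(2 m |Fo| - D_eff |Fc|) exp(i phi)` suppresses model-error peaks relative to the centroid map |
| `free_fraction` | 0.05 | cross-validation free set |
| `est_cycles` / `n_cycles` | 5 / 20 | estimation and production cycle counts |

The solvent mask is recomputed from the current map every cycle, operators
run in the fixed order flatten-then-histogram-match, and the
histogram-matching target defaults to the package's reference histogram
(built once from a fixed reference toy crystal), playing the role of the
library histograms real DM programs ship. A truth-derived target can be
passed explicitly; note that it turns the uncorrected loop into nearly
ideal phase retrieval, a regime in which aggressive over-iteration wins on
map quality even while its FOMs are meaningless.

## Numerical choices

* Phase integrals use a fixed 360-point rectangle rule, which is spectrally
  accurate for these periodic integrands; agreement with a 1e5-point
  brute-force rule is verified to 1e-6 in the tests.
* D and log(sigmaDelta^2) are refined jointly per bin by L-BFGS-B from
  moment estimates, D clamped to [0, 1.2], sigmaDelta^2 floored at 1e-6 of
  the bin's mean squared amplitude, ties broken toward smaller D by a
  vanishing penalty. log I0 switches to its asymptotic expansion above 1e4
  to survive the perfectly-correlated null regime.
* F(000) is excluded everywhere; maps are mean-zero. Synthesis places each
  hemisphere reflection and its Friedel mate, so a unit coefficient at
  (1,0,0) yields exactly cos(2 pi x); inversion is the exact inverse on
  band-limited maps.
* Free-set selection uses exact-count sampling without replacement (not
  Bernoulli thinning) so the realised fraction is exact; the thin-shell
  scheme frees whole contiguous resolution shells.
* Grids default to d_min/3 sampling rounded up to FFT-friendly sizes.

## Design decisions taken where the design was open

* D is parameterized and refined directly rather than through sigma_A; the
  two are interchangeable and direct refinement has fewer moving parts.
* A single global beta is used, not per-bin values: the free set is far too
  small to support per-bin ratios, and the quantity being corrected is a
  procedure-level artifact.
* The stage-1 exclusion is complete (free reflections contribute neither
  amplitude nor experimental phase); filling them with the experimental
  phase would re-couple the sets. The model-only fill from cycle 2 onward
  adds no observed information but lets the real-space constraints restore
  free amplitudes across cycles, which the covariance ratio needs in order
  to see the model's genuine predictive power.
* Covariances are mean-centred (within bins) rather than raw second
  moments; raw moments are dominated by the Wilson fall-off and barely
  sensitive to the correlation being measured.
* Map correlations are computed over the full cell without masking.
* Stage 2 restarts from the initial experimental map rather than continuing
  from stage-1 output, so the production run never inherits maps built
  without the free reflections.

## What the evaluation statistics mean

For ensembles of data sets with known true phases, `run_bias_experiment`
runs each data set uncorrected (beta = 1) and beta-corrected from identical
inputs and reports per data set the final mean FOM, the mean cosine of the
phase error (CPEM), their difference (the statistical bias), and the map
correlation with the true map. `statistical_bias`, `estimator_error`
(direct and leave-one-out Nadaraya–Watson regression estimates of CPEM from
FOM, Gaussian kernel, Silverman bandwidth by default) and
`phasing_corrected_fom` reproduce the corresponding summary statistics. On
the default 20-data-set ensemble (kappa from 0.5 to 3) the correction
reduces the ensemble bias by an order of magnitude, raises the FOM/CPEM
correlation to ~0.99, and leaves the mean map correlation slightly better
than uncorrected; in the null-modification stress test the uncorrected bias
exceeds 0.5 while the corrected one stays below 0.05. Those numbers are
computed, not asserted: `scripts/acceptance.R` regenerates them from
scratch for any seed, and the test suite checks their directions.

Problem sizes used throughout (20 data sets, ~2100 reflections each, 20
production cycles) are the package's own choice of desk-scale conditions:
large enough for stable per-bin likelihoods and clearly resolved effects,
small enough that the complete paired ensemble runs in a few minutes on one
CPU.

## Known limitations

* Acentric-only likelihoods; the centric branch is an extension point.
* No gamma-style feedback subtraction: the correction models the artificial
  correlation rather than removing its source, and the toy pipeline applies
  it on top of 2mFo-DFc synthesis only. Without any gamma correction the
  uncorrected loop overfits harder than real DM programs do, so the
  uncorrected arm here is a worst case, and estimated betas (~0.2-0.6 on
  mediocre toys) sit lower than one would expect for real programs.
* No NCS averaging, no anisotropy, no experimental-phase re-refinement:
  residual bias inherited from the simulated phasing step is measured
  (`phasing_corrected_fom`) but never repaired.
* beta estimates from ~100 free reflections carry sampling noise of order
  0.1; the defaults warn below that size.
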