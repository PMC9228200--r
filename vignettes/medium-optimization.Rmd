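---
title: "Methods: dual RSM/ANN modelling and desirability optimization of a cultivation medium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual RSM/ANN modelling and desirability optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medopt)
```

## The problem

A *Bacillus* biocontrol strain is cultivated in a liquid medium whose
composition — cellulose as carbon source, urea as organic nitrogen,
ammonium sulfate as inorganic nitrogen, dipotassium phosphate as phosphorus
source — governs how strongly the resulting broth suppresses aflatoxigenic
*Aspergillus flavus*. Activity is measured as the inhibition-zone diameter
(mm) of the broth in a well-diffusion assay against two fungal isolates
(SA2BSS and PA2DSS). The package models the concentration–activity
relationship two ways (a quadratic response surface and a neural-network
pipeline), compares the fits, and optimizes the medium composition under
economic goals.

## Screening statistics

The screening stage compares candidate carbon (and then nitrogen) sources
one factor at a time, six replicate zone measurements per source. The
analysis is a fixed-effects one-way ANOVA (delegated to `stats::lm`) plus
Duncan's multiple range test. Duncan's test declares a stretch of `p`
consecutive ordered means homogeneous when its range is below

    R_p = q(1 - alpha_p, p, df_error) * sqrt(MS_error / n),
    alpha_p = 1 - (1 - alpha)^(p - 1),

where `q` is the studentized-range quantile, evaluated numerically with
`stats::qtukey` rather than from printed tables, so any error degrees of
freedom are supported. Letter assignment is the classical step-down rule:
stretches are tested from widest to narrowest and a stretch found
homogeneous is never subdivided, so a non-significant span cannot be
contradicted by an inner pair. The letter `a` goes to the stretch holding
the smallest mean, matching the convention of the screening tables this
package reconstructs.

Since the raw replicates of the original screening experiments are not
available, `make_screening_groups()` rebuilds a dataset from the published
summaries: each group receives `n` replicates alternating `mean ± d` with
`d = sqrt(SS_error / (n_groups * n))`, which makes the group means and the
total error sum of squares exact. One-way ANOVA on the reconstruction
therefore reproduces the published F statistics exactly; this is an
algebraic identity, not a simulation.

## The Box–Behnken design

For `k` factors at three levels, the design takes, for every factor pair,
the four (±1, ±1) combinations with the remaining factors at their
midpoint, plus replicated center runs — for `k = 4` and three center
replicates, 27 runs. Coded levels map affinely to concentrations,
`x_nat = center + x_coded (high − low)/2`. The canonical run order (factor
pairs lexicographically, centers last) is fixed so fixtures and diffs are
stable; the execution order is a separately stored seeded permutation, and
a seed is mandatory — there is deliberately no unseeded path anywhere in
the package.

## The quadratic response-surface model

The model is the full second-degree polynomial in the four concentrations
(intercept, 4 linear, 6 interaction, 4 quadratic terms — 15 coefficients
against 27 runs, leaving 12 residual degrees of freedom). Fits are
ordinary least squares on the expanded basis, **in natural units by
default**: the published coefficient sets evaluate correctly at natural
concentrations (they reproduce the published optimum predictions of
30.66 and 27.84 mm), so natural units are what a user will exchange with
the literature. Fitting in coded units is available and yields identical
predictions with different coefficients; a test asserts this equivalence.

Numerical note: the natural-unit basis mixes scales badly (cellulose² runs
to ~1200 while phosphate interactions stay below 1), which costs several
digits in the QR solve. Each basis column is therefore scaled to unit
maximum absolute value before the fit and the coefficients and standard
errors are rescaled afterwards — an exact reparameterization that brings
noise-free coefficient recovery to ~1e−8 relative.

R² and the model ANOVA are computed on **corrected totals**
(`SS_model + SS_residual = SS_total` around the response mean). Adjusted
R² is `1 − (1 − R²)(n − 1)/(n − p)` with `p` counting the intercept. A fit
with zero residual sum of squares reports `F = Inf`, `p = 0`, and
coefficient inference is flagged as meaningless. Prediction outside the
design box is refused by default — a quadratic fitted over a box has no
validity beyond it — with an explicit `extrapolate` override.

## The synthetic-data generator

The generator is the package's stand-in for the unpublished run-level
data: responses are the published quadratic surfaces evaluated at the
design points plus i.i.d. Gaussian replicate noise. The defaults are the
study conditions — the two published coefficient sets as truth, the 27-run
design, and `noise_sd = 0.5` mm, chosen once because it yields fits with
R² ≈ 0.95–0.96 on the 27-run design, the precision level the original fits
reported. What the generator does **not** emulate: heteroscedastic or
non-Gaussian measurement error, run-order drift, lack-of-fit (the true
surface is exactly quadratic by construction), and any real biological
deviation from quadratic behaviour. Passing tests therefore establish that
the pipeline recovers a known quadratic truth at realistic noise — not
that a real broth obeys a quadratic law.

## The autoencoder / predictor branch

All six attributes (four concentrations, two responses) are min–max
normalized to [0, 1] over fixed instrument/formulation limits (cellulose
0–50, the other components 0–10 g/L, responses 10–40 mm). Per isolate, an
autoencoder (encoder 5→16→4, decoder 4→16→5) is trained to reconstruct the
27 normalized rows; elu activations everywhere except the sigmoid output,
which confines reconstructions to the unit cube. The elu embedding is
bounded below by −1, consistent with the [−1, 2.5] interval from which
`augment()` draws uniform embedding samples.

Two numerical choices matter and were made as follows:

* **Optimizer.** Training uses full-batch gradient descent with adaptive
  moment estimation (Adam) under an exponential step-size schedule (decay
  factor applied once per 1000 epochs), with early stopping when the
  relative loss improvement over a patience window falls below a
  tolerance. Plain momentum descent stalls on these problems: after
  normalization the response column has variance ~0.005, the raw gradients
  are minute, and the network sits at the predict-the-mean plateau for
  thousands of epochs. Adam's per-parameter scaling removes the plateau
  without changing the loss or the schedule.
* **Weight penalty.** The l2 coefficient (0.01) acts as decoupled weight
  decay (each step multiplies weights by `1 − lr·l2`). Added as a raw
  penalty gradient, 0.01·ΣW² exceeds the ~0.005 reconstruction MSE by
  orders of magnitude and the regularized optimum is the collapsed
  constant network; decoupled decay preserves the conventional meaning of
  the coefficient.
* **Embedding standardization.** After training, the embedding is affinely
  standardized per dimension so the training rows span [−0.75, 2.25], and
  the inverse map is folded into `decode()` — the autoencoder function is
  unchanged. The fixed [−1, 2.5] sampling cube is then a slightly expanded
  version of the range the embedding actually takes on the data, which is
  the stated rationale for that interval. Without this, the sampled cube
  and the data's embedding region drift apart run by run, and the quality
  of the augmented cloud at the original design points becomes a lottery
  (validation R² 0.4–0.9 across seeds in our experiments, against 0.83–0.90
  with standardization).

`augment()` decodes 10,000 i.i.d. uniform embedding points (the study's
augmented-set size). The predictor is a fixed three-hidden-layer MLP
(elu, sigmoid output, dropout 0.05, l2 0.01) trained **only** on augmented
rows; the 27 original rows are held out entirely and used as the final
validation set, so the validation metric is simultaneously the
augmentation-success check. Per-isolate hyperparameters default to the
published selections (7 neurons / rate 0.020 / decay 0.85 for SA2BSS,
10 / 0.035 / 0.70 for PA2DSS); `cross_validate_predictor()` implements the
five-fold seeded grid search used to find such settings, with ties broken
toward the smaller network. Validation R² is computed against the
validation set's own mean (the standard definition).

Problem sizes used in the shipped tests: the affine-manifold autoencoder
fixture uses 1000 rows and a 5000-epoch cap; end-to-end pipeline checks
train the predictor for up to 4000 epochs on the full 10,000-row
augmentation. These budgets were chosen as the point where the loss curves
flatten; training longer changes the metrics in the third decimal.

The pipeline-level comparison converts the ANN validation R² to an
adjusted R² using `p = 2` effective terms, treating the trained predictor
as a single fitted transformation plus intercept; the original comparison
table does not state its adjustment convention, so this is the package's
own, documented choice (it is conservative toward the ANN branch, which
still loses to the quadratic fit).

## Desirability optimization

Each goal maps a factor or predicted response onto [0, 1]: one-sided ramps
raised to a weight exponent for minimize/maximize, an indicator for
in-range, a two-sided ramp for target. The overall desirability D is the
geometric mean; any fully undesirable goal forces D = 0. The study's goal
set — minimize cellulose and urea, keep both salts in range, maximize both
responses, all weights 3 — is `default_goals()`.

The response-goal bounds are not published. The package defaults to the
observed response minimum/maximum of the supplied experiment, with the
fixed 10–40 mm normalization range available as an explicit option; the
published overall D = 0.75 is therefore **not** a reproduction target
(it depends on those unpublished bounds), while the optimized composition
itself is robust to the choice: because both surfaces decline with
cellulose, urea and phosphate at the optimum, those coordinates pin to
5.00, 0.00 and 0.50 g/L regardless, and only the interior ammonium-sulfate
coordinate (≈3–4 g/L against the published 3.77) shifts with the bounds.

The search is a seeded multi-start bounded simplex: Nelder–Mead from every
box corner, the center, and seeded uniform starts (64 total), with an
out-of-box penalty and final clamping; D ties are broken toward lower
total nutrient mass. D is piecewise-smooth (ramp clipping, in-range
indicators), which is why a derivative-free method is used.

## Limitations

* Published tables whose values depend on the unpublished raw responses
  (coefficient p-values, the fit ANOVA sums of squares, the autoencoder and
  predictor metric tables) are covered by property-level checks on
  synthetic data, not value-for-value reproduction. The fit-stage ANOVA of
  the original report is additionally stated on uncorrected totals, which
  this package deliberately does not mirror; corrected totals are used
  throughout.
* Duncan's test is implemented for balanced groups only; unbalanced data
  would need the harmonic-mean-n extension.
* The neural branch is full-batch and CPU-oriented; it is sized for
  27-run tables and 10⁴-row augmentations, not for large datasets.
* Lack-of-fit testing against center-replicate pure error is out of scope
  (the generator's truth is exactly quadratic, and the real replicate
  responses are unavailable).
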