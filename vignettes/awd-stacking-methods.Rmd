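---
title: "Adaptive weighted stacking for CGM forecasting: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive weighted stacking for CGM forecasting: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

glucostack forecasts blood glucose 30--60 minutes ahead from a univariate
continuous glucose monitoring (CGM) trace sampled every 5 minutes. This
vignette is the package's own account of the method: the preprocessing
model, the ensemble, the weighting scheme, the numerical choices made where
the design was genuinely open, and what the synthetic test bed does and
does not establish about real sensor data.

## The forecasting problem

A CGM sensor reports interstitial glucose (mg/dL) on a nominal 5-minute
grid, with sensor noise, drift and dropouts. Clinically useful forecasting
targets a *prediction horizon* (PH) of 30, 45 or 60 minutes — 6, 9 or 12
grid steps — far enough ahead for a patient or closed-loop controller to
act on an impending hypo- or hyperglycemic excursion. The forecaster sees
only a short *history window* of past values: 6, 9, 12 or 18 points (30-90
minutes). Because no single history length dominates, the pipeline runs all
four and reports each window's metrics along with their mean.

## Preprocessing

Stages run in a fixed order, and each output carries a provenance stamp so
the order can be enforced (`strict = TRUE`):

1. **Gap filling.** The series is snapped onto the exact 5-minute grid.
   Training series interpolate gaps linearly between observed neighbours.
   Test series are filled *causally*: each missing point is extrapolated
   linearly from the two most recent observed-or-filled values, so the
   test stream never consults its own future.
2. **Scalar Kalman filter.** A forward predict/update recursion with a
   random-walk state (`A = 1`, `H = 1`). Defaults `Q = 0.1`, `R = 4`
   (mg/dL)^2 encode a slowly drifting latent glucose observed through
   roughly 2 mg/dL of sensor noise; `x0` is the first observation and
   `P0 = R`. These are exposed in `kalman_config()` because the
   appropriate `Q/R` ratio is sensor-dependent. Only the forward filter is
   run — a backward smoothing pass would use future observations.
3. **Holt double exponential smoothing** with level coefficient
   `alpha = 0.1` and trend coefficient `beta = 0.5`. Initialization is
   `L1 = Y1`, `T1 = Y2 - Y1`, chosen so exactly linear series are
   invariant. The emitted value `L_t + T_t` is a one-step-ahead quantity;
   it is applied as written, without re-alignment, and the implied
   one-step shift is accepted as part of the smoother's definition.
4. **Min-max normalization** fitted on the training series only. Test
   values outside the training range map outside [0, 1] and are not
   clipped — clipping would silently distort exactly the excursions the
   forecaster most needs to see.
5. **Chronological 80/20 split** of the windowed training samples into a
   training subset and a validation set (floor rule on the count). The
   split is chronological, not random, to avoid temporal leakage between
   overlapping windows.

Normalization is applied to the series before windowing; windowing itself
is pure reshaping (stride-1 sliding windows, `n = L - h - p + 1` samples),
so the order of those two steps does not change any sample's content.

## Base learners

Three recurrent architectures, trained identically (Adam, learning rate
0.001, mean squared error, minibatches of 32, up to 500 epochs, early
stopping on validation loss with patience 10, best weights restored):

* **bilstm** — one bidirectional LSTM layer, 128 units per direction,
  final forward and backward hidden states concatenated; relu replaces
  tanh in the candidate and cell-output nonlinearities.
* **stacklstm** — three stacked LSTM layers (128, 64, 32 units), linear
  cell activation.
* **vlstm** — one 128-unit LSTM whose gates also observe the cell state
  (peephole connections), linear cell activation.

Each ends in a linear dense layer of width `p` emitting the whole
multi-step forecast as one vector; multi-step prediction is done in a
single shot, not recursively. The relu/linear activation assignments
follow the hyperparameter table that defines the architectures; `tanh`
remains available as a configuration switch.

The engine itself is implemented in the package: a readable
double-precision R implementation (`R/lstm.R`) serves as the reference —
its gradients are verified against finite differences — and a
single-precision C++ implementation is the production path, verified
against the R reference to float tolerance on loss, gradients and
forward passes. Training in single precision matches common deep-learning
practice. Numerical choices: Glorot-uniform initialization with the
forget-gate bias opened at 1, a global gradient-norm clip of 1.0 (relu
cells can otherwise overflow early in training; `Inf` disables it), and
all randomness drawn from R's RNG so a single `set.seed()` reproduces a
training run bit-for-bit on the same machine. Bitwise reproducibility
*across* machines is not promised (BLAS kernels differ), but same-machine
repeatability is tested.

## Stacking with adaptive weights

Per history window:

1. **Out-of-fold predictions.** The training subset is cut into 5
   contiguous, chronologically ordered folds (remainder to the first
   fold). For each architecture, each fold is predicted by the model
   trained on the other four, so every training sample carries exactly one
   prediction per architecture from a model that never saw it. All 15 fold
   models are retained; at validation and test time each architecture
   predicts with all 5 fold models and averages.
2. **Affinity-propagation weighting.** Validation samples are embedded as
   m-dimensional points of the base models' predictions at the final
   horizon step and clustered with affinity propagation on the similarity
   `S(i,j) = -d(i,j) - alpha (var_i + var_j)`, where `d` is Euclidean
   distance and `var_i` the spread of point i's own coordinates
   (`alpha = 0.5` by default; the penalty pulls samples on which the
   models disagree away from tight clusters). Each model's raw weight is
   its cluster-weighted variance — the average over clusters of its
   squared deviations from the cluster mean — normalized to sum to one.
   This reading (samples as points, models as features) is the only one
   under which the cluster-variance formula is well-defined, and it is the
   package default; with `invert_weights = TRUE` the reciprocal variances
   are normalized instead, upweighting models that are *consistent* within
   clusters of similar samples. Both modes ship because the direction is a
   genuinely open design point; the directional recovery property (an
   exact-prediction oracle model earns the largest weight) holds in the
   inverted mode, which is why that mode exists.
3. **Meta-learner.** The meta-features per sample are the base models'
   predictions (m x p columns), their weighted combination (p columns) and
   the original history window (h columns) — `h + (m+1)p` columns in a
   fixed block order with a recorded block map. An ordinary least-squares
   linear map (with intercept, one map per horizon output) is fit on the
   training subset's out-of-fold features. The weighted-combination block
   is an exact linear combination of the base blocks, so this design is
   rank-deficient *by construction*; the fit goes through the
   Moore-Penrose pseudoinverse (minimum-norm solution), which leaves the
   fitted values — the only thing used downstream — unchanged and
   well-defined.
4. **Test path.** Fold-averaged base predictions on the test windows are
   combined with the *same* weights, assembled into meta-features, passed
   through the fitted meta-map, denormalized, and scored at the final
   horizon step (the value PH minutes ahead). Nothing on the test path is
   fitted: the normalizer, the weights and the meta-coefficients all come
   from training data, and an audit test confirms that replacing the test
   series changes none of them.

A documented exception: the `"oracle"` pseudo-learner deliberately leaks
true targets into the prediction slots. It exists only as an audit
instrument — driving the pipeline's identity path (oracle predictions in,
zero error out) and the weight-recovery check — and is never a default.

## Affinity propagation: implementation notes

The clustering is the canonical responsibility/availability message
passing with damping, median-of-similarities preference, and a tiny seeded
jitter to break exact symmetry deterministically. Damping defaults to 0.5,
the canonical choice; heavier damping (0.9) was evaluated and rejected
because it fails to converge on small symmetric instances (duplicated
points) and measurably degrades exemplar quality — behaviour reproduced
identically by an independent reference implementation, so it is a
property of the algorithm, not of this code. After convergence the
exemplar set gets the standard medoid refinement, and on instances of at
most `polish_max = 64` points a deterministic greedy add/remove/swap local
search on the net similarity; with it, the returned exemplar set attains
the exhaustively enumerated optimum on every random instance up to n = 8
that the acceptance suite draws. Inputs larger than `sample_cap = 500`
points are subsampled with a seeded draw before clustering, bounding the
quadratic message-passing cost.

## Evaluation

All metrics are computed on the denormalized (mg/dL) scale at the final
horizon step:

* **RMSE / MAE** as usually defined.
* **Glycemic-band MCC.** Values are banded low (< 70), normal (70 to
  < 126) and high (>= 126) mg/dL; low and high form the *adverse* class
  and the Matthews correlation coefficient is computed on the binary
  adverse/normal confusion counts. A zero denominator factor (degenerate
  single-class data) defines MCC = 0, the standard convention.
* **Clarke error grid.** Each (reference, predicted) pair lands in exactly
  one zone A-E. The boundary geometry is the canonical rule set, shipped
  as a data file (`inst/extdata/clarke_zones.json`) of half-plane
  predicates evaluated in fixed precedence A, E, C, D with B as the
  remainder — swap the file to change the geometry. The suite checks the
  table point-for-point against an independently coded nested-condition
  oracle over a dense grid.
* **Relative error bands**: fractions of predictions within 10% and 20%
  of the reference.

## The synthetic test bed

Real CGM corpora with clinical provenance are access-restricted, so the
package carries a seeded generator whose defaults define its study
conditions, chosen once as a plausible adult trace: 7 days at 288
points/day; 140 mg/dL baseline; a 15 mg/dL circadian sinusoid; meals as a
Poisson process at 3/day, each a difference-of-exponentials impulse
(20-minute rise, 90-minute decay) peaking 80 mg/dL over baseline; AR(1)
sensor noise with 2 mg/dL stationary standard deviation and lag
correlation 0.5; 2% of grid points dropped as gaps; everything clipped to
the 40-400 mg/dL sensor range. The chronologically last 20% of the trace
is the held-out test segment, mirroring the held-out final days of a
clinical trace.

What this emulates: the sampling geometry, plausible dynamic range,
meal-like excursions, autocorrelated noise and dropout patterns that the
pipeline must survive. What it does not: insulin and activity dynamics,
sensor drift and recalibration jumps, biphasic meal absorption, nocturnal
hypoglycemia patterns, inter-patient variability. Consequently the
end-to-end checks establish that the machinery is correct and that
stacking does not lose to its own base learners on clean dynamics
(the suite asserts the stacked RMSE stays within a factor 1.1 of the best
single base model across seeds, and in practice it is well below 1x);
absolute error levels on this generator say nothing about accuracy
on real patients.

## Problem sizes and profiles

The full training protocol (500-epoch cap, patience 10) is the package
default. `fast_profile()` shrinks it to a 30-epoch cap with patience 5;
the test suite and the acceptance script run the 7-day trace (2016
points, about 1600 training points) under this profile, a deliberate
desk-scale choice documented here as such. Structural and determinism
tests use 2-day traces with 2-epoch budgets, since they exercise plumbing
rather than convergence.

## Known limitations

* The smoother's one-step-ahead output shifts the series by one trend
  step; with the default small `alpha` the effect is minor, but it is a
  definitional bias, not noise.
* Early stopping and weighting share one validation set; with very short
  traces the weight estimates get noisy before anything else breaks.
* Minimum-norm meta-coefficients are not individually interpretable
  (the design is deliberately redundant); only the fitted map is.
* The engine targets short windows and univariate input; it is not a
  general-purpose sequence library.
* Multivariate inputs (insulin, carbohydrates, activity) are out of
  scope, as is any streaming/online update of a fitted pipeline.
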