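---
title: "Connectome-based prediction of intellectual capacity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based prediction of intellectual capacity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmiq)
```

## The problem

`cpmiq` predicts a continuous cognitive phenotype — the Full-Scale
Intelligence Quotient (FSIQ, population mean 100, SD 15) — from resting-state
functional connectivity (FC), across a transdiagnostic cohort (healthy
controls and several psychiatric diagnosis groups pooled). A connectome here
is the vector of Fisher-z-transformed Pearson correlations between the time
series of `n_roi` cortical regions; for the default 100-ROI parcellation
that is 4950 edges. Subjects may contribute one or two scan runs.

The pipeline has five statistical components:

1. **Edge screening + sparse regression with nested cross-validation** (the
   "standard model"): within each training fold, edges are screened by their
   Pearson correlation with FSIQ across training subjects (two-sided p <
   0.05 from the t transform with n − 2 df), and a LASSO regression is
   fitted on the retained edges, with the penalty chosen by an inner,
   subject-grouped cross-validation. Ten rounds of five-fold CV yield 50
   fold models; out-of-fold predictions are averaged over a subject's runs
   and performance is Pearson r (and R², the coefficient of determination
   1 − SS_res/SS_tot) per round, summarized as mean ± SD.
2. **A unified model**: per-edge weights averaged over all 50 fold models,
   counting an edge as zero in folds where the LASSO did not select it, plus
   the averaged intercept. This single linear predictor is what transfers to
   external cohorts.
3. **Permutation inference**: the entire pipeline rerun on label-permuted
   data (FSIQ shuffled across subjects; runs keep their subject's permuted
   value), both to test within-cohort CV performance and — via an ensemble
   of permuted unified models — transfer performance on external cohorts.
   p-values use the add-one formula (1 + #{null ≥ observed}) / (1 + n_perm),
   one-sided (larger r = better).
4. **Importance decompositions**: signed edge importance (the unified
   weights); ROI importance (mean or sum of |w| over incident edges — both
   aggregations are in use for displays); a 7×7 network matrix (mean |w|
   per within/between-network block over the Yeo-style seven networks); and
   leave-one-network-out lesioning — zero all weights on edges incident to
   one network in every fold model, regenerate the out-of-fold predictions,
   and measure Δr = r_standard − r_removed on exactly the same prediction
   set (paired design), with Fisher r-to-z tests and Benjamini–Hochberg FDR
   across the seven networks.
5. **Subdomain analysis and differentiability**: the top-k (default 500)
   edges by |unified weight| form the "IQ-correlated" set; in-sample
   multiple linear regressions of FSIQ and the five WISC subdomain indices
   (WMI, FRI, VCI, VSI, PSI) on that set report the true–fitted Pearson r,
   with a controlled permutation null that redraws k edges from the
   uncorrelated complement; weight-vector pattern similarity (unit-length
   inner products) compares subdomains; and the individual-differentiability
   statistic ID_i = Σ_j |FC_ij − mean_j| measures each subject's L1
   deviation from the cohort mean connectome.

## The synthetic cohort generator

Real clinical cohorts of this kind are access-restricted, so the package
ships a generator whose output exercises every stage. It is a single-latent
model: one standard-normal trait g per subject drives both the FC signal
and FSIQ.

* **Mean connectome**: within-network edges have mean FC 0.35 (z-scale),
  between-network edges 0.10, with N(0, 0.02²) per-edge jitter. The
  magnitudes are conventional, not estimates of any real cohort.
* **Planted edges**: `n_true_edges` (default 50) edges get the loading
  γ·sign_j (γ = `effect_scale`, default 0.1 z-units per latent SD; signs
  random). Optionally the planted edges are confined to one network.
* **Noise**: subject-level N(0, 0.1²) per edge, plus run-level N(0, 0.1²)
  per edge and run (two runs by default).
* **FSIQ calibration**: the quantity of interest is the population R² of
  the *oracle* linear predictor built from the planted edges. Averaging the
  planted edges attenuates the trait by
  κ = γ²m / (γ²m + σ_e² + σ_r²/runs); the generator therefore couples FSIQ
  to the latent trait with h′ = h/κ, so that the oracle predictor attains
  population R² = h exactly (default h = 0.35, hence oracle r = √0.35 ≈
  0.59). `h = 0` produces a null cohort. Subdomains load on the same latent
  trait with loadings a_k ∈ (0,1) (defaults 0.75/0.80/0.70/0.65/0.55).
* **Nuisance structure**: six diagnosis groups with realistic proportions
  and small FSIQ shifts, four sites with small uniform edge-mean shifts —
  both chosen once as plausible magnitudes; per-group network-FC shifts are
  supported but default to zero.

What the generator does **not** emulate: autocorrelated BOLD time series
(FC is simulated directly; `compute_fc` is tested separately), heavy-tailed
FC distributions, motion artifacts, site-by-edge interaction structure, and
any real atlas geometry. Passing tests therefore demonstrate correctness of
the estimation machinery under a known truth, not performance claims about
real neuroimaging data.

## Numerical choices

* **FC is stored Fisher-z transformed.** The z-scale has unbounded support,
  which suits linear modeling and the L1 sums of the differentiability
  statistic. `compute_fc` refuses |r| within 1e-12 of 1 (the transform
  diverges) and names the offending ROI pair.
* **Edge indexing** is 0-based with row-major upper-triangle order
  (`edge_id(a, b, n) = a·n − a(a+1)/2 + (b − a − 1)` for a < b); one
  documented convention shared by every module and the `e0000`-style file
  columns.
* **Screening is across subjects**: the fold's training runs are averaged
  per subject before correlating with FSIQ. This makes screening invariant
  to duplicating a run, and its retention count independent of the run
  multiplicity.
* **LASSO**: objective (1/(2n))·RSS + λ‖w‖₁ after standardizing features to
  population SD 1 and centering the target; weights are reported back in
  original FC units so cross-fold averaging is on a common scale. The
  penalty grid is 50 log-spaced values from λ_max down to λ_max·10⁻³; ties
  in the inner-CV error go to the largest (sparsest) λ. The single-feature
  case and the λ ≥ λ_max case use exact closed forms; λ = 0 falls back to
  (minimum-norm) least squares.
* **Inner CV re-screens per inner fold.** Screening on the full outer
  training set makes inner validation errors optimistic (the retained noise
  edges correlate with the validation subjects' scores by construction) and
  systematically under-penalizes — in pilot runs this halved the holdout
  correlation. Each inner fold therefore repeats screening on its own
  training subjects before fitting the penalty path.
* **Degenerate folds** (screening retains nothing) predict the training
  mean with a warning, never crash. Constant predictions leave r `NA` with
  an explicit status while R² is still reported; a permuted model that
  predicts a constant enters the permutation null as r = 0.
* **Fisher z test**: the plain independent-samples form
  z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)), even though compared CV
  correlations share subjects; a dependent-correlation variant would need
  the cross-correlation of predictions and is out of scope. FDR control is
  Benjamini–Hochberg across the seven networks within each subject group.
* **Determinism**: every stochastic stage takes a seed; fold partitions and
  inner-fold assignments are drawn from it before any data-dependent
  branch, so reruns are bit-identical and perturbing a held-out subject's
  FSIQ provably cannot alter that subject's out-of-fold prediction.

## Design decisions that were genuinely open

* **Unified averaging divides by all 50 fold models** (zeros included for
  unselected edges), not by the number of selecting folds; selection
  frequency is reported separately so the other convention is recoverable.
* **"Top k strong connections"** means rank by |unified weight| with ties
  broken by edge id.
* **ROI-level regressors** are per-subject weighted incident-edge sums
  (Σ over scope edges incident to the ROI of w_j·FC_ij): a subject-constant
  "ROI importance" cannot regress across subjects, so the subject-varying
  reading is the only coherent one. Both the top-k scope and the
  full-connectome scope are exposed for the paired contrast.
* **Screening uses a single signed edge set** (positive and negative edges
  together feed one LASSO), not separate positive/negative sum scores.
* **Permutations shuffle the subject→FSIQ assignment globally** and rerun
  the full pipeline including screening — the conservative reading; runs
  never separate from their subject.
* **ID is the unnormalized L1 sum** over all edges; multi-run subjects
  contribute their run-averaged connectome both to the mean and to their
  own ID.

## Problem sizes used by the test-suite

The package's own checks run on reduced cohorts chosen to keep the full
suite at desk scale while leaving each property identifiable: most unit
tests use 20-ROI (190-edge) cohorts of 20–150 subjects; the parameter
recovery check runs the full default conditions (600 subjects, 100 ROIs,
50 planted edges, oracle R² = 0.35) over 10 seeds with 3 CV rounds; null
calibration of the permutation test uses 30-subject, 16-ROI cohorts at 99
permutations × 20 repetitions; the leave-network-out localization check
uses 30-ROI cohorts with the planted edges confined to the default-mode
network. The pre-registered recovery band for the mean CV r at the default
conditions, [0.45, 0.62], comes from the generative closed form (population
r = √0.35 ≈ 0.59) minus estimation attenuation observed in a pilot sweep.

## Known limitations

* The correlated-versus-full ROI-scope contrast (top-k ROI scores
  predicting better than full-connectome ROI scores) is a property of the
  full-scale regime, where the complement of the top-500 set is
  overwhelmingly noise. At reduced scale the unified support is small and
  almost entirely informative, so the contrast is a wash in either
  direction; the tests assert the mechanics of both scopes rather than a
  sign.
* The independent-samples Fisher z test is anti-conservative for paired CV
  correlations; treat its p-values as descriptive, as the FDR table does.
* At the default synthetic scale the unified model's support (edges ever
  selected across the 50 fold models) typically stays below 500, so
  restricting the model to its top-500 edges reproduces it exactly and the
  restriction shows no performance drop; the drop only appears when the
  support is wider than k.
* In-sample subdomain regressions inflate like E[R²] ≈ k/(n−1) under the
  null; the controlled permutation exists precisely to calibrate that
  inflation away, and cross-validated subdomain prediction is deliberately
  out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 150, n_roi = 20,
                  network_sizes = c(Visual = 3, Motor = 3, DAN = 3, VAN = 3,
                                    Limbic = 2, FPCN = 3, DMN = 3),
                  n_true_edges = 10)
sim <- simulate_cohort(cfg, seed = 1)
cv  <- nested_cv(sim$dataset, rounds = 2, outer_folds = 5, seed = 1)
cv$summary            # mean/SD of per-round r and R^2
model <- unify(cv)
part  <- top_k_edges(model, k = 50)
mean(sim$truth$true_edge_ids %in% part$correlated)  # recovery fraction
```
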