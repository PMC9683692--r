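---
title: "Task-specific calibration of a lumped-parameter cardiovascular model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-specific calibration of a lumped-parameter cardiovascular model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lumped-parameter (0D) models of the circulation describe compartments of
the cardiovascular system — heart chambers, arteries, terminal vascular
beds, veins — by ordinary differential equations in volume, pressure, and
flow, in direct analogy to RCL electrical circuits. Calibrating such a
model to the data actually available for a patient (echocardiographic
chamber volumes, cuff pressures, a handful of mean flows) is hard for two
reasons: the optimisation is expensive, and the data rarely identify all
parameters uniquely. `cvscalib` implements a task-specific answer: reduce
the fitting parameter set until it is locally structurally identifiable,
quantify the posterior of the reduced set by ensemble MCMC, and judge the
calibration by the uncertainty of the one prediction the model is for —
here the middle cerebral artery pressure, a quantity relevant to
hemorrhagic stroke risk that is not measurable non-invasively.

The pipeline is: (1) fit the current free parameters by a genetic
algorithm; (2) compute normalized sensitivities at the optimum; (3) fix
parameters that are unimportant or pairwise collinear, provided fixing
them cannot artificially shrink the core-prediction uncertainty; (4)
repeat until the thresholds are satisfied; (5) run affine-invariant
ensemble MCMC over the reduced set; (6) propagate posterior draws through
the model to obtain the prediction distribution.

## The forward model

The packaged model (`cvs_parameters()`, `cvs_topology()`,
`simulate_cvs()`) is a closed loop of 17 volume states: four heart
chambers, pulmonary artery and vein, an aortic/systemic arterial
compartment, a carotid/cerebral arterial compartment, seven terminal
vascular beds (leg LE, brachial BR, anterior/external/middle/posterior
cerebral AC/EC/MC/PC, trunk TR), and upper/lower-body venous
compartments.

* **Chambers** follow a time-varying elastance law
  $p = E(t)\,(q - q_\mathrm{un})$ with
  $E(t) = (E_A - E_B)\,e(t) + E_B$ and a smooth $\sin^2$ activation
  $e(t) \in [0,1]$ (ventricles active for the first 30% of the cycle,
  atria for 17% starting at 80%).
* **Valves** are smoothed ideal diodes: flow
  $= \mathrm{softplus}(k\,\Delta p)/(k R)$. The softplus form was chosen
  over a plain sigmoid multiplier because its slope is bounded by $1/R$,
  so valve sharpness ($k = 3\times10^4\,\mathrm{MPa}^{-1}$, a transition
  width of about 0.25 mmHg) adds no stiffness to the system. It also
  keeps all valve flows strictly non-negative.
* **Terminal beds** are a terminal resistance $R_{x,T}$ feeding a small
  bed compliance, drained by a venous return resistance. Brachial
  pressure is reported just downstream of the brachial segment
  resistance (the cuff site); the middle cerebral pressure $p_{MC}$ is
  the pressure of the cerebral arterial compartment.
* **Units** are the SI-derived set m$^3$, MPa, s (so resistances are
  MPa·s/m$^3$, compliances m$^3$/MPa); pressures in reported observables
  are in kPa, with 1 mmHg = 0.133322 kPa.

The stressed blood volume `q_sbv` is distributed over the compartments
proportionally to their compliances at initialization, and the closed
loop conserves total volume exactly (the test suite checks conservation
to ten times the solver tolerance on every run).

Nominal parameter values were set from standard physiology — arterial
compliance ~1.5 ml/mmHg, venous compliance 0.5 m$^3$/MPa, terminal
resistances giving a cardiac output near 5 L/min at a mean arterial
pressure near 115 mmHg and a middle cerebral territory flow near
2.5 ml/s — with the 12 candidate fitting parameters (`q_sbv`, `E_LVa`,
`E_RVa`, `R_par`, the seven `R_x_T`, `C_V`) bracketed by wide
physiological bounds that serve as the GA limits and the uniform prior.

Integration uses `deSolve::lsoda` over a compiled C right-hand side, in
chunks of a few cycles per solver call, until the cycle-start state
changes by less than the periodicity tolerance (default $10^{-6}$
relative, at least 5 cycles); because the approach to the limit cycle is
dominated by one slow geometric mode (arterial–venous volume exchange,
time constant of a couple of seconds), the cycle map is
Aitken-accelerated between chunks — the extrapolated state is only a
better starting point, and convergence is still certified by a genuine
cycle-to-cycle difference. The final cycle is then sampled at 500 Hz. Means are trapezoidal time
averages over exactly one period. Integrator failure is deliberately not
an error: it returns `solver_ok = FALSE`, and every caller (GA, MCMC)
maps it to infinite cost / $-\infty$ log-posterior, i.e. rejection.

During fitting stages every evaluation warm-starts from a *fixed* anchor
steady state (the nominal state during reduction, the GA optimum's state
for MCMC and prediction). A fixed anchor — rather than chaining from the
previous evaluation — keeps evaluations independent, so results are
identical whether candidates are evaluated serially or concurrently. The
anchor state's stressed part is rescaled to the candidate's `q_sbv`, so
the stressed-volume sensitivity survives warm-starting. The MCMC and
prediction stages relax the periodicity tolerance to $10^{-5}$ (minimum
3 cycles): the induced output error is orders of magnitude below the
smallest measurement CV (1.5%).

## Measurements and likelihood

A measurement set is a tibble of named scalar observables
(`measurement_set()`). Uncertainty enters either as a standard deviation
or as a coefficient of variation, related by $\sigma = \mathrm{CV}\,
|\hat z|$; a repeatability coefficient in percent converts as
$\mathrm{CV} = \mathrm{RC}\%/2.77$. The default CV table
(`default_cv_table()`) reflects inter-observer variability of the
echocardiographic volumes (10–23.5%), cuff pressures (1.5–4%, with a
consolidated 2.25% for the mean pressure), cerebral terminal flows
(8%), and deliberately large values (30–50%) for the arm/leg/trunk flows
so those targets only weakly constrain the fit. Missing measurements are
simply absent rows — no imputation.

The objective is the standard weighted sum of squares
$\sum_i \left((f_i(\theta)-\hat z_i)/\sigma_i\right)^2$ and the MCMC
log-likelihood is $-\tfrac12$ times it (independent Gaussian noise, no
correlation structure).

## Identifiability analysis

Sensitivities are first-order forward finite differences at the optimum
$\theta^*$, normalized by parameter value and measurement SD:
$S_{kl} = \partial f_k/\partial\theta_l \cdot \theta_l^*/\sigma_k$, with
relative step $10^{-3}$ (balancing truncation error against solver
noise; the step is halved and retried if a perturbed solve fails).
Parameter importance is the column RMS
$\delta_l = \sqrt{\frac1{n_z}\sum_k S_{kl}^2}$. For a pair $(i,j)$ the
columns are unit-normalized, the smallest eigenvalue $\mu$ of their
2×2 Gram matrix is taken, and the collinearity index is
$\gamma_{ij} = 1/\sqrt{\mu}$ — equivalently
$1/\sqrt{1-\lvert\cos\angle(S_{\cdot i},S_{\cdot j})\rvert}$, a closed
form the tests verify to $10^{-10}$. Orthogonal columns give
$\gamma = 1$; parameters that compensate each other exactly give
$\gamma = \infty$ (serialized as the sentinel $10^{12}$). The default
thresholds are $t_i = 0.1$ (only clearly unimportant parameters are
dropped) and $t_c = 10$, inside the 5–20 range generally regarded as
critical for this index; $\lvert\cos\rvert = 0.99$ corresponds exactly
to $\gamma = 10$.

Each reduction iteration fixes at most one parameter — the
lower-importance member of the worst offending pair above $t_c$, or
failing that the least important parameter below $t_i$ — then refits.
Fixing one parameter per round at the freshly refit optimum avoids
cascading removals from a stale linearization. Ties in importance are
broken deterministically toward the name that sorts later. Fixed
parameters are held at their nominal (approximate physiological) table
values, not at the fit value: the fit value of a collinear parameter is
arbitrary along the compensation direction.

**Prediction safety.** The same importance/collinearity quantities are
computed with respect to the core predictions (max/min/mean of
$p_{MC}$), normalized by the prediction magnitude, which makes
$\delta^p$ a relative (elasticity-like) influence measure — predictions
have no measurement $\sigma$. A candidate is fixed only if
$\delta^p < t_i$ (it barely moves the prediction) or it is
prediction-collinear ($\gamma^p \ge t_c$) with a parameter that stays
free (the retained partner can express the same prediction variation).
Otherwise fixing it would fictitiously shrink the prediction
uncertainty, so it is retained and the next candidate is considered; if
no candidate can be fixed safely the loop stops and flags the report.
The exact boolean form of this check is a design choice of this package;
other consistent readings exist. An optional threshold `t_u` on the
prediction-uncertainty half-width is reported but never gates the
pipeline — whether an uncertainty is acceptable is a clinical, not an
algorithmic, judgment.

On the packaged model with the full 15-observable set the loop typically
fixes `C_V` (collinear with `q_sbv`: both set the preload state) and
`R_par` (collinear with `E_RVa`: both shape the right-heart/pulmonary
offset), retaining 9–10 of the 12 candidates.

## Optimisation and sampling

The genetic algorithm is real-coded with tournament selection (size 3),
BLX-0.5 crossover, per-gene Gaussian mutation (SD 5% of the box width,
rate 0.2), elitism of 2, and clip-to-box bound handling (the prior is
uniform on the box, so clipping introduces no bias worth correcting).
Candidates with failed forward solves get infinite cost. Defaults are
population 100 for 300 generations with a 50-generation stall stop; the
packaged pipeline uses population 36 × 40 generations for the reduction
refits, which reliably reaches the basin that the subsequent MCMC then
explores. Identical seed and configuration reproduce the trajectory
bit-for-bit.

MCMC is the affine-invariant ensemble ("stretch move") sampler: each
walker proposes against a partner from the complementary half of the
ensemble with scale $z \sim g(z) \propto 1/\sqrt z$ on $[1/a, a]$,
accepted with probability $\min(1, z^{d-1} e^{\Delta \log p})$. The
scale is $a = 2$ and the ensemble has 32 walkers regardless of
dimension. Walkers initialize at the GA optimum perturbed by
$\mathcal N(0, (0.01\,\theta^*)^2)$ per coordinate, redrawn until inside
the box with a successful solve. The prior is uniform on the
physiological box, so the log-posterior is $-\tfrac12\,\mathrm{cost}$
inside and $-\infty$ outside.

**Convergence** is tested per parameter with the Geweke diagnostic:
$Z = (\bar x_\mathrm{first} - \bar x_\mathrm{last}) / \sqrt{\hat
s_\mathrm{first} + \hat s_\mathrm{last}}$ comparing the first 10% and
last 50% of the post-burn-in chain, with each segment-mean variance
estimated from the spectral density at zero frequency (AR model, AIC
order — the classical estimator). For ensemble chains the Z statistic is
computed from the per-step ensemble means: these have exactly the same
segment means as the flattened walker-interleaved series, but the
spectral estimate then sees the true between-step autocorrelation.
Estimating the spectrum directly on the interleaved series with a short
lag window drastically underestimates the variance (walkers decorrelate
within a step, steps do not) and produced order-of-magnitude inflated
$\lvert Z\rvert$ on otherwise healthy chains. The pipeline passes when
every parameter has two-sided $p > 0.05$. Two caveats are inherent to
this criterion. First, under perfect convergence the minimum of ~10
uniform p-values falls below 0.05 in roughly a third of runs, so
occasional failures are expected behaviour of the diagnostic itself.
Second, weakly-constrained parameters (here the terminal resistances
whose only direct measurements carry 30–50% CVs) have broad,
heavy-tailed posteriors on which the ensemble mean moves with
integrated autocorrelation times of hundreds of ensemble steps; when
the early segment of the retained chain is comparable to that
autocorrelation time, the Z statistic detects residual drift even while
posterior summaries, credible-interval coverage, and predictions are
already stable. A failed Geweke flag should therefore prompt inspection
of the trace plots and, if needed, longer chains - the pipeline reports
it and retains the chains rather than discarding the run.

Default chain lengths follow the reference schedule (32 × 5000, burn-in
2500). The packaged desk-scale runs use 32 × 2500 with burn-in 1250 (half the reference schedule):
the ensemble needs on the order of 1000 steps to expand from the tight
initialization ball to the posterior spread in ~10 dimensions, so
shorter runs fail the drift diagnostic for honest reasons.

## Prediction uncertainty

`sample_predictions()` draws (default) 100 parameter vectors uniformly
*without replacement* from the flattened post-burn-in samples — 100 is
far below the retained sample count, and sampling without replacement
avoids duplicate-dominated bands — simulates each, aligns the $p_{MC}$
waveforms at cycle start (a simple deterministic reference; valve-event
alignment was not needed at fixed heart period), and reports pointwise
mean/SD/2.5–97.5 percentiles plus per-sample max/min/mean summaries.
Draws whose forward solve fails are replaced and counted; more than 50%
failures aborts, since that means the posterior mass sits on a failure
region. The "95% confidence interval" is the equal-tailed empirical
percentile interval with the default (type 7) quantile interpolation —
stated explicitly because percentile conventions differ; `{1,...,100}`
yields (3.475, 97.525). The central value reported is the
posterior-sample median (the best-fit simulation is available separately
from the pipeline result). Half-widths `(upper − lower)/2` are reported
in kPa and mmHg.

Because no model-discrepancy term is included, this uncertainty reflects
parameter estimation only and is a lower bound on the true predictive
uncertainty.

## The synthetic-patient generator

`generate_patient()` defines the study conditions for every test:
simulate the model at a known true parameter vector (default: the
nominal table), then apply independent multiplicative Gaussian noise
$z_i = f_i\,(1 + \mathrm{CV}_i\,\xi)$, $\xi \sim \mathcal N(0,1)$, per
observable, with the default CV table above. Multiplicative noise
matches the CV definition of $\sigma$ relative to the measurement.
Positivity is enforced by resampling $\xi$ (not clipping, which would
pile mass at zero). `preset_patients()` provides three
missing-data patterns seen in practice: the full 15-observable set, a
set without `min(q_la)`, and a set without both LV volume extrema.

What the generator does *not* emulate: inter-observable noise
correlations (max and min volumes traced from the same image are surely
correlated; independence is assumed), model mismatch (the synthetic data
come from the same equations that are fitted — real data do not), and
acquisition artefacts. Passing tests therefore demonstrate correctness
of the machinery and recoverability under the stated noise model, not
clinical accuracy.

## Numerical choices and degenerate inputs

* Solver: `lsoda`, rtol $10^{-7}$, atol $10^{-12}$, ≤ 40 cycles.
* Sensitivities: forward differences, relative step $10^{-3}$, halved on
  solve failure (4 attempts); zero-valued parameters are an error (the
  relative normalization is undefined).
* $\gamma$ for a zero-importance column is `NA` — such a parameter is
  handled by the importance rule instead.
* GA with an entirely infeasible initial population resamples once, then
  errors with advice to revise the bounds.
* Degenerate (zero-variance) chains make the Geweke test error rather
  than return a spurious pass.
* All randomness is confined: every stochastic function takes a seed or
  a seeded config, a run restores the caller's RNG state, and the
  pipeline fans one global seed out to fixed per-stage seeds.

## Problem sizes used in the packaged runs

The test suite and the acceptance script run the full pipeline once on a
synthetic patient at these sizes, chosen as the package's desk-scale
defaults: GA population 36 × 40 generations (stall 15) per reduction
iteration; 32 walkers × 2500 steps (burn-in 1250); 100 prediction draws;
recovery properties at 4 free parameters with 600-step chains. A full
clinical-scale run simply raises these to the reference schedule
(population 100 × 300; 32 × 5000, burn-in 2500).

## Known limitations

* Identifiability is *local* (one linearization point per iteration);
  global structural identifiability is out of scope.
* The reduced topology lumps the cerebral circulation into one arterial
  compartment; $p_{MC}$ is its pressure, so intra-cerebral wave
  propagation is not represented.
* Fixed heart period per patient; no baroreflex or autoregulation.
* The Geweke minimum-p criterion over many parameters is conservative by
  construction (multiplicity), as discussed above.
* Uniform box priors can slow MCMC convergence relative to informative
  priors; the walker count (32) is fixed by design even when
  $2 d < 32$ would allow fewer.
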