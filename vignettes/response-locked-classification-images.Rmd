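---
title: "Response-locked classification images: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-locked classification images: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a speeded detection task an observer watches two adjacent fields of
flickering one-dimensional luminance noise and presses a button as soon as a
target — a luminance increment whose contrast ramps up slowly — is seen in
one of them. A classification image (CI) correlates the recorded noise with
the behavioral response to map which parts of the stimulus, at which times,
drove the decision. Because the observer responds *during* the stimulus,
the informative alignment is not stimulus onset but the response itself:
this package computes CIs locked backward from the reaction time, the
associated *impact curves* (the CI averaged over designated bars), their
reaction-time-split variants, and fits a mechanistic observer model to them.

No public trial-level human data exist for this paradigm, so the package is
organized around a synthetic-data front door: a stimulus generator that
reproduces the experimental displays, and a model observer that produces
choices and reaction times with the statistical structure the analysis
assumes.

## The stimulus generator

`stimulus_config()` defaults describe the experiment the package emulates:
two 4.8 × 4.8 deg fields of 16 vertical bars (0.3 deg each) whose contrasts
refresh at 30 Hz as independent Gaussian noise with RMS contrast 0.1, for
8000 ms (240 frames). On one side a target increment is added to the two
central bars; its Michelson contrast follows

$$\log_{10} C_{\mathrm{target}}(t) \;=\; \min(\alpha t - 3,\; 0),$$

with `t` the frame index from onset and ramp rate `α ∈ {0.05, 0.1, 0.2}`
per frame: the target starts three log units down (contrast $10^{-3}$) and
saturates at full contrast at `t = 3/α`. Combined contrasts are clipped to
[−1, 1]; the *noise-only* record is kept untouched, because the reverse
correlation must correlate noise — not noise plus the deterministic ramp —
with the response. Two conventions here were genuinely open:

* the logarithm's base is taken as 10, making the initial contrast
  $10^{-3}$, a standard sub-threshold starting point;
* the target occupies the two central bars (indices 8 and 9), since a
  16-bar field has no single central bar and the impact curves average "the
  central two bars". Both are configurable.

Spatial filters are parameterized in 0.04-deg pixels, so
`rasterize_to_samples()` expands each field onto a 120-sample grid
(`floor(i / 7.5)` mapping, alternating 7- and 8-sample bar widths). Any
fixed deterministic convention works here — the analysis and the fit are
self-consistent under it — and averaging samples within a bar returns the
bar contrast exactly.

## The model observer

The perceptual front end is a space–time separable linear filter. Space is
a difference of Gaussians,

$$F_s(x) = e^{-x^2/2\sigma_c^2} - \frac{\sigma_c^2}{\sigma_s^2}
  e^{-x^2/2\sigma_s^2},$$

and time a biphasic cascaded-integrator impulse response,

$$F_t(t) = \left(\frac{1}{n!} - B\,\frac{(t/\tau)^2}{(n+2)!}\right)
  (t/\tau)^n e^{-t/\tau},$$

applied by causal convolution (`filter_response()`). Momentary evidence is
the difference of spatially pooled absolute responses,
$\Delta R(t) = \sum_x |R_L(x,t)| - \sum_x |R_R(x,t)|$, accumulated leakily
with additive internal noise until $|S(T)|$ reaches the bound $b$; the
button press follows after a fixed 250 ms motor delay. Crossings whose
reaction time would exceed the 8000 ms response deadline are recorded as
timeouts, and timeout and error trials are retained (flagged) in the log —
the analysis excludes them itself, as the experimental procedure did.

### Units and normalization conventions

The shipped defaults are fitted constants for an observer performing this
task: `σc = 4.15`, `σs = 17.4` (pixels), `n = 5`, `τ = 1.360`, `B = 0.47`,
`γ = 0.046`, `b = 496.5`, `ε = 49.6`. Three conventions fix how those
numbers enter the computation. They were selected once, by requiring that
this parameter vector reproduce the behavior such an observer shows
(error rates of a few percent; mean reaction times near 1.9, 1.2 and 0.9 s
for α = 0.05, 0.1, 0.2; a biphasic central impact curve peaking ~300 ms
before the response; reaction-time-split curves whose positive lobe
dominates fast trials and negative lobe slow trials), and then frozen:

1. **Temporal filter time base.** `τ` is in display-refresh units
   (16.7 ms; the stimuli are shown on a 60 Hz monitor whose noise refreshes
   every second frame). The discrete kernel samples $F_t$ at every second
   refresh (`temporal_kernel(step = 2)`). Parameterizing `τ = 1.36` in
   33-ms noise frames instead slows the impulse response twofold and
   pushes the kernel peak and trough ~100–150 ms too late.

2. **Unit peak gain.** The temporal kernel is normalized to the peak of the
   continuous impulse response. $F_s$ and $F_t$ carry no free gain
   parameter, so the scale of `b` and `ε` is only meaningful relative to a
   fixed filter normalization; a gain `g` on the filter is exactly
   equivalent to dividing both `b` and `ε` by `g`. Unit peak gain puts
   filter outputs on the stimulus contrast scale and is the convention
   under which the shipped `b` and `ε` give sensible dynamics; with the
   raw (un-normalized) kernel the internal noise would be an order of
   magnitude stronger than the stimulus-driven evidence and the observer
   would behave near chance with α-independent reaction times.

3. **Leak rate, not retention.** `γ` is the per-frame *leak rate*: the
   accumulator retains `1 − γ` of its evidence each frame
   (`accumulate_evidence()` itself takes the retention factor). Read
   instead as a retention factor of 0.046, the accumulator would have a
   memory below one frame, which abolishes the reaction-time dependence of
   the kernels — the signature phenomenon here, which arises precisely
   because slow trials give the delayed negative filter lobe and the leak
   time to act. The default leak, `1 − 0.046` per 33-ms frame, has a time
   constant of ~720 ms.

Internal noise enters *inside* the leaky sum by default
($S(T) = \sum_t \gamma_{\mathrm{ret}}^{\,T-t}(\Delta R(t) + \epsilon_t)$);
the variant with an undiscounted noise random walk is available via
`leak_noise = FALSE`. The default keeps error rates at the few-percent
level observed in practice; the random-walk variant drives them above 15%
at the slowest ramp because an unbounded noise walk eventually dominates
the bounded leaky evidence.

Evidence is evaluated on the 33-ms frame grid with no sub-frame
interpolation of the crossing. The discrete temporal kernel is truncated
where it falls below $10^{-6}$ of its peak (a few tens of frames), bounding
convolution cost with no visible effect at double precision.

## The response-locked analysis

`response_locked_kernel()` mirrors every correct trial onto a canonical
orientation (chosen side vs unchosen side; errors and timeouts are
excluded, so the chosen side is the target side) and averages the
noise-only contrast at each bar and each look-back lag:
$\mathrm{kernel}(x, \ell) = \mu_1(x,\ell) - \mu_0(x,\ell)$. Lag 0 is the
frame in which the boundary was crossed, recovered from the logged reaction
time by subtracting the motor delay; the lag axis is reported in ms
*before the button press*, i.e. `lag × 33.3 ms + 250 ms`, so simulated and
button-press-locked axes coincide. Trials too short for a given look-back
drop out of that lag, so per-lag counts shrink backward in time; cells with
fewer than `min_count = 10` trials are masked as missing rather than
zeroed. The default look-back of 36 frames (~1.2 s plus the motor delay)
covers the informative range at the slowest ramp.

`impact_curves()` averages the kernel over the two target bars (and their
flankers), `rt_split()` forms the overlapping short/intermediate/long
groups (percentile windows [0, 50], [25, 75], [50, 100], computed within
each α condition, ties broken by trial position), `variance_kernel()`
repeats the analysis on squared contrasts, and `rt_summary()` reports log-
and linear-scale reaction-time means with a cumulative distribution.
`average_kernels()` provides unweighted across-observer averaging with
standard errors.

## Simulation-based fitting

`fit_parameters()` minimizes the squared difference between model and
target impact curves over any subset of the seven constants (`n` stays
fixed), by Nelder–Mead in transformed
coordinates (log for positive scale parameters, logit for `γ`, linear for
`B`) with perturbed restarts (each restart starts at the base vector times
independent U[0.5, 2] factors, so recovery runs never start at the truth).
Invalid vectors incur a finite penalty instead of an error so the simplex
can roam.

Three choices make the stochastic objective well behaved:

* **Common random numbers.** The stimulus set and the internal-noise
  streams are frozen in an `objective_context()`, so the objective is a
  deterministic function of the parameters.
* **Fitting on the target's own stimuli.** When target curves come from a
  trial log, the fit simulates the model observer on the *same stimulus
  movies* (rebuilt from the logged seeds). The Monte-Carlo wiggles of the
  target curves produced by stimulus sampling are then shared with the
  model curves and cancel in the difference; fitting on fresh stimuli
  roughly doubles the effective noise floor.
* **Replicate averaging.** Model curves are averaged over `n_reps`
  internal-noise replicates per evaluation. The expensive filter stage
  depends only on the parameters and runs once; accumulation, crossing
  detection and kernel estimation are cheap and run per replicate. This
  suppresses the model-side simulation noise well below the target's.
* **Which curves enter the objective.** The default target
  (`target_curve_set()`) pools four curves: the full-data central and
  adjacent impact curves — the adjacent curve constrains the surround
  scale — plus the central curves of the short- and long-reaction-time
  halves. The split curves are what identify the leak rate `γ`: the
  full-data curves are nearly flat in `γ` at realistic trial counts
  (recovery under a two-curve objective converges tens of percent away
  from the truth with a *better* objective value than the truth), whereas
  the short-minus-long difference is driven by the leak directly. A plain
  `impact_curves()` target is still accepted and falls back to the
  two-curve comparison.

With these in place, a ±20% change in `σc`, `B` or `γ` moves the curve
vector by 2–4 times the residual noise of a 2000–3000-trial target, which
is what makes recovery to within ±20% feasible at all; without stimulus
sharing and replicate averaging the objective profile is flat within ±50%
of the truth at the same trial counts. `b` and `ε` trade off against each
other (both scale the decision stage), so their recovery is inherently
looser. `parameter_recovery()` packages the whole loop — simulate, analyze,
refit on the experiment's stimuli with fresh internal noise, report
relative errors.

## Problem sizes used by the shipped checks

The test suite validates kernel phenomenology on a 6000-trial simulated
experiment at α = 0.05, reaction-time ordering on 800 trials per ramp rate,
and parameter recovery of the reduced set {`σc`, `B`, `γ`} from a
3000-trial experiment with 6 noise replicates and 100 evaluations per
restart; these sizes give per-cell kernel standard errors near 0.0013 and
recovery precision of a few percent to ~15%, and were chosen as a
precision/runtime balance for routine validation. The full 7-parameter fit
uses the same machinery (`fit_config()` defaults) and is simply a longer
run of the same search.

## What the generator does and does not emulate

The synthetic data reproduce the stimulus statistics (independent Gaussian
bar noise, the contrast ramp, the clipping), the trial protocol (balanced
sides, response deadline, error/timeout exclusion) and a mechanistically
plausible observer. They do not emulate: luminance calibration or monitor
gamma, the 60 Hz frame interleaving of the physical display, lapses or
attention fluctuations, variable (non-constant) motor delay,
response-side biases, or any learning across sessions. Passing tests
therefore certify the estimators and the model pipeline — not that a human
observer obeys this model; with real logs the analysis functions apply
unchanged (`read_trial_log()` accepts any log matching the schema), but
motor-delay misspecification shifts the lag axis by its error, and
perceptual nonstationarity would smear the kernels.

## Known limitations

* The absolute scales of `b` and `ε` are convention-bound (see above);
  comparing them across implementations requires matching the filter
  normalization.
* Boundary crossings are detected at frame resolution; reaction times are
  quantized to 33.3 ms plus the motor delay.
* The kernel's negative lobe is shallow and broad at the default
  parameters; locating its minimum needs several thousand trials before
  the lag-of-minimum stabilizes, and its location is more variable
  than the positive peak's.
* Likelihood-based fitting of full reaction-time distributions,
  hierarchical across-observer fitting, and bootstrap uncertainty are out
  of scope (hooks exist: the objective machinery accepts any target
  curves).
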