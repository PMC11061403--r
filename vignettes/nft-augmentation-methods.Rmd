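---
title: "Model-based augmentation of motor-imagery EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based augmentation of motor-imagery EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Motor-imagery brain-computer interfaces classify short EEG epochs into
imagined-movement conditions. Their weak spot is data hunger: a usable
classifier needs more calibration epochs than users enjoy providing. This
package enlarges a small training set with *artificial* epochs generated
from a physiological model of the EEG itself, and quantifies whether the
enlargement actually buys classification accuracy.

This vignette explains the model, the estimation machinery, the evaluation
protocol, and the design decisions that were genuinely open, in that order.
It states no empirical result that the package's test suite and
`scripts/acceptance.R` do not themselves recompute.

## The corticothalamic model

The generative model is a neural field model of the corticothalamic system
with four populations — cortical excitatory (*e*) and inhibitory (*i*)
neurons, thalamic relay (*s*) and reticular (*r*) nuclei — driven by sensory
input noise. Each population's mean soma potential is a sum of dendritically
filtered afferent activity; the firing response is a sigmoid in the
potential; and the excitatory cortical field propagates as a damped wave.
Signals traversing the cortex–thalamus loop are delayed by half the loop
delay `t0` in each direction.

Linearizing about the stable low-firing steady state and Fourier
transforming collapses the model onto a small set of dimensionless gains:
the cortical gains `G_ee > 0` and `G_ei < 0`, and three loop gains —
excitatory corticothalamic `G_ese`, inhibitory corticothalamic `G_esre`, and
intrathalamic `G_srs`. Together with the synaptic decay and rise rates
`alpha`, `beta` (1/s), the loop delay `t0` (s), the cortical damping
`gamma_e` (1/s) and the excitatory axonal range `r_e` (m), these fully
determine the shape of the EEG power spectrum. `nftda` stores exactly this
parameterization (`ctm_gains()`): individual connection gains are *not*
identifiable from a power spectrum, only their loop products are, and one
overall `amplitude` absorbs the input gain and drive power. The full
nonlinear parameterization (`physio_params()`) remains available and
`gains_from_physio()` / `physio_from_gains()` convert in both directions
under a canonical factorization of the loop products; any factorization
that preserves the loop gains yields the same spectrum, which is why the
choice is free.

`analytic_spectrum()` evaluates the closed-form transfer function of the
excitatory field on a rectangular cortical sheet (default 0.5 m x 0.5 m)
and sums squared magnitudes over discrete spatial modes, low-pass filtered
by volume conduction (`F(k) = exp(-k^2/k0^2)`, `k0 = 10` per metre).
These sheet constants are not critical: the filter suppresses modes so fast
that the sum is converged to well below 0.1% band power by truncation order
8 (an acceptance check). Sheet size, filter scale, damping and axonal range
follow the neural-field literature and are configurable; they are flagged
in `spectrum_grid()` and `ctm_gains()` docs as literature-typical rather
than fitted.

The default operating point (`ctm_gains_default()`) is a relaxed-wakefulness
set with a clear alpha resonance near 9 Hz and a beta harmonic near 18 Hz.
It was chosen once, by two requirements: a pronounced sensorimotor-band
structure, and a comfortable margin from the loop's bifurcation (see
*Stability screening*). The known directional effects hold for it and are
asserted as tests: shortening `t0` moves both resonances up in frequency,
reducing `gamma_e` lowers and left-shifts the alpha peak, and halving
`alpha` drains band power with the largest relative loss above 20 Hz.

## Simulating source signals

`simulate_source()` generates artificial cortical source activity from a
gain set by two interchangeable routes:

* **Time domain** (`method = "time_domain"`): semi-implicit Euler
  integration of the linearized delay-differential system (the two
  second-order dendritic equations per population, the damped-oscillator
  field equation, circular delay buffers of `t0/2`), driven by white noise
  scaled by `1/sqrt(dt)` so the driving spectral density is step-size
  invariant. The step (default 0.1 ms) is shrunk so the half-loop delay is
  an integer number of steps. Output is anti-alias filtered and resampled
  to 250 Hz.
* **Spectral synthesis** (`method = "spectral_synthesis"`): independent
  complex Gaussian Fourier coefficients with expected squared magnitude
  proportional to the analytic spectrum, inverse transformed. This realizes
  exactly the model's second-order statistics, unconditionally.

The two routes agree: over 300 s, the Welch spectrum of either matches the
uniform-mode analytic spectrum to within 10% mean relative band error, and
they match each other (acceptance check). Spectral comparisons use the
uniform-mode (`m_max = 0`) analytic spectrum because the simulator runs the
spatially uniform mode; the spatial sum only rescales and mildly reshapes
sensor-level spectra, and all downstream calibration is band-power based.

Two numerical caveats shaped the defaults. First, sharp resonances leak
badly under rectangular windows, so simulator validation uses a Hann-taper
Welch estimator (`welch_spectrum()`); the rectangular per-epoch
periodogram (`epoch_average_spectrum()`, Parseval-consistent normalization)
remains the fitting-path estimator because fitting targets are epoch
averages, not long continuous records. Second, a linear delay system can be
*weakly* unstable (growth times of tens of seconds) while its real-axis
spectrum looks perfectly finite; the augmentation and cohort-generation
paths therefore default to spectral synthesis, which cannot diverge, while
the time-domain route guards itself and reports the offending gain set.

## Fitting spectra

`fit_ctm_mcmc()` fits eight parameters (`G_ee, G_ei, G_ese, G_esre, G_srs,
alpha, beta, t0`) inside a literature-typical box prior, holding `gamma_e`
and `r_e` fixed — a single spectrum cannot constrain all of them at once.
The objective is the band (8–30 Hz) sum of squared log-power differences
with the amplitude profiled out in closed form, making the fit exactly
invariant to target rescaling. CSP source spectra are single-spatial-mode
signals, so source-level fits default to the uniform-mode grid.

The sampler is a random-walk Metropolis with three practical devices, each
documented because each was forced by a measured failure mode:

* **Annealing**: the acceptance temperature decays geometrically across the
  burn-in (0.03 to 1e-4 in squared-log10 units) and stays cold after. A hot
  chain hops between resonance-comb basins; a cold chain refines the point
  estimate. At a fixed unit temperature the chain wandered (3–4% band shape
  error on noise-free targets).
* **Joint proposals**: alongside single-site updates, a full-vector
  proposal along the chain's running covariance (classic adaptive
  Metropolis). The profiled objective has a narrow curved ridge in which
  `t0` trades against the synaptic rates; single-site moves stall on it.
* **Delay profiling** (`refine = TRUE`): after sampling, a warm-started
  BFGS walk steps `t0` across its prior while re-optimizing the remaining
  parameters at each step, then a fine walk brackets the best slice. The
  ridge contains adjacent micro-basins ~1.5 ms apart; samplers and one-shot
  local optimizers end in the nearest one, while the profile walk follows
  the ridge floor to the true basin. With it, noise-free recovery of `t0`
  is sub-millisecond across seeds.

Convergence is flagged (advisory) by split-chain potential scale reduction
on `t0` and `alpha`. A 72-epoch target's periodogram carries an irreducible
per-bin noise of about 12% (1/sqrt(72)), so recovery quality on noisy
targets is measured against the *true* generating spectrum, where the fit
lands well inside 10%; the misfit against the noisy target itself cannot
fall below its ~11% noise floor and is reported alongside.

## Stability screening

Fits and jitter draws must avoid parameter sets near a bifurcation, where
the spectrum changes qualitatively. The screen (`stability_check()`)
evaluates the *resonance enhancement factor* — the spectrum divided by the
open-loop (gainless) spectrum of the same synaptic and propagation
parameters — on a dense 0.5–45 Hz grid, and rejects a set when the factor's
peak-to-median ratio exceeds a ceiling (default 5). The division is what
makes the proxy meaningful: the raw spectrum conflates resonance sharpness
with the steepness of the dendritic low-pass, rejecting quiet low-`alpha`
sets and passing genuinely unstable ones. The enhancement ratio is ~1 for
weak feedback regardless of `alpha`, grows rapidly toward the bifurcation,
and its default ceiling sits where long time-domain integrations of the
default family empirically begin to diverge (excitatory loop gain around
8). The screen is a proxy, not a proof: it is not exactly monotone under
rescaling all loops at once (rescaled loops can realign a sharp resonance),
and the property tests assert only what holds — deep attenuation always
restores acceptance, and the default family is monotone.

## The classification pipeline

The pipeline mirrors standard motor-imagery practice: zero-phase 8–30 Hz
Butterworth band-pass; two-class common spatial patterns from
trace-normalized per-epoch covariances (whitening plus eigendecomposition),
keeping `2 * ceiling(1 + n_conditions/2)` components, half from each end of
the eigenvalue spectrum; one feature per component per epoch — total power
(mean square; identical to its unitary-transform frequency-domain form by
Parseval) or the Higuchi fractal dimension (curve-length log-log slope over
scales 1..10, returned with the sign convention ramp = 1, white noise = 2);
and a pooled-covariance linear discriminant with a small conditioning ridge
(1e-6 of the trace). Accuracy is always balanced accuracy, the mean of
per-condition recalls.

The Higuchi slope sign deserves one line: the raw least-squares slope of
`log2 L(n)` on `log2 n` is negative for fractal signals, so the estimator
returns its negation, giving the standard convention (exactly 1 for a
straight ramp — an identity the tests assert — and 2.0 +/- 0.1 for white
noise).

## Augmentation

`nft_augment()` works at the level of CSP sources, not channels: for every
(condition, component) pair of the *training fold only*, the epoch-averaged
source spectrum is fitted, source signals are simulated from the fitted
parameters, band-pass filtered exactly like the real sources, calibrated so
their 8–30 Hz band power matches the fitted spectrum, and cut into epochs
of the training epoch length. The calibration step is mandatory: the
total-power feature is scale dependent, and without the band-pass the
artificial sources would carry out-of-band power the real (filtered)
sources lack — in development this single omission turned the augmentation
benefit negative.

Optional jittering perturbs `alpha`, `gamma_e` and/or `t0` (never the loop
gains, which risk bifurcation) with zero-mean Gaussians of spread 1.5 times
the field-typical values (14/s, 25/s, 3 ms respectively), drawing
`10 * factor` parameter sets and cycling them round-robin over the required
epochs, one continuous simulation per draw. Unstable draws are redrawn,
with a bounded retry budget. For jittered draws the jittered-to-fitted
analytic band-power ratio is applied on top of the calibration, so jitter
changes shape and shape-driven power changes survive.

The feature-space baseline (`noise_augment()`) draws synthetic feature rows
from a per-condition Gaussian with 1.5 times the sample covariance — the
naive comparison method. One convention note: for signal-level jitter the
1.5 factor inflates the standard deviation; for the feature-space baseline
it inflates the covariance, following the respective conventions of each
procedure's description.

## Evaluation protocol

`inverse_cv()` implements the deliberately data-starved protocol: a
stratified three-way partition in which each fold *trains* once (CSP fit,
spectral fits, augmentation and classifier training all see only that
fold) and the other two validate. `full_cv()` is the regular stratified
7-fold reference. Validation epochs are never touched by any fitted
component; every rotation's index partition is returned as an audit trail
and asserted disjoint in tests. `run_benchmark()` assembles per-subject
full/small/augmented accuracies, drops subjects with no assessable headroom
(full or small accuracy at chance, or small above full), and reports
per-strategy means with two-sided paired t-tests against both baselines.
`proficiency_grid_search()` sweeps a minimum-baseline-accuracy threshold
and reports the one that maximizes the number of significantly improved
strategies, with ties going to the lowest threshold.

Open choices resolved here: fold partitions are stratified by condition
(unstratified partitions of 24-epoch training sets degenerate too easily);
a single seeded partition is used per subject (repeats are available by
seed); t-tests are two-sided; and equality `small == full` is retained by
the subject filter since such a subject still has headroom to lose.

## The synthetic cohort

`make_cohort()` generates fully synthetic two-condition subjects with the
geometry of a standard motor-imagery benchmark: 72 epochs per condition,
2.5 s epochs, 22 channels, 250 Hz. Two mirrored discriminative sources
(active in one condition, idle in the other) and one shared background
source are simulated from the corticothalamic model and mixed into channels
through fixed smooth topographies plus white sensor noise. The class
contrast is planted *through the model parameters* — the active state has
a 10 ms shorter loop delay and 40% larger amplitude than the idle state —
so the generating process lies inside the model family the augmentation
fits, enabling clean parameter-recovery and benefit tests. Per-subject
parameter offsets (2 ms delay s.d., 8% log-amplitude s.d.) and a
sensor-noise ladder spanning 0.5-2.75 times the base level produce
full-set accuracies from near ceiling down to ~0.6, exercising the subject
filter and the proficiency search. These contrast and noise levels were
fixed once, when the generator was designed, and are part of the shipped
defaults.

What the cohort does *not* emulate: eye blinks and muscle artifacts,
nonstationarity within a session, volume-conduction correlation structure
beyond the smooth mixing patterns, and model mismatch (real EEG is not a
linear corticothalamic process). Passing benefit tests on this cohort
therefore show the machinery is correct and the method works where its
model assumptions hold — not that it will transfer to any particular
recording.

## Problem sizes and reproducibility

Every stochastic step takes an explicit integer seed, and same-seed runs
are bit-identical, including the full augmentation path. The shipped
problem sizes — 300 s spectral-agreement runs, 20 000-sweep reference fits,
5 000-sweep fits (2 chains) inside augmentation, a 12-subject cohort with
factor-2 augmentation under inverse 3-fold CV — were chosen so the whole
evidence chain recomputes in minutes on a single core while leaving each
check comfortable statistical margin; all of them are configuration, not
constants.

Known limitations: multi-class CSP is out of scope (two-condition designs
only); the fit holds `gamma_e` and `r_e` fixed; the Higuchi-feature path is
implemented and tested but, consistent with the method's phase-blind
fitting, no benefit claim is made for it; and absolute spectral calibration
is meaningful only relative to the fitted amplitude, as all comparisons are
band-power or shape based.
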