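---
title: "Inferring pressure-to-oxygenation coupling functions from phase dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pressure-to-oxygenation coupling functions from phase dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cacoupling)
```

## The model

Cerebral autoregulation is interrogated here through the *phase* interaction
between two oscillatory signals: beat-wise mean arterial pressure (MAP) and
cortical oxyhemoglobin (ΔHbO₂) measured by NIRS. In each physiological
frequency interval, both signals are reduced to instantaneous phases
$\phi_{MAP}(t)$, $\phi_{HbO_2}(t)$ and modelled as a pair of coupled
stochastic phase oscillators

$$\dot\phi_i(t) = \omega_i + q_i(\phi_1, \phi_2) + \xi_i(t), \qquad
\langle \xi_i(t)\xi_j(s) \rangle = 2 D_{ij}\,\delta(t-s),$$

with each coupling function $q_i$ expanded in a Fourier basis
$\{\cos,\sin\}(k_1\phi_1 + k_2\phi_2)$ up to order $K=2$: one constant
(absorbing $\omega_i$) plus 12 index pairs × two trig functions = 25
parameters per phase equation. The directional coupling strength (CS) is the
Euclidean norm of the inferred coefficients in the target's phase equation
whose index has nonzero order on the source; the coupling function itself is
evaluated on a $2\pi \times 2\pi$ grid.

## Inference

Given phases sampled at step $h$, the phase velocity is the forward
difference $\dot\phi_l = (\phi_{l+1}-\phi_l)/h$ and base functions are
evaluated at midpoint phases $(\phi_l + \phi_{l+1})/2$. The negative
log-likelihood

$$S(c, D) = \frac{L}{2}\ln|D| + \frac{h}{2}\sum_l \left[
c\!\cdot\!\frac{\partial \Phi}{\partial \phi} +
(\dot\phi_l - c\,\Phi_l)^\top D^{-1} (\dot\phi_l - c\,\Phi_l)\right]$$

is minimised by alternating closed-form updates: the noise matrix $D$ is the
residual covariance, and for fixed $D$ the Gaussian posterior over $c$ has
concentration $\Xi = \Xi_{prior} + h\,\Phi^\top D^{-1} \Phi$ and mean
$\Xi^{-1}\Gamma$, iterated until the relative change in $c$ drops below
$10^{-6}$ (cap 100 iterations, with a warning on non-convergence).
`infer_time_evolving()` runs consecutive windows and propagates each
posterior into the next prior after inflating its covariance diagonally by
$(\text{propagation} \times c)^2$, so parameters may drift between windows.
Because the first window is fitted without an informative prior its estimate
is a transient; when the pipeline averages CS over windows it drops that
first window as burn-in (`coupling_strength(..., burn_in = 1)`), for the
observed CS and for every surrogate alike.

Correctness is anchored by an independent oracle: for fixed $c$ the optimal
$D$ is closed-form, and substituting it collapses the quadratic term to a
constant, leaving a profiled objective
$S^*(c) = (L/2)\ln|D(c)| + L + (h/2)\sum c\cdot\partial\Phi/\partial\phi$
that `infer_window_direct()` minimises with a generic quasi-Newton optimizer.
On 200-sample problems the recursion and the direct minimizer agree to
better than $10^{-8}$ per coefficient.

## Numerical choices

* **Under-determined windows.** A window carrying only one or two cycles of
  a slow band, or a phase-locked pair whose phase difference barely moves,
  leaves near-null directions in $\Xi$: a plain solve then returns huge,
  meaningless coefficients. Whenever the reciprocal condition number falls
  below $10^{-4}$, linear systems are solved by truncated SVD (singular
  values below $10^{-4}$ of the largest are dropped), i.e. the minimum-norm
  solution on the identifiable subspace; the model is flagged
  `regularized`. Well-conditioned problems (rcond $\sim 10^{-1}$ in
  practice) are untouched. Because surrogates pass through the identical
  estimator, significance comparisons remain fair.
* **Window lengths.** `infer_time_evolving()` defaults to 50 s windows with
  propagation 0.2 (≥ 10 windows on a 10-minute record), appropriate for
  detuned pairs and for tracking coupling changes. For the per-cell CS in
  `run_subject()` the windows are half the usable record: within-band
  MAP/HbO₂ pairs are typically phase-locked, and only long windows
  accumulate enough phase-difference exploration for the $K=2$ basis to be
  identifiable — 50–100 s windows both starve the coupled-cell estimate and
  inflate null-cell estimator variance, making CS magnitudes incomparable
  across cells. The trade-off is temporal resolution of the coupling, which
  the windowed API still provides when asked.
* **Degenerate noise.** In the noise-free exact-model limit $D \to 0$; a
  relative jitter of $10^{-12}$ keeps it invertible, and non-finite
  iterates abort the recursion returning the last sane iterate.
* **Edges.** The first and last 10 s of filtered records, and one period of
  each band's lower edge (cone of influence), are excluded from inference.

## Wavelet phases

The analytic Morlet wavelet with centre frequency $f_0 = 1$ (cycle
convention, Gaussian envelope of one period SD) is applied on a logarithmic
grid of 16 voices per octave, normalized so equal-amplitude tones give
equal-magnitude ridges. The band phase is the argument of the
amplitude-weighted sum of complex coefficients across the interval's
frequencies — robust to ridge jumps, and exact for a single tone (phase
velocity error below $10^{-9}$ relative). If the band amplitude stays below
1% of the strongest ridge for more than half the record, the phase series is
flagged low-amplitude.

## What the synthetic data emulate — and what they do not

The generator produces (i) pulsatile ABP at 1000 Hz with an asymmetric beat
template (half-Gaussian upstroke, exponential decay with a dicrotic bump)
whose per-beat extrema equal the specified systolic/diastolic values
exactly; (ii) slow MAP modulation driven by stochastic band oscillators
(respiratory 0.25 Hz, myogenic 0.1 Hz, neurogenic 0.033 Hz, phase noise
$D = 0.01\ \mathrm{rad^2/s}$, amplitudes 1.5–2 mmHg); (iii) 24 HbO₂-like
channels at 10 Hz, each a sum of band oscillations whose phases are driven
by the MAP band phases through configurable coupling terms, plus white
measurement noise and sparse boxcar-plus-ramp movement spikes. Ground truth
(coupling coefficients, band phases, spike times) rides along as
attributes, and a JSON sidecar when written to disk.

Deliberate simplifications: no beat-to-beat heart-rate variability, no
amplitude dynamics of the band oscillations (amplitudes are free
parameters), no scalp/skull contamination of the NIRS channels, and
phenomenological phase oscillators rather than a hemodynamic forward model.
Passing tests therefore demonstrate that the *estimator chain* recovers
known phase-level coupling under realistic noise and artifacts — not that
real stroke recordings would reproduce any particular clinical contrast.

Two frequency choices deserve a note. Validation pairs use a source at
0.25 Hz against a target at 0.1 Hz: with coupling up to 0.5 rad/s the pair
stays outside the phase-locking region ($|\Delta\omega| > a$), the torus is
well sampled and the coefficient is identifiable — recovery of an injected
$0.3\sin(\phi_{MAP}-\phi_{HbO_2})$ is unbiased to ±0.01 with SD ≈ 0.01
across seeds. Inside one band (driver 0.1 Hz, target 0.065 Hz) a 0.3 rad/s
coupling *necessarily* locks the pair; there the truncated-SVD estimator
still localizes the coupled cell and its CS, and the surrogate comparison
carries the inference burden. The uncoupled cardiac oscillator is detuned
to 0.9× the heart rate so null channels do not sit exactly on the driver
frequency.

## Surrogates and significance

Surrogates rotate the wrapped increments of the *source* phase cyclically by
a random offset of at least 10 s and re-integrate: increment distribution,
mean frequency and increment autocorrelation are preserved exactly while
cross-signal alignment is destroyed. The significance rule is
$\sigma > \text{mean} + 2\,\text{SD}$ of 100 surrogate CS values (a
Fourier-style alternative was considered and rejected as it also destroys
the phase's non-Gaussian increment structure). Monte-Carlo calibration of
the rule on uncoupled pairs yields an empirical type-I rate of a few
percent; detection of $a = 0.5$ coupling exceeds 95%. The spike-repair
residual is reported as the RMS over repaired samples, the natural scale for
comparison with the measurement-noise floor.

## Group statistics

Channel-wise comparisons use the classical equal-variance one-way ANOVA
(Welch available via `oneway.test` directly), which for two groups equals
the squared two-sample t-test. The Bonferroni family is 4 intervals × 2
patient-vs-control contrasts = 8, so the corrected threshold is
$0.05/8 = 0.00625$, reported as 0.006; per-channel multiplicity is
deliberately not added because NIRS channels share global vascular signal
and are far from independent. Hemispheric comparisons are paired t-tests on
region-averaged CS, the affected hemisphere being contralateral to the
hemiparetic side. Degenerate cells (identical values in both groups) report
$p = 1$ rather than NaN.

The default channel→region map assigns channels 1–4, 5–8, … to LPFC, RPFC,
LPL, RPL, LOL, ROL; any montage can be supplied and is validated strictly
(every channel mapped once, exactly the six regions).

## Problem sizes

Validation experiments use 600-s records at 10 Hz (6000 samples), matching
resting-state recording practice; the Euler–Maruyama step is 0.01–0.02 s
for simulation (0.1 s suffices for the slow cohort oscillators), and the
cohort experiment runs 17 + 9 subjects × 24 channels × 25 replicates. The
surrogate count defaults to 100; calibration and end-to-end experiments use
the reduced 25- and 15-surrogate settings.

## Known limitations

* Within-band coupled pairs operate in the phase-locked, partially
  identifiable regime; their CS is a lower bound on the identifiable
  coupling, not an unbiased estimate of the injected coefficient.
* The windowed estimator assumes both phases are uniformly sampled and
  aligned; `run_subject()` aligns the MAP and NIRS grids to the nearest
  sample (≤ 0.05 s offset), which is negligible for bands below 2 Hz.
* The reverse direction (HbO₂→MAP) is computed and stored but reported
  secondarily; no network inference beyond oscillator pairs is attempted.
* MAT/XLSX side-files from external acquisitions are not parsed; signals
  enter as plain CSV.
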