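# cacoupling

Frequency-specific coupling-function analysis between mean arterial pressure
(MAP) and cerebral oxyhemoglobin (ΔHbO₂) oscillations — an R pipeline for
assessing dynamic cerebral autoregulation from simultaneous arterial blood
pressure and multichannel NIRS recordings.

## The problem and the method

Cerebral autoregulation (CA) keeps cortical blood flow roughly constant while
arterial pressure fluctuates. How strongly pressure oscillations drive
cortical oxygenation — and through what functional form — can be read off the
*phase dynamics* of the two signals. This package implements that analysis
end-to-end:

1. **Preprocessing** — gradient-based beat detection on the ABP waveform,
   per-beat MAP = DBP + ⅓·(SBP − DBP), cubic-spline resampling to 10 Hz,
   moving-statistics despiking, zero-phase Butterworth band-pass
   (0.005–2 Hz), z-score normalization.
2. **Wavelet phase extraction** — continuous Morlet transform on a
   logarithmic frequency grid; one instantaneous phase per signal in each of
   four physiological intervals: I cardiac (0.6–2 Hz), II respiratory
   (0.145–0.6 Hz), III myogenic (0.052–0.145 Hz), IV neurogenic
   (0.021–0.052 Hz).
3. **Dynamical Bayesian inference (DBI)** — each (MAP, HbO₂) phase pair is
   modelled as coupled stochastic phase oscillators

   φ̇ᵢ = ωᵢ + qᵢ(φ₁, φ₂) + ξᵢ(t),

   with qᵢ expanded in a Fourier basis of order K = 2 (25 parameters per
   phase equation). Parameters, their concentration matrix and the 2×2 noise
   matrix are inferred window by window, each posterior propagating into the
   next window's prior.
4. **Coupling quantification** — the coupling function
   q(φ_HbO₂, φ_MAP) is reconstructed on a 2π×2π grid, and the coupling
   strength (CS) σ is the Euclidean norm of the source-dependent basis
   coefficients, per direction (MAP→HbO₂ and HbO₂→MAP).
5. **Surrogate significance** — each CS is compared against 100
   phase-randomized surrogates (cyclic rotation of phase increments); a CS is
   kept only if it exceeds the surrogate mean + 2 SD.
6. **Group statistics** — channel-wise one-way ANOVA between groups, paired
   affected/unaffected hemisphere t-tests on region-averaged CS, Bonferroni
   correction over the 4-interval × 2-contrast family (threshold
   0.05/8 = 0.00625, reported as 0.006), and region/group-averaged coupling
   surfaces.

A first-class synthetic-data module generates every input with known ground
truth — coupled stochastic phase oscillators, pulsatile ABP waveforms with
slow MAP modulation, and artifact-contaminated 24-channel HbO₂-like
recordings — so the whole pipeline is validated against injected truth.

## Worked example

```r
library(cacoupling)

# a synthetic subject: MAP->HbO2 coupling only at channel 8, interval III
subject <- simulate_subject(
  coupling = data.frame(channel = 8, interval = "III", coefficient = 0.3),
  n_channels = 24, duration = 600, seed = 1
)

cfg <- pipeline_config(surrogate = list(n = 15))
res <- run_subject(subject$abp, subject$hbo2, cfg, subject = "demo")

cs <- res$cs[res$cs$direction == "map->hbo2" & res$cs$significant, ]
cs[order(-cs$sigma), c("channel", "interval", "sigma", "threshold")]
```

```
  channel interval      sigma  threshold
1       8      III 0.26545524 0.16854079
2       3        I 0.13891666 0.13058924
3      23        I 0.11451302 0.11190414
4      19        I 0.09836114 0.09657666
5       1       II 0.06642432 0.05315400
```

The injected cell (channel 8, interval III) carries the largest significant
MAP→HbO₂ coupling strength — its σ ≈ 0.27 rad/s sits close to the injected
coefficient 0.3 and well above its surrogate threshold, while the remaining
entries are borderline null cells flagged at roughly the type-I rate of the
mean + 2 SD rule. `autoplot(res$surfaces[[8]]$III)` draws the reconstructed
coupling function for that cell, and a cohort of such subjects feeds
`run_cohort()` for the group comparison tables.

At the phase level, a single pair shows the estimator directly:

```r
pair <- simulate_phase_pair(
  oscillator_spec(0.25, noise_intensity = 0.01),
  oscillator_spec(0.1, coupling_term(0.3), noise_intensity = 0.01),
  duration = 600, dt = 0.02, seed = 1, fs_out = 10
)
model <- infer_window(pair)
coupling_strength(model, "1->2")$sigma   # 0.308 (injected 0.3)
coupling_strength(model, "2->1")$sigma   # 0.041 (no reverse coupling)
```

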