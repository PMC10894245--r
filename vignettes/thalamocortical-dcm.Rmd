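---
title: "Fitting a thalamocortical conductance model to EEG cross-spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting a thalamocortical conductance model to EEG cross-spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`tcdcm` implements a conductance-based neural mass model of two
hierarchically connected cortical sources — a frontal node (medial
prefrontal cortex, MNI −12 36 60) and a parietal node (superior parietal
lobule, MNI −24 −66 66) — each containing eight neuronal populations:
superficial pyramidal (SP), superficial interneuron (SI), spiny stellate
(SS), deep pyramidal (DP), deep interneuron (DI), thalamic-projection
pyramidal (TP), reticular (RT) and relay (RL) cells. Every population
carries AMPA, NMDA and GABA-A receptor conductances, giving
2 × 8 × 4 = 64 dynamical states.

Each population obeys a capacitive membrane equation

$$C \dot V = g_L (V_L - V) + g_A (V_A - V) + g_N\, m(V) (V_N - V) +
  g_G (V_G - V),$$

with first-order receptor kinetics
$\dot g_r = \kappa_r (a_r - g_r)$, where the afferent drive $a_r$ is the
connection-weighted, delay-lagged presynaptic firing of the populations
projecting through receptor class $r$ (clamped at zero so conductances can
never be driven negative). Firing is a sigmoid of depolarization relative
to rest, $\sigma(x) = 1/(1+e^{-\rho_1 (x-\rho_2)}) - \sigma_0$, normalized
to vanish at rest; the NMDA channel is additionally gated by the
magnesium-block sigmoid $m(V) = 1/(1+0.2 e^{-\alpha V})$ of the absolute
membrane potential.

The wiring follows the canonical microcircuit extended with a thalamic
loop: granular input RL→SS, superficial relay SS→SP, separate superficial
(SI) and deep (DI) inhibition, a descending chain SP→DP→TP, corticothalamic
projections TP→RL and TP→RT, and reciprocal reticular–relay inhibition.
Extrinsic forward connections (parietal→frontal) target granular
populations (SS, DP); backward connections (frontal→parietal) target the
superficial pair (SP, SI); both are AMPA- and NMDA-mediated with separate
gains. Inhibitory populations project only through GABA-A.

Every scalar parameter is carried as a prior mean $\bar\theta$ with a
log-scaling latent $\lambda$, $\theta = \bar\theta e^{\lambda}$, and a
prior variance on $\lambda$; parameters with zero prior variance are fixed.
The 23 free latents comprise the four extrinsic gains, eight analysed
intrinsic gains (per node: SP self-gain, SI→SP, RL→SS, TP→RL), six receptor
rate constants (per node: AMPA, GABA-A, NMDA), two electrode gains, two
innovation amplitudes and the innovation spectral exponent.

### Defaults and their rationale

| quantity | default | note |
|---|---|---|
| reversal potentials $V_L, V_A, V_G, V_N$ | −70, 60, −90, 10 mV | canonical conductance-model values |
| Mg-block slope $\alpha$ | 0.06 /mV | canonical |
| receptor time constants $\tau = 1/\kappa$ | AMPA 4 ms, GABA-A 16 ms, NMDA 100 ms | prior means; the inversion estimates the scalings |
| membrane | $C = 10$, $g_L = 1$ | membrane time constant 10 ms |
| sigmoid | $\rho_1 = 2/3$ /mV, $\rho_2 = 3$ mV | threshold sits a few mV above rest, see below |
| delays | intrinsic 1 ms, cortico-cortical and cortex↔thalamus 8 ms | common practice for laminar models |
| analysis grid | 4–90 Hz, 1 Hz steps | a single contiguous band; configurable |
| observation weights $J$ | SP 0.8, DP 0.2, TP 0.1 | superficial-pyramidal dominance of EEG; fixed, not estimated |
| innovations | $G_u(f) = \alpha_u f^{-\beta_u}$, $\beta_u$ prior 1 | pink innovations driving SS and RL |

The firing threshold deserves a note. With the threshold exactly at rest,
baseline sits at the sigmoid's maximum slope, so any depolarizing drug
effect can only *reduce* synaptic gain — and simulated "ketamine" effects
(forward AMPA gain up, frontal GABA-A rate up) would then *decrease*
high-frequency power, contradicting the well-replicated gamma increase
under NMDA-antagonist challenge. Placing the threshold 3 mV above rest puts
the baseline operating point on the rising limb of the sigmoid: planted
drug effects then produce the expected fingerprint (alpha suppression,
beta/gamma enhancement at the frontal node), which
`spectral_fingerprint_shift()` exposes and the test suite asserts.

Coupling magnitudes (`g0` in the edge table, an overall conversion
`g_scale` = 1/16, tonic drive 0.003) were chosen once so that (i) the
fixed point exists and is stable at the prior means and for ≥95% of
prior-plausible draws, (ii) the spectrum shows a damped resonance rather
than a bare 1/f decay, and (iii) the planted-effect fingerprint has the
physiological sign. They are deliberately ordinary numbers, stored in the
model object and overridable through the YAML configuration
(`write_model_config()` / `read_model_config()`).

## From model to spectrum

`find_fixed_point()` locates the equilibrium by damped Newton iteration
from the leak equilibrium (fallback: a long noiseless relaxation), to a
residual below $10^{-8}$. The dynamics are linearized there;
delayed couplings keep their own Jacobian blocks, and the transfer
function applies each delay as an exact frequency-domain phase factor
$e^{-i\omega d}$ rather than a small-delay matrix approximation:

$$H(\omega) = L\,J\,(i\omega I - A(\omega))^{-1} B, \qquad
  S(\omega) = H G_u(\omega) H^* + S_{\text{chan}}(\omega) +
  S_{\text{comm}}(\omega).$$

Innovations enter through the AMPA afferents of SS and RL of each node
(thalamo-granular drive); channel and common observation-noise spectra are
fixed small 1/f-plus-floor terms. `predict_csd()` returns a Hermitian
positive-semidefinite 2 × 2 matrix per frequency.

The brute-force oracle for all of this is `simulate_tcm()`: Euler–Maruyama
integration (default dt = 0.1 ms) of the full nonlinear delayed system,
driven by FFT-colored noise whose spectrum matches $G_u$. In the
small-noise regime the Welch cross-spectrum of a long simulation agrees
with the analytic prediction band-wise within 20%; the agreement degrades
as `noise_scale` grows and the nonlinearity engages, which is why the test
asserts it only in the linear regime.

## Inversion

`invert_csd()` fits the latents by variational Laplace. Features are the
real and imaginary parts of the upper-triangular CSD entries across
frequencies, weighted by the inverse absolute data amplitude of each entry
(floored at 5% of the entry's band-median amplitude). Entry-wise weighting
does two jobs at once: it stops the 1/f low-frequency mass from dominating
the residual, and it whitens observation noise whose size scales with each
entry's magnitude — with plain band-level scaling the weighted optimum is
measurably displaced from the generating parameters, which shows up as
sign flips in recovered condition effects. The objective is the free energy: accuracy (Gaussian
log-likelihood with precision $e^{h}$) minus complexity (the KL divergence
of the Gaussian posterior from the prior). Gauss–Newton/Levenberg–Marquardt
proposals use central finite-difference Jacobians (step $10^{-3}$ in log
units); the noise precision $h$ is re-estimated between parameter steps
under a broad Gaussian hyperprior. A step is accepted only if it improves
on the best free energy reached so far, so the recorded trace is
non-decreasing by construction; proposals with an unstable linearization
are rejected outright, which keeps the search inside the stationary
regime. Iteration stops after 4 consecutive improvements below 0.01 nats
or 128 iterations. The procedure is deterministic given data and
configuration.

Fit quality is summarized as mean-centered percent variance explained of
the unweighted features; noise-free self-inversion attains ≈100% and
recovers the generating latents to within 0.05 log units, and self-data
with 5% observation noise stays comfortably above the 90% criterion used
for real fits.

Identifiability is uneven, as expected for this model class: electrode
gain and innovation amplitude trade off; the NMDA rate constants
(τ ≈ 100 ms, a sub-4-Hz pole) barely move the 4–90 Hz spectrum and are
essentially returned at their priors; the frontal GABA-A rate constant is
identifiable but its signature can be partially mimicked by combinations
of intrinsic gains, so single-subject estimates are noisy while
cohort-level directions recover reliably.

## The synthetic cohort

Patient EEG underlying the motivating analyses is not publicly shareable,
so `generate_cohort()` produces virtual cohorts with the statistical
structure the group analysis assumes: per-subject baseline variability
(SD 0.1 on every free latent), condition effects with between-subject
SD 0.15 planted on forward AMPA gain (+0.15 bolus, +0.30 infusion),
frontal GABA-A rate (+0.20, +0.25 — most of the change in the bolus, i.e.
a shortened time constant), parietal NMDA rate (−0.10, −0.15) and frontal
SI→SP gain (−0.10, −0.15); 5% Hermitian observation noise on the spectra;
and clinical change scores linearly coupled to the realized shifts with
correlations calibrated to 0.43 (forward AMPA) and −0.38 (GABA-A time
constant) at 24 h. Because the couplings are set as $b = rS/\mathrm{sd}(z)$
with the residual SD absorbing the rest of the fixed total SD, the expected
sample correlation equals the target exactly.

Each free latent additionally receives small condition-level state noise
(SD 0.05, all three conditions). This represents within-subject
physiological variability between recording blocks, and it matters
statistically: without it, parameters that the spectrum barely constrains
would differ across conditions only through a tiny deterministic leakage
from the planted effects, and the repeated-measures F statistics of those
parameters would be spuriously inflated. With state noise present, null
parameters fluctuate the way the ANOVA assumes and reject at the nominal
rate.

What the generator does *not* emulate: real sensor-level EEG, MR gradient
artifacts, source localization error, non-Gaussian or heavy-tailed
between-subject distributions, model mismatch (the data-generating model
is the fitted model). Passing recovery tests therefore demonstrates that
the pipeline is correct and well-calibrated, not that the model is a true
description of any patient's cortex.

## Group statistics

`run_group_analysis()` mirrors the standard reporting shape: one-way
repeated-measures ANOVA (pre / bolus / infusion) per parameter, organized
in three families — extrinsics (4), intrinsics (8), time constants (6, on
the $\log\tau$ scale) — with Benjamini–Hochberg FDR applied within each
family; parameters significant before correction are carried to Pearson
correlations of their infusion-minus-pre change against clinical change at
24 h and 7 days, themselves FDR-corrected. Both degree-of-freedom
conventions are reported: the univariate $(k-1, (k-1)(n-1))$ pair drives
the p-values, and the multivariate-style $(k-1, n-k+1)$ pair is carried
alongside because published tables sometimes print that convention.

## Numerical choices and edge cases

* Fixed-point tolerance $10^{-10}$ (assertion threshold $10^{-8}$); Newton
  steps are halved until the residual decreases.
* Unstable parameter proposals are *rejected*, not clamped.
* The Gauss–Newton curvature is symmetrized and given a $10^{-12}$
  relative ridge before inversion, which matters only at the extreme
  precisions reached on noise-free data.
* Zero-residual starts (data generated at the prior mean) are recognized
  by the expected quadratic-model gain falling below tolerance; the fit
  returns immediately instead of erroring.
* A fit converging below 90% variance explained triggers one cautious
  restart with 16-fold initial damping, keeping whichever result has the
  higher free energy. This rescues some — not all — wrong-basin fits:
  free-energy ascent is local, and a subject whose latents sit several
  prior SDs from the prior mean can present a landscape whose basin of
  attraction from the prior-mean start excludes the generating
  parameters. Such fits are visible in the per-fit diagnostics
  (`fit_cohort()$fits`) as low variance explained.
* Epochs straddling a condition boundary belong to the earlier condition
  when at least half their samples precede it.
* Hilbert envelopes trim 10% of samples at each end before averaging.
* Welch estimation uses Hann-tapered, non-overlapping 2200 ms epochs (the
  natural segments of the recording design) and linear interpolation onto
  the analysis grid.

## Problem sizes used by the tests

The suite exercises the full pipeline at desk scale: single inversions on
the default 87-frequency grid; a 4-subject cohort (12 inversions) for
end-to-end recovery; 200 zero-effect replicate cohorts at the latent level
for type-I-error calibration; a 120 s stochastic simulation for the
linearization oracle; 27-subject latent-level cohorts for power and
calibration checks. Larger cohorts (the study-sized n = 27 with full
spectra and fits, or the 30-subject repeatability layout) run through
exactly the same code paths via `generate_cohort()` / `fit_cohort()` /
`run_group_analysis()`.

## Known limitations

* Two nodes only; the node count is validated and anything else rejected.
* The observation model is a fixed population-weight vector per node, not
  a full lead field, and $J$ is not estimated.
* NMDA parameters are weakly identified from 4–90 Hz spectra (see above);
  their group-level rows are reported but carry little evidence either
  way, matching their role as the least-constrained receptor class.
* Exact prior magnitudes for coupling gains are conventional choices, not
  certified to match any external implementation.
* The delay structure uses two delay classes (1 ms intrinsic, 8 ms
  long-range); per-edge delay estimation is out of scope.
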