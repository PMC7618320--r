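---
title: "Methods: functionally specific inhibitory connectivity — analysis and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functionally specific inhibitory connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pvcircuit` implements a complete, tested pipeline for studying how the
synaptic weights of parvalbumin-expressing (PV+) interneurons relate to the
visual responses of the pyramidal cells they connect with, together with a
structured excitatory/inhibitory (E/I) spiking-network model of the
consequences of such connectivity. Because the original in vivo / in vitro
dataset cannot be regenerated, the package ships a first-class synthetic-data
generator whose statistical structure matches what the analyses assume, and
every downstream statistic is validated against it.

# The tuning model

Single-trial responses $r(i,j)$ (mean dF/F during the moving phase of grating
$i$ on repeat $j$) are fit with a 9-parameter model: the product of a double
Gaussian in direction (a preferred lobe and a null-direction lobe of relative
amplitude $q$) and a bivariate Gaussian in log2-SF/log2-TF space with
orientation $\alpha$, plus an offset $b$. Angular differences are wrapped
onto $[0, \pi]$ and squared; the direction exponent is
$\exp(-h(\Delta\theta)/(2\sigma_{dir}^2))$ with $\sigma_{dir}$ in radians
inside the exponent. The printed rendering of the equation is ambiguous about
the placement of the factor 2; we adopt the conventional $2\sigma^2$
denominator and isolate the choice in one function (`wrap_sq` +
`predict_response`) so it can be audited in a single place.

Constraints follow the published parameter table: $0 < r_{max} \le 2\max
r_{ij}$; SF/TF preferences within 1 octave of the probed range (implemented
as $[\min-1, \max+1]$ in log2 units relative to the lowest probed value);
$\alpha \in [0^\circ, 90^\circ]$; $\sigma_x, \sigma_y \in [0.25, 4]$ octaves;
$\sigma_{dir} \in [0^\circ, 180^\circ]$; $q \in [0,1]$. The fit is
bound-constrained nonlinear least squares (`nlminb`, a trust-region method)
with one data-driven start (peak stimulus) plus seeded uniform restarts
(default 50), keeping the best SSE. On noiseless data the fit recovers all
parameters to well under 5% relative error.

Responsiveness is the fraction of dF/F variance explained by the stimulus,
$R^2 = 1 - \mathrm{Var}(f - \bar f)/\mathrm{Var}(f)$, thresholded at 15%
(deliberately more stringent than a one-way ANOVA at $p<0.05$). Selectivity
is the population skewness (1/N moment estimators) of the per-stimulus mean
responses. Direction FWHM is $2.355\,\sigma_{dir}$; SF/TF FWHMs are measured
from half-maximum crossings of the model curve on a dense log2 grid over
0.0025–2.56 cycles/deg and 0.125–16 Hz. Half maximum is taken above the
offset $b$, because the offset is not stimulus-driven. The grid step
defaults to 0.05 octave (configurable); cells with FWHM > 180 deg
(direction) or > 6 octaves (SF/TF) are untuned.

# Similarity metrics

*Response similarity* is the cosine of trial-average response tensors
$r(i,t)$; *total similarity* is the per-segment cosine of single-trial
traces averaged over segments (sensitive to co-fluctuation); time-averaged
signal similarity, per-segment Pearson (total correlation), and signal
correlation complete the set. Negative similarities are retained in all
computation (hiding them is purely a display convention). Feature deltas use
octave differences, speed = TF − SF in octaves, and the orientation wrap
$\Delta Ori = 90 - ||\varphi - \varphi'| - 90|$. Pairs closer than 10 um in
the same or adjacent imaging planes are excluded (fluorescence cross-talk);
plane adjacency comes from the z-plane index in the cell table. The printed
total-correlation formula conflates segments and repeats in its index; we
average over segments, consistent with total similarity.

# Synaptic statistics

PSP amplitude is the baseline-subtracted extremum of the mean trace
(baseline = mean Vm in the 5 ms before the presynaptic spike; at most the
first 20 trials), restricted to the window before a second overlapping PSP
when one is present. Paired-pulse ratio re-measures the baseline before the
second pulse. Kinetics are fit with
$V(t) = V_{max}(1 - e^{-t/\tau_r})^p e^{-t/\tau_d}$, excluding the first
5 ms, over 100 seeded restarts. Pairs with $\tau_d > 25$ ms belong to the
slow-decay exclusion set.

The slice-quality control normalizes each log10 amplitude by the PV cell's
mean log10 amplitude (equivalently, amplitudes by their geometric mean; an
arithmetic-mean variant is a switch). The printed ratio-of-logs is
sign-unstable when the mean log amplitude is near zero (amplitudes near
1 mV); cells with $|\overline{\log_{10}}| < 0.05$ are excluded with a
warning — this guard is ours, not the publication's. The significance test
permutes IPSP magnitudes within each PV cell only, and the two-sided p value
is the exact proportion of shuffles with $|R|$ at or above the observed
value (ties count; no add-one smoothing). Logistic regression of
connection probability on similarity uses IRLS (`glm`) with an explicit
separation detector, because datasets of this size are separation-prone.
Partial correlations are Pearson correlations of OLS residuals against the
covariate (distance).

# Synthetic-data generator

The generator states a world matching the published recording conditions:
288 grating stimuli (8 directions x 6 SF x 6 TF, log-spaced), a stationary
phase (5 volumes) followed by a moving phase (8 volumes) at 3.65 volumes/s,
and 6–10 segments per session (default `n_rep = 8`; the per-session
distribution is unpublished, so a fixed default in the middle of the range
is used). PV+ cells draw broader tuning than pyramidal cells
(e.g. $\sigma_{dir}$ from U(50,140) vs U(15,45) deg, SF/TF widths from
U(1.5,3.5) vs U(0.5,1.5) octaves, null-direction ratio U(0.3,1) vs
U(0,0.5)); response gains are log-normal; frame noise is i.i.d. Gaussian
(sd 0.25 dF/F), the simplest model satisfying the analyses' assumptions.
The stimulus-locked component is convolved with a causal single-exponential
calcium kernel (tau = 0.7 s, configurable; the indicator is not modelled
further) so that time-resolved and time-averaged similarity genuinely
differ.

Connectivity draws each tested pair's category from the observed rate table
(64/15/9/12% reciprocal / IPSP-only / EPSP-only / none over 138 pairs by
default). Log10 amplitudes are
$\beta\,s + \text{cell offset} + \text{pair latent} + \varepsilon$ where $s$
is the pair's response similarity; $\beta$ is set from the realized
similarity SD so the similarity–log-amplitude correlation equals
`rho_target` (default 0.43), the per-PV-cell offset emulates slice quality
(so the geometric-mean normalization has something real to remove), and the
latent term shared within a reciprocal pair sets the log-EPSP/log-IPSP
coupling (`reciprocal_rho`, default 0.6). For null-calibration runs both
`rho_target` and `reciprocal_rho` are set to 0: the permutation test probes
E/I coupling, so its type-I calibration requires the coupling itself to be
null, not merely the similarity effect.

What a green test does *not* establish: the generator has no neuropil
contamination (the external neuropil model is replaced by a pass-through
surrogate), no motion artefacts, no correlated (shared) trial-to-trial
noise, and Gaussian rather than heavy-tailed fluorescence noise. Statistical
conclusions about those failure modes are outside its reach.

# The structured E/I network

Neurons receive preferences $\gamma^{(d)}$ uniform on $[-\pi,\pi)$ for
$D = 2$ features. Connection affinity from neuron $i$ to $j$ is the product
over dimensions of the circular kernel
$\varphi(\gamma_i, \gamma_j, \kappa) = e^{\kappa\cos(\gamma_i - \gamma_j)}$,
normalized per source over available targets (subtract the minimum, divide
by the sum) to a probability density; for negative inhibitory specificity
the affinity is $1 - \prod_d \varphi$ before normalization (anti-tuned,
"lateral" inhibition). Degenerate constant affinities (e.g. $\kappa = 0$)
fall back to the uniform density, since the printed rule would divide by
zero. The per-source reading of the normalization ("over target synaptic
partners") is adopted; a per-block-global alternative would change only the
relative weighting between sources.

Blocks compose as $W_{BA} = w_{A,B}\,[s\,S_{BA} + (1-s)\,U]$ with $s = |s_E|$
for E-to-E and $|s_I|$ elsewhere, $U$ uniform over available targets, and
totals $w_{E,E} = w_E f_E$, $w_{E,I} = w_E d_{IE} f_I$, $w_{I,E} = w_I f_E$,
$w_{I,I} = w_I f_I$ — algebraically identical to the printed block equations
up to self-connection handling. Autapses are excluded (diagonal zero before
normalization; they are not part of the described model), and the form above
keeps each neuron's summed output weight per target class exactly conserved
(to 1e-9) for any specificity, which the tests assert. The negative-$s_I$
kernel applies to the inhibitory-source blocks (I-to-E, I-to-I); E-to-I keeps
the positive kernel with $|s_I|$, matching the description of "inhibitory
connections" being redistributed. $\kappa_{EE}^{(d)}$ is printed once and
taken equal across both dimensions.

Simulation uses leaky integrate-and-fire neurons with alpha-function
conductance synapses, integrated by fixed-step exponential-Euler at
dt = 0.1 ms (matching the 0.1 ms conductance sampling), with an exact
two-state update for the alpha synapse and a 1 ms delivery delay. The
publication defers neuron constants to a standard simulator without printing
them; we adopt and expose: membrane tau 10 ms (C = 200 pF, gL = 20 nS),
threshold −55 mV, reset and leak −70 mV, refractory 2 ms, synaptic tau
0.5 ms (E) / 1.0 ms (I), reversal potentials 0 / −80 mV. Each neuron
receives an independent 2400 Hz Poisson excitatory barrage; the per-event
weight is unprinted and is calibrated (`calibrate_background`) so the
unconnected network fires at ~2 Hz. Stimulus inputs are deterministic
currents into the excitatory population only, tuned by the same product
kernel, min–max normalized, and scaled to a maximum current.

## Scaled-down calibration

The published network has N = 5000 with unprinted weights. At the test sizes
(N = 500 and 1000) the regime boundaries were re-calibrated **once**, before
any acceptance measurement was frozen: `network_preset()` fixes
w_E = 3000 nS, w_I = 16500 nS (total output weight per neuron; per-target
weights are ~N times smaller) and background event weight 1.2 nS. Because
per-target input in this construction is independent of N (each source
spreads a fixed total), the same preset transfers from N = 500 to N = 1000.
The 12 pA published stimulus maximum produces sub-millivolt depolarizations
that the scaled network's weaker recurrence cannot amplify measurably, so
scaled protocols use 100 pA (`preset_stim_pA`); all network acceptance
checks are direction-of-effect labels, never absolute rates.

With this preset the specificity progression reproduces the published
phenomenology: the uniform network (s_E = s_I = 0) responds weakly and
returns to baseline (stable); s_E = 0.55 with uniform inhibition ignites
persistent recurrent activity after stimulus offset (unstable); adding
co-tuned inhibitory specificity s_I = 0.8 restores transient responses
(stable); anti-tuned inhibition s_I = −0.8 destabilizes again. The
stability label is the ratio of population E rate in the last 200 ms of each
off period to the rate during stimulation, unstable when the ratio exceeds
0.5 in a majority of cycles; the acceptance test pools cycles across three
preference-assignment seeds, as single short runs at N = 500 are
ignition-noise limited.

The 16-stimulus battery (pi/2 increments in both features, 400 ms on per 1 s
cycle, 250 ms rate bins) feeds the pairwise weight-prediction analysis. Here
feature preferences are *estimated from activity* (rate-weighted circular
means), mirroring the experimental procedure: with ground-truth preferences
the single-feature predictor would be unrealistically noise-free and the
comparison meaningless. With estimated preferences, overall activity
similarity predicts I-to-E weights better (rank correlation ~0.59) than
either single-feature preference difference (~0.51 and ~0.44) — the
conjunctive-tuning effect the model was built to demonstrate.

Cohort perturbation raises the background to 3500 Hz, picks the 11
excitatory neurons nearest the feature-1 target among those within pi/16 of
the feature-2 target (tolerance unpublished; pi/16 keeps the cohort tight
without emptying it), and injects 200 nA for 10 ms at 10 Hz. Rates are
compared in the 20 ms before each pulse and the 50 ms after onset.
Facilitation of most inhibitory neurons, suppression of most non-cohort
excitatory neurons, and greater preference-proximity of facilitated vs
suppressed cells all replicate at N = 1000.

# Numerical and design choices

- Seeds: a single master seed fans out deterministically
  (`derive_seeds`) so stages can be rerun independently; all derived seeds
  stay below 2^31.
- Running-percentile detrend truncates windows at trace boundaries rather
  than padding (no fabricated data at edges).
- The two-Gaussian baseline fit reads "smaller Gaussian" as smaller *mean*
  (the baseline component); smaller *weight* is available as a switch since
  the published wording is ambiguous.
- dF/F is (F − F0)/F0; the quotient form is unstated but standard.
- Dataset store is a plain-text directory (CSV tables + long-form tensor +
  JSON metadata); no HDF5 bindings exist in the supported environment.
- The PSP generator normalizes each kernel to its realized grid peak so the
  constructed extremum is exact at any sampling step.
- Permutation shuffles are materialized as an index matrix and evaluated by
  one matrix product (columns of the shuffled matrix share mean/SD, so only
  cross-products vary).

# Known limitations

- The neuropil-correction model of the original preprocessing chain is
  external; the package substitutes a configurable scalar surrogate and
  accepts pre-corrected traces.
- Orientation-only (non-direction) tuning fits and receptive-field mapping
  are out of scope.
- The scaled network reproduces regime labels and effect directions, not
  the absolute rates or figure pixel values of the full-size model.
- Type-I calibration of the permutation test runs at 500 shuffles per
  replicate (p resolution 0.002), not the 10,000-shuffle default used for a
  single dataset.
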