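---
title: "Modeling serotonergic psychedelic effects with coupled laminar neural masses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling serotonergic psychedelic effects with coupled laminar neural masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanmm)
```

## The model

`lanmm` simulates a cortical column as a *laminar neural mass model*: two
coupled population circuits that jointly generate the two rhythms most
affected by serotonin-2A (5-HT2A) agonists such as classical psychedelics.

* A **Jansen-Rit circuit** — layer-5 pyramidal cells `P1`, spiny stellate
  cells `SS`, and slow (somatostatin-type) inhibitory interneurons `SST` —
  produces alpha-band activity, calibrated to 10 Hz at baseline.
* A **PING circuit** — layer-2/3 pyramidal cells `P2` and fast
  (parvalbumin-type) inhibitory interneurons `PV` — produces gamma-band
  activity, calibrated to 40 Hz at baseline.

Every connection `s` between populations is a second-order synapse
converting the presynaptic firing rate $\varphi_n(t)$ into a postsynaptic
potential perturbation $u_s(t)$:

$$\frac{1}{A_s}\Big[\frac{1}{a_s}\ddot u_s + 2\dot u_s + a_s u_s\Big]
  = C_{m\leftarrow n}\,\varphi_n(t),$$

with synaptic gain $A_s$ (mV), rate constant $a_s = 1/\tau_s$ (1/s) and
connectivity constant $C_{m\leftarrow n}$ (mean synaptic contacts).
Membrane potentials are signed sums of incoming $u_s$ (inhibitory
synapses enter negatively), and population output rates follow the
sigmoid $\varphi(\nu) = 2\varphi_0/(1+e^{r(\nu_0-\nu)})$ with
$\varphi_0 = 2.5\,\mathrm{s^{-1}}$, $\nu_0 = 6$ mV, $r = 0.56$ mV$^{-1}$.

Psychedelic action is modeled as increased excitability of layer-5
pyramidal cells: the gain of every glutamatergic synapse onto `P1`
(`SS->P1`, `P2->P1`, the external input `e1->P1`, and — in networks — the
long-range lateral input) follows the dose relation

$$A_{L5P}(i) = A_0 + \psi\, R_i\, (A_{max} - A_0),$$

with dose $\psi \in [0,1]$, normalized regional receptor density
$R_i \in [0,1]$, nominal gain $A_0 = 3.25$ mV and maximum gain
$A_{max} = 3.75$ mV.

## The default parameter set and its calibration

The main published account of the model fixes the circuit topology, the
sigmoid, $A_0$ and $A_{max}$, but defers the full 13-synapse table to
supplementary material.  The packaged default
(`lanmm_parameters()`) therefore combines:

* the classic Jansen-Rit values for the alpha circuit
  (excitatory $A = 3.25$ mV, $a = 100\,\mathrm{s^{-1}}$; slow inhibition
  $22$ mV with $a = 46\,\mathrm{s^{-1}}$, slightly slower than the
  textbook $50\,\mathrm{s^{-1}}$ to center the coupled column's alpha peak
  at exactly 10 Hz; connectivity 135/108/33.75/33.75), and
* a PING circuit calibrated once so that the baseline column oscillates
  at 40 Hz: fast AMPA onto `PV` ($a = 200\,\mathrm{s^{-1}}$,
  $\tau = 5$ ms), strong perisomatic fast inhibition ($A = 30$ mV,
  $a = 240\,\mathrm{s^{-1}}$, $\tau \approx 4.2$ ms), and cross-circuit
  drive dominated by `P1 -> P2` ($C = 220$).

External inputs are Gaussian firing-rate perturbations sampled once per
integration step: `e1` $\sim N(316, 54)\,\mathrm{s^{-1}}$ onto `P1` and a
zero-mean perturbation with SD $25\,\mathrm{s^{-1}}$ onto `P2`.  The `e1`
mean sits at the upper end of the classic Jansen-Rit drive range; it was
chosen, together with the noise SD, during the same one-off calibration
so that the column reproduces the published qualitative spectral profile
of the gain sweep: alpha and gamma coexisting around the nominal gain,
gamma onset below $A_0$, and alpha extinction above $A_{max}$.

With the frozen set, the measured landmarks of the sweep
(`run_sweep()`, 40 s per point, 0.05 mV grid) are: gamma onset at
2.65–2.70 mV, alpha mean PSD first below $0.1\,\mathrm{mV^2/Hz}$ near
3.90 mV, and coexistence window top near 3.85–4.00 mV.  These are
*emergent* quantities — they were measured after freezing the table, not
tuned — and they sit within a few percent of the published landmarks
(2.75, 3.75 and 4.15 mV).  One qualitative difference is documented
here: in the published profile the alpha decay "becomes nonlinear" at
$A_{max}$ and hovers near the floor for a further 0.4 mV, so the floor
crossing (3.75) lies *below* the window top (4.15); in the reconstructed
column the alpha tail crosses the floor once, so these two landmarks
nearly coincide.

```{r column, eval = FALSE}
ts <- simulate_node(duration = 40, fs = 1000, seed = 1)
keep <- 10001:40000
spectral_peak(ts$potentials[keep, "P1"], 1000, c(1, 30))   # 10 Hz
spectral_peak(ts$potentials[keep, "P2"], 1000, c(25, 80))  # 40 Hz
```

## Numerical scheme

The column and network are integrated with a classical fourth-order
Runge-Kutta scheme at `dt = 1/fs` (1 ms by default).  Noise is treated as
a band-limited input rate, held constant within each step — no
$\sqrt{dt}$ scaling, following common neural-mass practice.  All synaptic
states start at rest (zero) and a 10 s transient is flagged for exclusion
(`discard`); it is never removed from the returned series, so downstream
stages choose their own window.  A divergence guard aborts when any
membrane potential exceeds $10^6$ mV (configurable), naming the first
offending time and parcel.  A deterministic convergence check (constant
drive) shows band powers change by well under 2% when the step is halved.
Welch spectra use 1000-sample segments, a Hann window, 50% overlap and
per-segment constant detrending; "mean band PSD" is the arithmetic mean
of the in-band frequency bins, in $\mathrm{mV^2/Hz}$.

## Whole-brain networks

`build_network()` couples identical columns through a connectome with the
three published long-range projection types and relative weights:
lateral `P1 -> P1` (0.5), feedback `P1 -> P2` (0.5) and feedforward
`P2 -> P2` (1).  Long-range input enters through a dedicated excitatory
synapse (local excitatory kernel); for `P1` targets that synapse's gain
is the receptor-modulated $A_{L5P}(i)$, so the dose also scales
cortico-cortical excitation.  Coupling is instantaneous (the source
describes no conduction delays).  Two scale conventions are recorded in
the model object rather than hidden: the connectome is rescaled to unit
mean column sum so the global gain $G$ is comparable across parcel
counts, and the long-range synapses carry connectivity constants 60
(onto `P1`) and 15 (onto `P2`).  The asymmetry keeps the feedforward
drive from saturating the PING circuit at moderate $G$; with symmetric
constants the gamma response to the dose inverted above $G \approx 1.5$.

The noise driving each parcel's `e1` input decomposes into a stream
shared by all parcels (SD $\sigma_c$) and a stream shared within each
homotopic pair (SD $\sigma_i$); the personalization fits the ratio
$\sigma_c/\sigma_i$ with total variance fixed
(`noise_sigmas_from_ratio()`).

Personalization follows the published procedure: simulate at candidate
$(G, \sigma_c/\sigma_i)$, convert the z-scored `P1` firing rate to BOLD
with the Balloon-Windkessel model (standard constants
$\kappa=0.65$, $\gamma=0.41$, $\tau=0.98$ s, $\alpha=0.32$, $E_0=0.34$,
$V_0=0.02$; output TR 2 s), compute the Pearson FC, and pick the
RMSE-minimizing grid point among those whose FC-to-empirical correlation
exceeds the empirical-FC-to-structure correlation.  Grid bounds, TR and
the dynamic-FC surrogate settings (30 s windows, 5 s steps,
phase-randomized surrogates) are not stated in the main published text;
the defaults here are declared stand-ins, all configurable.

## Synthetic data: what it emulates and what it does not

The study's inputs are neuroimaging-derived (tractography connectomes,
PET receptor maps, rs-fMRI FC, a template head model).  The
`synth_*` generators replace them with controllable stand-ins sharing
one spatial embedding (parcels on two mirrored unit hemispheres):

* `synth_connectome()` — random geometric graph with log-normal
  streamline counts, boosted homotopic connections, normalized by total
  streamlines x parcel count;
* `synth_receptor_map()` — kernel-smoothed Gaussian field, min-max
  normalized to exactly $[0,1]$;
* `synth_leadfield()` — 19 electrodes of a 10-20-style montage, gains
  proportional to a signed orientation factor over a steep
  $1/d^4$ distance kernel.  The signed factors emulate the mixed
  gyral/sulcal dipole polarities of real cortex, and the steep kernel
  keeps each channel dominated by nearby parcels.  Both choices matter:
  with all-positive broad gains, coherent alpha is amplified ~100-fold at
  the channels and its 30–70 Hz harmonics swamp the genuine gamma
  response, inverting the channel-level dose contrast;
* `synth_empirical_fc()` — the forward model run at a known
  $(G, \sigma_c/\sigma_i)$ plus symmetric observation noise, so fitting
  has a recoverable ground truth;
* `synth_cohort()` — per-subject connectome jitter and a subject-specific
  true $G$ drawn from `g_range`, with one shared receptor map.  The
  default `g_range` of $(0.8, 1.6)$ spans the regime in which models
  remain *responsive* to 5-HT2A stimulation, emulating the retained
  cohort of the study, which excluded a too-weakly and a too-strongly
  coupled subject; above $G \approx 1.8$ the reconstructed models lose
  most alpha and their channel-level gamma response saturates.

Passing tests on this synthetic cohort demonstrate that the pipeline's
machinery is correct and that the published *directions* of the dose
effects emerge from the mechanism; they do not certify quantitative
agreement with human neuroimaging, which would require the original
multimodal inputs.

## EEG, dipoles and complexity

The multicompartment current-source-density biophysics used in the
original study is replaced by a declared linear stand-in:
`dipole_strength()` combines the mean-centered `P1` and `P2` potentials
with layer weights `w_P1 = 1`, `w_P2 = 0.25`.  The strong deep-layer
dominance is deliberate: the column's superficial gamma variance exceeds
its deep alpha variance, and more balanced weights produce gamma-dominated
synthetic EEG, unlike empirical scalp recordings (and with inverted
broadband-entropy responses to the dose).  `project_eeg()` applies the
leadfield and an average reference.

Complexity metrics follow the published recipe: a single 5 s broadband
(0.5–100 Hz, zero-phase 4th-order Butterworth) epoch, per-channel median
binarization (values at the median map to `1`), channel-concatenated
strings, LZW compression with fixed-width final-dictionary coding
($\rho_0 = \mathrm{codes}\cdot\lceil\log_2 \mathrm{dict}\rceil / n$),
plug-in entropy rates for Markov orders 0–5, and Shannon spectral entropy
(base 2) of the channel-averaged unit-normalized PSD.  Two estimator
facts are worth knowing: order-0 entropy is pinned at 1 bit by the median
binarization (balanced strings), so dose effects appear at orders
$\geq 1$; and the plug-in conditional entropy can violate the
conditioning inequality by its $O(2^{\mathrm{order}}/n)$ bias, so
monotonicity holds only up to that slack.

## Problem sizes and reproducibility

Default study-scale settings are 40 s runs at 1000 Hz with a 10 s
transient, 300 s runs for FC fitting with five noise realizations, and
0.05 mV gain grids.  The test-suite and worked examples use reduced
scales chosen as standard desk-scale exercises: 16-parcel networks,
120 s fitting runs with three realizations, and 5-subject cohorts.
Every stochastic step takes an explicit integer seed; identical seeds
give bit-identical trajectories on one platform.  The paired
baseline/psychedelic contrast shares one noise realization between arms
(a variance-reduction choice recorded in the stage-2 object; the
original study does not state whether its arms shared noise).

## Known limitations

* The 13-synapse table is a reconstruction: baseline peak frequencies and
  the qualitative sweep profile match the published column, but the
  window top and alpha-floor landmarks differ by ~5% and the alpha tail
  lacks the published near-floor plateau.
* Conduction delays, subcortical nodes, plasticity and the
  PV-damage disease variant are out of scope.
* The EEG stage is a linear stand-in; topographic claims (which channels
  change most) should not be read off the synthetic leadfield.
* Channel-level gamma contrasts are sensitive to source coherence and
  reference choices; the packaged defaults document one reasonable
  operating point rather than a unique one.
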