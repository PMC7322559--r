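---
title: "Multimodal dynamic causal modelling of neurovascular coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal dynamic causal modelling of neurovascular coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdcm)
```

## The problem

The BOLD contrast measured with fMRI is an indirect, haemodynamically
filtered readout of neuronal activity. Which aspect of that activity drives
the vasculature — presynaptic input or postsynaptic depolarisation, local
populations only or also afferents from distal regions, instantaneously or
with an astrocytic delay — is an open physiological question. `mmdcm`
implements a three-stage procedure for asking such questions in a single
subject who performed the same task under M/EEG and fMRI:

1. A **canonical microcircuit (CMC) neural mass model** is fitted to the
   condition-wise event-related fields (variational Laplace on the
   principal spatial modes of the sensor data).
2. The posterior neuronal parameters generate **neuronal drive functions**
   — stereotyped per-condition pre- or postsynaptic response templates —
   which are shifted and summed over the fMRI event onsets.
3. A factorial space of **neurovascular-coupling + Balloon haemodynamic
   models**, all driven by those functions, is fitted to the region-wise
   BOLD series, and hypotheses are adjudicated by Bayesian (family-wise)
   model comparison and Bayesian model reduction.

## The neuronal model

Each region contains four populations — spiny stellate (ss), superficial
pyramidal (sp), inhibitory interneurons (ii) and deep pyramidal (dp) —
with second-order synaptic dynamics per population:

$$\ddot V_i = \kappa_i^2\,(f_i - V_i) - 2\kappa_i \dot V_i,$$

where $f_i$ sums the signed afferents of population $i$: intrinsic
connections (with the laminar pattern of the canonical microcircuit),
extrinsic forward connections (distal sp firing onto ss and dp), extrinsic
backward connections (distal dp firing onto sp and ii), and — for the spiny
stellates of input regions — a Gaussian exogenous input (peak ~70 ms,
dispersion 16 ms). Firing rates are a centred logistic
$\sigma(V) = 1/(1+e^{-V}) - 1/2$, i.e. deviations from baseline that may be
negative. A literal reading of the printed equation puts the sigmoid's
range at $(-\tfrac12, \tfrac12)$ even though its "maximum firing" is
described as one; we implement the equation literally, since the
connectivity scales absorb any constant.

All gains are log-normal: effective value = scale $\times\ e^\theta$, with
$\theta$ Gaussian. The fixed scales are $\kappa = (256, 128, 16, 32)$ s$^{-1}$
assigned in the canonical population order (ss, sp, ii, dp) — the
literature does not standardise this assignment, so it is a documented
convention, overridable via `cmc_scales()` — and intrinsic gains $a = (2,1,1,1)\times
512$, mapped so the ss self-inhibition takes the doubled scale and every
other intrinsic connection the base scale (again a convention, also
overridable). Rate constants and intrinsic gains have zero prior variance
(fixed); extrinsic and condition-effect log-gains have variance 1/8, the
input log-gain 1/32. Zero-variance parameters are excluded from the
estimation vector.

Condition effects (a between-trial-effects matrix with the first condition
as baseline) add to the forward, backward and self-inhibition log-gains of
the active effect columns, so a condition effect of $\ln 2$ doubles the
corresponding effective gain.

### Numerical integration

Event-related responses are integrated from rest over 0–400 ms and reported
on a 1 ms grid. Internally each reported step is subdivided into four RK4
substeps (0.25 ms). This matters: with intrinsic gains of order 512 the
coupled system has oscillatory eigenvalues near $|\lambda| \approx 3/\mathrm{ms}$,
outside the RK4 stability region at a 1 ms step — a 1 ms fixed-step RK4
integration of this model diverges at prior-mean parameters. At 0.25 ms,
halving the step changes trajectories by under $10^{-5}$ relative L2 norm.
(DCM implementations commonly integrate this model family by local linearisation —
matrix exponentials of the Jacobian — which is unconditionally stable;
fixed-step RK4 with substeps is a simpler equivalent at these step sizes.)
The integrator also stores each signed afferent component of $f_i$
(intrinsic-excitatory, intrinsic-inhibitory, extrinsic, input) at every
output sample, so presynaptic drive functions can be reassembled without
re-integration; their sum reproduces the forcing term to $10^{-10}$.

## Observation model and ERP inversion

Sensor predictions are $\sum_K \Upsilon_K\,\Delta_{0K} \sum_j \Psi_j V_j(t)$:
populations mixed by a contribution vector $\Psi$ (prior mean $(0,1,0,0)$ —
superficial pyramidal cells dominate the measured field — variance 1/16),
scaled per region by a log-parameterised spatial-basis coefficient (default:
a single basis pattern per region), and projected through a gain matrix.
Real lead fields are out of scope; gain matrices are user-supplied or
synthesised as random orthonormal columns. Model fitting uses the top
principal spatial modes (default 8) of the observed data as features; the
projector is computed once from the data and applied identically to data
and predictions, never refreshed during iteration.

## Drives, neurovascular coupling and haemodynamics

Per condition, drive templates are built from the posterior-mean neuronal
parameters on the 1 ms grid, resampled to the fMRI microtime grid (default
0.1 s) by integral-preserving binning, and summed over event onsets
(overlap adds). Three parameterisations exist: `pre` (the signed afferent
components per population; the exogenous input counts as a presynaptic
afferent of ss), `post` (the depolarisations), and `decomposed` (presynaptic
components grouped into excitatory, inhibitory and extrinsic channels by
their source class: self-inhibition and interneuron terms are inhibitory;
ss/sp/dp-sourced intrinsic terms and the input are excitatory). Distal
(extrinsic, A-weighted) afferents either form separate weighted channels
(`include`) or are dropped (`exclude`); presynaptic channels are kept signed
— the coupling weights are unconstrained in sign, so rectification would
only remove information (a rectified variant can be built from the stored
components if wanted). A 4-entry exclusion vector zeroes all channels of a
population; both the canonical (ss, sp, ii, dp) and the toolbox
(sp, ii, ss, dp) orderings are accepted.

The per-region neurovascular signal is a weighted sum of drive channels
(weights shared across regions or region-specific, prior N(0, 1/16)),
optionally convolved with the delay kernel
$f_{nc}(t) = (t/\tau_{nc})e^{-t/\tau_{nc}}$, $\tau_{nc} = 0.7\,e^{\theta}$ s.
The kernel is kept with its printed area $\tau_{nc}$ — normalising it would
silently rescale the weight posteriors — so the short-delay limit of the
delay form is $\tau_{nc}$ times the direct form, which is what the
corresponding regression test asserts. The kernel support is truncated at
$8\tau_{nc}$ (omitted mass < 0.3%).

The Balloon model maps the neurovascular signal through a vasodilatory
signal, inflow, venous volume and deoxyhaemoglobin:
$\dot h_s = z - \eta h_s - \chi(h_{in}-1)$, $\dot h_{in} = h_s$,
$\dot h_v = (h_{in} - h_v^{1/\alpha})/\tau_h$, and the corresponding dHb
balance; BOLD is $V_0\{k_1(1-h_q) + k_2(1-h_q/h_v) + k_3(1-h_v)\}$ with
$k_1 = 6.9 E_0$, $k_2 = \varepsilon E_0$, $k_3 = 1-\varepsilon$. Priors:
$\eta = 0.64 e^\theta$, $\tau_h = 2 e^\theta$, $\varepsilon = e^\theta$
(each N(0, 1/256)); $\chi = 0.32$, $\alpha = 0.32$, $E_0 = 0.40$ fixed;
$V_0 = 0.08$ by default with an override (more recent estimates sit near
5%). The linearised vasomotor loop resonates at
$\sqrt{\chi}/2\pi \approx 0.09$ Hz. Integration is RK4 at the microtime
step with inflow/volume/dHb in log space, so positivity is structural and
rest is preserved to $10^{-10}$ over 100 s; integration starts at exact
rest with no burn-in. Scans are sampled at $t = 0, TR, 2TR, \ldots$. A
configurable discrete-cosine confound set was considered and left out:
the synthetic data carry no drift, and drift handling belongs to the
preprocessing that produces the region time series.

## Inference

`variational_laplace()` maximises the Laplace free energy under a Gaussian
posterior: Gauss–Newton ascent with Levenberg–Marquardt damping, central
finite-difference gradients (step $10^{-3}$; the generator contains ODE
integrations, so analytic gradients are out of scope), and a single i.i.d.
noise stream whose log precision is a hyperparameter updated by
step-capped Newton iterations. The damping schedule starts conservative
(the free-energy landscape of the ERP model has local optima that an
aggressive first step falls into — verified by comparing prior-mean and
truth-initialised inversions) and relaxes toward pure Gauss–Newton as steps
are accepted; accepted free energies are non-decreasing, convergence is
declared after three consecutive improvements below 0.01, and a short
near-undamped refinement phase then polishes the optimum so linear-Gaussian
problems land on the conjugate answer to $10^{-6}$. The noise hyperprior
default is N(0, 16): a tight hyperprior (e.g. variance 1/16) would pin the
noise SD within a factor ~2 of 1, inconsistent with BOLD- and
femtotesla-scale signals; 16 spans the precisions that arise here while
still regularising.

Bayesian model reduction computes reduced-model posteriors and evidence
analytically from the full prior/posterior pair; greedy pruning removes
parameters whose near-zero-variance reduction does not decrease the free
energy and reports per-parameter absent-vs-present log odds. Model
probabilities are softmax in the free energies under uniform model priors;
family posteriors use a prior uniform over families and uniform within
each family, which corrects for the unequal family sizes of the
16-model space (8 pre / 4 post / 4 decomposed under Q1).

## The synthetic study conditions

The generator emulates a four-condition roving-oddball design — standards
and deviants under computer-controlled ("respond": SR, DR) and
self-controlled ("control": SC, DC) blocks — with SR as baseline and one
condition effect per non-baseline condition. Defaults were chosen once as
a realistic desk-scale stand-in and are not tuned per analysis:

* **Network**: 2 regions, one forward and one backward connection, input
  to region 1 (a stand-in for the 5-region auditory hierarchy of the
  motivating study; a 5-region architecture is a constructor call away).
* **Schedule**: blocks of 12 tones at 2 s stimulus-onset asynchrony, 2 s
  cue, 1 s inter-block gap; TR 2 s; microtime 0.1 s. Test runs use 8
  blocks (~216 s); the default is 16 (~7 min).
* **Neuronal truth**: forward log-gain $\ln 1.5$, backward $\ln 1.2$;
  condition effects of 0.1–0.4 on extrinsic gains and up to ±0.1 on
  sp/ii self-inhibition. The circuit is very sensitive to self-inhibition:
  reductions beyond ~10% cross a bifurcation into large limit-cycle
  responses, two orders of magnitude above a realistic trial-averaged
  evoked response, so the truth keeps all four conditions' sensor RMS
  within a factor of ~5.
* **Coupling truth**: presynaptic, local, shared weights, direct form;
  weights of about 0.2 in magnitude (within one prior SD), giving BOLD
  excursions of ~1–5% — realistic sizes, and honest for
  credible-interval calibration because the truth is prior-typical.
* **Noise**: i.i.d. Gaussian at a stated amplitude SNR for both
  modalities; "high SNR" in the recovery studies means 10–20, plausible
  for trial-averaged evoked responses and a clean fMRI ROI series.

What the generator does **not** emulate: correlated (AR) fMRI noise and
scanner drift, sensor-noise spatial covariance, trial-by-trial response
variability (drives are stereotyped per condition by construction),
realistic lead fields, and MRI/MEG physics. Passing recovery tests
therefore show that the estimator chain is correct and well calibrated
under its own assumptions — not that those assumptions hold in real
recordings.

### Recovery scenarios

Two deliberate scenario choices deserve a note. First, the
parameter-recovery study (free log-gains vs truth, sensor SNR 10, ten
replicates) restricts condition effects to the extrinsic forward/backward
gains — the classic mismatch-negativity modulation design. With effects
free on every extrinsic *and* self-inhibition gain, 30 condition-effect
parameters would be informed by only three condition contrasts in a
2-region network; the problem is genuinely under-determined and the
posterior correctly shrinks the unidentified directions, capping the
pooled correlation near 0.7 no matter how the optimiser is run (we checked
with truth-initialised inversions). The full modulation set is still
exercised end to end by the pipeline-closure test. Second, the
coupling-weight calibration study uses drives computed from the generating
neuronal parameters: drives estimated from a finite-SNR MEG session carry
a few-percent amplitude bias which would confound the weights' scale, so
credible-interval coverage is only a well-posed property of the fMRI-stage
estimator. Family-level conclusions are robust to that amplitude bias, and
the pipeline-closure test shows exactly that: drives from one high-SNR ERP
inversion still identify the generating coupling family in every replicate.

## Known limitations

* Within-region condition effects share the inversion's general
  under-determination: with rich modulation sets the posterior leans on
  its priors, as in the original framework.
* The drive-template window (0–400 ms) truncates any response component
  slower than the ERP window.
* Free energies from a single i.i.d. noise stream ignore serial
  correlation in real fMRI; model comparisons on real data would need
  pre-whitened inputs.
* Group-level (random-effects / empirical Bayes) comparison is out of
  scope; all inference is single-subject, fixed-effects.
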