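# mmdcm — multimodal dynamic causal modelling of neurovascular coupling

`mmdcm` asks where the BOLD signal comes from. It couples a laminar neural
mass model fitted to event-related M/EEG data with a family of
neurovascular-coupling and haemodynamic models fitted to region-wise fMRI
time series from the same paradigm, and adjudicates between hypotheses —
pre- vs postsynaptic drive, local vs distal afferents, shared vs
region-specific coupling, instantaneous vs delayed vasoactive signalling —
by Bayesian model comparison. It is aimed at methods-oriented
neuroimagers who have condition-wise evoked responses and extracted ROI
BOLD series and want single-subject, fixed-effects inference about
neurovascular physiology.

## The model, briefly

Each brain region is a canonical microcircuit of four populations
(spiny stellate `ss`, superficial pyramidal `sp`, inhibitory interneurons
`ii`, deep pyramidal `dp`) with second-order synaptic dynamics

```
V̈ᵢ = κᵢ² (fᵢ − Vᵢ) − 2 κᵢ V̇ᵢ,      σ(V) = 1/(1+e⁻ᵛ) − ½,
```

where `fᵢ` mixes intrinsic afferents, laminar-specific extrinsic forward
(sp → ss, dp) and backward (dp → sp, ii) connections, and a Gaussian
thalamic input to `ss` of the lowest region(s). All gains are
`scale · exp(θ)` with Gaussian priors on `θ`; condition effects add to the
forward, backward and self-inhibition log-gains. Sensor data are explained
through a gain matrix with a per-region spatial-basis coefficient and a
population contribution vector, using the principal spatial modes of the
observed ERPs as features.

From the fitted posterior, per-condition **neuronal drive functions**
`f_c^{ij}(t)` (pre- or postsynaptic, optionally decomposed into
excitatory/inhibitory/extrinsic channels) are shifted and summed over the
fMRI event onsets,

```
z_ij(t) = Σ_c Σ_l f_c^{ij}(t − t_l^c),
```

then combined per region, `z_j = Σᵢ βᵢⱼ z_ij` (optionally convolved with a
delay kernel `(t/τ)e^{−t/τ}`, prior τ = 0.7 s), and passed through the
Balloon model to BOLD:
`y = V₀{k₁(1−h_q) + k₂(1−h_q/h_v) + k₃(1−h_v)}`. The factorial crossing of
drive parameterisation × distal afferents × region-specificity ×
direct/delay yields 16 candidate models; all are inverted with variational
Laplace and compared by (family-wise) posterior probability, with Bayesian
model reduction for parameter pruning.

## Worked example

Simulate a two-region multimodal dataset with known ground truth
(presynaptic, local, shared-weight, direct coupling), fit the neuronal
model to the evoked fields, and compare four coupling hypotheses on the
BOLD data:

```r
library(mmdcm)

truth <- synthetic_truth()
sched <- generate_schedule(n_blocks = 8, seed = 2)
erp   <- simulate_erp_dataset(truth, snr = 20, seed = 7)
bold  <- simulate_bold_dataset(truth, sched, snr = 20, seed = 9)

fit_erp <- invert_erp(erp, truth$arch, truth$design, truth$gain_model,
                      control = list(max_iter = 32))

specs <- list(pre_direct  = nvc_model_spec("pre",  "exclude", FALSE, "direct"),
              pre_delay   = nvc_model_spec("pre",  "exclude", FALSE, "delay"),
              post_direct = nvc_model_spec("post", "na",      FALSE, "direct"),
              post_delay  = nvc_model_spec("post", "na",      FALSE, "delay"))
z_pre  <- build_drives(fit_erp, sched, specs$pre_direct)
z_post <- build_drives(fit_erp, sched, specs$post_direct)
fits <- lapply(specs, function(sp) {
  z <- if (sp$parameterisation == "pre") z_pre else z_post
  invert_fmri(bold$bold, z, sp, sched, control = list(max_iter = 32))
})
Fs <- sapply(fits, function(f) f$result$free_energy)
```

Output (free energies in nats; larger is better):

```
 pre_direct   pre_delay post_direct  post_delay
     2095.2      2045.6      1743.4      1724.3
family posteriors:
 pre post          direct  delay
   1    0               1      0
explained variance (winning model): 1 0.83
         beta[1] beta[2] beta[3] beta[4]
estimate   0.203   0.176  -0.095   0.217
truth      0.250   0.200  -0.150   0.200
```

The generating family (presynaptic, direct) wins decisively — a log Bayes
factor of ~50 over the delayed variant and ~350 over the postsynaptic
models — and the coupling weights are recovered up to the expected
shrinkage of correlated channels. `enumerate_model_space()` builds the
full 16-model factorial design, `fit_model_space()` fits it in one call,
and `prune_parameters()` performs Bayesian model reduction on any fit.

A thin command-line front end over the same functions lives at
`inst/cli/mmdcm.R`:

```sh
Rscript inst/cli/mmdcm.R model-space
Rscript inst/cli/mmdcm.R simulate --out-dir sim --seed 3 --n-blocks 8
Rscript inst/cli/mmdcm.R invert-fmri --bold sim/bold.csv \
    --params sim/truth_params.json --events sim/events.tsv \
    --options pre,s,int --out fit.json
```

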