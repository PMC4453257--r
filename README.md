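# odourcircuit

Fruit flies form aversive olfactory memories that are specific to the
odour *intensity* used during training: at test, conditioned avoidance is
strongest when the test intensity matches the trained one and falls off in
both directions.  This is puzzling because the first two stages of the fly
olfactory pathway — sensory neurons and projection neurons — respond
*monotonically* to intensity, so a stronger odour activates a superset of
what a weaker odour activates.  Somewhere downstream, intensity must be
re-coded non-monotonically before an associative memory can be attached to
it.

`odourcircuit` implements a minimal three-layer rate model of that
transformation and the analysis tools around it, for computational
neuroscientists who want to simulate, probe and stress-test the circuit
motif.

## The model

**Input layer.** K excitatory neurons with logistic intensity tuning
(`i` is log10 concentration)

    exc_k(i) = 1 / (exp(-4 b (i - a_k)) + 1)

shifted by one log unit per neuron (default `a_k` in {-1, 0, 1}), plus a
single shared inhibitory neuron

    inh(i) = inh_max / (exp(-4 b_inh (i - a_inh)) + 1)

that is shallower than the excitatory units (`b_inh < b`) and has a higher
ceiling (`inh_max > 1`).  The factor 4 makes `b` exactly the slope at the
turning point.

**Intermediate layer.** Each of K intermediate neurons receives its
cognate excitatory input and the shared inhibition through a
threshold-linear activation,

    inter_k(i) = Rect(w_exc[k] exc_k(i) + w_inh[k] inh(i)),

which yields bell-shaped (non-monotonic) intensity tuning: excitation
rises first, inhibition catches up and closes the bell.

**Homeostatic plasticity.** With uniform weights the bells are *nested* —
the most sensitive channel dominates everywhere — and no intensity-specific
memory is possible.  The package implements the static mean effect of
homeostatic plasticity through the sensitivity integral

    s(a) = Integral_{c0}^{c1} exc(i) di
         = ln[(1 + e^{4b(c1-a)}) / (1 + e^{4b(c0-a)})] / (4b),

either at the excitatory synapses (`w_exc(a) = -alpha (s(a) - d)`, with
inhibition fixed at -1) or at the inhibitory synapses
(`w_inh(a) = -alpha_tilde s(a)`, with excitation fixed at 1).  Both
variants de-nest the tuning curves so that they tile the intensity axis.

**Output layer and learning.** A single output neuron reads out

    out(i) = sum_k w_training[k] inter_k(i),

and a single odour–shock pairing at intensity `i_t` sets
`w_training[k] = Theta(shock) inter_k(i_t)` (Heaviside-gated copy of the
presynaptic activity).  With homeostasis the trained output peaks near
`i_t`; without it, every training intensity produces the same output peak.

The package also ships the behavioural-curve pipeline used to quantify
intensity generalization: normalization of conditioned-avoidance-score
(CAS) tables to the matched training/test point, Gaussian least-squares
fitting on the log relative-intensity axis, and HWHM extraction
(`HWHM = sigma * sqrt(2 ln 2)`), plus a seeded synthetic CAS generator for
validating the pipeline, and a deterministic parameter-robustness sweep.

## Worked example

```r
library(odourcircuit)

spec <- default_circuit_spec("excitatory")
spec
#> <circuit_spec> 3 excitatory units, mode = excitatory
#>   a_k: -1,  0,  1 (b = 6)
#>   inhibition: a_inh = 2.3846, b_inh = 0.325, inh_max = 3.5
#>   effective w_exc: 0.1189, 0.3788, 1.0675
#>   effective w_inh: -1, -1, -1

batt <- run_experiment_battery(spec, c(-1, 0, 1))
vapply(batt, `[[`, numeric(1), "peak_intensity")
#> [1] -0.85  0.15  1.15
specificity_score(batt)
#> [1] 0.15
```

Training at -1, 0 and 1 log units produces output peaks at -0.85, 0.15
and 1.15: the memory tracks the trained intensity with the model's
intrinsic localization resolution of about 0.15 log units (the residual
rightward shift of each intermediate bell relative to its half-activation
point; see the vignette).  The same battery on
`default_circuit_spec("none")` peaks at -0.83 for *all three* training
intensities (`specificity_score` 1.83): without homeostasis the memory
carries no usable intensity information.

Fitting a synthetic behavioural table:

```r
tab <- generate_cas(synthetic_cas_config(true_hwhm = 1.1, seed = 7))
fit_cas_gaussian(normalize_cas(tab))
#> <gaussian_fit> A = 1.035, mean = 0.009603, sigma = 0.9063, HWHM = 1.067 (log10 relative intensity)
```

The recovered half width at half maximum (1.07) matches the generating
value of 1.1 to within the noise of a single table.

A command-line wrapper with subcommands `simulate`, `train-test`,
`sweep`, `fit-cas` and `generate-cas` is installed at
`inst/cli/odourcircuit`; see `?cli_main`.

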