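Package: odourcircuit
Title: Feed-Forward Circuit Model of Odour-Intensity Coding and
    Intensity-Specific Associative Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a minimal three-layer feed-forward circuit that
    transforms monotonic (logistic) odour-intensity responses of sensory
    input neurons into non-monotonic, non-nested intensity tuning through
    convergent excitation and inhibition combined with the mean effect of
    homeostatic synaptic plasticity.  Provides a reinforcement-gated
    associative learning rule at the output synapses, simulated
    train/test experiments probing the intensity specificity of the
    acquired memory, shape metrics for tuning curves (peak, width,
    nestedness), a parameter-robustness sweep, and a behavioural analysis
    pipeline that normalizes conditioned-avoidance-score generalization
    data and extracts Gaussian half-widths, together with a synthetic
    data generator for testing that pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
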