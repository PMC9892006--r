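Package: dopaseq
Title: Dopamine Fluctuations and Sub-Second Behavioural Syllable Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis machinery linking sub-second behavioural syllables to
    striatal dopamine fluctuations measured by fiber photometry. Provides a
    synthetic-session generator with known ground truth (Markovian syllable
    sequences without self-transitions, bi-exponential dopamine transients on
    a bleaching baseline, shared motion artifacts, closed-loop optogenetic
    stimulation schedules); photometry preprocessing (sliding-percentile
    dF/F0, robust reference subtraction, sliding z-scoring, quality control,
    transient detection); syllable-level statistics (peak extraction,
    expanding-bin correlations, transition entropy, exponential decay
    timescales, robust regression with shuffle inference); encoding models
    (ZCA-whitened Bayesian linear regression and convolution-kernel
    regression); a dopamine-dependent sequence decoding model with control
    models and an extra-dopamine variant; Q-learning agents with softmax
    policies using dopamine as reward or as the full prediction-error term;
    and closed-loop reinforcement quantification (excess target counts,
    learner classification, temporal and kinematic specificity, learning
    scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
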