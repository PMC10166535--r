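Package: drowsival
Title: Convergent Validity Analysis of Observer-Rated Driver Drowsiness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating video-based observer rating of drowsiness
    (ORD) against subjective, behavioural and physiological drowsiness
    measures recorded during simulated driving. Provides signal-level
    extraction of seven trial-wise measures (mean ORD, Karolinska sleepiness
    scale, standard deviation of lateral lane position, PERCLOS, percentage
    of time occupied by slow eye movements, and EEG alpha and theta band
    power), a synthetic multimodal cohort generator driven by a latent
    drowsiness process, and the convergent-validity statistical battery:
    per-participant Pearson correlations, Fisher z-transformation with
    one-sample t-tests, and one-way repeated-measures ANOVA over trials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
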