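Package: cotrans
Title: Decomposition of Purinergic and Cholinergic Cotransmission in
    Nerve-Mediated Frequency-Response Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse nerve-mediated smooth muscle responses evoked
    by electrical field stimulation. Frequency-response curves for tension
    and neurotransmitter (ATP) release are decomposed into low-frequency
    (purinergic) and high-frequency (cholinergic) Hill-type components by
    multi-start bounded Levenberg-Marquardt least squares; acetylcholine
    release is fitted with a one-component curve and intervention-induced
    percentage-reduction profiles with a sigmoidal interpolating curve.
    Includes nested one- versus two-component model selection by the
    extra-sum-of-squares F test, bioluminescence/fluorescence assay
    calibration (log-log and linear) with detection-limit handling, paired
    statistics (paired t, repeated-measures one-way ANOVA with Holm post
    hoc tests, Pearson correlation, paired power calculations), a seeded
    synthetic cohort generator for paired control/intervention designs, and
    a pipeline that produces per-preparation fits and cohort summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
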