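Package: somnaudit
Title: Design Audits for Sleepiness Speech Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and auditing speech corpora annotated with
    clinical sleepiness measures (Karolinska Sleepiness Scale, Maintenance of
    Wakefulness Test, Multiple Sleep Latency Test). Provides manifest I/O and
    validation for speech-health corpora, binarization of clinical labels into
    sleepy/non-sleepy classes with saturation-aware handling of sleep-latency
    ceilings, covariate bias audits (Mann-Whitney, Yates-corrected chi-squared,
    Spearman correlation), samples-per-speaker outlier detection, a guideline
    linter, and a per-feature convergence procedure that estimates the minimum
    audio sample length needed for acoustic functionals to stabilize. A
    synthetic corpus generator with controllable bias injections makes every
    stage testable without access to restricted clinical datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
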