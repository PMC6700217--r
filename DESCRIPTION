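Package: lfpdrink
Title: Corticostriatal LFP Oscillations and Alcohol-Drinking Phenotype
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline linking corticostriatal local field
    potential (LFP) oscillations to high- versus low-alcohol-drinking
    phenotype in rats. Provides a synthetic multichannel LFP and drinking
    generator with known ground truth, signal preprocessing (60 Hz notch
    filtering, decimation, amplitude-threshold artifact rejection, fixed
    length epoching), Welch band-power and magnitude-squared-coherence
    feature extraction into a 60-feature table, median-split phenotype
    labelling, permutation-validated L1-penalized logistic classification
    with single-feature information ranking, and two-by-two mixed ANOVA
    stimulation-response statistics. All user-facing functions take and
    return tidy data frames so stages compose with the pipe.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
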