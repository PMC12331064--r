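Package: wordtrf
Title: Recurrent Word-Recognition Models and Temporal Response Function
    Encoding Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation pipeline linking spoken-word recognition by stacked
    LSTM networks to continuous neural response data. Generates synthetic
    phoneme-coded lexicons with controlled cohort structure and multi-talker
    spectrogram tokens; trains LSTM word recognizers under localist, sparse
    random vector, or dense semantic output codings with a standard or
    competition-friendly binary cross-entropy loss; decodes lexical
    activation, word error rates and cohort-competition profiles; reduces
    hidden-unit activity to population predictors (summed magnitude and
    rectified change); and estimates multivariate temporal response functions
    by boosting with validation-based kernel freezing under 4-fold
    cross-validation, including model comparison and unique-variance
    attribution on simulated multi-subject response data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
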