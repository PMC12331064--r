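# Small shared fixtures, generated in code.

tiny_lexicon <- function(n_words = 6, n_talkers = 2, density = 0.5,
                         seed = 7, ...) {
  build_lexicon(n_words, n_phonemes = 8, length_range = c(2, 4),
                neighborhood_density = density, n_talkers = n_talkers,
                seed = seed, ...)
}

# a lexicon with hand-chosen phoneme sequences, for enumeration oracles
manual_lexicon <- function(words, n_phonemes = 6, n_talkers = 1, seed = 1) {
  lex <- build_lexicon(max(2, length(words)), n_phonemes = n_phonemes,
                       length_range = c(1, 6), neighborhood_density = 0,
                       n_talkers = n_talkers, seed = seed)
  lex$words <- lapply(words, as.integer)
  lex
}

# smooth stochastic series for TRF predictors
smooth_noise_series <- function(T, width = 8) {
  as.numeric(stats::filter(rnorm(T + 3 * width),
                           rep(1 / width, width), sides = 1))[
    (3 * width + 1):(T + 3 * width)]
}

smooth_predictors <- function(P, T, seed = 1) {
  with_seed(seed, t(vapply(seq_len(P), function(i) smooth_noise_series(T),
                           numeric(T))))
}
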