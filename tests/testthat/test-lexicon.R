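test_that("build_lexicon produces unique words and respects capacity limits", {
  # forced uniqueness: 3 words from a 2-phoneme inventory at length 2
  lex <- build_lexicon(3, n_phonemes = 2, length_range = c(2, 2),
                       neighborhood_density = 0, seed = 1)
  keys <- vapply(lex$words, paste, collapse = ".", FUN.VALUE = "")
  expect_length(unique(keys), 3)
  expect_true(all(lengths(lex$words) == 2))

  # inventory too small for the requested lexicon
  expect_error(build_lexicon(10, n_phonemes = 2, length_range = c(1, 1)),
               "cannot support")
})

test_that("neighborhood density creates onset-sharing cohorts, homophone-free", {
  lex <- build_lexicon(50, neighborhood_density = 0.5, seed = 5)
  keys <- vapply(lex$words, paste, collapse = ".", FUN.VALUE = "")
  expect_length(unique(keys), 50)   # duplicates discarded during generation
  overlaps <- vapply(1:49, function(i)
    max(vapply((i + 1):50, function(j)
      shared_onset_phonemes(lex$words[[i]], lex$words[[j]]), integer(1))),
    integer(1))
  expect_gte(max(overlaps), 1)      # at least one onset-sharing pair
  expect_gte(sum(overlaps >= 2), 1) # cohorts exist at depth >= 2
})

test_that("shared_onset_phonemes is a symmetric, bounded common-prefix length", {
  expect_identical(shared_onset_phonemes(c(1, 2, 3, 4, 5), c(1, 2, 6, 7)), 2L)
  w <- c(3, 1, 4, 1)
  expect_identical(shared_onset_phonemes(w, w), 4L)
  expect_identical(shared_onset_phonemes(c(1, 2), c(2, 2)), 0L)
  set.seed(1)
  for (i in 1:20) {
    a <- sample(4, sample(1:5, 1), replace = TRUE)
    b <- sample(4, sample(1:5, 1), replace = TRUE)
    k <- shared_onset_phonemes(a, b)
    expect_identical(k, shared_onset_phonemes(b, a))
    expect_lte(k, min(length(a), length(b)))
  }
})

test_that("cohort matches exhaustive prefix enumeration", {
  lex <- manual_lexicon(list(c(1, 2), c(1, 3), c(1, 4)))
  expect_setequal(cohort(lex, 1, 0), 1:3)
  expect_setequal(cohort(lex, 1, 1), 1:3)
  expect_setequal(cohort(lex, 1, 2), 1)
  # longer words extending a full prefix stay in the cohort
  lex2 <- manual_lexicon(list(c(1, 2), c(1, 2, 3), c(2, 2)))
  expect_setequal(cohort(lex2, 1, 2), c(1, 2))
})

test_that("theoretical target probability follows 1 / cohort size", {
  lex <- manual_lexicon(list(c(1, 2), c(1, 3), c(1, 4)))
  p <- theoretical_target_probability(lex, 1, c(0, 1, 2))
  expect_equal(p, c(1 / 3, 1 / 3, 1))
  # unique first phoneme: probability 1 from the first phoneme onward
  lex2 <- manual_lexicon(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(theoretical_target_probability(lex2, 2, c(0, 1, 2)),
               c(1 / 3, 1, 1))
})

test_that("token synthesis is deterministic, rate-scaled, onset-shared", {
  lex <- tiny_lexicon(seed = 3)
  tk1 <- lex$talkers[[1]]; tk2 <- lex$talkers[[2]]
  a <- synthesize_token(lex, 1, tk1, token_seed = 42)
  b <- synthesize_token(lex, 1, tk1, token_seed = 42)
  expect_identical(a$spectrogram, b$spectrogram)
  expect_true(all(is.finite(a$spectrogram)) && all(a$spectrogram >= 0))
  expect_identical(a$duration_frames, ncol(a$spectrogram))

  # duration ratio across talkers tracks the rate factor
  c2 <- synthesize_token(lex, 1, tk2, token_seed = 42)
  expected_ratio <- max(2, round(8 * tk2$rate_factor)) / 8
  expect_equal(c2$duration_frames / a$duration_frames, expected_ratio)

  # words sharing the first phoneme and talker: identical initial frames
  lexm <- manual_lexicon(list(c(1, 2, 3), c(1, 4, 5)))
  lexm$talkers[[1]]$jitter_scale <- 0
  t1 <- synthesize_token(lexm, 1, lexm$talkers[[1]], 1)
  t2 <- synthesize_token(lexm, 2, lexm$talkers[[1]], 1)
  d1 <- t1$phoneme_frames[1]
  expect_identical(t1$spectrogram[, 1:(d1 - 1)], t2$spectrogram[, 1:(d1 - 1)])
})

test_that("token partition is a disjoint cover honoring pins and fractions", {
  lex <- build_lexicon(32, n_talkers = 4, seed = 9)
  tok <- synthesize_tokens(lex, seed = 10)
  part <- partition_tokens(tok, holdout_fraction = 1 / 16, seed = 2)
  key <- function(df) paste(df$word_id, df$talker_id)
  expect_length(intersect(key(part$train), key(part$test)), 0)
  expect_identical(nrow(part$train) + nrow(part$test), 32L * 4L)
  per_talker <- table(part$test$talker_id)
  expect_true(all(abs(per_talker - 32 / 16) <= 1))
  # every word still trainable
  expect_true(all(seq_len(32) %in% part$train$word_id))

  # degenerate fraction rejected
  expect_error(partition_tokens(tok, holdout_fraction = 1e-4),
               "empty test set")

  # pinned tokens never land in test
  pin <- data.frame(word_id = 1:32, talker_id = 1L)
  part2 <- partition_tokens(tok, 1 / 16, seed = 3, pinned = pin)
  expect_false(any(part2$test$talker_id == 1 & part2$test$word_id %in% 1:32))
})

test_that("lexicon round-trips through its delimited text format", {
  lex <- tiny_lexicon(seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  expect_identical(read_lexicon_words(path), lapply(lex$words, as.integer))
})
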