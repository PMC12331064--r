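test_that("activation transforms match each coding's decoding rule", {
  # localist: identity
  coding <- make_coding("localist", 3)
  out <- matrix(runif(9), 3)
  expect_identical(to_activation(out, coding), out)

  # srv: per-word minimum across assigned elements
  srv <- make_coding("srv", 2, dim = 6, srv_k = 2, seed = 1)
  srv$elements <- list(c(2L, 5L), c(1L, 3L))
  o <- matrix(0.1, 6, 1); o[2] <- 0.8; o[5] <- 0.3; o[1] <- 0.9; o[3] <- 0.4
  a <- to_activation(o, srv)
  expect_equal(a[1, 1], 0.3)
  expect_equal(a[2, 1], 0.4)

  # semantic: negative distance; exact hit gives 0, all others negative
  sem <- make_coding("semantic", 4, dim = 5, seed = 2)
  a2 <- to_activation(sem$vectors[, 3, drop = FALSE], sem)
  expect_equal(a2[3, 1], 0, tolerance = 1e-7)
  expect_true(all(a2[-3, 1] < 0))
})

test_that("recognition uses the final-window mean with deterministic ties", {
  act <- matrix(0, 3, 20)
  act[2, 11:20] <- 1
  expect_identical(recognize(act, 1, 20), 2L)
  # constant activation favoring a wrong word returns that word
  act2 <- matrix(0, 3, 20); act2[3, ] <- 0.5
  expect_identical(recognize(act2, 1, 20), 3L)
  # exact tie: lowest word id wins
  act3 <- matrix(0.5, 3, 20)
  expect_identical(recognize(act3, 1, 20), 1L)
  # positive affine transforms leave the decision unchanged
  set.seed(1)
  act4 <- matrix(runif(60), 3)
  expect_identical(recognize(act4, 5, 20), recognize(3 * act4 + 2, 5, 20))
})

test_that("word error rate counts misrecognized tokens, optionally per talker", {
  ann <- data.frame(word_id = c(1, 2), talker_id = c(1, 2),
                    onset = c(1, 11), offset = c(10, 20))
  perfect <- rbind(c(rep(1, 10), rep(0, 10)), c(rep(0, 10), rep(1, 10)))
  expect_equal(word_error_rate(perfect, ann), 0)
  expect_equal(word_error_rate(perfect[2:1, ], ann), 1)
  half <- perfect; half[, 11:20] <- 0.5
  expect_equal(word_error_rate(half, ann), 0.5)
  expect_equal(unname(word_error_rate(half, ann, by_talker = TRUE)[2]), 1)
  # a model that outputs the targets themselves has WER exactly 0
  coding <- make_coding("localist", 2)
  y <- make_targets(ann, coding, 20)
  expect_equal(word_error_rate(y, ann), 0)
})

test_that("relative target activation normalizes over the lexicon", {
  ann <- data.frame(word_id = 2, onset = 1, offset = 4)
  act <- matrix(1, 5, 4)
  expect_equal(relative_target_activation(act, ann), rep(1 / 5, 4))
  act2 <- matrix(0, 5, 4); act2[2, ] <- 0.7
  expect_equal(relative_target_activation(act2, ann), rep(1, 4))
  act3 <- matrix(0.1, 5, 4); act3[2, ] <- 0.5
  expect_equal(relative_target_activation(act3, ann), rep(0.5 / 0.9, 4))
  # near-zero total activation falls back to the uninformative prior
  act4 <- matrix(1e-14, 5, 4)
  expect_equal(relative_target_activation(act4, ann), rep(1 / 5, 4))
  # relative activations over the whole lexicon sum to 1 by construction
  set.seed(2)
  act5 <- matrix(runif(20), 5)
  rel <- vapply(1:5, function(w)
    relative_target_activation(act5, data.frame(word_id = w, onset = 1,
                                                offset = 4)), numeric(4))
  expect_equal(rowSums(rel), rep(1, 4))
})

test_that("competition profiles group competitors by onset overlap", {
  # no onset overlap: only the k=0 group and the target are populated
  lex <- manual_lexicon(list(c(1, 2), c(2, 3), c(3, 4)))
  ann <- data.frame(word_id = 1, talker_id = 1, onset = 1, offset = 4)
  act <- matrix(runif(12), 3)
  prof <- competition_profile(act, ann, lex, max_k = 2, window = 4)
  expect_true(all(is.finite(prof$competitor[1, ])))
  expect_true(all(is.na(prof$competitor[2:3, ])))
  # single token: profile equals that token's group means
  expect_equal(prof$competitor[1, ], colMeans(act[2:3, ]))
  expect_equal(prof$target, act[1, ])

  # activations equal to theoretical cohort probabilities reproduce the
  # theoretical relative activation exactly
  lex2 <- manual_lexicon(list(c(1, 2), c(1, 3), c(2, 3)))
  tl <- c(0, 1, 2)
  p <- theoretical_target_probability(lex2, 1, tl)
  act2 <- rbind(p,
                theoretical_target_probability(lex2, 2, tl) *
                  c(1, 1, 0),   # competitor drops out when excluded
                theoretical_target_probability(lex2, 3, tl) * c(1, 0, 0))
  ann2 <- data.frame(word_id = 1, talker_id = 1, onset = 1, offset = 3)
  prof2 <- competition_profile(act2, ann2, lex2, max_k = 1, window = 3)
  expect_equal(prof2$target, p)
})

test_that("early competitor activation summary averages the k >= k_min group", {
  lex <- manual_lexicon(list(c(1, 2, 3), c(1, 2, 4), c(5, 6)))
  ann <- data.frame(word_id = 1, talker_id = 1, onset = 1, offset = 6)
  act <- matrix(0, 3, 6)
  act[2, 1:3] <- 0.9   # deep competitor active early
  expect_equal(mean_competitor_activation(act, ann, lex, k_min = 2,
                                          window = 3), 0.9)
})

test_that("output-space structure detects onset-graded distances", {
  # vectors constructed so distance shrinks with onset overlap: r < 0
  lex <- manual_lexicon(list(c(1, 2, 3), c(1, 2, 4), c(1, 5, 6), c(2, 5, 6)))
  base <- diag(4) * 2
  v <- base
  v[2, ] <- v[1, ] + 0.1   # shares 2 onset phonemes with word 1: very close
  v[3, ] <- v[1, ] + 1.0   # shares 1: moderately close
  res <- output_space_structure(v, lex)
  expect_lt(res$r, 0)
  expect_identical(res$n_pairs, 6L)

  # seeded random vectors: negligible correlation
  lex2 <- build_lexicon(120, neighborhood_density = 0.5, seed = 12)
  v2 <- with_seed(1, matrix(rnorm(120 * 16), 120))
  res2 <- output_space_structure(v2, lex2)
  expect_lt(abs(res2$r), 0.08)

  # degenerate: identical vectors
  expect_warning(res3 <- output_space_structure(matrix(1, 4, 3), lex),
                 "undefined")
  expect_true(is.na(res3$r))
  expect_error(output_space_structure(matrix(1, 1, 3), lex), "at least 2")
})

test_that("output mapping vectors have one row per word", {
  coding <- make_coding("localist", 5)
  m <- build_model(model_config(8, coding))
  v <- output_mapping_vectors(m)
  expect_identical(dim(v), c(5L, 8L))
})
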