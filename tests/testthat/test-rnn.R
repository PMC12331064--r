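test_that("parameter count matches construction and the closed form", {
  expect_identical(count_parameters(1, input_dim = 1), 12)
  # brute-force count of a built model's core weights (output head excluded)
  coding <- make_coding("localist", 5)
  cfg <- model_config(c(6, 4), coding, input_dim = 3)
  m <- build_model(cfg)
  brute <- sum(vapply(m$weights$layers, function(l)
    length(l$Wx) + length(l$Wh) + length(l$b), numeric(1)))
  expect_identical(brute, count_parameters(c(6, 4), input_dim = 3))
})

test_that("binary cross-entropy matches hand computations", {
  y <- matrix(c(1, 0)); p <- matrix(c(0.5, 0.5))
  expect_equal(bce_loss(y, p), log(2))
  expect_lt(bce_loss(y, matrix(c(1 - 1e-7, 1e-7))), 1e-6)
  expect_lt(bce_loss(matrix(0, 3, 2), matrix(1e-7, 3, 2)), 1e-6)
})

test_that("competition loss reduces to bce at c = 1 and discounts non-targets", {
  y <- matrix(c(1, 0)); p <- matrix(c(0.5, 0.5))
  expect_equal(lill_loss(y, p, c = 2, word_mask = TRUE), 0.75 * log(2))
  set.seed(2)
  for (i in 1:10) {
    yy <- matrix(rbinom(40, 1, 0.2), 8)
    pp <- matrix(runif(40, 0.05, 0.95), 8)
    mask <- runif(5) < 0.6
    expect_equal(lill_loss(yy, pp, 1, mask), bce_loss(yy, pp),
                 tolerance = 1e-12)
    # non-increasing in c when masked non-target errors exist
    cs <- c(1, 2, 8, 64)
    ls <- vapply(cs, function(cc) lill_loss(yy, pp, cc, mask), numeric(1))
    expect_true(all(diff(ls) <= 1e-12))
  }
  # c -> Inf limit keeps only the target term on masked frames
  expect_equal(lill_loss(y, p, c = 1e12, word_mask = TRUE), 0.5 * log(2),
               tolerance = 1e-9)
})

test_that("lill gradient on masked non-targets is 1/c of the bce gradient", {
  set.seed(3)
  y <- matrix(rbinom(20, 1, 0.3), 4)
  p <- matrix(runif(20, 0.1, 0.9), 4)
  mask <- rep(TRUE, 5)
  nt <- which(y == 0)[1]
  eps <- 1e-6
  fd <- function(f) {
    pp <- p; pp[nt] <- pp[nt] + eps
    pm <- p; pm[nt] <- pm[nt] - eps
    (f(pp) - f(pm)) / (2 * eps)
  }
  g_bce <- fd(function(pp) bce_loss(y, pp))
  g_lill <- fd(function(pp) lill_loss(y, pp, c = 8, word_mask = mask))
  expect_equal(g_lill, g_bce / 8, tolerance = 1e-5)
})

test_that("model construction honors codings and rejects lill + semantic", {
  loc <- build_model(model_config(16, make_coding("localist", 7)))
  expect_identical(nrow(loc$weights$Wy), 7L)
  sem <- build_model(model_config(16, make_coding("semantic", 7, dim = 50,
                                                  seed = 1)))
  expect_identical(nrow(sem$weights$Wy), 50L)
  srv <- build_model(model_config(16, make_coding("srv", 7, dim = 300,
                                                  srv_k = 10, seed = 1)))
  expect_identical(nrow(srv$weights$Wy), 300L)
  expect_error(model_config(16, make_coding("semantic", 7, dim = 10, seed = 1),
                            loss = "lill"), "binary")
})

test_that("analytic BPTT gradients match finite differences", {
  set.seed(4)
  coding <- make_coding("localist", 3)
  cfg <- model_config(c(4, 3), coding, input_dim = 3)
  m <- build_model(cfg, seed = 2)
  B <- 2L; Tn <- 5L
  x <- matrix(rnorm(3 * B * Tn), 3)
  y <- matrix(rbinom(3 * B * Tn, 1, 0.3), 3)
  w <- matrix(ifelse(runif(3 * B * Tn) < 0.5, 1, 0.25), 3)
  h0 <- list(matrix(0, 4, B), matrix(0, 3, B))
  f <- function(wt) wordtrf:::cpp_lstm_run(wt, x, y, w, B, 0L, FALSE, h0, h0,
                                           FALSE, FALSE, FALSE)$loss
  res <- wordtrf:::cpp_lstm_run(m$weights, x, y, w, B, 0L, FALSE, h0, h0,
                                TRUE, FALSE, FALSE)
  eps <- 1e-6
  for (l in 1:2) for (nm in c("Wx", "Wh", "b")) {
    g <- res$grads$layers[[l]][[nm]]
    for (i in sample(length(g), 6)) {
      wp <- m$weights; wp$layers[[l]][[nm]][i] <- wp$layers[[l]][[nm]][i] + eps
      wm <- m$weights; wm$layers[[l]][[nm]][i] <- wm$layers[[l]][[nm]][i] - eps
      fd <- (f(wp) - f(wm)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss, is seeded, and keeps the best weights", {
  lex <- build_lexicon(2, n_phonemes = 6, length_range = c(2, 3),
                       neighborhood_density = 0, n_talkers = 1, seed = 5)
  tok <- synthesize_tokens(lex, seed = 6)
  coding <- make_coding("localist", 2)
  cfg <- model_config(16, coding, lr = 5e-3)
  src <- make_stream_source(tok, coding, batch_size = 2,
                            segments_per_stream = 4, segment_frames = 200)
  m1 <- train_model(build_model(cfg, seed = 1), src, n_epochs = 25, seed = 9)
  expect_lt(tail(m1$history, 1), m1$history[1])
  expect_equal(m1$best_loss, min(m1$history))
  # identical seed: identical loss history
  m2 <- train_model(build_model(cfg, seed = 1), src, n_epochs = 25, seed = 9)
  expect_identical(m1$history, m2$history)
  # returned weights are the best ones: re-evaluating them cannot be worse
  expect_identical(m1$weights, {
    m3 <- train_model(build_model(cfg, seed = 1), src, n_epochs = 25, seed = 9)
    m3$weights
  })
})

test_that("run_model is exactly invariant to segmentation with state carry", {
  coding <- make_coding("localist", 4)
  m <- build_model(model_config(c(8, 6), coding), seed = 3)
  set.seed(10)
  x <- matrix(abs(rnorm(64 * 120)), 64)
  full <- run_model(m, x)
  segd <- run_model(m, x, segment_frames = 37)
  expect_equal(full$outputs, segd$outputs, tolerance = 1e-12)
  expect_equal(full$hidden, segd$hidden, tolerance = 1e-12)
  # sigmoid head keeps localist outputs in (0, 1); traces aligned to frames
  expect_true(all(full$outputs > 0 & full$outputs < 1))
  expect_identical(ncol(full$hidden[[1]]), 120L)
  expect_identical(nrow(full$hidden[[2]]), 6L)
})
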