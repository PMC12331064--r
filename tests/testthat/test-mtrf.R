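test_that("TRF convolution is an impulse-faithful linear operator", {
  delays <- trf_delays()
  set.seed(1)
  x <- matrix(rnorm(2 * 300), 2)
  # unit impulse at delay 0 for one predictor reproduces that predictor
  h <- matrix(0, 2, length(delays)); h[1, which(delays == 0)] <- 1
  expect_equal(convolve_predict(h, x), x[1, ])
  # impulse at delay k shifts the predictor by k
  h2 <- matrix(0, 2, length(delays)); h2[2, which(delays == 7)] <- 1
  yh <- convolve_predict(h2, x)
  expect_equal(yh[8:300], x[2, 1:293])
  expect_equal(yh[1:7], rep(0, 7))
  # linearity
  h3 <- matrix(rnorm(2 * length(delays)), 2)
  h4 <- matrix(rnorm(2 * length(delays)), 2)
  expect_equal(convolve_predict(h3 + h4, x),
               convolve_predict(h3, x) + convolve_predict(h4, x))
  # default 50 Hz grid spans -100..1000 ms in 56 delays
  expect_identical(delays, -5:50)
})

test_that("boosting returns a zero kernel for a constant response", {
  set.seed(2)
  x <- matrix(rnorm(2 * 400), 2)
  f <- boost_fit(x, rep(1, 400), train = list(1:200), validation = 201:400,
                 delays = 0:9)
  expect_equal(sum(abs(f$h)), 0)
})

test_that("boosting recovers a noiseless sparse kernel", {
  set.seed(3)
  delays <- 0:19
  x <- matrix(rnorm(2 * 2000), 2)
  h_true <- matrix(0, 2, 20)
  h_true[1, 5] <- 1; h_true[1, 9] <- -0.5; h_true[2, 2] <- 0.8
  y <- convolve_predict(h_true, x, delays)
  f <- boost_fit(x, y, train = list(1:800, 801:1400), validation = 1401:2000,
                 delta = 0.01, delays = delays, max_steps = 5000)
  expect_gt(cor(as.numeric(f$h), as.numeric(h_true)), 0.95)
})

test_that("boosting training error is monotone and frozen kernels stay frozen", {
  set.seed(4)
  delays <- 0:14
  x <- matrix(rnorm(3 * 900), 3)
  h_true <- matrix(0, 3, 15); h_true[1, 3] <- 1; h_true[2, 7] <- -0.7
  y <- convolve_predict(h_true, x, delays) + rnorm(900, 0, 1)
  f <- boost_fit(x, y, train = list(1:400, 401:650), validation = 651:900,
                 delta = 0.03, delays = delays, max_steps = 400,
                 record_steps = TRUE)
  expect_true(all(diff(f$train_sse) <= 1e-9))
  # after a predictor's freeze event (sign 0), it never receives a step again
  for (p in unique(f$steps$predictor[f$steps$sign == 0])) {
    frozen_at <- min(which(f$steps$predictor == p & f$steps$sign == 0))
    later <- f$steps[-seq_len(frozen_at), ]
    expect_false(any(later$predictor == p))
  }
})

test_that("boosting matches the brute-force greedy reference", {
  delays <- 0:19
  for (s in 1:3) {
    set.seed(100 + s)
    x <- matrix(rnorm(2 * 500), 2)
    h_true <- matrix(0, 2, 20); h_true[1, 4] <- 1; h_true[2, 9] <- -0.6
    y <- convolve_predict(h_true, x, delays) + rnorm(500, 0, 0.5)
    f1 <- boost_fit(x, y, list(1:200, 201:350), 351:500, delta = 0.05,
                    delays = delays, max_steps = 150, record_steps = TRUE)
    f2 <- oracle_boost(x, y, list(1:200, 201:350), 351:500, delta = 0.05,
                       delays = delays, max_steps = 150)
    expect_identical(nrow(f1$steps), nrow(f2$steps))
    expect_true(all(as.matrix(f1$steps) == f2$steps))
    expect_equal(f1$h, f2$h, tolerance = 1e-10)
  }
})

test_that("pure-noise responses yield near-zero cross-validated fit", {
  set.seed(5)
  x <- smooth_predictors(3, 10000, seed = 6)
  y <- rnorm(10000)
  fit <- crossval_fit(x, y)
  expect_lt(abs(fit$ve), 1)
  # fold bookkeeping: contiguous, disjoint, covering
  idx <- unlist(fit$folds)
  expect_identical(idx, 1:10000)
  expect_true(all(vapply(fit$folds, function(f) all(diff(f) == 1),
                         logical(1))))
})

test_that("cross-validated fits explain known-kernel responses", {
  set.seed(7)
  delays <- trf_delays()
  x <- smooth_predictors(2, 4000, seed = 8)
  sim <- simulate_subjects(x, n_subjects = 2, n_channels = 2, snr_db = 15,
                           seed = 9, roi_fraction = 1)
  fit <- crossval_fit(x, sim$subjects[[1]]$response)
  expect_true(all(fit$ve > 50))
  expect_identical(dim(fit$h), c(2L, length(delays), 2L))
})

test_that("model comparison attributes variance only to informative predictors", {
  set.seed(10)
  x_base <- smooth_predictors(2, 4000, seed = 11)
  x_add <- smooth_predictors(2, 4000, seed = 12)
  delays <- trf_delays()
  hb <- with_seed(13, t(vapply(1:2, function(i)
    wordtrf:::smooth_random_kernel(delays, 50), numeric(length(delays)))))
  ha <- with_seed(14, t(vapply(1:2, function(i)
    wordtrf:::smooth_random_kernel(delays, 50), numeric(length(delays)))))
  sig_b <- convolve_predict(hb, x_base)
  noise <- rnorm(4000, 0, sd(sig_b) * 10^(-10 / 20))

  # added predictors identical to the baseline: no unique variance
  mc_dup <- model_comparison(x_base, x_base, sig_b + noise)
  expect_lt(abs(mc_dup$improvement_pct), 2)

  # added predictors that truly drive the response: positive improvement
  sig_a <- convolve_predict(ha, x_add)
  sig_a <- sig_a * sd(sig_b) / sd(sig_a)
  mc_real <- model_comparison(x_base, x_add, sig_b + sig_a + noise)
  expect_gt(mc_real$improvement_pct, 5)

  # pure-noise additions do not help
  x_noise <- matrix(rnorm(2 * 4000), 2)
  mc_noise <- model_comparison(x_base, x_noise, sig_b + noise)
  expect_lt(mc_noise$improvement_pct, 1)
})

test_that("unique variance separates driving from duplicated parts", {
  set.seed(15)
  x_base <- smooth_predictors(1, 4000, seed = 16)
  xa <- smooth_predictors(1, 4000, seed = 17)
  xb <- smooth_predictors(1, 4000, seed = 18)
  delays <- trf_delays()
  hb <- with_seed(19, matrix(wordtrf:::smooth_random_kernel(delays, 50), 1))
  haa <- with_seed(20, matrix(wordtrf:::smooth_random_kernel(delays, 50), 1))
  y <- convolve_predict(hb, x_base) + convolve_predict(haa, xa)
  y <- y + rnorm(4000, 0, sd(y) * 0.2)
  uv <- unique_variance(x_base, list(a = xa, b = xb), y)
  expect_gt(uv$share["a", 1], 0.8)
  expect_lt(abs(uv$share["b", 1]), 0.2)
  # collinear parts: duplicated predictors have no unique share
  uv2 <- unique_variance(x_base, list(a = xa, b = xa), y)
  expect_lt(max(abs(uv2$share)), 0.3)
  # a single part carries the whole added contribution
  uv3 <- unique_variance(x_base, list(a = xa), y)
  expect_equal(unname(uv3$share["a", 1]), 1, tolerance = 0.05)
})
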