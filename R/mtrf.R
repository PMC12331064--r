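# Multivariate temporal response functions estimated by boosting coordinate
# descent with validation-based kernel freezing, scored by cross-validated
# % variance explained, with model comparison and unique-variance attribution.

#' Delay grid for TRF estimation
#'
#' @param rate analysis rate in Hz (default 50).
#' @param tmin,tmax delay range in seconds (default -0.1 to 1.0, i.e. 56
#'   delays at 50 Hz).
#' @return integer vector of delays in samples.
#' @export
trf_delays <- function(rate = 50, tmin = -0.1, tmax = 1.0) {
  seq(as.integer(round(tmin * rate)), as.integer(round(tmax * rate)))
}

#' Predict a response by linear convolution with a TRF
#'
#' `yhat_t = sum_i sum_tau h[i, tau] * x[i, t - tau]`, zero-padded outside the
#' series.
#'
#' @param h `P x n_delays` kernel matrix.
#' @param x `P x T` predictor matrix.
#' @param delays integer delays in samples (default [trf_delays()]).
#' @return numeric series of length T.
#' @export
convolve_predict <- function(h, x, delays = trf_delays()) {
  stopifnot(nrow(h) == nrow(x), ncol(h) == length(delays))
  as.numeric(cpp_convolve(h, x, delays[1]))
}

scale_rows <- function(x, centers, scales) {
  (x - centers) / scales
}

#' Boosting estimation of one TRF
#'
#' Greedy coordinate descent: at each step the single kernel element whose
#' change by `+/-delta` most reduces the training sum of squared errors is
#' selected (ties: lowest predictor, then lowest delay, then `+delta`); if the
#' change would increase the error on the validation segment it is reverted
#' and the whole kernel of that predictor is frozen. Fitting stops when every
#' predictor is frozen, no step strictly improves the training error, or
#' `max_steps` is reached. Predictors and response are mean-centered and
#' scaled to unit variance on the training segments, so `delta` is a fixed
#' step in standardized units; the returned kernel is on the original scale.
#'
#' @param x `P x T` predictor matrix.
#' @param y response vector of length T.
#' @param train list of integer index vectors (disjoint contiguous training
#'   segments).
#' @param validation integer index vector (validation segment).
#' @param delta step size in standardized units (default 0.005).
#' @param delays integer delays in samples.
#' @param max_steps cap on boosting steps.
#' @param record_steps also return the per-step log and training error trace.
#' @return list with `h` (`P x n_delays`, original scale), `delays`,
#'   `y_mean`, `x_center`, `x_scale`, and (if recorded) `steps` (data.frame
#'   `predictor`, `delay`, `sign`; `sign = 0` marks a freeze event) and
#'   `train_sse`.
#' @export
boost_fit <- function(x, y, train, validation, delta = 0.005,
                      delays = trf_delays(), max_steps = 10000,
                      record_steps = FALSE) {
  stopifnot(is.matrix(x), length(y) == ncol(x), delta > 0)
  tr_idx <- unlist(train)
  xc <- rowMeans(x[, tr_idx, drop = FALSE])
  xs <- apply(x[, tr_idx, drop = FALSE], 1, sd)
  xs[xs == 0] <- 1
  ym <- mean(y[tr_idx])
  ys <- sd(y[tr_idx])
  P <- nrow(x); D <- length(delays)
  if (ys == 0) {   # constant response: nothing to fit
    return(list(h = matrix(0, P, D), delays = delays, y_mean = ym,
                x_center = xc, x_scale = xs))
  }
  Xs <- scale_rows(x, xc, xs)
  yn <- (y - ym) / ys
  fit <- cpp_boost_multi(lapply(train, function(ix) Xs[, ix, drop = FALSE]),
                         lapply(train, function(ix) matrix(yn[ix], 1)),
                         Xs[, validation, drop = FALSE],
                         matrix(yn[validation], 1),
                         delays[1], D, delta, max_steps, record_steps)
  h <- matrix(fit$h[, , 1], P, D) * ys / xs
  out <- list(h = h, delays = delays, y_mean = ym, x_center = xc,
              x_scale = xs)
  if (record_steps) {
    st <- fit$steps[[1]]
    out$steps <- data.frame(predictor = st[, 1] + 1L, delay = st[, 2] + 1L,
                            sign = st[, 3])
    out$train_sse <- as.numeric(fit$sse[[1]])
  }
  out
}

#' Contiguous cross-validation folds
#' @keywords internal
make_folds <- function(n, n_folds) {
  sizes <- rep(n %/% n_folds, n_folds)
  sizes[seq_len(n %% n_folds)] <- sizes[seq_len(n %% n_folds)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

#' Cross-validated TRF estimation and predictive power
#'
#' The series is divided into `n_folds` contiguous segments. For each test
#' segment, the remaining segments are used to estimate one TRF per rotation
#' of the validation segment (each remaining segment serves once as
#' validation, the others as training); the rotations' TRFs are averaged and
#' used to predict the test segment. Test predictions are concatenated and
#' scored as % variance explained, `100 * (1 - SS_resid / SS_total)`, per
#' channel.
#'
#' @param x `P x T` predictor matrix.
#' @param y response: vector or `channels x T` matrix.
#' @param n_folds number of contiguous folds (default 4).
#' @param delta boosting step size.
#' @param delays integer delays in samples.
#' @param max_steps cap on boosting steps per fit.
#' @return a `"trf_fit"`: `ve` (% variance explained per channel), `h`
#'   (`P x n_delays x channels`, averaged over folds), `predicted`
#'   (`channels x T`), `folds`, `delays`.
#' @export
crossval_fit <- function(x, y, n_folds = 4, delta = 0.005,
                         delays = trf_delays(), max_steps = 10000) {
  if (is.vector(y)) y <- matrix(y, 1)
  Tn <- ncol(x)
  stopifnot(ncol(y) == Tn, Tn >= 2 * n_folds)
  Cn <- nrow(y)
  P <- nrow(x); D <- length(delays)
  folds <- make_folds(Tn, n_folds)
  pred <- matrix(0, Cn, Tn)
  h_sum <- array(0, c(P, D, Cn))
  for (f in seq_len(n_folds)) {
    others <- setdiff(seq_len(n_folds), f)
    tr_idx <- unlist(folds[others])
    xc <- rowMeans(x[, tr_idx, drop = FALSE])
    xs <- apply(x[, tr_idx, drop = FALSE], 1, sd); xs[xs == 0] <- 1
    ym <- rowMeans(y[, tr_idx, drop = FALSE])
    ys <- apply(y[, tr_idx, drop = FALSE], 1, sd); ys[ys == 0] <- 1
    Xn <- scale_rows(x, xc, xs)
    Yn <- scale_rows(y, ym, ys)
    h_fold <- array(0, c(P, D, Cn))
    for (v in others) {
      tr <- setdiff(others, v)
      fit <- cpp_boost_multi(
        lapply(folds[tr], function(ix) Xn[, ix, drop = FALSE]),
        lapply(folds[tr], function(ix) Yn[, ix, drop = FALSE]),
        Xn[, folds[[v]], drop = FALSE], Yn[, folds[[v]], drop = FALSE],
        delays[1], D, delta, max_steps, FALSE)
      h_fold <- h_fold + fit$h / length(others)
    }
    for (ch in seq_len(Cn)) {
      h_ch <- matrix(h_fold[, , ch], P, D)
      yh <- cpp_convolve(h_ch, Xn[, folds[[f]], drop = FALSE], delays[1])
      pred[ch, folds[[f]]] <- yh * ys[ch] + ym[ch]
      h_sum[, , ch] <- h_sum[, , ch] + (h_ch * ys[ch] / xs) / n_folds
    }
  }
  ve <- vapply(seq_len(Cn), function(ch) {
    sst <- sum((y[ch, ] - mean(y[ch, ]))^2)
    if (sst == 0) return(NA_real_)
    100 * (1 - sum((y[ch, ] - pred[ch, ])^2) / sst)
  }, numeric(1))
  structure(list(ve = ve, h = h_sum, predicted = pred, folds = folds,
                 delays = delays),
            class = "trf_fit")
}

#' Compare a full encoding model against a baseline
#'
#' Fits the baseline predictors and baseline + added predictors by
#' [crossval_fit()] and reports the raw difference and the % improvement in
#' explained variance, `100 * (ve_full - ve_base) / ve_base`, per channel.
#' Channels whose baseline variance explained is not positive get `NA`
#' improvement (flagged).
#'
#' @param x_base `P_base x T` baseline predictors.
#' @param x_added predictors added by the model under test.
#' @param y response matrix or vector.
#' @param ... passed to [crossval_fit()].
#' @return list with `ve_base`, `ve_full`, `improvement_raw`,
#'   `improvement_pct`, `undefined` (logical per channel).
#' @export
model_comparison <- function(x_base, x_added, y, ...) {
  stopifnot(ncol(x_base) == ncol(x_added))
  fit_base <- crossval_fit(x_base, y, ...)
  fit_full <- crossval_fit(rbind(x_base, x_added), y, ...)
  undefined <- !is.na(fit_base$ve) & fit_base$ve <= 0
  pct <- 100 * (fit_full$ve - fit_base$ve) / fit_base$ve
  pct[undefined] <- NA_real_
  list(ve_base = fit_base$ve, ve_full = fit_full$ve,
       improvement_raw = fit_full$ve - fit_base$ve,
       improvement_pct = pct, undefined = undefined)
}

#' Unique variance attribution among added predictor parts
#'
#' For each named part of the added predictors, the share of the RNN-attributed
#' variance that is lost when the part is removed:
#' `(ve_full - ve_without_part) / (ve_full - ve_base)`.
#'
#' @param x_base baseline predictor matrix.
#' @param parts named list of added predictor matrices.
#' @param y response.
#' @param ... passed to [crossval_fit()].
#' @return list with `ve_base`, `ve_full`, and `share` (matrix parts x
#'   channels).
#' @export
unique_variance <- function(x_base, parts, y, ...) {
  stopifnot(length(names(parts)) == length(parts))
  x_all <- do.call(rbind, parts)
  fit_base <- crossval_fit(x_base, y, ...)
  fit_full <- crossval_fit(rbind(x_base, x_all), y, ...)
  denom <- fit_full$ve - fit_base$ve
  share <- vapply(names(parts), function(nm) {
    x_wo <- do.call(rbind, parts[setdiff(names(parts), nm)])
    ve_wo <- crossval_fit(rbind(x_base, x_wo), y, ...)$ve
    (fit_full$ve - ve_wo) / denom
  }, numeric(length(fit_base$ve)))
  share <- matrix(share, ncol = length(parts),
                  dimnames = list(NULL, names(parts)))
  list(ve_base = fit_base$ve, ve_full = fit_full$ve, share = t(share))
}
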