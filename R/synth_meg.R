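# Synthetic multi-subject, multi-channel response data with the statistical
# structure the encoding analysis assumes (linear convolution of predictors
# with smooth kernels plus Gaussian noise), and the auditory baseline
# predictor set derived from a stimulus stream.

#' Auditory baseline predictors for a stream
#'
#' Seventeen series at the analysis rate: an 8-band log spectrogram (the 64
#' spectrogram bands averaged in adjacent groups of 8, log-transformed as
#' `log(x + 1e-3)`), an 8-band onset spectrogram (per-band half-wave rectified
#' temporal difference of the log spectrogram — a simple acoustic-edge
#' detector), and one word-onset predictor with a unit impulse at each
#' annotation onset.
#'
#' @param stream a `"word_stream"` at 100 Hz.
#' @param annotations defaults to the stream's annotations.
#' @param to_rate analysis rate (default 50 Hz). Spectrogram bands are
#'   FIR-decimated; the impulse series is rebinned so impulses stay unit
#'   impulses.
#' @return a `"predictor_set"`: `x` (17 x T'), `rate`.
#' @export
make_baseline_predictors <- function(stream, annotations = stream$annotations,
                                     to_rate = 50) {
  stopifnot(stream$rate == 100)
  nb <- nrow(stream$input)
  stopifnot(nb %% 8 == 0)
  grp <- rep(seq_len(8), each = nb / 8)
  spec8 <- log(rowsum(stream$input, grp) / (nb / 8) + 1e-3)
  Tn <- ncol(spec8)
  onset8 <- cbind(0, spec8[, -1, drop = FALSE] - spec8[, -Tn, drop = FALSE])
  onset8[onset8 < 0] <- 0
  q <- stream$rate / to_rate
  dn <- function(m) t(apply(m, 1, resample_series, from_rate = stream$rate,
                            to_rate = to_rate))
  spec_d <- dn(spec8)
  onset_d <- dn(onset8)
  T2 <- ncol(spec_d)
  imp <- numeric(T2)
  if (nrow(annotations) > 0) {
    pos <- pmin(ceiling(annotations$onset / q), T2)
    imp[pos] <- 1
  }
  x <- rbind(spec_d, onset_d, imp)
  rownames(x) <- c(paste0("spec", 1:8), paste0("onset", 1:8), "word_onset")
  structure(list(x = x, rate = to_rate), class = "predictor_set")
}

#' Smooth random kernel on a delay grid
#'
#' Sum of 1-2 Gaussian bumps with peaks confined to `peak_range` (seconds), so
#' the kernel is compactly supported well inside the delay window.
#' @keywords internal
smooth_random_kernel <- function(delays, rate, peak_range = c(0.02, 0.45)) {
  tau_s <- delays / rate
  nb <- sample(1:2, 1)
  k <- numeric(length(delays))
  for (j in seq_len(nb)) {
    center <- runif(1, peak_range[1], peak_range[2])
    width <- runif(1, 0.03, 0.1)
    amp <- rnorm(1, 0, 1)
    k <- k + amp * exp(-(tau_s - center)^2 / (2 * width^2))
  }
  k
}

#' Simulate multi-subject response sets from known kernels
#'
#' Per subject, true TRFs are drawn as smooth random kernels: a shared group
#' mean plus a subject-level smooth perturbation scaled by `subject_sd`. Each
#' channel's response is a gain-scaled copy of the convolved signal plus
#' Gaussian noise at `snr_db` (amplitude SNR on standard deviations). Channels
#' in the region of interest (the first `round(roi_fraction * n_channels)`)
#' have gains drawn from `U(0.5, 1.5)`; the remaining channels have zero gain
#' and carry noise only (scaled to the median in-ROI signal).
#'
#' @param predictors `P x T` matrix at the analysis rate (or a
#'   `"predictor_set"`).
#' @param n_subjects number of subjects (>= 2 for group statistics).
#' @param n_channels channels per subject (default 20).
#' @param snr_db response SNR in dB (default 10); `Inf` for noiseless.
#' @param seed integer seed.
#' @param subject_sd scale of subject-level kernel perturbations.
#' @param roi_fraction fraction of channels with signal.
#' @param rate analysis rate (Hz).
#' @param delays delay grid in samples.
#' @return list with `subjects` (each: `response` `n_channels x T`, `truth`
#'   `P x D` subject kernel, `gains`, `noise_sd`), `roi` (channel ids),
#'   `delays`, `rate`.
#' @export
simulate_subjects <- function(predictors, n_subjects = 10, n_channels = 20,
                              snr_db = 10, seed = 1, subject_sd = 0.2,
                              roi_fraction = 0.5, rate = 50,
                              delays = trf_delays(rate)) {
  if (inherits(predictors, "predictor_set")) predictors <- predictors$x
  stopifnot(n_subjects >= 2 || n_subjects == 1)
  P <- nrow(predictors); D <- length(delays)
  roi <- seq_len(max(1L, round(roi_fraction * n_channels)))
  with_seed(derive_seed(seed, 91L), {
    group <- t(vapply(seq_len(P), function(i)
      smooth_random_kernel(delays, rate), numeric(D)))
    subjects <- lapply(seq_len(n_subjects), function(s) {
      pert <- t(vapply(seq_len(P), function(i)
        smooth_random_kernel(delays, rate), numeric(D)))
      truth <- group + subject_sd * pert
      signal <- convolve_predict(truth, predictors, delays)
      sig_sd <- sd(signal)
      gains <- numeric(n_channels)
      gains[roi] <- runif(length(roi), 0.5, 1.5)
      noise_mult <- if (is.infinite(snr_db)) 0 else 10^(-snr_db / 20)
      noise_sd <- ifelse(gains > 0, gains * sig_sd, sig_sd) * noise_mult
      response <- outer(gains, signal) +
        matrix(rnorm(n_channels * length(signal)), n_channels) * noise_sd
      list(response = response, truth = truth, gains = gains,
           noise_sd = noise_sd)
    })
    list(subjects = subjects, roi = roi, delays = delays, rate = rate)
  })
}

#' Simulate responses driven by baseline and RNN predictors
#'
#' Builds ground-truth responses as `baseline convolution + mixing * RNN
#' convolution + noise`, so that with `mixing > 0` an encoding-model
#' comparison must attribute unique variance to the RNN predictor set, and
#' with `mixing = 0` the expected improvement is nil.
#'
#' @param x_base `P_base x T` baseline predictors.
#' @param x_rnn `P_rnn x T` RNN-derived predictors.
#' @param mixing weight of the RNN contribution, in units of the baseline
#'   signal's standard deviation (the RNN signal is rescaled to the baseline
#'   signal scale before weighting).
#' @param n_subjects,n_channels,snr_db,seed,subject_sd,roi_fraction,rate,delays
#'   as in [simulate_subjects()].
#' @return list as in [simulate_subjects()], with per-subject `truth_base` and
#'   `truth_rnn` kernels.
#' @export
make_rnn_ground_truth <- function(x_base, x_rnn, mixing = 1, n_subjects = 10,
                                  n_channels = 20, snr_db = 10, seed = 1,
                                  subject_sd = 0.2, roi_fraction = 0.5,
                                  rate = 50, delays = trf_delays(rate)) {
  stopifnot(ncol(x_base) == ncol(x_rnn))
  Pb <- nrow(x_base); Pr <- nrow(x_rnn); D <- length(delays)
  roi <- seq_len(max(1L, round(roi_fraction * n_channels)))
  with_seed(derive_seed(seed, 92L), {
    gb <- t(vapply(seq_len(Pb), function(i)
      smooth_random_kernel(delays, rate), numeric(D)))
    gr <- t(vapply(seq_len(Pr), function(i)
      smooth_random_kernel(delays, rate), numeric(D)))
    subjects <- lapply(seq_len(n_subjects), function(s) {
      tb <- gb + subject_sd * t(vapply(seq_len(Pb), function(i)
        smooth_random_kernel(delays, rate), numeric(D)))
      tr <- gr + subject_sd * t(vapply(seq_len(Pr), function(i)
        smooth_random_kernel(delays, rate), numeric(D)))
      sig_b <- convolve_predict(tb, x_base, delays)
      sig_r <- convolve_predict(tr, x_rnn, delays)
      sr_sd <- sd(sig_r)
      if (sr_sd > 0) sig_r <- sig_r * (sd(sig_b) / sr_sd)
      signal <- sig_b + mixing * sig_r
      sig_sd <- sd(signal)
      gains <- numeric(n_channels)
      gains[roi] <- runif(length(roi), 0.5, 1.5)
      noise_mult <- if (is.infinite(snr_db)) 0 else 10^(-snr_db / 20)
      noise_sd <- ifelse(gains > 0, gains * sig_sd, sig_sd) * noise_mult
      response <- outer(gains, signal) +
        matrix(rnorm(n_channels * length(signal)), n_channels) * noise_sd
      list(response = response, truth_base = tb, truth_rnn = tr,
           gains = gains, noise_sd = noise_sd)
    })
    list(subjects = subjects, roi = roi, delays = delays, rate = rate)
  })
}
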