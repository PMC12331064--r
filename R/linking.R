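# Linking hypothesis: reduce hidden-unit traces to population predictors.
# Each unit group contributes two series: summed absolute activation
# (magnitude) and the half-wave rectified temporal derivative of absolute
# activation (change), mirroring how M/EEG signals pool over neural
# populations rather than single cells.

stack_trace <- function(trace) {
  if (is.list(trace)) do.call(rbind, trace) else trace
}

#' Magnitude predictor of a unit group
#'
#' At each frame, the sum of absolute hidden-unit values over the group.
#' Additive over disjoint group unions.
#'
#' @param trace `units x T` hidden activation matrix (or list of per-layer
#'   matrices, stacked).
#' @param group integer indices of the units in the group.
#' @return numeric series of length T.
#' @export
magnitude_predictor <- function(trace, group) {
  trace <- stack_trace(trace)
  stopifnot(length(group) >= 1)
  colSums(abs(trace[group, , drop = FALSE]))
}

#' Change predictor of a unit group
#'
#' Per unit, the backward first difference of absolute activation with
#' negative values clipped to 0 (units moving away from zero represent new
#' information; returning to zero is a return to baseline), summed across the
#' group. The first frame is 0. Non-negative everywhere.
#'
#' @inheritParams magnitude_predictor
#' @return numeric series of length T.
#' @export
change_predictor <- function(trace, group) {
  trace <- stack_trace(trace)
  stopifnot(ncol(trace) >= 2)
  a <- abs(trace[group, , drop = FALSE])
  d <- a[, -1, drop = FALSE] - a[, -ncol(a), drop = FALSE]
  d[d < 0] <- 0
  c(0, colSums(d))
}

#' Group units by layer
#'
#' @param hidden list of per-layer `units x T` matrices.
#' @return a `"unit_grouping"`: `assignment` (unit -> group id over the
#'   stacked units), `method`, `K`.
#' @export
layer_grouping <- function(hidden) {
  sizes <- vapply(hidden, nrow, integer(1))
  structure(list(assignment = rep(seq_along(sizes), sizes),
                 method = "layer", K = length(sizes)),
            class = "unit_grouping")
}

#' Group units by K-means clustering of their time courses
#'
#' Units are clustered on their full activation time courses (z-scored per
#' unit; constant units map to zero) with the squared-Euclidean K-means
#' objective and multiple seeded restarts. Layer membership is ignored: for
#' deep models all units are clustered together.
#'
#' @param trace `units x T` matrix or list of per-layer matrices (stacked).
#' @param K number of clusters, `1 <= K <= n_units`.
#' @param seed integer seed.
#' @param n_init random restarts (default 10).
#' @return a `"unit_grouping"`.
#' @export
kmeans_grouping <- function(trace, K, seed = 1, n_init = 10) {
  trace <- stack_trace(trace)
  n_units <- nrow(trace)
  stopifnot(K >= 1, K <= n_units)
  if (K == n_units) assignment <- seq_len(n_units)
  else if (K == 1) assignment <- rep(1L, n_units)
  else {
    feats <- t(apply(trace, 1, function(u) {
      s <- sd(u)
      if (s > 0) (u - mean(u)) / s else u * 0
    }))
    assignment <- with_seed(derive_seed(seed, 81L),
                            kmeans(feats, centers = K, nstart = n_init,
                                   iter.max = 200)$cluster)
  }
  structure(list(assignment = as.integer(assignment), method = "kmeans",
                 K = as.integer(K)),
            class = "unit_grouping")
}

#' Resample a series from 100 Hz to the analysis rate
#'
#' Polyphase FIR low-pass decimation (via `signal::decimate`); identity when
#' the rates match.
#'
#' @param x numeric series.
#' @param from_rate,to_rate sampling rates; `from_rate` must be an integer
#'   multiple of `to_rate`.
#' @return resampled series.
#' @export
resample_series <- function(x, from_rate = 100, to_rate = 50) {
  if (from_rate == to_rate) return(x)
  q <- from_rate / to_rate
  stopifnot(q == round(q))
  as.numeric(signal::decimate(x, q, ftype = "fir"))
}

#' Build the population predictor set from hidden traces
#'
#' For every unit group, emits the magnitude and change predictors (two per
#' group), resampled from the model's 100 Hz frame rate to the analysis rate.
#'
#' @param hidden list of per-layer `units x T` matrices (or a single matrix).
#' @param grouping a `"unit_grouping"` consistent with the stacked trace.
#' @param from_rate trace frame rate.
#' @param to_rate analysis rate (default 50 Hz, matching the response data).
#' @return a `"predictor_set"`: `x` (`2 * K x T'` matrix with rownames
#'   `g<id>_mag` / `g<id>_chg`), `rate`, `grouping`.
#' @export
build_predictor_set <- function(hidden, grouping, from_rate = 100,
                                to_rate = 50) {
  trace <- stack_trace(hidden)
  stopifnot(length(grouping$assignment) == nrow(trace))
  gids <- sort(unique(grouping$assignment))
  rows <- list()
  for (g in gids) {
    members <- which(grouping$assignment == g)
    rows[[paste0("g", g, "_mag")]] <-
      resample_series(magnitude_predictor(trace, members), from_rate, to_rate)
    rows[[paste0("g", g, "_chg")]] <-
      resample_series(change_predictor(trace, members), from_rate, to_rate)
  }
  x <- do.call(rbind, rows)
  structure(list(x = x, rate = to_rate, grouping = grouping),
            class = "predictor_set")
}
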