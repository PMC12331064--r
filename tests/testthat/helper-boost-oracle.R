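# Independent brute-force reference for the boosting coordinate descent.
# Every candidate's training error is evaluated directly by rebuilding the
# residual (no incremental cross-correlation bookkeeping), so this checks the
# fast implementation's greedy rule step for step.
oracle_boost <- function(x, y, train, validation, delta,
                         delays = wordtrf::trf_delays(), max_steps = 200) {
  tr_idx <- unlist(train)
  xc <- rowMeans(x[, tr_idx, drop = FALSE])
  xs <- apply(x[, tr_idx, drop = FALSE], 1, sd)
  xs[xs == 0] <- 1
  ym <- mean(y[tr_idx]); ys <- sd(y[tr_idx])
  xn <- (x - xc) / xs
  yn <- (y - ym) / ys
  P <- nrow(x); D <- length(delays)

  shift_seg <- function(i, tau, idx) {
    Tn <- length(idx)
    src <- seq_len(Tn) - tau
    out <- numeric(Tn)
    ok <- src >= 1 & src <= Tn
    out[ok] <- xn[i, idx][src[ok]]
    out
  }
  resid <- function(h, idx) {
    r <- yn[idx]
    for (i in seq_len(P)) for (d in seq_len(D))
      if (h[i, d] != 0) r <- r - h[i, d] * shift_seg(i, delays[d], idx)
    r
  }

  h <- matrix(0, P, D)
  frozen <- rep(FALSE, P)
  steps <- list()
  rtr <- lapply(train, function(idx) resid(h, idx))
  rval <- resid(h, validation)
  sse_val <- sum(rval^2)
  for (s in seq_len(max_steps)) {
    if (all(frozen)) break
    best <- list(dsse = 0)
    sse_now <- sum(vapply(rtr, function(r) sum(r^2), 1))
    for (i in which(!frozen)) for (d in seq_len(D)) for (sg in c(1, -1)) {
      cand <- sum(vapply(seq_along(train), function(k) {
        r2 <- rtr[[k]] - sg * delta * shift_seg(i, delays[d], train[[k]])
        sum(r2^2)
      }, 1)) - sse_now
      if (cand < best$dsse) best <- list(dsse = cand, i = i, d = d, sg = sg)
    }
    if (is.null(best$i)) break
    rv2 <- rval - best$sg * delta * shift_seg(best$i, delays[best$d],
                                              validation)
    if (sum(rv2^2) > sse_val) {
      frozen[best$i] <- TRUE
      steps[[length(steps) + 1L]] <- c(best$i, best$d, 0)
      next
    }
    h[best$i, best$d] <- h[best$i, best$d] + best$sg * delta
    for (k in seq_along(train))
      rtr[[k]] <- rtr[[k]] - best$sg * delta *
        shift_seg(best$i, delays[best$d], train[[k]])
    rval <- rv2
    sse_val <- sum(rv2^2)
    steps[[length(steps) + 1L]] <- c(best$i, best$d, best$sg)
  }
  list(h = h * ys / xs,
       steps = do.call(rbind, steps))
}
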