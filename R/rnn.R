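# Stacked LSTM word recognizers: parameter counting, the two loss functions,
# model construction, segment-wise training with state carry-over and a
# patience schedule, and frame-aligned inference with hidden-unit traces.

#' Trainable parameters of a stacked LSTM core
#'
#' Standard LSTM (no peepholes, one bias vector per gate set): each layer has
#' `4 * ((in + h) * h + h)` parameters where `in` is the layer's input width.
#' The output mapping is excluded.
#'
#' @param layer_sizes hidden units per layer.
#' @param input_dim input dimension (64 spectrogram bands by default).
#' @return integer parameter count.
#' @examples
#' count_parameters(512)          # 1181696
#' count_parameters(c(320, 320))  # 1313280
#' @export
count_parameters <- function(layer_sizes, input_dim = 64) {
  stopifnot(length(layer_sizes) >= 1, all(layer_sizes > 0))
  ins <- c(input_dim, layer_sizes[-length(layer_sizes)])
  sum(4 * ((ins + layer_sizes) * layer_sizes + layer_sizes))
}

clip01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy loss
#'
#' Mean over all output elements and frames of
#' `-(y * log(yhat) + (1 - y) * log(1 - yhat))`, with outputs clipped to
#' `(eps, 1 - eps)`.
#'
#' @param y binary target matrix (elements x frames).
#' @param y_hat predicted probabilities, same shape.
#' @param eps clipping constant for the logs.
#' @return scalar loss.
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  stopifnot(all(dim(y) == dim(y_hat)))
  p <- clip01(y_hat, eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Competition-friendly ("live and let live") loss
#'
#' Binary cross-entropy in which, on frames where `word_mask` is TRUE (from
#' word onset until 100 ms before word end), the non-target terms (`y == 0`)
#' are divided by `c`. Target terms, and all terms on unmasked frames (the
#' last 100 ms of each word, and silence), keep the standard weighting. With
#' `c = 1` this reduces exactly to [bce_loss()].
#'
#' @param y,y_hat as in [bce_loss()].
#' @param c discount constant, `>= 1`.
#' @param word_mask logical vector over frames where the discount applies.
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
lill_loss <- function(y, y_hat, c, word_mask, eps = 1e-7) {
  stopifnot(all(dim(y) == dim(y_hat)), c >= 1,
            length(word_mask) == ncol(y))
  p <- clip01(y_hat, eps)
  w <- matrix(1, nrow(y), ncol(y))
  if (any(word_mask)) {
    sub <- y[, word_mask, drop = FALSE] == 0
    wm <- w[, word_mask, drop = FALSE]
    wm[sub] <- 1 / c
    w[, word_mask] <- wm
  }
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Model configuration
#'
#' @param layer_sizes hidden units per LSTM layer (stacked).
#' @param coding an `"output_coding"`.
#' @param loss `"bce"` or `"lill"` for binary codings; semantic codings are
#'   trained with mean squared error regardless.
#' @param c discount constant for the lill loss (`>= 1`).
#' @param lill_guard_ms guard window before word end where the standard loss
#'   applies (default 100 ms).
#' @param input_dim input bands.
#' @param lr Adam learning rate.
#' @param grad_clip global gradient-norm clip.
#' @return list of class `"model_config"`.
#' @export
model_config <- function(layer_sizes, coding, loss = c("bce", "lill"), c = 1,
                         lill_guard_ms = 100, input_dim = 64, lr = 1e-3,
                         grad_clip = 5) {
  loss <- match.arg(loss)
  stopifnot(length(layer_sizes) >= 1, all(layer_sizes > 0), c >= 1)
  if (loss == "lill" && !coding$binary)
    stop("the lill loss requires a binary (localist or srv) output coding")
  structure(list(layer_sizes = as.integer(layer_sizes), coding = coding,
                 loss = loss, c = c, lill_guard_ms = lill_guard_ms,
                 input_dim = as.integer(input_dim), lr = lr,
                 grad_clip = grad_clip),
            class = "model_config")
}

#' Build an LSTM word-recognition model
#'
#' Stacked LSTM with a dense output head: sigmoid activation for binary
#' codings (trained with binary cross-entropy or its competition-friendly
#' variant), linear for semantic codings (trained with mean squared error).
#' Weights are uniform in `[-1/sqrt(h), 1/sqrt(h)]`; forget-gate biases are
#' initialized to 1.
#'
#' @param config a `"model_config"`.
#' @param seed initialization seed.
#' @return object of class `"lstm_wordrec"`.
#' @export
build_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "model_config"))
  weights <- with_seed(derive_seed(seed, 61L), {
    ins <- c(config$input_dim,
             config$layer_sizes[-length(config$layer_sizes)])
    layers <- lapply(seq_along(config$layer_sizes), function(l) {
      h <- config$layer_sizes[l]
      k <- 1 / sqrt(h)
      b <- numeric(4 * h)
      b[(h + 1):(2 * h)] <- 1   # forget-gate bias
      list(Wx = matrix(runif(4 * h * ins[l], -k, k), 4 * h),
           Wh = matrix(runif(4 * h * h, -k, k), 4 * h),
           b = b)
    })
    hl <- config$layer_sizes[length(config$layer_sizes)]
    k <- 1 / sqrt(hl)
    # binary codings: start the sigmoid head at a low-activation prior so early
    # training is not spent learning the rare-positive base rate
    by0 <- if (config$coding$binary) -4 else 0
    list(layers = layers,
         Wy = matrix(runif(config$coding$dim * hl, -k, k), config$coding$dim),
         by = rep(by0, config$coding$dim))
  })
  structure(list(config = config, weights = weights, history = numeric(0),
                 best_loss = NA_real_, trained = FALSE),
            class = "lstm_wordrec")
}

#' @export
print.lstm_wordrec <- function(x, ...) {
  cat("LSTM word recognizer: layers [",
      paste(x$config$layer_sizes, collapse = ", "), "], ",
      x$config$coding$kind, " output (dim ", x$config$coding$dim, "), loss ",
      if (x$config$coding$binary) x$config$loss else "mse",
      if (x$config$loss == "lill") paste0(" (c = ", x$config$c, ")") else "",
      "; ", count_parameters(x$config$layer_sizes, x$config$input_dim),
      " core parameters\n", sep = "")
  if (length(x$history))
    cat("trained ", length(x$history), " epochs, best loss ",
        signif(x$best_loss, 4), "\n", sep = "")
  invisible(x)
}

# --- nested weight-list arithmetic helpers -----------------------------------

map_weights <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]]))
    do.call(Map, c(list(function(...) map_weights(f, ...)), args))
  else do.call(f, args)
}

weights_sumsq <- function(w) {
  if (is.list(w)) sum(vapply(w, weights_sumsq, numeric(1))) else sum(w^2)
}

zero_like <- function(w) map_weights(function(x) x * 0, w)

#' Default desk-scale training stream source
#'
#' Returns a function `(epoch, seed)` producing one epoch of training data:
#' `batch_size` independent streams, each `segments_per_stream` segments of
#' `segment_frames` frames, with per-band noise at `snr_db`, targets under
#' `coding`, and per-element loss weights implementing the lill discount
#' (all ones when `lill_c = 1`). Fresh streams are generated every epoch from
#' seeds derived from the master seed.
#'
#' @param token_set a `"token_set"`.
#' @param coding an `"output_coding"`.
#' @param allowed optional token whitelist (training partition).
#' @param batch_size parallel streams per epoch.
#' @param segments_per_stream segments per stream.
#' @param segment_frames frames per segment (default 1000 = 10 s).
#' @param snr_db per-band training SNR (default 20 dB).
#' @param lill_c discount constant used for the loss weights.
#' @param guard_frames lill guard in frames.
#' @return function `(epoch, seed) -> list(segments, B)` where each segment
#'   has `x`, `y`, `w` laid out as `dim x (B * segment_frames)` with
#'   time-major blocks of `B` columns.
#' @export
make_stream_source <- function(token_set, coding, allowed = NULL,
                               batch_size = 8, segments_per_stream = 3,
                               segment_frames = 1000, snr_db = 20,
                               lill_c = 1, guard_frames = 10) {
  force(token_set); force(coding)
  function(epoch, seed) {
    B <- batch_size
    Tn <- segments_per_stream * segment_frames
    xs <- vector("list", B); ys <- vector("list", B); ws <- vector("list", B)
    for (b in seq_len(B)) {
      st <- build_training_stream(token_set, Tn,
                                  seed = derive_seed(seed, epoch, b),
                                  allowed = allowed)
      st <- add_noise(st, snr_db, seed = derive_seed(seed, epoch, b, 2L))
      xs[[b]] <- st$input
      ys[[b]] <- make_targets(st$annotations, coding, Tn)
      if (lill_c > 1) {
        m <- lill_mask(st$annotations, Tn, guard_frames)
        w <- matrix(1, coding$dim, Tn)
        if (any(m)) {
          sub <- ys[[b]][, m, drop = FALSE] == 0
          wm <- w[, m, drop = FALSE]; wm[sub] <- 1 / lill_c
          w[, m] <- wm
        }
        ws[[b]] <- w
      } else ws[[b]] <- matrix(1, coding$dim, Tn)
    }
    stack <- function(lst, cols) {
      arr <- vapply(lst, function(m) m[, cols, drop = FALSE],
                    matrix(0, nrow(lst[[1]]), length(cols)))
      arr <- aperm(arr, c(1, 3, 2))      # dim x B x T
      dim(arr) <- c(dim(arr)[1], B * length(cols))
      arr
    }
    segments <- lapply(seq_len(segments_per_stream), function(s) {
      cols <- ((s - 1) * segment_frames + 1):(s * segment_frames)
      list(x = stack(xs, cols), y = stack(ys, cols), w = stack(ws, cols))
    })
    list(segments = segments, B = B)
  }
}

#' Train an LSTM word recognizer
#'
#' Minimizes the configured loss over all frames with Adam, carrying LSTM
#' state across consecutive segments within each stream. Training loss is
#' evaluated after each epoch; when it has not improved on the previous
#' minimum for `patience_restore` epochs, weights are restored to that
#' minimum; after `patience_stop` evaluations without improvement (or
#' `n_epochs`), training stops and the best weights are returned.
#'
#' @param model an `"lstm_wordrec"`.
#' @param stream_source function `(epoch, seed)` as returned by
#'   [make_stream_source()].
#' @param n_epochs maximum epochs.
#' @param seed master training seed (streams and their noise derive from it).
#' @param patience_restore epochs over the minimum before weights are restored.
#' @param patience_stop evaluations without a new minimum before termination.
#' @param verbose print per-epoch loss.
#' @return the trained model, with `history` (per-epoch loss) and `best_loss`.
#' @export
train_model <- function(model, stream_source, n_epochs = 100, seed = 1,
                        patience_restore = 20, patience_stop = 200,
                        verbose = FALSE) {
  cfg <- model$config
  loss_type <- if (cfg$coding$binary) 0L else 1L
  w <- model$weights
  m <- zero_like(w); v <- zero_like(w)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; tstep <- 0
  history <- numeric(0)
  best <- Inf; best_w <- w; since_best <- 0L
  for (epoch in seq_len(n_epochs)) {
    batch <- stream_source(epoch, derive_seed(seed, 71L, epoch))
    B <- batch$B
    hu <- cfg$layer_sizes
    h0 <- lapply(hu, function(h) matrix(0, h, B))
    c0 <- h0
    epoch_loss <- 0
    for (seg in batch$segments) {
      res <- cpp_lstm_run(w, seg$x, seg$y, seg$w, B, loss_type, FALSE,
                          h0, c0, TRUE, FALSE, FALSE)
      if (!is.finite(res$loss))
        stop("training loss diverged (non-finite) at epoch ", epoch)
      g <- res$grads
      gn <- sqrt(weights_sumsq(g))
      if (gn > cfg$grad_clip)
        g <- map_weights(function(x) x * (cfg$grad_clip / gn), g)
      tstep <- tstep + 1
      m <- map_weights(function(mm, gg) b1 * mm + (1 - b1) * gg, m, g)
      v <- map_weights(function(vv, gg) b2 * vv + (1 - b2) * gg^2, v, g)
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      w <- map_weights(function(ww, mm, vv)
        ww - cfg$lr * corr * mm / (sqrt(vv) + adam_eps), w, m, v)
      h0 <- res$h_final; c0 <- res$c_final
      epoch_loss <- epoch_loss + res$loss / length(batch$segments)
    }
    history <- c(history, epoch_loss)
    if (verbose) message("epoch ", epoch, " loss ", signif(epoch_loss, 5))
    if (epoch_loss < best) {
      best <- epoch_loss; best_w <- w; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best %% patience_restore == 0L) w <- best_w
      if (since_best >= patience_stop) break
    }
  }
  model$weights <- best_w
  model$history <- c(model$history, history)
  model$best_loss <- best
  model$trained <- TRUE
  model
}

#' Run a model over a stream
#'
#' Frame-aligned outputs (sigmoid probabilities for binary codings, linear
#' values for semantic codings) and hidden-unit traces for every layer. When
#' `segment_frames` is given the input is processed in consecutive segments
#' with recurrent state carried over, which is exactly equivalent to one pass.
#'
#' @param model an `"lstm_wordrec"`.
#' @param input 64 x T spectrogram matrix or a `"word_stream"`.
#' @param segment_frames optional segment length.
#' @param state optional list(h, c) of initial states (each a list of
#'   `h_l x 1` matrices).
#' @return list with `outputs` (`dim x T`), `hidden` (list per layer,
#'   `units x T`), `state` (final recurrent state).
#' @export
run_model <- function(model, input, segment_frames = NULL, state = NULL) {
  if (inherits(input, "word_stream")) input <- input$input
  cfg <- model$config
  hu <- cfg$layer_sizes
  if (is.null(state))
    state <- list(h = lapply(hu, function(h) matrix(0, h, 1)),
                  c = lapply(hu, function(h) matrix(0, h, 1)))
  Tn <- ncol(input)
  starts <- if (is.null(segment_frames)) 1L
            else seq(1L, Tn, by = segment_frames)
  outs <- vector("list", length(starts))
  hids <- vector("list", length(starts))
  empty <- matrix(0, 1, 1)
  for (k in seq_along(starts)) {
    e <- if (k < length(starts)) starts[k + 1L] - 1L else Tn
    res <- cpp_lstm_run(model$weights,
                        input[, starts[k]:e, drop = FALSE],
                        empty, empty, 1L, -1L, cfg$coding$binary,
                        state$h, state$c, FALSE, TRUE, TRUE)
    outs[[k]] <- res$outputs
    hids[[k]] <- res$hidden
    state <- list(h = res$h_final, c = res$c_final)
  }
  hidden <- lapply(seq_along(hu), function(l)
    do.call(cbind, lapply(hids, `[[`, l)))
  list(outputs = do.call(cbind, outs), hidden = hidden, state = state)
}
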