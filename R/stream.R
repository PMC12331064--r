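# Continuous training/evaluation streams: concatenated spectrogram tokens and
# silence, time-aligned target matrices per output coding, calibrated additive
# noise, and segmentation with a continuous time axis.

#' Define an output-space coding
#'
#' Three ways to represent words at the network output:
#' \describe{
#'   \item{localist}{one output element per word, one-hot binary targets.}
#'   \item{srv}{sparse random vectors: each word's target sets `srv_k`
#'     randomly selected elements of a long binary vector to 1; element sets
#'     are sampled without replacement within a word, independently across
#'     words (collisions between words allowed).}
#'   \item{semantic}{dense real vectors (seeded Gaussian, unit norm), a
#'     stand-in for corpus-derived embeddings; a custom matrix of vectors can
#'     be supplied instead.}
#' }
#'
#' @param kind one of `"localist"`, `"srv"`, `"semantic"`.
#' @param n_words lexicon size.
#' @param dim output dimension (ignored for localist; default 300 for srv,
#'   50 for semantic).
#' @param srv_k number of active elements per word (srv only; default 10).
#' @param seed integer seed.
#' @param vectors optional `dim x n_words` matrix overriding the generated
#'   word vectors (semantic only).
#' @return object of class `"output_coding"`: `kind`, `dim`, `srv_k`,
#'   `vectors` (`dim x n_words`), `elements` (srv: list of active indices),
#'   `binary` flag.
#' @export
make_coding <- function(kind = c("localist", "srv", "semantic"), n_words,
                        dim = NULL, srv_k = 10, seed = 1, vectors = NULL) {
  kind <- match.arg(kind)
  elements <- NULL
  if (kind == "localist") {
    dim <- n_words
    vectors <- diag(n_words)
  } else if (kind == "srv") {
    if (is.null(dim)) dim <- 300
    stopifnot(srv_k <= dim)
    elements <- with_seed(derive_seed(seed, 41L),
                          lapply(seq_len(n_words),
                                 function(i) sort(sample.int(dim, srv_k))))
    vectors <- vapply(elements, function(ix) {
      v <- numeric(dim); v[ix] <- 1; v
    }, numeric(dim))
  } else {
    if (is.null(vectors)) {
      if (is.null(dim)) dim <- 50
      vectors <- with_seed(derive_seed(seed, 42L),
                           matrix(rnorm(dim * n_words), dim))
      vectors <- sweep(vectors, 2, sqrt(colSums(vectors^2)), "/")
    } else {
      dim <- nrow(vectors)
      stopifnot(ncol(vectors) == n_words)
    }
  }
  structure(list(kind = kind, dim = as.integer(dim),
                 srv_k = if (kind == "srv") as.integer(srv_k) else NULL,
                 vectors = vectors, elements = elements,
                 binary = kind %in% c("localist", "srv"),
                 n_words = as.integer(n_words)),
            class = "output_coding")
}

new_stream <- function(input, annotations, rate = 100) {
  structure(list(input = input, annotations = annotations, rate = rate),
            class = "word_stream")
}

#' @export
print.word_stream <- function(x, ...) {
  cat("word_stream:", nrow(x$input), "bands x", ncol(x$input), "frames at",
      x$rate, "Hz;", nrow(x$annotations), "word tokens\n")
  invisible(x)
}

#' Build a continuous training stream of words and silence
#'
#' Mimics connected speech: (1) select a talker at random; (2) produce a
#' phrase by emitting one of that talker's tokens and, with probability
#' `continue_prob`, emitting another; (3) insert silence drawn uniformly from
#' `silence_range_ms`; after `phrases_per_talker` phrases, re-select the
#' talker. The stream is truncated to exactly `n_frames`, clipping the last
#' annotation if it straddles the end.
#'
#' @param token_set a `"token_set"`.
#' @param n_frames stream length in frames (100 Hz).
#' @param seed integer seed.
#' @param silence_range_ms silence duration range after each phrase.
#' @param continue_prob probability of continuing a phrase with another token.
#' @param phrases_per_talker phrases before re-selecting the talker.
#' @param allowed optional data.frame (`word_id`, `talker_id`) restricting the
#'   token pool (e.g., a training partition).
#' @return a `"word_stream"`: `input` (64 x `n_frames`), `annotations`
#'   (data.frame `word_id`, `talker_id`, `onset`, `offset`; 1-based inclusive
#'   frame indices), `rate`.
#' @export
build_training_stream <- function(token_set, n_frames, seed = 1,
                                  silence_range_ms = c(200, 500),
                                  continue_prob = 0.5, phrases_per_talker = 2,
                                  allowed = NULL) {
  stopifnot(n_frames >= 1)
  pool <- lapply(seq_len(token_set$n_talkers), function(tk) {
    if (is.null(allowed)) seq_len(token_set$n_words)
    else sort(allowed$word_id[allowed$talker_id == tk])
  })
  talker_ok <- which(vapply(pool, length, integer(1)) > 0)
  sil_lo <- as.integer(round(silence_range_ms[1] / 10))
  sil_hi <- as.integer(round(silence_range_ms[2] / 10))
  n_bands <- nrow(token_set$tokens[[1]][[pool[[talker_ok[1]]][1]]]$spectrogram)
  with_seed(seed, {
    pieces <- list()
    ann <- list()
    total <- 0L
    while (total < n_frames) {
      tk <- talker_ok[sample.int(length(talker_ok), 1)]
      for (ph in seq_len(phrases_per_talker)) {
        repeat {
          wd <- pool[[tk]][sample.int(length(pool[[tk]]), 1)]
          tok <- token_set$tokens[[tk]][[wd]]
          pieces[[length(pieces) + 1L]] <- tok$spectrogram
          ann[[length(ann) + 1L]] <- c(wd, tk, total + 1L,
                                       total + tok$duration_frames)
          total <- total + tok$duration_frames
          if (runif(1) > continue_prob) break
        }
        gap <- sample(sil_lo:sil_hi, 1)
        pieces[[length(pieces) + 1L]] <- matrix(0, n_bands, gap)
        total <- total + gap
        if (total >= n_frames) break
      }
    }
    input <- do.call(cbind, pieces)[, seq_len(n_frames), drop = FALSE]
    ann <- do.call(rbind, ann)
    annotations <- data.frame(word_id = as.integer(ann[, 1]),
                              talker_id = as.integer(ann[, 2]),
                              onset = as.integer(ann[, 3]),
                              offset = as.integer(ann[, 4]))
    annotations <- annotations[annotations$onset <= n_frames, , drop = FALSE]
    annotations$offset <- pmin(annotations$offset, as.integer(n_frames))
    rownames(annotations) <- NULL
    new_stream(input, annotations)
  })
}

#' Build an evaluation stream
#'
#' All requested tokens concatenated without intervening silence and without
#' added noise; training-set tokens are presented before test-set tokens, the
#' order otherwise shuffled without replacement.
#'
#' @param token_set a `"token_set"`.
#' @param partition optional result of [partition_tokens()]; when `NULL` all
#'   tokens are used (shuffled).
#' @param seed shuffle seed.
#' @return a `"word_stream"` whose annotations carry a logical `train` column
#'   when a partition is supplied.
#' @export
build_eval_stream <- function(token_set, partition = NULL, seed = 1) {
  if (is.null(partition)) {
    sets <- list(expand.grid(word_id = seq_len(token_set$n_words),
                             talker_id = seq_len(token_set$n_talkers)))
    flags <- NA
  } else {
    sets <- list(partition$train, partition$test)
    flags <- c(TRUE, FALSE)
  }
  with_seed(derive_seed(seed, 51L), {
    pieces <- list(); ann <- list(); total <- 0L
    for (si in seq_along(sets)) {
      df <- sets[[si]]
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      for (r in seq_len(nrow(df))) {
        tok <- token_set$tokens[[df$talker_id[r]]][[df$word_id[r]]]
        pieces[[length(pieces) + 1L]] <- tok$spectrogram
        ann[[length(ann) + 1L]] <-
          data.frame(word_id = df$word_id[r], talker_id = df$talker_id[r],
                     onset = total + 1L, offset = total + tok$duration_frames,
                     train = if (is.logical(flags)) flags[si] else NA)
        total <- total + tok$duration_frames
      }
    }
    new_stream(do.call(cbind, pieces), do.call(rbind, ann))
  })
}

#' Target matrix for a stream under an output coding
#'
#' Column `t` equals the word vector of the word spanning frame `t`, and the
#' zero vector during silence.
#'
#' @param annotations stream annotations (`word_id`, `onset`, `offset`).
#' @param coding an `"output_coding"` covering all annotated word ids.
#' @param n_frames number of stream frames.
#' @return `coding$dim` x `n_frames` matrix.
#' @export
make_targets <- function(annotations, coding, n_frames) {
  if (nrow(annotations) > 0 && any(annotations$word_id > coding$n_words))
    stop("annotation references a word id unknown to the coding")
  y <- matrix(0, coding$dim, n_frames)
  for (r in seq_len(nrow(annotations)))
    y[, annotations$onset[r]:annotations$offset[r]] <-
      coding$vectors[, annotations$word_id[r]]
  y
}

#' Frames where the competition-friendly loss discount applies
#'
#' TRUE from each word's onset up to `guard_frames` (100 ms at 100 Hz) before
#' its end; the final guard window and all silence frames keep the standard
#' loss. Words no longer than the guard get no discounted frames.
#'
#' @param annotations stream annotations.
#' @param n_frames stream length.
#' @param guard_frames guard length in frames (default 10 = 100 ms).
#' @return logical vector of length `n_frames`.
#' @export
lill_mask <- function(annotations, n_frames, guard_frames = 10) {
  m <- logical(n_frames)
  for (r in seq_len(nrow(annotations))) {
    last <- annotations$offset[r] - guard_frames
    if (last >= annotations$onset[r])
      m[annotations$onset[r]:last] <- TRUE
  }
  m
}

#' Add band-calibrated Gaussian noise to a stream
#'
#' Per band, noise standard deviation is the band's signal standard deviation
#' times `10^(-snr_db / 20)`, so the requested per-band SNR holds in variance
#' terms. Zero-variance bands receive no noise (the SNR is undefined there);
#' `snr_db = Inf` returns the stream unchanged.
#'
#' @param stream a `"word_stream"`.
#' @param snr_db signal-to-noise ratio in dB (default 20).
#' @param seed integer seed.
#' @return a `"word_stream"` with noisy input.
#' @export
add_noise <- function(stream, snr_db = 20, seed = 1) {
  stopifnot(!is.na(snr_db))
  if (is.infinite(snr_db) && snr_db > 0) return(stream)
  sds <- apply(stream$input, 1, sd)
  noise_sd <- ifelse(sds > 0, sds * 10^(-snr_db / 20), 0)
  noisy <- with_seed(seed, {
    stream$input +
      matrix(rnorm(length(stream$input)), nrow(stream$input)) * noise_sd
  })
  new_stream(noisy, stream$annotations, stream$rate)
}

#' Split a stream into consecutive segments
#'
#' Segments preserve a continuous time axis: words may straddle segment
#' boundaries (annotations are kept intact at the stream level, the split is
#' at the array level only), and consumers must carry recurrent state across
#' consecutive segments. A shorter final segment is kept.
#'
#' @param stream a `"word_stream"`.
#' @param segment_frames segment length (>= 1).
#' @return list of segments, each `list(input, start_frame)`.
#' @export
segment_stream <- function(stream, segment_frames) {
  stopifnot(segment_frames >= 1)
  Tn <- ncol(stream$input)
  starts <- seq(1L, Tn, by = segment_frames)
  lapply(starts, function(s) {
    e <- min(s + segment_frames - 1L, Tn)
    list(input = stream$input[, s:e, drop = FALSE], start_frame = s)
  })
}

#' Export stream annotations as a BED-like table
#'
#' Tab-separated, 0-based half-open frame coordinates.
#'
#' @param stream a `"word_stream"`.
#' @param path output file.
#' @export
write_annotations <- function(stream, path) {
  a <- stream$annotations
  df <- data.frame(start = a$onset - 1L, end = a$offset,
                   word_id = a$word_id - 1L, talker_id = a$talker_id - 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
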