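# Synthetic lexicons with controlled cohort structure, and parametric
# multi-talker spectrogram tokens. Phoneme identity is synthetic: each phoneme
# is a smooth 64-band spectral template, which is all the downstream analyses
# need (they depend on onset-overlap structure, not phonetic realism).

#' Generate a synthetic phoneme inventory
#'
#' Each phoneme is defined by a smooth, non-negative spectral template over
#' `n_bands` frequency bands (a mixture of 2-3 Gaussian bumps plus a small
#' baseline) and a nominal duration in ms.
#'
#' @param n_phonemes inventory size.
#' @param n_bands number of frequency bands (64 matches the spectrogram front
#'   end used throughout).
#' @param duration_ms nominal phoneme duration; 80 ms yields word durations
#'   comparable to natural speech at 100 Hz frames.
#' @param seed integer seed.
#' @return list with `templates` (`n_bands` x `n_phonemes`, non-negative),
#'   `duration_ms`, `n_bands`.
#' @export
make_phoneme_inventory <- function(n_phonemes = 20, n_bands = 64,
                                   duration_ms = 80, seed = 1) {
  stopifnot(n_phonemes >= 1, n_bands >= 1, duration_ms > 0)
  templates <- with_seed(seed, {
    vapply(seq_len(n_phonemes), function(p) {
      nb <- sample(2:3, 1)
      centers <- runif(nb, 1, n_bands)
      widths <- runif(nb, 2, 8)
      amps <- runif(nb, 0.5, 1.5)
      tpl <- rep(0.05, n_bands)
      for (j in seq_len(nb))
        tpl <- tpl + amps[j] * exp(-(seq_len(n_bands) - centers[j])^2 /
                                     (2 * widths[j]^2))
      tpl
    }, numeric(n_bands))
  })
  list(templates = templates, duration_ms = duration_ms, n_bands = n_bands,
       n_phonemes = n_phonemes)
}

#' Generate talker profiles
#'
#' Talker 1 is the reference talker (no template shift, unit rate). Additional
#' talkers get a smooth per-band template shift, a speaking-rate factor that
#' scales phoneme durations, and a token-jitter scale, emulating a pool of
#' synthetic voices.
#'
#' @param n_talkers number of talkers (>= 1).
#' @param seed integer seed.
#' @param shift_sd standard deviation of the per-band template shift.
#' @param rate_range range of the multiplicative duration factor.
#' @param jitter_scale scale of smooth token-specific spectral jitter; gives
#'   each token idiosyncratic acoustic details that a model can exploit.
#' @param n_bands number of bands.
#' @return list of talker profiles (`id`, `template_shift`, `rate_factor`,
#'   `jitter_scale`).
#' @export
make_talkers <- function(n_talkers, seed = 1, shift_sd = 0.15,
                         rate_range = c(0.85, 1.2), jitter_scale = 0.15,
                         n_bands = 64) {
  stopifnot(n_talkers >= 1, all(rate_range > 0))
  with_seed(seed, {
    lapply(seq_len(n_talkers), function(i) {
      if (i == 1L) {
        list(id = 1L, template_shift = rep(0, n_bands), rate_factor = 1,
             jitter_scale = jitter_scale)
      } else {
        raw <- rnorm(n_bands, 0, shift_sd)
        sm <- as.numeric(stats::filter(c(raw[1], raw[1], raw, raw[n_bands],
                                         raw[n_bands]),
                                       rep(1 / 5, 5), sides = 2))[3:(n_bands + 2)]
        list(id = as.integer(i), template_shift = sm,
             rate_factor = runif(1, rate_range[1], rate_range[2]),
             jitter_scale = jitter_scale)
      }
    })
  })
}

#' Build a phoneme-transcribed lexicon with controlled cohort structure
#'
#' A fraction `1 - neighborhood_density` of words is sampled at random from the
#' inventory; the remainder are single-phoneme substitutions of already
#' accepted words, which creates onset-sharing cohorts at multiple depths.
#' Homophones (duplicate phoneme sequences) are discarded and regenerated, so
#' the lexicon is always homophone-free.
#'
#' @param n_words number of words (>= 2).
#' @param n_phonemes phoneme inventory size.
#' @param length_range word length range in phonemes (default 3-7).
#' @param neighborhood_density fraction of words generated as single-phoneme
#'   neighbors of existing words, in `[0, 1]`.
#' @param n_talkers number of talker profiles attached to the lexicon.
#' @param seed integer seed.
#' @param duration_ms nominal phoneme duration (ms).
#' @param talker_args extra arguments for [make_talkers()].
#' @return object of class `"lexicon"`: list with `words` (list of integer
#'   phoneme-index vectors; word ids are their positions), `inventory`,
#'   `talkers`.
#' @export
build_lexicon <- function(n_words, n_phonemes = 20, length_range = c(3, 7),
                          neighborhood_density = 0.5, n_talkers = 1, seed = 1,
                          duration_ms = 80, talker_args = list()) {
  stopifnot(n_words >= 2, neighborhood_density >= 0, neighborhood_density <= 1,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  capacity <- sum(as.double(n_phonemes)^(length_range[1]:length_range[2]))
  if (capacity < n_words)
    stop("phoneme inventory cannot support ", n_words,
         " unique sequences within the length range")
  inventory <- make_phoneme_inventory(n_phonemes, duration_ms = duration_ms,
                                      seed = derive_seed(seed, 11L))
  words <- with_seed(derive_seed(seed, 12L), {
    words <- list()
    seen <- character(0)
    n_base <- max(1L, round(n_words * (1 - neighborhood_density)))
    tries <- 0L
    while (length(words) < n_base) {
      lens <- length_range[1]:length_range[2]
      len <- lens[sample.int(length(lens), 1)]
      w <- sample.int(n_phonemes, len, replace = TRUE)
      key <- paste(w, collapse = ".")
      if (!key %in% seen) {
        words[[length(words) + 1L]] <- w
        seen <- c(seen, key)
      }
      tries <- tries + 1L
      if (tries > 1000L * n_words) stop("failed to sample unique base words")
    }
    tries <- 0L
    while (length(words) < n_words) {
      src <- words[[sample.int(length(words), 1)]]
      pos <- sample.int(length(src), 1)
      w <- src
      alts <- setdiff(seq_len(n_phonemes), src[pos])
      w[pos] <- alts[sample.int(length(alts), 1)]
      key <- paste(w, collapse = ".")
      if (!key %in% seen) {   # homophone collisions are discarded, regenerated
        words[[length(words) + 1L]] <- w
        seen <- c(seen, key)
      }
      tries <- tries + 1L
      if (tries > 1000L * n_words) stop("failed to generate unique neighbors")
    }
    words
  })
  talkers <- do.call(make_talkers,
                     c(list(n_talkers = n_talkers,
                            seed = derive_seed(seed, 13L),
                            n_bands = inventory$n_bands), talker_args))
  structure(list(words = words, inventory = inventory, talkers = talkers),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("Synthetic lexicon:", length(x$words), "words,",
      x$inventory$n_phonemes, "phonemes,", length(x$talkers), "talkers\n")
  invisible(x)
}

#' Number of shared word-initial phonemes
#'
#' Length of the longest common prefix of two phoneme sequences. Symmetric and
#' bounded by the shorter word's length.
#'
#' @param word_a,word_b integer phoneme-index vectors.
#' @return integer.
#' @export
shared_onset_phonemes <- function(word_a, word_b) {
  n <- min(length(word_a), length(word_b))
  if (n == 0L) return(0L)
  same <- word_a[seq_len(n)] == word_b[seq_len(n)]
  if (all(same)) n else which.min(same) - 1L
}

#' Cohort of a word after k phonemes
#'
#' All words in the lexicon whose first `k` phonemes equal the target's first
#' `k` phonemes (the target itself included). `k = 0` returns the whole
#' lexicon. Words shorter than `k` phonemes cannot match.
#'
#' @param lexicon a `"lexicon"`.
#' @param word_id target word id.
#' @param k number of phonemes heard, `0 <= k <= length(word)`.
#' @return integer vector of word ids.
#' @export
cohort <- function(lexicon, word_id, k) {
  w <- lexicon$words[[word_id]]
  stopifnot(k >= 0, k <= length(w))
  if (k == 0L) return(seq_along(lexicon$words))
  prefix <- w[seq_len(k)]
  which(vapply(lexicon$words, function(v)
    length(v) >= k && all(v[seq_len(k)] == prefix), logical(1)))
}

#' Theoretical relative target activation from cohort size
#'
#' At each frame, the probability of the target given the phonemes fully heard
#' so far is `1 / |cohort(k)|`: a uniform distribution over the words
#' compatible with the heard prefix.
#'
#' @param lexicon a `"lexicon"`.
#' @param word_id target word id.
#' @param timeline integer vector, per frame, of the number of phonemes of the
#'   target fully heard (see [token_phoneme_timeline()]).
#' @return numeric vector in `(0, 1]`, same length as `timeline`.
#' @export
theoretical_target_probability <- function(lexicon, word_id, timeline) {
  w <- lexicon$words[[word_id]]
  stopifnot(all(timeline >= 0), all(timeline <= length(w)))
  sizes <- vapply(0:length(w), function(k) length(cohort(lexicon, word_id, k)),
                  integer(1))
  1 / sizes[timeline + 1L]
}

#' Per-frame count of fully heard phonemes for a token
#'
#' @param durations_frames per-phoneme durations in frames.
#' @param n_frames total frames (defaults to the token duration).
#' @return integer vector: at frame t, the number of phonemes whose final
#'   frame is at or before t.
#' @export
token_phoneme_timeline <- function(durations_frames,
                                   n_frames = sum(durations_frames)) {
  ends <- cumsum(durations_frames)
  vapply(seq_len(n_frames), function(t) sum(ends <= t), integer(1))
}

#' Per-phoneme durations of a word for one talker
#' @keywords internal
word_durations_frames <- function(lexicon, word_id, talker) {
  w <- lexicon$words[[word_id]]
  base <- lexicon$inventory$duration_ms / 10   # ms -> frames at 100 Hz
  rep(max(2L, as.integer(round(base * talker$rate_factor))), length(w))
}

#' Synthesize one spectrogram token
#'
#' Concatenates per-phoneme spectral templates (shifted by the talker's
#' template shift, durations scaled by the talker's rate factor), smooths
#' across frame boundaries with a short (3-frame) kernel, and adds smooth
#' token-specific jitter (low-pass filtered Gaussian noise scaled by the
#' talker's `jitter_scale`). Deterministic given `(word_id, talker,
#' token_seed)`.
#'
#' @param lexicon a `"lexicon"`.
#' @param word_id word id.
#' @param talker a talker profile from `lexicon$talkers`.
#' @param token_seed integer seed for the token jitter.
#' @return list (`"token"`): `word_id`, `talker_id`, `spectrogram` (64 x T,
#'   non-negative), `duration_frames`, `phoneme_frames`, `rate` (100 Hz).
#' @export
synthesize_token <- function(lexicon, word_id, talker, token_seed = 1) {
  inv <- lexicon$inventory
  w <- lexicon$words[[word_id]]
  durs <- word_durations_frames(lexicon, word_id, talker)
  blocks <- lapply(seq_along(w), function(j) {
    tpl <- pmax(inv$templates[, w[j]] + talker$template_shift, 0)
    matrix(tpl, inv$n_bands, durs[j])
  })
  S <- do.call(cbind, blocks)
  Tn <- ncol(S)
  # 3-point boundary smoothing with edge replication
  Sp <- cbind(S[, 1], S, S[, Tn])
  S <- (Sp[, 1:Tn] + 2 * Sp[, 2:(Tn + 1)] + Sp[, 3:(Tn + 2)]) / 4
  if (talker$jitter_scale > 0) {
    jit <- with_seed(token_seed, matrix(rnorm(inv$n_bands * Tn), inv$n_bands))
    jp <- cbind(jit[, c(1, 1)], jit, jit[, c(Tn, Tn)])
    sm <- 0
    for (k in 0:4) sm <- sm + jp[, (1 + k):(Tn + k)]
    S <- S + talker$jitter_scale * sm / 5
  }
  S <- pmax(S, 0)
  list(word_id = as.integer(word_id), talker_id = talker$id, spectrogram = S,
       duration_frames = ncol(S), phoneme_frames = durs, rate = 100)
}

#' Synthesize all word-by-talker tokens of a lexicon
#'
#' @param lexicon a `"lexicon"`.
#' @param seed master seed; per-token jitter seeds are derived from it.
#' @return object of class `"token_set"`: `tokens[[talker]][[word]]`,
#'   `n_words`, `n_talkers`, `rate`.
#' @export
synthesize_tokens <- function(lexicon, seed = 1) {
  nw <- length(lexicon$words)
  nt <- length(lexicon$talkers)
  seeds <- with_seed(derive_seed(seed, 21L),
                     matrix(sample.int(2^31 - 2, nw * nt), nw, nt))
  tokens <- lapply(seq_len(nt), function(tk)
    lapply(seq_len(nw), function(wd)
      synthesize_token(lexicon, wd, lexicon$talkers[[tk]], seeds[wd, tk])))
  structure(list(tokens = tokens, n_words = nw, n_talkers = nt, rate = 100,
                 lexicon = lexicon),
            class = "token_set")
}

#' Partition tokens into training and test sets
#'
#' Per talker, approximately `holdout_fraction` of the word tokens are
#' assigned to the test set; pinned tokens are always kept in training. Every
#' word remains trainable through at least one talker: sampling is
#' constraint-aware, so a talker's test share shrinks (possibly to zero, e.g.
#' when all its tokens are pinned) rather than stranding a word without
#' training tokens.
#'
#' @param token_set a `"token_set"`.
#' @param holdout_fraction fraction in `(0, 1)`; a globally empty test set is
#'   rejected.
#' @param seed integer seed.
#' @param pinned optional data.frame with columns `word_id`, `talker_id` of
#'   tokens forced into the training set.
#' @return list with data.frames `train` and `test` (`word_id`, `talker_id`),
#'   a disjoint cover of all tokens.
#' @export
partition_tokens <- function(token_set, holdout_fraction = 1 / 16, seed = 1,
                             pinned = NULL) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  nw <- token_set$n_words
  nt <- token_set$n_talkers
  n_test <- round(nw * holdout_fraction)
  if (n_test < 1)
    stop("holdout_fraction would produce an empty test set")
  test <- with_seed(derive_seed(seed, 31L), {
    # constraint-aware sampling: a word is eligible for a talker's test set
    # only while it keeps at least one training token elsewhere, and pinned
    # tokens are never eligible
    train_left <- rep(nt, nw)
    out <- vector("list", nt)
    for (tk in seq_len(nt)) {
      eligible <- which(train_left >= 2)
      if (!is.null(pinned))
        eligible <- setdiff(eligible, pinned$word_id[pinned$talker_id == tk])
      take <- min(n_test, length(eligible))
      chosen <- if (take > 0)
        sort(eligible[sample.int(length(eligible), take)]) else integer(0)
      train_left[chosen] <- train_left[chosen] - 1L
      out[[tk]] <- data.frame(word_id = chosen,
                              talker_id = rep(tk, length(chosen)))
    }
    do.call(rbind, out)
  })
  if (nrow(test) == 0)
    stop("holdout_fraction would produce an empty test set")
  key <- function(df) paste(df$word_id, df$talker_id)
  all_tokens <- expand.grid(word_id = seq_len(nw), talker_id = seq_len(nt))
  train <- all_tokens[!key(all_tokens) %in% key(test), ]
  rownames(train) <- NULL
  n_train_per_word <- table(factor(train$word_id, levels = seq_len(nw)))
  if (any(n_train_per_word == 0))
    stop("a word would have zero training tokens; lower holdout_fraction")
  list(train = train, test = test)
}

#' Write a lexicon as a delimited text table
#'
#' Tab-separated columns: 0-based word id and the phoneme index sequence as a
#' space-separated string.
#'
#' @param lexicon a `"lexicon"`.
#' @param path output file.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- data.frame(
    id = seq_along(lexicon$words) - 1L,
    phonemes = vapply(lexicon$words, paste, collapse = " ", FUN.VALUE = ""))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a lexicon word table written by [write_lexicon()]
#'
#' @param path file path.
#' @return list of integer phoneme-index vectors, in id order.
#' @export
read_lexicon_words <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df <- df[order(df$id), ]
  lapply(strsplit(df$phonemes, " ", fixed = TRUE), as.integer)
}
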