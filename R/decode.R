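# Lexical decoding: map model outputs to per-word activation, score word
# error rates, and characterize cohort competition and the learned structure
# of the output space.

#' Transform model outputs into lexical activation
#'
#' Localist outputs are already one activation per word. For sparse random
#' vector codings, each word's activation is the minimum across the output
#' elements assigned to that word. For semantic codings, activation is the
#' negative Euclidean distance of the output from each word's vector
#' (cosine distance available via `metric`).
#'
#' @param outputs `dim x T` model output matrix.
#' @param coding the `"output_coding"` the model was trained with.
#' @param metric distance for semantic codings: `"euclidean"` (default) or
#'   `"cosine"`.
#' @return `n_words x T` activation matrix (higher = more active).
#' @export
to_activation <- function(outputs, coding, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (nrow(outputs) != coding$dim)
    stop("output dimension does not match the coding")
  Tn <- ncol(outputs)
  switch(coding$kind,
    localist = outputs,
    srv = {
      act <- vapply(coding$elements, function(ix) {
        if (length(ix) == 1L) outputs[ix, ]
        else apply(outputs[ix, , drop = FALSE], 2, min)
      }, numeric(Tn))
      if (Tn == 1L) matrix(act, ncol = 1) else t(act)
    },
    semantic = {
      V <- coding$vectors
      if (metric == "euclidean") {
        cross <- t(V) %*% outputs
        d2 <- matrix(colSums(V^2), ncol(V), Tn) +
          matrix(colSums(outputs^2), ncol(V), Tn, byrow = TRUE) - 2 * cross
        -sqrt(pmax(d2, 0))
      } else {
        vn <- sqrt(colSums(V^2)); on <- sqrt(colSums(outputs^2))
        cs <- t(V / rep(vn, each = nrow(V))) %*%
          sweep(outputs, 2, pmax(on, 1e-12), "/")
        -(1 - cs)
      }
    })
}

#' Decode the recognized word for one annotation
#'
#' The word with the highest mean activation over the final 100 ms (10
#' frames, or the whole word if shorter) of the annotated token; exact ties go
#' to the lowest word id.
#'
#' @param activations `n_words x T` activation matrix.
#' @param onset,offset annotation frame bounds (1-based inclusive).
#' @param window_frames evaluation window length (default 10).
#' @return recognized word id.
#' @export
recognize <- function(activations, onset, offset, window_frames = 10) {
  lo <- max(onset, offset - window_frames + 1L)
  which.max(rowMeans(activations[, lo:offset, drop = FALSE]))
}

#' Word error rate
#'
#' Fraction of annotated tokens whose decoded word differs from the target,
#' optionally per talker.
#'
#' @param activations `n_words x T` activation matrix.
#' @param annotations stream annotations.
#' @param by_talker return one rate per talker.
#' @return numeric rate, or named vector of per-talker rates.
#' @export
word_error_rate <- function(activations, annotations, by_talker = FALSE) {
  stopifnot(nrow(annotations) >= 1)
  pred <- vapply(seq_len(nrow(annotations)), function(r)
    recognize(activations, annotations$onset[r], annotations$offset[r]),
    integer(1))
  err <- pred != annotations$word_id
  if (by_talker) tapply(err, annotations$talker_id, mean) else mean(err)
}

#' Relative target activation over a word's frames
#'
#' Target activation divided by the summed activation of all words, per frame,
#' restricted to the annotated word; interpretable as a probability estimate
#' for the target. Frames whose total activation is below `floor` return the
#' uninformative prior `1 / n_words`. For semantic models (activations can be
#' negative) use `transform = "softmax"`.
#'
#' @param activations `n_words x T` activation matrix.
#' @param annotation one annotation row (`word_id`, `onset`, `offset`).
#' @param transform `"identity"` (raw activations) or `"softmax"`.
#' @param floor guard on the per-frame total.
#' @return numeric vector over the word's frames, in `[0, 1]`.
#' @export
relative_target_activation <- function(activations, annotation,
                                       transform = c("identity", "softmax"),
                                       floor = 1e-12) {
  transform <- match.arg(transform)
  a <- activations[, annotation$onset:annotation$offset, drop = FALSE]
  if (transform == "softmax") {
    a <- exp(sweep(a, 2, apply(a, 2, max)))
  }
  tot <- colSums(a)
  out <- a[annotation$word_id, ] / tot
  out[tot < floor] <- 1 / nrow(activations)
  out
}

#' Onset-locked cohort-competition profile
#'
#' For each word token, non-target activations are grouped by how many
#' word-initial phonemes the non-target shares with the target (counts of
#' `max_k` or more are pooled), averaged within group, aligned to word onset,
#' and then averaged across tokens. The target's own activation is reported
#' separately.
#'
#' @param activations `n_words x T` activation matrix.
#' @param annotations stream annotations.
#' @param lexicon the `"lexicon"`.
#' @param max_k competitor groups are `0, 1, ..., max_k+` shared onset
#'   phonemes.
#' @param window frames after onset to aggregate (default: longest token).
#' @return list with `k` (group labels), `competitor` (`(max_k + 1) x window`
#'   mean activation), `target` (length-`window` mean target activation),
#'   `n_tokens`.
#' @export
competition_profile <- function(activations, annotations, lexicon,
                                max_k = 3, window = NULL) {
  if (is.null(window))
    window <- max(annotations$offset - annotations$onset + 1L)
  n_words <- length(lexicon$words)
  Tn <- ncol(activations)
  ks_cache <- list()
  comp_sum <- matrix(0, max_k + 1L, window)
  comp_n <- matrix(0, max_k + 1L, window)
  targ_sum <- numeric(window); targ_n <- numeric(window)
  for (r in seq_len(nrow(annotations))) {
    wid <- annotations$word_id[r]
    key <- as.character(wid)
    if (is.null(ks_cache[[key]])) {
      ks <- vapply(seq_len(n_words), function(j)
        shared_onset_phonemes(lexicon$words[[wid]], lexicon$words[[j]]),
        integer(1))
      ks_cache[[key]] <- pmin(ks, max_k)
    }
    ks <- ks_cache[[key]]
    jmax <- min(window, Tn - annotations$onset[r] + 1L)
    cols <- annotations$onset[r]:(annotations$onset[r] + jmax - 1L)
    a <- activations[, cols, drop = FALSE]
    targ_sum[1:jmax] <- targ_sum[1:jmax] + a[wid, ]
    targ_n[1:jmax] <- targ_n[1:jmax] + 1
    for (k in 0:max_k) {
      members <- which(ks == k & seq_len(n_words) != wid)
      if (length(members) == 0) next
      comp_sum[k + 1L, 1:jmax] <- comp_sum[k + 1L, 1:jmax] +
        colMeans(a[members, , drop = FALSE])
      comp_n[k + 1L, 1:jmax] <- comp_n[k + 1L, 1:jmax] + 1
    }
  }
  list(k = c(paste(0:(max_k - 1)), paste0(max_k, "+")),
       competitor = comp_sum / pmax(comp_n, 1) *
         ifelse(comp_n > 0, 1, NA),
       target = targ_sum / pmax(targ_n, 1) * ifelse(targ_n > 0, 1, NA),
       n_tokens = nrow(annotations))
}

#' Mean early competitor activation
#'
#' Mean activation, over the first `window` frames of each token, of
#' non-target words sharing at least `k_min` onset phonemes with the target;
#' averaged across tokens that have such competitors. This is the summary used
#' to compare cohort competition across loss functions.
#'
#' @param activations,annotations,lexicon as in [competition_profile()].
#' @param k_min minimum shared onset phonemes (default 2).
#' @param window frames from word onset (default 10 = 100 ms).
#' @return scalar mean activation.
#' @export
mean_competitor_activation <- function(activations, annotations, lexicon,
                                       k_min = 2, window = 10) {
  n_words <- length(lexicon$words)
  Tn <- ncol(activations)
  vals <- c()
  for (r in seq_len(nrow(annotations))) {
    wid <- annotations$word_id[r]
    ks <- vapply(seq_len(n_words), function(j)
      shared_onset_phonemes(lexicon$words[[wid]], lexicon$words[[j]]),
      integer(1))
    members <- which(ks >= k_min & seq_len(n_words) != wid)
    if (length(members) == 0) next
    jmax <- min(window, Tn - annotations$onset[r] + 1L)
    cols <- annotations$onset[r]:(annotations$onset[r] + jmax - 1L)
    vals <- c(vals, mean(activations[members, cols]))
  }
  mean(vals)
}

#' Acoustic-phonetic structure of a learned output mapping
#'
#' Pairwise distances between per-word vectors (e.g., the rows of the dense
#' output layer), summarized by the number of shared onset phonemes, plus the
#' Pearson correlation between pairwise distance and onset overlap across all
#' word pairs. A negative correlation indicates that words sharing onsets sit
#' closer together in the learned space.
#'
#' @param vectors `n_words x dim` matrix, one row per word.
#' @param lexicon the `"lexicon"`.
#' @param max_k pool overlap counts at `max_k` and above (default: no
#'   pooling).
#' @return list with `mean_dist` (named by shared-onset count), `r`, `n_pairs`.
#' @export
output_space_structure <- function(vectors, lexicon, max_k = NULL) {
  n <- nrow(vectors)
  if (n < 2) stop("need at least 2 words")
  d <- as.matrix(dist(vectors))
  ut <- upper.tri(d)
  dd <- d[ut]
  kk <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    shared_onset_phonemes(lexicon$words[[i]], lexicon$words[[j]])))[ut]
  if (!is.null(max_k)) kk <- pmin(kk, max_k)
  if (sd(dd) == 0) {
    warning("all pairwise distances identical; correlation undefined")
    r <- NA_real_
  } else r <- cor(dd, kk)
  list(mean_dist = tapply(dd, kk, mean), r = r, n_pairs = length(dd))
}

#' Per-word vectors of a model's output mapping
#'
#' For localist models each word's vector is the corresponding row of the
#' dense output weight matrix (its embedding in hidden-unit space); for srv
#' models, the mean of the rows for its active elements; for semantic models,
#' the coding's word vectors themselves.
#'
#' @param model an `"lstm_wordrec"`.
#' @return `n_words x dim` matrix.
#' @export
output_mapping_vectors <- function(model) {
  Wy <- model$weights$Wy
  coding <- model$config$coding
  switch(coding$kind,
    localist = Wy,
    srv = t(vapply(coding$elements, function(ix)
      colMeans(Wy[ix, , drop = FALSE]), numeric(ncol(Wy)))),
    semantic = t(coding$vectors))
}
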