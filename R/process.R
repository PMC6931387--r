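# The generative process: the world's true emotion-to-outcome sampling
# distributions, distinct from (and typically more precise than) the
# agent's model.

#' Construct the generative process
#'
#' Builds the world's true content-outcome distributions by passing the
#' fully precise emotion-to-content pattern through the temperature
#' transform at `a_temp` (the default 2 gives a moderately precise
#' world: deterministic base cells leak roughly 1% of their mass, and
#' either/or cells stay at 50/50). The true emotional state is held
#' fixed within a trial; social feedback is emitted deterministically by
#' the report-match rule.
#'
#' @param a_temp Non-negative temperature of the true outcome mappings
#'   (`Inf` = fully deterministic world).
#' @param b_temp Non-negative temperature of the true emotional
#'   stability within a trial. The default `Inf` holds the emotion
#'   fixed; finite values let the true state drift between timesteps
#'   (an identity transition mapping passed through the temperature
#'   transform), degrading the consistency of observed outcome
#'   patterns.
#' @param epsilon Log floor of the temperature transform.
#' @return An object of class `emo_process`.
#' @export
generative_process <- function(a_temp = 2, b_temp = Inf, epsilon = 0.1) {
  base <- base_content_pattern()
  P <- lapply(base, apply_precision, temp = a_temp, epsilon = epsilon)
  B_true <- apply_precision(diag(N_EMOTION), b_temp, epsilon)
  dimnames(B_true) <- list(EMOTIONS, EMOTIONS)
  structure(list(P = P, B_true = B_true, a_temp = a_temp, b_temp = b_temp,
                 epsilon = epsilon),
            class = "emo_process")
}

#' @export
print.emo_process <- function(x, ...) {
  cat("<emo_process> true outcome sampler, a_temp =", x$a_temp,
      ", b_temp =", x$b_temp, "\n")
  invisible(x)
}

# Evolve the true emotion by one timestep under the process's
# stability mapping.
step_true_state <- function(process, e) {
  if (is.infinite(process$b_temp)) return(e)
  sample.int(N_EMOTION, 1L, prob = process$B_true[, e])
}

#' Sample one timestep of observations from the generative process
#'
#' The content modality gated by the occupied attention state is sampled
#' from its true distribution given the current emotion; every other
#' content modality emits its null level. In a report state, social
#' feedback is "correct" iff the report matches the true emotion; the
#' attended-location outcome always mirrors the attention state.
#'
#' @param process An `emo_process`.
#' @param true_emotion Emotion label or index.
#' @param attention Attention-state label or index.
#' @param outcomes Optional fixed realization of the five content
#'   outcomes (integer vector, values 1 or 2 indexing the informative
#'   levels) used instead of sampling.
#' @return Integer vector of outcome indices, one per modality.
#' @export
sample_observation <- function(process, true_emotion, attention,
                               outcomes = NULL) {
  stopifnot(inherits(process, "emo_process"))
  e <- emotion_index(true_emotion)
  att <- attention_index(attention)
  o <- stats::setNames(rep(1L, length(MODALITIES)), MODALITIES)
  if (att %in% ATTEND_IDX) {
    m <- att - 1L
    draw <- if (!is.null(outcomes)) outcomes[m]
            else sample.int(2L, 1L, prob = process$P[[m]][, e])
    o[CONTENT_MODALITIES[m]] <- draw + 1L   # skip the null level
  }
  if (att %in% REPORT_IDX) {
    o["feedback"] <- if ((att - 6L) == e) 2L else 3L
  }
  o["location"] <- att
  o
}

# Draw a full per-trial content realization (one outcome per modality),
# used when two agents must see identical observation sequences.
sample_trial_outcomes <- function(process, true_emotion) {
  e <- emotion_index(true_emotion)
  vapply(seq_along(CONTENT_MODALITIES), function(m)
    sample.int(2L, 1L, prob = process$P[[m]][, e]), integer(1))
}

#' Trial schedules
#'
#' `schedule_interleaved()` cycles evenly through the given emotions
#' (`n_per_emotion` occurrences each). `schedule_skewed()` realizes a
#' childhood in which one emotion is experienced `ratio` times more
#' often than each of the others, with the dominant trials interleaved
#' with the sparse ones in a deterministic even spread.
#'
#' @param n_per_emotion Occurrences of each emotion.
#' @param emotions Emotion labels to include.
#' @param dominant Dominant emotion label for the skewed schedule.
#' @param ratio Dominance ratio (>= 1).
#' @param n_total Total trials of the skewed schedule.
#' @return Character vector of true-emotion labels, one per trial.
#' @export
schedule_interleaved <- function(n_per_emotion, emotions = EMOTIONS) {
  if (n_per_emotion == 0L) return(character(0))
  rep(emotions, times = n_per_emotion)
}

#' @rdname schedule_interleaved
#' @export
schedule_skewed <- function(dominant, ratio = 50, n_total = 200,
                            emotions = EMOTIONS) {
  if (ratio < 1) stop("ratio must be >= 1")
  dominant <- EMOTIONS[emotion_index(dominant)]
  others <- setdiff(emotions, dominant)
  k <- length(others)
  if (ratio == 1)
    return(schedule_interleaved(ceiling(n_total / (k + 1L)),
                                c(dominant, others))[seq_len(n_total)])
  n_other <- max(1L, round(n_total / (ratio + k)))
  sched <- rep(dominant, n_total)
  # spread the sparse emotions evenly through the run
  pos <- round(seq(1, n_total, length.out = k * n_other + 2L))
  pos <- unique(pos[-c(1L, length(pos))])
  sched[pos] <- rep(others, length.out = length(pos))
  sched
}
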