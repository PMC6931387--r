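# Construction of the agent's generative model: likelihood mappings (A),
# controllable transitions (B), outcome preferences (C), initial-state
# priors (D), and the habit prior over actions (E).

#' Precision settings for the likelihood and transition mappings
#'
#' Precision is manipulated by passing each column of a base (fully
#' precise) categorical mapping through a softmax with a temperature
#' parameter: temperature 0 yields a flat (uninformative) mapping, large
#' temperatures recover the base mapping, and intermediate values give
#' graded leakage onto unsupported outcomes.
#'
#' @param a_temp Softmax temperature for the emotion-to-content
#'   likelihood mappings (>= 0; `Inf` keeps the base mapping exact).
#' @param b_temp Temperature for the emotion transition (stability)
#'   matrix (>= 0).
#' @param epsilon Floor added to base probabilities before taking logs
#'   inside the transform; must lie in (0, 1). The default 0.1 makes a
#'   deterministic base cell leak roughly 1% of its mass at temperature 2
#'   and leaves equiprobable cells exactly equiprobable.
#' @return An object of class `precision_settings`.
#' @export
precision_settings <- function(a_temp = 2, b_temp = 2, epsilon = 0.1) {
  if (!is.numeric(a_temp) || length(a_temp) != 1L || is.na(a_temp) || a_temp < 0)
    stop("a_temp must be a single non-negative number")
  if (!is.numeric(b_temp) || length(b_temp) != 1L || is.na(b_temp) || b_temp < 0)
    stop("b_temp must be a single non-negative number")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must lie strictly between 0 and 1")
  structure(list(a_temp = a_temp, b_temp = b_temp, epsilon = epsilon),
            class = "precision_settings")
}

#' Temperature transform of a column-stochastic mapping
#'
#' Applies a column-wise softmax of `temp * log(base + epsilon)`. Each
#' column of `base` must sum to one. Temperature 0 returns uniform
#' columns; `Inf` returns the base mapping unchanged; equal entries
#' within a column remain equal at every temperature.
#'
#' @param base Column-stochastic matrix (entries typically 0, 0.5, 1).
#' @param temp Non-negative softmax temperature (higher = more precise).
#' @param epsilon Log floor in (0, 1); see [precision_settings()].
#' @return A column-stochastic matrix of the same shape.
#' @export
apply_precision <- function(base, temp, epsilon = 0.1) {
  base <- as.matrix(base)
  if (!is.numeric(temp) || length(temp) != 1L || is.na(temp) || temp < 0)
    stop("temp must be a single non-negative number")
  if (epsilon <= 0 || epsilon >= 1)
    stop("epsilon must lie strictly between 0 and 1")
  cs <- colSums(base)
  if (any(abs(cs - 1) > 1e-8) || any(base < 0))
    stop("base must be column-stochastic")
  if (is.infinite(temp)) return(base)
  out <- apply(base, 2L, function(col) softmax(temp * log(col + epsilon)))
  dimnames(out) <- dimnames(base)
  out
}

# Fully precise emotion -> content mappings (rows are the two informative
# levels of each modality, columns are emotions). 0.5/0.5 encodes an
# "either/or" association, 1/0 a deterministic one:
#   SAD    - unpleasant, high or low arousal, avoid, rejection, self-blame
#   AFRAID - unpleasant, high arousal, avoid, rejection or crowd, other-blame
#   ANGRY  - unpleasant, high arousal, approach, rejection, other-blame
#   HAPPY  - pleasant, high or low arousal, approach or avoid, crowd, flat blame
base_content_pattern <- function() {
  mk <- function(rows, ...) {
    m <- matrix(c(...), nrow = 2L, dimnames = list(rows, EMOTIONS))
    m
  }
  list(
    valence = mk(c("pleasant", "unpleasant"),
                 0, 1,   0, 1,   0, 1,   1, 0),
    arousal = mk(c("high", "low"),
                 0.5, 0.5,   1, 0,   1, 0,   0.5, 0.5),
    action  = mk(c("approach", "avoid"),
                 0, 1,   0, 1,   1, 0,   0.5, 0.5),
    context = mk(c("social-rejection", "crowded-event"),
                 1, 0,   0.5, 0.5,   1, 0,   0, 1),
    blame   = mk(c("self", "other"),
                 1, 0,   0, 1,   0, 1,   0.5, 0.5)
  )
}

# Assemble the full per-modality likelihood arrays P(o | emotion, attention)
# from 2 x 4 content blocks. Content is informative only in its own
# attention state; elsewhere the null level is emitted with certainty.
build_A_arrays <- function(content) {
  A <- list()
  for (m in CONTENT_MODALITIES) {
    lv <- MODALITY_LEVELS[[m]]
    arr <- array(0, dim = c(length(lv), N_EMOTION, N_ATTENTION),
                 dimnames = list(lv, EMOTIONS, ATTENTION_STATES))
    arr[1L, , ] <- 1                      # null everywhere ...
    att <- attend_state_of(m)
    arr[1L, , att] <- 0                   # ... except when attended
    arr[2:3, , att] <- content[[m]]
    A[[m]] <- arr
  }
  # Social feedback: correct iff the occupied report state matches the true
  # emotion; null outside report states. Kept fully precise.
  lv <- MODALITY_LEVELS$feedback
  fb <- array(0, dim = c(3L, N_EMOTION, N_ATTENTION),
              dimnames = list(lv, EMOTIONS, ATTENTION_STATES))
  fb[1L, , 1:6] <- 1
  for (r in REPORT_IDX) {
    e_match <- r - 6L
    fb[2L, e_match, r] <- 1
    fb[3L, setdiff(1:N_EMOTION, e_match), r] <- 1
  }
  A$feedback <- fb
  # Attended location: identity on the attention factor (the agent always
  # knows where its attention is directed).
  loc <- array(0, dim = c(N_ATTENTION, N_EMOTION, N_ATTENTION),
               dimnames = list(ATTENTION_STATES, EMOTIONS, ATTENTION_STATES))
  for (s in seq_len(N_ATTENTION)) loc[s, , s] <- 1
  A$location <- loc
  A
}

# Attention transition array B[to, from, action]: action 1 stays put,
# action k (k >= 2) moves any non-report state to attention state k;
# report states absorb under every action.
build_B_attention <- function() {
  B <- array(0, dim = c(N_ATTENTION, N_ATTENTION, N_ACTION),
             dimnames = list(ATTENTION_STATES, ATTENTION_STATES, ACTIONS))
  for (u in seq_len(N_ACTION)) {
    for (from in seq_len(N_ATTENTION)) {
      to <- if (from %in% REPORT_IDX) from else if (u == 1L) from else u
      B[to, from, u] <- 1
    }
  }
  B
}

#' Build the emotion-inference generative model
#'
#' Constructs the two-factor generative model: four emotion concepts and
#' ten attention states, seven outcome modalities (five content
#' modalities, social feedback, and attended location), an identity
#' emotion transition mapping (emotions are stable within a trial) whose
#' precision is set by `b_temp`, controllable attention transitions, a
#' preference for correct over incorrect social feedback, flat initial
#' emotion priors, and a uniform habit prior over the ten actions.
#'
#' Preferences are timestep-resolved: besides valuing "correct" and
#' avoiding "incorrect" social feedback throughout, the agent expects to
#' have committed to a report by the end of the trial, expressed as an
#' aversion (`c_end`) to still observing null feedback at the final
#' timestep. Early in the trial this leaves attention free to forage for
#' evidence; at the last decision point it drives a report even under
#' uncertainty, so no trial ends without an answer.
#'
#' @param precisions A [precision_settings()] object; `a_temp` sets the
#'   precision of the emotion-to-content likelihoods and `b_temp` the
#'   precision of the within-trial emotional stability beliefs.
#' @param c_reward,c_punish Log-preference (nat) values assigned to
#'   "correct" and "incorrect" social feedback. Their spread and
#'   asymmetry set how confident the agent must be before reporting
#'   pays better than a further attentional shift.
#' @param c_end Log-preference assigned to null feedback at the final
#'   timestep (an aversion to ending the trial without having
#'   reported).
#' @param gamma Policy precision (inverse temperature on expected free
#'   energy in the policy posterior). May be overridden per call.
#' @return An object of class `emo_model`.
#' @export
build_emotion_model <- function(precisions = precision_settings(),
                                c_reward = engine_defaults()$c_reward,
                                c_punish = engine_defaults()$c_punish,
                                c_end = engine_defaults()$c_end,
                                gamma = NULL) {
  stopifnot(inherits(precisions, "precision_settings"))
  base <- base_content_pattern()
  content <- lapply(base, apply_precision,
                    temp = precisions$a_temp, epsilon = precisions$epsilon)
  A <- build_A_arrays(content)

  B_emotion <- apply_precision(diag(N_EMOTION), precisions$b_temp,
                               precisions$epsilon)
  dimnames(B_emotion) <- list(EMOTIONS, EMOTIONS)

  # log-preferences per outcome level and timestep
  C <- lapply(MODALITY_LEVELS, function(lv) {
    matrix(0, length(lv), N_TIMESTEP, dimnames = list(lv, NULL))
  })
  C$feedback["correct", ] <- c_reward
  C$feedback["incorrect", ] <- c_punish
  C$feedback["null", N_TIMESTEP] <- c_end

  D <- list(
    emotion = stats::setNames(rep(1 / N_EMOTION, N_EMOTION), EMOTIONS),
    attention = stats::setNames(c(1, rep(0, N_ATTENTION - 1L)),
                                ATTENTION_STATES)
  )
  E <- stats::setNames(rep(1 / N_ACTION, N_ACTION), ACTIONS)

  model <- structure(list(
    A = A,
    B = list(emotion = B_emotion, attention = build_B_attention()),
    C = C,
    D = D,
    E = E,
    a = NULL,                 # concentration blocks, set when learning
    d = NULL,
    precisions = precisions,
    control = list(gamma = if (is.null(gamma)) engine_defaults()$gamma else gamma)
  ), class = "emo_model")
  validate_model(model)
  model
}

#' @export
print.emo_model <- function(x, ...) {
  cat("<emo_model> active-inference emotion model\n")
  cat("  precisions: a_temp =", x$precisions$a_temp,
      " b_temp =", x$precisions$b_temp, "\n")
  cat("  learning:  a", if (is.null(x$a)) "off" else "on",
      " | d", if (is.null(x$d)) "off" else "on", "\n")
  cat("  habit prior (E):",
      if (max(x$E) / min(x$E) > 1 + 1e-9) "biased" else "uniform", "\n")
  invisible(x)
}

# Internal consistency checks (normalization, absorption).
validate_model <- function(model, tol = 1e-10) {
  for (m in MODALITIES) {
    cs <- apply(model$A[[m]], c(2, 3), sum)
    if (any(abs(cs - 1) > tol)) stop("A[", m, "] columns do not sum to 1")
  }
  if (any(abs(colSums(model$B$emotion) - 1) > tol))
    stop("emotion transition columns do not sum to 1")
  for (u in seq_len(N_ACTION)) {
    Bu <- model$B$attention[, , u]
    if (any(abs(colSums(Bu) - 1) > tol))
      stop("attention transition columns do not sum to 1")
    for (r in REPORT_IDX)
      if (Bu[r, r] != 1) stop("report state ", r, " is not absorbing")
  }
  for (f in names(model$D))
    if (abs(sum(model$D[[f]]) - 1) > tol) stop("D[", f, "] does not sum to 1")
  if (abs(sum(model$E) - 1) > tol) stop("E does not sum to 1")
  if (!is.null(model$a)) {
    for (m in CONTENT_MODALITIES)
      if (any(model$a[[m]] <= 0)) stop("concentration entries must be positive")
  }
  if (!is.null(model$d) && any(model$d <= 0))
    stop("d concentration entries must be positive")
  invisible(TRUE)
}

#' Blank ("childhood") concept model
#'
#' Returns a copy of `template` whose emotion-to-content likelihood
#' blocks are replaced by flat Dirichlet concentration parameters
#' (every emotion predicts every content outcome equally), with
#' likelihood learning enabled for those blocks. The attention-location
#' identity, the feedback mapping, and all null-emission structure stay
#' precise and frozen. The initial emotion prior is given uniform
#' concentration `d0` and is likewise learnable.
#'
#' @param template An `emo_model` from [build_emotion_model()].
#' @param a0 Positive initial concentration per content cell.
#' @param d0 Positive initial concentration per emotion prior cell
#'   (`NULL` disables prior learning).
#' @return An `emo_model` with active concentration parameters.
#' @export
blank_concept_model <- function(template, a0 = engine_defaults()$a0,
                                d0 = engine_defaults()$d0) {
  stopifnot(inherits(template, "emo_model"))
  if (!is.numeric(a0) || length(a0) != 1L || a0 <= 0) stop("a0 must be > 0")
  model <- template
  model$a <- lapply(base_content_pattern(), function(blk) {
    a <- blk; a[] <- a0; a
  })
  if (!is.null(d0)) {
    if (d0 <= 0) stop("d0 must be > 0")
    model$d <- stats::setNames(rep(d0, N_EMOTION), EMOTIONS)
  }
  refresh_from_counts(model)
}

# Rebuild the normalized A content blocks and D prior from concentration
# parameters after construction or a learning update.
refresh_from_counts <- function(model) {
  if (!is.null(model$a)) {
    for (m in CONTENT_MODALITIES) {
      blk <- sweep(model$a[[m]], 2L, colSums(model$a[[m]]), "/")
      model$A[[m]][2:3, , attend_state_of(m)] <- blk
    }
  }
  if (!is.null(model$d)) {
    model$D$emotion[] <- model$d / sum(model$d)
  }
  model
}

#' Named attention-bias action sets
#'
#' The three habitual attention biases studied with this model:
#' `external` (context and blame), `internal` (valence and arousal), and
#' `somatic` (arousal and action tendency).
#' @return Named list of action-label character vectors.
#' @export
attention_bias_sets <- function() {
  list(
    external = c("attend-context", "attend-blame"),
    internal = c("attend-valence", "attend-arousal"),
    somatic  = c("attend-arousal", "attend-action")
  )
}

#' Bias the habit prior toward a subset of attention actions
#'
#' Multiplies the habit-prior (E) entries of the favored attend actions
#' by `factor` and renormalizes, leaving the relative weights of all
#' other actions unchanged.
#'
#' @param model An `emo_model`.
#' @param favored_actions Character vector of attend-action labels, or a
#'   bias name from [attention_bias_sets()] (`"external"`, `"internal"`,
#'   `"somatic"`).
#' @param factor Positive multiplier (the bias strength; 1 = no bias).
#' @return The model with an updated habit prior.
#' @export
set_attention_bias <- function(model, favored_actions, factor = 50) {
  stopifnot(inherits(model, "emo_model"))
  if (length(favored_actions) == 1L &&
      favored_actions %in% names(attention_bias_sets()))
    favored_actions <- attention_bias_sets()[[favored_actions]]
  if (length(favored_actions) == 0L) {
    if (factor != 1) stop("empty favored set with factor != 1")
    return(model)
  }
  idx <- action_index(favored_actions)
  if (!all(idx %in% ATTEND_IDX))
    stop("favored actions must be attend actions")
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  E <- model$E
  E[idx] <- E[idx] * factor
  model$E <- E / sum(E)
  model
}

# Engine-level defaults shared by the simulation protocols; see the
# methods vignette for the calibration rationale.
engine_defaults <- function() {
  list(gamma = 8, iterations = 16L, eta = 1, a0 = 0.5, d0 = 1,
       c_reward = 4, c_punish = -16, c_end = -16)
}
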