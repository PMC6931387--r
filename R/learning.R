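# Between-trial Dirichlet learning of the likelihood (a) and initial
# emotion prior (d), plus the expected-evidence diagnostic.

#' Learning configuration
#'
#' @param eta Positive count increment added per observation for the
#'   likelihood concentrations.
#' @param eta_d Count increment per trial for the initial-state prior
#'   concentrations. The default is a fiftieth of `eta`: the prior
#'   receives one full count per trial on a four-cell vector while each
#'   likelihood column receives at most one, so an undamped prior
#'   concentrates much faster than the likelihood it must arbitrate,
#'   dominates single-observation posteriors, and amplifies early
#'   mislabeling into self-reinforcing concept confusions.
#' @param learn_a Update the likelihood concentration parameters?
#' @param learn_d Update the initial emotion-prior concentrations?
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(eta = 1, eta_d = eta / 50, learn_a = TRUE,
                            learn_d = TRUE) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0)
    stop("eta must be a single positive number")
  if (!is.numeric(eta_d) || length(eta_d) != 1L || eta_d < 0)
    stop("eta_d must be a single non-negative number")
  structure(list(eta = eta, eta_d = eta_d, learn_a = isTRUE(learn_a),
                 learn_d = isTRUE(learn_d)),
            class = "learning_config")
}

#' Update likelihood concentration parameters from a completed trial
#'
#' For every timestep at which a content modality was attended, the
#' concentration cell linking the observed outcome to each emotion is
#' incremented by `eta` times the end-of-trial retrospective posterior
#' over emotions at that timestep. Frozen structure (null emissions,
#' feedback, attended location) is untouched; the normalized likelihood
#' is refreshed from the counts.
#'
#' @param model An `emo_model` with active concentrations (see
#'   [blank_concept_model()]).
#' @param record An `emo_trial`.
#' @param cfg A [learning_config()].
#' @return The updated model.
#' @export
update_A_counts <- function(model, record, cfg = learning_config()) {
  stopifnot(inherits(model, "emo_model"), inherits(record, "emo_trial"))
  if (!cfg$learn_a) return(model)
  if (is.null(model$a)) stop("model has no likelihood concentration parameters")
  for (t in seq_len(N_TIMESTEP)) {
    att <- record$attention[t]
    if (att %in% ATTEND_IDX) {
      m <- att - 1L
      o <- record$observations[CONTENT_MODALITIES[m], t]
      if (o > 1L) {      # informative content level observed
        post <- record$retrospective_posteriors[, t]
        model$a[[m]][o - 1L, ] <- model$a[[m]][o - 1L, ] + cfg$eta * post
      }
    }
  }
  refresh_from_counts(model)
}

#' Update initial-state prior concentrations from a completed trial
#'
#' Adds `eta` times the retrospective posterior over the trial's initial
#' emotion state to the prior concentrations `d` and refreshes `D`.
#'
#' @inheritParams update_A_counts
#' @return The updated model.
#' @export
update_D_counts <- function(model, record, cfg = learning_config()) {
  stopifnot(inherits(model, "emo_model"), inherits(record, "emo_trial"))
  if (!cfg$learn_d) return(model)
  if (is.null(model$d)) stop("model has no prior concentration parameters")
  model$d <- model$d + cfg$eta_d * record$retrospective_posteriors[, 1L]
  refresh_from_counts(model)
}

#' Expected log-likelihood under a Dirichlet column
#'
#' Converts concentration parameters into expected log probabilities,
#' `psi(a) - psi(colsum(a))`, applied column-wise.
#'
#' @param a Matrix of positive concentration parameters (columns are
#'   conditioning states).
#' @return Matrix of expected log probabilities.
#' @export
expected_log_likelihood <- function(a) {
  a <- as.matrix(a)
  if (any(a <= 0)) stop("concentration parameters must be positive")
  digamma(a) - rep(digamma(colSums(a)), each = nrow(a))
}

#' Expected model evidence for each emotion concept
#'
#' Treats each emotion concept as a candidate model of the attended
#' outcome pattern and computes the expectation, under the generative
#' process's outcome distributions given the true emotion, of the
#' agent's likelihood of those outcomes given each concept. Content
#' modalities are conditionally independent given the state, so the
#' expectation factorizes into a product over the five content
#' modalities (each evaluated in its attended state).
#'
#' @param model An `emo_model`.
#' @param process An `emo_process`.
#' @param true_emotion The emotion generating outcomes in the world.
#' @param log Return log evidence?
#' @return Named numeric vector over the four emotion concepts.
#' @export
expected_evidence <- function(model, process, true_emotion, log = FALSE) {
  stopifnot(inherits(model, "emo_model"), inherits(process, "emo_process"))
  e <- emotion_index(true_emotion)
  ev <- rep(1, N_EMOTION)
  for (m in seq_along(CONTENT_MODALITIES)) {
    mod <- CONTENT_MODALITIES[m]
    p_true <- process$P[[m]][, e]                        # 2 levels
    lik <- model$A[[mod]][2:3, , attend_state_of(mod)]   # 2 x 4
    ev <- ev * as.numeric(t(lik) %*% p_true)
  }
  names(ev) <- EMOTIONS
  if (log) log(ev) else ev
}
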