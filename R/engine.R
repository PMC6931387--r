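# Within-trial inversion of the generative model: variational state
# inference, expected free energy of one-step policies, policy posterior
# with habits and precision gamma, action selection, and trial execution.

# Expected log-likelihood arrays per modality. Learnable blocks use the
# digamma transform of concentration parameters; frozen structure uses
# plain (floored) logs of the normalized likelihood.
model_loglik <- function(model) {
  lnA <- lapply(model$A, ln_safe)
  if (!is.null(model$a)) {
    for (m in CONTENT_MODALITIES) {
      a <- model$a[[m]]
      elog <- digamma(a) - rep(digamma(colSums(a)), each = 2L)
      lnA[[m]][2:3, , attend_state_of(m)] <- elog
    }
  }
  lnA
}

# Per-modality conditional entropy H(o | emotion, attention) used by the
# ambiguity term of expected free energy.
model_ambiguity <- function(model) {
  lapply(model$A, function(arr) {
    plogp <- ifelse(arr > 0, arr * log(arr), 0)
    -apply(plogp, c(2, 3), sum)
  })
}

# Dirichlet novelty blocks 0.5 * (1/a - 1/colsum(a)) for the learnable
# content cells; zero elsewhere (frozen mappings carry no novelty).
model_novelty <- function(model) {
  if (is.null(model$a)) return(NULL)
  lapply(model$a, function(a) {
    0.5 * (1 / a - rep(1 / colSums(a), each = 2L))
  })
}

#' Variational state inference over a partial trial
#'
#' Computes posterior beliefs about the emotion state at every observed
#' timestep, by fixed-point (coordinate-ascent) iteration of the
#' mean-field free energy under the within-trial model: likelihood
#' messages from all observed modalities, forward and backward
#' transition messages through the emotional-stability mapping, and the
#' initial prior at the first timestep. Attention-state beliefs follow
#' directly from the (identity-mapped) attended-location outcome.
#'
#' @param model An `emo_model`.
#' @param observations Integer matrix of outcome indices, one row per
#'   modality (in the order of `MODALITY_LEVELS`), one column per
#'   observed timestep.
#' @param iterations Number of fixed-point sweeps (default 16).
#' @param keep_iterates Keep the per-iteration belief trajectory (the
#'   depolarization analogue used for simulated neural responses)?
#' @return A list of class `emo_beliefs`: `s` (4 x T emotion
#'   posteriors), `attention` (integer attention-state sequence),
#'   `F` (free energy per iteration), and optionally `iterates`
#'   (4 x T x iterations array).
#' @export
infer_states <- function(model, observations, iterations = 16L,
                         keep_iterates = FALSE) {
  obs <- as.matrix(observations)
  n_t <- ncol(obs)
  if (nrow(obs) != length(MODALITIES))
    stop("observations must have one row per modality")
  for (m in seq_along(MODALITIES)) {
    n_lv <- length(MODALITY_LEVELS[[m]])
    bad <- !is.na(obs[m, ]) & (obs[m, ] < 1 | obs[m, ] > n_lv)
    if (any(bad)) stop("observation index out of range for modality ",
                       MODALITIES[m])
  }
  lnA <- model_loglik(model)
  att <- obs[match("location", MODALITIES), ]

  # Log-likelihood message over emotions for each timestep.
  lnL <- matrix(0, N_EMOTION, n_t)
  for (t in seq_len(n_t)) {
    for (m in seq_along(MODALITIES)) {
      o <- obs[m, t]
      if (!is.na(o)) lnL[, t] <- lnL[, t] + lnA[[m]][o, , att[t]]
    }
  }

  lnB <- ln_safe(model$B$emotion)
  lnD <- ln_safe(model$D$emotion)
  B <- model$B$emotion
  L <- exp(lnL)                       # per-timestep likelihood vectors
  s <- matrix(1 / N_EMOTION, N_EMOTION, n_t,
              dimnames = list(EMOTIONS, NULL))
  iterates <- if (keep_iterates)
    array(NA_real_, c(N_EMOTION, n_t, iterations)) else NULL
  Ftrace <- numeric(iterations)

  # Each sweep is a full forward-backward message pass along the
  # emotion chain; the sweep's fixed point is the exact smoothed
  # posterior (mutual mean-field coupling through the near-identity
  # stability mapping would instead polarize the per-timestep factors
  # and yield overconfident beliefs).
  for (it in seq_len(iterations)) {
    alpha <- matrix(0, N_EMOTION, n_t)
    a_cur <- model$D$emotion * L[, 1L]
    alpha[, 1L] <- a_cur / sum(a_cur)
    if (n_t > 1L) for (t in 2:n_t) {
      a_cur <- L[, t] * as.numeric(B %*% alpha[, t - 1L])
      alpha[, t] <- a_cur / sum(a_cur)
    }
    beta <- matrix(1, N_EMOTION, n_t)
    if (n_t > 1L) for (t in (n_t - 1L):1L) {
      b_cur <- as.numeric(t(B) %*% (L[, t + 1L] * beta[, t + 1L]))
      beta[, t] <- b_cur / sum(b_cur)
    }
    for (t in seq_len(n_t)) {
      p <- alpha[, t] * beta[, t]
      s[, t] <- p / sum(p)
    }
    if (keep_iterates) iterates[, , it] <- s
    Ftrace[it] <- mean_field_F(s, lnL, lnB, lnD)
  }

  structure(list(s = s, attention = att, F = Ftrace, lnL = lnL,
                 iterates = iterates),
            class = "emo_beliefs")
}

# Mean-field variational free energy of the within-trial chain.
mean_field_F <- function(s, lnL, lnB, lnD) {
  n_t <- ncol(s)
  F <- sum(s * ln_safe(s)) - sum(s * lnL) - sum(s[, 1L] * lnD)
  if (n_t > 1L)
    for (t in 2:n_t) F <- F - sum(s[, t] * (lnB %*% s[, t - 1L]))
  F
}

#' Expected free energy of a single action
#'
#' One-step lookahead: the candidate action fixes the next attention
#' state; predicted emotion beliefs follow the stability mapping. The
#' expected free energy decomposes exactly as
#' `G = risk + ambiguity - novelty`, where risk is the divergence of
#' predicted outcomes from preferred outcomes (preferences are
#' timestep-resolved, so the outcome predicted for timestep `t + 1` is
#' scored against the preference column for that timestep), ambiguity
#' is the expected conditional entropy of outcomes given states, and
#' novelty is the expected information gain about the likelihood's
#' Dirichlet parameters (zero when learning is disabled).
#'
#' @param model An `emo_model`.
#' @param s_emotion Current posterior over emotion states (length 4).
#' @param attention Current attention-state index or label.
#' @param action Action index or label.
#' @param t Current timestep (the action realizes its outcome at
#'   `t + 1`).
#' @param cache Optional precomputed cache from [efe_cache()].
#' @return List with `G`, `risk`, `ambiguity`, `novelty`.
#' @export
expected_free_energy <- function(model, s_emotion, attention, action,
                                 t = 1L, cache = NULL) {
  if (is.null(cache)) cache <- efe_cache(model)
  if (t >= N_TIMESTEP) stop("t must be an intra-trial decision point")
  att <- attention_index(attention)
  u <- action_index(action)
  att_next <- which(model$B$attention[, att, u] == 1)
  s_pred <- as.numeric(model$B$emotion %*% s_emotion)

  risk <- 0; ambiguity <- 0; novelty <- 0
  for (m in seq_along(MODALITIES)) {
    mod <- MODALITIES[m]
    q <- as.numeric(model$A[[mod]][, , att_next] %*% s_pred)
    risk <- risk + sum(q * (ln_safe(q) - model$C[[mod]][, t + 1L]))
    ambiguity <- ambiguity + sum(s_pred * cache$H[[mod]][, att_next])
    if (!is.null(cache$W) && mod %in% CONTENT_MODALITIES &&
        att_next == attend_state_of(mod)) {
      qc <- q[2:3]
      novelty <- novelty + as.numeric(t(qc) %*% cache$W[[mod]] %*% s_pred)
    }
  }
  list(G = risk + ambiguity - novelty,
       risk = risk, ambiguity = ambiguity, novelty = novelty)
}

#' @rdname expected_free_energy
#' @export
efe_cache <- function(model) {
  list(H = model_ambiguity(model), W = model_novelty(model))
}

#' Policy posterior from expected free energy and habits
#'
#' `pi = softmax(ln E - gamma * G)`. Optionally iterates the
#' inverse-precision state beta: `beta <- beta0 + (pi - pi0) . (-G)`,
#' `gamma = 1/beta`, where `pi0` is the habit-only posterior.
#'
#' @param G Numeric vector of per-action expected free energies.
#' @param E Normalized habit prior over actions.
#' @param gamma Policy precision (fixed mode).
#' @param update_gamma Iterate the beta update instead of using fixed
#'   gamma?
#' @param beta0 Prior inverse precision for the beta update.
#' @return List with `pi`, `gamma`.
#' @export
policy_posterior <- function(G, E, gamma = engine_defaults()$gamma,
                             update_gamma = FALSE, beta0 = 1) {
  if (any(!is.finite(G))) stop("non-finite expected free energy")
  if (abs(sum(E) - 1) > 1e-8) stop("E must be normalized")
  lnE <- ln_safe(E)
  if (!update_gamma) {
    return(list(pi = softmax(lnE - gamma * G), gamma = gamma))
  }
  pi0 <- softmax(lnE)
  beta <- beta0
  for (i in 1:8) {
    g <- 1 / beta
    p <- softmax(lnE - g * G)
    beta <- max(beta0 + sum((p - pi0) * (-G)), 1e-3)
  }
  g <- 1 / beta
  list(pi = softmax(lnE - g * G), gamma = g)
}

#' Select an action from the policy posterior
#'
#' @param pi Normalized categorical over actions.
#' @param mode `"sample"` draws from `pi` using the current RNG stream;
#'   `"argmax"` picks the most probable action, breaking ties by lowest
#'   action index.
#' @return Integer action index.
#' @export
select_action <- function(pi, mode = c("sample", "argmax")) {
  mode <- match.arg(mode)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must be normalized")
  if (mode == "argmax") which.max(pi)
  else sample.int(length(pi), 1L, prob = pi)
}

#' Run a single six-timestep emotion-inference trial
#'
#' The agent starts in the uninformative attention state, and at each of
#' the five decision points evaluates the expected free energy of all
#' ten one-step policies, forms the policy posterior, and enacts an
#' action. Attending reveals the corresponding content outcome sampled
#' by the generative process; entering a report state is absorbing and
#' elicits correct/incorrect social feedback at every remaining
#' timestep. A trial with no report is scored incorrect.
#'
#' @param model An `emo_model` (the agent).
#' @param process An `emo_process` (the world); see
#'   [generative_process()].
#' @param true_emotion Emotion label or index.
#' @param mode Action selection mode, `"sample"` or `"argmax"`.
#' @param outcomes Optional fixed content-outcome realization (integer
#'   vector of length 5, values 1/2 indexing the informative levels).
#'   By default one realization is drawn from the process at the start
#'   of the trial — a trial is one "set of observations", so attending
#'   the same modality twice reveals the same state of the world.
#'   Supplying `outcomes` lets different agents see identical
#'   observation sequences.
#' @param record_iterates Keep belief iterates for [neural_traces()]?
#' @param update_gamma Use the dynamic beta/gamma update.
#' @return An object of class `emo_trial`.
#' @export
run_trial <- function(model, process, true_emotion, mode = "sample",
                      outcomes = NULL, record_iterates = FALSE,
                      update_gamma = FALSE) {
  stopifnot(inherits(model, "emo_model"), inherits(process, "emo_process"))
  e_true <- emotion_index(true_emotion)
  # one content realization per trial and (reachable) true state; under
  # an unstable process the true emotion can drift between timesteps
  oc_tab <- if (!is.null(outcomes)) {
    matrix(rep(as.integer(outcomes), N_EMOTION), 5L)
  } else if (is.infinite(process$b_temp)) {
    tab <- matrix(NA_integer_, 5L, N_EMOTION)
    tab[, e_true] <- sample_trial_outcomes(process, e_true)
    tab
  } else {
    vapply(seq_len(N_EMOTION), function(e)
      sample_trial_outcomes(process, e), integer(5))
  }
  e_cur <- e_true
  cache <- efe_cache(model)
  gamma <- model$control$gamma

  obs <- matrix(NA_integer_, length(MODALITIES), N_TIMESTEP,
                dimnames = list(MODALITIES, NULL))
  att_seq <- integer(N_TIMESTEP)
  actions <- rep(NA_integer_, N_TIMESTEP - 1L)
  pol <- matrix(NA_real_, N_ACTION, N_TIMESTEP - 1L,
                dimnames = list(ACTIONS, NULL))
  Gmat <- matrix(NA_real_, N_ACTION, N_TIMESTEP - 1L,
                 dimnames = list(ACTIONS, NULL))
  online <- matrix(NA_real_, N_EMOTION, N_TIMESTEP,
                   dimnames = list(EMOTIONS, NULL))
  gamma_trace <- rep(NA_real_, N_TIMESTEP - 1L)
  iter_log <- if (record_iterates) vector("list", N_TIMESTEP) else NULL

  att <- 1L
  att_seq[1L] <- att
  obs[, 1L] <- sample_observation(process, e_cur, att,
                                  outcomes = oc_tab[, e_cur])

  for (t in seq_len(N_TIMESTEP)) {
    inf <- infer_states(model, obs[, seq_len(t), drop = FALSE],
                        keep_iterates = record_iterates)
    online[, t] <- inf$s[, t]
    if (record_iterates) iter_log[[t]] <- inf$iterates
    if (t == N_TIMESTEP) break

    if (att %in% REPORT_IDX) {
      att_seq[t + 1L] <- att          # absorbed: no further decisions
    } else {
      Gs <- vapply(seq_len(N_ACTION), function(u)
        expected_free_energy(model, inf$s[, t], att, u, t = t,
                             cache = cache)$G,
        numeric(1))
      pp <- policy_posterior(Gs, model$E, gamma = gamma,
                             update_gamma = update_gamma)
      u <- select_action(pp$pi, mode = mode)
      actions[t] <- u
      pol[, t] <- pp$pi
      Gmat[, t] <- Gs
      gamma_trace[t] <- pp$gamma
      att <- which(model$B$attention[, att, u] == 1)
      att_seq[t + 1L] <- att
    }
    e_cur <- step_true_state(process, e_cur)
    obs[, t + 1L] <- sample_observation(process, e_cur, att_seq[t + 1L],
                                        outcomes = oc_tab[, e_cur])
  }

  retro <- infer_states(model, obs, keep_iterates = record_iterates)
  report_idx <- att_seq[att_seq %in% REPORT_IDX]
  report <- if (length(report_idx)) EMOTIONS[report_idx[1L] - 6L] else NA_character_
  # correctness follows the social feedback actually received (which
  # tracks the true state at the moment of the report)
  fb <- obs["feedback", ]
  fb <- fb[fb != 1L]
  correct <- length(fb) > 0L && fb[1L] == 2L

  structure(list(
    true_emotion = EMOTIONS[e_true],
    observations = obs,
    attention = att_seq,
    actions = actions,
    policy_posteriors = pol,
    G = Gmat,
    online_posteriors = online,
    retrospective_posteriors = retro$s,
    report = report,
    correct = correct,
    gamma_trace = gamma_trace,
    iterates = iter_log,
    retro_iterates = retro$iterates
  ), class = "emo_trial")
}

#' @export
print.emo_trial <- function(x, ...) {
  shifts <- ACTIONS[stats::na.omit(x$actions)]
  cat("<emo_trial> true:", x$true_emotion,
      "| report:", ifelse(is.na(x$report), "none", x$report),
      "|", if (x$correct) "correct" else "incorrect", "\n")
  cat("  actions:", paste(shifts, collapse = " -> "), "\n")
  invisible(x)
}

#' Simulated neural responses for a trial
#'
#' Converts the stored belief-update iterates of a trial into firing
#' rates (posterior expectations of each emotion unit at each trial
#' timestep, on a fine within-timestep grid given by the variational
#' iterations) and local field potentials (first temporal differences
#' of firing), plus the policy-precision trace.
#'
#' @param record An `emo_trial` produced with `record_iterates = TRUE`.
#' @return List of class `emo_neural`: `firing` (emotion x trial
#'   timestep x global iteration), `lfp` (same shape, first
#'   differences), `gamma_trace`.
#' @export
neural_traces <- function(record) {
  stopifnot(inherits(record, "emo_trial"))
  if (is.null(record$iterates)) stop("trial was run without iterate logging")
  n_iter <- dim(record$iterates[[1L]])[3L]
  n_grid <- N_TIMESTEP * n_iter
  firing <- array(1 / N_EMOTION, c(N_EMOTION, N_TIMESTEP, n_grid),
                  dimnames = list(EMOTIONS, NULL, NULL))
  for (t in seq_len(N_TIMESTEP)) {
    it <- record$iterates[[t]]           # beliefs after observing 1..t
    for (k in seq_len(n_iter)) {
      g <- (t - 1L) * n_iter + k
      for (tau in seq_len(t)) firing[, tau, g:n_grid] <- it[, tau, k]
    }
  }
  lfp <- firing
  lfp[] <- 0
  lfp[, , 2:n_grid] <- firing[, , 2:n_grid] - firing[, , 1:(n_grid - 1L)]
  structure(list(firing = firing, lfp = lfp,
                 gamma_trace = record$gamma_trace),
            class = "emo_neural")
}
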