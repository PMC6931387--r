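# Shared fixtures and independent oracles for the test suite.

trained_model <- function(a_temp = 2, b_temp = 2, ...) {
  build_emotion_model(precision_settings(a_temp, b_temp), ...)
}

blank_model <- function(a0 = 0.5, d0 = 1, ...) {
  blank_concept_model(trained_model(...), a0 = a0, d0 = d0)
}

# Observation matrix builder: a list of (attention label, modality label,
# outcome label) triples, one per timestep; unspecified modalities null.
make_obs <- function(steps) {
  obs <- matrix(NA_integer_, length(affectinf:::MODALITIES), length(steps),
                dimnames = list(affectinf:::MODALITIES, NULL))
  for (t in seq_along(steps)) {
    st <- steps[[t]]
    att <- match(st$attention, affectinf:::ATTENTION_STATES)
    obs[, t] <- 1L
    obs["location", t] <- att
    if (!is.null(st$modality))
      obs[st$modality, t] <-
        match(st$outcome, affectinf:::MODALITY_LEVELS[[st$modality]])
  }
  obs
}

# Independent single-timestep Bayes oracle: posterior over emotions from
# the prior and the raw likelihood arrays (no message passing involved).
bayes_posterior_oracle <- function(model, obs_col) {
  att <- obs_col[match("location", affectinf:::MODALITIES)]
  lik <- rep(1, 4)
  for (m in seq_along(affectinf:::MODALITIES)) {
    o <- obs_col[m]
    if (!is.na(o))
      lik <- lik * model$A[[affectinf:::MODALITIES[m]]][o, , att]
  }
  p <- model$D$emotion * lik
  p / sum(p)
}

# Brute-force expected free energy oracle: enumerates the full joint
# outcome space (all level combinations of all seven modalities) under
# the predicted state distribution, computing risk, ambiguity and
# novelty from first principles.
efe_oracle <- function(model, s_emotion, attention, action, t = 1L) {
  att <- match(attention, affectinf:::ATTENTION_STATES)
  if (is.na(att)) att <- attention
  u <- action
  att_next <- which(model$B$attention[, att, u] == 1)
  s_pred <- as.numeric(model$B$emotion %*% s_emotion)
  mods <- affectinf:::MODALITIES
  levels <- lapply(mods, function(m) seq_along(affectinf:::MODALITY_LEVELS[[m]]))
  grid <- expand.grid(levels)
  names(grid) <- mods

  W <- affectinf:::model_novelty(model)
  risk <- 0; ambiguity <- 0; novelty <- 0
  # joint predicted outcome probability and preference per combination
  for (i in seq_len(nrow(grid))) {
    q_joint <- 1; c_joint <- 0
    for (m in mods) {
      o <- grid[i, m]
      q_m <- sum(model$A[[m]][o, , att_next] * s_pred)
      q_joint <- q_joint * q_m
      c_joint <- c_joint + model$C[[m]][o, t + 1L]
    }
    if (q_joint > 0) risk <- risk + q_joint * (log(q_joint + 1e-16) - c_joint)
  }
  # expected conditional entropy over the joint outcome space per state
  for (e in 1:4) {
    H_e <- 0
    for (m in mods) {
      p <- model$A[[m]][, e, att_next]
      H_e <- H_e - sum(ifelse(p > 0, p * log(p), 0))
    }
    ambiguity <- ambiguity + s_pred[e] * H_e
  }
  if (!is.null(W)) {
    for (m in affectinf:::CONTENT_MODALITIES) {
      if (att_next == affectinf:::attend_state_of(m)) {
        for (o in 2:3) for (e in 1:4) {
          q_m <- sum(model$A[[m]][o, , att_next] * s_pred)
          novelty <- novelty + q_m * W[[m]][o - 1L, e] * s_pred[e]
        }
      }
    }
  }
  list(G = unname(risk + ambiguity - novelty), risk = unname(risk),
       ambiguity = unname(ambiguity), novelty = unname(novelty))
}

# Enumeration oracle for expected evidence: sums over all 2^5 joint
# content patterns.
expected_evidence_oracle <- function(model, process, true_emotion) {
  e <- match(true_emotion, affectinf:::EMOTIONS)
  combos <- expand.grid(rep(list(1:2), 5))
  ev <- rep(0, 4)
  for (i in seq_len(nrow(combos))) {
    p_true <- 1; lik <- rep(1, 4)
    for (m in seq_len(5)) {
      o <- combos[i, m]
      mod <- affectinf:::CONTENT_MODALITIES[m]
      p_true <- p_true * process$P[[m]][o, e]
      lik <- lik * model$A[[mod]][o + 1L, , affectinf:::attend_state_of(mod)]
    }
    ev <- ev + p_true * lik
  }
  unname(ev)
}

# Minimal trial record carrying just what the learning updates read.
fake_trial <- function(attention, observations, retro) {
  structure(list(attention = attention, observations = observations,
                 retrospective_posteriors = retro),
            class = "emo_trial")
}
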