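# State, action, and outcome spaces of the emotion-inference MDP.
#
# Factor 1 (emotion) has 4 levels; factor 2 (attention) has 10 levels:
# an uninformative start state, five covert attention states (one per
# content modality), and four absorbing report states. The 10 actions
# are "stay" plus one action per non-start attention state.

EMOTIONS <- c("SAD", "AFRAID", "ANGRY", "HAPPY")

ATTENTION_STATES <- c(
  "start",
  "attend-valence", "attend-arousal", "attend-action",
  "attend-context", "attend-blame",
  "report-SAD", "report-AFRAID", "report-ANGRY", "report-HAPPY"
)

ACTIONS <- c("stay", ATTENTION_STATES[2:10])

N_EMOTION <- 4L
N_ATTENTION <- 10L
N_ACTION <- 10L
N_TIMESTEP <- 6L

ATTEND_IDX <- 2:6    # attention states gating a content modality
REPORT_IDX <- 7:10   # absorbing report states

CONTENT_MODALITIES <- c("valence", "arousal", "action", "context", "blame")

# First level of every non-location modality is an uninformative "null"
# outcome, emitted whenever the modality is not being attended.
MODALITY_LEVELS <- list(
  valence  = c("null", "pleasant", "unpleasant"),
  arousal  = c("null", "high", "low"),
  action   = c("null", "approach", "avoid"),
  context  = c("null", "social-rejection", "crowded-event"),
  blame    = c("null", "self", "other"),
  feedback = c("null", "correct", "incorrect"),
  location = ATTENTION_STATES
)

MODALITIES <- names(MODALITY_LEVELS)

# Attention state that renders content modality m informative.
attend_state_of <- function(m) match(m, CONTENT_MODALITIES) + 1L

# Numerical floor used inside logarithms (beliefs and likelihoods are
# never exactly zero in log space).
LOG_FLOOR <- 1e-16

ln_safe <- function(x) log(x + LOG_FLOOR)

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

emotion_index <- function(x) {
  if (is.character(x)) {
    i <- match(x, EMOTIONS)
    if (anyNA(i)) stop("unknown emotion label: ", paste(x[is.na(i)], collapse = ", "))
    i
  } else as.integer(x)
}

attention_index <- function(x) {
  if (is.character(x)) {
    i <- match(x, ATTENTION_STATES)
    if (anyNA(i)) stop("unknown attention state: ", paste(x[is.na(i)], collapse = ", "))
    i
  } else as.integer(x)
}

action_index <- function(x) {
  if (is.character(x)) {
    i <- match(x, ACTIONS)
    if (anyNA(i)) stop("unknown action: ", paste(x[is.na(i)], collapse = ", "))
    i
  } else as.integer(x)
}
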