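# Simulation protocols: schedule runner, accuracy metrics, precision
# sweep, childhood/adulthood concept acquisition, skewed early
# experience, and attention-bias experiments.

#' Run a schedule of trials, optionally with between-trial learning
#'
#' Executes one trial per entry of `schedule`, applying likelihood and
#' prior-concentration updates after each trial when a learning
#' configuration is supplied. Randomness is drawn from the current RNG
#' stream; callers seed it (all exported protocols take a `seed`).
#'
#' @param model The agent (`emo_model`).
#' @param process The world (`emo_process`).
#' @param schedule Character vector of true-emotion labels.
#' @param learn A [learning_config()] or `NULL` for no learning.
#' @param mode Action-selection mode (`"sample"` or `"argmax"`).
#' @param snapshot_at Trial indices at which to store a copy of the
#'   normalized likelihood blocks and prior.
#' @param track_evidence Record per-trial expected evidence for each
#'   concept under the scheduled emotion's outcome distribution?
#' @return An object of class `emo_experiment`.
#' @export
run_schedule <- function(model, process, schedule, learn = NULL,
                         mode = "sample", snapshot_at = integer(0),
                         track_evidence = FALSE) {
  n <- length(schedule)
  true_emotion <- character(n); report <- character(n); correct <- logical(n)
  n_attended <- integer(n)
  snapshots <- list()
  evidence <- if (track_evidence)
    matrix(NA_real_, n, N_EMOTION, dimnames = list(NULL, EMOTIONS)) else NULL

  for (i in seq_len(n)) {
    if (track_evidence)
      evidence[i, ] <- expected_evidence(model, process, schedule[i], log = TRUE)
    tr <- run_trial(model, process, schedule[i], mode = mode)
    true_emotion[i] <- tr$true_emotion
    report[i] <- ifelse(is.na(tr$report), "none", tr$report)
    correct[i] <- tr$correct
    n_attended[i] <- sum(tr$attention %in% ATTEND_IDX)
    if (!is.null(learn)) {
      if (learn$learn_a && !is.null(model$a))
        model <- update_A_counts(model, tr, learn)
      if (learn$learn_d && !is.null(model$d))
        model <- update_D_counts(model, tr, learn)
    }
    if (i %in% snapshot_at)
      snapshots[[as.character(i)]] <- list(
        A = lapply(CONTENT_MODALITIES, function(m)
          model$A[[m]][2:3, , attend_state_of(m)]),
        D = model$D$emotion)
  }
  structure(list(
    trials = data.frame(trial = seq_len(n), true_emotion = true_emotion,
                        report = report, correct = correct,
                        n_attended = n_attended,
                        stringsAsFactors = FALSE),
    schedule = schedule,
    model = model,
    snapshots = snapshots,
    evidence = evidence
  ), class = "emo_experiment")
}

#' @export
print.emo_experiment <- function(x, ...) {
  n <- nrow(x$trials)
  cat("<emo_experiment>", n, "trials, overall accuracy",
      sprintf("%.1f%%", 100 * mean(x$trials$correct)), "\n")
  invisible(x)
}

#' Binned accuracy curves
#'
#' `accuracy_bins()` returns percent-correct in consecutive bins of
#' `bin` trials; `accuracy_per_emotion_bins()` bins each emotion's own
#' occurrences (default 5 per bin). `accuracy_last()` is the percent
#' correct over the final `n` trials, optionally restricted to one
#' emotion's occurrences.
#'
#' @param result An `emo_experiment` (or its `trials` data frame).
#' @param bin Bin width in trials (or per-emotion occurrences).
#' @param n Number of trailing trials/occurrences.
#' @param emotion Optional emotion label filter.
#' @return Numeric vector (or list of vectors) of accuracies in percent.
#' @export
accuracy_bins <- function(result, bin = 10) {
  tr <- if (inherits(result, "emo_experiment")) result$trials else result
  if (nrow(tr) == 0L) return(numeric(0))
  g <- ceiling(seq_len(nrow(tr)) / bin)
  as.numeric(tapply(tr$correct, g, function(z) 100 * mean(z)))
}

#' @rdname accuracy_bins
#' @export
accuracy_per_emotion_bins <- function(result, bin = 5) {
  tr <- if (inherits(result, "emo_experiment")) result$trials else result
  out <- lapply(EMOTIONS, function(e) {
    z <- tr$correct[tr$true_emotion == e]
    if (!length(z)) return(numeric(0))
    g <- ceiling(seq_along(z) / bin)
    as.numeric(tapply(z, g, function(w) 100 * mean(w)))
  })
  names(out) <- EMOTIONS
  out
}

#' @rdname accuracy_bins
#' @export
accuracy_last <- function(result, n = 10, emotion = NULL) {
  tr <- if (inherits(result, "emo_experiment")) result$trials else result
  if (!is.null(emotion)) tr <- tr[tr$true_emotion == emotion, , drop = FALSE]
  if (nrow(tr) == 0L) return(NA_real_)
  z <- utils::tail(tr$correct, n)
  100 * mean(z)
}

#' Precision sweep: inference accuracy relative to an infinite-precision agent
#'
#' For each pair of temperatures, runs `n_trials` interleaved trials in
#' which the agent's likelihood precision is `a_temp` and its emotional
#' stability precision is `b_temp`; the world samples outcomes at the
#' same `a_temp`, and a reference agent with infinite precision is run
#' on the identical per-trial outcome realizations. The reported score
#' is the percent agreement between the two agents' reports.
#'
#' @param a_temps,b_temps Numeric vectors of temperatures.
#' @param n_trials Trials per grid cell.
#' @param seed Integer seed.
#' @param mode Action-selection mode.
#' @return Matrix of percent agreement, rows = `a_temps`, cols =
#'   `b_temps`.
#' @export
run_precision_sweep <- function(a_temps = c(0, 0.5, 1, 2, Inf),
                                b_temps = c(0, 0.5, 1, 2, Inf),
                                n_trials = 30, seed = 1, mode = "argmax") {
  grid <- matrix(NA_real_, length(a_temps), length(b_temps),
                 dimnames = list(paste0("a=", a_temps), paste0("b=", b_temps)))
  ref_model <- build_emotion_model(precision_settings(Inf, Inf))
  schedule <- schedule_interleaved(ceiling(n_trials / 4))[seq_len(n_trials)]
  for (i in seq_along(a_temps)) {
    for (j in seq_along(b_temps)) {
      set.seed(seed + 7919L * (i - 1L) + 104729L * (j - 1L))
      model <- build_emotion_model(precision_settings(a_temps[i], b_temps[j]))
      process <- generative_process(a_temp = a_temps[i])
      agree <- logical(n_trials)
      for (k in seq_len(n_trials)) {
        oc <- sample_trial_outcomes(process, schedule[k])
        t1 <- run_trial(model, process, schedule[k], mode = mode,
                        outcomes = oc)
        t2 <- run_trial(ref_model, process, schedule[k], mode = mode,
                        outcomes = oc)
        agree[k] <- identical(t1$report, t2$report)
      }
      grid[i, j] <- 100 * mean(agree)
    }
  }
  grid
}

# Shared setup for learning protocols: a blank-concept agent whose
# stability beliefs carry the stated b precision, and a world at the
# stated a precision whose true state is held fixed within each trial.
blank_agent_and_world <- function(temps, a0, d0, process_instability = FALSE) {
  template <- build_emotion_model(precision_settings(a_temp = 2,
                                                     b_temp = temps[2]))
  agent <- blank_concept_model(template, a0 = a0, d0 = d0)
  world <- generative_process(a_temp = temps[1],
                              b_temp = if (process_instability) temps[2]
                                       else Inf)
  list(agent = agent, world = world)
}

#' Childhood emotion concept learning
#'
#' A blank-concept agent learns all four emotion concepts over
#' `4 * n_per_emotion` evenly interleaved trials, with Dirichlet
#' updates of the likelihood and initial prior after every trial.
#'
#' @param temps Length-2 numeric: precision temperature of the world's
#'   outcome mappings and of the emotional-stability beliefs.
#' @param n_per_emotion Learning trials per emotion (default 50).
#' @param learn A [learning_config()].
#' @param a0,d0 Initial concentrations of the blank model.
#' @param seed Integer seed.
#' @param snapshot_at Trial indices for model snapshots.
#' @return An `emo_experiment`.
#' @export
run_childhood <- function(temps = c(2, 2), n_per_emotion = 50,
                          learn = learning_config(),
                          a0 = engine_defaults()$a0,
                          d0 = engine_defaults()$d0,
                          seed = 1, snapshot_at = integer(0)) {
  set.seed(seed)
  setup <- blank_agent_and_world(temps, a0, d0)
  schedule <- schedule_interleaved(n_per_emotion)
  run_schedule(setup$agent, setup$world, schedule, learn = learn,
               snapshot_at = snapshot_at)
}

#' Adulthood learning of a new emotion concept
#'
#' The agent first learns three of the four concepts from a blank start
#' (`n_pretrain` trials, held-out emotion excluded), then faces a main
#' phase containing all four. Variants: `"standard"` (interleaved main
#' phase), `"flood"` (a block of 100 consecutive held-out trials before
#' the interleaved phase), `"extended"` (interleaved main phase extended
#' to `n_main = 600`).
#'
#' @param held_out Emotion withheld during pretraining.
#' @param n_pretrain Pretraining trials (150, or 225 for an enriched
#'   childhood).
#' @param n_main Main-phase trials.
#' @param variant `"standard"`, `"flood"`, or `"extended"`.
#' @param flood_n Length of the flood block.
#' @inheritParams run_childhood
#' @param track_evidence Log per-trial expected evidence in the main
#'   phase?
#' @return List with `pretrain` and `main` experiments.
#' @export
run_adulthood <- function(held_out = "AFRAID", n_pretrain = 150,
                          n_main = NULL,
                          variant = c("standard", "flood", "extended"),
                          flood_n = 100,
                          temps = c(2, 2), learn = learning_config(),
                          a0 = engine_defaults()$a0,
                          d0 = engine_defaults()$d0,
                          seed = 1, track_evidence = FALSE) {
  variant <- match.arg(variant)
  held_out <- EMOTIONS[emotion_index(held_out)]
  if (is.null(n_main)) n_main <- if (variant == "extended") 600 else 200
  set.seed(seed)
  setup <- blank_agent_and_world(temps, a0, d0)
  pre_sched <- schedule_interleaved(round(n_pretrain / 3),
                                    setdiff(EMOTIONS, held_out))
  pre <- run_schedule(setup$agent, setup$world, pre_sched, learn = learn)

  main_sched <- schedule_interleaved(round(n_main / 4))
  if (variant == "flood")
    main_sched <- c(rep(held_out, flood_n), main_sched)
  main <- run_schedule(pre$model, setup$world, main_sched, learn = learn,
                       track_evidence = track_evidence,
                       snapshot_at = length(main_sched))
  list(pretrain = pre, main = main, held_out = held_out, variant = variant)
}

#' Skewed early experience ("adversity") protocol
#'
#' A blank agent's childhood is dominated by a single emotion
#' (`ratio`:1 relative to each other emotion) for `n_childhood` trials,
#' followed by a balanced interleaved phase of `n_adult` trials.
#'
#' @param dominant Dominant childhood emotion.
#' @param ratio Dominance ratio (>= 1; 1 reduces to a balanced
#'   childhood).
#' @param n_childhood,n_adult Phase lengths.
#' @inheritParams run_childhood
#' @return List with `childhood` and `adult` experiments.
#' @export
run_adversity <- function(dominant = "AFRAID", ratio = 50,
                          n_childhood = 200, n_adult = 200,
                          temps = c(2, 2), learn = learning_config(),
                          a0 = engine_defaults()$a0,
                          d0 = engine_defaults()$d0, seed = 1) {
  if (ratio < 1) stop("ratio must be >= 1")
  set.seed(seed)
  setup <- blank_agent_and_world(temps, a0, d0)
  child_sched <- schedule_skewed(dominant, ratio = ratio,
                                 n_total = n_childhood)
  child <- run_schedule(setup$agent, setup$world, child_sched, learn = learn,
                        snapshot_at = n_childhood)
  adult_sched <- schedule_interleaved(round(n_adult / 4))
  adult <- run_schedule(child$model, setup$world, adult_sched, learn = learn)
  list(childhood = child, adult = adult, dominant = dominant)
}

#' Attention-biased inference in a fully trained agent
#'
#' A trained agent (precise concepts at the given temperatures, no
#' learning) whose habit prior is biased `factor`-fold toward the named
#' attention actions is tested on `4 * n_per_emotion` interleaved
#' trials; returns percent correct per emotion.
#'
#' @param bias `"external"`, `"internal"`, `"somatic"`, or `"none"`.
#' @param n_per_emotion Test trials per emotion.
#' @param factor Habit-bias strength.
#' @inheritParams run_childhood
#' @return List with `accuracy` (named percent-correct vector) and
#'   `result` (the `emo_experiment`).
#' @export
run_bias_inference <- function(bias = "external", n_per_emotion = 10,
                               factor = 50, temps = c(2, 2), seed = 1) {
  set.seed(seed)
  model <- build_emotion_model(precision_settings(temps[1], temps[2]))
  if (!identical(bias, "none"))
    model <- set_attention_bias(model, bias, factor = factor)
  process <- generative_process(a_temp = temps[1])
  res <- run_schedule(model, process, schedule_interleaved(n_per_emotion))
  acc <- vapply(EMOTIONS, function(e)
    accuracy_last(res, n = n_per_emotion, emotion = e), numeric(1))
  list(accuracy = acc, result = res, bias = bias)
}

#' Attention-biased concept learning from a blank start
#'
#' Childhood learning protocol with a habit prior biased toward the
#' named attention actions.
#'
#' @inheritParams run_bias_inference
#' @inheritParams run_childhood
#' @return An `emo_experiment`.
#' @export
run_bias_learning <- function(bias = "external", n_per_emotion = 50,
                              factor = 50, temps = c(2, 2),
                              learn = learning_config(),
                              a0 = engine_defaults()$a0,
                              d0 = engine_defaults()$d0, seed = 1) {
  set.seed(seed)
  setup <- blank_agent_and_world(temps, a0, d0)
  agent <- setup$agent
  if (!identical(bias, "none"))
    agent <- set_attention_bias(agent, bias, factor = factor)
  run_schedule(agent, setup$world, schedule_interleaved(n_per_emotion),
               learn = learn,
               snapshot_at = 4L * n_per_emotion)
}
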