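# Configuration-driven orchestration, serialization, and logging.

#' Per-timestep trial log of an experiment
#'
#' Flattens an experiment into one row per trial (columns: trial index,
#' true emotion, report, correctness, number of attentional shifts).
#' For a single `emo_trial`, returns one row per timestep with the
#' attention state, action, per-modality outcome labels, MAP emotion
#' and the posterior over emotions.
#'
#' @param x An `emo_experiment` or `emo_trial`.
#' @return A data frame.
#' @export
trial_log <- function(x) {
  if (inherits(x, "emo_experiment")) return(x$trials)
  stopifnot(inherits(x, "emo_trial"))
  out <- data.frame(
    t = seq_len(N_TIMESTEP),
    true_emotion = x$true_emotion,
    attention_state = ATTENTION_STATES[x$attention],
    action = c(ifelse(is.na(x$actions), "none", ACTIONS[x$actions]), "none"),
    stringsAsFactors = FALSE
  )
  for (m in MODALITIES)
    out[[paste0("obs_", m)]] <- MODALITY_LEVELS[[m]][x$observations[m, ]]
  out$map_emotion <- EMOTIONS[apply(x$online_posteriors, 2L, which.max)]
  for (e in EMOTIONS)
    out[[paste0("p_", e)]] <- round(x$online_posteriors[e, ], 6)
  out
}

#' Summary of an experiment as a serializable list
#'
#' Collects overall and per-emotion binned accuracy curves, per-emotion
#' accuracy, and the run configuration echo into a stable, versioned
#' structure suitable for `jsonlite::write_json()`.
#'
#' @param result An `emo_experiment`.
#' @param bin,emotion_bin Bin widths for the overall and per-emotion
#'   curves.
#' @param config Optional configuration list echoed verbatim.
#' @return A named list.
#' @export
experiment_summary <- function(result, bin = 10, emotion_bin = 5,
                               config = NULL) {
  stopifnot(inherits(result, "emo_experiment"))
  tr <- result$trials
  list(
    schema_version = "1.0",
    n_trials = nrow(tr),
    overall_accuracy = 100 * mean(tr$correct),
    accuracy_bins = accuracy_bins(result, bin),
    accuracy_per_emotion_bins = accuracy_per_emotion_bins(result, emotion_bin),
    accuracy_per_emotion = vapply(EMOTIONS, function(e)
      accuracy_last(result, n = Inf, emotion = e), numeric(1)),
    mean_attended = mean(tr$n_attended),
    config = config
  )
}

#' Serialize a generative model to labeled JSON
#'
#' Writes the likelihood arrays, transitions, preferences, priors,
#' habit prior, and any concentration parameters as labeled nested
#' lists; `model_from_json()` restores the model.
#'
#' @param model An `emo_model`.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "emo_model"))
  payload <- list(
    schema_version = "1.0",
    labels = list(emotions = EMOTIONS, attention = ATTENTION_STATES,
                  actions = ACTIONS, modalities = MODALITY_LEVELS),
    A = model$A, B = model$B, C = model$C, D = model$D, E = model$E,
    a = model$a, d = model$d,
    precisions = unclass(model$precisions),
    control = model$control
  )
  if (is.null(path))
    return(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @param json A path to, or string of, JSON written by
#'   [model_to_json()].
#' @export
model_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  pr <- do.call(precision_settings, raw$precisions)
  model <- build_emotion_model(pr)
  restore_arr <- function(tmpl, x) {
    arr <- array(unlist(x), dim = dim(tmpl), dimnames = dimnames(tmpl))
    arr
  }
  for (m in MODALITIES) model$A[[m]] <- restore_arr(model$A[[m]], raw$A[[m]])
  model$B$emotion <- restore_arr(model$B$emotion, raw$B$emotion)
  model$B$attention <- restore_arr(model$B$attention, raw$B$attention)
  for (m in MODALITIES) model$C[[m]] <- restore_arr(model$C[[m]], raw$C[[m]])
  model$D$emotion[] <- raw$D$emotion
  model$D$attention[] <- raw$D$attention
  model$E[] <- raw$E
  if (length(raw$a))
    model$a <- lapply(stats::setNames(CONTENT_MODALITIES, CONTENT_MODALITIES),
                      function(m) {
      tmpl <- base_content_pattern()[[m]]
      matrix(unlist(raw$a[[m]]), 2L, N_EMOTION, dimnames = dimnames(tmpl))
    })
  if (length(raw$d)) model$d <- stats::setNames(unlist(raw$d), EMOTIONS)
  model$control <- raw$control
  validate_model(model)
  model
}

# Default run configuration: the standard study conditions (moderately
# precise world at temperature 2, 6 timesteps, 50 trials per emotion,
# bias factor 50, 10/5-trial accuracy bins).
default_config <- function() {
  list(
    experiment = "childhood",
    temps = c(2, 2),
    n_per_emotion = 50,
    eta = engine_defaults()$eta,
    a0 = engine_defaults()$a0,
    d0 = engine_defaults()$d0,
    held_out = "AFRAID",
    variant = "standard",
    n_pretrain = 150,
    dominant = "AFRAID",
    ratio = 50,
    bias = "external",
    bias_factor = 50,
    a_temps = c(0, 0.5, 1, 2, Inf),
    b_temps = c(0, 0.5, 1, 2, Inf),
    n_sweep_trials = 30,
    seed = 1,
    out_dir = NULL,
    plot = FALSE
  )
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  experiments <- c("childhood", "adulthood", "adversity", "bias-inference",
                   "bias-learning", "sweep", "simulate-trial")
  if (!cfg$experiment %in% experiments)
    stop("unknown experiment: ", cfg$experiment)
  if (any(cfg$temps < 0)) stop("temps must be non-negative")
  if (cfg$ratio < 1) stop("ratio must be >= 1")
  if (cfg$a0 <= 0 || cfg$eta <= 0) stop("a0 and eta must be positive")
  if (!is.numeric(cfg$seed)) stop("seed must be numeric")
  cfg
}

#' Run an experiment from a configuration
#'
#' Dispatches to the named protocol with the configured parameters and,
#' if an output directory is set, writes `trials.csv` (one row per
#' trial), `summary.json` (binned accuracies and the configuration
#' echo), and optionally PNG learning-curve plots. All defaults encode
#' the standard study conditions so every protocol runs with only its
#' name.
#'
#' @param config A named list (merged over the defaults), or a path to
#'   a YAML/JSON file of the same shape.
#' @return The protocol's result object, invisibly, with the summary
#'   attached as attribute `"summary"`.
#' @export
run_from_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  lc <- learning_config(eta = cfg$eta)
  res <- switch(cfg$experiment,
    "childhood" = run_childhood(temps = cfg$temps,
                                n_per_emotion = cfg$n_per_emotion,
                                learn = lc, a0 = cfg$a0, d0 = cfg$d0,
                                seed = cfg$seed),
    "adulthood" = run_adulthood(held_out = cfg$held_out,
                                n_pretrain = cfg$n_pretrain,
                                variant = cfg$variant, temps = cfg$temps,
                                learn = lc, a0 = cfg$a0, d0 = cfg$d0,
                                seed = cfg$seed),
    "adversity" = run_adversity(dominant = cfg$dominant, ratio = cfg$ratio,
                                temps = cfg$temps, learn = lc,
                                a0 = cfg$a0, d0 = cfg$d0, seed = cfg$seed),
    "bias-inference" = run_bias_inference(bias = cfg$bias,
                                          factor = cfg$bias_factor,
                                          temps = cfg$temps,
                                          seed = cfg$seed),
    "bias-learning" = run_bias_learning(bias = cfg$bias,
                                        n_per_emotion = cfg$n_per_emotion,
                                        factor = cfg$bias_factor,
                                        temps = cfg$temps, learn = lc,
                                        a0 = cfg$a0, d0 = cfg$d0,
                                        seed = cfg$seed),
    "sweep" = run_precision_sweep(a_temps = cfg$a_temps,
                                  b_temps = cfg$b_temps,
                                  n_trials = cfg$n_sweep_trials,
                                  seed = cfg$seed),
    "simulate-trial" = {
      set.seed(cfg$seed)
      model <- build_emotion_model(precision_settings(cfg$temps[1],
                                                      cfg$temps[2]))
      run_trial(model, generative_process(cfg$temps[1]), cfg$held_out,
                record_iterates = TRUE)
    })

  main <- pick_main_experiment(res)
  summary <- if (inherits(main, "emo_experiment"))
    experiment_summary(main, config = cfg)
  else list(schema_version = "1.0", config = cfg,
            result = serialize_other(res))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    log_df <- if (inherits(main, "emo_experiment")) trial_log(main)
              else if (inherits(res, "emo_trial")) trial_log(res)
              else NULL
    if (!is.null(log_df))
      utils::write.csv(log_df, file.path(cfg$out_dir, "trials.csv"),
                       row.names = FALSE)
    if (isTRUE(cfg$plot) && inherits(main, "emo_experiment")) {
      grDevices::png(file.path(cfg$out_dir, "learning_curve.png"),
                     width = 900, height = 600)
      plot_learning_curve(main)
      grDevices::dev.off()
    }
  }
  attr(res, "summary") <- summary
  invisible(res)
}

pick_main_experiment <- function(res) {
  if (inherits(res, "emo_experiment")) return(res)
  if (is.list(res)) {
    if (!is.null(res$main)) return(res$main)
    if (!is.null(res$adult)) return(res$adult)
    if (!is.null(res$result)) return(res$result)
  }
  res
}

serialize_other <- function(res) {
  if (inherits(res, "emo_trial"))
    return(list(kind = "trial", true_emotion = res$true_emotion,
                report = res$report, correct = res$correct,
                actions = ACTIONS[stats::na.omit(res$actions)]))
  if (is.matrix(res))
    return(list(kind = "grid", rows = rownames(res), cols = colnames(res),
                values = unname(apply(res, 1L, as.numeric, simplify = FALSE))))
  list(kind = class(res)[1])
}

#' Plot a binned learning curve
#'
#' Overall accuracy in 10-trial bins plus per-emotion accuracy in
#' 5-occurrence bins.
#'
#' @param result An `emo_experiment`.
#' @param main Plot title.
#' @export
plot_learning_curve <- function(result, main = "Emotion concept learning") {
  overall <- accuracy_bins(result, 10)
  per <- accuracy_per_emotion_bins(result, 5)
  graphics::par(mfrow = c(1, 2))
  plot(seq_along(overall) * 10, overall, type = "b", pch = 16,
       ylim = c(0, 100), xlab = "trial", ylab = "% correct (10-trial bins)",
       main = main)
  graphics::abline(h = 25, lty = 3)
  n_bins <- max(vapply(per, length, integer(1)))
  plot(NULL, xlim = c(1, max(n_bins, 2)), ylim = c(0, 100),
       xlab = "5-occurrence bin", ylab = "% correct", main = "per emotion")
  for (i in seq_along(per))
    graphics::lines(seq_along(per[[i]]), per[[i]], col = i, type = "b",
                    pch = 16)
  graphics::legend("bottomright", legend = names(per), col = seq_along(per),
                   lty = 1, pch = 16, bty = "n")
  graphics::par(mfrow = c(1, 1))
  invisible(result)
}

#' Plot simulated neural responses for a trial
#'
#' Raster-style image of per-unit firing (posterior expectations over
#' the fine within-trial grid) and the corresponding local field
#' potential traces.
#'
#' @param traces An `emo_neural` from [neural_traces()].
#' @export
plot_neural_traces <- function(traces) {
  stopifnot(inherits(traces, "emo_neural"))
  firing <- traces$firing
  n_grid <- dim(firing)[3]
  flat <- matrix(NA_real_, N_EMOTION * N_TIMESTEP, n_grid)
  for (tau in seq_len(N_TIMESTEP))
    flat[(tau - 1L) * N_EMOTION + seq_len(N_EMOTION), ] <- firing[, tau, ]
  graphics::par(mfrow = c(2, 1))
  graphics::image(t(1 - flat), axes = FALSE, col = grDevices::gray.colors(64),
                  main = "firing rates (units = emotion x timestep)")
  graphics::axis(1, at = seq(0, 1, length.out = N_TIMESTEP),
                 labels = paste0("t", seq_len(N_TIMESTEP)))
  lfp <- apply(traces$lfp, c(1, 3), sum)
  graphics::matplot(t(lfp), type = "l", lty = 1, xlab = "iteration grid",
                    ylab = "rate of change", main = "local field potentials")
  graphics::legend("topright", legend = EMOTIONS, col = 1:4, lty = 1,
                   bty = "n")
  graphics::par(mfrow = c(1, 1))
  invisible(traces)
}
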