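# End-to-end experiment pipeline: window, reduce (KPCA / PCA / time-domain
# features / raw), train the DRSN, evaluate, and rank muscle contributions.

#' Chronological train/validation/test window split
#'
#' Splits windows by their start time into contiguous blocks, discarding
#' windows that straddle a boundary and enforcing a gap of one window
#' length after each boundary so no raw sample is shared between sets.
#'
#' @param windows A `semg_windows`.
#' @param fractions Length-3 positive vector of train/validation/test time
#'   fractions (normalized to sum to 1).
#' @return List of integer window-id vectors `train`, `val`, `test`.
#' @export
split_windows <- function(windows, fractions = c(0.6, 0.2, 0.2)) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  fractions <- fractions / sum(fractions)
  t_start <- unique_window_field(windows, "t_start")
  win_s <- windows$window_len / windows$fs
  t_end <- t_start + win_s
  total <- max(t_end)
  b1 <- total * fractions[1]
  b2 <- total * (fractions[1] + fractions[2])
  ids <- seq_len(windows$n_windows)
  list(
    train = ids[t_end <= b1],
    val = ids[t_start >= b1 + win_s & t_end <= b2],
    test = ids[t_start >= b2 + win_s]
  )
}

subset_window_rows <- function(windows, window_ids) {
  keep <- windows$window_id %in% window_ids
  out <- windows
  out$x <- windows$x[keep, , drop = FALSE]
  out$y <- windows$y[keep]
  out$window_id <- windows$window_id[keep]
  out$channel <- windows$channel[keep]
  out$t_start <- windows$t_start[keep]
  out$n_windows <- length(window_ids)
  out
}

#' Fit the full sEMG-to-force pipeline on one recording
#'
#' Windows the recording, fits the chosen per-window representation on the
#' training block (Gaussian-kernel KPCA or PCA per channel with components
#' selected by cumulative contribution rate, classical time-domain
#' features, or raw samples), trains the DRSN on it, and evaluates on the
#' held-out chronological test block.
#'
#' @param recording A `semg_recording`.
#' @param reduction One of `"kpca"`, `"pca"`, `"features"`, `"none"`.
#' @param window_len,stride Window length and hop in samples.
#' @param xi_threshold Cumulative contribution cutoff for KPCA/PCA
#'   component selection.
#' @param gamma Gaussian-kernel width for KPCA; `NULL` for the median
#'   heuristic.
#' @param n_components Optional fixed component count overriding the
#'   cumulative-contribution choice.
#' @param features A [feature_spec()] for `reduction = "features"`.
#' @param drsn A [drsn_config()].
#' @param channels Optional channel subset (names or indices).
#' @param fractions Chronological split fractions, see [split_windows()].
#' @return A `force_pipeline` with the fitted reducers, the trained
#'   `drsn_model`, test metrics, and per-window test predictions.
#' @export
fit_force_pipeline <- function(recording,
                               reduction = c("kpca", "pca", "features", "none"),
                               window_len = 200, stride = 100,
                               xi_threshold = 0.85, gamma = NULL,
                               n_components = NULL,
                               features = feature_spec(),
                               drsn = drsn_config(),
                               channels = NULL,
                               fractions = c(0.6, 0.2, 0.2)) {
  reduction <- match.arg(reduction)
  ws <- build_windows(recording, window_len, stride,
                      channel_mode = "per_channel", channels = channels)
  split <- split_windows(ws, fractions)
  if (length(split$train) == 0 || length(split$test) == 0) {
    abort("recording too short for the requested split.")
  }

  reducers <- NULL
  if (reduction %in% c("kpca", "pca")) {
    train_rows <- lapply(ws$labels, function(ch) {
      cw <- channel_windows(ws, ch)
      cw$x[cw$window_id %in% split$train, , drop = FALSE]
    })
    reducers <- lapply(train_rows, function(xtr) {
      if (reduction == "kpca") {
        kpca_fit(xtr, gamma = gamma, xi_threshold = xi_threshold)
      } else {
        ev <- eigen(stats::cov(xtr), symmetric = TRUE, only.values = TRUE)$values
        k <- which(cumsum(pmax(ev, 0)) / sum(pmax(ev, 0)) >=
                     xi_threshold - 1e-12)[1]
        pca_fit(xtr, k)
      }
    })
    names(reducers) <- ws$labels
  }

  channel_components <- NULL
  if (!is.null(reducers)) {
    channel_components <- vapply(reducers, function(r) {
      p <- if (reduction == "kpca") r$P else r$k
      as.integer(if (is.null(n_components)) p else min(n_components, p))
    }, integer(1))
  }

  pipe <- structure(list(
    reduction = reduction, window_len = window_len, stride = stride,
    labels = ws$labels, fs = ws$fs, reducers = reducers,
    n_components = n_components, channel_components = channel_components,
    features = features, fractions = fractions, version = "1"
  ), class = "force_pipeline")

  tf <- transform_windows(pipe, ws)
  pipe$n_components <- dim(tf$x)[3]
  y <- windows_targets(ws)
  pick <- function(ids) list(x = tf$x[ids, , , drop = FALSE], y = y[ids])
  tr <- pick(split$train)
  vl <- pick(split$val)
  te <- pick(split$test)

  model <- train_drsn(drsn, tr$x, val = if (length(vl$y)) vl$x,
                      train_y = tr$y, val_y = if (length(vl$y)) vl$y)
  pred_test <- predict_force(model, te$x)

  pipe$drsn <- model
  pipe$split <- split
  pipe$metrics <- metrics_suite(te$y, pred_test)
  pipe$test_predictions <- tibble(
    window_id = split$test,
    t_start = unique_window_field(ws, "t_start")[split$test],
    force_obs = te$y, force_pred = pred_test
  )
  pipe
}

# Map a windowed dataset through the pipeline's representation; returns the
# [B, C', L'] input array the DRSN consumes.
transform_windows <- function(pipe, ws) {
  if (pipe$reduction == "none") {
    return(list(x = windows_array(ws)))
  }
  if (pipe$reduction == "features") {
    fw <- featurize(ws, pipe$features)
    return(list(x = windows_array(fw)))
  }
  scores <- lapply(pipe$labels, function(ch) {
    cw <- channel_windows(ws, ch)
    red <- pipe$reducers[[ch]]
    p <- pipe$channel_components[[ch]]
    if (pipe$reduction == "kpca") {
      kpca_project(red, cw$x, n_components = p)
    } else {
      pca_project(red, cw$x)[, seq_len(p), drop = FALSE]
    }
  })
  p_max <- max(vapply(scores, ncol, integer(1)))
  n_win <- nrow(scores[[1]])
  x <- array(0, c(n_win, length(pipe$labels), p_max))
  for (c in seq_along(scores)) {
    x[, c, seq_len(ncol(scores[[c]]))] <- scores[[c]]
  }
  list(x = x)
}

#' Predict force for a (new) recording with a fitted pipeline
#'
#' @param object A `force_pipeline`.
#' @param recording A `semg_recording` with the pipeline's channels.
#' @param ... Unused.
#' @return Tibble with `window_id`, `t_start`, `force_obs`, `force_pred`.
#' @export
predict.force_pipeline <- function(object, recording, ...) {
  ws <- build_windows(recording, object$window_len, object$stride,
                      channel_mode = "per_channel", channels = object$labels)
  tf <- transform_windows(object, ws)
  tibble(
    window_id = seq_len(ws$n_windows),
    t_start = unique_window_field(ws, "t_start"),
    force_obs = windows_targets(ws),
    force_pred = predict_force(object$drsn, tf$x)
  )
}

#' @export
print.force_pipeline <- function(x, ...) {
  cat(sprintf("<force_pipeline> reduction %s, channels %s\n",
              x$reduction, paste(x$labels, collapse = ",")))
  print(x$metrics)
  invisible(x)
}

#' @export
glance.force_pipeline <- function(x, ...) x$metrics

#' Muscle-level Mean Impact Values for a fitted pipeline
#'
#' Perturbs each raw muscle channel of the recording by the perturbation
#' fraction before windowing and reduction, so impact values attach to
#' muscles rather than to abstract components, and evaluates on held-out
#' windows by default to reflect generalizable sensitivity.
#'
#' With correlated muscle channels the sensitivity of a single trained
#' network is a high-variance estimator (any one fit may place its weight
#' anywhere in the collinear subspace); [miv_muscles_ensemble()] averages
#' the impact values of several independently initialized fits, which is
#' the package's recommended protocol for contribution ranking.
#'
#' @param pipe A [fit_force_pipeline()] result.
#' @param recording The recording to perturb (typically the one the
#'   pipeline was fitted on).
#' @param perturbation Perturbation fraction (default 0.10).
#' @param cutoff Cumulative contribution cutoff for variable selection.
#' @param set Which windows to evaluate: `"test"`, `"train"`, or `"all"`.
#' @return A `miv_report` over muscle channels.
#' @export
miv_muscles <- function(pipe, recording, perturbation = 0.1, cutoff = 0.9,
                        set = c("test", "train", "all")) {
  set <- match.arg(set)
  ids <- switch(set, test = pipe$split$test, train = pipe$split$train,
                all = NULL)
  predict_set <- function(rec) {
    pred <- predict(pipe, rec)
    if (is.null(ids)) pred$force_pred else pred$force_pred[ids]
  }
  labels <- pipe$labels
  iv <- NULL
  for (c in seq_along(labels)) {
    up <- predict_set(scale_channels(recording, labels[c], 1 + perturbation))
    dn <- predict_set(scale_channels(recording, labels[c], 1 - perturbation))
    if (is.null(iv)) iv <- matrix(0, length(up), length(labels),
                                  dimnames = list(NULL, labels))
    iv[, c] <- up - dn
  }
  new_miv_report(iv, perturbation, cutoff, labels)
}

#' Ensemble-averaged muscle Mean Impact Values
#'
#' Re-trains the pipeline's network `n_models` times with distinct seeds
#' and averages the per-sample impact values across fits before ranking.
#'
#' @inheritParams miv_muscles
#' @param fit_fn Function of a seed returning a fitted `force_pipeline`
#'   for the recording.
#' @param seeds Integer vector of training seeds, one per ensemble member.
#' @return A `miv_report` over muscle channels (averaged ensemble).
#' @export
miv_muscles_ensemble <- function(fit_fn, recording, seeds,
                                 perturbation = 0.1, cutoff = 0.9,
                                 set = c("test", "train", "all")) {
  set <- match.arg(set)
  ivs <- lapply(seeds, function(s) {
    pipe <- fit_fn(s)
    miv_muscles(pipe, recording, perturbation = perturbation,
                cutoff = cutoff, set = set)$iv_per_sample
  })
  new_miv_report(Reduce(`+`, ivs) / length(ivs), perturbation, cutoff,
                 colnames(ivs[[1]]))
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs; nested configs keep their
#' own defaults. The global seed drives the generator, noise injection, and
#' network training.
#'
#' @param synth A [synth_config()] used when `input_file` is `NULL`.
#' @param input_file Optional recording CSV (see [read_recording()]).
#' @param window_len,stride Windowing in samples.
#' @param reduction `"kpca"`, `"pca"`, `"features"`, or `"none"`.
#' @param xi_threshold,gamma,n_components Reduction settings, see
#'   [fit_force_pipeline()].
#' @param features A [feature_spec()].
#' @param drsn A [drsn_config()].
#' @param miv_perturbation,miv_cutoff MIV settings.
#' @param miv_ensemble Number of independently seeded network fits whose
#'   impact values are averaged for the muscle contribution ranking (see
#'   [miv_muscles_ensemble()]); 1 uses the single fitted pipeline.
#' @param noise_snr_db SNR of extra white noise injected into every raw
#'   channel before processing (`Inf` = none), emulating degraded
#'   acquisition.
#' @param channels Optional channel subset.
#' @param seed Global integer seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(), input_file = NULL,
                              window_len = 200, stride = 100,
                              reduction = "kpca", xi_threshold = 0.85,
                              gamma = NULL, n_components = NULL,
                              features = feature_spec(),
                              drsn = drsn_config(),
                              miv_perturbation = 0.1, miv_cutoff = 0.9,
                              miv_ensemble = 5, noise_snr_db = Inf,
                              channels = NULL, seed = 1) {
  structure(as.list(environment()), class = "experiment_config")
}

load_experiment_recording <- function(config) {
  rec <- if (!is.null(config$input_file)) {
    read_recording(config$input_file)
  } else {
    synth <- config$synth
    synth$seed <- config$seed
    generate_recording(validate_synth_config(synth))
  }
  if (is.finite(config$noise_snr_db)) {
    for (c in seq_along(rec_labels(rec))) {
      ch <- rec_labels(rec)[c]
      rec[[ch]] <- add_noise_snr(rec[[ch]], config$noise_snr_db,
                                 seed = config$seed + 7919L * c)
    }
  }
  rec
}

#' Run a full force-prediction experiment
#'
#' Generates (or loads) the recording, optionally injects noise, fits the
#' pipeline, computes test metrics and the muscle MIV report, and — when
#' `out_dir` is given — writes a deterministic flat results file, the MIV
#' table, the model checkpoint, and the test predictions.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory.
#' @return List with `pipeline`, `metrics`, `miv`, `recording`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  rec <- load_experiment_recording(config)
  drsn <- config$drsn
  drsn$seed <- config$seed
  pipe <- fit_force_pipeline(
    rec, reduction = config$reduction,
    window_len = config$window_len, stride = config$stride,
    xi_threshold = config$xi_threshold, gamma = config$gamma,
    n_components = config$n_components, features = config$features,
    drsn = drsn, channels = config$channels
  )
  miv <- experiment_miv(config, rec, pipe)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    m <- pipe$metrics
    kv <- list(
      seed = config$seed, reduction = config$reduction,
      n_channels = length(pipe$labels),
      n_components = pipe$n_components,
      test_mse = m$mse, test_rms = m$rms, test_mave = m$mave,
      test_rho = m$rho,
      miv_top_muscle = pipe$labels[miv$ranking[1]],
      miv_selected = paste(pipe$labels[miv$selected], collapse = "+")
    )
    write_results_kv(kv, file.path(out_dir, "results.txt"))
    write_miv_report(miv, file.path(out_dir, "miv.csv"))
    drsn_save(pipe$drsn, file.path(out_dir, "model.rds"))
    readr::write_csv(pipe$test_predictions,
                     file.path(out_dir, "test_predictions.csv"))
  }
  list(pipeline = pipe, metrics = pipe$metrics, miv = miv, recording = rec)
}

# Ensemble (or single-fit) muscle MIV under an experiment config.
experiment_miv <- function(config, rec, pipe, channels = NULL) {
  n_ens <- config$miv_ensemble %||% 1
  if (n_ens <= 1) {
    return(miv_muscles(pipe, rec, perturbation = config$miv_perturbation,
                       cutoff = config$miv_cutoff))
  }
  fit_fn <- function(s) {
    drsn <- config$drsn
    drsn$seed <- s
    fit_force_pipeline(
      rec, reduction = config$reduction,
      window_len = config$window_len, stride = config$stride,
      xi_threshold = config$xi_threshold, gamma = config$gamma,
      n_components = config$n_components, features = config$features,
      drsn = drsn, channels = channels %||% config$channels
    )
  }
  miv_muscles_ensemble(fit_fn, rec, seeds = config$seed + seq_len(n_ens) - 1L,
                       perturbation = config$miv_perturbation,
                       cutoff = config$miv_cutoff)
}

#' Single-muscle versus combined-muscle comparison across tasks
#'
#' For each contraction task, trains one pipeline per single channel and
#' one on all channels, collects the held-out test MSE of each, and builds
#' the per-task muscle contribution heat map from the combined models' MIV.
#'
#' @param config An [experiment_config()]; its `synth` entry is the base
#'   config for the four-task suite.
#' @param out_dir Optional output directory for the MSE table and heat map
#'   CSVs.
#' @return List with `table` (task x input-set test metrics) and `heatmap`
#'   (task x muscle normalized contributions).
#' @export
compare_muscles <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  base <- config$synth
  base$seed <- config$seed
  suite <- generate_task_suite(validate_synth_config(base))
  labels <- base$channel_labels
  drsn <- config$drsn
  drsn$seed <- config$seed

  rows <- list()
  reports <- list()
  for (task in names(suite)) {
    rec <- suite[[task]]
    input_sets <- c(as.list(labels), list(labels))
    set_names <- c(labels, "combined")
    for (i in seq_along(input_sets)) {
      pipe <- fit_force_pipeline(
        rec, reduction = config$reduction,
        window_len = config$window_len, stride = config$stride,
        xi_threshold = config$xi_threshold, gamma = config$gamma,
        features = config$features, drsn = drsn,
        channels = input_sets[[i]]
      )
      rows[[length(rows) + 1L]] <- bind_cols(
        tibble(task = task, input_set = set_names[i]), pipe$metrics
      )
      if (set_names[i] == "combined") {
        reports[[task]] <- experiment_miv(config, rec, pipe,
                                          channels = labels)
      }
    }
  }
  table <- bind_rows(rows)
  heatmap <- muscle_contribution_table(reports)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(table, file.path(out_dir, "muscle_mse_table.csv"))
    readr::write_csv(heatmap, file.path(out_dir, "muscle_contribution_heatmap.csv"))
  }
  list(table = table, heatmap = heatmap)
}
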