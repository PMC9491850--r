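# Mean Impact Value: perturb each input variable by +/- a fixed fraction,
# run both perturbed sets through the trained model, and average the
# per-sample output differences. |MIV| ranks variable importance; a
# cumulative cutoff over normalized |MIV| selects variables.

#' Compute Mean Impact Values for each input variable
#'
#' For each variable `j`, scales column `j` of the dataset by `(1 + p)` and
#' `(1 - p)`, predicts both perturbed sets, and records the per-sample
#' prediction difference (the impact value, IV). `MIV_j` is the mean IV
#' over samples.
#'
#' @param predict_fn Function mapping a samples-by-variables matrix to a
#'   prediction vector.
#' @param dataset Samples-by-variables numeric matrix (or data frame).
#' @param perturbation Perturbation fraction `p >= 0` (default 0.10).
#' @param cutoff Cumulative normalized-|MIV| cutoff used by
#'   [select_variables()] (default 0.90).
#' @param labels Optional variable names.
#' @return A `miv_report`: per-sample IV matrix, `miv`, `abs_normalized`
#'   (`|miv| / sum|miv|`), `ranking` (by `|miv|` descending), `selected`
#'   (prefix of the ranking reaching the cutoff), and a `degenerate` flag
#'   set when every MIV is zero.
#' @export
compute_miv <- function(predict_fn, dataset, perturbation = 0.1,
                        cutoff = 0.9, labels = colnames(dataset)) {
  x <- as.matrix(dataset)
  if (perturbation < 0) abort("perturbation must be >= 0.")
  d <- ncol(x)
  if (is.null(labels)) labels <- paste0("x", seq_len(d))
  iv <- matrix(0, nrow(x), d, dimnames = list(NULL, labels))
  for (j in seq_len(d)) {
    up <- x; up[, j] <- up[, j] * (1 + perturbation)
    dn <- x; dn[, j] <- dn[, j] * (1 - perturbation)
    iv[, j] <- predict_fn(up) - predict_fn(dn)
  }
  new_miv_report(iv, perturbation, cutoff, labels)
}

new_miv_report <- function(iv, perturbation, cutoff, labels) {
  miv <- colMeans(iv)
  total <- sum(abs(miv))
  degenerate <- total == 0
  if (degenerate) {
    warning("all Mean Impact Values are zero; the model output is insensitive to every variable")
  }
  abs_norm <- if (degenerate) rep(0, length(miv)) else abs(miv) / total
  ranking <- order(abs(miv), decreasing = TRUE)
  rep <- structure(list(
    iv_per_sample = iv, miv = miv, abs_normalized = abs_norm,
    ranking = ranking, perturbation = perturbation, cutoff = cutoff,
    labels = labels, degenerate = degenerate
  ), class = "miv_report")
  rep$selected <- select_variables(rep)
  rep
}

#' Select variables by cumulative normalized impact
#'
#' Returns the smallest prefix of the |MIV| ranking whose cumulative
#' normalized contribution reaches the report's cutoff; variables with zero
#' MIV are never selected.
#'
#' @param report A [compute_miv()] result.
#' @param cutoff Optional override of the report's cutoff.
#' @return Integer indices of the selected variables (a prefix of
#'   `report$ranking`).
#' @export
select_variables <- function(report, cutoff = report$cutoff) {
  if (report$degenerate) return(integer(0))
  contrib <- report$abs_normalized[report$ranking]
  n_pos <- sum(contrib > 0)
  k <- which(cumsum(contrib) >= cutoff - 1e-12)[1]
  if (is.na(k)) k <- n_pos
  report$ranking[seq_len(min(k, n_pos))]
}

#' @export
print.miv_report <- function(x, ...) {
  cat(sprintf("<miv_report> %d variables, perturbation %.0f%%, cutoff %.0f%%\n",
              length(x$miv), 100 * x$perturbation, 100 * x$cutoff))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.miv_report <- function(x, ...) {
  tibble(
    variable = x$labels,
    miv = unname(x$miv),
    abs_normalized = unname(x$abs_normalized),
    rank = match(seq_along(x$miv), x$ranking),
    selected = seq_along(x$miv) %in% x$selected
  ) %>% arrange(.data$rank)
}

#' Write an MIV report as delimited text
#'
#' @param report A `miv_report`.
#' @param path Output CSV path.
#' @export
write_miv_report <- function(report, path) {
  readr::write_csv(tidy(report), path)
  invisible(path)
}

#' Per-task muscle contribution matrix
#'
#' Stacks the normalized |MIV| contributions of several per-task reports
#' into a tasks-by-muscles matrix; each row sums to 1 and its argmax is the
#' task's dominant muscle.
#'
#' @param reports Named list of `miv_report`s (one per task) whose
#'   variables are muscle channels.
#' @return A tibble with a `task` column and one column per muscle.
#' @export
muscle_contribution_table <- function(reports) {
  stopifnot(length(reports) >= 1)
  rows <- imap(reports, function(rep, task) {
    bind_cols(tibble(task = task),
              as_tibble(as.list(stats::setNames(rep$abs_normalized,
                                                rep$labels))))
  })
  bind_rows(rows)
}
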