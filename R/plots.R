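# ggplot2 views of the package's result types.

#' Plot a recording's channels and force trace
#'
#' @param object A `semg_recording`.
#' @param ... Unused.
#' @return A ggplot: one facet per channel plus the force trace.
#' @export
autoplot.semg_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(as.data.frame(object)),
                              -"time", names_to = "trace",
                              values_to = "value")
  long$trace <- factor(long$trace,
                       levels = c(rec_labels(object), "force"))
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.2) +
    facet_wrap(~trace, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Scree plot of contribution rates for a KPCA or PCA model
#'
#' @param object A `kpca_model` or `pca_model`.
#' @param n_components How many leading components to show.
#' @param ... Unused.
#' @export
autoplot.kpca_model <- function(object, n_components = 10, ...) {
  df <- head(tidy(object), n_components)
  ggplot(df, aes(x = .data$component)) +
    geom_col(aes(y = .data$contribution), fill = "grey70") +
    geom_line(aes(y = .data$cumulative)) +
    geom_point(aes(y = .data$cumulative)) +
    labs(x = "component", y = "contribution rate",
         title = "Cumulative contribution rate") +
    theme_minimal()
}

#' @rdname autoplot.kpca_model
#' @export
autoplot.pca_model <- autoplot.kpca_model

#' Bar chart of normalized muscle impact values
#'
#' @param object A `miv_report`.
#' @param ... Unused.
#' @export
autoplot.miv_report <- function(object, ...) {
  df <- tidy(object)
  df$variable <- factor(df$variable, levels = df$variable[order(df$rank)])
  ggplot(df, aes(x = .data$variable, y = .data$abs_normalized,
                 fill = .data$selected)) +
    geom_col() +
    labs(x = NULL, y = "normalized |MIV|", fill = "selected") +
    theme_minimal()
}

#' Power spectral density plot
#'
#' @param object A [power_spectrum()] result.
#' @param ... Unused.
#' @export
autoplot.semg_spectrum <- function(object, ...) {
  ggplot(as_tibble(as.data.frame(object)),
         aes(x = .data$frequency, y = .data$power)) +
    geom_line(linewidth = 0.3) +
    labs(x = "frequency (Hz)", y = "power density") +
    theme_minimal()
}

#' Measured versus predicted force on the test block
#'
#' @param object A `force_pipeline`.
#' @param ... Unused.
#' @export
autoplot.force_pipeline <- function(object, ...) {
  df <- tidyr::pivot_longer(object$test_predictions,
                            c("force_obs", "force_pred"),
                            names_to = "series", values_to = "force")
  ggplot(df, aes(x = .data$t_start, y = .data$force,
                 colour = .data$series)) +
    geom_line() +
    labs(x = "time (s)", y = "force (N)", colour = NULL) +
    theme_minimal()
}

#' Heat map of per-task muscle contributions
#'
#' @param heatmap A [muscle_contribution_table()] tibble.
#' @return A ggplot tile map, tasks by muscles.
#' @export
plot_muscle_heatmap <- function(heatmap) {
  long <- tidyr::pivot_longer(heatmap, -"task", names_to = "muscle",
                              values_to = "contribution")
  ggplot(long, aes(x = .data$muscle, y = .data$task,
                   fill = .data$contribution)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "contribution") +
    theme_minimal()
}
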