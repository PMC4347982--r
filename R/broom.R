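# Tidiers and plots for fitted agents and analysis reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted spiking FERL agent
#'
#' @param x A `ferl_fit`.
#' @param ... Unused.
#' @return The per-episode learning log as a tibble.
#' @export
tidy.ferl_fit <- function(x, ...) x$log

#' One-row summary of a fitted spiking FERL agent
#'
#' Medians are taken over the final `window` episodes, where behavior has
#' stabilized.
#'
#' @param x A `ferl_fit`.
#' @param window Number of trailing episodes summarized (default 50).
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ferl_fit <- function(x, window = 50, ...) {
  tl <- utils::tail(x$log, min(window, nrow(x$log)))
  tibble::tibble(
    task = x$task, estimator = x$estimator, episodes = x$episodes,
    median_steps_to_goal = stats::median(tl$steps_to_goal, na.rm = TRUE),
    goal_rate = mean(!is.na(tl$steps_to_goal)),
    median_discounted_return = stats::median(tl$discounted_return),
    median_reward_sum = stats::median(tl$reward_sum),
    mean_F = mean(tl$mean_F))
}

#' Learning-curve plot for a fitted agent
#'
#' Steps to goal and discounted return per episode.
#'
#' @param object A `ferl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ferl_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$log[, c("episode", "steps_to_goal", "discounted_return")],
    -"episode", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$episode, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x,
                         linewidth = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "episode", y = NULL,
                  title = sprintf("%s task, %s estimator",
                                  object$task, object$estimator)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of the SNN/RBM free-energy equivalence
#'
#' @param object An `fe_equivalence` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fe_equivalence <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$neg_F_rbm, y = .data$neg_ife,
                               color = .data$action)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "equivalent RBM  -F", y = "SNN  -iFE",
                  subtitle = sprintf("r = %.4f (c = %g)", object$r_fe, object$c)) +
    ggplot2::theme_minimal()
}

#' Heatmap of learned couplings
#'
#' @param W An [rbm_weights()] object (e.g. `fit$agent$W`).
#' @param block `"w_sh"` or `"w_ah"`.
#' @return A ggplot object.
#' @export
plot_weights <- function(W, block = c("w_sh", "w_ah")) {
  block <- match.arg(block)
  m <- W[[block]]
  df <- tidyr::expand_grid(visible = seq_len(nrow(m)), hidden = seq_len(ncol(m)))
  df$weight <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hidden, y = .data$visible,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = block) +
    ggplot2::theme_minimal()
}

#' Heatmap of a firing-pattern distance matrix
#'
#' @param pd A [pattern_distance()] result.
#' @return A ggplot object.
#' @export
plot_pattern_distance <- function(pd) {
  D <- pd$distance
  df <- tidyr::expand_grid(bin_i = seq_len(nrow(D)), bin_j = seq_len(ncol(D)))
  df$distance <- as.vector(D)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_i, y = .data$bin_j,
                                   fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(subtitle = sprintf("dominant period: %d bins", pd$period)) +
    ggplot2::theme_minimal()
}

#' Raster plot of spikes
#'
#' @param raster A `spike_raster`.
#' @return A ggplot object.
#' @export
plot_raster <- function(raster) {
  m <- unclass(raster)
  idx <- which(m == 1, arr.ind = TRUE)
  df <- tibble::tibble(
    neuron = idx[, 1],
    time = attr(raster, "t0") + (idx[, 2] - 1) * attr(raster, "dt_bin"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}
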