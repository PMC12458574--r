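#' Plot a shift-aligned summary
#'
#' Group mean +/- SE of accuracy or confidence from five trials before to
#' five trials after each covert rule shift, faceted by shift type. The
#' dashed line marks the boundary between the last pre-shift trial (-1) and
#' the first trial governed by the new rule (+1).
#'
#' @param object An `rs_shift_aligned` table (see [shift_aligned_summary()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rs_shift_aligned <- function(object, ...) {
  metric <- attr(object, "metric") %||% "metric"
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$distance, y = .data$mean,
    colour = .data$group, fill = .data$group
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_wrap(~shift_type) +
    ggplot2::labs(x = "trial distance from rule shift", y = metric,
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted model
#'
#' Fixed-effect estimates with +/- 1.96 SE intervals.
#'
#' @param object An `rs_model`.
#' @param ... Unused.
#' @export
autoplot.rs_model <- function(object, ...) {
  df <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                                         xmax = .data$estimate + 1.96 * .data$se),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Recovery-experiment estimate distributions
#'
#' Histograms of the replicate estimates of the group intercept effect and
#' the CC x group interaction, with the generative truth marked.
#'
#' @param object An `rs_recovery`.
#' @param ... Unused.
#' @export
autoplot.rs_recovery <- function(object, ...) {
  df <- object$replicates |>
    tidyr::pivot_longer(c("b_estimate", "w_estimate"),
                        names_to = "effect", values_to = "estimate") |>
    dplyr::mutate(effect = dplyr::recode(.data$effect,
                                         b_estimate = "group intercept",
                                         w_estimate = "CC x group"))
  truth <- tibble(
    effect = c("group intercept", "CC x group"),
    value = c(object$truth$delta_b, object$truth$delta_w)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = truth,
                        ggplot2::aes(xintercept = .data$value),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(~effect, scales = "free_x") +
    ggplot2::labs(x = "replicate estimate", y = "count") +
    ggplot2::theme_minimal()
}

#' Observer certainty time course around a rule shift
#'
#' Plots the General and Choice Certainty traces of one participant and
#' level, optionally centred on the n-th shift of that level.
#'
#' @param traces Trial log with observer traces (see [run_observer()]).
#' @param participant,level Which run to plot.
#' @param timing `"pre"` (report-aligned) or `"post"` (post-feedback)
#'   traces.
#' @return A ggplot.
#' @export
plot_observer_trace <- function(traces, participant, level = 1,
                                timing = c("post", "pre")) {
  timing <- match.arg(timing)
  df <- traces |>
    dplyr::filter(.data$participant_id == participant,
                  .data$level == !!level) |>
    dplyr::select("trial", "shift",
                  gc = dplyr::all_of(paste0("gc_", timing)),
                  cc = dplyr::all_of(paste0("cc_", timing))) |>
    tidyr::pivot_longer(c("gc", "cc"), names_to = "trace",
                        values_to = "certainty")
  shifts <- unique(df$trial[df$shift])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$certainty,
                                   colour = .data$trace,
                                   linetype = .data$trace)) +
    ggplot2::geom_vline(xintercept = shifts, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(gc = "#4477aa", cc = "#aa3377"),
                                 labels = c(gc = "General Certainty",
                                            cc = "Choice Certainty")) +
    ggplot2::scale_linetype_manual(values = c(gc = "dashed", cc = "solid"),
                                   guide = "none") +
    ggplot2::labs(x = "trial (0-based, within level)",
                  y = "certainty (0-100)", colour = NULL) +
    ggplot2::theme_minimal()
}
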