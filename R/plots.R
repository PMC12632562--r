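# ggplot2 views of the main result types.

#' Scatter plot of inclusion levels, mutant vs wild-type
#'
#' The classic differential-inclusion view: each point is an event, the
#' reference (wild-type) inclusion on the x-axis and the alternative
#' (mutant) on the y-axis, colored by call direction, with the y = x
#' diagonal marking no change.
#'
#' @param calls A calls tibble from [diff_splicing()].
#' @return A ggplot object.
#' @export
plot_psi_scatter <- function(calls) {
  check_cols(calls, c("psi_wt", "psi_mut", "direction"), "calls")
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$psi_wt, y = .data$psi_mut,
                                      colour = .data$direction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::scale_colour_manual(values = c(increased = "#c0392b",
                                            decreased = "#2980b9",
                                            none = "grey70")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = expression(Psi ~ "(wild-type)"),
                  y = expression(Psi ~ "(mutant)"), colour = "call") +
    ggplot2::theme_minimal()
}

#' @describeIn metagene_profile Line-and-ribbon plot of the positional
#'   log2 enrichment profile, faceted by splice-site anchor.
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                            y = .data$log2_ratio))
  if ("ci_low" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                               ymax = .data$ci_high),
                                  fill = "steelblue", alpha = 0.25)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~anchor, scales = "free_x",
                        labeller = ggplot2::as_labeller(
                          c("3ss" = "3' splice site", "5ss" = "5' splice site"))) +
    ggplot2::labs(x = "position relative to splice-site junction (nt)",
                  y = sprintf("log2 %s count ratio (increased/decreased)",
                              attr(object, "motif_class"))) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_4pl Dose-response points with the fitted 4PL curve on a
#'   log10 concentration axis.
#' @param object A `pl4_fit`.
#' @export
autoplot.pl4_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(concentration = 10^seq(log10(min(dat$concentration)) - 0.5,
                                        log10(max(dat$concentration)) + 0.5,
                                        length.out = 200))
  grid$viability <- predict(object, grid$concentration)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$concentration,
                                         y = .data$viability)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "viability (fraction of control)") +
    ggplot2::theme_minimal()
  if (!is.na(object$ic50_abs)) {
    p <- p + ggplot2::geom_vline(xintercept = object$ic50_abs,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @describeIn compute_gr GR values with the fitted sigmoid and the GR50
#'   crossing.
#' @param object A `gr_curve`.
#' @export
autoplot.gr_curve <- function(object, ...) {
  dat <- object$gr
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$concentration, y = .data$gr)) +
    ggplot2::geom_hline(yintercept = c(0, 1), colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "GR value") +
    ggplot2::theme_minimal()
  if (!is.na(object$gec50)) {
    grid <- tibble(concentration = 10^seq(log10(min(dat$concentration)) - 0.5,
                                          log10(max(dat$concentration)) + 0.5,
                                          length.out = 200))
    grid$gr <- object$gr_inf + (1 - object$gr_inf) /
      (1 + (grid$concentration / object$gec50)^object$hill)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  if (!is.na(object$gr50)) {
    p <- p + ggplot2::geom_vline(xintercept = object$gr50, linetype = "dashed",
                                 colour = "steelblue")
  }
  p
}

#' Bar chart of significant calls by event class
#'
#' Mirrors the per-class differential-splicing summary: increased-inclusion
#' counts to the right, decreased to the left.
#'
#' @param class_summary Output of [summarize_by_class()].
#' @return A ggplot object.
#' @export
plot_class_summary <- function(class_summary) {
  check_cols(class_summary, c("event_class", "n_increased", "n_decreased"),
             "class_summary")
  long <- class_summary |>
    tidyr::pivot_longer(c("n_increased", "n_decreased"),
                        names_to = "direction", values_to = "n") |>
    mutate(direction = sub("^n_", "", .data$direction),
           n = ifelse(.data$direction == "decreased", -.data$n, .data$n))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$event_class,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::scale_fill_manual(values = c(increased = "#c0392b",
                                          decreased = "#2980b9")) +
    ggplot2::labs(x = "significant events", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
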