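# broom-style tidiers for the fitted-object classes.

#' @describeIn fit_4pl One row per 4PL parameter (`top`, `bottom`, `ec50`,
#'   `hill`).
#' @param x A `pl4_fit` object.
#' @param ... Unused.
#' @export
tidy.pl4_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @describeIn fit_4pl One-row model summary: `ic50_abs`, `ec50`,
#'   `no_response`, `rss`, `aic`, `n`.
#' @export
glance.pl4_fit <- function(x, ...) {
  tibble(ic50_abs = x$ic50_abs, ec50 = unname(x$coefficients["ec50"]),
         hill = unname(x$coefficients["hill"]),
         no_response = x$no_response, rss = x$rss, aic = x$aic, n = x$n)
}

#' @describeIn compute_gr Per-concentration GR values.
#' @param x A `gr_curve` object.
#' @param ... Unused.
#' @export
tidy.gr_curve <- function(x, ...) x$gr

#' @describeIn compute_gr One-row fit summary: `gr_inf`, `gec50`, `hill`,
#'   `gr50`.
#' @export
glance.gr_curve <- function(x, ...) {
  tibble(gr_inf = x$gr_inf, gec50 = x$gec50, hill = x$hill, gr50 = x$gr50)
}

#' @describeIn anova_tukey Pairwise Tukey-adjusted contrasts.
#' @param x An `anova_tukey` object.
#' @param ... Unused.
#' @export
tidy.anova_tukey <- function(x, ...) x$pairwise

#' @describeIn anova_tukey One-row ANOVA summary (`statistic` = F,
#'   `p_value`, degrees of freedom).
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble(statistic = x$statistic, df_between = x$df[1], df_within = x$df[2],
         p_value = x$p_value, log_transform = x$log_transform)
}
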