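#' Normalize raw viability signal to vehicle (DMSO) controls
#'
#' Divides each drug well's signal by the mean DMSO signal of its
#' sample/drug context, yielding viability as a fraction of control
#' (values above 1 -- growth stimulation -- are permitted; negative raw
#' signal is clamped to viability 0). Replicate wells are retained;
#' averaging happens downstream where each score needs it.
#'
#' @param raw A data frame of wells: `sample_id`, `drug`, `concentration`
#'   (molar), `replicate`, `signal`, `is_dmso` (logical).
#' @return A tibble of drug wells with `viability` and `inhibition`
#'   (percent, `100 * (1 - viability)`) appended and DMSO rows removed;
#'   `n_dmso` records how many control wells backed each normalization.
#' @examples
#' sim <- sim_dose_response(sim_config(noise_sd = 0, seed = 2))
#' normalize_viability(sim$viability)
#' @export
normalize_viability <- function(raw) {
  check_cols(raw, c("sample_id", "drug", "concentration", "replicate",
                    "signal", "is_dmso"), "raw")
  dmso <- raw |>
    filter(.data$is_dmso) |>
    group_by(.data$sample_id, .data$drug) |>
    summarise(dmso_mean = mean(.data$signal), n_dmso = n(), .groups = "drop")
  drugw <- filter(raw, !.data$is_dmso)
  missing <- dplyr::anti_join(distinct(drugw, .data$sample_id, .data$drug),
                              dmso, by = c("sample_id", "drug"))
  if (nrow(missing) > 0) {
    abort(sprintf("No DMSO control wells for %s / %s.",
                  missing$sample_id[1], missing$drug[1]))
  }
  if (any(dmso$dmso_mean <= 0)) {
    abort("DMSO control mean is zero or negative; cannot normalize.")
  }
  drugw |>
    left_join(dmso, by = c("sample_id", "drug")) |>
    mutate(viability = pmax(0, .data$signal / .data$dmso_mean),
           inhibition = 100 * (1 - .data$viability)) |>
    select(-"dmso_mean", -"is_dmso") |>
    arrange(.data$sample_id, .data$drug, .data$concentration, .data$replicate)
}

# Area of the positive part of the piecewise-linear curve (x, y - t),
# with threshold crossings located exactly.
positive_area <- function(x, y, t) {
  g <- y - t
  a <- 0
  for (i in seq_len(length(x) - 1)) {
    g1 <- g[i]; g2 <- g[i + 1]; dx <- x[i + 1] - x[i]
    if (g1 >= 0 && g2 >= 0) {
      a <- a + dx * (g1 + g2) / 2
    } else if (g1 > 0 && g2 < 0) {
      a <- a + dx * g1 / (g1 - g2) * g1 / 2
    } else if (g1 < 0 && g2 > 0) {
      a <- a + dx * g2 / (g2 - g1) * g2 / 2
    }
  }
  a
}

#' Drug sensitivity score (DSS) from a dose-response curve
#'
#' Integrates the inhibition curve above an activity threshold over the
#' log10-concentration range and normalizes to the maximal achievable area:
#' `DSS = 100 * A / ((100 - t) * (log10 Cmax - log10 Cmin))`, where `A` is
#' the trapezoidal integral of `max(0, inhibition - t)` over log10
#' concentration, with threshold crossings located exactly on the
#' piecewise-linear curve. A fully inactive drug scores 0; complete
#' inhibition across the whole range scores 100; higher DSS means greater
#' sensitivity.
#'
#' @param curve A data frame with `concentration` (molar) and `inhibition`
#'   (percent) or `viability` (fraction); replicate rows are averaged per
#'   concentration. If `sample_id`/`drug` columns are present, one score is
#'   returned per curve.
#' @param threshold Activity threshold in percent inhibition; default 10.
#' @return A tibble with one row per curve: any grouping columns, `dss`,
#'   `activity_threshold`, `log10_cmin`, `log10_cmax`, `n_conc`.
#' @examples
#' compute_dss(tibble::tibble(concentration = 10^(-9:-5),
#'                            inhibition = c(0, 10, 50, 90, 100)))
#' @export
compute_dss <- function(curve, threshold = 10) {
  check_cols(curve, "concentration", "curve")
  if (!"inhibition" %in% names(curve)) {
    check_cols(curve, "viability", "curve")
    curve$inhibition <- 100 * (1 - curve$viability)
  }
  if (threshold < 0 || threshold >= 100) abort("`threshold` must be in [0, 100).")
  grp <- intersect(c("sample_id", "drug"), names(curve))

  one <- function(df) {
    avg <- df |>
      group_by(.data$concentration) |>
      summarise(inhibition = mean(.data$inhibition), .groups = "drop") |>
      arrange(.data$concentration)
    if (nrow(avg) < 2) abort("DSS needs at least two concentrations.")
    x <- log10(avg$concentration)
    a <- positive_area(x, avg$inhibition, threshold)
    tibble(
      dss = 100 * a / ((100 - threshold) * (max(x) - min(x))),
      activity_threshold = threshold,
      log10_cmin = min(x), log10_cmax = max(x), n_conc = nrow(avg)
    )
  }
  if (length(grp) == 0) return(one(curve))
  curve |>
    group_by(across(dplyr::all_of(grp))) |>
    dplyr::group_modify(~ one(.x)) |>
    ungroup()
}

#' Growth-rate-corrected drug response (GR metrics)
#'
#' Converts treated/control cell counts into growth-rate inhibition values
#' that are insensitive to division-rate differences between cell lines:
#' `GR(c) = 2^(log2(x(c)/x0) / log2(x_ctrl/x0)) - 1`, where `x0` is the
#' cell count at treatment start, `x(c)` the treated count and `x_ctrl` the
#' untreated count at assay end. GR is 1 for no effect, 0 for complete
#' cytostasis, and negative for cytotoxicity. When at least four
#' concentrations are supplied, a sigmoidal curve
#' `GR(c) = gr_inf + (1 - gr_inf) / (1 + (c/gec50)^hill)` is fitted and
#' GR50 (the concentration where GR = 0.5) solved from the fit.
#'
#' @param x0 Cell count at treatment start (> 0).
#' @param x_treated Treated cell counts at assay end, one per concentration.
#' @param x_ctrl Untreated (control) count at assay end; must exceed `x0`.
#' @param concentration Optional molar concentrations matching `x_treated`;
#'   required for curve fitting and GR50.
#' @return An object of class `"gr_curve"`: a list with `gr` (tibble of
#'   `concentration`, `gr`), and fitted `gr_inf`, `gec50`, `hill`, `gr50`
#'   (NA when no fit was requested, the fit failed, or the curve never
#'   reaches GR = 0.5).
#' @examples
#' compute_gr(x0 = 1000, x_treated = c(4000, 2000, 500),
#'            x_ctrl = 4000, concentration = c(1e-9, 1e-8, 1e-7))
#' @export
compute_gr <- function(x0, x_treated, x_ctrl, concentration = NULL) {
  if (x0 <= 0) abort("`x0` must be > 0.")
  if (x_ctrl <= x0) abort("Control did not grow (x_ctrl <= x0); GR undefined.")
  if (any(x_treated <= 0)) abort("`x_treated` counts must be > 0.")
  gr <- 2^(log2(x_treated / x0) / log2(x_ctrl / x0)) - 1
  res <- list(
    gr = tibble(concentration = concentration %||% rep(NA_real_, length(gr)),
                gr = gr),
    gr_inf = NA_real_, gec50 = NA_real_, hill = NA_real_, gr50 = NA_real_,
    x0 = x0, x_ctrl = x_ctrl
  )
  if (!is.null(concentration) && length(concentration) >= 4) {
    stopifnot(length(concentration) == length(gr))
    fit <- fit_gr_sigmoid(concentration, gr)
    res[c("gr_inf", "gec50", "hill")] <- fit[c("gr_inf", "gec50", "hill")]
    if (!is.na(fit$gr_inf) && fit$gr_inf < 0.5) {
      res$gr50 <- fit$gec50 * (0.5 / (0.5 - fit$gr_inf))^(1 / fit$hill)
    }
  }
  structure(res, class = "gr_curve")
}

fit_gr_sigmoid <- function(conc, gr) {
  lx <- log10(conc)
  df <- data.frame(lx = lx, gr = gr)
  starts <- lapply(quantile(lx, c(0.25, 0.5, 0.75)), function(l) {
    list(gr_inf = max(-0.99, min(gr)), lgec50 = unname(l), hill = 1)
  })
  fits <- purrr::map(starts, function(s) {
    tryCatch(
      minpack.lm::nlsLM(
        gr ~ gr_inf + (1 - gr_inf) / (1 + 10^((lx - lgec50) * hill)),
        data = df, start = s,
        lower = c(gr_inf = -1, lgec50 = min(lx) - 2, hill = 0.1),
        upper = c(gr_inf = 1, lgec50 = max(lx) + 2, hill = 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    return(list(gr_inf = NA_real_, gec50 = NA_real_, hill = NA_real_))
  }
  best <- fits[[which.min(purrr::map_dbl(fits, stats::deviance))]]
  cf <- coef(best)
  list(gr_inf = unname(cf["gr_inf"]), gec50 = 10^unname(cf["lgec50"]),
       hill = unname(cf["hill"]))
}

#' Fit a four-parameter logistic (4PL) dose-response curve
#'
#' Least-squares fit of
#' `viability = bottom + (top - bottom) / (1 + (c/ec50)^hill)` on
#' replicate-level points, with bounded parameters (`top` in `[0.5, 1.5]`,
#' `bottom` in `[0, 1]`, `hill` in `[0.3, 5]`, `ec50` within the tested
#' range extended two log units) and three deterministic multi-starts.
#' The fit is compared with a flat (no-response) model by AIC; when the flat
#' model wins, or every sigmoidal start fails, the curve is flagged
#' `no_response`. The absolute IC50 -- the concentration where the fitted
#' curve crosses viability 0.5 -- is reported when that crossing lies inside
#' the tested range extended one log unit; the relative EC50 (inflection) is
#' always part of the coefficients.
#'
#' @param curve A data frame with `concentration` (molar) and `viability`
#'   (fraction of control); replicate rows are used as-is so noise enters
#'   the objective at the level it was measured.
#' @return An object of class `"pl4_fit"`: coefficients (`top`, `bottom`,
#'   `ec50`, `hill`), `ic50_abs`, `no_response`, fit diagnostics, and the
#'   data. Supports [tidy()], [glance()], [autoplot()] and `predict()`.
#' @examples
#' sim <- sim_dose_response(sim_config(noise_sd = 0, seed = 2))
#' fit_4pl(normalize_viability(sim$viability))
#' @export
fit_4pl <- function(curve) {
  check_cols(curve, c("concentration", "viability"), "curve")
  curve <- filter(curve, !is.na(.data$viability))
  if (length(unique(curve$concentration)) < 4) {
    abort("4PL fitting needs at least 4 distinct concentrations.")
  }
  df <- data.frame(lx = log10(curve$concentration), v = curve$viability)
  lo <- min(df$lx); hi <- max(df$lx)

  starts <- lapply(quantile(df$lx, c(0.25, 0.5, 0.75)), function(l) {
    list(top = min(1.5, max(0.5, max(df$v))),
         bottom = min(1, max(0, min(df$v))),
         lec50 = unname(l), hill = 1)
  })
  fits <- purrr::compact(purrr::map(starts, function(s) {
    tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + 10^((lx - lec50) * hill)),
        data = df, start = s,
        lower = c(top = 0.5, bottom = 0, lec50 = lo - 2, hill = 0.3),
        upper = c(top = 1.5, bottom = 1, lec50 = hi + 2, hill = 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
  }))

  n <- nrow(df)
  rss_flat <- sum((df$v - mean(df$v))^2)
  aic_flat <- n * log(max(rss_flat, 1e-12) / n) + 2 * 1

  res <- list(
    coefficients = c(top = NA_real_, bottom = NA_real_, ec50 = NA_real_,
                     hill = NA_real_),
    ic50_abs = NA_real_, no_response = TRUE,
    rss = rss_flat, aic = aic_flat, aic_flat = aic_flat, n = n,
    data = as_tibble(curve[, c("concentration", "viability")]),
    conc_range = 10^c(lo, hi)
  )
  class(res) <- "pl4_fit"
  if (length(fits) == 0) return(res)

  best <- fits[[which.min(purrr::map_dbl(fits, stats::deviance))]]
  rss <- stats::deviance(best)
  aic <- n * log(max(rss, 1e-12) / n) + 2 * 4
  if (aic >= aic_flat) return(res)

  cf <- coef(best)
  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  ec50 <- 10^unname(cf["lec50"]); hill <- unname(cf["hill"])
  ic50 <- NA_real_
  if (bottom < 0.5 && top > 0.5) {
    cand <- ec50 * ((top - 0.5) / (0.5 - bottom))^(1 / hill)
    if (cand >= 10^(lo - 1) && cand <= 10^(hi + 1)) ic50 <- cand
  }
  res$coefficients <- c(top = top, bottom = bottom, ec50 = ec50, hill = hill)
  res$ic50_abs <- ic50
  res$no_response <- FALSE
  res$rss <- rss
  res$aic <- aic
  res
}

#' @export
predict.pl4_fit <- function(object, concentration, ...) {
  if (object$no_response) return(rep(mean(object$data$viability),
                                     length(concentration)))
  cf <- object$coefficients
  cf["bottom"] + (cf["top"] - cf["bottom"]) /
    (1 + (concentration / cf["ec50"])^cf["hill"])
}

#' @export
print.pl4_fit <- function(x, ...) {
  cat("<4PL dose-response fit>\n")
  if (x$no_response) {
    cat("  flagged no-response (flat model preferred); IC50 undefined\n")
  } else {
    cf <- x$coefficients
    cat(sprintf("  top %.3f  bottom %.3f  ec50 %.3g M  hill %.2f\n",
                cf["top"], cf["bottom"], cf["ec50"], cf["hill"]))
    cat(sprintf("  absolute IC50: %s\n",
                if (is.na(x$ic50_abs)) "undefined in tested range"
                else sprintf("%.3g M", x$ic50_abs)))
  }
  cat(sprintf("  n = %d wells, RSS = %.4g\n", x$n, x$rss))
  invisible(x)
}

#' @export
print.gr_curve <- function(x, ...) {
  cat("<GR dose-response>\n")
  print(x$gr, n = 5)
  cat(sprintf("  gr_inf %.3f  gec50 %.3g M  hill %.2f  GR50 %s\n",
              x$gr_inf, x$gec50, x$hill,
              if (is.na(x$gr50)) "undefined" else sprintf("%.3g M", x$gr50)))
  invisible(x)
}

#' Two-sided Mann-Whitney U comparison of two score groups
#'
#' Compares two groups of scores (e.g. DSS values of mutant vs wild-type
#' samples) with the Mann-Whitney U test. For small problems (combined
#' n <= 12, the regime of patient-group contrasts) the two-sided p-value is
#' computed by exact enumeration of all group assignments of the observed
#' ranks; larger problems use the normal approximation with tie correction.
#'
#' @param a,b Numeric score vectors; both must be non-empty.
#' @param method `"auto"` (exact when combined n <= 12), `"exact"`, or
#'   `"normal"`.
#' @return A one-row tibble: `statistic` (U for group `a`), `p_value`,
#'   `method`, `n_a`, `n_b`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
compare_groups <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) abort("Both groups must be non-empty.")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto") method <- if (n1 + n2 <= 12) "exact" else "normal"

  if (method == "exact") {
    mu <- n1 * n2 / 2
    sets <- combn(n1 + n2, n1)
    u_all <- apply(sets, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    p <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  tibble(statistic = u_obs, p_value = p, method = paste0("mann-whitney-", method),
         n_a = n1, n_b = n2)
}

#' Linear regression of drug sensitivity on variant allele frequency
#'
#' Ordinary least squares of a sensitivity score (DSS) on variant allele
#' frequency, the per-sample dosage-response relationship. The p-value is
#' the two-sided t-test on the slope.
#'
#' @param vaf Variant allele frequencies (percent), length >= 3 with
#'   non-zero variance.
#' @param dss Matching sensitivity scores.
#' @return A one-row tibble: `slope`, `intercept`, `r` (Pearson), `r_squared`,
#'   `p_value`, `n`.
#' @examples
#' regress_vaf_dss(c(10, 40, 80), c(5, 14, 31))
#' @export
regress_vaf_dss <- function(vaf, dss) {
  if (length(vaf) != length(dss)) abort("`vaf` and `dss` must have equal length.")
  if (length(vaf) < 3) abort("Regression needs n >= 3.")
  if (sd(vaf) == 0) abort("`vaf` has zero variance; slope is unidentifiable.")
  fit <- lm(dss ~ vaf)
  # summary.lm warns on exact fits; the degenerate cases are handled below
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  if (sd(dss) == 0) {
    r <- 0; p <- 1
  } else {
    r <- stats::cor(vaf, dss)
    p <- unname(sm$coefficients[2, 4])
    if (is.nan(p)) p <- 0  # exact collinearity: zero residual variance
  }
  tibble(slope = slope, intercept = unname(coef(fit)[1]),
         r = r, r_squared = unname(sm$r.squared), p_value = p,
         n = length(vaf))
}

#' One-way ANOVA with Tukey's multiple-comparison correction
#'
#' Compares potency estimates (IC50s by default on the log10 scale, where
#' fold-changes are additive) across >= 2 groups by one-way ANOVA, with
#' pairwise contrasts adjusted by Tukey's honestly-significant-difference
#' procedure (studentized-range distribution).
#'
#' @param values Numeric vector of measurements, or a named list of numeric
#'   vectors (one per group; `group` is then ignored).
#' @param group Group labels matching `values`.
#' @param log_transform Analyze `log10(values)`; default TRUE, the usual
#'   scale for IC50s.
#' @return An object of class `"anova_tukey"`: `statistic` (F), `df`,
#'   `p_value`, and `pairwise`, a tibble of contrasts with Tukey-adjusted
#'   p-values. Supports [tidy()] and [glance()].
#' @examples
#' anova_tukey(list(wt = c(1, 1.1, 0.9), mut = c(0.2, 0.25, 0.22)))
#' @export
anova_tukey <- function(values, group = NULL, log_transform = TRUE) {
  if (is.list(values) && !is.data.frame(values)) {
    group <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (is.null(group) || length(group) != length(values)) {
    abort("Supply `group` labels matching `values`, or a named list.")
  }
  sizes <- table(group)
  if (length(sizes) < 2) abort("Need at least 2 groups.")
  if (any(sizes < 2)) {
    abort(sprintf("Every group needs n >= 2 (group '%s' has %d).",
                  names(sizes)[which.min(sizes)], min(sizes)))
  }
  y <- if (log_transform) log10(values) else values
  df <- data.frame(y = y, g = factor(group))
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  f_val <- an[["F value"]][1]
  p_val <- an[["Pr(>F)"]][1]
  if (is.na(f_val) || an[["Mean Sq"]][1] == 0) { # no between-group variance
    f_val <- 0; p_val <- 1
  }
  tk <- TukeyHSD(fit)$g
  pairwise <- tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  structure(list(statistic = f_val, df = unname(an[["Df"]]),
                 p_value = p_val, pairwise = pairwise,
                 log_transform = log_transform),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F(%d, %d) = %.3f, p = %.4g\n",
              if (x$log_transform) " on log10 scale" else "",
              x$df[1], x$df[2], x$statistic, x$p_value))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise)
  invisible(x)
}
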