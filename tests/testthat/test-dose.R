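test_that("DMSO normalization maps signal to fraction-of-control viability", {
  raw <- tibble::tibble(
    sample_id = "s1", drug = "d",
    concentration = c(1e-8, 1e-7, 1e-6, 0, 0),
    replicate = c(1, 1, 1, 1, 2),
    signal = c(1000, 1000, 0, 1000, 1000),
    is_dmso = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  norm <- normalize_viability(raw)
  expect_equal(norm$viability, c(1, 1, 0))
  expect_equal(norm$inhibition, c(0, 0, 100))
  expect_true(all(norm$n_dmso == 2))

  # replicate wells retained; values above 1 (stimulation) permitted
  raw2 <- tibble::tibble(
    sample_id = "s1", drug = "d", concentration = c(1e-7, 1e-7, 0),
    replicate = c(1, 2, 1), signal = c(400, 600, 1000),
    is_dmso = c(FALSE, FALSE, TRUE)
  )
  norm2 <- normalize_viability(raw2)
  expect_equal(norm2$viability, c(0.4, 0.6))
  expect_equal(mean(norm2$viability), 0.5)

  expect_error(normalize_viability(dplyr::filter(raw, !is_dmso)), "DMSO")
  raw$signal[raw$is_dmso] <- 0
  expect_error(normalize_viability(raw), "zero or negative")
})

test_that("DSS hits its closed-form anchors and respects monotonicity", {
  conc <- 10^seq(-9, -5, length.out = 5)
  expect_equal(compute_dss(tibble::tibble(concentration = conc,
                                          inhibition = rep(0, 5)))$dss, 0)
  expect_equal(compute_dss(tibble::tibble(concentration = conc,
                                          inhibition = rep(100, 5)),
                           threshold = 10)$dss, 100)
  # linear ramp 0 -> 100 over the log range at t = 0: triangle = half the box
  ramp <- tibble::tibble(concentration = conc, inhibition = seq(0, 100, 25))
  expect_equal(compute_dss(ramp, threshold = 0)$dss, 50)

  # pointwise-greater inhibition never lowers DSS; threshold -> 100 kills DSS
  withr::with_seed(61, {
    for (k in 1:20) {
      y1 <- sort(runif(5, 0, 90)); y2 <- pmin(100, y1 + runif(5, 0, 10))
      d1 <- compute_dss(tibble::tibble(concentration = conc, inhibition = y1))$dss
      d2 <- compute_dss(tibble::tibble(concentration = conc, inhibition = y2))$dss
      expect_gte(d2, d1)
      d_hi <- compute_dss(tibble::tibble(concentration = conc, inhibition = y2),
                          threshold = 99.9)$dss
      expect_lt(d_hi, 1)
    }
  })
  expect_error(compute_dss(tibble::tibble(concentration = 1e-7, inhibition = 50)),
               "two concentrations")
})

test_that("DSS locates threshold crossings exactly on the piecewise-linear curve", {
  # inhibition crosses t = 10 exactly halfway through the single log segment:
  # area = 0.5 * 40 * 0.5 log-units; normalizer = 90 * 1
  crv <- tibble::tibble(concentration = c(1e-8, 1e-7), inhibition = c(-30, 50))
  expect_equal(compute_dss(crv, threshold = 10)$dss,
               100 * (0.5 * 40 * 0.5) / (90 * 1))
})

test_that("GR values match closed forms at the anchor cases", {
  expect_equal(compute_gr(1000, 4000, 4000)$gr$gr, 1)     # treated = control
  expect_equal(compute_gr(1000, 1000, 4000)$gr$gr, 0)     # cytostasis
  expect_equal(compute_gr(1000, 500, 4000)$gr$gr, 2^(-0.5) - 1)
  expect_error(compute_gr(1000, 500, 900), "GR undefined")
  expect_error(compute_gr(0, 500, 900), "x0")
  # gr > -1 always
  g <- compute_gr(1000, c(1, 10, 100), 64000)
  expect_true(all(g$gr$gr > -1))
})

test_that("GR50 is recovered within 1% from noise-free GR curves", {
  x0 <- 1000; x_ctrl <- 8000 # three doublings
  conc <- 10^seq(-9, -5, length.out = 9)
  cases <- list(c(gr_inf = -0.4, gec50 = 1e-7, hill = 1),
                c(gr_inf = 0.0, gec50 = 5e-8, hill = 1.6),
                c(gr_inf = -0.8, gec50 = 3e-7, hill = 0.8))
  for (cs in cases) {
    gr_true <- cs["gr_inf"] + (1 - cs["gr_inf"]) /
      (1 + (conc / cs["gec50"])^cs["hill"])
    # invert GR to cell counts, then run the full pipeline back
    k <- log2(x_ctrl / x0)
    x_treated <- x0 * 2^(k * log2(gr_true + 1))
    fit <- compute_gr(x0, x_treated, x_ctrl, conc)
    gr50_true <- cs["gec50"] * (0.5 / (0.5 - cs["gr_inf"]))^(1 / cs["hill"])
    expect_equal(fit$gr50 / unname(gr50_true), 1, tolerance = 0.01)
    expect_equal(fit$gr_inf, unname(cs["gr_inf"]), tolerance = 0.02)
  }
})

test_that("4PL fits recover noise-free parameters and flag non-responders", {
  crv <- pl4_curve(10^seq(-9, -5, length.out = 7), top = 1, bottom = 0,
                   ec50 = 1e-7, hill = 1)
  fit <- fit_4pl(crv)
  expect_false(fit$no_response)
  expect_equal(unname(fit$coefficients["ec50"]) / 1e-7, 1, tolerance = 0.01)
  expect_equal(fit$ic50_abs / 1e-7, 1, tolerance = 0.01) # symmetric curve: IC50 = EC50

  flat <- tibble::tibble(concentration = 10^seq(-9, -5, length.out = 5),
                         viability = 1)
  ffit <- fit_4pl(flat)
  expect_true(ffit$no_response); expect_true(is.na(ffit$ic50_abs))

  rising <- tibble::tibble(concentration = 10^seq(-9, -5, length.out = 5),
                           viability = c(0.8, 0.9, 1.0, 1.1, 1.2))
  expect_true(fit_4pl(rising)$no_response)
  expect_error(fit_4pl(crv[1:3, ]), "4 distinct")
})

test_that("4PL EC50 recovery under noise meets the calibration bound", {
  cfg0 <- sim_config(noise_sd = 0.02, dr_ec50 = 1e-7, seed = 1)
  errs <- vapply(1:100, function(k) {
    cfg <- sim_config(noise_sd = 0.02, dr_ec50 = 1e-7, seed = 7000 + k)
    curves <- normalize_viability(sim_dose_response(cfg)$viability)
    fit <- fit_4pl(curves)
    abs(unname(fit$coefficients["ec50"]) / 1e-7 - 1)
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("the absolute IC50 is reported only when the curve crosses 50% in range", {
  # bottom above 0.5: no crossing
  high <- pl4_curve(10^seq(-9, -5, length.out = 6), top = 1, bottom = 0.6,
                    ec50 = 1e-7, hill = 1.2)
  expect_true(is.na(fit_4pl(high)$ic50_abs))
  # asymmetric curve: absolute IC50 differs from the EC50 inflection
  asym <- pl4_curve(10^seq(-10, -4, length.out = 9), top = 1, bottom = 0.3,
                    ec50 = 1e-7, hill = 1)
  f <- fit_4pl(asym)
  ic50_expected <- 1e-7 * ((1 - 0.5) / (0.5 - 0.3))^(1 / 1)
  expect_equal(f$ic50_abs / ic50_expected, 1, tolerance = 0.02)
  expect_gt(f$ic50_abs, unname(f$coefficients["ec50"]))
})

test_that("Mann-Whitney comparisons: enumeration oracle, ties, and identity", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1) # 2 of the 20 assignments are as extreme

  # independent enumeration oracle for a second configuration
  a <- c(1.2, 3.4, 5.1, 2.2); b <- c(4.4, 6.7, 8.1)
  r <- rank(c(a, b)); n1 <- 4
  u_all <- apply(combn(7, n1), 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[1:4]) - n1 * (n1 + 1) / 2
  p_oracle <- mean(abs(u_all - 6) >= abs(u_obs - 6))
  got <- compare_groups(a, b)
  expect_equal(got$p_value, p_oracle)
  expect_equal(got$statistic, u_obs)

  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")

  # exact path matches wilcox.test exact p where both are defined
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6))$p_value,
               wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p.value)
})

test_that("exact and normal-approximation p-values agree for n = (6, 6)", {
  withr::with_seed(71, {
    for (k in 1:10) {
      a <- rnorm(6); b <- rnorm(6, 0.5)
      pe <- compare_groups(a, b, method = "exact")$p_value
      pn <- compare_groups(a, b, method = "normal")$p_value
      expect_lt(abs(pe - pn), 0.02)
    }
  })
})

test_that("VAF-DSS regression returns exact answers on constructed lines", {
  line <- regress_vaf_dss(c(10, 20, 40), c(20, 40, 80)) # dss = 2 * vaf
  expect_equal(line$slope, 2); expect_equal(line$r, 1)
  expect_lt(line$p_value, 1e-6)

  flat <- regress_vaf_dss(c(10, 20, 40), c(5, 5, 5))
  expect_equal(flat$slope, 0); expect_equal(flat$r, 0); expect_equal(flat$p_value, 1)

  dup <- regress_vaf_dss(c(10, 10, 40, 40), c(1, 2, 5, 7)) # duplicated x
  expect_lt(dup$r, 1); expect_gt(dup$r, 0)

  expect_error(regress_vaf_dss(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(regress_vaf_dss(c(5, 5, 5), c(1, 2, 3)), "variance")
})

test_that("ANOVA with Tukey correction matches closed-form small cases", {
  idn <- anova_tukey(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(idn$statistic, 0); expect_equal(idn$p_value, 1)

  mix <- anova_tukey(list(g1 = c(1, 1.1), g2 = c(1, 1.1), g3 = c(10, 11)),
                     log_transform = TRUE)
  pw <- tidy(mix)
  expect_gt(pw$p_adj[pw$contrast == "g2-g1"], 0.5)
  expect_lt(mix$p_value, 0.01)

  # two groups: F equals t^2 from the equal-variance t-test
  two <- anova_tukey(list(x = c(1, 2, 3), y = c(4, 5, 7)), log_transform = FALSE)
  tt <- t.test(c(4, 5, 7), c(1, 2, 3), var.equal = TRUE)
  expect_equal(two$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(two$p_value, tt$p.value, tolerance = 1e-10)

  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(anova_tukey(list(a = c(1, 2))), "2 groups")
})

test_that("tidiers expose fit results in broom shape", {
  crv <- pl4_curve(10^seq(-9, -5, length.out = 6), ec50 = 1e-7)
  fit <- fit_4pl(crv)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("top", "bottom", "ec50", "hill"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_false(gl$no_response)

  g <- compute_gr(1000, c(3900, 3000, 1500, 400), 4000, 10^c(-9, -8, -7, -6))
  expect_named(glance(g), c("gr_inf", "gec50", "hill", "gr50"))
  expect_equal(nrow(tidy(g)), 4)
})
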