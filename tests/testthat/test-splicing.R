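test_that("posterior PSI estimates match the conjugate closed forms", {
  sym <- estimate_psi(tibble::tibble(inclusion_reads = 10, exclusion_reads = 10))
  expect_equal(sym$psi_mean, 0.5)

  empty <- estimate_psi(tibble::tibble(inclusion_reads = 0, exclusion_reads = 0))
  expect_equal(empty$psi_mean, 0.5)
  expect_equal(empty$ci_low, 0.025, tolerance = 1e-10)
  expect_equal(empty$ci_high, 0.975, tolerance = 1e-10)

  skew <- estimate_psi(tibble::tibble(inclusion_reads = 30, exclusion_reads = 10))
  expect_equal(skew$psi_mean, 31 / 42)
  expect_true(skew$ci_low <= skew$psi_mean && skew$psi_mean <= skew$ci_high)
  expect_error(estimate_psi(tibble::tibble(inclusion_reads = 1,
                                           exclusion_reads = 1), prior_a = 0),
               "Prior")
})

test_that("Bayes factors behave as evidence: direction, nulls, and weak data", {
  expect_lt(bayes_factor(50, 50, 50, 50), 1)     # deep identical counts favor H0
  expect_gte(bayes_factor(95, 5, 5, 95), 5)      # clear separation
  bf_weak <- bayes_factor(1, 1, 1, 1)            # near-uninformative data
  expect_gt(bf_weak, 0.5); expect_lt(bf_weak, 2)
})

test_that("grid Bayes factor matches the closed-form Beta-overlap oracle", {
  # spot values, frozen from the Beta-function identity
  expect_equal(bayes_factor(1, 1, 1, 1), 1 / 1.2, tolerance = 1e-4)
  withr::with_seed(17, {
    for (k in 1:40) {
      d1 <- sample(100, 1); d2 <- sample(100, 1)
      i1 <- sample(0:d1, 1); i2 <- sample(0:d2, 1)
      g <- bayes_factor(i1, d1 - i1, i2, d2 - i2)
      cf <- bf_beta_closed_form(i1, d1 - i1, i2, d2 - i2)
      expect_equal(g, cf, tolerance = 1e-3)
    }
  })
})

test_that("Monte-Carlo Bayes factor agrees with the grid route", {
  withr::with_seed(5, {
    cases <- list(c(30, 70, 50, 50), c(10, 10, 15, 5), c(70, 30, 45, 55),
                  c(5, 5, 5, 5))
    for (cc in cases) {
      g <- bayes_factor(cc[1], cc[2], cc[3], cc[4])
      m <- bayes_factor(cc[1], cc[2], cc[3], cc[4], method = "mc", n_draws = 1e6)
      expect_equal(m, g, tolerance = 0.05)
    }
  })
})

test_that("Bayes factor is invariant to swapping the two conditions", {
  pairs <- list(c(30, 10, 5, 25), c(95, 5, 5, 95), c(12, 0, 3, 9))
  for (p in pairs) {
    expect_equal(bayes_factor(p[1], p[2], p[3], p[4]),
                 bayes_factor(p[3], p[4], p[1], p[2]), tolerance = 1e-12)
  }
})

test_that("the grid refuses counts it cannot resolve, with a diagnostic", {
  expect_error(bayes_factor(1e6, 1e6, 1e6, 1e6, grid_size = 201), "grid")
  expect_error(bayes_factor(10, 10, 10, 10, grid_size = 100), "201")
  # the same counts succeed on a finer grid
  expect_gt(bayes_factor(1e6, 1e6, 1e6, 1e6, grid_size = 20001), 0)
})

test_that("median Bayes factor does not decrease with true separation", {
  depth <- 100
  med_bf <- vapply(c(0, 0.1, 0.2, 0.3), function(sep) {
    withr::with_seed(100 + round(1000 * sep), {
      bfs <- replicate(40, {
        ia <- rbinom(1, depth, 0.5 - sep / 2)
        ib <- rbinom(1, depth, 0.5 + sep / 2)
        bayes_factor(ia, depth - ia, ib, depth - ib)
      })
      median(bfs)
    })
  }, numeric(1))
  expect_true(all(diff(med_bf) >= 0))
})

test_that("differential calls require both the effect-size and evidence thresholds", {
  up <- call_differential(0.75, 0.50, 10)
  expect_true(up$significant); expect_equal(up$direction, "increased")

  small <- call_differential(0.55, 0.50, 100)   # |dPsi| = 0.05 < 0.10
  expect_false(small$significant); expect_equal(small$direction, "none")

  down <- call_differential(0.30, 0.50, 7)
  expect_true(down$significant); expect_equal(down$direction, "decreased")

  weak <- call_differential(0.80, 0.50, 4.9)    # BF below threshold
  expect_false(weak$significant)

  # ties at both thresholds are significant (>= comparisons)
  tie <- call_differential(0.60, 0.50, 5)
  expect_true(tie$significant)
  expect_error(call_differential(0.6, 0.5, 5, delta_threshold = 0), "Thresholds")
})

test_that("per-class summary partitions significant calls and zero-fills", {
  events <- tibble::tibble(event_id = sprintf("e%d", 1:5),
                           event_class = c("CE", "CE", "CE", "RI", "RI"))
  empty <- summarize_by_class(
    tibble::tibble(event_id = character(), significant = logical(),
                   direction = character()), events)
  expect_equal(nrow(empty), 5)
  expect_true(all(empty$n_increased == 0 & empty$n_decreased == 0))

  calls <- tibble::tibble(
    event_id = sprintf("e%d", 1:5),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    direction = c("increased", "increased", "increased", "decreased", "decreased")
  )
  smry <- summarize_by_class(calls, events)
  expect_equal(smry$n_increased[smry$event_class == "CE"], 3)
  expect_equal(smry$n_decreased[smry$event_class == "RI"], 2)
  expect_equal(sum(smry$n_increased + smry$n_decreased), sum(calls$significant))

  expect_error(summarize_by_class(dplyr::mutate(calls, event_id = "nope"), events),
               "nope")
})

test_that("pooling replicates sums counts before testing and is recorded", {
  counts <- tibble::tibble(
    event_id = "e1", sample_id = c("w1", "w2", "m1", "m2"),
    inclusion_reads = c(10, 20, 40, 50), exclusion_reads = c(30, 40, 10, 0)
  )
  samples <- tibble::tibble(sample_id = c("w1", "w2", "m1", "m2"),
                            condition = c("wt", "wt", "mut", "mut"))
  calls <- diff_splicing(counts, samples)
  expect_equal(calls$psi_wt, (30 + 1) / (100 + 2))   # pooled 30/100 + uniform prior
  expect_equal(calls$psi_mut, (90 + 1) / (100 + 2))
  expect_match(attr(calls, "pooled"), "summed")
  expect_error(diff_splicing(counts, samples, condition_ref = "xx"), "xx")
})

test_that("per-group PSI medians track planted allele-dosage monotonicity", {
  # constant counts: all group medians equal
  cc <- tibble::tibble(event_id = "e1", sample_id = sprintf("s%d", 1:6),
                       inclusion_reads = 20, exclusion_reads = 20)
  lab <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                        group = rep(c("0", "1/3", "2/3"), each = 2))
  flat <- psi_by_group(cc, lab, "e1")
  expect_equal(length(unique(flat$psi_median)), 1)
  expect_equal(flat$group, c("0", "1/3", "2/3"))

  # planted monotone inclusion by allele count at high depth
  withr::with_seed(29, {
    psis <- c(0.1, 0.2, 0.3, 0.4); depth <- 5000
    counts <- purrr::map_dfr(seq_along(psis), function(g) {
      tibble::tibble(event_id = "ez", sample_id = sprintf("g%d_s%d", g, 1:3),
                     inclusion_reads = rbinom(3, depth, psis[g]),
                     exclusion_reads = depth - inclusion_reads)
    })
    labels <- tibble::tibble(sample_id = counts$sample_id,
                             group = rep(c("0", "1/3", "2/3", "3/3"), each = 3))
    res <- psi_by_group(counts, labels, "ez")
    expect_true(all(diff(res$psi_median) > 0))
  })

  # single group degenerates to one median; missing sample warns
  one <- psi_by_group(cc[1:2, ], lab[1:2, ], "e1")
  expect_equal(nrow(one), 1)
  expect_warning(psi_by_group(cc[1:5, ], lab, "e1"), "omitted")
})
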