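#' Posterior percent-spliced-in (PSI) estimates from junction counts
#'
#' Models the inclusion level Psi of each event in each sample with a
#' conjugate Beta-Binomial: given `inclusion_reads` successes and
#' `exclusion_reads` failures and a `Beta(prior_a, prior_b)` prior, the
#' posterior is `Beta(inclusion + prior_a, exclusion + prior_b)`. The
#' estimate is the posterior mean and the interval the central 95%
#' posterior interval; zero-read events fall back to the prior.
#'
#' @param counts A data frame with columns `inclusion_reads` and
#'   `exclusion_reads` (any identifier columns are carried through).
#' @param prior_a,prior_b Positive Beta prior parameters; the default
#'   `(1, 1)` is the uniform prior.
#' @return The input as a tibble with columns `psi_mean`, `ci_low`,
#'   `ci_high`, and `n_reads` appended.
#' @examples
#' estimate_psi(tibble::tibble(inclusion_reads = 30, exclusion_reads = 10))
#' @export
estimate_psi <- function(counts, prior_a = 1, prior_b = 1) {
  check_cols(counts, c("inclusion_reads", "exclusion_reads"), "counts")
  if (prior_a <= 0 || prior_b <= 0) abort("Prior parameters must be > 0.")
  if (any(counts$inclusion_reads < 0) || any(counts$exclusion_reads < 0)) {
    abort("Read counts must be non-negative.")
  }
  a <- counts$inclusion_reads + prior_a
  b <- counts$exclusion_reads + prior_b
  as_tibble(counts) |>
    mutate(
      psi_mean = a / (a + b),
      ci_low = qbeta(0.025, a, b),
      ci_high = qbeta(0.975, a, b),
      n_reads = .data$inclusion_reads + .data$exclusion_reads
    )
}

#' Bayes factor for differential inclusion of one event
#'
#' Tests H1: `Psi_a != Psi_b` against H0: `Psi_a = Psi_b` with a
#' Savage-Dickey density ratio at `dPsi = 0`. Both inclusion levels get
#' independent Uniform(0, 1) priors, under which the induced prior on the
#' difference is triangular with density exactly 1 at zero, so
#' `BF10 = 1 / p(dPsi = 0 | data)`. The posterior density of the difference
#' at zero is the overlap integral of the two Beta posteriors,
#' `integral f_a(psi) f_b(psi) dpsi` -- the value at zero of the convolution
#' of the posterior of `Psi_a` with that of `-Psi_b`.
#'
#' Two estimators are provided. `"grid"` (default) evaluates the overlap
#' integral by the trapezoid rule on a uniform grid over `[0, 1]` and is
#' fully deterministic. `"mc"` estimates the same integral by Monte Carlo,
#' drawing from an equal mixture of the two Beta posteriors and averaging
#' the importance weight `2 f_a f_b / (f_a + f_b)`; the weight is bounded
#' by twice the smaller of the two densities, so the estimator stays
#' accurate even when the posteriors barely overlap and the Bayes factor is
#' very large. It serves as an independent stochastic cross-check of the
#' grid values.
#'
#' @param inc_a,exc_a,inc_b,exc_b Inclusion/exclusion read counts for the two
#'   conditions; vectors are accepted and recycled to a common length.
#' @param grid_size Number of grid points (>= 201) for the `"grid"` method.
#' @param prior_a,prior_b Beta prior parameters shared by both conditions.
#' @param method `"grid"` or `"mc"`.
#' @param n_draws Posterior draws per direction for `"mc"`.
#' @return A numeric vector of Bayes factors (BF10; values above 1 favor
#'   differential inclusion).
#' @examples
#' bayes_factor(95, 5, 5, 95)   # strong separation, large BF
#' bayes_factor(50, 50, 50, 50) # identical deep counts, BF < 1
#' @export
bayes_factor <- function(inc_a, exc_a, inc_b, exc_b,
                         grid_size = 1001L, prior_a = 1, prior_b = 1,
                         method = c("grid", "mc"), n_draws = 1e5) {
  method <- match.arg(method)
  if (grid_size < 201L) abort("`grid_size` must be at least 201.")
  if (prior_a <= 0 || prior_b <= 0) abort("Prior parameters must be > 0.")
  n <- max(length(inc_a), length(exc_a), length(inc_b), length(exc_b))
  inc_a <- rep_len(inc_a, n); exc_a <- rep_len(exc_a, n)
  inc_b <- rep_len(inc_b, n); exc_b <- rep_len(exc_b, n)
  if (any(c(inc_a, exc_a, inc_b, exc_b) < 0)) abort("Counts must be non-negative.")

  a1 <- inc_a + prior_a; a2 <- exc_a + prior_b
  b1 <- inc_b + prior_a; b2 <- exc_b + prior_b

  if (method == "grid") {
    step <- 1 / (grid_size - 1)
    # refuse when a posterior is too narrow for the grid to resolve
    w_a <- qbeta(0.995, a1, a2) - qbeta(0.005, a1, a2)
    w_b <- qbeta(0.995, b1, b2) - qbeta(0.005, b1, b2)
    if (any(pmin(w_a, w_b) < 2 * step)) {
      abort(sprintf(
        "Posterior width (%.2g) spans fewer than 2 grid cells at grid_size = %d; increase `grid_size`.",
        min(w_a, w_b), grid_size))
    }
    x <- seq(0, 1, length.out = grid_size)
    vapply(seq_len(n), function(i) {
      dens0 <- trapz(x, dbeta(x, a1[i], a2[i]) * dbeta(x, b1[i], b2[i]))
      1 / dens0
    }, numeric(1))
  } else {
    vapply(seq_len(n), function(i) {
      third <- ceiling(n_draws / 3)
      # defensive mixture: both posteriors plus an averaged-parameter
      # bridge component that covers the region between them, keeping the
      # importance weights well-behaved when the posteriors barely overlap
      m1 <- (a1[i] + b1[i]) / 2; m2 <- (a2[i] + b2[i]) / 2
      x <- c(rbeta(third, a1[i], a2[i]), rbeta(third, b1[i], b2[i]),
             rbeta(third, m1, m2))
      fa <- dbeta(x, a1[i], a2[i]); fb <- dbeta(x, b1[i], b2[i])
      fm <- dbeta(x, m1, m2)
      g <- (fa + fb + fm) / 3
      w <- ifelse(g > 0, fa * fb / g, 0)
      1 / mean(w)
    }, numeric(1))
  }
}

#' Call differential inclusion at fixed effect-size and evidence thresholds
#'
#' An event is significant when the inclusion difference (mutant minus
#' wild-type posterior mean) reaches `delta_threshold` in magnitude *and*
#' the Bayes factor reaches `bf_threshold`; both comparisons are inclusive
#' (`>=`). Direction follows the sign of the difference for significant
#' events and is `"none"` otherwise.
#'
#' @param psi_mut,psi_wt Posterior-mean inclusion levels per event.
#' @param bayes_factor Bayes factor per event (BF10).
#' @param delta_threshold Minimum `|dPsi|`; default 0.10 (10 percentage
#'   points).
#' @param bf_threshold Minimum Bayes factor; default 5.
#' @return A tibble with `delta_psi`, `bayes_factor`, `significant`, and
#'   `direction` (`"increased"`, `"decreased"`, or `"none"`).
#' @examples
#' call_differential(psi_mut = 0.75, psi_wt = 0.50, bayes_factor = 10)
#' @export
call_differential <- function(psi_mut, psi_wt, bayes_factor,
                              delta_threshold = 0.10, bf_threshold = 5) {
  if (delta_threshold <= 0 || bf_threshold <= 0) abort("Thresholds must be > 0.")
  check_fraction(psi_mut, "psi_mut"); check_fraction(psi_wt, "psi_wt")
  delta <- psi_mut - psi_wt
  # inclusive thresholds; guard the >= comparison against FP representation
  eps <- 1e-9
  sig <- abs(delta) >= delta_threshold - eps & bayes_factor >= bf_threshold - eps
  tibble(
    delta_psi = delta,
    bayes_factor = bayes_factor,
    significant = sig,
    direction = ifelse(!sig, "none", ifelse(delta > 0, "increased", "decreased"))
  )
}

#' Differential-splicing analysis of a two-condition experiment
#'
#' End-to-end wrapper: pools replicate libraries within each condition by
#' summing junction counts, estimates per-condition inclusion with
#' [estimate_psi()], computes the Savage-Dickey Bayes factor per event with
#' [bayes_factor()], and calls events with [call_differential()]. The
#' difference is oriented alternative-minus-reference (mutant minus
#' wild-type by default).
#'
#' @param counts Data frame of junction evidence: `event_id`, `sample_id`,
#'   `inclusion_reads`, `exclusion_reads`.
#' @param samples Data frame mapping `sample_id` to `condition`.
#' @param condition_ref,condition_alt The reference (wild-type) and
#'   alternative (mutant) condition labels in `samples`.
#' @param events Optional event table with `event_id` and `event_class`,
#'   joined onto the result.
#' @param delta_threshold,bf_threshold Calling thresholds, see
#'   [call_differential()].
#' @param grid_size,prior_a,prior_b Passed to [bayes_factor()] and
#'   [estimate_psi()].
#' @return A tibble of calls, one row per event: `event_id`, optional
#'   `event_class`, `psi_wt`, `psi_mut`, `delta_psi`, `bayes_factor`,
#'   `significant`, `direction`. The attribute `"pooled"` records that
#'   replicates were summed within condition before testing.
#' @examples
#' sim <- sim_splicing(sim_config(n_events = 10, seed = 11))
#' diff_splicing(sim$counts, sim$samples, events = sim$events)
#' @export
diff_splicing <- function(counts, samples,
                          condition_ref = "wt", condition_alt = "mut",
                          events = NULL,
                          delta_threshold = 0.10, bf_threshold = 5,
                          grid_size = 1001L, prior_a = 1, prior_b = 1) {
  check_cols(counts, c("event_id", "sample_id", "inclusion_reads", "exclusion_reads"),
             "counts")
  check_cols(samples, c("sample_id", "condition"), "samples")
  if (!condition_ref %in% samples$condition) {
    abort(sprintf("Reference condition '%s' not present in `samples`.", condition_ref))
  }
  if (!condition_alt %in% samples$condition) {
    abort(sprintf("Alternative condition '%s' not present in `samples`.", condition_alt))
  }

  pooled <- counts |>
    left_join(samples, by = "sample_id") |>
    filter(.data$condition %in% c(condition_ref, condition_alt)) |>
    group_by(.data$event_id, .data$condition) |>
    summarise(inclusion_reads = sum(.data$inclusion_reads),
              exclusion_reads = sum(.data$exclusion_reads), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("inclusion_reads", "exclusion_reads"))

  inc_wt <- pooled[[paste0("inclusion_reads_", condition_ref)]]
  exc_wt <- pooled[[paste0("exclusion_reads_", condition_ref)]]
  inc_mut <- pooled[[paste0("inclusion_reads_", condition_alt)]]
  exc_mut <- pooled[[paste0("exclusion_reads_", condition_alt)]]

  psi_wt <- (inc_wt + prior_a) / (inc_wt + exc_wt + prior_a + prior_b)
  psi_mut <- (inc_mut + prior_a) / (inc_mut + exc_mut + prior_a + prior_b)
  bf <- bayes_factor(inc_mut, exc_mut, inc_wt, exc_wt,
                     grid_size = grid_size, prior_a = prior_a, prior_b = prior_b)

  calls <- tibble(event_id = pooled$event_id, psi_wt = psi_wt, psi_mut = psi_mut) |>
    dplyr::bind_cols(call_differential(psi_mut, psi_wt, bf,
                                       delta_threshold, bf_threshold))
  if (!is.null(events)) {
    check_cols(events, c("event_id", "event_class"), "events")
    calls <- calls |>
      left_join(distinct(events[, c("event_id", "event_class")]), by = "event_id") |>
      select("event_id", "event_class", dplyr::everything())
  }
  attr(calls, "pooled") <- "replicates summed within condition before testing"
  calls
}

#' Tally significant calls by splicing event class
#'
#' Counts significant increased- and decreased-inclusion events per class,
#' always returning one row per class (`CE`, `RI`, `MXE`, `A5SS`, `A3SS`),
#' zero-filled. Non-significant calls are excluded from the tallies.
#'
#' @param calls A calls tibble (see [diff_splicing()]) with `event_id`,
#'   `significant`, `direction`.
#' @param events Event table with `event_id` and `event_class`; every call
#'   must resolve to an event.
#' @return A five-row tibble: `event_class`, `n_increased`, `n_decreased`.
#' @examples
#' sim <- sim_splicing(sim_config(n_events = 30, seed = 8))
#' calls <- diff_splicing(sim$counts, sim$samples)
#' summarize_by_class(calls, sim$events)
#' @export
summarize_by_class <- function(calls, events) {
  check_cols(calls, c("event_id", "significant", "direction"), "calls")
  check_cols(events, c("event_id", "event_class"), "events")
  unknown <- setdiff(calls$event_id, events$event_id)
  if (length(unknown) > 0) {
    abort(sprintf("Call(s) reference unknown event id(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  calls |>
    filter(.data$significant) |>
    left_join(distinct(events[, c("event_id", "event_class")]), by = "event_id",
              suffix = c(".call", "")) |>
    group_by(event_class = factor(.data$event_class, levels = SPLICE_CLASSES)) |>
    summarise(n_increased = sum(.data$direction == "increased"),
              n_decreased = sum(.data$direction == "decreased"),
              .groups = "drop") |>
    tidyr::complete(event_class = factor(SPLICE_CLASSES, levels = SPLICE_CLASSES),
                    fill = list(n_increased = 0L, n_decreased = 0L)) |>
    mutate(event_class = as.character(.data$event_class)) |>
    arrange(match(.data$event_class, SPLICE_CLASSES))
}

#' Inclusion of one event across samples grouped by allele dosage
#'
#' Summarizes the posterior-mean inclusion of a single event across samples
#' stratified by a group label (e.g. mutant-allele count 0, 1/3, 2/3, 3/3),
#' the layout used to relate poison-exon inclusion to mutant allele dosage.
#'
#' @param counts Junction counts (`event_id`, `sample_id`, `inclusion_reads`,
#'   `exclusion_reads`).
#' @param samples Data frame mapping `sample_id` to `group`; every sample in
#'   `counts` for this event must have a label. Samples without counts for
#'   the event are omitted with a warning.
#' @param event_id The event to summarize.
#' @param prior_a,prior_b Beta prior for [estimate_psi()].
#' @return A tibble with one row per group, ordered by label: `group`,
#'   `n_samples`, `psi` (list-column of per-sample posterior means),
#'   `psi_median`.
#' @examples
#' sim <- sim_splicing(sim_config(n_events = 5, n_samples_per_condition = 3,
#'                                seed = 6))
#' grp <- dplyr::mutate(sim$samples, group = condition)
#' psi_by_group(sim$counts, grp, event_id = sim$events$event_id[1])
#' @export
psi_by_group <- function(counts, samples, event_id, prior_a = 1, prior_b = 1) {
  check_cols(counts, c("event_id", "sample_id", "inclusion_reads", "exclusion_reads"),
             "counts")
  check_cols(samples, c("sample_id", "group"), "samples")
  ev <- counts[counts$event_id == event_id, , drop = FALSE]
  if (nrow(ev) == 0) abort(sprintf("Event '%s' absent from `counts`.", event_id))
  unlabelled <- setdiff(ev$sample_id, samples$sample_id)
  if (length(unlabelled) > 0) {
    abort(sprintf("Sample(s) without a group label: %s",
                  paste(unlabelled, collapse = ", ")))
  }
  missing <- setdiff(samples$sample_id, ev$sample_id)
  if (length(missing) > 0) {
    warn(sprintf("Event '%s' has no counts in sample(s) %s; omitted.",
                 event_id, paste(missing, collapse = ", ")))
  }
  est <- estimate_psi(ev, prior_a, prior_b) |>
    left_join(samples[, c("sample_id", "group")], by = "sample_id")
  grp_levels <- if (is.factor(samples$group)) levels(samples$group) else
    sort(unique(as.character(samples$group)))
  est |>
    group_by(group = factor(as.character(.data$group), levels = grp_levels)) |>
    summarise(n_samples = n(),
              psi = list(.data$psi_mean),
              psi_median = median(.data$psi_mean), .groups = "drop") |>
    filter(!is.na(.data$group)) |>
    arrange(.data$group) |>
    mutate(group = as.character(.data$group))
}
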