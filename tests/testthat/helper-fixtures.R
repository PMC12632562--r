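# Shared fixtures, built in code at test time.

# closed-form Savage-Dickey Bayes factor for two Beta-Binomial conditions:
# the product of two Beta densities is a Beta kernel, so the posterior
# overlap integral is a ratio of Beta functions. Independent of the
# package's grid/MC code paths.
bf_beta_closed_form <- function(inc_a, exc_a, inc_b, exc_b,
                                prior_a = 1, prior_b = 1) {
  a1 <- inc_a + prior_a; a2 <- exc_a + prior_b
  b1 <- inc_b + prior_a; b2 <- exc_b + prior_b
  exp(lbeta(a1, a2) + lbeta(b1, b2) - lbeta(a1 + b1 - 1, a2 + b2 - 1))
}

# exon-set tibble from explicit sequences; exon spans the whole record
# unless flank lengths are given
make_exon_set <- function(seqs, flank = 0) {
  tibble::tibble(
    exon_id = sprintf("ex%03d", seq_along(seqs)),
    sequence = seqs,
    exon_start = flank,
    exon_end = nchar(seqs) - flank
  )
}

# random background exon set over A/C/G/T
random_exon_set <- function(n, exon_len = 60, flank = 0, seed = 1) {
  withr::with_seed(seed, {
    total <- exon_len + 2 * flank
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), total, replace = TRUE), collapse = "")
    }, character(1))
    make_exon_set(seqs, flank = flank)
  })
}

# noise-free 4PL viability curve at given concentrations
pl4_curve <- function(conc, top = 1, bottom = 0, ec50 = 1e-7, hill = 1,
                      reps = 1) {
  v <- bottom + (top - bottom) / (1 + (conc / ec50)^hill)
  tibble::tibble(
    concentration = rep(conc, each = reps),
    viability = rep(v, each = reps)
  )
}
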