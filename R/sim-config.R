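#' Simulation configuration with planted ground truth
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults describe the study designs the generators emulate: a
#' clone-versus-control splicing comparison read out as junction counts, exon
#' sequences with SSNG enhancer motifs planted at an elevated rate, five-point
#' dose-response series spanning 0.001--10 uM, and deep amplicon sequencing of
#' a heterozygous-range variant on a triploid locus.
#'
#' @param n_events Number of alternative-splicing events to simulate.
#' @param psi_base Baseline (wild-type) inclusion level Psi per event, in
#'   `[0, 1]`. Either a scalar, a vector of length `n_events`, or `NULL`
#'   (default) to draw each event's baseline uniformly from `[0.2, 0.8]`.
#' @param delta_psi Magnitude of the planted inclusion change for "true"
#'   events, in `[0, 1]`. The sign is drawn per event; clamping at the unit
#'   interval is avoided by flipping the sign where the baseline leaves no
#'   room, so the planted effect is always fully realized.
#' @param fraction_true Fraction of events planted with a real inclusion
#'   change; the rest are null.
#' @param read_depth Junction reads per event and sample (inclusion +
#'   exclusion evidence).
#' @param n_samples_per_condition Libraries per condition. The default 1
#'   mirrors a one-clone-versus-one-control comparison.
#' @param motif_rate_increased,motif_rate_decreased Expected number of motifs
#'   planted per exon: CCNG motifs in increased-inclusion exons and GGNG
#'   motifs in decreased-inclusion exons.
#' @param exon_len,flank_len Exon and flank lengths in nucleotides.
#' @param dr_top,dr_bottom,dr_ec50,dr_hill Four-parameter-logistic truth for
#'   simulated dose-response curves: upper/lower asymptote on the
#'   fraction-of-control scale, EC50 in molar, and Hill slope.
#' @param concentrations Tested concentrations in molar, strictly ascending.
#'   Default: five points, equal log-steps from 1 nM to 10 uM.
#' @param n_replicates Replicate wells per concentration.
#' @param n_dmso Vehicle-control wells per sample.
#' @param noise_sd Additive Gaussian noise on the viability signal, as a
#'   fraction of the control signal.
#' @param vaf_true True variant allele frequency for amplicon simulation.
#' @param amplicon_depth Reads per amplicon sample.
#' @param seed Master seed. Every generator derives its own RNG stream from
#'   this seed and a stable label, so outputs are byte-identical under a
#'   fixed seed and adding one output never perturbs another.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_events = 50, seed = 7)
#' cfg$read_depth
#' @export
sim_config <- function(n_events = 200,
                       psi_base = NULL,
                       delta_psi = 0.3,
                       fraction_true = 0.5,
                       read_depth = 200,
                       n_samples_per_condition = 1,
                       motif_rate_increased = 3,
                       motif_rate_decreased = 3,
                       exon_len = 100,
                       flank_len = 100,
                       dr_top = 1,
                       dr_bottom = 0,
                       dr_ec50 = 1e-7,
                       dr_hill = 1,
                       concentrations = 10^seq(-9, -5, length.out = 5),
                       n_replicates = 3,
                       n_dmso = 6,
                       noise_sd = 0.02,
                       vaf_true = 2 / 3,
                       amplicon_depth = 10000,
                       seed = 1L) {
  check_count(n_events, "n_events")
  if (!is.null(psi_base)) {
    check_fraction(psi_base, "psi_base")
    if (!length(psi_base) %in% c(1L, n_events)) {
      abort("`psi_base` must be scalar or length `n_events`.")
    }
  }
  check_fraction(delta_psi, "delta_psi")
  check_fraction(fraction_true, "fraction_true")
  check_count(read_depth, "read_depth")
  check_count(n_samples_per_condition, "n_samples_per_condition")
  if (motif_rate_increased < 0) abort("`motif_rate_increased` must be >= 0.")
  if (motif_rate_decreased < 0) abort("`motif_rate_decreased` must be >= 0.")
  check_count(exon_len, "exon_len")
  if (exon_len < 8) abort("`exon_len` must be at least 8 nt.")
  check_count(flank_len, "flank_len", positive = FALSE)
  if (dr_hill == 0) abort("`dr_hill` must be nonzero (flat curves are degenerate).")
  if (length(concentrations) < 4 || any(diff(concentrations) <= 0)) {
    abort("`concentrations` must be >= 4 strictly ascending values.")
  }
  if (any(concentrations <= 0)) abort("`concentrations` must be positive molar values.")
  check_count(n_replicates, "n_replicates")
  check_count(n_dmso, "n_dmso")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  check_fraction(vaf_true, "vaf_true")
  check_count(amplicon_depth, "amplicon_depth")
  stopifnot(length(seed) == 1L, is.finite(seed))

  structure(
    list(
      n_events = as.integer(n_events), psi_base = psi_base,
      delta_psi = delta_psi, fraction_true = fraction_true,
      read_depth = as.integer(read_depth),
      n_samples_per_condition = as.integer(n_samples_per_condition),
      motif_rate_increased = motif_rate_increased,
      motif_rate_decreased = motif_rate_decreased,
      exon_len = as.integer(exon_len), flank_len = as.integer(flank_len),
      dr_top = dr_top, dr_bottom = dr_bottom, dr_ec50 = dr_ec50,
      dr_hill = dr_hill, concentrations = concentrations,
      n_replicates = as.integer(n_replicates), n_dmso = as.integer(n_dmso),
      noise_sd = noise_sd, vaf_true = vaf_true,
      amplicon_depth = as.integer(amplicon_depth), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  splicing : %d events, depth %d, |dPsi| %.2f, %d%% true, %d sample(s)/condition\n",
              x$n_events, x$read_depth, x$delta_psi,
              round(100 * x$fraction_true), x$n_samples_per_condition))
  cat(sprintf("  sequence : exon %d nt + %d nt flanks; planted CCNG %.2g / GGNG %.2g per exon\n",
              x$exon_len, x$flank_len, x$motif_rate_increased, x$motif_rate_decreased))
  cat(sprintf("  dose     : %d concentrations %.3g-%.3g M, %d reps, noise sd %.3g\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), x$n_replicates, x$noise_sd))
  cat(sprintf("  amplicon : VAF %.3f at depth %d\n", x$vaf_true, x$amplicon_depth))
  cat(sprintf("  seed     : %d\n", x$seed))
  invisible(x)
}
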