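SPLICE_CLASSES <- c("CE", "RI", "MXE", "A5SS", "A3SS")

#' Simulate a clone-versus-control splicing dataset
#'
#' Generates alternative-splicing events, per-sample junction read counts, and
#' a truth table. Each event has a wild-type inclusion level `psi_wt`; a
#' planted fraction of events carries a real inclusion change
#' `psi_mut = psi_wt + delta` with the sign chosen so the mutant level stays
#' inside `[0, 1]` without truncation. Inclusion reads are drawn as
#' `Binomial(read_depth, psi)` per event and sample; exclusion reads make up
#' the remainder, so inclusion + exclusion equals the depth exactly.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"splicing_sim"` with tibbles `events` (id, gene,
#'   class, BED-style 0-based half-open coordinates), `samples` (sample id and
#'   condition, `"wt"` or `"mut"`), `counts` (event x sample junction
#'   evidence), and `truth` (per-event planted `psi_wt`, `psi_mut`, signed
#'   `delta_psi`, and `is_true` flag).
#' @examples
#' sim <- sim_splicing(sim_config(n_events = 20, seed = 3))
#' head(sim$counts)
#' @export
sim_splicing <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "splicing", {
    n <- cfg$n_events
    ids <- sprintf("EV%05d", seq_len(n))
    event_class <- sample(SPLICE_CLASSES, n, replace = TRUE)
    starts <- sort(sample.int(2e8, n))
    events <- tibble(
      event_id = ids,
      gene = sprintf("GENE%05d", seq_len(n)),
      event_class = event_class,
      chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
      start = starts,
      end = starts + cfg$exon_len,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )

    psi_wt <- if (is.null(cfg$psi_base)) {
      runif(n, 0.2, 0.8)
    } else {
      rep_len(cfg$psi_base, n)
    }
    # a zero planted effect means there are no "true" events to list
    n_true <- if (cfg$delta_psi > 0) round(cfg$fraction_true * n) else 0L
    is_true <- rep(FALSE, n)
    if (n_true > 0) is_true[sample.int(n, n_true)] <- TRUE

    sign <- ifelse(runif(n) < 0.5, -1, 1)
    # flip the sign where the planted shift would leave [0, 1]
    sign <- ifelse(psi_wt + sign * cfg$delta_psi > 1, -1,
                   ifelse(psi_wt + sign * cfg$delta_psi < 0, 1, sign))
    delta <- ifelse(is_true, sign * cfg$delta_psi, 0)
    psi_mut <- pmin(1, pmax(0, psi_wt + delta))

    truth <- tibble(
      event_id = ids, event_class = event_class, is_true = is_true,
      psi_wt = psi_wt, psi_mut = psi_mut, delta_psi = psi_mut - psi_wt
    )

    n_s <- cfg$n_samples_per_condition
    samples <- tibble(
      sample_id = c(sprintf("wt_%02d", seq_len(n_s)),
                    sprintf("mut_%02d", seq_len(n_s))),
      condition = rep(c("wt", "mut"), each = n_s)
    )

    counts <- tidyr::crossing(event_id = ids, sample_id = samples$sample_id) |>
      left_join(samples, by = "sample_id") |>
      left_join(truth[, c("event_id", "psi_wt", "psi_mut")], by = "event_id") |>
      mutate(
        psi = ifelse(.data$condition == "mut", .data$psi_mut, .data$psi_wt),
        inclusion_reads = rbinom(n(), cfg$read_depth, .data$psi),
        exclusion_reads = cfg$read_depth - .data$inclusion_reads
      ) |>
      select("event_id", "sample_id", "inclusion_reads", "exclusion_reads") |>
      arrange(.data$event_id, .data$sample_id)

    structure(list(events = events, samples = samples, counts = counts,
                   truth = truth, config = cfg),
              class = "splicing_sim")
  })
}

#' Simulate exon sequences with planted splicing-enhancer motifs
#'
#' Builds flank-exon-flank sequences with uniform A/C/G/T background, then
#' plants CCNG motifs in exons labelled `"increased"` (at
#' `motif_rate_increased` expected motifs per exon) and GGNG motifs in exons
#' labelled `"decreased"` (at `motif_rate_decreased`). Planted motif counts
#' are Poisson draws; positions are rejection-sampled so motifs never overlap
#' each other and always lie fully inside the exon, never straddling a splice
#' site.
#'
#' @param events A data frame with columns `event_id` and `direction`
#'   (values in `"increased"`, `"decreased"`; other rows get background-only
#'   sequence). Typically `sim$truth` with a direction derived from the sign
#'   of `delta_psi`, or a constructed label table.
#' @param cfg A [sim_config()]; uses `exon_len`, `flank_len`, the two motif
#'   rates, and the seed.
#' @return A list of class `"exon_seq_sim"` with `sequences`, a tibble usable
#'   directly by the motif-enrichment functions (`exon_id`, `direction`,
#'   `sequence`, `exon_start`, `exon_end` -- 0-based half-open within the
#'   record), and `truth`, the planted per-exon motif counts and positions.
#' @examples
#' labs <- tibble::tibble(event_id = c("a", "b"),
#'                        direction = c("increased", "decreased"))
#' sim <- sim_exon_sequences(labs, sim_config(seed = 5))
#' sim$sequences
#' @export
sim_exon_sequences <- function(events, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  check_cols(events, c("event_id", "direction"), "events")
  L <- cfg$exon_len
  Fl <- cfg$flank_len

  with_stream(cfg$seed, "sequences", {
    n <- nrow(events)
    rate <- ifelse(events$direction == "increased", cfg$motif_rate_increased,
                   ifelse(events$direction == "decreased", cfg$motif_rate_decreased, 0))
    n_plant <- rpois(n, rate)
    if (any(4L * n_plant > L)) {
      abort(sprintf(
        "Planted motif load exceeds exon capacity (need %d nt, exon is %d nt); lower the motif rate or lengthen the exon.",
        max(4L * n_plant), L))
    }
    core <- ifelse(events$direction == "decreased", "GG", "CC")

    seqs <- character(n)
    planted <- vector("list", n)
    total_len <- L + 2L * Fl
    for (i in seq_len(n)) {
      s <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
      pos <- integer(0)
      k <- n_plant[i]
      attempts <- 0L
      while (length(pos) < k) {
        cand <- sample.int(L - 3L, 1L) - 1L  # 0-based start within exon
        if (all(abs(cand - pos) >= 4L)) pos <- c(pos, cand)
        attempts <- attempts + 1L
        if (attempts > 1000L) {
          abort("Could not place non-overlapping motifs; rate too high for exon length.")
        }
      }
      for (p in pos) {
        s[Fl + p + seq_len(4L)] <- c(substring(core[i], 1, 1),
                                     substring(core[i], 2, 2),
                                     sample(c("A", "C", "G", "T"), 1L), "G")
      }
      seqs[i] <- paste(s, collapse = "")
      planted[[i]] <- sort(pos)
    }

    sequences <- tibble(
      exon_id = events$event_id,
      direction = events$direction,
      sequence = seqs,
      exon_start = Fl,
      exon_end = Fl + L
    )
    truth <- tibble(
      exon_id = events$event_id,
      motif_class = ifelse(rate > 0, ifelse(core == "CC", "CCNG", "GGNG"), NA_character_),
      n_planted = n_plant,
      positions = planted
    )
    structure(list(sequences = sequences, truth = truth, config = cfg),
              class = "exon_seq_sim")
  })
}

#' Simulate plate-style dose-response viability tables
#'
#' Produces raw viability signal for one or more samples treated across a
#' concentration series, following a four-parameter logistic (Hill) curve with
#' additive Gaussian noise, plus vehicle (DMSO) control wells at the upper
#' asymptote. The raw signal is on an arbitrary luminescence-like scale
#' (control mean 1000), so downstream DMSO normalization is exercised.
#'
#' @param cfg A [sim_config()]; `dr_top`, `dr_bottom`, `dr_ec50`, `dr_hill`
#'   may be vectors, one entry per curve (recycled across `n_curves`).
#' @param n_curves Number of sample curves to generate.
#' @param drug Drug label recorded in the table.
#' @return A list of class `"dose_sim"` with `viability`, a tibble of raw
#'   wells (`sample_id`, `drug`, `concentration` in molar, `replicate`,
#'   `signal`, `is_dmso`), and `truth`, the per-curve 4PL parameters with an
#'   `ec50_in_range` flag marking EC50s outside the tested span.
#' @examples
#' sim <- sim_dose_response(sim_config(noise_sd = 0, seed = 2))
#' head(sim$viability)
#' @export
sim_dose_response <- function(cfg, n_curves = 1L, drug = "drugA") {
  stopifnot(inherits(cfg, "sim_config"))
  conc <- cfg$concentrations
  scale <- 1000
  top <- rep_len(cfg$dr_top, n_curves)
  bottom <- rep_len(cfg$dr_bottom, n_curves)
  ec50 <- rep_len(cfg$dr_ec50, n_curves)
  hill <- rep_len(cfg$dr_hill, n_curves)
  if (any(hill == 0)) abort("`dr_hill` must be nonzero (flat curves are degenerate).")

  with_stream(cfg$seed, "dose_response", {
    out <- purrr::map(seq_len(n_curves), function(i) {
      sid <- sprintf("S%03d", i)
      mu <- bottom[i] + (top[i] - bottom[i]) / (1 + (conc / ec50[i])^hill[i])
      drug_wells <- tidyr::crossing(concentration = conc,
                                    replicate = seq_len(cfg$n_replicates)) |>
        mutate(
          sample_id = sid, drug = drug, is_dmso = FALSE,
          signal = scale * (rep(mu, each = cfg$n_replicates) +
                              rnorm(n(), 0, cfg$noise_sd))
        )
      dmso_wells <- tibble(
        concentration = 0, replicate = seq_len(cfg$n_dmso),
        sample_id = sid, drug = drug, is_dmso = TRUE,
        signal = scale * (top[i] + rnorm(cfg$n_dmso, 0, cfg$noise_sd))
      )
      bind_rows(drug_wells, dmso_wells)
    }) |>
      bind_rows() |>
      select("sample_id", "drug", "concentration", "replicate", "signal", "is_dmso")

    truth <- tibble(
      sample_id = sprintf("S%03d", seq_len(n_curves)), drug = drug,
      top = top, bottom = bottom, ec50 = ec50, hill = hill,
      ec50_in_range = ec50 >= min(conc) & ec50 <= max(conc)
    )
    structure(list(viability = out, truth = truth, config = cfg),
              class = "dose_sim")
  })
}

#' Simulate amplicon-sequencing allele counts
#'
#' Draws alt-allele read counts as `Binomial(amplicon_depth, vaf_true)` per
#' sample; reference reads make up the remainder, so ref + alt equals the
#' depth exactly.
#'
#' @param cfg A [sim_config()]; `vaf_true` may be a vector, one entry per
#'   sample (recycled across `n_samples`).
#' @param n_samples Number of amplicon samples.
#' @return A list of class `"amplicon_sim"` with `counts` (tibble:
#'   `sample_id`, `ref_reads`, `alt_reads`) and `truth` (`sample_id`,
#'   `vaf_true`).
#' @examples
#' sim_amplicon(sim_config(vaf_true = 0.5, seed = 4), n_samples = 3)$counts
#' @export
sim_amplicon <- function(cfg, n_samples = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  vaf <- rep_len(cfg$vaf_true, n_samples)
  with_stream(cfg$seed, "amplicon", {
    alt <- rbinom(n_samples, cfg$amplicon_depth, vaf)
    counts <- tibble(
      sample_id = sprintf("clone_%02d", seq_len(n_samples)),
      ref_reads = cfg$amplicon_depth - alt,
      alt_reads = alt
    )
    truth <- tibble(sample_id = counts$sample_id, vaf_true = vaf)
    structure(list(counts = counts, truth = truth, config = cfg),
              class = "amplicon_sim")
  })
}
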