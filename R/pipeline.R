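#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the stages behind one call: `simulate` writes every input
#' with planted truth (events BED6, junction-count TSV, exon FASTA,
#' viability TSV, amplicon TSV, truth JSONs); `splice` produces
#' differential-inclusion calls and the per-class summary; `motif` produces
#' SSNG enrichment and metagene profiles from the exon FASTA; `dose`
#' normalizes viability and derives DSS and 4PL IC50 per curve; `genotype`
#' computes VAF and mutant-allele copies. Each output TSV gets a JSON
#' sidecar with the parameters and seed that produced it, and the run ends
#' with a machine-readable report. Later stages read the files earlier
#' stages wrote, so a stage-only run reuses existing outputs; all
#' randomness derives from the config seed, making the whole run
#' reproducible byte for byte.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param out_dir Output directory, created if needed.
#' @param stages Character vector of stages, subset of `"simulate"`,
#'   `"splice"`, `"motif"`, `"dose"`, `"genotype"`, or `"all"`.
#' @param delta_threshold,bf_threshold Differential-calling thresholds.
#' @param dss_threshold DSS activity threshold (percent inhibition).
#' @param window Metagene window, `c(exonic = , intronic = )` in nt.
#' @param n_bootstrap Metagene bootstrap replicates.
#' @param n_curves Dose-response curves to simulate.
#' @param n_amplicon_samples Amplicon samples to simulate.
#' @param verbose Print per-stage progress.
#' @return The run report (a list), invisibly; also written to
#'   `run_report.json` in `out_dir`.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' rep <- run_pipeline(sim_config(n_events = 30, seed = 5), dir,
#'                     n_bootstrap = 20)
#' names(rep$stages)
#' }
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir,
                         stages = "all",
                         delta_threshold = 0.10, bf_threshold = 5,
                         dss_threshold = 10,
                         window = c(exonic = 25, intronic = 25),
                         n_bootstrap = 200,
                         n_curves = 4,
                         n_amplicon_samples = 14,
                         verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  all_stages <- c("simulate", "splice", "motif", "dose", "genotype")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  say <- function(...) if (verbose) message(sprintf(...))

  need <- function(path) {
    if (!file.exists(path)) {
      abort(sprintf("Required input '%s' not found; run the producing stage first.", path))
    }
    path
  }
  sidecar <- function(path, params) {
    jsonlite::write_json(
      c(list(seed = config$seed,
             package = paste0("splicedose ", packageVersion("splicedose"))),
        params),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  report <- list(seed = config$seed, config_hash = config_hash(config),
                 stages = list())
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    say("stage %s ...", name)
    n_rec <- fn()
    report$stages[[name]] <<- list(records = n_rec,
                                   elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sp <- sim_splicing(config)
    write_events_bed(sp$events, pth("events.bed"))
    write_tsv_commented(sp$counts, pth("junction_counts.tsv"),
                        list(seed = config$seed, depth = config$read_depth))
    write_tsv_commented(sp$samples, pth("samples.tsv"), list(seed = config$seed))
    write_truth_json(sp$truth, pth("truth_splicing.json"))

    labels <- sp$truth |>
      mutate(direction = ifelse(!.data$is_true, "none",
                                ifelse(.data$delta_psi > 0, "increased", "decreased"))) |>
      select("event_id", "direction")
    sq <- sim_exon_sequences(labels, config)
    write_exon_fasta(sq$sequences, pth("exons.fa"))
    write_truth_json(sq$truth[, c("exon_id", "motif_class", "n_planted")],
                     pth("truth_motifs.json"))

    dr <- sim_dose_response(config, n_curves = n_curves)
    write_tsv_commented(dr$viability, pth("viability.tsv"),
                        list(seed = config$seed, noise_sd = config$noise_sd))
    write_truth_json(dr$truth, pth("truth_dose.json"))

    am <- sim_amplicon(config, n_samples = n_amplicon_samples)
    write_tsv_commented(am$counts, pth("amplicon_counts.tsv"),
                        list(seed = config$seed, depth = config$amplicon_depth))
    write_truth_json(am$truth, pth("truth_vaf.json"))
    sidecar(pth("junction_counts.tsv"),
            list(n_events = config$n_events, read_depth = config$read_depth))
    nrow(sp$counts)
  })

  if ("splice" %in% stages) run_stage("splice", function() {
    counts <- read_tsv_commented(need(pth("junction_counts.tsv")))
    samples <- read_tsv_commented(need(pth("samples.tsv")))
    events <- read_events_bed(need(pth("events.bed")))
    calls <- diff_splicing(counts, samples, events = events,
                           delta_threshold = delta_threshold,
                           bf_threshold = bf_threshold)
    write_tsv_commented(calls, pth("splicing_calls.tsv"),
                        list(delta_threshold = delta_threshold,
                             bf_threshold = bf_threshold,
                             replicate_handling = attr(calls, "pooled")))
    sidecar(pth("splicing_calls.tsv"),
            list(delta_threshold = delta_threshold, bf_threshold = bf_threshold))
    cls <- summarize_by_class(calls, events)
    write_tsv_commented(cls, pth("class_summary.tsv"), list())
    nrow(calls)
  })

  if ("motif" %in% stages) run_stage("motif", function() {
    sq <- read_exon_fasta(need(pth("exons.fa")))
    inc <- filter(sq, .data$direction == "increased")
    dec <- filter(sq, .data$direction == "decreased")
    enr <- mean_enrichment(inc, dec)
    write_tsv_commented(enr, pth("motif_enrichment.tsv"),
                        list(pseudocount = attr(enr, "pseudocount")))
    sidecar(pth("motif_enrichment.tsv"), list(n_increased = nrow(inc),
                                              n_decreased = nrow(dec)))
    mg_seed <- stream_seed(config$seed, "metagene_bootstrap")
    mg <- metagene_profile(inc, dec, motif_class = "CCNG", window = window,
                           n_bootstrap = n_bootstrap, seed = mg_seed)
    write_tsv_commented(as_tibble(mg), pth("metagene_ccng.tsv"),
                        list(n_bootstrap = n_bootstrap, seed = mg_seed,
                             window_exonic = window[["exonic"]],
                             window_intronic = window[["intronic"]]))
    nrow(enr)
  })

  if ("dose" %in% stages) run_stage("dose", function() {
    raw <- read_tsv_commented(need(pth("viability.tsv")))
    curves <- normalize_viability(raw)
    dss <- compute_dss(curves, threshold = dss_threshold)
    fits <- curves |>
      group_by(.data$sample_id, .data$drug) |>
      dplyr::group_modify(~ glance(fit_4pl(.x))) |>
      ungroup()
    out <- left_join(dss, fits, by = c("sample_id", "drug"))
    write_tsv_commented(out, pth("dose_response_scores.tsv"),
                        list(dss_threshold = dss_threshold))
    sidecar(pth("dose_response_scores.tsv"), list(dss_threshold = dss_threshold))
    nrow(out)
  })

  if ("genotype" %in% stages) run_stage("genotype", function() {
    am <- read_tsv_commented(need(pth("amplicon_counts.tsv")))
    vaf <- compute_vaf(am)
    out <- dplyr::bind_cols(vaf,
                            infer_allele_copies(vaf$vaf)[, c("vaf_percent",
                                                             "mutant_copies",
                                                             "total_copies")])
    write_tsv_commented(out, pth("allele_copies.tsv"), list(total_copies = 3))
    sidecar(pth("allele_copies.tsv"), list(total_copies = 3))
    nrow(out)
  })

  jsonlite::write_json(report, pth("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done; report at %s", pth("run_report.json"))
  invisible(report)
}

# Polynomial rolling hash of the deparsed config; stable across sessions
# for identical configs, used only as a provenance fingerprint.
config_hash <- function(config) {
  u <- unclass(config)
  s <- paste(deparse(u[order(names(u))]), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}
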