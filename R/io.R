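# Plain-text IO: TSV with provenance header comments, BED6 for event
# coordinates, FASTA for exon sequences, JSON for truth tables and reports.

#' Write a table as TSV with provenance header comments
#'
#' Prepends `# key=value` comment lines (parameters, seeds, package version)
#' before a standard header+data TSV, so every output records how it was
#' made.
#'
#' @param x Data frame to write. List-columns are not supported.
#' @param path Output path.
#' @param meta Named list of provenance values written as `# key=value`.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, meta = list()) {
  meta <- c(list(package = paste0("splicedose ", packageVersion("splicedose")),
                 written = "seeded-deterministic"), meta)
  hdr <- sprintf("# %s=%s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = ","), ""))
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path Input path; `# `-prefixed lines are treated as comments.
#' @return A tibble; parsed provenance is attached as attribute `"meta"`.
#' @export
read_tsv_commented <- function(path) {
  lines <- readLines(path, n = 50)
  meta_lines <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                   vapply(kv, `[`, "", 1))
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "meta") <- meta
  out
}

#' Write splicing events as BED6
#'
#' Coordinates are 0-based half-open; the name field carries
#' `event_id|event_class` so the class survives the round trip, score is 0,
#' and the strand column is used.
#'
#' @param events Event tibble (`event_id`, `event_class`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  check_cols(events, c("event_id", "event_class", "chrom", "start", "end",
                       "strand"), "events")
  bed <- tibble(
    chrom = events$chrom, start = events$start, end = events$end,
    name = paste(events$event_id, events$event_class, sep = "|"),
    score = 0L, strand = events$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read splicing events from BED6 written by [write_events_bed()]
#'
#' @param path Input BED6 path.
#' @return An event tibble with `event_id`, `event_class`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_events_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE, progress = FALSE)
  parts <- stringr::str_split_fixed(bed$name, stringr::fixed("|"), 2)
  tibble(
    event_id = parts[, 1],
    event_class = parts[, 2],
    chrom = bed$chrom, start = bed$start, end = bed$end, strand = bed$strand
  )
}

#' Write exon sequence sets as FASTA
#'
#' The record id is the exon id; the description carries the exon interval
#' within the record (0-based half-open) and the inclusion-direction label,
#' e.g. `exon=100-200 dir=increased`.
#'
#' @param sequences Exon sequence tibble (`exon_id`, `sequence`,
#'   `exon_start`, `exon_end`, optional `direction`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_exon_fasta <- function(sequences, path) {
  check_cols(sequences, c("exon_id", "sequence", "exon_start", "exon_end"),
             "sequences")
  dir <- sequences$direction %||% rep("NA", nrow(sequences))
  ss <- Biostrings::DNAStringSet(sequences$sequence)
  names(ss) <- sprintf("%s exon=%d-%d dir=%s", sequences$exon_id,
                       sequences$exon_start, sequences$exon_end, dir)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

#' Read exon sequence sets from FASTA written by [write_exon_fasta()]
#'
#' @param path Input FASTA path.
#' @return An exon sequence tibble (`exon_id`, `direction`, `sequence`,
#'   `exon_start`, `exon_end`).
#' @export
read_exon_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  id <- sub(" .*$", "", hdr)
  iv <- stringr::str_match(hdr, "exon=(\\d+)-(\\d+)")
  dir <- stringr::str_match(hdr, "dir=(\\S+)")[, 2]
  tibble(
    exon_id = id,
    direction = ifelse(is.na(dir) | dir == "NA", NA_character_, dir),
    sequence = unname(as.character(ss)),
    exon_start = as.integer(iv[, 2]),
    exon_end = as.integer(iv[, 3])
  )
}

#' Write a truth table (or any list) as JSON
#'
#' @param truth A list or data frame of planted ground truth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
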