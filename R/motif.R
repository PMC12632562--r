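#' SSNG exonic-splicing-enhancer motif variants
#'
#' Expands the SSNG consensus (S = G or C at positions 1-2, any base at
#' position 3, G at position 4) into its 16 concrete 4-mers, optionally
#' restricted to one S-S class.
#'
#' @param class `"all"` (16 variants) or one of `"CCNG"`, `"CGNG"`,
#'   `"GCNG"`, `"GGNG"` (4 variants each).
#' @return Character vector of 4-mer patterns.
#' @examples
#' ssng_motifs("CCNG")
#' @export
ssng_motifs <- function(class = c("all", "CCNG", "CGNG", "GCNG", "GGNG")) {
  class <- match.arg(class)
  ss <- if (class == "all") c("CC", "CG", "GC", "GG") else substr(class, 1, 2)
  as.vector(t(outer(ss, c("A", "C", "G", "T"),
                    function(s, n) paste0(s, n, "G"))))
}

check_sequences <- function(x, name = "sequences") {
  if (any(grepl("[^ACGTN]", x))) {
    abort(sprintf("`%s` must be uppercase A/C/G/T (N allowed, never matches).", name))
  }
  invisible(x)
}

#' Count SSNG motif occurrences in sequences
#'
#' Slides a 4-nt window over each sequence and counts every occurrence of
#' each pattern; overlapping occurrences are all counted, and windows
#' containing `N` never match. Counts are zero-filled across all requested
#' patterns.
#'
#' @param x Character vector of sequences over `A/C/G/T/N` (uppercase), or a
#'   [Biostrings::DNAStringSet].
#' @param patterns Patterns to count; defaults to the 16 SSNG variants.
#' @return A tibble in long form: `seq_id`, `motif`, `count`.
#' @examples
#' count_motifs("CCAGCCTG")          # CCAG and CCTG once each
#' count_motifs("GGGGG", "GGGG")     # overlapping windows: count 2
#' @export
count_motifs <- function(x, patterns = ssng_motifs()) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  ids <- names(x) %||% sprintf("seq%d", seq_along(x))
  ids[ids == ""] <- sprintf("seq%d", which(ids == ""))
  check_sequences(x)
  counts <- count_matrix(x, patterns)
  tibble(
    seq_id = rep(ids, each = length(patterns)),
    motif = rep(patterns, times = length(x)),
    count = as.vector(counts)
  )
}

# patterns x sequences count matrix (overlapping hits; N never matches)
count_matrix <- function(seqs, patterns) {
  subj <- Biostrings::DNAStringSet(ifelse(nchar(seqs) == 0, "N", seqs))
  pd <- Biostrings::PDict(patterns)
  m <- Biostrings::vcountPDict(pd, subj)
  rownames(m) <- patterns
  m
}

# 0-based match start positions of `patterns` in one sequence; a
# zero-width lookahead captures overlapping occurrences, and windows
# containing N can never match the concrete A/C/G/T patterns
match_starts <- function(seq, patterns) {
  if (nchar(seq) < 4) return(integer(0))
  hits <- lapply(patterns, function(p) {
    m <- gregexpr(sprintf("(?=%s)", p), seq, perl = TRUE)[[1]]
    m[m > 0]
  })
  sort(unlist(hits)) - 1L
}

check_exon_set <- function(x, name) {
  check_cols(x, c("exon_id", "sequence", "exon_start", "exon_end"), name)
  if (nrow(x) == 0) {
    abort(sprintf(
      "`%s` is empty: enrichment over an empty exon set is undefined (the pseudocount guards zero counts, not zero exons).", name))
  }
  check_sequences(x$sequence, paste0(name, "$sequence"))
  if (any(x$exon_start < 0 | x$exon_end > nchar(x$sequence) |
            x$exon_start >= x$exon_end)) {
    abort(sprintf("`%s` has exon intervals outside the record bounds.", name))
  }
  invisible(x)
}

exon_only <- function(x) substr(x$sequence, x$exon_start + 1L, x$exon_end)

#' Mean enrichment of SSNG motifs in increased- vs decreased-inclusion exons
#'
#' For each motif variant, totals occurrences within the exon intervals
#' (flanks excluded) of the increased-inclusion set and of the
#' decreased-inclusion set, and reports their ratio: the mean enrichment of
#' the motif among exons whose inclusion rises under the mutation relative to
#' exons whose inclusion falls. A pseudocount is added to both numerator and
#' denominator so the ratio is always defined; per-exon-normalized rates
#' (totals divided by set sizes) are also reported for use when the two sets
#' differ in size.
#'
#' @param increased,decreased Exon sequence sets: data frames with `exon_id`,
#'   `sequence` (uppercase A/C/G/T/N), `exon_start`, `exon_end` (0-based
#'   half-open within the record). Both must be non-empty.
#' @param motifs Patterns to score (default: all 16 SSNG variants).
#' @param by `"motif"` for one row per variant, `"class"` to aggregate
#'   counts over the four S-S classes (CCNG, CGNG, GCNG, GGNG).
#' @param pseudocount Added to both totals before the ratio; default 1.
#' @param n_bootstrap If > 0, percentile-bootstrap confidence intervals for
#'   `mean_enrichment` by resampling exons with replacement within each set.
#' @param seed RNG seed for the bootstrap (required when `n_bootstrap > 0`).
#' @param conf_level Bootstrap confidence level.
#' @return A tibble with `motif` (or `motif_class`), `count_increased`,
#'   `count_decreased`, `rate_increased`, `rate_decreased` (per-exon),
#'   `mean_enrichment`, `log2_enrichment`, and bootstrap `ci_low`/`ci_high`
#'   when requested.
#' @examples
#' set.seed(1)
#' mk <- function(n) tibble::tibble(
#'   exon_id = paste0("e", seq_len(n)),
#'   sequence = vapply(seq_len(n), function(i)
#'     paste(sample(c("A","C","G","T"), 60, TRUE), collapse = ""), ""),
#'   exon_start = 0, exon_end = 60)
#' mean_enrichment(mk(5), mk(5), by = "class")
#' @export
mean_enrichment <- function(increased, decreased, motifs = ssng_motifs(),
                            by = c("motif", "class"), pseudocount = 1,
                            n_bootstrap = 0, seed = NULL, conf_level = 0.95) {
  by <- match.arg(by)
  check_exon_set(increased, "increased")
  check_exon_set(decreased, "decreased")
  if (n_bootstrap > 0 && is.null(seed)) {
    abort("Supply `seed` when requesting bootstrap intervals.")
  }

  m_inc <- count_matrix(exon_only(increased), motifs)  # motif x exon
  m_dec <- count_matrix(exon_only(decreased), motifs)
  if (by == "class") {
    cls <- substr(motifs, 1, 2)
    m_inc <- rowsum(m_inc, paste0(cls, "NG"))
    m_dec <- rowsum(m_dec, paste0(cls, "NG"))
  }

  ratio <- function(a, b) (a + pseudocount) / (b + pseudocount)
  ci <- unname(rowSums(m_inc)); cd <- unname(rowSums(m_dec))
  out <- tibble(
    motif = rownames(m_inc),
    count_increased = as.integer(ci),
    count_decreased = as.integer(cd),
    rate_increased = ci / nrow(increased),
    rate_decreased = cd / nrow(decreased),
    mean_enrichment = ratio(ci, cd),
    log2_enrichment = log2(ratio(ci, cd))
  )
  if (by == "class") out <- rename(out, motif_class = "motif")

  if (n_bootstrap > 0) {
    qs <- withr::with_seed(seed, {
      reps <- vapply(seq_len(n_bootstrap), function(b) {
        i <- sample.int(ncol(m_inc), replace = TRUE)
        j <- sample.int(ncol(m_dec), replace = TRUE)
        ratio(rowSums(m_inc[, i, drop = FALSE]),
              rowSums(m_dec[, j, drop = FALSE]))
      }, numeric(nrow(m_inc)))
      apply(matrix(reps, nrow = nrow(m_inc)), 1, quantile,
            probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
    })
    out$ci_low <- qs[1, ]
    out$ci_high <- qs[2, ]
    attr(out, "n_bootstrap") <- n_bootstrap
    attr(out, "seed") <- seed
  }
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Positional metagene enrichment profile around cassette-exon splice sites
#'
#' Anchors two windows on each exon -- one at the 3' splice site (exon
#' start) and one at the 5' splice site (exon end) -- and, at every
#' nucleotide offset, totals motif start positions within the
#' increased-inclusion and decreased-inclusion sets. The profile value is
#' `log2((count_inc + pc) / (count_dec + pc))` per offset; positive values
#' mean the motif class is enriched among exons gaining inclusion.
#' Confidence bands come from a percentile bootstrap that resamples exons
#' with replacement within each set.
#'
#' Offsets are 0-based relative to the splice-site junction: at the 3' splice
#' site, intronic positions are `-window["intronic"] .. -1` and exonic
#' positions `0 .. window["exonic"] - 1`; the 5' splice site mirrors this
#' (exonic negative, intronic non-negative).
#'
#' @inheritParams mean_enrichment
#' @param motif_class `"CCNG"` or `"GGNG"` (or another S-S class).
#' @param window Named vector `c(exonic = , intronic = )`, in nucleotides.
#'   Must fit inside every record's exon and flanks.
#' @param n_bootstrap Bootstrap replicates; 0 for point estimates only (no
#'   CI columns).
#' @return A tibble of class `"metagene_profile"`: `anchor` (`"3ss"` /
#'   `"5ss"`), `offset`, `region`, `count_increased`, `count_decreased`,
#'   `log2_ratio`, plus `ci_low`/`ci_high` when `n_bootstrap > 0`.
#'   Attributes record the motif class, window, bootstrap size and seed.
#' @examples
#' labs <- tibble::tibble(event_id = sprintf("e%d", 1:40),
#'                        direction = rep(c("increased", "decreased"), 20))
#' sq <- sim_exon_sequences(labs, sim_config(seed = 9))$sequences
#' metagene_profile(sq[sq$direction == "increased", ],
#'                  sq[sq$direction == "decreased", ],
#'                  window = c(exonic = 20, intronic = 20),
#'                  n_bootstrap = 50, seed = 1)
#' @export
metagene_profile <- function(increased, decreased,
                             motif_class = c("CCNG", "GGNG", "CGNG", "GCNG"),
                             window = c(exonic = 50, intronic = 50),
                             n_bootstrap = 1000, seed = NULL,
                             pseudocount = 1, conf_level = 0.95) {
  motif_class <- match.arg(motif_class)
  check_exon_set(increased, "increased")
  check_exon_set(decreased, "decreased")
  if (!all(c("exonic", "intronic") %in% names(window))) {
    abort("`window` must be a named vector with `exonic` and `intronic` parts.")
  }
  w_e <- as.integer(window[["exonic"]]); w_i <- as.integer(window[["intronic"]])
  if (n_bootstrap > 0 && is.null(seed)) {
    abort("Supply `seed` when requesting bootstrap intervals.")
  }
  patterns <- ssng_motifs(motif_class)

  check_fit <- function(x, name) {
    bad <- x$exon_start < w_i | (nchar(x$sequence) - x$exon_end) < w_i |
      (x$exon_end - x$exon_start) < w_e
    if (any(bad)) {
      abort(sprintf("Window (%d exonic, %d intronic) exceeds record '%s' in `%s`.",
                    w_e, w_i, x$exon_id[which(bad)[1]], name))
    }
  }
  check_fit(increased, "increased"); check_fit(decreased, "decreased")

  # position layout: per anchor, w_i + w_e offsets
  off_3ss <- seq(-w_i, w_e - 1L)
  off_5ss <- seq(-w_e, w_i - 1L)
  n_pos <- length(off_3ss) + length(off_5ss)

  # exon x position matrix of motif-start counts
  pos_matrix <- function(x) {
    t(vapply(seq_len(nrow(x)), function(k) {
      p0 <- match_starts(x$sequence[k], patterns)
      d3 <- p0 - x$exon_start[k]
      d5 <- p0 - x$exon_end[k]
      c(tabulate(match(d3, off_3ss), length(off_3ss)),
        tabulate(match(d5, off_5ss), length(off_5ss)))
    }, numeric(n_pos)))
  }
  M_inc <- pos_matrix(increased)
  M_dec <- pos_matrix(decreased)

  lr <- function(a, b) log2((a + pseudocount) / (b + pseudocount))
  out <- tibble(
    anchor = rep(c("3ss", "5ss"), c(length(off_3ss), length(off_5ss))),
    offset = c(off_3ss, off_5ss),
    region = c(ifelse(off_3ss < 0, "intron", "exon"),
               ifelse(off_5ss < 0, "exon", "intron")),
    count_increased = colSums(M_inc),
    count_decreased = colSums(M_dec),
    log2_ratio = lr(colSums(M_inc), colSums(M_dec))
  )

  if (n_bootstrap > 0) {
    qs <- withr::with_seed(seed, {
      reps <- vapply(seq_len(n_bootstrap), function(b) {
        i <- sample.int(nrow(M_inc), replace = TRUE)
        j <- sample.int(nrow(M_dec), replace = TRUE)
        lr(colSums(M_inc[i, , drop = FALSE]), colSums(M_dec[j, , drop = FALSE]))
      }, numeric(n_pos))
      apply(reps, 1, quantile,
            probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
    })
    out$ci_low <- qs[1, ]
    out$ci_high <- qs[2, ]
  }
  structure(out, class = c("metagene_profile", class(out)),
            motif_class = motif_class, window = c(exonic = w_e, intronic = w_i),
            n_bootstrap = n_bootstrap, seed = seed, pseudocount = pseudocount,
            n_increased = nrow(increased), n_decreased = nrow(decreased))
}
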