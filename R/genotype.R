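#' Variant allele frequency from amplicon read counts
#'
#' Computes VAF = alt / (ref + alt) per sample, reported to 4 decimal
#' places. Zero-depth rows get an undefined (NA) VAF and are flagged.
#'
#' @param counts A data frame with `ref_reads` and `alt_reads` (identifier
#'   columns are carried through).
#' @return The input as a tibble with `depth`, `vaf`, and `vaf_defined`
#'   appended.
#' @examples
#' compute_vaf(tibble::tibble(sample_id = "c1", ref_reads = 1, alt_reads = 2))
#' @export
compute_vaf <- function(counts) {
  check_cols(counts, c("ref_reads", "alt_reads"), "counts")
  if (any(counts$ref_reads < 0) || any(counts$alt_reads < 0)) {
    abort("Read counts must be non-negative.")
  }
  as_tibble(counts) |>
    mutate(
      depth = .data$ref_reads + .data$alt_reads,
      vaf = ifelse(.data$depth > 0,
                   round(.data$alt_reads / .data$depth, 4), NA_real_),
      vaf_defined = .data$depth > 0
    )
}

#' Infer mutant allele copy number from VAF on a locus of known ploidy
#'
#' Bins the variant allele frequency into mutant-allele copy counts. The VAF
#' is expressed as a percent and rounded to the nearest integer; 0 maps to 0
#' copies and otherwise the copy number is the smallest `k` with
#' `percent <= floor(k * 100 / total_copies)`. On a triploid locus
#' (`total_copies = 3`, the default) this reproduces the ranges 1--33% = one
#' mutant allele, 34--66% = two, 67--100% = three. Note the bins are bounded
#' above by `k / total_copies`, so an observed VAF sitting exactly at
#' `k / total_copies` for `k < total_copies` lies on a bin edge and
#' integer rounding decides its side. For `total_copies` other than 3 the
#' same rule is applied as an extrapolation beyond the setting it was
#' defined for.
#'
#' @param vaf Variant allele frequencies as fractions in `[0, 1]` (NA
#'   propagates).
#' @param total_copies Total allele copies at the locus (>= 1); default 3.
#' @return A tibble with `vaf`, `vaf_percent` (integer), `mutant_copies`,
#'   and `total_copies`; the attribute `"bin_edges"` gives the upper percent
#'   edge of each copy bin.
#' @examples
#' infer_allele_copies(c(0, 0.2, 0.5, 0.9))
#' @export
infer_allele_copies <- function(vaf, total_copies = 3L) {
  if (total_copies < 1) abort("`total_copies` must be >= 1.")
  check_fraction(vaf, "vaf", allow_na = TRUE)
  pct <- as.integer(round(100 * vaf))
  copies <- ifelse(pct == 0L, 0L,
                   pmin(as.integer(ceiling(pct * total_copies / 100)),
                        as.integer(total_copies)))
  out <- tibble(
    vaf = vaf, vaf_percent = pct,
    mutant_copies = copies, total_copies = as.integer(total_copies)
  )
  attr(out, "bin_edges") <- floor(seq_len(total_copies) * 100 / total_copies)
  out
}

#' Read per-sample allele depths from a VCF
#'
#' Extracts the allelic-depth (AD) field at a single site into a ref/alt
#' counts table suitable for [compute_vaf()]. Requires the `vcfR` package.
#'
#' @param path Path to a VCF file containing one variant record.
#' @return A tibble: `sample_id`, `ref_reads`, `alt_reads`.
#' @export
read_variant_counts_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF input requires the `vcfR` package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) != 1) abort("Expected a single-site VCF (one variant record).")
  ad <- vcfR::extract.gt(v, element = "AD")
  parts <- strsplit(ad[1, ], ",", fixed = TRUE)
  tibble(
    sample_id = colnames(ad),
    ref_reads = as.integer(vapply(parts, `[`, "", 1)),
    alt_reads = as.integer(vapply(parts, `[`, "", 2))
  )
}
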