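# Internal helpers: validation and seeded sub-stream derivation.

check_fraction <- function(x, name, allow_na = FALSE) {
  ok <- is.numeric(x) & (allow_na | !is.na(x))
  if (!all(ok) || any(x < 0 | x > 1, na.rm = TRUE)) {
    abort(sprintf("`%s` must be a fraction in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || any(is.na(x)) || any(x != floor(x)) ||
      any(if (positive) x <= 0 else x < 0)) {
    abort(sprintf("`%s` must be %s integer-valued.",
                  name, if (positive) "positive" else "non-negative"))
  }
  invisible(x)
}

check_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Derive a reproducible sub-stream seed from a master seed and a stable
# label, so that each generated output consumes its own RNG stream and
# adding an output never perturbs the others. Plain polynomial string
# hash folded into [0, 2^31 - 1).
stream_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(master_seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

with_stream <- function(master_seed, label, code) {
  withr::with_seed(stream_seed(master_seed, label), code)
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}
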