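# internal validation helpers

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower) {
    if (x <= lower) abort(sprintf("`%s` must be > %s.", name, lower))
  } else if (x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, lower))
  }
  if (x > upper) abort(sprintf("`%s` must be <= %s.", name, upper))
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single whole number.", name))
  }
  if (x < lower) abort(sprintf("`%s` must be >= %d.", name, lower))
  as.integer(x)
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame.", name))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Stage seeds derived from a run-level seed by fixed offsets, kept < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}
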