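# Internal helpers shared across modules.

# Significance stars matching the usual matched-pair reporting convention:
# * p < 0.05; ** p <= 0.01; *** p <= 0.001; **** p <= 0.0001.
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ ""
  )
}

# A probability (or vector of them) must live in [0, 1].
check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1].", what))
  }
  invisible(x)
}

check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
  invisible(as.integer(x))
}

# Columns a caller-supplied table must carry.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
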