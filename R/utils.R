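#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value (the convention of
#' hand-rounded published tables), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a stream of independent sub-seeds from one master seed (kept below
# 2^31 so they remain valid R integer seeds).
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_label <- function(x, space, what) {
  bad <- setdiff(unique(x[!is.na(x)]), space)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s must be one of %s; found %s.",
      what, paste(space, collapse = "/"), paste(bad, collapse = ", ")
    ))
  }
  invisible(x)
}
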