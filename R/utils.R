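# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes programmatically.
.amc_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "amc_error")))
}

.assert_exposure <- function(values, what = "values") {
  if (!is.numeric(values)) {
    .amc_error("amc_input_error", sprintf("`%s` must be numeric", what))
  }
  if (length(values) < 2L) {
    .amc_error("amc_input_error",
               sprintf("`%s` must contain at least 2 observations", what))
  }
  if (!all(is.finite(values))) {
    .amc_error("amc_input_error",
               sprintf("`%s` contains non-finite values; resolve missing data upstream",
                       what))
  }
  invisible(as.numeric(values))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.  seed = NULL runs on the ambient stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Prefix sums of x and x^2 for O(1) sums of squares of contiguous segments of
# sorted data.  `s1`/`s2` carry a leading zero, so segment [i, j] (1-based)
# uses s[j + 1] - s[i].
.prefix_sums <- function(xs) {
  list(s1 = c(0, cumsum(xs)), s2 = c(0, cumsum(xs * xs)))
}

# Sum of squared deviations from the segment mean for sorted positions i..j.
# Vectorized over parallel i, j.  Clamped at zero against cancellation error.
.seg_ss <- function(ps, i, j) {
  len <- j - i + 1
  ss <- (ps$s2[j + 1] - ps$s2[i]) - (ps$s1[j + 1] - ps$s1[i])^2 / len
  pmax(ss, 0)
}
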