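# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-unit substream seed from a master seed and a counter,
# kept inside the 32-bit integer range.
substream_seed <- function(master, counter) {
  as.integer((as.double(master) + 10007 * as.double(counter)) %% 2147483647)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("`", name, "` must be positive", call. = FALSE)
  invisible(x)
}

# Truncated-normal draws on (lo, hi) by reject-and-resample.
rnorm_truncated <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
    guard <- guard + 1L
    if (guard > 10000L)
      stop("truncated-normal sampling failed to converge; mean/SD place ",
           "essentially no mass in (", lo, ", ", hi, ")", call. = FALSE)
  }
  out
}

#' Format a p-value the way clinical tables print it
#'
#' Three decimals; values below 0.0005 round to and are shown as
#' `"0.000"`.  Stored p-values always keep full precision; this helper is
#' for display only.
#'
#' @param p numeric vector of p-values
#' @return character vector
#' @examples
#' format_p3(c(0.052, 3e-6))
#' @export
format_p3 <- function(p) {
  sprintf("%.3f", p)
}
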