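# Internal helpers shared across modules.

#' Round half away from zero to the nearest integer
#'
#' Blood-pressure minute grids are stored as integers; ties at .5 round up
#' (72.5 -> 73), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated-normal draws via inverse-CDF; lo/hi may be -Inf/Inf.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Categorical draws from a named probability vector (renormalized).
rcat <- function(n, probs) {
  stopifnot(!is.null(names(probs)), all(probs >= 0))
  sample(names(probs), n, replace = TRUE, prob = probs / sum(probs))
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

assert_flag01 <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a single number in [0, 1]")
  invisible(x)
}
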