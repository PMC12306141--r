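#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; availability percentages are
#' conventionally reported with ordinary "half-up" rounding (e.g. 96/105 of
#' scheduled beeps -> 91.43%), so this helper is used wherever percentages
#' are formatted.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.005, 2)  # 2.01, whereas round(2.005, 2) may give 2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# multivariate normal draws via Cholesky; sigma must be symmetric PD
rmvn <- function(n, sigma) {
  p <- nrow(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% chol(sigma)
}

# TRUE if m is symmetric positive definite (via Cholesky)
is_pd <- function(m, tol = 1e-8) {
  if (max(abs(m - t(m))) > tol) return(FALSE)
  !inherits(try(chol(m), silent = TRUE), "try-error")
}

# log-determinant of a PD matrix via Cholesky
logdet_pd <- function(m) 2 * sum(log(diag(chol(m))))

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
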