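#' Model parameters of the forced oscillator chain
#'
#' The chain consists of identical phase oscillators on the circle
#' \eqn{T = R/Z}, each advancing at base speed 1 (time is rescaled so the
#' natural frequency is 1). Site \eqn{s} accelerates to speed
#' \eqn{1+\epsilon} exactly while the upstream phase lies in the stimulus
#' window \eqn{[0, a_0]} (mod 1) and its own phase lies in the response
#' window \eqn{[0, a_1]} (mod 1). Both windows are closed intervals anchored
#' at phase 0; this is the square-pulse caricature of a type-I phase
#' response curve.
#'
#' @param epsilon coupling intensity, dimensionless, > 0.
#' @param a0 stimulus window width, in circle units, in (0, 1).
#' @param a1 response (PRC) window width, in circle units, in (0, 1).
#'
#' Parameters may be given as numerics or as [rational()] values; rational
#' parameters propagate exactly through the closed-form wave constructor.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(0.5, 0.3, 0.6)
#' model_params(rational(1, 2), rational(3, 10), rational(3, 5))
#' @export
model_params <- function(epsilon, a0, a1) {
  for (nm in c("epsilon", "a0", "a1")) {
    v <- get(nm)
    if (!(is_rational(v) || (is.numeric(v) && length(v) == 1 && is.finite(v))))
      stop(nm, " must be a finite numeric scalar or a rational")
  }
  e <- as.numeric(epsilon); z0 <- as.numeric(a0); z1 <- as.numeric(a1)
  if (e <= 0) stop("epsilon must be > 0")
  if (z0 <= 0 || z0 >= 1) stop("a0 must lie in (0, 1)")
  if (z1 <= 0 || z1 >= 1) stop("a1 must lie in (0, 1)")
  structure(list(epsilon = epsilon, a0 = a0, a1 = a1),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Oscillator chain parameters (natural frequency 1):\n")
  cat(sprintf("  epsilon (coupling)        : %s\n", .fmt_maybe_rat(x$epsilon)))
  cat(sprintf("  a0 (stimulus window)      : %s\n", .fmt_maybe_rat(x$a0)))
  cat(sprintf("  a1 (PRC window)           : %s\n", .fmt_maybe_rat(x$a1)))
  invisible(x)
}

.fmt_maybe_rat <- function(x) {
  if (is_rational(x)) sprintf("%s (= %.10g)", format(x), as.numeric(x))
  else sprintf("%.10g", as.numeric(x))
}

# numeric view of parameters, for the floating-point engines
.mp_num <- function(params) {
  list(epsilon = as.numeric(params$epsilon),
       a0 = as.numeric(params$a0),
       a1 = as.numeric(params$a1))
}

#' Distance on the circle
#'
#' Distance between two phases given as lifts (arbitrary reals): the
#' minimum over integers \eqn{k} of \eqn{|x - y - k|}, always in
#' \eqn{[0, 1/2]}. Vectorized with recycling.
#'
#' @param x,y lift values.
#' @return numeric vector of circle distances.
#' @examples
#' circle_distance(0.95, 0.05) # 0.1 across the wrap
#' @export
circle_distance <- function(x, y) {
  d <- (as.numeric(x) - as.numeric(y)) %% 1
  pmin(d, 1 - d)
}

# fractional part with snapping: values within tol of an integer count as
# phase 0 (window entry), so closed-form event times that land on integers
# up to rounding are treated exactly.
.frac_snap <- function(x, tol = 1e-12) {
  f <- x %% 1
  ifelse(f > 1 - tol | f < tol, 0, f)
}
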