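#' Piecewise-affine lifted trajectory
#'
#' A continuous, strictly increasing, piecewise-affine function of time,
#' stored as breakpoints and values of its lift. Trajectories produced by
#' the chain dynamics have slopes alternating within \{1, 1+epsilon\}; the
#' constructor accepts any strictly increasing profile so the same container
#' also backs forcing profiles.
#'
#' @param time strictly increasing breakpoint times, first one 0.
#' @param value lift value at each breakpoint, strictly increasing.
#' @return An object of class `pw_path` with fields `t`, `v` and computed
#'   `slope` per piece.
#' @examples
#' p <- pw_path(c(0, 0.3, 1), c(0.4, 0.85, 1.55))
#' pw_eval(p, c(0, 0.5, 1))
#' @export
pw_path <- function(time, value) {
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) < 2 || length(time) != length(value))
    stop("pw_path needs matching time/value vectors of length >= 2")
  if (any(diff(time) <= 0)) stop("pw_path: breakpoint times must be strictly increasing")
  if (any(diff(value) <= 0)) stop("pw_path: values must be strictly increasing")
  structure(list(t = time, v = value, slope = diff(value) / diff(time)),
            class = "pw_path")
}

#' @export
print.pw_path <- function(x, ...) {
  cat(sprintf("Piecewise-affine path on [%g, %g], %d pieces\n",
              x$t[1], x$t[length(x$t)], length(x$t) - 1L))
  cat(sprintf("  value range: [%.10g, %.10g]\n", x$v[1], x$v[length(x$v)]))
  cat(sprintf("  slopes: %s\n",
              paste(format(unique(round(x$slope, 10))), collapse = ", ")))
  invisible(x)
}

#' Evaluate a piecewise path at given times
#'
#' @param path a [pw_path()].
#' @param t times inside the path's domain (a small tolerance beyond the
#'   ends is accepted and clamped).
#' @param tol clamping tolerance at the domain ends.
#' @return numeric lift values.
#' @export
pw_eval <- function(path, t, tol = 1e-9) {
  t <- as.numeric(t)
  lo <- path$t[1]; hi <- path$t[length(path$t)]
  if (any(t < lo - tol | t > hi + tol))
    stop(sprintf("pw_eval: time outside domain [%g, %g]", lo, hi))
  t <- pmin(pmax(t, lo), hi)
  stats::approx(path$t, path$v, xout = t, ties = "ordered")$y
}

#' Validate a path as a chain trajectory
#'
#' Checks the invariants that every trajectory of the chain dynamics
#' satisfies: slopes within \{1, 1+epsilon\}, and every maximal slope-1
#' piece that is followed by another piece has length at least
#' \eqn{1 - a_1} (an oscillator must traverse the slow arc of its circle
#' between accelerated phases).
#'
#' @param path a [pw_path()].
#' @param params a [model_params()].
#' @param tol absolute tolerance.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_trajectory <- function(path, params, tol = 1e-9) {
  p <- .mp_num(params)
  ok1 <- abs(path$slope - 1) < tol
  ok2 <- abs(path$slope - (1 + p$epsilon)) < tol
  if (!all(ok1 | ok2))
    stop("trajectory slopes must lie in {1, 1+epsilon}")
  # merge consecutive pieces of equal slope before the length check
  n <- length(path$slope)
  if (n >= 2 && any(abs(diff(path$slope)) < tol))
    stop("trajectory pieces must alternate slopes (merge equal-slope pieces)")
  # interior slope-1 pieces start at a response-window exit and cannot end
  # before the phase completes the slow arc of length 1 - a1; the first
  # piece (truncated by the observation start) and the last (truncated by
  # the horizon) are exempt
  len <- diff(path$t)
  slow <- which(ok1)
  slow_interior <- slow[slow > 1L & slow < n]
  if (any(len[slow_interior] < 1 - p$a1 - tol))
    stop("interior slope-1 piece is shorter than 1 - a1")
  invisible(TRUE)
}

# time at which an increasing pw lift reaches value v (v within range)
.pw_time_at_value <- function(path, v) {
  i <- findInterval(v, path$v, rightmost.closed = TRUE, all.inside = TRUE)
  path$t[i] + (v - path$v[i]) / path$slope[i]
}

# sup over the common domain of |p(t) - g(t)| where g is an evaluator
# function; exact for piecewise-affine g if grid contains g's breakpoints.
.pw_sup_abs_diff <- function(path, fun, extra_knots = numeric(0)) {
  grid <- sort(unique(c(path$t, extra_knots)))
  grid <- grid[grid >= path$t[1] & grid <= path$t[length(path$t)]]
  max(abs(pw_eval(path, grid) - fun(grid)))
}
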