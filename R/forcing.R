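#' Periodic forcing signals
#'
#' A forcing signal is the lift of a degree-1 circle map of time: a
#' continuous increasing function with slope (wherever defined) at least 1,
#' satisfying the periodic-lift identity \eqn{f(t + \tau) = f(t) + 1}. It
#' drives site 1 of the chain and doubles as the traveling-wave shape.
#' Internally the signal is stored as one period of a piecewise-affine
#' profile; evaluation extends it by the lift identity.
#'
#' `forcing_from_profile()` builds a signal from user-supplied breakpoints
#' (must start at (0, 0) and end at (period, 1)); `uniform_forcing()` builds
#' the linear ramp \eqn{g(t) = t/\tau}.
#'
#' @param time breakpoint times in `[0, period]`, starting at 0 and ending
#'   at `period`.
#' @param value lift values at the breakpoints, from 0 to 1.
#' @param period the period \eqn{\tau > 0}.
#' @param tol validation tolerance.
#' @return An object of class `forcing_signal`.
#' @examples
#' g <- uniform_forcing(14 / 15)
#' f_eval(g, c(0, 2 / 15, 14 / 15, 1))
#' @export
forcing_from_profile <- function(time, value, period, tol = 1e-9) {
  time <- as.numeric(time); value <- as.numeric(value)
  period <- as.numeric(period)
  if (period <= 0) stop("forcing: period must be > 0")
  if (abs(time[1]) > tol || abs(time[length(time)] - period) > tol)
    stop("forcing: breakpoints must start at 0 and end at the period")
  if (abs(value[1]) > tol)
    stop("forcing: profile must start at value 0 (f(0) = 0)")
  if (abs(value[length(value)] - 1) > tol)
    stop("forcing: profile must end at value 1 (f(tau) = 1)")
  if (any(diff(value) <= 0))
    stop("forcing: profile must be increasing")
  time[1] <- 0; time[length(time)] <- period
  value[1] <- 0; value[length(value)] <- 1
  f <- .new_forcing(time, value, period)
  validate_forcing(f, tol)
  f
}

# internal constructor: profile may start at any value v0 (time-shifted
# signals), but must end exactly one revolution higher.
.new_forcing <- function(time, value, period) {
  structure(list(period = period,
                 profile = pw_path(time, value)),
            class = "forcing_signal")
}

#' @rdname forcing_from_profile
#' @param tau period of the uniform ramp; must satisfy `0 < tau <= 1` so
#'   the slope `1/tau` is at least 1.
#' @export
uniform_forcing <- function(tau) {
  tau <- as.numeric(tau)
  if (tau <= 0) stop("uniform forcing: period must be > 0")
  if (tau > 1) stop("uniform forcing: period must be <= 1 (slope 1/tau >= 1 required)")
  .new_forcing(c(0, tau), c(0, 1), tau)
}

#' Validate a forcing signal
#'
#' Checks slope at least 1 on every piece, monotonicity, the one-revolution
#' profile range, and the periodic-lift identity at sampled points.
#'
#' @param f a `forcing_signal`.
#' @param tol absolute tolerance.
#' @return invisibly `TRUE`; stops with the violated constraint otherwise.
#' @export
validate_forcing <- function(f, tol = 1e-9) {
  pr <- f$profile
  if (any(pr$slope < 1 - tol))
    stop("forcing: slope must be at least 1 everywhere")
  v0 <- pr$v[1]; v1 <- pr$v[length(pr$v)]
  if (abs(v1 - v0 - 1) > tol)
    stop("forcing: profile must rise by exactly 1 over one period")
  ts <- seq(0, 2 * f$period, length.out = 17)
  if (max(abs(f_eval(f, ts + f$period) - f_eval(f, ts) - 1)) > tol)
    stop("forcing: periodic-lift identity f(t + tau) = f(t) + 1 violated")
  invisible(TRUE)
}

#' Evaluate a forcing signal lift
#'
#' @param f a `forcing_signal`.
#' @param t times (any non-negative reals; negative times are also valid
#'   through the lift identity).
#' @return lift values `f(t)`.
#' @export
f_eval <- function(f, t) {
  t <- as.numeric(t)
  k <- floor(t / f$period)
  tr <- t - k * f$period
  # guard against tr == period from rounding
  over <- tr >= f$period
  tr[over] <- tr[over] - f$period
  k[over] <- k[over] + 1
  pw_eval(f$profile, tr) + k
}

#' Time-shift operator on forcing signals
#'
#' Returns \eqn{R^T f} with \eqn{(R^T f)(t) = f(t + T)}. The result is a
#' valid forcing signal with the same period; its value at 0 is `f(T)`
#' (generally non-zero), and it still satisfies the periodic-lift identity.
#'
#' @param f a `forcing_signal`.
#' @param T shift, `T >= 0`.
#' @return shifted `forcing_signal`.
#' @export
time_shift <- function(f, T) {
  T <- as.numeric(T)
  if (T < 0) stop("time_shift: T must be >= 0")
  if (T == 0) return(f)
  tau <- f$period
  base <- f$profile$t
  bp <- sort(unique(c(0, (base[-length(base)] - T) %% tau, tau)))
  .new_forcing(bp, f_eval(f, T + bp), tau)
}

#' @export
print.forcing_signal <- function(x, ...) {
  cat(sprintf("Periodic forcing signal, period tau = %.10g\n", x$period))
  cat(sprintf("  profile: %d affine pieces, value at 0 = %.10g\n",
              length(x$profile$slope), x$profile$v[1]))
  cat(sprintf("  slopes: %s\n",
              paste(format(unique(round(x$profile$slope, 10))), collapse = ", ")))
  invisible(x)
}

#' @export
plot.forcing_signal <- function(x, n_periods = 2, ...) {
  tt <- seq(0, n_periods * x$period, length.out = 400)
  tt <- sort(unique(c(tt, rep(x$profile$t, n_periods) +
                        rep(seq_len(n_periods) - 1, each = length(x$profile$t)) * x$period)))
  tt <- tt[tt <= n_periods * x$period]
  graphics::plot(tt, f_eval(x, tt), type = "l",
                 xlab = "time", ylab = "forcing lift f(t)", ...)
  graphics::abline(h = 0:(n_periods + 1), col = "grey80", lty = 3)
  invisible(x)
}

## ---- lift abstraction shared by forcing signals and finite paths ----

.lift_eval <- function(x, t) {
  if (inherits(x, "forcing_signal")) f_eval(x, t) else pw_eval(x, t)
}

.lift_domain_end <- function(x) {
  if (inherits(x, "forcing_signal")) Inf else x$t[length(x$t)]
}

# time at which the lift reaches value v (first such time; lifts are
# strictly increasing so it is unique)
.lift_time_at_value <- function(x, v) {
  if (inherits(x, "forcing_signal")) {
    pr <- x$profile
    v0 <- pr$v[1]
    k <- floor(v - v0 + 1e-12)
    pv <- v - k
    # clamp into the profile's value range against rounding
    pv <- min(max(pv, v0), v0 + 1)
    k * x$period + .pw_time_at_value(pr, pv)
  } else {
    vmax <- x$v[length(x$v)]
    if (v > vmax) return(Inf)
    .pw_time_at_value(x, v)
  }
}

# next time strictly after t at which frac(lift) crosses a0 (window exit)
# or an integer (window entry). Returns list(time, kind).
.lift_next_window_event <- function(x, t, a0, tol = 1e-12) {
  v <- .lift_eval(x, t)
  b <- floor(v)
  fv <- v - b
  if (fv > 1 - tol) { b <- b + 1; fv <- 0 }
  if (fv < a0 - tol) {
    target <- b + a0; kind <- "up_stim_exit"
  } else {
    target <- b + 1; kind <- "up_fire"
  }
  list(time = .lift_time_at_value(x, target), kind = kind)
}

#' Read and write piecewise profiles
#'
#' Profiles are exchanged as CSV files with header `t,value` listing the
#' breakpoints of one period, plus a JSON sidecar `<path>.json` holding
#' `{"period": tau}`.
#'
#' @param f a `forcing_signal` (for writing).
#' @param path CSV file path; the sidecar uses `paste0(path, ".json")`.
#' @return `write_profile()` returns the path invisibly;
#'   `read_profile()` returns a `forcing_signal`.
#' @export
write_profile <- function(f, path) {
  utils::write.csv(data.frame(t = f$profile$t, value = f$profile$v),
                   path, row.names = FALSE)
  writeLines(sprintf('{"period": %.17g}', f$period), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t", "value") %in% names(d)))
    stop("profile CSV must have columns t,value")
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar ", side)
  txt <- paste(readLines(side, warn = FALSE), collapse = " ")
  m <- regmatches(txt, regexec('"period"\\s*:\\s*([0-9.eE+-]+)', txt))[[1]]
  if (length(m) < 2) stop("sidecar does not contain a period field")
  forcing_from_profile(d$t, d$value, as.numeric(m[2]))
}
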