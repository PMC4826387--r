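#' Closed-form times of the case-(a) traveling wave
#'
#' For a case-(a) traveling wave with phase shift `alpha` per site, the
#' shape is the three-piece profile \eqn{\Theta_{\alpha,\sigma}} and its
#' fast-piece duration \eqn{\sigma} is determined by two candidate exit
#' times: `t0`, when the upstream signal leaves the stimulus window
#' (\eqn{\Theta_{\alpha,t_0}(t_0) = a_0}), and `t1`, when the oscillator
#' itself leaves the response window
#' (\eqn{\Theta_{\alpha,t_1}(t_1+\alpha) = a_1}). In closed form
#' \deqn{t_0 = \min\{a_0, (a_0 + \alpha\epsilon)/(1+\epsilon)\}, \qquad
#'       t_1 = (a_1 - \alpha)/(1+\epsilon),}
#' the fast piece lasts \eqn{\sigma = \min\{t_0, t_1\}} and the period is
#' \eqn{\tau = 1 - \epsilon\sigma}.
#'
#' With [rational()] parameters all four values are exact fractions.
#'
#' @param params a [model_params()].
#' @param alpha phase shift per site, `0 <= alpha < a1` (numeric or
#'   rational).
#' @return list with fields `t0`, `t1`, `sigma`, `tau` (rational when the
#'   inputs are rational).
#' @examples
#' tw_times(model_params(0.5, 0.3, 0.6), 0.4) # t0 = 0.3, t1 = 2/15
#' @export
tw_times <- function(params, alpha) {
  exact <- is_rational(alpha) || is_rational(params$epsilon)
  if (exact) {
    e <- .as_rat(params$epsilon); a0 <- .as_rat(params$a0)
    a1 <- .as_rat(params$a1); al <- .as_rat(alpha)
  } else {
    p <- .mp_num(params)
    e <- p$epsilon; a0 <- p$a0; a1 <- p$a1; al <- as.numeric(alpha)
  }
  if (as.numeric(al) < 0) stop("alpha must be >= 0")
  t1 <- (a1 - al) / (1 + e)
  if (as.numeric(t1) < 0)
    stop("no case-(a) fast onset: alpha exceeds the PRC window width a1")
  t0 <- min(a0, (a0 + al * e) / (1 + e))
  sigma <- min(t0, t1)
  tau <- 1 - e * sigma
  list(t0 = t0, t1 = t1, sigma = sigma, tau = tau)
}

#' Admissibility intervals of the phase shift
#'
#' Three nested intervals of the per-site phase shift \eqn{\alpha} for
#' given parameters:
#' \describe{
#'   \item{existence}{case-(a) traveling waves exist iff
#'     \eqn{0 \le \alpha < a_1} and \eqn{\alpha \le \alpha_{hi}}. For
#'     \eqn{a_0 < a_1} the bound is
#'     \eqn{\alpha_{hi} = \max\{\alpha_0,\,(1+\epsilon)(1-a_0)-\epsilon a_1,\,
#'     (1-a_0+\epsilon(1-a_1))/(1+\epsilon)\}}; for \eqn{a_0 \ge a_1} it is
#'     \eqn{1 - a_0} (the shape value when the site fires is \eqn{1-\alpha},
#'     which must already clear the stimulus window edge — with a wide
#'     stimulus window the \eqn{\max\{\cdot\}} form overstates the bound,
#'     as direct simulation of the would-be shape shows).}
#'   \item{stable}{the wave's stroboscopic fixed point is asymptotically
#'     stable iff \eqn{t_1 < t_0}, i.e.
#'     \eqn{\alpha > \alpha_0 = \max\{a_1-(1+\epsilon)a_0,\,
#'     (a_1-a_0)/(1+\epsilon)\}}. Non-empty for every valid parameter set.}
#'   \item{uniform}{the sub-range for which the uniform ramp
#'     \eqn{g(t) = t/\tau} also generates the wave:
#'     \eqn{(a_1-a_0-\epsilon a_0(1-a_1))/(1+\epsilon a_0) < \alpha <
#'     (1-a_0)(1+\epsilon(1-a_1))/(1+\epsilon a_0)}, intersected with the
#'     stable interval. May be empty for large \eqn{\epsilon}.}
#' }
#' The corresponding period ranges under \eqn{\alpha \mapsto
#' \tau(\alpha) = 1-\epsilon\,\min\{t_0(\alpha),t_1(\alpha)\}} are also
#' reported.
#'
#' @param params a [model_params()].
#' @return An object of class `alpha_intervals` with fields `existence`,
#'   `stable`, `uniform` (each `c(lo, hi)`), openness flags, `alpha0`,
#'   and matching `tau_*` ranges.
#' @examples
#' alpha_intervals(model_params(0.5, 0.3, 0.6))
#' @export
alpha_intervals <- function(params) {
  p <- .mp_num(params)
  e <- p$epsilon; a0 <- p$a0; a1 <- p$a1
  alpha0_pre <- max(a1 - (1 + e) * a0, (a1 - a0) / (1 + e))
  # upper existence bound: when the site fires (theta reaches 1) the
  # upstream shape sits at f(tau - alpha); requiring it to have cleared
  # the stimulus window gives, branch by branch of the shape:
  B <- if (a0 >= a1) 1 - a0
       else max((1 + e) * (1 - a0) - e * a1,
                (1 - a0 + e * (1 - a1)) / (1 + e))
  hi_raw <- max(alpha0_pre, B)
  ex_hi <- min(a1, hi_raw)
  ex_hi_open <- a1 <= hi_raw   # strict "alpha < a1" binds
  alpha0 <- alpha0_pre
  st_lo <- max(alpha0, 0)
  lo10 <- (a1 - a0 - e * a0 * (1 - a1)) / (1 + e * a0)
  hi10 <- (1 - a0) * (1 + e * (1 - a1)) / (1 + e * a0)
  un_lo <- max(st_lo, lo10)
  un_hi <- min(ex_hi, hi10)
  tau_rng <- function(lo, hi) {
    if (hi <= lo) return(c(NA_real_, NA_real_))
    crit <- c(lo, hi, alpha0, a0)  # kinks of alpha -> tau
    crit <- sort(unique(pmin(pmax(crit, lo), hi)))
    grid <- sort(unique(c(crit, seq(lo, hi, length.out = 65))))
    taus <- vapply(grid, function(a)
      as.numeric(tw_times(params, a)$tau), numeric(1))
    range(taus)
  }
  structure(list(existence = c(0, ex_hi),
                 existence_open = c(FALSE, ex_hi_open),
                 stable = c(st_lo, ex_hi),
                 uniform = c(un_lo, un_hi),
                 uniform_empty = un_hi <= un_lo,
                 alpha0 = alpha0,
                 alpha_hi_raw = hi_raw,
                 tau_existence = tau_rng(0, ex_hi),
                 tau_stable = tau_rng(st_lo, ex_hi),
                 tau_uniform = tau_rng(un_lo, un_hi),
                 params = params),
            class = "alpha_intervals")
}

#' @export
print.alpha_intervals <- function(x, ...) {
  br <- function(iv, lo_open = TRUE, hi_open = TRUE)
    sprintf("%s%.10g, %.10g%s", if (lo_open) "(" else "[",
            iv[1], iv[2], if (hi_open) ")" else "]")
  cat("Admissible phase-shift intervals (per-site shift alpha):\n")
  cat("  existence :", br(x$existence, x$existence_open[1], x$existence_open[2]),
      sprintf(" -> tau in [%.10g, %.10g]\n", x$tau_existence[1], x$tau_existence[2]))
  cat("  stable    :", br(x$stable),
      sprintf(" -> tau in [%.10g, %.10g]\n", x$tau_stable[1], x$tau_stable[2]))
  if (x$uniform_empty) {
    cat("  uniform   : empty (uniform-forcing condition not satisfiable)\n")
  } else {
    cat("  uniform   :", br(x$uniform),
        sprintf(" -> tau in [%.10g, %.10g]\n", x$tau_uniform[1], x$tau_uniform[2]))
  }
  invisible(x)
}

#' Construct the case-(a) traveling wave
#'
#' Builds the unique case-(a) traveling wave with phase shift `alpha`: the
#' shape is the three-piece profile
#' \deqn{\Theta_{\alpha,\sigma}(t) = t \ (t \le \alpha);\quad
#'   \alpha + (1+\epsilon)(t-\alpha) \ (\alpha \le t \le \sigma+\alpha);\quad
#'   \epsilon\sigma + t \ (t \ge \sigma+\alpha),}
#' restricted to one period \eqn{[0, \tau]} and extended periodically.
#' The accelerated piece starts exactly at \eqn{\alpha}, which pins down
#' the stable-wave representative among the waves with the same period.
#'
#' The constructed shape is verified by simulation: one site forced with
#' the shape and started on the wave must reproduce the shape shifted by
#' `alpha` (the defining identity of a traveling wave).
#'
#' @param params a [model_params()].
#' @param alpha phase shift per site; must lie inside the existence
#'   interval, and be positive unless `allow_zero`.
#' @param allow_zero permit the degenerate shift `alpha = 0` (wave number
#'   0); excluded by default.
#' @param verify run the self-consistency simulation check (default TRUE).
#' @return An object of class `traveling_wave` with fields `params`,
#'   `alpha`, `sigma`, `tau`, `t0`, `t1`, `shape` (a `forcing_signal`),
#'   `case` and, for rational inputs, `exact` (the exact times).
#' @examples
#' tw <- build_tw(model_params(0.5, 0.3, 0.6), 0.4)
#' tw$tau # 14/15
#' @export
build_tw <- function(params, alpha, allow_zero = FALSE, verify = TRUE) {
  iv <- alpha_intervals(params)
  a <- as.numeric(alpha)
  tol <- 1e-12
  if (a < 0) stop("alpha must be >= 0")
  if (a == 0 && !allow_zero)
    stop("alpha = 0 (wave number 0) excluded; set allow_zero = TRUE for the degenerate shape")
  if (a >= as.numeric(params$a1))
    stop("alpha outside existence interval: requires alpha < a1 (shape value at alpha must stay below the PRC window edge)")
  if (a > iv$alpha_hi_raw + tol)
    stop(paste0("alpha outside existence interval: when the site fires the ",
                "upstream shape must have cleared the stimulus window ",
                "(f(tau - alpha) >= a0), which requires alpha <= ",
                format(iv$alpha_hi_raw)))
  tm <- tw_times(params, alpha)
  exact <- is_rational(tm$tau)
  t0 <- as.numeric(tm$t0); t1 <- as.numeric(tm$t1)
  sigma <- as.numeric(tm$sigma); tau <- as.numeric(tm$tau)
  e <- as.numeric(params$epsilon)
  if (a > 0) {
    bp <- c(0, a, a + sigma, tau)
    vv <- c(0, a, a + (1 + e) * sigma, 1)
  } else {
    bp <- c(0, sigma, tau)
    vv <- c(0, (1 + e) * sigma, 1)
  }
  keep <- c(TRUE, diff(bp) > tol)
  shape <- .new_forcing(bp[keep], vv[keep], tau)
  validate_forcing(shape)
  tw <- structure(list(params = params, alpha = a, sigma = sigma,
                       tau = tau, t0 = t0, t1 = t1, shape = shape,
                       case = NA_character_,
                       exact = if (exact) tm else NULL),
                  class = "traveling_wave")
  tw$case <- classify_tw_case(shape, a, params)
  if (verify && a > 0) {
    path <- evolve_site(shape, f_eval(shape, a), params, tau)
    err <- .pw_sup_abs_diff(path, function(t) f_eval(shape, t + a),
                            extra_knots = sort(c(shape$profile$t - a,
                                                 shape$profile$t - a + tau)))
    if (err > 1e-9)
      stop(sprintf("internal error: constructed shape fails the wave identity (sup error %.3g)", err))
  }
  tw
}

#' @export
print.traveling_wave <- function(x, ...) {
  cat(sprintf("Case-(%s) traveling wave\n", x$case))
  cat(sprintf("  phase shift alpha : %.10g  (wave number alpha/tau = %.10g)\n",
              x$alpha, x$alpha / x$tau))
  cat(sprintf("  period tau        : %.10g\n", x$tau))
  cat(sprintf("  fast piece sigma  : %.10g  (t0 = %.10g, t1 = %.10g)\n",
              x$sigma, x$t0, x$t1))
  if (!is.null(x$exact))
    cat(sprintf("  exact: t0 = %s, t1 = %s, sigma = %s, tau = %s\n",
                format(x$exact$t0), format(x$exact$t1),
                format(x$exact$sigma), format(x$exact$tau)))
  invisible(x)
}

#' @export
summary.traveling_wave <- function(object, ...) {
  print(object)
  iv <- alpha_intervals(object$params)
  print(iv)
  cat(sprintf("  stability (t1 vs t0): %s\n", classify_stability(object)))
  invisible(object)
}

#' @export
plot.traveling_wave <- function(x, n_periods = 2, ...) {
  plot(x$shape, n_periods = n_periods,
       main = sprintf("TW shape: alpha = %.4g, tau = %.4g", x$alpha, x$tau),
       ...)
  graphics::abline(v = x$alpha + (0:(n_periods - 1)) * x$tau,
                   col = "firebrick", lty = 2)
  invisible(x)
}

#' Classify a shape/shift pair into the four traveling-wave cases
#'
#' The case is decided by the position of \eqn{f(\alpha)} relative to the
#' PRC window edge \eqn{a_1} and of \eqn{f(\tau-\alpha)} relative to the
#' stimulus window edge \eqn{a_0}:
#' (a) \eqn{f(\alpha) < a_1} and \eqn{f(\tau-\alpha) \ge a_0};
#' (b) both reversed; (c) both at-or-above; (c') both below.
#'
#' @param f a `forcing_signal`.
#' @param alpha candidate phase shift, `0 < alpha < period`.
#' @param params a [model_params()].
#' @return one of `"a"`, `"b"`, `"c"`, `"cprime"`.
#' @export
classify_tw_case <- function(f, alpha, params) {
  p <- .mp_num(params)
  a <- as.numeric(alpha)
  if (a <= 0 || a >= f$period) {
    if (!(a == 0))  # alpha = 0 tolerated for the degenerate shape
      stop("classify_tw_case: alpha must lie in (0, period)")
  }
  fa <- f_eval(f, a)
  fta <- f_eval(f, f$period - a)
  low1 <- fa < p$a1
  high0 <- fta >= p$a0
  if (low1 && high0) "a"
  else if (!low1 && !high0) "b"
  else if (!low1 && high0) "c"
  else "cprime"
}

#' Map a forcing period back to admissible phase shifts
#'
#' Inverts \eqn{\alpha \mapsto \tau(\alpha) = 1 - \epsilon\sigma(\alpha)}
#' over the existence interval. The map is continuous and piecewise affine
#' but not injective in general (decreasing while \eqn{\sigma = t_0}
#' grows, increasing once \eqn{\sigma = t_1} shrinks), so all preimages
#' are returned.
#'
#' @param params a [model_params()].
#' @param tau target period.
#' @param tol bisection tolerance.
#' @return numeric vector of phase shifts `alpha` (possibly empty).
#' @export
alpha_of_tau <- function(params, tau, tol = 1e-12) {
  iv <- alpha_intervals(params)
  lo <- iv$existence[1]; hi <- iv$existence[2]
  kinks <- sort(unique(pmin(pmax(c(lo, iv$alpha0, as.numeric(params$a0), hi),
                                 lo), hi)))
  tau_of <- function(a) as.numeric(tw_times(params, a)$tau)
  out <- numeric(0)
  for (i in seq_len(length(kinks) - 1)) {
    a_lo <- kinks[i]; a_hi <- kinks[i + 1]
    if (a_hi - a_lo < tol) next
    f_lo <- tau_of(a_lo) - tau; f_hi <- tau_of(a_hi) - tau
    if (f_lo == 0) out <- c(out, a_lo)
    if (f_lo * f_hi < 0) {
      while (a_hi - a_lo > tol) {
        m <- (a_lo + a_hi) / 2
        fm <- tau_of(m) - tau
        if (fm == 0) { a_lo <- m; a_hi <- m; break }
        if (fm * f_lo < 0) a_hi <- m else { a_lo <- m; f_lo <- fm }
      }
      out <- c(out, (a_lo + a_hi) / 2)
    }
  }
  last <- tau_of(kinks[length(kinks)])
  if (abs(last - tau) < tol) out <- c(out, kinks[length(kinks)])
  sort(unique(out))
}
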