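#' Stroboscopic (period return) map of the forced site
#'
#' For a forcing signal with period tau, the stroboscopic map advances the
#' first site's phase over one forcing period and translates back:
#' \eqn{F_f(\vartheta) = \theta_1^{(f)}(\vartheta, \tau) - 1}. It is the
#' lift of an orientation-preserving circle homeomorphism of degree 1, and
#' its orbits capture the asymptotics of site 1:
#' \eqn{F_f^n(\vartheta) = \theta_1(\vartheta, n\tau) - n}.
#'
#' @param forcing a `forcing_signal`.
#' @param params a [model_params()].
#' @param theta phase(s) in `[0, 1)` (any lift accepted).
#' @return `F(theta)`, same length as `theta`.
#' @examples
#' par <- model_params(0.5, 0.3, 0.6)
#' tw <- build_tw(par, 0.4)
#' strobe_eval(tw$shape, par, 0.4) # fixed point f(alpha) = 0.4
#' @export
strobe_eval <- function(forcing, params, theta) {
  vapply(as.numeric(theta), function(th)
    pw_eval(evolve_site(forcing, th, params, forcing$period), forcing$period) - 1,
    numeric(1))
}

# event signature of the one-period trajectory started at theta: the
# ordered list of event kinds plus the initial window memberships. The
# map F is affine in theta exactly while the signature is constant.
.strobe_sig <- function(forcing, params, theta, tol = 1e-12) {
  path <- evolve_site(forcing, theta, params, forcing$period, tol = tol)
  ev <- attr(path, "events")
  p <- .mp_num(params)
  ft <- .frac_snap(theta, tol)
  paste(c(if (ft < p$a1 - tol) "S" else "s", ev$kind), collapse = "|")
}

#' Piecewise-affine decomposition of the stroboscopic map
#'
#' The stroboscopic map of a piecewise-affine forcing is itself exactly
#' piecewise affine on `[0, 1)`, with every slope an integer power of
#' `(1 + epsilon)`. For a stable-case traveling-wave forcing the
#' decomposition has exactly four pieces: two rigid rotations (slope 1)
#' interspersed by one contracting and one expanding piece.
#'
#' Breakpoints are located where the event-pattern signature of the
#' one-period trajectory changes (the map is affine within a fixed event
#' pattern), then sharpened to the intersection of the adjacent affine
#' branches, so no bisection residual is left when the branches' slopes
#' differ.
#'
#' @param forcing a `forcing_signal`.
#' @param params a [model_params()].
#' @param n_grid size of the scanning grid on `[0, 1)`.
#' @param max_pieces complexity cap; exceeding it raises an error.
#' @param tol tolerance for merging affine branches.
#' @return An object of class `strobo_map`: list with `pieces` (data frame
#'   `left, right, slope, intercept, power`), `fixed_points` (data frame
#'   `theta, slope, class`), `neutral_segments`, `tau`, `forcing`,
#'   `params`.
#' @export
strobe_decompose <- function(forcing, params, n_grid = 384,
                             max_pieces = 64, tol = 1e-9) {
  thetas <- (seq_len(n_grid) - 1) / n_grid
  Fv <- strobe_eval(forcing, params, thetas)
  sig <- vapply(thetas, function(th) .strobe_sig(forcing, params, th),
                character(1))
  r <- rle(sig)
  n_runs <- length(r$lengths)
  if (n_runs > max_pieces * 3)
    stop("unexpected map complexity: raise max_pieces or inspect the forcing")
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  # affine coefficients per run (extend single-point runs by a local probe)
  run_affine <- function(i) {
    i1 <- starts[i]; i2 <- ends[i]
    if (i2 > i1) {
      m <- (Fv[i2] - Fv[i1]) / (thetas[i2] - thetas[i1])
      c(m, Fv[i1] - m * thetas[i1])
    } else {
      h <- 1 / (8 * n_grid)
      x2 <- thetas[i1] + h
      if (.strobe_sig(forcing, params, x2) != sig[i1]) {
        x2 <- thetas[i1] - h
        if (x2 < 0 || .strobe_sig(forcing, params, x2) != sig[i1])
          return(c(NA_real_, NA_real_))
      }
      F2 <- strobe_eval(forcing, params, x2)
      m <- (F2 - Fv[i1]) / (x2 - thetas[i1])
      c(m, Fv[i1] - m * thetas[i1])
    }
  }
  coefs <- t(vapply(seq_len(n_runs), run_affine, numeric(2)))
  if (anyNA(coefs))
    stop("unexpected map complexity: affine branch narrower than the probe step")

  # boundary between run i and i+1: bisect the signature change, then
  # sharpen with the affine intersection when slopes differ
  boundary <- function(i) {
    lo <- thetas[ends[i]]; hi <- thetas[starts[i + 1L]]
    s_lo <- sig[ends[i]]
    for (k in 1:48) {
      mid <- (lo + hi) / 2
      if (.strobe_sig(forcing, params, mid) == s_lo) lo <- mid else hi <- mid
    }
    b <- (lo + hi) / 2
    m1 <- coefs[i, 1]; c1 <- coefs[i, 2]
    m2 <- coefs[i + 1L, 1]; c2 <- coefs[i + 1L, 2]
    if (abs(m1 - m2) > 1e-6) {
      x <- (c2 - c1) / (m1 - m2)
      if (abs(x - b) < 2 / n_grid) b <- x
    }
    b
  }
  cuts <- if (n_runs > 1) vapply(seq_len(n_runs - 1L), boundary, numeric(1))
          else numeric(0)

  left <- c(0, cuts); right <- c(cuts, 1)
  slope <- coefs[, 1]; intercept <- coefs[, 2]
  # merge adjacent runs that lie on the same affine branch
  keep <- rep(TRUE, length(left))
  for (i in seq_len(length(left) - 1L)) {
    j <- max(which(keep[seq_len(i)]))
    if (abs(slope[i + 1L] - slope[j]) < tol &&
        abs(intercept[i + 1L] - intercept[j]) < tol) {
      keep[i + 1L] <- FALSE
      right[j] <- right[i + 1L]
    }
  }
  pieces <- data.frame(left = left[keep], right = right[keep],
                       slope = slope[keep], intercept = intercept[keep])
  pieces$right[nrow(pieces)] <- 1
  if (nrow(pieces) > max_pieces)
    stop("unexpected map complexity: more pieces than the configured cap")

  e <- .mp_num(params)$epsilon
  pw <- round(log(pieces$slope) / log(1 + e))
  if (any(abs(pieces$slope - (1 + e)^pw) > 1e-6))
    warning("piece slopes are not clean powers of (1+epsilon)")
  pieces$power <- as.integer(pw)

  # consistency: continuity across cuts and the degree-1 identity
  if (nrow(pieces) > 1) {
    xi <- pieces$left[-1]
    lhs <- pieces$slope[-nrow(pieces)] * xi + pieces$intercept[-nrow(pieces)]
    rhs <- pieces$slope[-1] * xi + pieces$intercept[-1]
    if (max(abs(lhs - rhs)) > 1e-7)
      warning("decomposition continuity residual above 1e-7")
  }
  map <- structure(list(pieces = pieces, tau = forcing$period,
                        forcing = forcing, params = params),
                   class = "strobo_map")
  fp <- find_fixed_points(map)
  map$fixed_points <- fp$points
  map$neutral_segments <- fp$neutral_segments
  map
}

#' @export
print.strobo_map <- function(x, ...) {
  cat(sprintf("Stroboscopic map (period %.10g): %d affine pieces on [0,1)\n",
              x$tau, nrow(x$pieces)))
  print(transform(x$pieces,
                  slope = round(slope, 10), intercept = round(intercept, 10)),
        row.names = FALSE)
  if (nrow(x$fixed_points)) {
    cat("fixed points:\n")
    print(transform(x$fixed_points, theta = round(theta, 10)),
          row.names = FALSE)
  } else cat("no fixed points (non-zero rotation)\n")
  if (length(x$neutral_segments))
    cat(sprintf("neutral segments: %d\n", length(x$neutral_segments)))
  invisible(x)
}

#' @export
plot.strobo_map <- function(x, ...) {
  grid <- seq(0, 1, length.out = 401)
  y <- strobe_apply(x, grid) %% 1
  graphics::plot(grid, y, pch = ".", xlab = expression(vartheta),
                 ylab = expression(F(vartheta)), ...)
  graphics::abline(0, 1, col = "grey60")
  if (nrow(x$fixed_points))
    graphics::points(x$fixed_points$theta, x$fixed_points$theta,
                     col = ifelse(x$fixed_points$class == "stable",
                                  "forestgreen", "firebrick"), pch = 19)
  invisible(x)
}

#' Apply a decomposed stroboscopic map
#'
#' Evaluates the lift of the decomposed map at arbitrary lift values,
#' using \eqn{F(\vartheta + k) = F(\vartheta) + k}.
#'
#' @param map a `strobo_map`.
#' @param theta lift values.
#' @return lift values `F(theta)`.
#' @export
strobe_apply <- function(map, theta) {
  th <- as.numeric(theta)
  b <- floor(th)
  fr <- th - b
  i <- findInterval(fr, c(map$pieces$left, 1), rightmost.closed = TRUE,
                    all.inside = TRUE)
  map$pieces$slope[i] * fr + map$pieces$intercept[i] + b
}

#' Fixed points of a decomposed stroboscopic map
#'
#' Solves \eqn{\vartheta = F(\vartheta) - m} on each affine piece for the
#' integers `m` in range, classifying each solution by the local slope:
#' below 1 stable, above 1 unstable, equal to 1 neutral. A slope-1 piece
#' whose translate is an exact integer is a neutral continuum and is
#' reported as a segment.
#'
#' @param map a `strobo_map`.
#' @param tol classification tolerance.
#' @return list with `points` (data frame `theta, slope, class`) and
#'   `neutral_segments` (list of `c(left, right)`).
#' @export
find_fixed_points <- function(map, tol = 1e-9) {
  pts <- list(); segs <- list()
  for (i in seq_len(nrow(map$pieces))) {
    l <- map$pieces$left[i]; r <- map$pieces$right[i]
    m <- map$pieces$slope[i]; cc <- map$pieces$intercept[i]
    g <- (m - 1) * c(l, r) + cc   # F(theta) - theta at the edges
    ks <- seq(ceiling(min(g) - tol), floor(max(g) + tol))
    if (abs(m - 1) <= tol) {
      for (k in ks) if (abs(cc - k) <= tol)
        segs[[length(segs) + 1L]] <- c(l, r)
      next
    }
    for (k in ks) {
      th <- (k - cc) / (m - 1)
      if (th >= l - tol && th < r + tol) {
        cls <- if (m < 1 - tol) "stable" else if (m > 1 + tol) "unstable"
               else "neutral"
        pts[[length(pts) + 1L]] <- data.frame(theta = min(max(th, 0), 1),
                                              slope = m, class = cls,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  points <- if (length(pts)) unique(do.call(rbind, pts))
            else data.frame(theta = numeric(0), slope = numeric(0),
                            class = character(0), stringsAsFactors = FALSE)
  list(points = points, neutral_segments = segs)
}

#' Stability class of a constructed traveling wave
#'
#' For a case-(a) wave the stroboscopic fixed point \eqn{f(\alpha)} is
#' asymptotically stable exactly when the oscillator leaves its response
#' window before the upstream leaves the stimulus window, i.e.
#' \eqn{t_1 < t_0} (equivalently \eqn{\alpha > \alpha_0}); when
#' \eqn{t_1 > t_0} the fixed point is neutral. The boundary tie
#' \eqn{t_1 = t_0} is reported as neutral with a warning. (The unstable
#' label belongs to case-(b) waves, which this constructor does not
#' build; [find_fixed_points()] classifies arbitrary decompositions.)
#'
#' @param tw a [build_tw()] result.
#' @param tol tie tolerance.
#' @return one of `"stable"`, `"neutral"`.
#' @export
classify_stability <- function(tw, tol = 1e-12) {
  if (abs(tw$t1 - tw$t0) <= tol) {
    warning("t0 = t1 boundary case: stability is neutral to this tolerance")
    return("neutral")
  }
  if (tw$t1 < tw$t0) "stable" else "neutral"
}

#' Rotation number of the stroboscopic map
#'
#' Estimates \eqn{\lim_n F^n(\vartheta)/n} by iteration. The raw estimate
#' \eqn{(F^n(\vartheta)-\vartheta)/n} converges at rate O(1/n); the
#' reported `value` uses the tail average
#' \eqn{(F^n - F^{n/2})/(n - n/2)}, which kills the transient exactly
#' for maps with an attracting fixed point (rotation number 0) and is
#' exact for rigid rotations.
#'
#' @param forcing a `forcing_signal` (ignored if `map` is given).
#' @param params a [model_params()] (ignored if `map` is given).
#' @param n_iter number of iterations, >= 2.
#' @param theta0 starting phase.
#' @param map optional precomputed `strobo_map` (much faster).
#' @return list with `value`, `raw`, `n_iter`, `fixed_point_detected`.
#' @export
rotation_number <- function(forcing = NULL, params = NULL, n_iter = 256,
                            theta0 = 0, map = NULL) {
  if (n_iter < 2) stop("n_iter must be >= 2")
  if (is.null(map)) {
    if (is.null(forcing) || is.null(params))
      stop("provide either a decomposed map or (forcing, params)")
    map <- strobe_decompose(forcing, params)
  }
  orbit <- iterate_map(map, theta0, n_iter)$orbit
  n <- n_iter
  h <- floor(n / 2)
  value <- (orbit[n + 1] - orbit[h + 1]) / (n - h)
  raw <- (orbit[n + 1] - orbit[1]) / n
  list(value = value, raw = raw, n_iter = n,
       fixed_point_detected = abs(orbit[n + 1] - orbit[n]) < 1e-9)
}

#' Iterate a decomposed stroboscopic map
#'
#' @param map a `strobo_map`.
#' @param theta0 starting lift value.
#' @param n number of iterations, >= 0.
#' @param tol convergence-detection tolerance.
#' @return list with `orbit` (length `n + 1` lift values), `theta_end`,
#'   `limit_mod1`, `translate` (the integer translate of the limit when
#'   convergent), `converged`.
#' @export
iterate_map <- function(map, theta0, n, tol = 1e-10) {
  orbit <- numeric(n + 1)
  orbit[1] <- as.numeric(theta0)
  th <- orbit[1]
  for (i in seq_len(n)) {
    th <- strobe_apply(map, th)
    orbit[i + 1] <- th
  }
  converged <- n >= 1 && abs(orbit[n + 1] - orbit[n]) < tol
  list(orbit = orbit, theta_end = th, limit_mod1 = th %% 1,
       translate = if (converged) floor(th + 1e-9) else NA_integer_,
       converged = converged)
}

#' Stroboscopic orbit of a downstream site
#'
#' The phase of site `s` at stroboscopic times follows the non-autonomous
#' composition of the return maps driven by site `s-1`'s trajectory. It is
#' computed here by direct chain simulation sampled at multiples of the
#' period: \eqn{\theta_s(\vartheta_1,...,\vartheta_s, n\tau) - n}.
#'
#' @param forcing a `forcing_signal`.
#' @param params a [model_params()].
#' @param upstream_initials initial phases of sites `1..s-1`.
#' @param theta_s initial phase of site `s`.
#' @param n number of periods.
#' @return list with `orbit` (length `n + 1`), `theta_end`, `limit_mod1`,
#'   `converged`.
#' @export
composed_site_map <- function(forcing, params, upstream_initials, theta_s, n) {
  if (length(upstream_initials) < 1)
    stop("composed_site_map targets sites s >= 2; use strobe_eval/iterate_map for site 1")
  tau <- forcing$period
  sol <- simulate_chain(forcing, c(upstream_initials, theta_s), params,
                        n * tau)
  s <- length(upstream_initials) + 1L
  ks <- 0:n
  orbit <- pw_eval(sol$paths[[s]], ks * tau) - ks
  list(orbit = orbit, theta_end = orbit[n + 1],
       limit_mod1 = orbit[n + 1] %% 1,
       converged = abs(orbit[n + 1] - orbit[n]) < 1e-10)
}

#' Locate the exceptional (unstable) initial phase of a site
#'
#' Every site has exactly one exceptional initial phase that fails to be
#' attracted to the wave (given non-exceptional upstream phases). Across
#' it, the integer translate of the orbit limit jumps by one; the
#' location is found by bisection on that jump. For site 1 this is the
#' unstable fixed point of the stroboscopic map.
#'
#' @param forcing a `forcing_signal`.
#' @param params a [model_params()].
#' @param upstream_initials initial phases of sites `1..s-1` (empty vector
#'   for site 1); they must avoid their own exceptional values.
#' @param bracket `c(lo, hi)` bracketing the jump (orbit limits must
#'   differ by one revolution).
#' @param n_periods periods used per orbit evaluation.
#' @param tol target precision of the location.
#' @param max_iter bisection cap.
#' @return the location estimate (numeric), with attribute `iterations`.
#' @export
find_unstable_initial <- function(forcing, params,
                                  upstream_initials = numeric(0),
                                  bracket = c(0, 1 - 1e-9),
                                  n_periods = 150, tol = 1e-10,
                                  max_iter = 60) {
  tau <- forcing$period
  s <- length(upstream_initials) + 1L
  orbit_end <- function(th) {
    sol <- simulate_chain(forcing, c(upstream_initials, th), params,
                          n_periods * tau)
    pw_eval(sol$paths[[s]], n_periods * tau) - n_periods
  }
  lo <- bracket[1]; hi <- bracket[2]
  z_lo <- orbit_end(lo); z_hi <- orbit_end(hi)
  if (abs((z_hi - z_lo) - 1) > 0.25)
    stop("no unstable point bracketed: orbit limits at the bracket ends do not differ by one revolution")
  it <- 0L
  while (hi - lo > tol && it < max_iter) {
    mid <- (lo + hi) / 2
    if (orbit_end(mid) - z_lo >= 0.5) hi <- mid else lo <- mid
    it <- it + 1L
  }
  structure((lo + hi) / 2, iterations = it)
}
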