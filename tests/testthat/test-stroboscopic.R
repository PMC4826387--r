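test_that("stroboscopic map values match hand event computations", {
  par <- worked_params()
  tw <- worked_tw()
  # the wave fixed point f(alpha)
  expect_equal(strobe_eval(tw$shape, par, 0.4), 0.4, tolerance = 1e-12)
  # theta = 0: accelerated on [0, t0], drift after -> eps*(t0 - sigma)
  expect_equal(strobe_eval(tw$shape, par, 0), 1 / 12, tolerance = 1e-12)
  # theta = 0.9 lies on the expanding branch: F = 1.5*theta - 5/12
  expect_equal(strobe_eval(tw$shape, par, 0.9), 1.5 * 0.9 - 5 / 12,
               tolerance = 1e-12)
  # iterate property: F^n(theta) = theta(n*tau) - n
  th <- 0.27
  p <- evolve_site(tw$shape, th, par, 3 * tw$tau)
  f3 <- strobe_eval(tw$shape, par,
                    strobe_eval(tw$shape, par, strobe_eval(tw$shape, par, th)))
  expect_equal(f3, pw_eval(p, 3 * tw$tau) - 3, tolerance = 1e-12)
})

test_that("worked-set decomposition has the four known pieces and fixed points", {
  par <- worked_params()
  tw <- worked_tw()
  m <- strobe_decompose(tw$shape, par)
  expect_equal(nrow(m$pieces), 4L)
  expect_equal(m$pieces$left, c(0, 0.15, 0.6, 0.7), tolerance = 1e-9)
  expect_equal(m$pieces$slope, c(1, 2 / 3, 1, 1.5), tolerance = 1e-9)
  expect_equal(m$pieces$intercept, c(1 / 12, 2 / 15, -1 / 15, -5 / 12),
               tolerance = 1e-9)
  expect_equal(m$pieces$power, c(0L, -1L, 0L, 1L))
  fp <- m$fixed_points[order(m$fixed_points$theta), ]
  expect_equal(fp$theta, c(0.4, 5 / 6), tolerance = 1e-9)
  expect_identical(fp$class, c("stable", "unstable"))
  # degree-1 identity: sum slope*length = 1
  expect_equal(sum(m$pieces$slope * (m$pieces$right - m$pieces$left)), 1,
               tolerance = 1e-12)
  # decomposition evaluates identically to direct simulation
  grid <- seq(0, 1 - 1e-9, length.out = 200)
  expect_equal(strobe_apply(m, grid), strobe_eval(tw$shape, par, grid),
               tolerance = 1e-11)
})

test_that("map is a strictly increasing degree-1 lift on random fixtures", {
  for (k in 1:8) {
    fx <- sample_admissible_fixture(seed = 900 + k, mode = "stable")
    tw <- build_tw(fx$params, fx$alpha)
    m <- strobe_decompose(tw$shape, fx$params)
    grid <- seq(0, 1 - 1e-9, length.out = 300)
    Fv <- strobe_apply(m, grid)
    expect_true(all(diff(Fv) > -1e-12))
    expect_equal(strobe_apply(m, grid + 1), Fv + 1, tolerance = 1e-12)
    expect_equal(sum(m$pieces$slope * (m$pieces$right - m$pieces$left)), 1,
                 tolerance = 1e-10)
    # slopes are integer powers of (1 + eps)
    e <- as.numeric(fx$params$epsilon)
    expect_lt(max(abs(m$pieces$slope - (1 + e)^m$pieces$power)), 1e-7)
    # exactly one stable and one unstable fixed point, stable at f(alpha)
    expect_identical(sort(m$fixed_points$class), c("stable", "unstable"))
    st <- m$fixed_points$theta[m$fixed_points$class == "stable"]
    expect_lt(circle_distance(st, f_eval(tw$shape, tw$alpha)), 1e-8)
  }
})

test_that("fixed-point solver handles rotations and the identity", {
  rot <- structure(list(pieces = data.frame(left = 0, right = 1, slope = 1,
                                            intercept = 0.3, power = 0L),
                        tau = 1), class = "strobo_map")
  fp <- find_fixed_points(rot)
  expect_equal(nrow(fp$points), 0L)
  expect_length(fp$neutral_segments, 0L)
  ident <- structure(list(pieces = data.frame(left = 0, right = 1, slope = 1,
                                              intercept = 0, power = 0L),
                          tau = 1), class = "strobo_map")
  fpi <- find_fixed_points(ident)
  expect_length(fpi$neutral_segments, 1L)
})

test_that("wave stability classification follows the t1 vs t0 dichotomy", {
  par <- worked_params()
  expect_identical(classify_stability(worked_tw()), "stable")
  tw_lo <- build_tw(par, 0.1)  # t1 = 1/3 > t0 = 7/30
  expect_equal(tw_lo$t0, 7 / 30, tolerance = 1e-12)
  expect_identical(classify_stability(tw_lo), "neutral")
  tw_b <- build_tw(par, 0.2, verify = FALSE)  # alpha = alpha0: t0 = t1 tie
  expect_warning(cls <- classify_stability(tw_b), "boundary")
  expect_identical(cls, "neutral")
  # agreement with the local slope at the wave point of the decomposition
  for (k in 1:5) {
    fx <- sample_admissible_fixture(seed = 30 + k, mode = "stable")
    tw <- build_tw(fx$params, fx$alpha)
    m <- strobe_decompose(tw$shape, fx$params)
    st <- m$fixed_points[m$fixed_points$class == "stable", ]
    expect_identical(classify_stability(tw), "stable")
    expect_lt(st$slope, 1)
  }
})

test_that("rotation number vanishes for waves and equals c for rigid rotations", {
  par <- worked_params()
  tw <- worked_tw()
  m <- strobe_decompose(tw$shape, par)
  rn <- rotation_number(map = m, n_iter = 300, theta0 = 0.05)
  expect_equal(rn$value, 0, tolerance = 1e-12)
  expect_true(rn$fixed_point_detected)
  rot <- structure(list(pieces = data.frame(left = 0, right = 1, slope = 1,
                                            intercept = 0.3, power = 0L),
                        tau = 1), class = "strobo_map")
  rr <- rotation_number(map = rot, n_iter = 64)
  expect_equal(rr$value, 0.3, tolerance = 1e-12)
  # two starting points differ by < 2/n in the raw estimate
  r1 <- rotation_number(map = m, n_iter = 100, theta0 = 0.1)$raw
  r2 <- rotation_number(map = m, n_iter = 100, theta0 = 0.9)$raw
  expect_lt(abs(r1 - r2), 2 / 100)
})

test_that("orbits converge to the stable point at the contraction rate", {
  par <- worked_params()
  tw <- worked_tw()
  m <- strobe_decompose(tw$shape, par)
  it <- iterate_map(m, 0, 100)
  expect_true(it$converged)
  expect_equal(it$limit_mod1, 0.4, tolerance = 1e-9)
  # eventual geometric rate <= 1/(1+eps) = 2/3 once inside the contracting piece
  d <- abs(it$orbit - it$theta_end)
  i <- which(d < 0.05 & d > 1e-12)
  if (length(i) > 3) {
    ratios <- d[i[-1]] / d[i[-length(i)]]
    expect_true(all(ratios <= 2 / 3 + 1e-6))
  }
  # the unstable point stays fixed; the wave point stays fixed
  expect_equal(iterate_map(m, 5 / 6, 30)$orbit[16], 5 / 6, tolerance = 1e-6)
  expect_equal(iterate_map(m, 0.4, 50)$theta_end, 0.4, tolerance = 1e-12)
})

test_that("global stability: 200 seeded starts all reach the wave point", {
  par <- worked_params()
  tw <- worked_tw()
  m <- strobe_decompose(tw$shape, par)
  set.seed(123)
  starts <- runif(200)
  starts <- starts[abs(starts - 5 / 6) > 1e-9]
  ends <- vapply(starts, function(s) iterate_map(m, s, 200)$limit_mod1,
                 numeric(1))
  expect_true(all(circle_distance(ends, 0.4) < 1e-9))
})

test_that("downstream stroboscopic orbits reach the shifted wave values", {
  par <- worked_params()
  tw <- worked_tw()
  set.seed(3)
  th1 <- runif(1)
  o2 <- composed_site_map(tw$shape, par, th1, 0.1, 300)
  expect_lt(circle_distance(o2$limit_mod1, 13 / 15), 1e-6)  # f(2 alpha)
  o3 <- composed_site_map(tw$shape, par, c(th1, 0.1), 0.55, 300)
  expect_lt(circle_distance(o3$limit_mod1, 4 / 15), 1e-6)   # f(3 alpha)
})

test_that("exceptional initial phases are located by translate bisection", {
  par <- worked_params()
  tw <- worked_tw()
  u1 <- find_unstable_initial(tw$shape, par)
  expect_lt(abs(u1 - 5 / 6), 1e-10)
  # site 2 with site 1 on the wave: the driving signal is the
  # alpha-shifted shape, whose unstable fixed point sits at the unstable
  # periodic solution evaluated at alpha (= 0.3 for the worked set)
  u2 <- find_unstable_initial(tw$shape, par,
                              upstream_initials = f_eval(tw$shape, tw$alpha))
  expect_lt(abs(u2 - 0.3), 1e-9)
  # independent route: decomposition of the shifted forcing
  m2 <- strobe_decompose(time_shift(tw$shape, tw$alpha), par)
  un <- m2$fixed_points$theta[m2$fixed_points$class == "unstable"]
  expect_lt(abs(un - 0.3), 1e-9)
  # the defining property: +/- perturbations converge to f(2 alpha) on
  # both sides, with integer translates differing by one
  lo <- composed_site_map(tw$shape, par, 0.4, u2 - 1e-6, 150)
  hi <- composed_site_map(tw$shape, par, 0.4, u2 + 1e-6, 150)
  expect_lt(circle_distance(lo$limit_mod1, 13 / 15), 1e-6)
  expect_lt(circle_distance(hi$limit_mod1, 13 / 15), 1e-6)
  expect_equal(round(hi$theta_end - lo$theta_end), 1)
  # a bracket with no jump is rejected
  expect_error(find_unstable_initial(tw$shape, par, bracket = c(0.3, 0.5),
                                     n_periods = 60),
               "no unstable point bracketed")
})
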