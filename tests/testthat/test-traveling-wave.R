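test_that("closed-form wave times match hand evaluation, exactly in rational mode", {
  tm <- tw_times(worked_params(), 0.4)
  expect_equal(tm$t0, 0.3)
  expect_equal(tm$t1, 2 / 15)
  expect_equal(tm$sigma, 2 / 15)
  expect_equal(tm$tau, 14 / 15)

  tme <- tw_times(worked_params_exact(), rational(2, 5))
  expect_true(tme$t0 == rational(3, 10))
  expect_true(tme$t1 == rational(2, 15))
  expect_true(tme$sigma == rational(2, 15))
  expect_true(tme$tau == rational(14, 15))

  # boundary behaviours of the two candidate times
  expect_equal(tw_times(worked_params(), 0.6)$t1, 0)       # alpha = a1
  expect_equal(tw_times(worked_params(), 0.35)$t0, 0.3)    # alpha >= a0
  expect_error(tw_times(worked_params(), 0.7), "no case-\\(a\\)")
  expect_error(tw_times(worked_params(), -0.1), ">= 0")
})

test_that("sigma = min(t0, t1) and tau = 1 - eps*sigma on random draws", {
  set.seed(101)
  for (i in 1:1000) {
    par <- model_params(runif(1, 0.05, 1), runif(1, 0.05, 0.95),
                        runif(1, 0.05, 0.95))
    a <- runif(1, 0, as.numeric(par$a1) * 0.999)
    tm <- tw_times(par, a)
    expect_true(abs(tm$sigma - min(tm$t0, tm$t1)) <= 1e-12)
    expect_true(abs(tm$tau - (1 - as.numeric(par$epsilon) * tm$sigma)) <= 1e-12)
    expect_true(tm$sigma >= 0 && tm$sigma <= tm$tau)
  }
})

test_that("worked-set admissibility intervals match the closed forms", {
  iv <- alpha_intervals(worked_params())
  expect_equal(iv$existence, c(0, 0.6))
  expect_true(iv$existence_open[2])     # bound is the strict alpha < a1
  expect_equal(iv$stable, c(0.2, 0.6))  # alpha0 = max(0.15, 0.2)
  expect_equal(iv$alpha0, 0.2)
  expect_equal(iv$uniform, c(24 / 115, 0.6), tolerance = 1e-12)
  expect_false(iv$uniform_empty)
})

test_that("stable interval is non-empty for random valid parameters and nests", {
  set.seed(202)
  for (i in 1:1000) {
    par <- model_params(runif(1, 0.05, 1), runif(1, 0.05, 0.95),
                        runif(1, 0.05, 0.95))
    iv <- alpha_intervals(par)
    # lower stability threshold strictly below the existence upper bound
    expect_lt(iv$stable[1], iv$stable[2])
    expect_true(iv$stable[1] >= iv$existence[1])
    expect_true(iv$stable[2] <= iv$existence[2])
    if (!iv$uniform_empty) {
      expect_true(iv$uniform[1] >= iv$stable[1] - 1e-12)
      expect_true(iv$uniform[2] <= iv$stable[2] + 1e-12)
    }
    # alpha0 never exceeds the raw upper bound (printed ordering)
    expect_true(max(0, iv$alpha0) < min(as.numeric(par$a1), iv$alpha_hi_raw) + 1e-12)
  }
})

test_that("a1 <= a0 makes the whole existence interval stable", {
  par <- model_params(0.4, 0.6, 0.3)
  iv <- alpha_intervals(par)
  expect_true(iv$alpha0 <= 0)
  expect_equal(iv$stable[1], 0)
})

test_that("constructed shape has the closed-form knots and case-(a) markers", {
  tw <- worked_tw()
  expect_equal(tw$shape$profile$t, c(0, 0.4, 8 / 15, 14 / 15), tolerance = 1e-15)
  expect_equal(tw$shape$profile$v, c(0, 0.4, 0.6, 1), tolerance = 1e-15)
  expect_equal(f_eval(tw$shape, 0), 0)
  # f(tau - alpha) = f(8/15) = 0.6 >= a0: case (a)
  expect_equal(f_eval(tw$shape, tw$tau - tw$alpha), 0.6, tolerance = 1e-12)
  expect_identical(tw$case, "a")
  # shape(alpha) = alpha < a1
  expect_equal(f_eval(tw$shape, tw$alpha), tw$alpha, tolerance = 1e-12)
})

test_that("build_tw enforces the existence interval and alpha > 0", {
  par <- worked_params()
  expect_error(build_tw(par, 0.6), "alpha < a1")
  expect_error(build_tw(par, 0), "wave number 0")
  tw0 <- build_tw(par, 0, allow_zero = TRUE)
  expect_equal(f_eval(tw0$shape, 0), 0)
  # a parameter set where the second (non-strict) bound binds:
  # eps=0.5, a0=0.9, a1=0.8 -> bound 1 - a0 = 0.1 < a1
  par2 <- model_params(0.5, 0.9, 0.8)
  iv2 <- alpha_intervals(par2)
  expect_lt(iv2$alpha_hi_raw, as.numeric(par2$a1))
  expect_error(build_tw(par2, iv2$alpha_hi_raw + 0.01), "stimulus window")
})

test_that("case classification covers all four cases", {
  tw <- worked_tw()
  expect_identical(classify_tw_case(tw$shape, tw$alpha, worked_params()), "a")
  # synthetic signals (period 1/2 leaves slope headroom above 1) steering
  # f(alpha) vs a1 = 0.6 and f(tau - alpha) vs a0 = 0.3:
  par <- worked_params()
  fc <- forcing_from_profile(c(0, 0.1, 0.5), c(0, 0.6, 1), 0.5)
  expect_identical(classify_tw_case(fc, 0.2, par), "c")   # f(.2)=.7, f(.3)=.8
  fb <- forcing_from_profile(c(0, 0.25, 0.5), c(0, 0.25, 1), 0.5)
  expect_identical(classify_tw_case(fb, 0.45, par), "b")  # f(.45)=.85, f(.05)=.05
  expect_identical(classify_tw_case(fb, 0.25, par), "cprime") # f(.25)=.25 both below
})

test_that("round trip: every admissible alpha classifies as case (a)", {
  par <- worked_params()
  iv <- alpha_intervals(par)
  for (a in seq(0.02, iv$existence[2] - 0.02, length.out = 15)) {
    tw <- build_tw(par, a, verify = FALSE)
    expect_identical(tw$case, "a")
  }
})

test_that("tau(alpha) is continuous, bounded, and invertible piecewise", {
  set.seed(7)
  for (k in 1:20) {
    fx <- sample_admissible_fixture(seed = 400 + k, mode = "existence")
    par <- fx$params
    iv <- alpha_intervals(par)
    as_ <- seq(0, iv$existence[2] * 0.999, length.out = 101)
    taus <- vapply(as_, function(a) as.numeric(tw_times(par, a)$tau), numeric(1))
    # continuity at grid resolution
    expect_lt(max(abs(diff(taus))), 0.1)
    p <- lapply(par[c("epsilon", "a0", "a1")], as.numeric)
    lo <- 1 - p$epsilon * min(p$a0, p$a1 / (1 + p$epsilon))
    expect_true(all(taus >= lo - 1e-12 & taus <= 1 + 1e-12))
    # preimages recover alpha
    a_star <- fx$alpha
    tau_star <- as.numeric(tw_times(par, a_star)$tau)
    pre <- alpha_of_tau(par, tau_star)
    expect_true(any(abs(pre - a_star) < 1e-9))
  }
})

test_that("wide stimulus windows cap the shift at 1 - a0", {
  # with a0 > a1 the shape value at the firing time is 1 - alpha, so the
  # existence bound is alpha <= 1 - a0; just above it the three-piece
  # shape is no longer invariant (the site re-accelerates after firing)
  par <- model_params(0.2880204, 0.9082322, 0.5387497)
  iv <- alpha_intervals(par)
  expect_equal(iv$existence[2], 1 - 0.9082322, tolerance = 1e-12)
  expect_error(build_tw(par, 0.0963), "stimulus window")
  tw_ok <- build_tw(par, 0.09)  # verify = TRUE runs the invariance check
  expect_identical(tw_ok$case, "a")
  # direct falsification just above the bound: the would-be shape fails
  # the defining identity
  alpha <- 0.0921
  tm <- tw_times(par, alpha)
  e <- as.numeric(par$epsilon)
  sh <- forcing_from_profile(c(0, alpha, alpha + tm$sigma, tm$tau),
                             c(0, alpha, alpha + (1 + e) * tm$sigma, 1),
                             tm$tau)
  path <- evolve_site(sh, f_eval(sh, alpha), par, tm$tau)
  grid <- sort(unique(c(path$t, sh$profile$t)))
  expect_gt(max(abs(pw_eval(path, grid) - f_eval(sh, grid + alpha))), 1e-6)
  expect_identical(classify_tw_case(sh, alpha, par), "cprime")
})

test_that("wave identity: one forced site reproduces the shifted shape", {
  tw <- worked_tw()
  par <- worked_params()
  horizon <- 5 * tw$tau
  path <- evolve_site(tw$shape, f_eval(tw$shape, tw$alpha), par, horizon)
  err <- sup_vs_fun(path, function(t) f_eval(tw$shape, t + tw$alpha),
                    extra = forcing_knots(tw$shape, horizon + tw$alpha) - tw$alpha)
  expect_lt(err, 1e-9)
})
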