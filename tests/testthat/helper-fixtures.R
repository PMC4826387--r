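# Shared fixtures: the worked parameter set (epsilon = 1/2, a0 = 3/10,
# a1 = 3/5, alpha = 2/5) has fully hand-computable closed forms:
# t0 = 3/10, t1 = sigma = 2/15, tau = 14/15, shape knots
# (0,0), (2/5,2/5), (8/15,3/5), (14/15,1).

worked_params <- function() model_params(0.5, 0.3, 0.6)

worked_params_exact <- function()
  model_params(rational(1, 2), rational(3, 10), rational(3, 5))

worked_tw <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_tw(worked_params(), 0.4)
    cache
  }
})

# sup of |path - fun| over the union of the path's breakpoints and extra
# knots (exact for piecewise-affine fun whose knots are included)
sup_vs_fun <- function(path, fun, extra = numeric(0)) {
  grid <- sort(unique(c(path$t, extra)))
  grid <- grid[grid >= path$t[1] & grid <= path$t[length(path$t)]]
  max(abs(pw_eval(path, grid) - fun(grid)))
}

# all breakpoints of a forcing lift within [0, T]
forcing_knots <- function(f, T) {
  base <- f$profile$t[-length(f$profile$t)]
  ks <- 0:ceiling(T / f$period)
  kn <- as.vector(outer(base, ks * f$period, `+`))
  sort(kn[kn <= T])
}
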