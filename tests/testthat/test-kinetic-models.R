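test_that("Erlang unwound fraction behaves as a first-passage CDF", {
  expect_equal(erlang_fraction_unwound(0, n = 5, k = 10), 0)
  expect_equal(erlang_fraction_unwound(log(2) / 7, n = 1, k = 7), 0.5)
  expect_equal(erlang_fraction_unwound(1e6, n = 5, k = 10), 1)

  tt <- seq(0, 2, length.out = 100)
  f <- erlang_fraction_unwound(tt, n = 10, k = 5)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  # single step is a pure exponential
  expect_equal(erlang_fraction_unwound(tt, n = 1, k = 3),
               1 - exp(-3 * tt), tolerance = 1e-12)

  expect_error(erlang_fraction_unwound(-1, 5, 10))
  expect_error(erlang_fraction_unwound(1, 0, 10))
  expect_error(erlang_fraction_unwound(1, 5, -2))
})

test_that("n-step trace has baseline, plateau, lag and Erlang median", {
  p <- nstep_params(40, 150, 40, baseline = 0.3, amplitude = 2)
  expect_equal(nstep_trace(0, p), 0.3)
  expect_equal(nstep_trace(1e5, p), 2.3, tolerance = 1e-12)
  # presteady-state lag: far below 1% of amplitude at a tenth of the mean
  p10 <- nstep_params(10, 5, 40, amplitude = 1)
  expect_lt(nstep_trace(0.1 * 10 / 5, p10), 0.01)
  # half-amplitude is reached at the Erlang median, near the mean n/k
  t50 <- qgamma(0.5, shape = 40, rate = 150)
  expect_equal(nstep_trace(t50, p), 0.3 + 0.5 * 2, tolerance = 1e-12)
  expect_equal(t50, 40 / 150, tolerance = 0.02)
  expect_error(nstep_trace(c(2, 1), p))
})

test_that("average unwinding rate is step size times step rate", {
  expect_equal(average_unwinding_rate(nstep_params(40, 150, 40)), 150)
  expect_equal(average_unwinding_rate(nstep_params(20, 150, 40)), 300)
  k <- 73.2
  expect_equal(average_unwinding_rate(nstep_params(40, k, 40)),
               40 / (40 / k))
})

test_that("hyperbolic rate law evaluates and saturates correctly", {
  p <- hyperbolic_params(kcat = 150, Km = 80)
  expect_equal(hyperbolic_rate(0, p), 0)
  expect_equal(hyperbolic_rate(80, p), 75)
  expect_equal(hyperbolic_rate(500, p), 150 * 500 / 580)
  expect_equal(round(hyperbolic_rate(500, p), 2), 129.31)
  expect_error(hyperbolic_rate(-5, p))
})

test_that("ordered mechanism is hyperbolic with Km = Kd*(1 + 1/K1)", {
  for (K1 in c(1 / 3, 1 / 26)) {
    p <- ordered_params(K1, Kd_nt = 10, kcat = 160)
    lim <- capture_model_limits(p)
    expect_equal(lim$kcat, 160)
    expect_equal(lim$Km, 10 * (1 + 1 / K1))
    expect_equal(ordered_rate(1e9, p), 160, tolerance = 1e-6)
    expect_equal(ordered_rate(lim$Km, p), 80)
  }
  expect_equal(capture_model_limits(ordered_params(1 / 3, 10, 160))$Km, 40)
  expect_equal(capture_model_limits(ordered_params(1 / 26, 10, 160))$Km, 270)
  # capture never limiting: Km tends to Kd
  expect_equal(capture_model_limits(ordered_params(1e12, 10, 160))$Km, 10,
               tolerance = 1e-9)
  # degenerate boundary
  r0 <- ordered_rate(c(1, 10), ordered_params(0, 10, 160))
  expect_true(isTRUE(attr(r0, "degenerate")))
  expect_equal(as.numeric(r0), c(0, 0))
})

test_that("capture model variants obey their limits and nesting", {
  cc <- exp(seq(log(1), log(5000), length.out = 100))
  # variant C reduces exactly to variant B at K1 = 0
  for (K2 in c(0.2, 1, 5)) {
    pB <- capture_params(K2 = K2, Kd_t = 90, kcat = 130, variant = "B")
    pC <- capture_params(K1 = 0, K2 = K2, Kd_t = 90, kcat = 130,
                         variant = "C")
    expect_equal(capture_model_rate(cc, pC), capture_model_rate(cc, pB),
                 tolerance = 1e-12)
  }
  # variant A saturates at kcat regardless of K1
  for (K1 in 10^seq(-3, 3)) {
    pA <- capture_params(K1 = K1, Kd_t = 90, kcat = 130, variant = "A")
    expect_equal(capture_model_limits(pA)$kcat, 130, tolerance = 1e-10)
  }
  # saturating rates of variant C at the two printed extremes
  limC <- function(K2) capture_model_limits(
    capture_params(K1 = 0.5, K2 = K2, Kd_t = 90, kcat = 130,
                   variant = "C"))$kcat
  expect_equal(limC(1), 65)
  expect_equal(limC(3 / 23), 15)
  # degenerate flags
  expect_true(isTRUE(attr(capture_model_rate(
    10, capture_params(K1 = 0, Kd_t = 90, kcat = 130, variant = "A")),
    "degenerate")))
  expect_true(isTRUE(attr(capture_model_limits(
    capture_params(K1 = 1, K2 = 0, Kd_t = 90, kcat = 130, variant = "C")),
    "degenerate")))
})

test_that("apparent limits match a hyperbola fitted to the exact curve", {
  set.seed(7)
  models <- c(list(random_ordered()),
              lapply(c("A", "B", "C"), random_capture))
  for (p in models) {
    lim <- capture_model_limits(p)
    f <- fit_hyperbola(exact_titration(
      p, conc = exp(seq(log(lim$Km / 50), log(lim$Km * 100),
                        length.out = 50))))
    expect_equal(coef(f)[["kcat"]], lim$kcat, tolerance = 1e-6)
    expect_equal(coef(f)[["Km"]], lim$Km, tolerance = 1e-6)
  }
})

test_that("steady-state occupancy oracle validates every closed form", {
  cc <- c(0, exp(seq(log(0.5), log(1e5), length.out = 25)))
  set.seed(11)
  for (i in 1:20) {
    po <- random_ordered()
    expect_equal(steady_state_rate_oracle(scheme_ordered(po), cc),
                 ordered_rate(cc, po), tolerance = 1e-10)
    for (v in c("A", "B", "C")) {
      pv <- random_capture(v)
      expect_equal(steady_state_rate_oracle(scheme_capture(pv), cc),
                   as.numeric(capture_model_rate(cc, pv)),
                   tolerance = 1e-10)
    }
  }
})

test_that("oracle handles simple schemes and rejects broken ones", {
  # two-state scheme saturated at K = 1: half the enzyme is competent
  sch <- kinetic_scheme(
    states = c("E", "E.S"),
    edges = data.frame(from = "E", to = "E.S", type = "equilibrium", K = 1),
    catalytic_state = "E.S", kcat = 100)
  expect_equal(steady_state_rate_oracle(sch, c(1, 50)), c(50, 50))
  # ordered scheme at c = apparent Km gives kcat/2
  po <- ordered_params(1 / 3, 10, 160)
  expect_equal(steady_state_rate_oracle(scheme_ordered(po), 40), 80)
  # a cycle violating detailed balance is rejected
  bad <- kinetic_scheme(
    states = c("A", "B", "C"),
    edges = data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                       type = "equilibrium", K = c(2, 3, 5)),
    catalytic_state = "C", kcat = 1)
  expect_error(steady_state_rate_oracle(bad, 1), "detailed balance")
  # unreachable state is named
  orphan <- kinetic_scheme(
    states = c("A", "B", "C"),
    edges = data.frame(from = "A", to = "B", type = "equilibrium", K = 2),
    catalytic_state = "C", kcat = 1)
  expect_error(steady_state_rate_oracle(orphan, 1), "C")
})
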