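test_that("hyperbolic fitting round-trips noise-free data exactly", {
  d <- exact_titration(hyperbolic_params(150, 80))
  f <- fit_hyperbola(d)
  expect_equal(coef(f)[["kcat"]], 150, tolerance = 1e-6)
  expect_equal(coef(f)[["Km"]], 80, tolerance = 1e-6)
  expect_false(f$under_determined)
})

test_that("degenerate or non-saturating designs are flagged", {
  # replicates at a single concentration near Km
  one <- data.frame(conc_uM = rep(80, 6), rate = rep(75, 6))
  f1 <- fit_hyperbola(one)
  expect_true(f1$under_determined)
  # no concentration reaching twice the fitted Km
  low <- exact_titration(hyperbolic_params(150, 500),
                         conc = c(5, 10, 50, 100, 200))
  expect_true(fit_hyperbola(low)$under_determined)
})

test_that("hyperbolic fitting recovers truth from noisy titrations", {
  set.seed(42)
  ok <- replicate(200, {
    d <- simulate_titration(hyperbolic_params(90, 120),
                            relative_noise = 0.03,
                            seed = sample.int(1e6, 1))
    est <- coef(fit_hyperbola(d))
    abs(est["kcat"] - 90) / 90 < 0.15 && abs(est["Km"] - 120) / 120 < 0.15
  })
  expect_gte(mean(ok), 0.95)
})

test_that("global ordered fit recovers shared kcat and per-dataset K1", {
  K1s <- c(1 / 3, 1 / 26)
  ds <- lapply(K1s, function(K1)
    simulate_titration(ordered_params(K1, 10, 160), relative_noise = 0))
  g <- fit_ordered_global(ds, Kd_nt = 10)
  expect_equal(g$shared[["kcat"]], 160, tolerance = 1e-4)
  expect_equal(g$per_dataset$K1, K1s, tolerance = 1e-4)
  expect_equal(g$per_dataset$apparent_Km, c(40, 270), tolerance = 1e-3)
  expect_equal(g$fixed$Kd_nt, 10)

  # noisy recovery: K1 within 15%, kcat within 5% at 3% noise
  dn <- lapply(seq_along(K1s), function(i)
    simulate_titration(ordered_params(K1s[i], 10, 160),
                       relative_noise = 0.03, seed = 20 + i))
  gn <- fit_ordered_global(dn, Kd_nt = 10)
  expect_equal(gn$shared[["kcat"]], 160, tolerance = 0.05)
  expect_equal(gn$per_dataset$K1, K1s, tolerance = 0.15)
})

test_that("recovered K1 decreases with GC when generated that way", {
  gc <- c(20, 35, 50, 65)
  K1s <- c(0.6, 0.3, 0.12, 0.04)  # harder capture at higher GC
  ds <- lapply(seq_along(gc), function(i)
    simulate_titration(ordered_params(K1s[i], 10, 160),
                       relative_noise = 0.03, seed = 30 + i,
                       metadata = list(GC_percent = gc[i])))
  g <- fit_ordered_global(ds, Kd_nt = 10)
  expect_true(all(diff(g$per_dataset$K1) < 0))
  expect_equal(g$per_dataset$dataset, paste0("GC", gc))
})

test_that("global kcat is invariant to dataset ordering", {
  ds <- lapply(c(0.5, 0.1, 0.03), function(K1)
    simulate_titration(ordered_params(K1, 10, 160),
                       relative_noise = 0.03, seed = round(100 * K1)))
  a <- fit_ordered_global(ds, Kd_nt = 10)$shared[["kcat"]]
  b <- fit_ordered_global(rev(ds), Kd_nt = 10)$shared[["kcat"]]
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("all-zero-rate datasets are excluded with a warning", {
  good <- lapply(c(0.5, 0.1), function(K1)
    simulate_titration(ordered_params(K1, 10, 160), relative_noise = 0))
  dead <- data.frame(conc_uM = c(5, 50, 500), rate = c(0, 0, 0))
  expect_warning(g <- fit_ordered_global(c(good, list(dead)), Kd_nt = 10),
                 "excluding")
  expect_equal(nrow(g$per_dataset), 2L)
})

test_that("capture-model fitting round-trips and orders variants", {
  truth <- capture_params(K1 = 0.5, K2 = 1, Kd_t = 90, kcat = 130,
                          variant = "C")
  d <- list(simulate_titration(truth, relative_noise = 0))
  fits <- fit_capture_models(d, Kd_t = 90, kcat = 130)
  expect_equal(fits$C$per_dataset$K1, 0.5, tolerance = 1e-4)
  expect_equal(fits$C$per_dataset$K2, 1, tolerance = 1e-4)
  # fixed constants echoed verbatim
  expect_identical(fits$C$fixed, list(Kd_t = 90, kcat = 130))
  # variant A cannot reach the depressed plateau: strictly worse SSE
  expect_gt(fits$A$sse, fits$C$sse)

  # K2 > K1 truth is recovered with that ordering intact
  t2 <- capture_params(K1 = 0.2, K2 = 0.9, Kd_t = 90, kcat = 130,
                       variant = "C")
  d2 <- list(simulate_titration(t2, relative_noise = 0.03, seed = 4))
  f2 <- fit_capture_models(d2, variants = "C")$C
  expect_gt(f2$per_dataset$K2, f2$per_dataset$K1)
})

test_that("model selection demands an AIC gap before declaring a winner", {
  d <- list(simulate_titration(
    capture_params(K1 = 0.5, K2 = 1, Kd_t = 90, kcat = 130, variant = "C"),
    relative_noise = 0.03, seed = 2))
  fits <- fit_capture_models(d)
  r <- select_model(fits)
  expect_s3_class(r, "model_ranking")
  expect_true(all(diff(r$ranking$aic) >= 0))
  # identical fits are indistinguishable
  expect_equal(select_model(list(fits$C, fits$C))$winner,
               "indistinguishable")
  # fits on different data refuse to be ranked
  other <- fit_capture_models(list(simulate_titration(
    capture_params(K1 = 0.5, K2 = 1, Kd_t = 90, kcat = 130, variant = "C"),
    relative_noise = 0.03, seed = 99)))
  expect_error(select_model(list(fits$C, other$A)), "identical")
})

test_that("the true generating model wins the AIC ranking when it is A", {
  # A-generated data: C (which nests A's plateau only at K2 -> Inf) must
  # not beat A beyond the parameter penalty
  truth <- capture_params(K1 = 0.8, Kd_t = 90, kcat = 130, variant = "A")
  set.seed(42)
  wins_against_A <- replicate(25, {
    ds <- lapply(1:3, function(i)
      simulate_titration(truth, relative_noise = 0.03,
                         seed = sample.int(1e6, 1)))
    fits <- fit_capture_models(ds)
    sel <- select_model(fits)
    sel$winner == "capture_C" &&
      sel$ranking$delta_aic[sel$ranking$model == "capture_A"] > 2
  })
  expect_lt(mean(wins_against_A), 0.5)
})
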