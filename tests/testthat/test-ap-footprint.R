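test_that("background correction subtracts buffer and protein signal", {
  expect_equal(correct_intensity(100, 0, 0), 100)
  expect_equal(correct_intensity(120, 10, 25), 95)
  out <- correct_intensity(10, 10, 15)
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "unusable")))
  expect_error(correct_intensity(-1))
})

test_that("fold changes propagate first-order errors", {
  expect_equal(fold_change(100, 100)$fold, 1)
  expect_equal(fold_change(200, 100)$fold, 2)
  fc <- fold_change(200, 100, sd_with = 10, sd_dna = 5)
  expect_equal(fc$sd, 2 * sqrt((10 / 200)^2 + (5 / 100)^2),
               tolerance = 1e-12)
  expect_equal(round(fc$sd, 3), 0.141)
  expect_error(fold_change(0, 100))
  expect_error(fold_change(100, -2))
})

test_that("response calls require both effect size and significance", {
  expect_equal(classify_response(1.0, 0.01), "none")
  expect_equal(classify_response(1.5, 0.05), "increase")
  expect_equal(classify_response(1.5, 0.5), "none")    # fails z gate
  expect_equal(classify_response(1 / 1.5, 0.05), "decrease")
  expect_equal(classify_response(1.1, 0.01), "none")   # fails delta gate
  # thresholds are monotone: tightening never creates an increase
  folds <- seq(0.5, 3, by = 0.1)
  for (delta2 in c(0.25, 0.3)) {
    loose <- classify_response(folds, 0.02, delta = 0.2)
    tight <- classify_response(folds, 0.02, delta = delta2)
    expect_false(any(loose == "none" & tight != "none"))
  }
  for (z2 in c(3, 5)) {
    loose <- classify_response(folds, 0.1, z = 2)
    tight <- classify_response(folds, 0.1, z = z2)
    expect_false(any(loose == "none" & tight != "none"))
  }
})

test_that("polymerase pattern yields 2 melted bp and 3 contacted bases", {
  panel <- simulate_ap_panel(ap_pattern_dnap(noise = 0.02), seed = 3)
  # robust across the documented threshold range
  for (delta in c(0.1, 0.2, 0.3)) {
    fp <- infer_footprint(panel, "+DNAP", delta = delta)
    expect_equal(fp$status, "ok")
    expect_equal(fp$melted_bp, 2L)
    expect_equal(fp$contacted_template_bases, 3L)
  }
  # the internal N+3 increase carries an unstacking attribution note
  fp <- infer_footprint(panel, "+DNAP")
  n3 <- fp$calls[fp$calls$probe_position == 3 &
                   fp$calls$context == "internal" &
                   fp$calls$strand == "lagging", ]
  expect_match(n3$note, "unstacking")
})

test_that("helicase pattern yields 1 melted bp at every gap", {
  panel <- simulate_ap_panel(ap_pattern_helicase(gaps = 0:3, noise = 0.02),
                             seed = 4)
  for (g in 0:3) {
    sub <- panel[panel$gap_nt == g, ]
    class(sub) <- class(panel)
    for (delta in c(0.1, 0.2, 0.3)) {
      fp <- infer_footprint(sub, "+helicase", delta = delta)
      expect_equal(fp$melted_bp, 1L)
    }
  }
})

test_that("an all-flat panel has an empty footprint", {
  spec <- ap_effect_spec(c(1, 2, 3), "lagging",
                         c("junction", "internal", "internal"), 0,
                         "+DNAP", fold = 1, noise = 0)
  fp <- infer_footprint(simulate_ap_panel(spec, seed = 1), "+DNAP")
  expect_equal(fp$melted_bp, 0L)
  expect_equal(fp$contacted_template_bases, 0L)
})

test_that("missing disambiguation constructs give an ambiguous status", {
  # internal increase at N+2 but no junction-context probe of N+2 anywhere
  spec <- rbind(
    ap_effect_spec(1, "lagging", "junction", 0, "+DNAP", 1.6, 0),
    ap_effect_spec(2, "lagging", "internal", 0, "+DNAP", 1.6, 0))
  fp <- infer_footprint(simulate_ap_panel(spec, seed = 1), "+DNAP")
  expect_equal(fp$status, "ambiguous attribution")
  expect_true(is.na(fp$melted_bp))
})

test_that("footprints and synergy are scale-invariant", {
  panel <- simulate_ap_panel(ap_pattern_dnap(noise = 0.02), seed = 5)
  scaled <- panel
  scaled$intensity <- scaled$intensity * 37.5
  scaled$intensity_sd <- scaled$intensity_sd * 37.5
  a <- infer_footprint(panel, "+DNAP")
  b <- infer_footprint(scaled, "+DNAP")
  expect_equal(a$melted_bp, b$melted_bp)
  expect_equal(a$calls$fold, b$calls$fold, tolerance = 1e-12)

  sp <- simulate_ap_panel(ap_pattern_synergy(noise = 0.02), seed = 6)
  sp2 <- sp
  sp2$intensity <- sp2$intensity * 0.04
  sp2$intensity_sd <- sp2$intensity_sd * 0.04
  expect_equal(max_synergy_gap(sp)$max_gap, max_synergy_gap(sp2)$max_gap)
})

test_that("synergy needs excess beyond additivity and beyond error", {
  # exact additivity is not synergy
  expect_false(detect_synergy(1.3, 1.4, 1.7)$synergy)
  # a large combined excess is
  s <- detect_synergy(1.3, 1.4, 3.5, 0.02, 0.02, 0.05)
  expect_true(s$synergy)
  expect_gt(s$margin, 0)
  # 0.8 vs 0.7 excess fails the 2-sigma margin at sd 0.1 each
  expect_false(detect_synergy(1.3, 1.4, 1.8, 0.1, 0.1, 0.1)$synergy)
  expect_equal(detect_synergy(1.3, 1.4, 1.8, 0.1, 0.1, 0.1)$margin,
               0.8 - 0.7 - 2 * sqrt(3 * 0.01), tolerance = 1e-12)
  # symmetric in the two single-enzyme conditions
  expect_equal(detect_synergy(1.3, 1.6, 3.0, 0.05, 0.02, 0.03),
               detect_synergy(1.6, 1.3, 3.0, 0.02, 0.05, 0.03))
})

test_that("maximal synergistic gap is 1 nt for the canonical pattern", {
  panel <- simulate_ap_panel(ap_pattern_synergy(gaps = 0:3,
                                                synergy_gaps = 0:1,
                                                noise = 0.02), seed = 7)
  res <- max_synergy_gap(panel)
  expect_equal(res$status, "ok")
  expect_equal(res$max_gap, 1L)
  # no synergy anywhere reports "none", distinct from gap 0
  flat <- simulate_ap_panel(ap_pattern_synergy(synergy_gaps = integer(0),
                                               noise = 0.02), seed = 8)
  expect_equal(max_synergy_gap(flat)$max_gap, "none")
  # synergy only at gap 0 reports 0
  g0 <- simulate_ap_panel(ap_pattern_synergy(synergy_gaps = 0,
                                             noise = 0.02), seed = 9)
  expect_equal(max_synergy_gap(g0)$max_gap, 0L)
  # a hole in the pattern is flagged non-monotone
  holey <- simulate_ap_panel(ap_pattern_synergy(synergy_gaps = c(0, 2),
                                                noise = 0.02), seed = 10)
  expect_equal(max_synergy_gap(holey)$status, "non-monotone")
  # missing gap panels are named
  expect_error(max_synergy_gap(panel[panel$gap_nt != 1, ]), "1")
})
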