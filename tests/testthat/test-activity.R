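classify_window <- function(c_up, c_down, gabpa = TRUE) {
  call <- duplication_from_region(fx_window, fx_map, c_up, c_down)
  variant <- apply_insertion(fx_window, as_insertion(call))
  sites <- assign_origin(fx_window, variant, call)
  classify_activity(call, sites, gabpa_present = gabpa)
}

test_that("ETS 200 copies activate; ETS 195-only copies do not", {
  expect_equal(classify_window(-115, -94)$klass, "active")
  expect_equal(classify_window(-116, -95)$klass, "active")
  expect_equal(classify_window(-117, -96)$klass, "active")
  for (x in 94:98) {
    act <- classify_window(-x, -(x - 21))
    expect_equal(act$klass, "baseline")
    expect_true("contains_ETS195_only" %in% act$reasons)
  }
  # no motif copied at all
  expect_equal(classify_window(-88, -67)$klass, "baseline")
})

test_that("hotspot point variants classify active", {
  act <- classify_activity("G228A")
  expect_equal(act$klass, "active")
  expect_true("hotspot_site" %in% act$reasons)
  expect_error(classify_activity("G999A"), "unknown hotspot")
})

test_that("absence of GABPA forces baseline for every construct", {
  expect_equal(classify_window(-100, -79, gabpa = FALSE)$klass, "baseline")
  expect_equal(classify_activity("G228A", gabpa_present = FALSE)$klass, "baseline")
  rep <- window_panel_report(fx_window, fx_map)
  for (i in seq_len(nrow(rep))) {
    act <- classify_window(rep$c_up[i], rep$c_down[i], gabpa = FALSE)
    expect_equal(act$klass, "baseline")
  }
})

test_that("across the full window panel, activity is equivalent to ETS 200 containment", {
  rep <- window_panel_report(fx_window, fx_map)
  ets200_contained <- rep$template_start <= 1295200 & rep$template_end >= 1295203
  expect_equal(rep$predicted_activity == "active", ets200_contained)
  expect_equal(rep$contains_ets200, ets200_contained)
})

test_that("the spacing scan reproduces the engineered spacer series", {
  call <- duplication_from_region(fx_window, fx_map, -100, -79)
  scan <- spacing_scan(fx_window, call, deltas = c(-3, 0, 4, 8, 11))
  expect_equal(scan$d, c(19, 22, 26, 30, 33))
  expect_equal(
    scan$klass,
    c("baseline", "active", "baseline", "partial", "partial")
  )
  expect_error(spacing_scan(fx_window, call, deltas = -22), "degenerate|remove motif")
})

test_that("spacing-scan activity is periodic-peaked: non-baseline only in phase", {
  call <- duplication_from_region(fx_window, fx_map, -100, -79)
  cfg <- phase_config()
  scan <- spacing_scan(fx_window, call, deltas = -10:20, cfg = cfg)
  expect_equal(scan$klass != "baseline", scan$phase_deviation <= cfg$tol)
  expect_true(any(scan$klass == "active"))
  expect_true(any(scan$klass == "partial"))
})

test_that("reporter simulation is seeded, mean-correct and exact at zero noise", {
  exact <- simulate_reporter(c(a = "baseline"), n_replicates = 5, seed = 1, sd = 0)
  expect_true(all(exact$ratio == 1))
  a <- simulate_reporter(c(x = "active", y = "partial"), n_replicates = 4, seed = 9)
  b <- simulate_reporter(c(x = "active", y = "partial"), n_replicates = 4, seed = 9)
  expect_identical(a, b)
  big <- simulate_reporter(c(z = "active"), n_replicates = 10000, seed = 2)
  expect_equal(mean(big$ratio), 10, tolerance = 0.02)
  expect_true(all(big$firefly > 0 & big$renilla > 0))
})
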