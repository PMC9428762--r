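test_that("least squares recovers exact model coefficients to machine precision", {
  curve <- make_curve(265.5, 66.59, gait_params(peak_strain_target = 0.5))
  fit <- fit_kelvin_voigt(curve)
  expect_equal(fit$E, 265.5, tolerance = 1e-10)
  expect_equal(fit$eta, 66.59, tolerance = 1e-10)
  expect_lt(fit$residual_rms_kpa, 1e-9)
  expect_false(fit$eta_nonphysical)
})

test_that("a two-point system matches the hand-solved 2x2 solution", {
  # rows: (eps, eps*rate) = (0.2, 0.1) with sigma 50; (0.5, -0.2) with sigma 90
  # solve [0.2 0.1; 0.5 -0.2] beta = [50; 90] by hand:
  A <- matrix(c(0.2, 0.5, 0.1, -0.2), 2, 2)
  beta_hand <- solve(A, c(50, 90))
  curve <- tibble::tibble(strain = c(0.2, 0.5, 1e-9),
                          strain_rate = c(0.5, -0.4, 0),
                          stress_kpa = c(50, 90, 0))
  # third row is numerically null so the fit reduces to the 2x2 system
  fit <- fit_kelvin_voigt(structure(curve, class = c("stress_strain_curve",
                                                     class(tibble::tibble()))))
  expect_equal(fit$E, beta_hand[1], tolerance = 1e-6)
  expect_equal(fit$eta, beta_hand[2], tolerance = 1e-6)
})

test_that("static compression (zero strain rate) is unidentifiable", {
  curve <- tibble::tibble(strain = c(0.1, 0.2, 0.3, 0.4),
                          strain_rate = 0, stress_kpa = c(20, 40, 60, 80))
  expect_error(
    fit_kelvin_voigt(structure(curve, class = c("stress_strain_curve",
                                                class(tibble::tibble())))),
    class = "heelpad_unidentifiable_error")
})

test_that("tidy and glance expose the fit in broom form", {
  curve <- make_curve(220, 50, gait_params(peak_strain_target = 0.5))
  fit <- fit_kelvin_voigt(curve)
  td <- tidy(fit)
  expect_equal(td$term, c("youngs_modulus_kpa", "viscous_modulus_kpa_s"))
  expect_equal(td$estimate, c(220, 50), tolerance = 1e-8)
  gl <- glance(fit)
  expect_gt(gl$r.squared, 0.999)
  expect_equal(gl$nobs, fit$n)
})

test_that("the worked triangle loop integrates exactly", {
  tri <- tibble::tibble(strain = c(0, 0.5, 0), stress_kpa = c(0, 100, 20))
  res <- loop_areas(tri)
  expect_equal(res$dissipated, 5)
  expect_equal(res$loading_area, 25)
  expect_equal(res$edr, 20)
  # this loop's unloading branch lies above its loading branch
  expect_false(res$loop_clockwise)
})

test_that("a retraced loop dissipates nothing and degenerate loading errors", {
  flat <- tibble::tibble(strain = c(0, .25, .5, .25, 0),
                         stress_kpa = c(0, 50, 100, 50, 0))
  res <- loop_areas(flat)
  expect_equal(res$dissipated, 0)
  expect_equal(res$edr, 0)
  bad <- tibble::tibble(strain = c(0, .3, .6, .3, 0), stress_kpa = 0)
  expect_error(loop_areas(bad), class = "heelpad_degenerate_curve_error")
})

test_that("branch-wise dissipation equals the shoelace polygon area", {
  withr::with_seed(9, {
    for (rep in 1:50) {
      E <- runif(1, 150, 310); eta <- runif(1, 20, 140)
      a <- runif(1, 0.15, 0.6)
      curve <- make_curve(E, eta, gait_params(stance_duration = 0.6,
                                              peak_strain_target = a))
      res <- loop_areas(curve)
      oracle <- shoelace_area(curve$strain, curve$stress_kpa)
      expect_equal(res$dissipated, oracle, tolerance = 1e-9)
    }
  })
})

test_that("loop dissipation equals the viscous work eta * closed-path integral", {
  for (a in c(0.2, 0.4, 0.55)) {
    g <- gait_params(peak_strain_target = a)  # study-default stance window
    curve <- make_curve(280, 60, g)
    res <- loop_areas(curve)
    oracle <- viscous_work_quadrature(60, g)
    expect_equal(res$dissipated, oracle, tolerance = 0.01)
  }
})

test_that("EDR is invariant to uniform stress rescaling and nondecreasing in eta", {
  g <- gait_params(peak_strain_target = 0.5)
  curve <- make_curve(250, 50, g)
  scaled <- curve
  scaled$stress_kpa <- 3.7 * scaled$stress_kpa
  expect_equal(loop_areas(scaled)$edr, loop_areas(curve)$edr, tolerance = 1e-12)
  edrs <- vapply(c(0, 10, 30, 60, 90), function(eta) {
    loop_areas(make_curve(250, eta, g))$edr
  }, numeric(1))
  expect_true(all(diff(edrs) >= 0))
  expect_equal(edrs[1], 0, tolerance = 1e-9)
})

test_that("fitted coefficients are stable under frame-rate doubling", {
  f50 <- extract_properties(make_recording(E = 240, eta = 55, h0 = 13,
                                           peak_strain = 0.45,
                                           stance_duration = 0.6))
  f100 <- extract_properties(make_recording(E = 240, eta = 55, h0 = 13,
                                            peak_strain = 0.45,
                                            stance_duration = 0.6,
                                            frame_rate = 100))
  expect_equal(f50$youngs_modulus_kpa, f100$youngs_modulus_kpa,
               tolerance = 0.005)
  expect_equal(f50$viscous_modulus_kpa_s, f100$viscous_modulus_kpa_s,
               tolerance = 0.005)
})

test_that("full pipeline recovers generating parameters and elastic limits", {
  p <- extract_properties(make_recording(E = 214.39, eta = 42.28, h0 = 12.25,
                                         peak_strain = 0.6))
  expect_equal(p$youngs_modulus_kpa, 214.39, tolerance = 0.01)
  expect_equal(p$viscous_modulus_kpa_s, 42.28, tolerance = 0.01)
  expect_equal(p$primary_thickness_mm, 12.25, tolerance = 0.01)
  elastic <- extract_properties(make_recording(E = 200, eta = 0, h0 = 14,
                                               peak_strain = 0.5))
  expect_lt(elastic$edr_pct, 0.1)
  expect_lt(abs(elastic$viscous_modulus_kpa_s), 0.5)
})

test_that("stage errors carry the failing stage name", {
  rec <- tibble::tibble(time_s = (0:9) / 50, thickness_mm = rep(15, 10),
                        force_N = rep(0, 10), area_cm2 = rep(10, 10))
  err <- tryCatch(extract_properties(rec), error = function(e) e)
  expect_match(conditionMessage(err), "^\\[extract\\]")
})
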