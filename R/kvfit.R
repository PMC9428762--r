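#' Fit the modified Kelvin-Voigt model to a stress-strain cycle
#'
#' Ordinary least squares of stress on the two regressors \eqn{\varepsilon}
#' and \eqn{\varepsilon\dot\varepsilon} with no intercept (the model passes
#' through the origin by construction), over the full loading + unloading
#' cycle by default. The elastic coefficient is the Young's modulus E (kPa)
#' and the viscous coefficient the viscous modulus eta (kPa s); eta is
#' identified mainly by the asymmetry between the two branches.
#'
#' @param curve A `stress_strain_curve`.
#' @param branch Which branch to fit: `"cycle"` (default), `"loading"` or
#'   `"unloading"`.
#' @return A `kv_fit` object: list with `E`, `eta`, `h0_mm`,
#'   `residual_rms_kpa`, `n`, `branch`, `eta_nonphysical` (TRUE when the
#'   fitted eta is negative), `vcov`, `sigma_hat` and the fitted/observed
#'   stresses. Supports [tidy()] and [glance()].
#' @examples
#' gait <- gait_params(noise_sd_thickness = 0, noise_sd_force = 0)
#' fit <- fit_kelvin_voigt(stress_strain_curve(
#'   simulate_stance(kv_params(265.5, 66.59, 14.85), gait)))
#' tidy(fit)
#' @export
fit_kelvin_voigt <- function(curve, branch = c("cycle", "loading", "unloading")) {
  branch <- match.arg(branch)
  idx <- switch(branch,
                cycle = seq_len(nrow(curve)),
                loading = split_cycle(curve)$loading,
                unloading = split_cycle(curve)$unloading)
  if (length(idx) < 3)
    abort("Need at least 3 in-contact samples to fit.",
          class = "heelpad_length_error")
  eps <- curve$strain[idx]
  x2 <- eps * curve$strain_rate[idx]
  y <- curve$stress_kpa[idx]
  X <- cbind(strain = eps, strain_x_rate = x2)
  qrx <- qr(X)
  if (qrx$rank < 2)
    abort(paste("Regressors strain and strain*rate are collinear or constant;",
                "E and eta are not jointly identifiable",
                "(e.g. static compression with zero strain rate)."),
          class = "heelpad_unidentifiable_error")
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  dof <- length(y) - 2L
  s2 <- sum(res^2) / max(dof, 1L)
  XtXinv <- chol2inv(qr.R(qrx))
  structure(list(E = unname(beta[1]), eta = unname(beta[2]),
                 h0_mm = attr(curve, "h0_mm"),
                 residual_rms_kpa = sqrt(mean(res^2)),
                 sigma_hat = sqrt(s2),
                 vcov = s2 * XtXinv,
                 n = length(y), df_residual = dof, branch = branch,
                 eta_nonphysical = unname(beta[2]) < 0,
                 observed = y, fitted = fitted),
            class = "kv_fit")
}

#' @export
print.kv_fit <- function(x, ...) {
  cat(sprintf("Kelvin-Voigt fit (%s, n = %d): E = %.2f kPa, eta = %.2f kPa s\n",
              x$branch, x$n, x$E, x$eta))
  cat(sprintf("  residual RMS %.3f kPa%s\n", x$residual_rms_kpa,
              if (x$eta_nonphysical) "  [eta < 0: nonphysical]" else ""))
  invisible(x)
}

#' @rdname fit_kelvin_voigt
#' @param x A `kv_fit` object.
#' @param ... Unused.
#' @export
tidy.kv_fit <- function(x, ...) {
  est <- c(x$E, x$eta)
  se <- sqrt(diag(x$vcov))
  stat <- est / se
  tibble::tibble(
    term = c("youngs_modulus_kpa", "viscous_modulus_kpa_s"),
    estimate = est, std.error = se, statistic = stat,
    p.value = 2 * pt(abs(stat), df = x$df_residual, lower.tail = FALSE))
}

#' @rdname fit_kelvin_voigt
#' @export
glance.kv_fit <- function(x, ...) {
  ssr <- sum((x$observed - x$fitted)^2)
  sst <- sum(x$observed^2)  # no-intercept model: uncentred total SS
  tibble::tibble(r.squared = 1 - ssr / sst, sigma = x$sigma_hat,
                 residual_rms = x$residual_rms_kpa, nobs = x$n,
                 df.residual = x$df_residual,
                 eta_nonphysical = x$eta_nonphysical)
}

#' Hysteresis loop areas and energy dissipation ratio
#'
#' Integrates the stress-strain cycle: the area under the loading branch
#' (trapezoidal rule in strain, a strain-energy density in kPa), the area
#' under the unloading branch traversed in decreasing strain, and the
#' dissipated energy enclosed by the loop. The enclosed area is computed
#' branch-wise with the closing chord between the cycle's last and first
#' points, which is algebraically the shoelace area of the closed polygon.
#' The energy dissipation ratio is
#' \deqn{EDR = 100\,\frac{\textrm{dissipated}}{\textrm{loading area}}\,\%.}
#'
#' The magnitude of the enclosed area is reported; `loop_clockwise = FALSE`
#' flags the nonphysical orientation where the unloading branch lies above
#' the loading branch (an energy-generating loop).
#'
#' @param curve A `stress_strain_curve` (or data frame with `strain` and
#'   `stress_kpa` forming one cycle).
#' @return A named list: `dissipated` (kPa), `loading_area` (kPa),
#'   `unloading_area` (kPa), `edr` (%), `loop_clockwise`.
#' @examples
#' # straight loading to (0.5, 100 kPa), straight unloading back to (0, 20)
#' tri <- tibble::tibble(strain = c(0, 0.5, 0), stress_kpa = c(0, 100, 20))
#' loop_areas(tri)
#' @export
loop_areas <- function(curve) {
  sp <- split_cycle(curve)
  eps <- curve$strain
  sig <- curve$stress_kpa
  trapz <- function(i) sum(diff(eps[i]) * (head(sig[i], -1) + tail(sig[i], -1)) / 2)
  loading_area <- trapz(sp$loading)
  if (loading_area <= 0)
    abort("Area under the loading branch is not positive; degenerate curve.",
          class = "heelpad_degenerate_curve_error")
  # area under the unloading branch, traversed in decreasing strain
  unloading_area <- -trapz(sp$unloading)
  # closing chord from the cycle's last point back to its first
  n <- length(eps)
  closing <- (eps[1] - eps[n]) * (sig[n] + sig[1]) / 2
  # clockwise-positive circulation: positive for a dissipative loop whose
  # loading branch lies above its unloading branch
  signed <- trapz(sp$loading) + trapz(sp$unloading) + closing
  list(dissipated = abs(signed),
       loading_area = loading_area,
       unloading_area = unloading_area,
       edr = 100 * abs(signed) / loading_area,
       loop_clockwise = signed >= 0)
}

#' Extract the six heel-pad material properties from one recording
#'
#' Composes the full per-step pipeline: contact detection, primary
#' thickness, strain/stress/strain-rate derivation, cycle split, peak
#' point, Kelvin-Voigt least squares and hysteresis energetics. Errors
#' raised by a stage are annotated with the stage name.
#'
#' @param rec A stance recording.
#' @param force_threshold,rate_order,branch Passed to the respective stages.
#' @return A one-row tibble with columns `primary_thickness_mm`,
#'   `peak_strain_pct`, `peak_stress_kpa`, `youngs_modulus_kpa`,
#'   `viscous_modulus_kpa_s`, `edr_pct`, `residual_rms_kpa`,
#'   `eta_nonphysical`, `loop_clockwise`.
#' @examples
#' rec <- simulate_stance(kv_params(214.39, 42.28, 12.25),
#'                        gait_params(peak_strain_target = 0.6,
#'                                    noise_sd_thickness = 0,
#'                                    noise_sd_force = 0))
#' extract_properties(rec)
#' @export
extract_properties <- function(rec, force_threshold = NULL, rate_order = 4,
                               branch = "cycle") {
  with_stage <- function(stage, expr) {
    withCallingHandlers(expr, error = function(e) {
      abort(paste0("[", stage, "] ", conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
  }
  curve <- with_stage("extract",
                      stress_strain_curve(rec, force_threshold = force_threshold,
                                          rate_order = rate_order))
  pk <- peak_point(curve)
  fit <- with_stage("kvfit", fit_kelvin_voigt(curve, branch = branch))
  loop <- with_stage("loop", loop_areas(curve))
  tibble::tibble(
    primary_thickness_mm = attr(curve, "h0_mm"),
    peak_strain_pct = pk$peak_strain,
    peak_stress_kpa = pk$peak_stress,
    youngs_modulus_kpa = fit$E,
    viscous_modulus_kpa_s = fit$eta,
    edr_pct = loop$edr,
    residual_rms_kpa = fit$residual_rms_kpa,
    eta_nonphysical = fit$eta_nonphysical,
    loop_clockwise = loop$loop_clockwise)
}
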