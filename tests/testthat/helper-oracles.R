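# Independent oracles used across tests.

# shoelace polygon area (positive magnitude), independent of loop_areas()
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# noise-free recording with known parameters
make_recording <- function(E = 265.5, eta = 66.59, h0 = 14.85,
                           peak_strain = 0.523, ...) {
  simulate_stance(kv_params(E, eta, h0),
                  gait_params(peak_strain_target = peak_strain,
                              noise_sd_thickness = 0, noise_sd_force = 0, ...))
}

# stress-strain curve evaluated directly from the analytic trajectory
# (bypasses contact detection; exact strain reference)
make_curve <- function(E, eta, gait) {
  tr <- strain_trajectory(gait)
  curve <- tibble::tibble(frame = tr$frame, time_s = tr$time_s,
                          strain = tr$strain,
                          stress_kpa = E * tr$strain + eta * tr$strain * tr$strain_rate,
                          strain_rate = tr$strain_rate)
  peak <- which.max(curve$strain)[1]
  curve$phase <- ifelse(seq_len(nrow(curve)) <= peak, "loading", "unloading")
  out <- structure(curve, class = c("stress_strain_curve", class(tibble::tibble())))
  attr(out, "h0_mm") <- 14
  attr(out, "peak_index") <- peak
  out
}

# direct quadrature of the viscous work eta * closed-path int eps deps:
# along the trajectory this is eta * int eps(t) rate(t)^2 dt over the stance,
# integrated in the time domain on the recording's own sampling grid (an
# independent route from the strain-domain loop area)
viscous_work_quadrature <- function(eta, gait) {
  tr <- strain_trajectory(gait)
  dt <- tr$time_s[2] - tr$time_s[1]
  f <- tr$strain * tr$strain_rate^2
  eta * sum((head(f, -1) + tail(f, -1)) / 2) * dt
}
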