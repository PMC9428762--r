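#' Stance-phase compressive strain trajectory
#'
#' Evaluates the imposed compressive strain of the heel pad over one stance
#' window, together with its analytic time derivative. The trajectory is
#' zero at touchdown and toe-off and reaches a single interior maximum equal
#' to `peak_strain_target` at `peak_time_frac` of stance, so loading can be
#' faster than unloading.
#'
#' Two families are available. With `Tp = peak_time_frac * T`:
#' \describe{
#'   \item{`"smooth"`}{piecewise cubed sine,
#'     \eqn{\varepsilon(t) = a \sin^3(\pi t / 2T_p)} while loading and the
#'     mirrored arc while unloading. Strain grows as \eqn{t^3} just after
#'     touchdown, so contact force builds gradually and threshold-based
#'     contact detection resolves the onset to a small fraction of a frame's
#'     strain. This is the default used by the simulator.}
#'   \item{`"halfsine"`}{piecewise half sine,
#'     \eqn{\varepsilon(t) = a \sin(\pi t / 2T_p)} while loading; the
#'     loading rate is maximal at the instant of touchdown. Useful for
#'     exercising detection under an abrupt onset.}
#' }
#' Both have analytic derivatives and a continuous (zero) strain rate at the
#' peak.
#'
#' @param gait A [gait_params()] object.
#' @param derivative If `TRUE`, also return the analytic strain rate.
#'
#' @return A tibble with columns `frame` (0-based), `time_s`, `strain`
#'   (dimensionless) and, if requested, `strain_rate` (1/s).
#' @examples
#' tr <- strain_trajectory(gait_params(stance_duration = 0.6,
#'                                     peak_strain_target = 0.6))
#' max(tr$strain)
#' @export
strain_trajectory <- function(gait, derivative = TRUE) {
  stopifnot(inherits(gait, "gait_params"))
  a <- gait$peak_strain_target
  dt <- 1 / gait$frame_rate
  # stance duration rounded to a whole number of frames so that both the
  # touchdown and toe-off frames land on the grid with exactly zero strain
  n <- max(4L, as.integer(round(gait$stance_duration * gait$frame_rate)))
  T <- n * dt
  Tp <- gait$peak_time_frac * T
  time <- (0:n) * dt
  p <- if (gait$shape == "smooth") 3L else 1L
  load <- time <= Tp
  s_l <- sin(pi * time / (2 * Tp))
  s_u <- sin(pi * (T - time) / (2 * (T - Tp)))
  strain <- ifelse(load, a * s_l^p, a * s_u^p)
  strain[c(1, length(strain))] <- 0
  out <- tibble::tibble(frame = seq_along(time) - 1L, time_s = time,
                        strain = strain)
  if (derivative) {
    rate <- ifelse(load,
                   a * p * (pi / (2 * Tp)) * s_l^(p - 1) * cos(pi * time / (2 * Tp)),
                   -a * p * (pi / (2 * (T - Tp))) * s_u^(p - 1) *
                     cos(pi * (T - time) / (2 * (T - Tp))))
    out$strain_rate <- rate
  }
  out
}
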