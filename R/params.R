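#' Kelvin-Voigt material parameters
#'
#' Bundles the three material parameters of the modified Kelvin-Voigt model
#' of the heel pad: a linear elastic element (Young's modulus `E`, kPa) in
#' parallel with a nonlinear viscous element (viscous modulus `eta`, kPa s)
#' whose stress contribution scales with both strain and strain rate,
#' together with the unloaded primary thickness `h0` (mm).
#'
#' The constitutive law evaluated by [simulate_stance()] and estimated by
#' [fit_kelvin_voigt()] is
#' \deqn{\sigma = E\,\varepsilon + \eta\,\varepsilon\,\dot\varepsilon,}
#' with compressive strain and stress taken positive. Published versions of
#' this equation are sometimes garbled typographically (dropped strain factor
#' and stray signs); the form above is the parallel spring / strain-scaled
#' dashpot model.
#'
#' @param E Young's modulus, kPa. Must be positive.
#' @param eta Viscous modulus, kPa s. Must be non-negative.
#' @param h0 Primary (unloaded) thickness, mm. Must be positive.
#'
#' @return An object of class `kv_params` (named list).
#' @examples
#' kv_params(E = 265.5, eta = 66.59, h0 = 14.85)
#' @export
kv_params <- function(E, eta, h0) {
  if (!is.numeric(E) || length(E) != 1 || !is.finite(E) || E <= 0)
    abort("`E` must be a single positive number (kPa).", class = "heelpad_parameter_error")
  if (!is.numeric(eta) || length(eta) != 1 || !is.finite(eta) || eta < 0)
    abort("`eta` must be a single non-negative number (kPa s).", class = "heelpad_parameter_error")
  if (!is.numeric(h0) || length(h0) != 1 || !is.finite(h0) || h0 <= 0)
    abort("`h0` must be a single positive number (mm).", class = "heelpad_parameter_error")
  structure(list(E = E, eta = eta, h0 = h0), class = "kv_params")
}

#' Stance-phase simulation parameters
#'
#' Describes one simulated step: the stance window, sampling rate, target
#' peak compressive strain, the heel contact-area trajectory, and additive
#' measurement noise on the recorded channels.
#'
#' @param stance_duration Stance time, s. Default 0.75 s, a typical stance
#'   duration for gait at roughly 1.0 m/s.
#' @param frame_rate Sampling rate, Hz. Default 50.
#' @param peak_strain_target Peak compressive strain reached mid-stance,
#'   as a fraction in (0, 1).
#' @param peak_time_frac Fraction of stance at which peak strain occurs,
#'   in (0, 1). 0.5 gives a symmetric cycle; values below 0.5 load faster
#'   than they unload.
#' @param shape Strain trajectory family: `"smooth"` (default; cubed-sine
#'   onset, strain grows as \eqn{t^3} right after touchdown so the force
#'   onset is gradual) or `"halfsine"` (half-sine arch with an abrupt
#'   loading rate at touchdown). See [strain_trajectory()].
#' @param area_peak Heel-ground contact area at peak strain, cm^2.
#' @param area_min_frac Contact area at touchdown as a fraction of
#'   `area_peak`; the area grows with the square root of strain from this
#'   floor. Must be positive so that in-contact frames carry positive area.
#' @param noise_sd_thickness SD of additive Gaussian noise on the thickness
#'   channel, mm.
#' @param noise_sd_force SD of additive Gaussian noise on the force
#'   channel, N.
#' @param seed Optional integer seed for the noise draws; `NULL` uses the
#'   current RNG stream.
#'
#' @return An object of class `gait_params` (named list).
#' @examples
#' gait_params(peak_strain_target = 0.52)
#' @export
gait_params <- function(stance_duration = 0.75,
                        frame_rate = 50,
                        peak_strain_target = 0.55,
                        peak_time_frac = 0.5,
                        shape = c("smooth", "halfsine"),
                        area_peak = 20,
                        area_min_frac = 0.3,
                        noise_sd_thickness = 0.1,
                        noise_sd_force = 2,
                        seed = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(stance_duration) || stance_duration <= 0)
    abort("`stance_duration` must be positive (s).", class = "heelpad_parameter_error")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    abort("`frame_rate` must be positive (Hz).", class = "heelpad_parameter_error")
  if (!is.numeric(peak_strain_target) || peak_strain_target <= 0 || peak_strain_target >= 1)
    abort("`peak_strain_target` must lie strictly between 0 and 1.",
          class = "heelpad_parameter_error")
  if (!is.numeric(peak_time_frac) || peak_time_frac <= 0 || peak_time_frac >= 1)
    abort("`peak_time_frac` must lie strictly between 0 and 1.",
          class = "heelpad_parameter_error")
  if (!is.numeric(area_peak) || area_peak <= 0)
    abort("`area_peak` must be positive (cm^2).", class = "heelpad_parameter_error")
  if (!is.numeric(area_min_frac) || area_min_frac <= 0 || area_min_frac > 1)
    abort("`area_min_frac` must lie in (0, 1].", class = "heelpad_parameter_error")
  if (noise_sd_thickness < 0 || noise_sd_force < 0)
    abort("Noise SDs must be non-negative.", class = "heelpad_parameter_error")
  structure(list(stance_duration = stance_duration, frame_rate = frame_rate,
                 peak_strain_target = peak_strain_target,
                 peak_time_frac = peak_time_frac, shape = shape,
                 area_peak = area_peak, area_min_frac = area_min_frac,
                 noise_sd_thickness = noise_sd_thickness,
                 noise_sd_force = noise_sd_force, seed = seed),
            class = "gait_params")
}

# One group's generative parameters: per loading status, Gaussian
# (mean, sd) for each material property, truncated at physical bounds.
group_param_tbl <- function(status, h0, E, eta, strain) {
  tibble::tibble(
    status = status,
    h0_mean = h0[1], h0_sd = h0[2],
    E_mean = E[1], E_sd = E[2],
    eta_mean = eta[1], eta_sd = eta[2],
    strain_mean = strain[1], strain_sd = strain[2]
  )
}

#' Cohort generative specification
#'
#' Describes the synthetic study design: for each group and each loading
#' status (`time_zero`, after an hour of unloaded rest, vs `post_loading`,
#' after 15 minutes of continuous weight bearing) the Gaussian distribution
#' of each per-leg material property, plus the cohort layout (subjects,
#' legs per subject, within-subject correlations).
#'
#' Per-leg parameters are drawn from the stated Gaussians truncated at
#' physical bounds (positive moduli and thickness, strain in (0.05, 0.95)).
#' Correlation is induced by a shared latent factor per subject (between
#' legs, `leg_cor`) and per leg (between statuses, `status_cor`).
#'
#' @param groups Named list; each element is a tibble with one row per
#'   status and columns `status`, `h0_mean`, `h0_sd`, `E_mean`, `E_sd`,
#'   `eta_mean`, `eta_sd`, `strain_mean`, `strain_sd` (see
#'   [reference_cohort_spec()] for the shape).
#' @param n_subjects Subjects per group (>= 2).
#' @param legs_per_subject Legs recorded per subject; default 2.
#' @param leg_cor Correlation of a property between the two legs of one
#'   subject (same status). Default 0.7.
#' @param status_cor Correlation of a property between the two loading
#'   statuses of one leg. Default 0.8.
#' @param gait A [gait_params()] object supplying the stance window,
#'   sampling and noise shared by all simulated steps (its
#'   `peak_strain_target` is overridden per leg by the drawn strain).
#'
#' @return An object of class `cohort_spec`.
#' @seealso [reference_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(groups, n_subjects = 10, legs_per_subject = 2,
                        leg_cor = 0.7, status_cor = 0.8,
                        gait = gait_params()) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    abort("`groups` must be a named list of per-group parameter tables.",
          class = "heelpad_parameter_error")
  for (g in names(groups)) {
    need <- c("status", "h0_mean", "h0_sd", "E_mean", "E_sd",
              "eta_mean", "eta_sd", "strain_mean", "strain_sd")
    if (!all(need %in% names(groups[[g]])))
      abort(paste0("Group '", g, "' is missing columns: ",
                   paste(setdiff(need, names(groups[[g]])), collapse = ", ")),
            class = "heelpad_parameter_error")
    sds <- unlist(groups[[g]][grep("_sd$", names(groups[[g]]))])
    if (any(sds < 0))
      abort("All generative SDs must be non-negative.", class = "heelpad_parameter_error")
  }
  if (n_subjects < 2)
    abort("`n_subjects` must be at least 2.", class = "heelpad_parameter_error")
  if (leg_cor < 0 || leg_cor > 1 || status_cor < 0 || status_cor > 1)
    abort("Correlations must lie in [0, 1].", class = "heelpad_parameter_error")
  structure(list(groups = groups, n_subjects = n_subjects,
                 legs_per_subject = legs_per_subject,
                 leg_cor = leg_cor, status_cor = status_cor, gait = gait),
            class = "cohort_spec")
}

#' Reference cohort parameterization
#'
#' Generative distributions representing an elderly cohort study of heel-pad
#' material properties: age-matched healthy adults versus adults with type II
#' diabetes, the latter optionally split by disease duration (under vs over
#' ten years), each measured at time zero and again after continuous loading.
#' Values are summary statistics typical of in vivo heel-pad studies of such
#' cohorts (primary thickness around 12-15 mm, Young's modulus around
#' 200-270 kPa, viscous modulus around 25-70 kPa s, peak strain 50-65%).
#' Where the underlying summaries are medians with ranges (skewed
#' properties), the Gaussian here uses mean = median and sd = range/4.
#'
#' @param subgroups If `TRUE`, the diabetes group is split into
#'   `diabetes_early` (disease course < 10 years) and `diabetes_late`
#'   (>= 10 years) with `n_subjects` halved per subgroup in spirit (the
#'   caller still sets `n_subjects` in [cohort_spec()]).
#' @param statuses Which loading statuses to include; subset of
#'   `c("time_zero", "post_loading")`.
#'
#' @return A named list of per-group parameter tables suitable for
#'   [cohort_spec()].
#' @examples
#' spec <- cohort_spec(reference_cohort_spec(), n_subjects = 10)
#' @export
reference_cohort_spec <- function(subgroups = FALSE,
                                  statuses = c("time_zero", "post_loading")) {
  statuses <- match.arg(statuses, several.ok = TRUE)
  healthy <- rbind(
    group_param_tbl("time_zero",
                    h0 = c(14.85, 2.81), E = c(265.50, (306.28 - 154.79) / 4),
                    eta = c(66.59, (137.97 - 36.70) / 4), strain = c(0.5230, 0.1009)),
    group_param_tbl("post_loading",
                    h0 = c(14.55, 2.74), E = c(236.40, 47.21),
                    eta = c(46.30, 19.99), strain = c(0.5155, (0.7185 - 0.4109) / 4))
  )
  diabetes <- rbind(
    group_param_tbl("time_zero",
                    h0 = c(12.25, 2.34), E = c(214.39, 48.04),
                    eta = c(42.28, 18.93), strain = c(0.6065, 0.1173)),
    group_param_tbl("post_loading",
                    h0 = c(11.95, 2.21), E = c(209.95, 49.04),
                    eta = c(26.45, 16.55), strain = c(0.5861, (0.9292 - 0.4064) / 4))
  )
  diabetes_early <- rbind(
    group_param_tbl("time_zero",
                    h0 = c(12.69, 2.16), E = c(206.50, 43.08),
                    eta = c(36.20, 14.37), strain = c(0.5880, 0.1044)),
    group_param_tbl("post_loading",
                    h0 = c(11.90, 2.13), E = c(204.60, 34.58),
                    eta = c(23.10, 11.12), strain = c(0.5723, 0.0872))
  )
  diabetes_late <- rbind(
    group_param_tbl("time_zero",
                    h0 = c(12.54, 2.62), E = c(221.30, 53.69),
                    eta = c(47.60, 21.74), strain = c(0.6250, 0.1318)),
    group_param_tbl("post_loading",
                    h0 = c(12.00, 2.40), E = c(215.30, 61.79),
                    eta = c(29.80, 20.72), strain = c(0.5896, (0.9292 - 0.4812) / 4))
  )
  out <- if (subgroups) {
    list(healthy = healthy, diabetes_early = diabetes_early,
         diabetes_late = diabetes_late)
  } else {
    list(healthy = healthy, diabetes = diabetes)
  }
  lapply(out, function(tb) tb[tb$status %in% statuses, , drop = FALSE])
}

#' @export
print.kv_params <- function(x, ...) {
  cat(sprintf("Kelvin-Voigt parameters: E = %.2f kPa, eta = %.2f kPa s, h0 = %.2f mm\n",
              x$E, x$eta, x$h0))
  invisible(x)
}

#' @export
print.gait_params <- function(x, ...) {
  cat(sprintf(paste0("Stance simulation: %.2f s at %g Hz, peak strain %.1f%%",
                     " at %.0f%% of stance (%s), area %.1f cm^2\n"),
              x$stance_duration, x$frame_rate, 100 * x$peak_strain_target,
              100 * x$peak_time_frac, x$shape, x$area_peak))
  cat(sprintf("  noise: thickness sd %.3g mm, force sd %.3g N\n",
              x$noise_sd_thickness, x$noise_sd_force))
  invisible(x)
}
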