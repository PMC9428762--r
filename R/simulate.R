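#' Forward-simulate one stance-phase recording
#'
#' Evaluates the modified Kelvin-Voigt model
#' \eqn{\sigma = E\varepsilon + \eta\varepsilon\dot\varepsilon} along a
#' stance-phase strain trajectory and converts the result into the channels
#' a combined fluoroscopy / pressure-plate measurement chain would record:
#' per-frame pad thickness (mm), heel-ground contact force (N) and contact
#' area (cm^2), sampled at `gait$frame_rate`.
#'
#' Thickness is \eqn{h_0 (1 - \varepsilon(t))} plus Gaussian noise; force is
#' \eqn{\sigma(t)\,A(t) \times 0.1} (kPa cm^2 to N) plus Gaussian noise. The
#' contact area grows with the square root of strain from a floor of
#' `area_min_frac * area_peak` at touchdown, so every in-contact frame
#' carries positive area. Noise is applied only to the measured thickness
#' and force channels, mirroring the measurement chain; with both noise SDs
#' zero the recording is an exact model evaluation.
#'
#' For stiff trajectories with a large viscous modulus the model stress can
#' become negative during late unloading (the imposed-strain Kelvin-Voigt
#' model cannot lose contact). Such frames are clipped to zero in the force
#' channel only, and the recording carries a `clipped_frames` attribute plus
#' a warning.
#'
#' @param kv A [kv_params()] object (truth used for the simulation).
#' @param gait A [gait_params()] object.
#'
#' @return A `stance_recording`: a tibble with columns `frame` (0-based),
#'   `time_s`, `thickness_mm`, `force_N`, `area_cm2`, carrying attributes
#'   `frame_rate`, `truth` (the `kv` and per-step peak strain used) and
#'   `clipped_frames`.
#' @examples
#' rec <- simulate_stance(kv_params(265.5, 66.59, 14.85),
#'                        gait_params(peak_strain_target = 0.52,
#'                                    noise_sd_thickness = 0,
#'                                    noise_sd_force = 0))
#' extract_properties(rec)
#' @export
simulate_stance <- function(kv, gait = gait_params()) {
  stopifnot(inherits(kv, "kv_params"), inherits(gait, "gait_params"))
  tr <- strain_trajectory(gait, derivative = TRUE)
  eps <- tr$strain
  rate <- tr$strain_rate
  a <- gait$peak_strain_target
  stress <- kv$E * eps + kv$eta * eps * rate
  area <- gait$area_peak *
    (gait$area_min_frac + (1 - gait$area_min_frac) * sqrt(pmax(eps, 0) / a))
  force <- stress * area * 0.1
  clipped <- which(force < 0)
  if (length(clipped) > 0) {
    force[clipped] <- 0
    warn(sprintf(paste0("Model stress negative on %d frame(s) during unloading; ",
                        "force clipped to 0 (E too small relative to eta at ",
                        "this strain rate)."), length(clipped)),
         class = "heelpad_clipped_force")
  }
  noisy <- gait$noise_sd_thickness > 0 || gait$noise_sd_force > 0
  add_noise <- function() {
    n <- length(eps)
    th <- kv$h0 * (1 - eps)
    if (gait$noise_sd_thickness > 0)
      th <- th + rnorm(n, 0, gait$noise_sd_thickness)
    f <- force
    if (gait$noise_sd_force > 0)
      f <- pmax(f + rnorm(n, 0, gait$noise_sd_force), 0)
    list(th = th, f = f)
  }
  ch <- if (noisy && !is.null(gait$seed)) {
    withr::with_seed(gait$seed, add_noise())
  } else {
    add_noise()
  }
  out <- tibble::tibble(frame = tr$frame, time_s = tr$time_s,
                        thickness_mm = ch$th, force_N = ch$f,
                        area_cm2 = area)
  new_stance_recording(out, frame_rate = gait$frame_rate,
                       truth = list(E = kv$E, eta = kv$eta, h0 = kv$h0,
                                    peak_strain_target = a),
                       clipped_frames = clipped)
}

new_stance_recording <- function(df, frame_rate, truth = NULL,
                                 clipped_frames = integer()) {
  structure(df,
            class = c("stance_recording", class(tibble::tibble()))) -> out
  attr(out, "frame_rate") <- frame_rate
  attr(out, "truth") <- truth
  attr(out, "clipped_frames") <- clipped_frames
  out
}

#' Validate a stance recording
#'
#' Checks the structural invariants of a stance recording: equal-length
#' channels, strictly increasing uniformly spaced time, positive thickness
#' and non-negative force.
#'
#' @param rec A `stance_recording` or plain data frame with columns
#'   `time_s`, `thickness_mm`, `force_N`, `area_cm2`.
#' @return `rec`, invisibly, or an error.
#' @export
validate_recording <- function(rec) {
  need <- c("time_s", "thickness_mm", "force_N", "area_cm2")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    abort(paste("Recording is missing channel(s):", paste(miss, collapse = ", ")),
          class = "heelpad_parse_error")
  dt <- diff(rec$time_s)
  if (any(dt <= 0) || (length(dt) > 1 && diff(range(dt)) > 1e-6))
    abort("`time_s` must be strictly increasing with uniform spacing.",
          class = "heelpad_parse_error")
  if (any(rec$thickness_mm <= 0))
    abort("Thickness must be positive on every frame.", class = "heelpad_parse_error")
  if (any(rec$force_N < 0))
    abort("Force must be non-negative.", class = "heelpad_parse_error")
  invisible(rec)
}

#' Generate a synthetic cohort of stance recordings
#'
#' Assembles a full synthetic study: for each group in the specification,
#' `n_subjects` subjects with `legs_per_subject` legs, each leg recorded at
#' every loading status in the group table. Per-leg material parameters are
#' drawn from the group's Gaussians truncated at physical bounds
#' (h0 in (3, 40) mm, E in (10, 1000) kPa, eta in [0, 500) kPa s, peak
#' strain in (0.05, 0.95)); draws are correlated within subject and across
#' statuses via shared latent factors. The whole dataset is a deterministic
#' function of `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed controlling every random draw.
#'
#' @return A `cohort_dataset`: list with `recordings` (named list of
#'   `stance_recording`s) and `manifest` (tibble keyed by `subject`, `leg`,
#'   `group`, `status`, with the true per-leg parameters and the recording
#'   id).
#' @examples
#' cohort <- generate_cohort(
#'   cohort_spec(reference_cohort_spec(statuses = "time_zero"),
#'               n_subjects = 3), seed = 1)
#' cohort$manifest
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(as.integer(seed), generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  bounds <- list(h0 = c(3, 40), E = c(10, 1000), eta = c(0, 500),
                 strain = c(0.05, 0.95))
  b_subj <- sqrt(spec$leg_cor)
  b_leg <- sqrt(max(spec$status_cor - spec$leg_cor, 0))
  b_stat <- sqrt(max(1 - spec$status_cor, 0))
  props <- c("h0", "E", "eta", "strain")
  manifest <- list()
  recordings <- list()
  for (g in names(spec$groups)) {
    tbl <- spec$groups[[g]]
    for (s in seq_len(spec$n_subjects)) {
      z_subj <- rnorm(length(props))
      names(z_subj) <- props
      for (l in seq_len(spec$legs_per_subject)) {
        z_leg <- rnorm(length(props))
        names(z_leg) <- props
        for (r in seq_len(nrow(tbl))) {
          status <- tbl$status[r]
          draw <- vapply(props, function(p) {
            m <- tbl[[paste0(p, "_mean")]][r]
            sdev <- tbl[[paste0(p, "_sd")]][r]
            lo <- bounds[[p]][1]; hi <- bounds[[p]][2]
            for (i in seq_len(1000L)) {
              z <- b_subj * z_subj[[p]] + b_leg * z_leg[[p]] + b_stat * rnorm(1)
              x <- m + sdev * z
              if (x >= lo && x <= hi) return(x)
            }
            abort(sprintf(paste0("Truncation rejected 1000 draws for %s in group ",
                                 "'%s' (mean %.3g, sd %.3g outside bounds)."),
                          p, g, m, sdev),
                  class = "heelpad_parameter_error")
          }, numeric(1))
          gait <- spec$gait
          gait$peak_strain_target <- draw[["strain"]]
          gait$seed <- NULL  # noise from the cohort RNG stream
          rec <- withCallingHandlers(
            simulate_stance(kv_params(draw[["E"]], draw[["eta"]], draw[["h0"]]), gait),
            heelpad_clipped_force = function(w) invokeRestart("muffleWarning"))
          id <- sprintf("%s_s%02d_leg%d_%s", g, s, l, status)
          recordings[[id]] <- rec
          manifest[[length(manifest) + 1L]] <- tibble::tibble(
            id = id, group = g, subject = sprintf("%s_s%02d", g, s),
            leg = l, status = status,
            true_E = draw[["E"]], true_eta = draw[["eta"]],
            true_h0 = draw[["h0"]], true_peak_strain = draw[["strain"]],
            clipped = length(attr(rec, "clipped_frames")) > 0)
        }
      }
    }
  }
  structure(list(recordings = recordings,
                 manifest = dplyr::bind_rows(manifest)),
            class = "cohort_dataset")
}

#' Extract material properties for every recording in a cohort
#'
#' Runs [extract_properties()] on each recording and binds the results to
#' the cohort manifest, yielding the subject x leg x group x status property
#' table used by the statistical comparison framework.
#'
#' @param cohort A `cohort_dataset` from [generate_cohort()].
#' @param ... Passed on to [extract_properties()].
#' @return A tibble with the manifest keys and the six material properties
#'   per leg and status.
#' @export
cohort_properties <- function(cohort, ...) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  props <- purrr::map(cohort$manifest$id, function(id) {
    extract_properties(cohort$recordings[[id]], ...)
  })
  dplyr::bind_cols(cohort$manifest, dplyr::bind_rows(props))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic heel-pad cohort: %d recordings (%d groups x %d subjects)\n",
              nrow(m), length(unique(m$group)), length(unique(m$subject))))
  print(dplyr::count(m, .data$group, .data$status))
  invisible(x)
}
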