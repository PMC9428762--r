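#' Detect the initial-contact frame
#'
#' Finds the frame where the heel skin first contacts the plate, from the
#' force channel. The rule is: take the first frame whose force reaches the
#' threshold (default 1% of the recording's peak force), then walk back
#' along the strictly rising force edge while the preceding frame still
#' carries positive force. The walk-back refines the threshold crossing to
#' the start of the force build-up, which matters because at the crossing
#' frame the pad is already measurably compressed; frames with zero force
#' (no contact) are never entered.
#'
#' @param rec A stance recording (see [simulate_stance()], [read_recording()]).
#' @param force_threshold Absolute threshold, N. Default `NULL` uses 1% of
#'   the peak force.
#' @param refine If `FALSE`, return the raw first-crossing frame.
#' @return The contact frame as an R (1-based) row index into `rec`.
#'   (File dialects number frames from 0; subtract 1 for that convention.)
#' @examples
#' rec <- tibble::tibble(time_s = (0:3) / 50, thickness_mm = 15,
#'                       force_N = c(0, 0, 3, 80), area_cm2 = 10)
#' detect_contact(rec, force_threshold = 3)  # row 3 (0-based frame 2)
#' @export
detect_contact <- function(rec, force_threshold = NULL, refine = TRUE) {
  f <- rec$force_N
  thr <- force_threshold %||% (0.01 * max(f))
  if (thr <= 0 || !any(f >= thr) || max(f) <= 0)
    abort("No frame reaches the contact force threshold; no contact detected.",
          class = "heelpad_no_contact_error")
  k <- which(f >= thr)[1]
  if (refine) {
    while (k > 1 && f[k - 1] > 0 && f[k - 1] < f[k]) k <- k - 1L
  }
  k
}

# last in-contact frame: last frame at threshold, extended forward along the
# decaying positive tail (the mirror of the onset walk-back)
detect_contact_end <- function(rec, force_threshold = NULL, refine = TRUE) {
  f <- rec$force_N
  thr <- force_threshold %||% (0.01 * max(f))
  k <- tail(which(f >= thr), 1)
  if (refine) {
    while (k < length(f) && f[k + 1] > 0 && f[k + 1] < f[k]) k <- k + 1L
  }
  k
}

#' Primary (unloaded) thickness
#'
#' The primary thickness h0 is the pad thickness measured on the frame of
#' initial heel-plate contact; it is the reference length for all strains.
#'
#' @param rec A stance recording.
#' @param contact_index Contact frame (1-based row index), typically from
#'   [detect_contact()].
#' @return Thickness at the contact frame, mm.
#' @export
primary_thickness <- function(rec, contact_index) {
  if (contact_index < 1 || contact_index > nrow(rec))
    abort("`contact_index` out of range.", class = "heelpad_parameter_error")
  rec$thickness_mm[contact_index]
}

#' Compressive strain from thickness
#'
#' Strain is the change in thickness divided by the primary thickness,
#' positive in compression: \eqn{\varepsilon_i = (h_0 - d_i)/h_0}. Values
#' are not clamped at zero; noise-induced slightly negative strains are
#' retained so least-squares fitting stays unbiased.
#'
#' @param thickness Thickness channel, mm.
#' @param h0 Primary thickness, mm (> 0).
#' @return Dimensionless strain vector.
#' @examples
#' compute_strain(c(10, 8, 6, 8, 10), h0 = 10)
#' @export
compute_strain <- function(thickness, h0) {
  if (!is.numeric(h0) || length(h0) != 1 || h0 <= 0)
    abort("`h0` must be a single positive number (mm).",
          class = "heelpad_parameter_error")
  (h0 - thickness) / h0
}

#' Contact stress from force and area
#'
#' Stress is the heel-ground contact force divided by the instantaneous
#' contact area, converted to kPa: \eqn{\sigma_i = 10 F_i / A_i} with F in N
#' and A in cm^2. Frames with zero area and zero force yield zero stress by
#' convention; positive force over zero area is inconsistent.
#'
#' @param force Force channel, N.
#' @param area Contact-area channel, cm^2.
#' @return Stress vector, kPa.
#' @examples
#' compute_stress(260, 10)  # 260 kPa
#' @export
compute_stress <- function(force, area) {
  if (length(force) != length(area))
    abort("`force` and `area` must have equal length.",
          class = "heelpad_parameter_error")
  bad <- force > 0 & area <= 0
  if (any(bad))
    abort(sprintf("Positive force over zero contact area on %d frame(s).",
                  sum(bad)),
          class = "heelpad_inconsistency_error")
  ifelse(area > 0, 10 * force / area, 0)
}

#' Strain rate by finite differences
#'
#' Differentiates the sampled strain signal. The default (`order = 4`) uses
#' a five-point fourth-order central stencil in the interior, falling back
#' to three-point central differences beside the edges and second-order
#' one-sided differences at the two endpoints; at 50 Hz the plain
#' three-point scheme systematically attenuates a stance-frequency
#' derivative by about 0.7%, which propagates directly into the viscous
#' modulus, so the wider stencil is the default. `order = 2` gives the
#' classical three-point central scheme (forward/backward at the ends).
#'
#' @param strain Sampled strain (>= 3 values).
#' @param dt Sampling interval, s (> 0).
#' @param order Accuracy order, 2 or 4.
#' @return Strain rate, 1/s, same length as `strain`.
#' @examples
#' compute_strain_rate(c(0, 0.1, 0.2), dt = 0.02)  # 5 5 5
#' @export
compute_strain_rate <- function(strain, dt, order = 4) {
  n <- length(strain)
  if (n < 3)
    abort("Need at least 3 samples to differentiate.",
          class = "heelpad_length_error")
  if (dt <= 0)
    abort("`dt` must be positive.", class = "heelpad_parameter_error")
  d <- numeric(n)
  if (order == 2 || n < 5) {
    d[1] <- strain[2] - strain[1]
    d[n] <- strain[n] - strain[n - 1]
    if (n > 2) d[2:(n - 1)] <- (strain[3:n] - strain[1:(n - 2)]) / 2
  } else {
    d[1] <- (-3 * strain[1] + 4 * strain[2] - strain[3]) / 2
    d[n] <- (3 * strain[n] - 4 * strain[n - 1] + strain[n - 2]) / 2
    d[2] <- (strain[3] - strain[1]) / 2
    d[n - 1] <- (strain[n] - strain[n - 2]) / 2
    i <- 3:(n - 2)
    d[i] <- (-strain[i + 2] + 8 * strain[i + 1] - 8 * strain[i - 1] +
               strain[i - 2]) / 12
  }
  d / dt
}

#' Build a stress-strain curve from a stance recording
#'
#' Converts one stance recording into the per-frame stress-strain cycle:
#' detects initial contact (unless given), takes the primary thickness
#' there, computes strain, stress and strain rate, trims to the in-contact
#' window, and labels the loading and unloading branches.
#'
#' @param rec A stance recording.
#' @param force_threshold Passed to [detect_contact()]; `NULL` = 1% of peak
#'   force.
#' @param contact_index,end_index Optional explicit in-contact window
#'   (1-based row indices); both default to force-based detection.
#' @param h0 Optional explicit primary thickness, mm; default
#'   `primary_thickness(rec, contact_index)`.
#' @param rate_order Accuracy order for [compute_strain_rate()].
#'
#' @return A `stress_strain_curve`: tibble with columns `frame`, `time_s`,
#'   `strain`, `stress_kpa`, `strain_rate`, `phase`
#'   (`"loading"`/`"unloading"`, the peak frame labelled loading), with
#'   attributes `h0_mm`, `contact_index`, `peak_index` (row indices into
#'   the curve's own rows for `peak_index`; `contact_index` refers to the
#'   source recording).
#' @export
stress_strain_curve <- function(rec, force_threshold = NULL,
                                contact_index = NULL, end_index = NULL,
                                h0 = NULL, rate_order = 4) {
  validate_recording(rec)
  ci <- contact_index %||% detect_contact(rec, force_threshold)
  ei <- end_index %||% detect_contact_end(rec, force_threshold)
  if (ei <= ci + 1)
    abort("In-contact window too short to form a loading/unloading cycle.",
          class = "heelpad_split_error")
  h0 <- h0 %||% primary_thickness(rec, ci)
  idx <- ci:ei
  dt <- rec$time_s[2] - rec$time_s[1]
  strain <- compute_strain(rec$thickness_mm[idx], h0)
  stress <- compute_stress(rec$force_N[idx], rec$area_cm2[idx])
  rate <- compute_strain_rate(strain, dt, order = rate_order)
  curve <- tibble::tibble(
    frame = if ("frame" %in% names(rec)) rec$frame[idx] else idx - 1L,
    time_s = rec$time_s[idx],
    strain = strain, stress_kpa = stress, strain_rate = rate)
  peak <- which.max(curve$strain)[1]
  sp <- split_cycle(curve)
  curve$phase <- ifelse(seq_len(nrow(curve)) <= peak, "loading", "unloading")
  out <- structure(curve, class = c("stress_strain_curve", class(tibble::tibble())))
  attr(out, "h0_mm") <- h0
  attr(out, "contact_index") <- ci
  attr(out, "peak_index") <- peak
  out
}

#' Split a stress-strain cycle into loading and unloading branches
#'
#' The loading branch runs from the contact frame to the peak-strain frame
#' inclusive; the unloading branch from the peak-strain frame to the last
#' in-contact frame inclusive (the peak is shared). Ties in the maximum
#' strain break to the first occurrence.
#'
#' @param curve A `stress_strain_curve`, or any data frame with a `strain`
#'   column covering one cycle.
#' @return A list with integer vectors `loading` and `unloading` (row
#'   indices into `curve`).
#' @examples
#' split_cycle(tibble::tibble(strain = c(0, .2, .4, .6, .4, .2, 0)))
#' @export
split_cycle <- function(curve) {
  eps <- curve$strain
  n <- length(eps)
  peak <- which.max(eps)[1]
  if (peak == n || peak == 1)
    abort("Strain is monotone over the window; no loading/unloading cycle.",
          class = "heelpad_split_error")
  list(loading = 1:peak, unloading = peak:n)
}

#' Peak strain and peak stress
#'
#' Returns the strain and stress at the rightmost point of the
#' stress-strain cycle, i.e. the maximum-strain frame; even when the
#' maximum stress occurs on a different frame, both values are read at the
#' maximum-strain frame by definition. Strain is reported in percent.
#'
#' @param curve A `stress_strain_curve`.
#' @return A named list: `peak_strain` (%), `peak_stress` (kPa).
#' @export
peak_point <- function(curve) {
  peak <- attr(curve, "peak_index") %||% which.max(curve$strain)[1]
  list(peak_strain = 100 * curve$strain[peak],
       peak_stress = curve$stress_kpa[peak])
}
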