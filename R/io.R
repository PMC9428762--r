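#' File dialects for stance recordings
#'
#' Three plain-text dialects are supported:
#' \describe{
#'   \item{stance CSV}{header `frame,time_s,thickness_mm,force_N,area_cm2`,
#'     one row per frame, frames numbered from 0.}
#'   \item{plate XML}{a minimal element tree standing in for a pressure
#'     plate's XML export:
#'     `<recording frame_rate="50"><frame t="..."><force>..</force><area>..</area></frame>...</recording>`.
#'     Force in N, area in cm^2. When the `frame_rate` attribute is absent
#'     the reader assumes 50 Hz with a warning.}
#'   \item{thickness CSV}{header `frame,thickness_mm`, the fluoroscopy-side
#'     thickness series.}
#' }
#' The plate XML carries no thickness, and the thickness CSV no force, so a
#' full recording is read either from one stance CSV or from a thickness
#' CSV plus plate XML pair with matching frame counts.
#'
#' All writers are atomic (write to a temp file in the target directory,
#' then rename), so re-running a stage with identical inputs reproduces
#' identical files.
#'
#' @name recording_dialects
NULL

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    abort(paste("Could not move temporary file onto", path))
  invisible(path)
}

#' Write a stance recording to disk
#'
#' @param rec A stance recording.
#' @param path Output file path.
#' @param dialect One of `"stance_csv"`, `"plate_xml"`, `"thickness_csv"`
#'   (see [recording_dialects]).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            dialect = c("stance_csv", "plate_xml",
                                        "thickness_csv")) {
  dialect <- match.arg(dialect)
  fr <- attr(rec, "frame_rate") %||% round(1 / (rec$time_s[2] - rec$time_s[1]))
  frame <- rec$frame %||% (seq_len(nrow(rec)) - 1L)
  atomic_write(path, function(tmp) {
    if (dialect == "stance_csv") {
      readr::write_csv(tibble::tibble(frame = frame, time_s = rec$time_s,
                                      thickness_mm = rec$thickness_mm,
                                      force_N = rec$force_N,
                                      area_cm2 = rec$area_cm2), tmp)
    } else if (dialect == "thickness_csv") {
      readr::write_csv(tibble::tibble(frame = frame,
                                      thickness_mm = rec$thickness_mm), tmp)
    } else {
      doc <- xml2::xml_new_root("recording", frame_rate = as.character(fr))
      for (i in seq_len(nrow(rec))) {
        fnode <- xml2::xml_add_child(doc, "frame",
                                     t = format(rec$time_s[i], digits = 10))
        xml2::xml_add_child(fnode, "force", format(rec$force_N[i], digits = 10))
        xml2::xml_add_child(fnode, "area", format(rec$area_cm2[i], digits = 10))
      }
      xml2::write_xml(doc, tmp)
    }
  })
}

read_plate_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("Malformed plate XML '", path, "': ", conditionMessage(e)),
          class = "heelpad_parse_error")
  })
  fr_attr <- xml2::xml_attr(doc, "frame_rate")
  if (is.na(fr_attr)) {
    warn("Plate XML has no frame_rate attribute; assuming the pre-set 50 Hz.",
         class = "heelpad_missing_frame_rate")
    fr <- 50
  } else {
    fr <- as.numeric(fr_attr)
    if (!is.finite(fr) || fr <= 0)
      abort(paste("Invalid frame_rate attribute:", fr_attr),
            class = "heelpad_parse_error")
  }
  frames <- xml2::xml_find_all(doc, "./frame")
  if (length(frames) == 0)
    abort("Plate XML contains no <frame> elements.",
          class = "heelpad_parse_error")
  get_num <- function(node, what, i) {
    child <- xml2::xml_find_first(node, paste0("./", what))
    v <- suppressWarnings(as.numeric(xml2::xml_text(child)))
    if (is.na(v))
      abort(sprintf("Frame %d: missing or non-numeric <%s> element.", i, what),
            class = "heelpad_parse_error")
    v
  }
  list(frame_rate = fr,
       force_N = vapply(seq_along(frames),
                        function(i) get_num(frames[[i]], "force", i), numeric(1)),
       area_cm2 = vapply(seq_along(frames),
                         function(i) get_num(frames[[i]], "area", i), numeric(1)))
}

read_csv_dialect <- function(path, cols) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Malformed CSV '", path, "': ",
                                     conditionMessage(e)),
                              class = "heelpad_parse_error"))
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    abort(paste0("CSV '", path, "' is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "heelpad_parse_error")
  if ("frame" %in% names(df) &&
      !identical(as.integer(df$frame), seq_len(nrow(df)) - 1L))
    abort(paste0("CSV '", path, "': frame indices must be contiguous from 0."),
          class = "heelpad_parse_error")
  df
}

#' Read a stance recording
#'
#' Reads either a single stance CSV, or a thickness CSV plus plate XML pair
#' that is merged into one recording (the two sources must agree on frame
#' count). Time is reconstructed from the frame rate when a source carries
#' none.
#'
#' @param path Path to a stance CSV (when `thickness` and `plate` are
#'   `NULL`).
#' @param thickness,plate Paths to a thickness CSV and plate XML pair.
#' @param frame_rate Frame rate used to reconstruct time for CSV-pair input
#'   when the XML lacks the attribute handling; default comes from the XML.
#' @return A `stance_recording`.
#' @export
read_recording <- function(path = NULL, thickness = NULL, plate = NULL,
                           frame_rate = NULL) {
  if (!is.null(path)) {
    df <- read_csv_dialect(path, c("frame", "time_s", "thickness_mm",
                                   "force_N", "area_cm2"))
    fr <- frame_rate %||% round(1 / (df$time_s[2] - df$time_s[1]))
    rec <- new_stance_recording(
      tibble::tibble(frame = as.integer(df$frame), time_s = df$time_s,
                     thickness_mm = df$thickness_mm, force_N = df$force_N,
                     area_cm2 = df$area_cm2), frame_rate = fr)
    validate_recording(rec)
    return(rec)
  }
  if (is.null(thickness) || is.null(plate))
    abort("Provide either `path` or both `thickness` and `plate`.",
          class = "heelpad_parameter_error")
  th <- read_csv_dialect(thickness, c("frame", "thickness_mm"))
  pl <- read_plate_xml(plate)
  if (nrow(th) != length(pl$force_N))
    abort(sprintf(paste0("Frame-count mismatch: thickness CSV has %d frames ",
                         "but plate XML has %d."), nrow(th), length(pl$force_N)),
          class = "heelpad_alignment_error")
  fr <- frame_rate %||% pl$frame_rate
  rec <- new_stance_recording(
    tibble::tibble(frame = as.integer(th$frame),
                   time_s = (seq_len(nrow(th)) - 1) / fr,
                   thickness_mm = th$thickness_mm,
                   force_N = pl$force_N, area_cm2 = pl$area_cm2),
    frame_rate = fr)
  validate_recording(rec)
  rec
}

#' Write a synthetic cohort to a directory
#'
#' Writes one stance CSV per recording plus a flat `manifest.csv` with the
#' cohort keys (subject, leg, group, status), file paths and the true
#' generative parameters.
#'
#' @param cohort A `cohort_dataset` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  manifest$file <- paste0(manifest$id, ".csv")  # relative to the manifest
  for (i in seq_len(nrow(manifest))) {
    write_recording(cohort$recordings[[manifest$id[i]]],
                    file.path(dir, manifest$file[i]), dialect = "stance_csv")
  }
  mpath <- file.path(dir, "manifest.csv")
  atomic_write(mpath, function(tmp) readr::write_csv(manifest, tmp))
  invisible(mpath)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_cohort()].
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(dirname(manifest_path), manifest$file[i])
    read_recording(path)
  })
  names(recs) <- manifest$id
  structure(list(recordings = recs,
                 manifest = dplyr::select(manifest, -dplyr::any_of("file"))),
            class = "cohort_dataset")
}

#' Write a stress-strain curve to CSV
#'
#' Tabular export of one cycle: `frame,time_s,strain,stress_kpa,
#' strain_rate,phase`.
#'
#' @param curve A `stress_strain_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  atomic_write(path, function(tmp) {
    readr::write_csv(tibble::as_tibble(curve), tmp)
  })
}
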