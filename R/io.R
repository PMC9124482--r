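#' Read and write DLT coefficient files
#'
#' The coefficient file is a CSV with one column per camera (header row of
#' camera ids) and 11 rows in coefficient order `L1` .. `L11`.
#'
#' @param path File path.
#' @return `read_dlt_coefficients()`: a named list of [camera_dlt()].
#' @export
read_dlt_coefficients <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) != 11L) {
    stop("DLT coefficient file must have 11 rows (L1..L11), found ", nrow(df),
         call. = FALSE)
  }
  cams <- purrr::imap(as.list(df), ~ camera_dlt(.x, camera_id = .y))
  cams
}

#' @param cams Named list of [camera_dlt()].
#' @rdname read_dlt_coefficients
#' @export
write_dlt_coefficients <- function(cams, path) {
  df <- tibble::as_tibble(purrr::map(cams, "coeffs"))
  names(df) <- vapply(cams, `[[`, character(1), "camera_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read 2D point-track observations
#'
#' Two dialects are supported. The plain dialect has columns `frame`,
#' `camera_id`, `label`, `u`, `v`, `confidence` (single header row). The
#' pose-estimation dialect, as emitted by markerless trackers, has three
#' header rows (scorer / bodyparts / coords) and per-bodypart `x`, `y`,
#' `likelihood` column triples; one file per camera, so `camera_id` must be
#' supplied.
#'
#' @param path CSV file path.
#' @param dialect `"plain"` or `"pose"`.
#' @param camera_id Camera id to attach (pose dialect only).
#' @param units `"m"` is a no-op for pixels; retained for signature symmetry
#'   with the 3D readers.
#' @return Tibble with columns `camera_id`, `frame`, `label`, `u`, `v`,
#'   `confidence`.
#' @export
read_observations_2d <- function(path, dialect = c("plain", "pose"),
                                 camera_id = NULL, units = "m") {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    req <- c("frame", "camera_id", "label", "u", "v")
    check_schema(df, req, optional = "confidence", what = "2D track file")
    if (!"confidence" %in% names(df)) df$confidence <- NA_real_
    return(tibble::as_tibble(df[c("camera_id", "frame", "label", "u", "v",
                                  "confidence")]))
  }
  if (is.null(camera_id)) {
    stop("pose-estimation dialect files carry no camera id; pass `camera_id`",
         call. = FALSE)
  }
  hdr <- readr::read_csv(path, col_names = FALSE, n_max = 3,
                         show_col_types = FALSE)
  body <- readr::read_csv(path, col_names = FALSE, skip = 3,
                          show_col_types = FALSE)
  bodyparts <- as.character(unlist(hdr[2, -1]))
  coords <- as.character(unlist(hdr[3, -1]))
  frames <- as.integer(body[[1]])
  cols <- purrr::map2(bodyparts, seq_along(bodyparts) + 1L,
                      ~ tibble::tibble(label = .x, coord = coords[.y - 1L],
                                       col = .y))
  long <- dplyr::bind_rows(cols) |>
    dplyr::mutate(values = purrr::map(.data$col, ~ as.numeric(body[[.x]])))
  wide <- long |>
    tidyr::unnest("values") |>
    dplyr::group_by(.data$label, .data$coord) |>
    dplyr::mutate(frame = frames) |>
    dplyr::ungroup() |>
    dplyr::select("frame", "label", "coord", "values") |>
    tidyr::pivot_wider(names_from = "coord", values_from = "values")
  tibble::tibble(
    camera_id = camera_id,
    frame = wide$frame,
    label = wide$label,
    u = wide$x,
    v = wide$y,
    confidence = if ("likelihood" %in% names(wide)) wide$likelihood else NA_real_
  ) |>
    dplyr::arrange(.data$frame, .data$label)
}

#' Read and write 3D body-point tracks
#'
#' Plain CSV with columns `frame`, `label`, `x_m`, `y_m`, `z_m` (plus any
#' diagnostic columns, preserved). Coordinates are metres internally; files
#' declaring centimetres are converted on read with `units = "cm"`.
#'
#' @param path File path.
#' @param units `"m"` (default) or `"cm"`; cm values are divided by 100.
#' @return Tibble of the track.
#' @export
read_track_3d <- function(path, units = c("m", "cm")) {
  units <- match.arg(units)
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("frame", "label", "x_m", "y_m", "z_m"),
               optional = c("rms_px", "n_views", "low_confidence"),
               what = "3D track file")
  if (units == "cm") {
    df <- dplyr::mutate(df, dplyr::across(c("x_m", "y_m", "z_m"), ~ .x / 100))
  }
  tibble::as_tibble(df)
}

#' @param track Tibble as returned by [read_track_3d()] or
#'   [reconstruct_track()].
#' @rdname read_track_3d
#' @export
write_track_3d <- function(track, path) {
  readr::write_csv(track, path)
  invisible(path)
}

#' Read strike annotations
#'
#' CSV with one row per strike: `t_init_s`, `t_capture_s`, eye positions at
#' initiation/capture and the prey capture position, all in metres
#' (`eye_init_x` .. `prey_z`).
#'
#' @param path File path.
#' @param units `"m"` or `"cm"`.
#' @return Tibble of strike annotations.
#' @export
read_strikes <- function(path, units = c("m", "cm")) {
  units <- match.arg(units)
  df <- readr::read_csv(path, show_col_types = FALSE)
  pos_cols <- c("eye_init_x", "eye_init_y", "eye_init_z",
                "eye_capture_x", "eye_capture_y", "eye_capture_z",
                "prey_x", "prey_y", "prey_z")
  check_schema(df, c("t_init_s", "t_capture_s", pos_cols),
               what = "strike annotation file")
  if (units == "cm") {
    df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(pos_cols), ~ .x / 100))
  }
  tibble::as_tibble(df)
}

#' Read a flume trial table
#'
#' CSV with columns `eel_id`, `U_mps`, `rho_per_m3`, `released`, `recovered`,
#' `control_loss_fraction`. The schema is strict: unknown columns are an
#' error, so silent unit or naming mistakes fail loudly.
#'
#' @param path File path.
#' @return Tibble of trials.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("eel_id", "U_mps", "rho_per_m3", "released", "recovered",
                     "control_loss_fraction"),
               what = "trial table", strict = TRUE)
  tibble::as_tibble(df)
}

check_schema <- function(df, required, optional = character(), what = "file",
                         strict = FALSE) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         "; expected schema: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), c(required, optional))
  if (strict && length(extra)) {
    stop(what, " has unknown column(s): ", paste(extra, collapse = ", "),
         "; expected schema: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
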