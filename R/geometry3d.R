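#' DLT camera objects
#'
#' A `camera_dlt` holds the 11 direct-linear-transformation coefficients of
#' one camera, mapping flume coordinates (metres, x streamwise with upstream
#' positive, y lateral, z up) to image pixels:
#' \deqn{u = \frac{L_1 X + L_2 Y + L_3 Z + L_4}{D}, \quad
#'       v = \frac{L_5 X + L_6 Y + L_7 Z + L_8}{D}, \quad
#'       D = L_9 X + L_{10} Y + L_{11} Z + 1.}
#' The projection denominator `D` must be positive at every point projected
#' (the point is in front of the camera).
#'
#' @param coeffs Numeric vector of length 11 (`L1` .. `L11`).
#' @param camera_id Character scalar naming the camera.
#' @param image_size Optional integer vector `c(width, height)` in pixels.
#' @return An object of class `camera_dlt`.
#' @examples
#' cam <- camera_dlt(c(1, 0, 0, 0, 0, 1, rep(0, 5)), "camA")
#' dlt_project(cam, c(2, 3, 5))
#' @export
camera_dlt <- function(coeffs, camera_id = "cam", image_size = NULL) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != 11L || anyNA(coeffs)) {
    stop("`coeffs` must be 11 finite DLT coefficients (L1..L11)", call. = FALSE)
  }
  structure(
    list(camera_id = as.character(camera_id), coeffs = coeffs,
         image_size = image_size),
    class = "camera_dlt"
  )
}

#' @export
print.camera_dlt <- function(x, ...) {
  cat("<camera_dlt> ", x$camera_id, "\n", sep = "")
  cat("  L1..L11: ", paste(signif(x$coeffs, 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Build a camera from a pinhole model
#'
#' Convenience constructor for synthetic rigs: a pinhole camera with focal
#' length `f` (px), principal point `pp` (px), centre `centre` (m) and an
#' orthonormal orientation whose rows are the camera right/down/forward axes.
#' The resulting 3x4 projection matrix is renormalised so its (3,4) entry is
#' 1, which is exactly the 11-coefficient DLT parameterisation.
#'
#' @param centre Camera centre in flume coordinates (m).
#' @param look_at Point the optical axis passes through (m).
#' @param up Approximate up direction; orthogonalised internally.
#' @param f Focal length in pixels.
#' @param pp Principal point `c(u0, v0)` in pixels.
#' @param camera_id Camera name.
#' @inheritParams camera_dlt
#' @return A `camera_dlt`.
#' @export
camera_pinhole <- function(centre, look_at = c(0, 0, 0.1), up = c(0, 0, 1),
                           f = 1500, pp = c(960, 540), camera_id = "cam",
                           image_size = c(1920L, 1080L)) {
  centre <- as.numeric(centre)
  fwd <- as.numeric(look_at) - centre
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- pracma_cross(fwd, as.numeric(up))
  if (sqrt(sum(right^2)) < 1e-12) {
    stop("`up` is parallel to the viewing direction", call. = FALSE)
  }
  right <- right / sqrt(sum(right^2))
  down <- pracma_cross(fwd, right)
  R <- rbind(right, down, fwd)
  K <- rbind(c(f, 0, pp[1]), c(0, f, pp[2]), c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% centre)
  if (abs(P[3, 4]) < 1e-12) {
    stop("degenerate pinhole geometry: camera centre on the origin plane",
         call. = FALSE)
  }
  P <- P / P[3, 4]
  camera_dlt(c(P[1, ], P[2, ], P[3, 1:3]), camera_id = camera_id,
             image_size = image_size)
}

# cross product; tiny enough that importing a linear-algebra package
# for it is not warranted
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project 3D flume points to pixels
#'
#' Applies the DLT map of a camera to one or more 3D points. The projection
#' denominator must exceed `tol` for every point; points at or behind the
#' camera plane are an error.
#'
#' @param cam A [camera_dlt()].
#' @param p A length-3 numeric vector or an n x 3 matrix/data frame of
#'   points in metres.
#' @param tol Smallest admissible projection denominator.
#' @return A tibble with columns `u`, `v` (pixels), one row per point.
#' @export
dlt_project <- function(cam, p, tol = 1e-9) {
  stopifnot(inherits(cam, "camera_dlt"))
  P <- as_point_matrix(p)
  L <- cam$coeffs
  D <- P %*% L[9:11] + 1
  if (any(D <= tol)) {
    stop("projection denominator <= tolerance for camera '", cam$camera_id,
         "': point at or behind the camera plane", call. = FALSE)
  }
  tibble::tibble(
    u = as.numeric((P %*% L[1:3] + L[4]) / D),
    v = as.numeric((P %*% L[5:7] + L[8]) / D)
  )
}

as_point_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L || anyNA(p)) {
    stop("points must be finite with 3 columns (x, y, z)", call. = FALSE)
  }
  p
}

#' Calibrate a camera from 3D-2D correspondences
#'
#' Solves the overdetermined linear system for the 11 DLT coefficients by
#' least squares from at least 6 non-coplanar 3D points with known pixel
#' positions, and reports the RMS reprojection error over the training
#' correspondences.
#'
#' @param xyz n x 3 matrix/data frame of 3D points (m), n >= 6, non-coplanar.
#' @param uv n x 2 matrix/data frame of the corresponding pixels.
#' @param camera_id Name for the fitted camera.
#' @return A `camera_dlt` with an extra `rms_px` field (RMS reprojection
#'   error of the fit, pixels).
#' @export
dlt_calibrate <- function(xyz, uv, camera_id = "cam") {
  X <- as_point_matrix(xyz)
  U <- if (is.data.frame(uv)) as.matrix(uv) else uv
  if (is.null(dim(U))) U <- matrix(as.numeric(U), ncol = 2)
  if (nrow(X) != nrow(U) || ncol(U) != 2L) {
    stop("`xyz` and `uv` must have matching rows; `uv` needs 2 columns",
         call. = FALSE)
  }
  n <- nrow(X)
  if (n < 6L) {
    stop("DLT calibration needs at least 6 correspondences, got ", n,
         call. = FALSE)
  }
  # coplanarity check: 3D points must span three dimensions
  sv <- svd(scale(X, center = TRUE, scale = FALSE))$d
  if (sv[3] < 1e-10 * max(sv[1], 1e-300)) {
    stop("calibration points are (near-)coplanar: the DLT system is degenerate",
         call. = FALSE)
  }
  A <- matrix(0, 2 * n, 11)
  b <- numeric(2 * n)
  odd <- seq(1, 2 * n, by = 2)
  A[odd, 1:3] <- X
  A[odd, 4] <- 1
  A[odd, 9:11] <- -U[, 1] * X
  A[odd + 1, 5:7] <- X
  A[odd + 1, 8] <- 1
  A[odd + 1, 9:11] <- -U[, 2] * X
  b[odd] <- U[, 1]
  b[odd + 1] <- U[, 2]
  qrA <- qr(A)
  if (qrA$rank < 11L) {
    stop("degenerate correspondence configuration: DLT design matrix is rank ",
         qrA$rank, call. = FALSE)
  }
  L <- qr.coef(qrA, b)
  cam <- camera_dlt(L, camera_id = camera_id)
  proj <- dlt_project(cam, X)
  cam$rms_px <- sqrt(mean((proj$u - U[, 1])^2 + (proj$v - U[, 2])^2))
  cam
}

#' Triangulate a 3D point from two or more camera views
#'
#' Linear least-squares triangulation: each camera contributes two equations
#' obtained by clearing the projection denominator. At least two views with
#' non-parallel rays are required; a condition number of the column-normalised
#' design matrix above `cond_max` flags the result as low confidence.
#'
#' @param cams List of [camera_dlt()] objects.
#' @param uv n_cam x 2 matrix (or data frame) of pixel observations, rows
#'   aligned with `cams`. Rows with any `NA` are dropped.
#' @param cond_max Condition-number threshold for the low-confidence flag.
#' @return A list with `point` (xyz, m), `rms_px` (RMS reprojection residual
#'   over contributing views), `n_views`, and `low_confidence` (logical).
#' @export
dlt_reconstruct <- function(cams, uv, cond_max = 1e6) {
  if (inherits(cams, "camera_dlt")) cams <- list(cams)
  U <- if (is.data.frame(uv)) as.matrix(uv) else uv
  if (is.null(dim(U))) U <- matrix(as.numeric(U), ncol = 2, byrow = TRUE)
  stopifnot(length(cams) == nrow(U))
  keep <- stats::complete.cases(U)
  cams <- cams[keep]
  U <- U[keep, , drop = FALSE]
  if (length(cams) < 2L) {
    stop("triangulation needs >= 2 camera views, got ", length(cams),
         call. = FALSE)
  }
  m <- length(cams)
  A <- matrix(0, 2 * m, 3)
  b <- numeric(2 * m)
  for (i in seq_len(m)) {
    L <- cams[[i]]$coeffs
    u <- U[i, 1]; v <- U[i, 2]
    A[2 * i - 1, ] <- L[1:3] - u * L[9:11]
    b[2 * i - 1] <- u - L[4]
    A[2 * i, ] <- L[5:7] - v * L[9:11]
    b[2 * i] <- v - L[8]
  }
  # column-normalise before conditioning so pixel scale does not dominate
  nrm <- pmax(sqrt(colSums(A^2)), 1e-300)
  An <- sweep(A, 2, nrm, "/")
  d <- svd(An, nu = 0, nv = 0)$d
  kappa <- d[1] / max(d[3], 1e-300)
  p <- as.numeric(qr.coef(qr(A), b))
  if (anyNA(p)) {
    stop("triangulation failed: rays are parallel or views inconsistent",
         call. = FALSE)
  }
  res2 <- vapply(seq_len(m), function(i) {
    pr <- dlt_project(cams[[i]], p)
    (pr$u - U[i, 1])^2 + (pr$v - U[i, 2])^2
  }, numeric(1))
  list(point = p, rms_px = sqrt(mean(res2)), n_views = m,
       low_confidence = kappa > cond_max)
}

#' Reconstruct a full 3D track from multi-camera 2D observations
#'
#' Groups 2D observations by frame and body-point label, drops observations
#' below the confidence cutoff, and triangulates every (frame, label) seen by
#' at least two cameras.
#'
#' @param obs Tibble of 2D observations with columns `camera_id`, `frame`,
#'   `label`, `u`, `v` and optionally `confidence`.
#' @param cams Named list of [camera_dlt()] (names = camera ids), or an
#'   unnamed list whose elements carry `camera_id`.
#' @param min_confidence Observations with `confidence` below this are
#'   dropped before triangulation.
#' @param cond_max Passed to [dlt_reconstruct()].
#' @return A tibble with columns `frame`, `label`, `x_m`, `y_m`, `z_m`,
#'   `rms_px`, `n_views`, `low_confidence`.
#' @export
reconstruct_track <- function(obs, cams, min_confidence = 0.6,
                              cond_max = 1e6) {
  obs <- tibble::as_tibble(obs)
  req <- c("camera_id", "frame", "label", "u", "v")
  if (!all(req %in% names(obs))) {
    stop("observations need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(cams)) || any(names(cams) == "")) {
    names(cams) <- vapply(cams, `[[`, character(1), "camera_id")
  }
  missing_cams <- setdiff(unique(obs$camera_id), names(cams))
  if (length(missing_cams)) {
    stop("no DLT coefficients for camera(s): ",
         paste(missing_cams, collapse = ", "), call. = FALSE)
  }
  if ("confidence" %in% names(obs)) {
    n0 <- nrow(obs)
    obs <- dplyr::filter(obs, is.na(.data$confidence) |
                           .data$confidence >= min_confidence)
    dropped <- n0 - nrow(obs)
    if (dropped > 0) {
      rlang::inform(paste0("dropped ", dropped,
                           " low-confidence observation(s) (< ",
                           min_confidence, ")"))
    }
  }
  obs |>
    dplyr::group_by(.data$frame, .data$label) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::summarise(
      res = list(dlt_reconstruct(unname(cams[.data$camera_id]),
                                 cbind(.data$u, .data$v),
                                 cond_max = cond_max)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      x_m = purrr::map_dbl(.data$res, ~ .x$point[1]),
      y_m = purrr::map_dbl(.data$res, ~ .x$point[2]),
      z_m = purrr::map_dbl(.data$res, ~ .x$point[3]),
      rms_px = purrr::map_dbl(.data$res, "rms_px"),
      n_views = purrr::map_int(.data$res, ~ as.integer(.x$n_views)),
      low_confidence = purrr::map_lgl(.data$res, "low_confidence")
    ) |>
    dplyr::select(-"res") |>
    dplyr::arrange(.data$frame, .data$label)
}
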