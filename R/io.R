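# CXI-style HDF5 scan container and plain-text configuration.
#
# On-disk layout (group/dataset names follow the CXI deposition convention):
#   /entry_1/data_1/data                       frames (rows x cols x N as an
#                                              R array; HDF5 lists the axes
#                                              reversed)
#   /entry_1/sample_1/geometry/translation     N x 3 (x, y, z) in metres
#   /entry_1/instrument_1/detector_1/distance  sample-detector z (m)
#   /entry_1/instrument_1/detector_1/{x,y}_pixel_size (m)
#   /entry_1/instrument_1/detector_1/mask      1 = good pixel
#   /entry_1/instrument_1/source_1/energy      photon energy (eV)
#   /speckle_tracking/*                        results and focus distances
#   /truth/*                                   simulation ground truth
#
# Pixel convention: 0-based indices, pixel centres on integer coordinates,
# axis 0 = slow = y increasing downward in file order; physical y flips sign
# relative to file order nowhere (we keep y increasing with row index).

h5_write_scalar <- function(file, path, value, units = NULL) {
  rhdf5::h5write(value, file, path)
  if (!is.null(units)) {
    fid <- rhdf5::H5Fopen(file)
    on.exit(rhdf5::H5Fclose(fid), add = TRUE)
    did <- rhdf5::H5Dopen(fid, path)
    on.exit(rhdf5::H5Dclose(did), add = TRUE)
    rhdf5::h5writeAttribute(units, did, "units")
  }
}

#' Write a scan to a CXI-style HDF5 container
#'
#' @param scan a [scan_data()].
#' @param path output file path (overwritten).
#' @param truth optional ground-truth list (from [simulate_scan()]), stored
#'   under `/truth` for validation work.
#' @param extra_geometry store focus-sample distances under
#'   `/speckle_tracking` so the file is self-contained.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, truth = NULL, extra_geometry = TRUE) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  g <- scan$geometry
  for (grp in c("entry_1", "entry_1/data_1", "entry_1/sample_1",
                "entry_1/sample_1/geometry", "entry_1/instrument_1",
                "entry_1/instrument_1/detector_1",
                "entry_1/instrument_1/source_1", "speckle_tracking"))
    rhdf5::h5createGroup(path, grp)
  rhdf5::h5write(scan$images, path, "entry_1/data_1/data")
  tr <- cbind(x = scan$translations[, 2], y = scan$translations[, 1], z = 0)
  h5_write_scalar(path, "entry_1/sample_1/geometry/translation", tr, "m")
  det <- "entry_1/instrument_1/detector_1"
  h5_write_scalar(path, file.path(det, "distance"), g$sample_detector, "m")
  h5_write_scalar(path, file.path(det, "x_pixel_size"), g$pixel_size, "m")
  h5_write_scalar(path, file.path(det, "y_pixel_size"), g$pixel_size, "m")
  rhdf5::h5write(1L * scan$mask, path, file.path(det, "mask"))
  h5_write_scalar(path, "entry_1/instrument_1/source_1/energy",
                  g$energy_kev * 1e3, "eV")
  if (extra_geometry) {
    rhdf5::h5write(g$focus_sample_x, path, "speckle_tracking/focus_sample_x")
    rhdf5::h5write(g$focus_sample_y, path, "speckle_tracking/focus_sample_y")
    rhdf5::h5write(g$interpolation_factor, path,
                   "speckle_tracking/interpolation_factor")
  }
  if (!is.null(truth)) {
    rhdf5::h5createGroup(path, "truth")
    rhdf5::h5write(truth$W, path, "truth/white_field")
    rhdf5::h5write(truth$u, path, "truth/pixel_map")
    rhdf5::h5write(truth$reference$image, path, "truth/reference")
    rhdf5::h5write(truth$reference$pitch, path, "truth/reference_pitch")
    rhdf5::h5write(truth$reference$origin, path, "truth/reference_origin")
    rhdf5::h5write(truth$phase, path, "truth/phase")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a scan from a CXI-style HDF5 container
#'
#' @param path file path.
#' @param focus_sample optional length-2 override (z1x, z1y) in metres when
#'   the file carries no focus distances.
#' @return a [scan_data()] whose geometry is populated from the file.
#' @export
read_scan <- function(path, focus_sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  have <- file.path(sub("^/", "", ls$group), ls$name)
  need <- c("entry_1/data_1/data",
            "entry_1/sample_1/geometry/translation",
            "entry_1/instrument_1/detector_1/distance",
            "entry_1/instrument_1/detector_1/x_pixel_size",
            "entry_1/instrument_1/source_1/energy")
  for (p in need)
    if (!p %in% have)
      stop("missing dataset in container: /", p)
  imgs <- rhdf5::h5read(path, "entry_1/data_1/data")
  tr <- rhdf5::h5read(path, "entry_1/sample_1/geometry/translation")
  z <- as.numeric(rhdf5::h5read(path,
                                "entry_1/instrument_1/detector_1/distance"))
  px <- as.numeric(rhdf5::h5read(path,
                                 "entry_1/instrument_1/detector_1/x_pixel_size"))
  energy_ev <- as.numeric(rhdf5::h5read(path,
                                        "entry_1/instrument_1/source_1/energy"))
  mask <- if ("entry_1/instrument_1/detector_1/mask" %in% have)
    rhdf5::h5read(path, "entry_1/instrument_1/detector_1/mask") != 0
  else NULL
  if (is.null(focus_sample)) {
    if ("speckle_tracking/focus_sample_x" %in% have) {
      focus_sample <- c(
        as.numeric(rhdf5::h5read(path, "speckle_tracking/focus_sample_x")),
        as.numeric(rhdf5::h5read(path, "speckle_tracking/focus_sample_y")))
    } else {
      warning("no focus-sample distance in file; using 1 mm placeholder ",
              "(set via 'focus_sample' or a defocus search)")
      focus_sample <- c(1e-3, 1e-3)
    }
  }
  delta_pix <- if ("speckle_tracking/interpolation_factor" %in% have)
    as.numeric(rhdf5::h5read(path, "speckle_tracking/interpolation_factor"))
  else 1
  rhdf5::h5closeAll()
  if (max(abs(tr[, 3])) > 1e-9)
    warning("translation z-components are not ~0; they are ignored")
  g <- xrt_geometry(energy_kev = energy_ev / 1e3,
                    focus_sample_x = focus_sample[1],
                    focus_sample_y = focus_sample[2],
                    sample_detector = z,
                    detector_shape = dim(imgs)[1:2],
                    pixel_size = px,
                    interpolation_factor = delta_pix)
  scan_data(imgs, cbind(tr[, 2], tr[, 1]), g, mask = mask)
}

#' Write reconstruction results into a scan container
#'
#' Stores the reference image, pixel map, refined translations, error map and
#' per-iteration error log under `/speckle_tracking`, plus the recovered
#' phase, residual phase and ray angles.
#'
#' @param result a `pxst_result`.
#' @param path container path (created by [write_scan()]).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  if (!file.exists(path)) stop("no such file: ", path)
  st <- "speckle_tracking"
  ls <- rhdf5::h5ls(path)
  have <- file.path(sub("^/", "", ls$group), ls$name)
  if (!"speckle_tracking" %in% sub("^/", "", unique(ls$group)))
    rhdf5::h5createGroup(path, st)
  drop_if <- function(p) if (p %in% have) rhdf5::h5delete(path, p)
  img <- result$reference$image
  img[!is.finite(img)] <- -1
  for (p in c("reference_image", "reference_pitch", "reference_origin",
              "pixel_map", "translations", "error_map", "sse_log",
              "phase", "phase_residual", "ray_angles"))
    drop_if(file.path(st, p))
  rhdf5::h5write(img, path, file.path(st, "reference_image"))
  rhdf5::h5write(result$reference$pitch, path, file.path(st, "reference_pitch"))
  rhdf5::h5write(result$reference$origin, path,
                 file.path(st, "reference_origin"))
  rhdf5::h5write(result$pixel_map, path, file.path(st, "pixel_map"))
  rhdf5::h5write(result$translations, path, file.path(st, "translations"))
  rhdf5::h5write(result$sse, path, file.path(st, "sse_log"))
  rhdf5::h5write(result$wavefront$phase, path, file.path(st, "phase"))
  pr <- result$wavefront$phase_residual
  pr[!is.finite(pr)] <- 0
  rhdf5::h5write(pr, path, file.path(st, "phase_residual"))
  th <- array(0, c(dim(result$wavefront$theta_y), 2))
  th[, , 1] <- result$wavefront$theta_y
  th[, , 2] <- result$wavefront$theta_x
  rhdf5::h5write(th, path, file.path(st, "ray_angles"))
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Lines of `key = value`; `#` starts a comment. Recognized keys include
#' `energy_kev`, `focus_sample_x_m`, `focus_sample_y_m`, `sample_detector_m`,
#' `pixel_size_m`, `roi` (as `"r1:r2,c1:c2"`).
#'
#' @param path file path.
#' @return named list (numeric where possible).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", l)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Build a geometry from a configuration list
#'
#' @param config list from [read_config()].
#' @param detector_shape fallback detector shape if no `roi` key.
#' @return an [xrt_geometry()].
#' @export
geometry_from_config <- function(config, detector_shape = c(256L, 256L)) {
  if (!is.null(config$roi)) {
    parts <- strsplit(config$roi, "[,:]")[[1]]
    v <- as.integer(parts)
    detector_shape <- c(v[2] - v[1] + 1L, v[4] - v[3] + 1L)
  }
  xrt_geometry(
    energy_kev = config$energy_kev,
    focus_sample_x = config$focus_sample_x_m,
    focus_sample_y = config$focus_sample_y_m %||% config$focus_sample_x_m,
    sample_detector = config$sample_detector_m,
    detector_shape = detector_shape,
    pixel_size = config$pixel_size_m %||% 55e-6)
}

#' Experiment parameter sheet
#'
#' Summarizes the closed-form geometry of a scan the way beamline papers
#' tabulate it: magnification, effective defocus, effective pixel, validity
#' limits, and the ideal angular sensitivity.
#'
#' @param geometry an [xrt_geometry()].
#' @param iterations iteration count to report (optional).
#' @return named list.
#' @export
pxst_report <- function(geometry, iterations = NULL) {
  d <- derive_geometry(geometry)
  out <- list(
    energy_kev = geometry$energy_kev,
    wavelength_m = geometry$wavelength,
    focus_sample_x_m = geometry$focus_sample_x,
    focus_sample_y_m = geometry$focus_sample_y,
    sample_detector_m = geometry$sample_detector,
    magnification = d$M,
    magnification_x = d$M_x,
    magnification_y = d$M_y,
    effective_defocus_m = d$effective_defocus,
    effective_pixel_m = d$demagnified_pixel,
    field_of_view_m = d$fov,
    numerical_aperture = d$na,
    thickness_limit_m = d$thickness_limit,
    tilt_limit_rad = d$tilt_limit,
    angular_sensitivity_bound_rad = d$sensitivity_bound)
  if (!is.null(iterations)) out$iterations <- iterations
  out
}
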