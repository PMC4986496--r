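# HU <-> relative electron density calibration.  The linear model is
# HU = offset + slope * (rho_e - 1): `offset` is the HU of water (rho_e = 1)
# and `slope` the HU change per unit relative electron density.  MV
# calibrations drift over time, so lines carry a validity date and machine
# id and are selected by image date.

#' Calibration line
#'
#' @param offset HU at unit relative electron density (water); sanity bound
#'   +/- 100 HU.
#' @param slope HU per unit relative electron density; must be positive.
#' @param valid_from first date the line applies to.
#' @param machine_id machine identifier.
#' @param offset_sd,slope_sd optional 1-sd uncertainties (stored, not
#'   propagated into dose).
#' @return object of class `calibration_line`.
#' @export
calibration_line <- function(offset, slope, valid_from = as.Date("2000-01-01"),
                             machine_id = "A", offset_sd = NA_real_,
                             slope_sd = NA_real_) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  if (!is.finite(offset) || abs(offset) > 100)
    stop("offset outside the +/-100 HU sanity bound")
  structure(list(offset = offset, slope = slope,
                 valid_from = as.Date(valid_from), machine_id = machine_id,
                 offset_sd = offset_sd, slope_sd = slope_sd),
            class = "calibration_line")
}

#' The standard kV calibration line (offset 0, slope 1000)
#' @return a [calibration_line()].
#' @export
kv_calibration <- function() {
  calibration_line(0, 1000, as.Date("1990-01-01"), machine_id = "kV")
}

#' Convert HU to relative electron density
#'
#' `rho_e = 1 + (HU - offset) / slope`, clamped at zero (density is never
#' negative).  On the kV line (offset 0, slope 1000) an HU of -1000 maps to
#' zero density and HU 0 to water.
#'
#' @param hu numeric HU values (scalar or vector).
#' @param line a [calibration_line()].
#' @return relative electron densities, same shape as `hu`.
#' @export
hu_to_density <- function(hu, line) {
  pmax(0, 1 + (hu - line$offset) / line$slope)
}

#' Forward model: relative electron density to HU
#' @param rho relative electron density.
#' @param line a [calibration_line()].
#' @return HU values.
#' @export
density_to_hu <- function(rho, line) {
  line$offset + line$slope * (rho - 1)
}

#' Read a calibration table from CSV
#'
#' Columns: `machine_id`, `valid_from` (ISO date), `offset`, `slope`, and
#' optionally `offset_sd`, `slope_sd`.
#'
#' @param path CSV file.
#' @return data frame with `valid_from` parsed as `Date`.
#' @export
read_calibration_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("machine_id", "valid_from", "offset", "slope")
  if (!all(need %in% names(tb)))
    stop("calibration table must have columns: ", paste(need, collapse = ", "))
  tb$valid_from <- as.Date(tb$valid_from)
  tb
}

#' The bundled MV calibration history for machines "A" and "B"
#' @return data frame as from [read_calibration_table()].
#' @export
default_calibration_table <- function() {
  read_calibration_table(system.file("extdata", "mv_calibration.csv",
                                     package = "voxcalc", mustWork = TRUE))
}

#' Select the calibration line valid for an image date
#'
#' The line with the latest `valid_from` not after `date` applies: each
#' table row is used from its date until the next row's date
#' (piecewise-constant, right-continuous in date).
#'
#' @param date image acquisition date.
#' @param machine_id machine identifier.
#' @param table data frame from [read_calibration_table()].
#' @return a [calibration_line()].
#' @export
select_calibration <- function(date, machine_id,
                               table = default_calibration_table()) {
  date <- as.Date(date)
  rows <- table[table$machine_id == machine_id &
                  table$valid_from <= date, , drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("no calibration for machine '%s' on or before %s",
                 machine_id, format(date)))
  r <- rows[which.max(as.numeric(rows$valid_from)), ]
  calibration_line(r$offset, r$slope, r$valid_from, machine_id,
                   offset_sd = if ("offset_sd" %in% names(r)) r$offset_sd
                     else NA_real_,
                   slope_sd = if ("slope_sd" %in% names(r)) r$slope_sd
                     else NA_real_)
}

#' Fit a calibration line from density-insert measurements
#'
#' Ordinary least squares of measured HU on `(rho_e - 1)` -- the measurement
#' noise lives in HU, so HU is the response.  The intercept is the offset
#' (HU of water) and the gradient the slope.
#'
#' @param measurements data frame with columns `density` (nominal relative
#'   electron density) and `hu` (mean measured HU); see
#'   [measure_inserts()].
#' @param valid_from,machine_id metadata for the fitted line.
#' @return a [calibration_line()] with attribute `residual_sd`.
#' @export
fit_calibration <- function(measurements, valid_from = Sys.Date(),
                            machine_id = "A") {
  d <- measurements
  if (nrow(d) < 2 || length(unique(d$density)) < 2)
    stop("need at least 2 distinct densities to fit a calibration")
  if (any(d$density < 0)) stop("densities must be non-negative")
  fit <- stats::lm(hu ~ I(density - 1), data = d)
  co <- stats::coef(fit)
  line <- calibration_line(unname(co[1]), unname(co[2]), valid_from,
                           machine_id)
  attr(line, "residual_sd") <- stats::sigma(fit)
  line
}

#' Monthly HU QA check for water-equivalent material
#'
#' Fails when the measured water HU deviates from the calibrated value by
#' `tolerance` HU or more (the 30 HU criterion; boundary exclusive).
#'
#' @param water_hu measured mean HU of the water insert.
#' @param line a [calibration_line()].
#' @param tolerance HU tolerance, default 30.
#' @return list with `pass` (logical) and `deviation` (HU).
#' @export
qa_check <- function(water_hu, line, tolerance = 30) {
  dev <- water_hu - line$offset
  list(pass = abs(dev) < tolerance, deviation = dev)
}

#' Mean HU inside circular regions of interest
#'
#' The mean is taken over voxels whose centres fall inside each circle.
#'
#' @param vol an [image_volume()].
#' @param roi_specs data frame with columns `density` (nominal), `x`, `y`
#'   (centre, mm), `radius` (mm) and `slice` (index).
#' @return data frame of insert measurements with columns `density`, `hu`,
#'   `n_voxels`.
#' @export
measure_inserts <- function(vol, roi_specs) {
  xs <- vol_x(vol); ys <- vol_y(vol)
  out <- roi_specs
  out$hu <- NA_real_; out$n_voxels <- NA_integer_
  for (i in seq_len(nrow(roi_specs))) {
    r <- roi_specs[i, ]
    if (r$slice < 1 || r$slice > dim(vol$voxels)[3])
      stop("ROI slice index outside image")
    if (r$x - r$radius < min(xs) || r$x + r$radius > max(xs) ||
        r$y - r$radius < min(ys) || r$y + r$radius > max(ys))
      stop("ROI extends outside the image")
    inside <- outer(ys - r$y, xs - r$x,
                    function(dy, dx) dx^2 + dy^2 < r$radius^2)
    if (!any(inside)) stop("ROI contains no voxel centres")
    sl <- vol$voxels[, , r$slice]
    out$hu[i] <- mean(sl[inside])
    out$n_voxels[i] <- sum(inside)
  }
  out
}

#' The nominal relative electron densities of the calibration inserts
#'
#' The twelve density inserts plus air (0) and distilled water (1).
#' @return numeric vector of length 14.
#' @export
insert_densities <- function() {
  c(0, 0.30, 0.49, 0.942, 0.979, 1, 1.018, 1.053, 1.080, 1.104, 1.112,
    1.274, 1.472, 1.694)
}
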