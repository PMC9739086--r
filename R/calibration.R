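#' Calibration parameters
#'
#' Per-sensor, per-axis offset and slope constants.  Each raw reading is
#' corrected as `(raw - offset) * slope`.
#'
#' @param accelerometer,gyroscope,magnetometer lists with numeric `offset`
#'   and `slope`, each length 1 or 3 (recycled per axis).  Slopes must be
#'   nonzero.
#' @return A list of class `calibration_params`.
#' @export
calibration_params <- function(accelerometer = list(offset = 0, slope = 1),
                               gyroscope = list(offset = 0, slope = 1),
                               magnetometer = list(offset = 0, slope = 1)) {
  fix <- function(s, name) {
    s$offset <- rep(as.numeric(s$offset), length.out = 3)
    s$slope <- rep(as.numeric(s$slope), length.out = 3)
    if (any(s$slope == 0)) stop("zero slope for ", name, " is not invertible")
    s
  }
  structure(
    list(accelerometer = fix(accelerometer, "accelerometer"),
         gyroscope = fix(gyroscope, "gyroscope"),
         magnetometer = fix(magnetometer, "magnetometer")),
    class = "calibration_params")
}

.calibrate_mat <- function(m, offset, slope) {
  sweep(sweep(m, 2, offset), 2, slope, `*`)
}

#' Apply offset/slope calibration to a capture
#'
#' Corrects every channel of a capture (or a single n x 3 sensor matrix)
#' as `(raw - offset) * slope`, per axis.
#'
#' @param data an `imu_capture` tibble (columns `ax` .. `mz`) or an n x 3
#'   matrix of one sensor's readings.
#' @param params a [calibration_params()]; for a matrix input, a list with
#'   `offset` and `slope`.
#' @return The calibrated object, same shape as the input.
#' @export
apply_calibration <- function(data, params) {
  if (is.matrix(data) || (is.data.frame(data) && !("ax" %in% names(data)))) {
    m <- .as_xyz_matrix(data, "data")
    stopifnot(!is.null(params$offset), !is.null(params$slope))
    offset <- rep(as.numeric(params$offset), length.out = 3)
    slope <- rep(as.numeric(params$slope), length.out = 3)
    if (any(slope == 0)) stop("zero slope is not invertible")
    return(.calibrate_mat(m, offset, slope))
  }
  stopifnot(inherits(params, "calibration_params"))
  out <- data
  sensors <- list(accelerometer = c("ax", "ay", "az"),
                  gyroscope = c("gx", "gy", "gz"),
                  magnetometer = c("mx", "my", "mz"))
  for (s in names(sensors)) {
    cols <- sensors[[s]]
    m <- .calibrate_mat(as.matrix(data[cols]),
                        params[[s]]$offset, params[[s]]$slope)
    out[cols] <- as.data.frame(m)
  }
  out
}

#' Read / write calibration parameters as YAML
#'
#' One key per sensor, each with per-axis `offset` and `slope` vectors.
#'
#' @param path file path.
#' @return `read_calibration()` returns a [calibration_params()].
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(calibration_params, y[intersect(names(y),
    c("accelerometer", "gyroscope", "magnetometer"))])
}

#' @rdname read_calibration
#' @param params a [calibration_params()].
#' @export
write_calibration <- function(params, path) {
  stopifnot(inherits(params, "calibration_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Estimate accelerometer offsets from a stationary, level segment
#'
#' Convenience helper (not part of the device's own calibration procedure):
#' assuming the device is stationary and level so the true specific force
#' is `(0, 0, -g)`, the per-axis offsets are the mean readings minus that
#' expectation.  Slopes are left at 1.
#'
#' @param capture an `imu_capture` tibble covering a stationary, level
#'   period.
#' @param g gravity magnitude, m/s^2.
#' @return A list with `offset` (length 3) and `slope` (`c(1, 1, 1)`)
#'   suitable for the accelerometer slot of [calibration_params()].
#' @export
estimate_accel_offset <- function(capture, g = 9.80665) {
  m <- colMeans(as.matrix(capture[c("ax", "ay", "az")]))
  list(offset = as.numeric(m - c(0, 0, -g)), slope = c(1, 1, 1))
}

#' Sensor digitizer scale
#'
#' Full-scale range and bit depth of a sensor channel; fixes the physical
#' size of one least-significant bit (LSB) as
#' `2 * full_scale / 2^bit_depth`.
#'
#' @param full_scale full-scale magnitude in physical units (e.g. 8 for
#'   +/-8 g).
#' @param bit_depth digitizer resolution in bits (default 16).
#' @param unit unit label (informational).
#' @return A list of class `sensor_scale`.
#' @export
sensor_scale <- function(full_scale, bit_depth = 16, unit = "") {
  stopifnot(full_scale > 0, bit_depth > 0)
  structure(list(full_scale = full_scale, bit_depth = as.integer(bit_depth),
                 unit = unit),
            class = "sensor_scale")
}

#' Convert raw digitizer counts to physical units
#'
#' Linear and odd: `value = counts * 2 * full_scale / 2^bit_depth`.  At the
#' accelerometer's +/-8 g and 16 bits this LSB size is 0.244 mg (to 3
#' significant figures).
#'
#' @param counts integer counts within the signed `bit_depth` range.
#' @param scale a [sensor_scale()].
#' @return Numeric values in the scale's physical units.
#' @export
counts_to_units <- function(counts, scale) {
  stopifnot(inherits(scale, "sensor_scale"))
  lim <- 2^(scale$bit_depth - 1)
  if (any(counts < -lim | counts > lim - 1)) {
    stop("counts outside the signed ", scale$bit_depth, "-bit range [",
         -lim, ", ", lim - 1, "]")
  }
  counts * (2 * scale$full_scale / 2^scale$bit_depth)
}

#' LSB size of a sensor scale
#'
#' @param scale a [sensor_scale()].
#' @return The physical size of one count, `2 * full_scale / 2^bit_depth`.
#' @export
lsb_size <- function(scale) {
  2 * scale$full_scale / 2^scale$bit_depth
}

#' Device sensor configuration table
#'
#' The full scales used by the wrist device, with both the derived LSB size
#' (`2 * FS / 2^16`) and the manufacturer's stated resolution.  The stated
#' gyroscope and magnetometer resolutions are datasheet sensitivities that
#' do not equal the derived value; they are carried as data only.
#'
#' @return A tibble with one row per sensor.
#' @export
sensor_scales <- function() {
  tibble::tibble(
    sensor = c("accelerometer", "gyroscope", "magnetometer"),
    full_scale = c(8, 2000, 8),
    unit = c("g", "dps", "gauss"),
    odr_hz = c(476, 476, 40),
    lsb_derived = vapply(c(8, 2000, 8),
                         function(fs) lsb_size(sensor_scale(fs)), numeric(1)),
    resolution_stated = c("0.244 mg/LSB", "70 mdps/LSB", "0.29 mgauss/LSB"))
}
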