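#' Read and write IMU captures as CSV
#'
#' Captures serialize with a header row and columns `t` (s), `ax`, `ay`,
#' `az` (m/s^2), `gx`, `gy`, `gz` (rad/s), `mx`, `my`, `mz` (gauss).
#' Unit information is carried in `#`-prefixed header comment lines.
#'
#' @param capture an `imu_capture` tibble.
#' @param path file path.
#' @return `write_capture()` returns `path` invisibly; `read_capture()`
#'   returns an `imu_capture` tibble with attribute `sample_period`.
#' @export
write_capture <- function(capture, path) {
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  stopifnot(all(need %in% names(capture)))
  header <- c(
    "# wristkin IMU capture",
    "# units: t s; ax ay az m/s^2; gx gy gz rad/s; mx my mz gauss")
  readr::write_lines(header, path)
  readr::write_csv(capture[need], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_capture
#' @export
read_capture <- function(path) {
  cap <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  missing <- setdiff(need, names(cap))
  if (length(missing) > 0) {
    stop("capture file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  bad <- !vapply(cap[need], is.numeric, logical(1))
  if (any(bad)) {
    stop("capture file ", path, " has non-numeric columns: ",
         paste(need[bad], collapse = ", "))
  }
  cap <- tibble::as_tibble(cap[need])
  if (nrow(cap) >= 2) attr(cap, "sample_period") <- cap$t[2] - cap$t[1]
  class(cap) <- c("imu_capture", class(cap))
  cap
}

#' Read and write kinematic tracks as CSV
#'
#' Tracks serialize with columns `t` (s), `ax_e`, `ay_e`, `az_e` (m/s^2,
#' earth-frame dynamic acceleration), `vx`, `vy`, `vz` (m/s), `x`, `y`, `z`
#' (m), `speed` (m/s), with units in `#` header comments.
#'
#' @param track a `kinematic_track` tibble.
#' @param path file path.
#' @return `write_track()` returns `path` invisibly; `read_track()` returns
#'   a `kinematic_track` tibble.
#' @export
write_track <- function(track, path) {
  need <- c("t", "ax_e", "ay_e", "az_e", "vx", "vy", "vz", "x", "y", "z",
            "speed")
  stopifnot(all(need %in% names(track)))
  header <- c(
    "# wristkin kinematic track",
    "# units: t s; ax_e ay_e az_e m/s^2; vx vy vz m/s; x y z m; speed m/s")
  readr::write_lines(header, path)
  readr::write_csv(tibble::as_tibble(track)[need], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  trk <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("t", "ax_e", "ay_e", "az_e", "vx", "vy", "vz", "x", "y", "z",
            "speed")
  missing <- setdiff(need, names(trk))
  if (length(missing) > 0) {
    stop("track file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  trk <- tibble::as_tibble(trk[need])
  if (nrow(trk) >= 2) attr(trk, "sample_period") <- trk$t[2] - trk$t[1]
  class(trk) <- c("kinematic_track", class(trk))
  trk
}
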