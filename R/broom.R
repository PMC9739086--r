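#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinematic track
#'
#' Returns the per-sample results as a plain tibble (one row per sample),
#' with the zero-velocity mask exposed as a column.
#'
#' @param x a `kinematic_track`.
#' @param ... unused.
#' @return A tibble with the track columns plus `zupt` (logical).
#' @method tidy kinematic_track
#' @export
tidy.kinematic_track <- function(x, ...) {
  out <- tibble::as_tibble(x)
  mask <- attr(x, "zupt_mask")
  out$zupt <- if (is.null(mask)) NA else mask
  out
}

#' One-row summary of a kinematic track
#'
#' @param x a `kinematic_track`.
#' @param ... unused.
#' @return A one-row tibble: `n_samples`, `duration` (s), `peak_speed`
#'   (m/s), `peak_sample` (1-based index of the speed maximum),
#'   `net_displacement` (m, distance from start to end of the reconstructed
#'   path), `zupt_zeroed` (samples zeroed by the zero-velocity update, `NA`
#'   for tracks read from CSV).
#' @method glance kinematic_track
#' @export
glance.kinematic_track <- function(x, ...) {
  mask <- attr(x, "zupt_mask")
  tibble::tibble(
    n_samples = nrow(x),
    duration = if (nrow(x) >= 2) x$t[nrow(x)] - x$t[1] + (x$t[2] - x$t[1]) else 0,
    peak_speed = max(x$speed),
    peak_sample = which.max(x$speed),
    net_displacement = sqrt(sum((as.numeric(x[nrow(x), c("x", "y", "z")]) -
                                   as.numeric(x[1, c("x", "y", "z")]))^2)),
    zupt_zeroed = if (is.null(mask)) NA_integer_ else sum(mask))
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config> beta =", x$beta,
      "| dt =", x$sample_period, "s",
      "| mag ref =", paste(round(x$magnetic_reference, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> N =", x$smoothing_window, paste0("(", x$smoothing_type, ")"),
      "| highpass =", x$highpass_cutoff, "Hz",
      "| ZUPT +/-", x$zupt_limit, "m/s^2 x", x$zupt_count, "samples\n")
  invisible(x)
}

#' @export
print.stabilization <- function(x, ...) {
  e <- x$euler_history[nrow(x$euler_history), ]
  cat("<stabilization>", if (x$converged) "converged" else "NOT converged",
      sprintf("| final yaw %.2f pitch %.2f roll %.2f deg\n",
              e$yaw, e$pitch, e$roll))
  invisible(x)
}

#' @export
print.telemetry_stream <- function(x, ...) {
  cat("<telemetry_stream>", x$n, "frames,", x$n * 20, "bytes")
  if (any(x$offsets != 0)) {
    cat(" | offsets:", paste(names(x$offsets), x$offsets, sep = "=",
                             collapse = " "))
  }
  cat("\n")
  invisible(x)
}
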