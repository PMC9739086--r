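#' Plot the reconstructed speed profile
#'
#' Instantaneous speed against sample number, the view on which the
#' characteristic peaks of a throw (wind-up, turn, release) show up.
#'
#' @param track a `kinematic_track`.
#' @return A ggplot object.
#' @export
plot_speed <- function(track) {
  df <- tibble::tibble(sample = seq_len(nrow(track)), speed = track$speed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$speed)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "sample", y = "speed (m/s)",
                  title = "Instantaneous speed") +
    ggplot2::theme_minimal()
}

#' Top view (XY plane) of the reconstructed trajectory
#'
#' North (x) against east (y), equal-scaled, with the origin marked: the
#' view in which the rotation radius of a throw is read off.
#'
#' @param track a `kinematic_track`.
#' @return A ggplot object.
#' @export
plot_top_view <- function(track) {
  ggplot2::ggplot(tibble::as_tibble(track),
                  ggplot2::aes(x = .data$y, y = .data$x)) +
    ggplot2::geom_path(colour = "#2c7fb8") +
    ggplot2::annotate("point", x = 0, y = 0, shape = 4, size = 3,
                      colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y east (m)", y = "x north (m)",
                  title = "Top view (XY plane)") +
    ggplot2::theme_minimal()
}

#' Side view (XZ plane) of the reconstructed trajectory
#'
#' North (x) against height (-z; NED z points down), showing e.g. the arm
#' elevation during a release.
#'
#' @param track a `kinematic_track`.
#' @return A ggplot object.
#' @export
plot_side_view <- function(track) {
  ggplot2::ggplot(tibble::as_tibble(track),
                  ggplot2::aes(x = .data$x, y = -.data$z)) +
    ggplot2::geom_path(colour = "#2c7fb8") +
    ggplot2::annotate("point", x = 0, y = 0, shape = 4, size = 3,
                      colour = "red") +
    ggplot2::labs(x = "x north (m)", y = "height -z (m)",
                  title = "Side view (XZ plane)") +
    ggplot2::theme_minimal()
}

#' 3D view of the reconstructed trajectory
#'
#' Isometric projection of the 3D path onto the page (axes x north, y east,
#' height -z), coloured by sample order, with the origin marked.
#'
#' @param track a `kinematic_track`.
#' @return A ggplot object.
#' @export
plot_trajectory_3d <- function(track) {
  c30 <- cos(pi / 6); s30 <- sin(pi / 6)
  df <- tibble::tibble(
    u = (track$x - track$y) * c30,
    v = (track$x + track$y) * s30 + (-track$z),
    sample = seq_len(nrow(track)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   colour = .data$sample)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 0, y = 0, shape = 4, size = 3,
                      colour = "red") +
    ggplot2::scale_colour_viridis_c(guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "3D trajectory (isometric projection)") +
    ggplot2::theme_minimal()
}

#' Autoplot a kinematic track
#'
#' @param object a `kinematic_track`.
#' @param type one of `"speed"`, `"top"`, `"side"`, `"3d"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot kinematic_track
#' @export
autoplot.kinematic_track <- function(object, type = c("speed", "top", "side", "3d"),
                                     ...) {
  switch(match.arg(type),
         speed = plot_speed(object),
         top = plot_top_view(object),
         side = plot_side_view(object),
         `3d` = plot_trajectory_3d(object))
}

#' Plot the fusion stabilization history
#'
#' Yaw, pitch, and roll (degrees) against time during the warm-up phase,
#' showing the estimation error being worked off before capture starts.
#'
#' @param stab a `stabilization` object from [stabilize()], or its
#'   `euler_history` tibble.
#' @return A ggplot object.
#' @export
plot_stabilization <- function(stab) {
  history <- if (inherits(stab, "stabilization")) stab$euler_history else stab
  long <- tidyr::pivot_longer(history, c("yaw", "pitch", "roll"),
                              names_to = "angle", values_to = "degrees")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$degrees,
                                     colour = .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "angle (deg)",
                  title = "Fusion stabilization") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
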