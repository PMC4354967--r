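#' Ground footprint of the rig-mounted canopy sensor
#'
#' Computes the strip of ground scanned on each side of the vehicle by the
#' oblique-viewing spectrometer lenses, and the fraction of the total sensed
#' span the scanned strips cover. The inner and outer edges of the strip are
#' linear in mount height:
#' \deqn{X_1 = 0.5\,d + 1.13\,h, \qquad X_2 = 0.5\,d + 1.94\,h,}
#' measured laterally from the vehicle centreline, where \eqn{d} is the
#' length of the sensor rig and \eqn{h} the mounting height. The scanned
#' strip width is \eqn{y = X_2 - X_1 = 0.81\,h} per side, and coverage is
#' the total scanned width \eqn{2y} over the total sensed span \eqn{2 X_2}.
#'
#' @param rig_length rig length \eqn{d} in metres; must be positive.
#'   Default 2.0 m.
#' @param mount_height mounting height \eqn{h} in metres; must be
#'   non-negative. Default 1.6 m.
#' @return An object of class `"nsens_footprint"`: a list with elements
#'   `x1_inner`, `x2_outer`, `strip_width_y`, `scanned_width_total`,
#'   `span_total` (all metres), `coverage_fraction` in `[0, 1]` and
#'   `coverage_percent` (rounded to the nearest integer percent), plus the
#'   input configuration.
#' @export
#' @examples
#' fp <- sensor_footprint(rig_length = 2.0, mount_height = 1.6)
#' fp$coverage_percent  # ~32
sensor_footprint <- function(rig_length = 2.0, mount_height = 1.6) {
  .check_scalar_number(rig_length, "rig_length", lower = 0, strict_lower = TRUE)
  .check_scalar_number(mount_height, "mount_height", lower = 0)

  x1 <- 0.5 * rig_length + 1.13 * mount_height
  x2 <- 0.5 * rig_length + 1.94 * mount_height
  y <- x2 - x1
  scanned <- 2 * y
  span <- 2 * x2
  coverage <- scanned / span

  structure(list(
    rig_length = rig_length,
    mount_height = mount_height,
    x1_inner = x1,
    x2_outer = x2,
    strip_width_y = y,
    scanned_width_total = scanned,
    span_total = span,
    coverage_fraction = coverage,
    coverage_percent = round(100 * coverage)
  ), class = "nsens_footprint")
}

#' @export
print.nsens_footprint <- function(x, ...) {
  cat("Sensor footprint geometry\n")
  cat(sprintf("  rig length d     : %.3f m\n", x$rig_length))
  cat(sprintf("  mount height h   : %.3f m\n", x$mount_height))
  cat(sprintf("  inner edge X1    : %.3f m\n", x$x1_inner))
  cat(sprintf("  outer edge X2    : %.3f m\n", x$x2_outer))
  cat(sprintf("  strip width y    : %.3f m (per side)\n", x$strip_width_y))
  cat(sprintf("  scanned width    : %.3f m (both sides)\n", x$scanned_width_total))
  cat(sprintf("  total span       : %.3f m (both sides)\n", x$span_total))
  cat(sprintf("  coverage         : %.1f%% (~%d%%)\n",
              100 * x$coverage_fraction, x$coverage_percent))
  invisible(x)
}

#' @export
as.data.frame.nsens_footprint <- function(x, ...) {
  data.frame(
    rig_length = x$rig_length, mount_height = x$mount_height,
    x1_inner = x$x1_inner, x2_outer = x$x2_outer,
    strip_width_y = x$strip_width_y,
    scanned_width_total = x$scanned_width_total,
    span_total = x$span_total,
    coverage_fraction = x$coverage_fraction,
    coverage_percent = x$coverage_percent
  )
}
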