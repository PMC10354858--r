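#' Two-plane cylindrical diode detector geometry
#'
#' Builds a Delta4-like detector: two planes through the isocenter, both
#' containing the couch (gantry rotation) axis and inclined from the vertical
#' by `plane_angles` degrees in opposite senses. Diodes sit on a square
#' in-plane lattice with a fine pitch in the central region and a coarse pitch
#' outside it, clipped to the phantom cross-section.
#'
#' Coordinates are right-handed, mm, isocenter at the origin: x lateral,
#' y longitudinal (couch axis), z vertical. In-plane coordinates are
#' `(a, b)` with `a` along the transverse in-plane axis and `b` along y; the
#' 3D position of an in-plane point is `a * e_t + b * e_l`.
#'
#' @param plane_angles angles of the two planes from the vertical, degrees;
#'   the first plane is tilted clockwise, the second counterclockwise.
#' @param pitch_central diode pitch in the central region, mm.
#' @param pitch_peripheral diode pitch outside the central region, mm.
#' @param central_halfwidth half-width of the fine-pitch central square, mm.
#' @param extent half-width of the full diode lattice, mm.
#' @param phantom_radius cylinder radius, mm; all diodes must fall inside the
#'   phantom cross-section.
#' @return An object of class `detector_geometry`: plane angles, per-plane
#'   in-plane axes (`e_t`, `e_l`), in-plane diode coordinates (`inplane`),
#'   3D phantom-frame positions (`pos3d`) and per-diode pitch class.
#' @examples
#' geo <- make_detector_geometry()
#' geo$plane_angles
#' nrow(geo$planes[[1]]$inplane)
#' @export
make_detector_geometry <- function(plane_angles = c(50, 40),
                                   pitch_central = 5,
                                   pitch_peripheral = 10,
                                   central_halfwidth = 30,
                                   extent = 100,
                                   phantom_radius = 110) {
  if (length(plane_angles) != 2L)
    stop("exactly two detector planes are required")
  if (pitch_central <= 0 || pitch_peripheral <= 0)
    stop("diode pitch must be positive")
  if (extent <= 0) stop("lattice extent must be positive")
  if (phantom_radius <= 0) stop("phantom radius must be positive")
  if (extent > phantom_radius)
    stop("lattice extent exceeds the phantom radius: diodes would fall outside the phantom")
  if (central_halfwidth < 0 || central_halfwidth > extent)
    stop("central_halfwidth must lie in [0, extent]")

  signs <- c(1, -1)  # clockwise, counterclockwise tilt
  planes <- vector("list", 2L)
  for (k in 1:2) {
    ang <- plane_angles[k] * pi / 180
    e_t <- c(signs[k] * sin(ang), 0, cos(ang))  # transverse in-plane axis
    e_l <- c(0, 1, 0)                           # longitudinal (couch) axis
    coarse <- seq(-extent, extent, by = pitch_peripheral)
    fine <- seq(-central_halfwidth, central_halfwidth, by = pitch_central)
    grid_c <- expand.grid(a = coarse, b = coarse)
    grid_f <- expand.grid(a = fine, b = fine)
    inplane <- unique(rbind(grid_c, grid_f))
    inplane <- inplane[order(inplane$b, inplane$a), , drop = FALSE]
    rownames(inplane) <- NULL
    pitch_class <- ifelse(
      abs(inplane$a) <= central_halfwidth & abs(inplane$b) <= central_halfwidth,
      pitch_central, pitch_peripheral)
    pos3d <- cbind(inplane$a * e_t[1] + inplane$b * e_l[1],
                   inplane$a * e_t[2] + inplane$b * e_l[2],
                   inplane$a * e_t[3] + inplane$b * e_l[3])
    colnames(pos3d) <- c("x", "y", "z")
    planes[[k]] <- list(plane_id = k, angle = plane_angles[k],
                        e_t = e_t, e_l = e_l,
                        inplane = as.matrix(inplane), pos3d = pos3d,
                        pitch_class = pitch_class)
  }
  structure(list(plane_angles = plane_angles,
                 pitch_central = pitch_central,
                 pitch_peripheral = pitch_peripheral,
                 central_halfwidth = central_halfwidth,
                 extent = extent,
                 phantom_radius = phantom_radius,
                 planes = planes),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("Two-plane cylindrical diode geometry\n")
  cat(sprintf("  planes: %g and %g deg from vertical (cw/ccw)\n",
              x$plane_angles[1], x$plane_angles[2]))
  cat(sprintf("  diodes per plane: %d (pitch %g mm central / %g mm peripheral)\n",
              nrow(x$planes[[1]]$inplane), x$pitch_central, x$pitch_peripheral))
  cat(sprintf("  phantom radius: %g mm\n", x$phantom_radius))
  invisible(x)
}
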