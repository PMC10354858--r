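#' Compute the 3D dose grid and planar diode doses for a plan
#'
#' A deliberately simplified arc-dose engine that preserves the geometric and
#' scaling structure each delivery error perturbs: per control point, a
#' beam's-eye-view fluence is formed from the leaf openings (algebraic-sigmoid
#' penumbra of width `sigma_x` along leaf travel, soft leaf-row weighting of
#' width `sigma_y` along the couch axis, leaf transmission `transmission`),
#' attenuated exponentially with depth from the phantom surface toward the
#' source, and accumulated with the control point's MU weight. Dose is linear
#' in the MU weights by construction. Planar doses are the grid field sampled
#' at the diode 3D positions by trilinear interpolation.
#'
#' @param plan a [sample_plan()] object.
#' @param geometry a [make_detector_geometry()] object.
#' @param spacing isotropic grid spacing, mm.
#' @param half_extent grid half-extent per axis `(x, y, z)`, mm; must cover
#'   the diode positions.
#' @param sigma_x penumbra width along leaf travel, mm.
#' @param sigma_y softening width across leaf rows, mm.
#' @param transmission leaf transmission fraction.
#' @param mu_atten linear attenuation coefficient, 1/mm.
#' @return list with `grid` (a `dose_grid`: `values` array, `spacing`,
#'   `origin`) and `planar` (list of two per-diode dose vectors).
#' @examples
#' geo <- make_detector_geometry()
#' d <- compute_dose(sample_plan(1, n_cp = 4), geo)
#' range(d$grid$values)
#' @export
compute_dose <- function(plan, geometry, spacing = 2.5,
                         half_extent = c(80, 100, 80),
                         sigma_x = 2.5, sigma_y = 2, transmission = 0.02,
                         mu_atten = 0.005) {
  stopifnot(inherits(plan, "vmat_plan"), inherits(geometry, "detector_geometry"))
  if (length(plan$gantry) == 0L) stop("plan has no control points")
  if (spacing <= 0) stop("grid spacing must be positive")
  xs <- seq(-half_extent[1], half_extent[1], by = spacing)
  ys <- seq(-half_extent[2], half_extent[2], by = spacing)
  zs <- seq(-half_extent[3], half_extent[3], by = spacing)
  vals <- cpp_accumulate_dose(xs, ys, zs, plan$gantry, plan$mu_weight,
                              plan$leaf_a, plan$leaf_b, plan$row_edges,
                              sigma_x, sigma_y, transmission, mu_atten,
                              geometry$phantom_radius)
  grid <- structure(list(values = array(vals, c(length(xs), length(ys), length(zs))),
                         spacing = rep(spacing, 3),
                         origin = c(xs[1], ys[1], zs[1])),
                    class = "dose_grid")
  list(grid = grid, planar = sample_planar(grid, geometry))
}

#' Sample a dose grid at the diode positions of both detector planes
#'
#' @param grid a `dose_grid`.
#' @param geometry a [make_detector_geometry()] object.
#' @return list of two numeric vectors, one value per diode of each plane.
#' @export
sample_planar <- function(grid, geometry) {
  lapply(geometry$planes, function(pl)
    cpp_trilinear(as.numeric(grid$values), dim(grid$values),
                  grid$origin, grid$spacing, pl$pos3d))
}

#' Sample a dose grid on a fine regular in-plane lattice of a detector plane
#'
#' Used to build an interpolable calculated distribution for gamma analysis.
#'
#' @param grid a `dose_grid`.
#' @param geometry detector geometry.
#' @param plane plane index (1 or 2).
#' @param step lattice step, mm.
#' @param half_extent lattice half-extent, mm.
#' @return list with `values` (matrix indexed by transverse `a`, then
#'   longitudinal `b`), `origin` (in-plane), `step`.
#' @export
sample_plane_grid <- function(grid, geometry, plane, step = 2.5,
                              half_extent = 70) {
  pl <- geometry$planes[[plane]]
  av <- seq(-half_extent, half_extent, by = step)
  bv <- av
  gr <- expand.grid(a = av, b = bv)
  pts <- cbind(gr$a * pl$e_t[1] + gr$b * pl$e_l[1],
               gr$a * pl$e_t[2] + gr$b * pl$e_l[2],
               gr$a * pl$e_t[3] + gr$b * pl$e_l[3])
  v <- cpp_trilinear(as.numeric(grid$values), dim(grid$values), grid$origin,
                     grid$spacing, pts)
  list(values = matrix(v, length(av), length(bv)),
       origin = c(av[1], bv[1]), step = step)
}

grid_resample_affine <- function(grid, rot = diag(3), shift = c(0, 0, 0)) {
  vals <- cpp_affine_resample(as.numeric(grid$values), dim(grid$values),
                              grid$origin, grid$spacing, rot, shift)
  grid$values <- array(vals, dim(grid$values))
  grid
}

rotation_about_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th),
           0, 1, 0,
           -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
}
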