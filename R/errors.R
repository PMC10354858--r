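#' Specify a delivery error to inject
#'
#' The nine simulated error types plus the identity: systematic MLC offset
#' (2 mm, all leaves, single direction), random per-leaf MLC offsets
#' (Gaussian, 2 mm 1 sigma), gantry rotation (+/- 2 deg), radiation output
#' (+/- 3%) and 1-mm phantom setup shifts along each axis.
#'
#' @param kind one of `"none"`, `"mlc_systematic"`, `"mlc_random"`,
#'   `"gantry_cw"`, `"gantry_ccw"`, `"output_plus"`, `"output_minus"`,
#'   `"setup_lat"`, `"setup_lng"`, `"setup_vrt"`.
#' @param magnitude error size: mm for MLC and setup errors, degrees for
#'   gantry errors, a fraction for output errors. Defaults follow the kind.
#' @param seed seed for the per-leaf draw (`mlc_random` only).
#' @return An `error_spec` object.
#' @export
error_spec <- function(kind = c("none", "mlc_systematic", "mlc_random",
                                "gantry_cw", "gantry_ccw", "output_plus",
                                "output_minus", "setup_lat", "setup_lng",
                                "setup_vrt"),
                       magnitude = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(magnitude)) {
    magnitude <- switch(kind,
      none = 0,
      mlc_systematic = 2, mlc_random = 2,
      gantry_cw = 2, gantry_ccw = 2,
      output_plus = 0.03, output_minus = 0.03,
      setup_lat = 1, setup_lng = 1, setup_vrt = 1)
  }
  if (kind == "mlc_random" && is.null(seed))
    stop("mlc_random requires a seed for the per-leaf draw")
  structure(list(kind = kind, magnitude = magnitude, seed = seed),
            class = "error_spec")
}

#' Names of the nine simulated error kinds
#' @return character vector of error kinds (excluding `"none"`).
#' @export
error_kinds <- function() {
  c("mlc_systematic", "mlc_random", "gantry_cw", "gantry_ccw",
    "output_plus", "output_minus", "setup_lat", "setup_lng", "setup_vrt")
}

#' Inject a delivery error into a plan/dose pair
#'
#' MLC errors modify the plan's leaf positions and recompute the dose (as a
#' treatment planning system would). Gantry errors rotate the error-free dose
#' field about the gantry rotation axis through the isocenter and resample;
#' output errors rescale the dose; setup errors resample after a rigid
#' translation along the named axis. `kind = "none"` is the identity.
#'
#' @param plan a `vmat_plan`.
#' @param dose the result of [compute_dose()] for that plan (list with `grid`
#'   and `planar`).
#' @param spec an [error_spec()].
#' @param geometry detector geometry (needed to recompute or resample doses).
#' @param ... further arguments passed to [compute_dose()] for the MLC
#'   recomputation (must match those used for `dose`).
#' @return list with the (possibly modified) `plan` and the perturbed `dose`.
#' @export
inject_error <- function(plan, dose, spec, geometry, ...) {
  stopifnot(inherits(spec, "error_spec"))
  kind <- spec$kind
  mag <- spec$magnitude
  if (kind == "none") return(list(plan = plan, dose = dose))

  if (kind %in% c("mlc_systematic", "mlc_random")) {
    plan2 <- plan
    if (kind == "mlc_systematic") {
      # both banks shifted the same in-plane direction: aperture translation
      plan2$leaf_a <- plan$leaf_a + mag
      plan2$leaf_b <- plan$leaf_b + mag
    } else {
      n_rows <- ncol(plan$leaf_a)
      off <- with_seed(spec$seed, list(a = rnorm(n_rows, 0, mag),
                                       b = rnorm(n_rows, 0, mag)))
      # one offset per leaf, constant over the arc
      plan2$leaf_a <- sweep(plan$leaf_a, 2, off$a, `+`)
      plan2$leaf_b <- sweep(plan$leaf_b, 2, off$b, `+`)
      bad <- plan2$leaf_a > plan2$leaf_b
      if (any(bad)) {
        m <- (plan2$leaf_a[bad] + plan2$leaf_b[bad]) / 2
        plan2$leaf_a[bad] <- m
        plan2$leaf_b[bad] <- m
      }
    }
    return(list(plan = plan2, dose = compute_dose(plan2, geometry, ...)))
  }

  grid2 <- switch(kind,
    gantry_cw = grid_resample_affine(dose$grid, rot = rotation_about_y(-mag)),
    gantry_ccw = grid_resample_affine(dose$grid, rot = rotation_about_y(mag)),
    output_plus = { g <- dose$grid; g$values <- g$values * (1 + mag); g },
    output_minus = { g <- dose$grid; g$values <- g$values * (1 - mag); g },
    setup_lat = grid_resample_affine(dose$grid, shift = c(mag, 0, 0)),
    setup_lng = grid_resample_affine(dose$grid, shift = c(0, mag, 0)),
    setup_vrt = grid_resample_affine(dose$grid, shift = c(0, 0, mag)),
    stop("unknown error kind: ", kind))
  list(plan = plan, dose = list(grid = grid2,
                                planar = sample_planar(grid2, geometry)))
}
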