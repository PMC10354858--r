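#' Gamma-analysis criteria
#'
#' Global dose-difference / distance-to-agreement criteria with a low-dose
#' cutoff. The dose-difference tolerance is a percentage of a single global
#' normalization dose (by default the maximum of the evaluated calculated
#' distribution).
#'
#' @param dd_percent dose-difference criterion, percent (global).
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param low_dose_cutoff fraction of the maximum reference dose below which
#'   diodes are excluded from the pass rate.
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dd_percent = 3, dta_mm = 2, low_dose_cutoff = 0.1) {
  stopifnot(dd_percent > 0, dta_mm > 0,
            low_dose_cutoff > 0, low_dose_cutoff < 1)
  structure(list(dd_percent = dd_percent, dta_mm = dta_mm,
                 low_dose_cutoff = low_dose_cutoff),
            class = "gamma_criteria")
}

#' Gamma index of measured points against a calculated plane
#'
#' For each reference (measured) point, the gamma index is the minimum over
#' in-plane offsets `r` (search lattice step `dta/step_div`, radius
#' `radius_factor * dta`, early-stopped once the distance term alone exceeds
#' the current minimum) of
#' `sqrt((dose_diff(r) / (dd% * D_norm))^2 + (|r| / dta)^2)`,
#' with the evaluated distribution interpolated bilinearly.
#'
#' @param ref_points `n x 2` in-plane positions of the reference points, mm.
#' @param ref_dose reference (measured) dose per point.
#' @param eval_dist evaluated (calculated) distribution: list with `values`
#'   (matrix), `origin` (in-plane coords of `values[1,1]`) and `step` (mm),
#'   as produced by [sample_plane_grid()].
#' @param criteria a [gamma_criteria()].
#' @param norm_dose global normalization dose; default `max(eval_dist$values)`.
#' @param radius_factor,step_div search-lattice extent and resolution.
#' @return numeric vector of per-point gamma values.
#' @export
gamma_index <- function(ref_points, ref_dose, eval_dist,
                        criteria = gamma_criteria(), norm_dose = NULL,
                        radius_factor = 3, step_div = 10) {
  ref_points <- as.matrix(ref_points)
  if (nrow(ref_points) == 0L || length(ref_dose) == 0L)
    stop("empty reference input")
  if (nrow(ref_points) != length(ref_dose))
    stop("ref_points and ref_dose lengths differ")
  if (is.null(norm_dose)) norm_dose <- max(eval_dist$values)
  if (norm_dose <= 0) stop("normalization dose must be positive")
  dd_abs <- criteria$dd_percent / 100 * norm_dose
  cpp_gamma_plane(ref_points, ref_dose, as.numeric(eval_dist$values),
                  nrow(eval_dist$values), ncol(eval_dist$values),
                  eval_dist$origin[1], eval_dist$origin[2], eval_dist$step,
                  dd_abs, criteria$dta_mm, radius_factor, step_div)
}

#' Gamma pass rate with low-dose exclusion
#'
#' Diodes whose reference dose is below `low_dose_cutoff` of the maximum
#' reference dose are excluded; the pass rate is the percentage of remaining
#' diodes with gamma <= 1. To pool the two detector planes, concatenate
#' their gammas and reference doses.
#'
#' @param gammas per-diode gamma values.
#' @param ref_dose per-diode reference doses (same order).
#' @param criteria a [gamma_criteria()].
#' @param max_dose dose defining the cutoff level; defaults to
#'   `max(ref_dose)`.
#' @return list with `pass_rate` (percent) and `n_evaluated`.
#' @export
gamma_pass_rate <- function(gammas, ref_dose, criteria = gamma_criteria(),
                            max_dose = max(ref_dose)) {
  if (length(gammas) != length(ref_dose))
    stop("gammas and ref_dose lengths differ")
  keep <- ref_dose >= criteria$low_dose_cutoff * max_dose
  if (!any(keep)) stop("all points fall below the low-dose cutoff")
  list(pass_rate = 100 * mean(gammas[keep] <= 1),
       n_evaluated = sum(keep))
}

#' Classify a case by its gamma pass rate
#'
#' Above the threshold is "error-free"; at or below it is "any-error".
#'
#' @param pass_rate percent in `[0, 100]`.
#' @param threshold decision threshold, percent.
#' @return character vector of labels.
#' @export
classify_gamma <- function(pass_rate, threshold) {
  ifelse(pass_rate > threshold, "error-free", "any-error")
}

#' Gamma pass rate of one beam case (both planes pooled)
#'
#' Reference = corrected measured diode doses; evaluated = the case's
#' calculated distribution on the stored fine in-plane grids.
#'
#' @param dataset a [generate_dataset()] result with stored plane grids.
#' @param beam one element of `dataset$beams`.
#' @param kind condition name.
#' @param criteria a [gamma_criteria()].
#' @return list with `pass_rate`, `n_evaluated`, per-plane `gammas`.
#' @export
gamma_case <- function(dataset, beam, kind, criteria = gamma_criteria()) {
  cond <- beam$conditions[[kind]]
  if (is.null(cond$plane_grids))
    stop("no stored plane grids for beam ", beam$beam_id,
         " (generate the dataset with keep_plane_grids covering its split)")
  meas <- apply_daily_correction(beam$measured)
  norm_dose <- max(vapply(cond$plane_grids, function(g) max(g$values), 0))
  gammas <- lapply(1:2, function(k)
    gamma_index(dataset$geometry$planes[[k]]$inplane[, c("a", "b")],
                meas[[k]], cond$plane_grids[[k]], criteria,
                norm_dose = norm_dose))
  pr <- gamma_pass_rate(unlist(gammas), unlist(meas), criteria)
  c(pr, list(gammas = gammas))
}

#' Gamma pass rates for all test cases
#'
#' @param dataset a [generate_dataset()] result.
#' @param criteria a [gamma_criteria()].
#' @param verbose print progress.
#' @return data frame: `beam_id`, `error_kind`, `dd`, `dta`, `n_evaluated`,
#'   `pass_rate`.
#' @export
gamma_score_cases <- function(dataset, criteria = gamma_criteria(),
                              verbose = FALSE) {
  splits <- vapply(dataset$beams, `[[`, "", "split")
  rows <- list()
  for (beam in dataset$beams[splits == "test"]) {
    for (kind in names(beam$conditions)) {
      g <- gamma_case(dataset, beam, kind, criteria)
      rows[[length(rows) + 1L]] <- data.frame(
        beam_id = beam$beam_id, error_kind = kind,
        dd = criteria$dd_percent, dta = criteria$dta_mm,
        n_evaluated = g$n_evaluated, pass_rate = g$pass_rate,
        stringsAsFactors = FALSE)
    }
    if (verbose) message("gamma: beam ", beam$beam_id, " done")
  }
  do.call(rbind, rows)
}

#' Optimize the phantom position against the calculated dose
#'
#' Emulates the measurement-preprocessing step that corrects residual phantom
#' setup error: searches 3D translations of the diode array (coarse grid
#' `±search_mm` at `coarse_step`, then local refinement at `refine_step`)
#' for the best agreement with the calculated 3D dose. The coarse stage
#' maximizes the 3%/1 mm gamma pass rate; because that objective plateaus
#' once every diode is within the DTA tolerance, ties (and the refinement
#' stage) are resolved by the mean absolute dose difference at the shifted
#' positions, which has a sharp minimum at exact alignment.
#'
#' @param measured_pair list of two per-plane measured dose vectors.
#' @param grid calculated `dose_grid`.
#' @param geometry detector geometry.
#' @param criteria gamma criteria for the coarse objective (default 3%/1 mm).
#' @param search_mm coarse half-range, mm.
#' @param coarse_step,refine_step grid steps, mm.
#' @return list with `shift` (the translation applied to the diode positions),
#'   `pass_rate` at the optimum, and `positions` (shifted per-plane 3D diode
#'   positions for resampling the calculated dose).
#' @export
optimize_phantom_position <- function(measured_pair, grid, geometry,
                                      criteria = gamma_criteria(dd_percent = 3,
                                                                dta_mm = 1),
                                      search_mm = 3, coarse_step = 0.5,
                                      refine_step = 0.1) {
  vals <- as.numeric(grid$values)
  dims <- dim(grid$values)
  norm_dose <- max(vals)
  dd_abs <- criteria$dd_percent / 100 * norm_dose
  planes <- lapply(1:2, function(k) {
    pl <- geometry$planes[[k]]
    keep <- measured_pair[[k]] >=
      criteria$low_dose_cutoff * max(unlist(measured_pair))
    list(pts = pl$pos3d[keep, , drop = FALSE],
         meas = measured_pair[[k]][keep],
         e1 = pl$e_t, e2 = pl$e_l)
  })
  n_tot <- sum(vapply(planes, function(p) length(p$meas), 0L))
  if (n_tot == 0L) stop("all diodes fall below the low-dose cutoff")

  sweep_shifts <- function(shifts) {
    acc <- matrix(0, nrow(shifts), 2)
    for (p in planes)
      acc <- acc + cpp_shift_objective(vals, dims, grid$origin, grid$spacing,
                                       p$pts, p$meas, p$e1, p$e2, dd_abs,
                                       criteria$dta_mm, shifts)
    acc
  }
  ax <- seq(-search_mm, search_mm, by = coarse_step)
  if (length(ax) == 0L) ax <- 0
  coarse <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  obj <- sweep_shifts(coarse)
  best_pass <- max(obj[, 1])
  cand <- which(obj[, 1] == best_pass)
  cand <- cand[order(obj[cand, 2],
                     rowSums(coarse[cand, , drop = FALSE]^2))]
  s0 <- coarse[cand[1], ]

  # local refinement: minimize mean |dose difference| around the coarse best
  if (refine_step > 0 && search_mm > 0) {
    rx <- seq(-coarse_step, coarse_step, by = refine_step)
    fine <- sweep(as.matrix(expand.grid(x = rx, y = rx, z = rx)), 2, -s0)
    dd <- numeric(nrow(fine))
    for (p in planes)
      dd <- dd + length(p$meas) / n_tot *
        cpp_shift_dd(vals, dims, grid$origin, grid$spacing, p$pts, p$meas,
                     fine)
    ties <- which(dd == min(dd))
    ties <- ties[order(rowSums(fine[ties, , drop = FALSE]^2))]
    s0 <- fine[ties[1], ]
  }
  final <- sweep_shifts(matrix(s0, 1))
  list(shift = unname(s0),
       pass_rate = 100 * final[1, 1] / n_tot,
       positions = lapply(geometry$planes, function(pl)
         sweep(pl$pos3d, 2, -s0, `+`)))
}
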