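#' Generate a full synthetic QA dataset
#'
#' Emulates the study protocol: `n_beams` synthetic arcs are split into
#' training / validation / test sets; every beam gets an error-free
#' calculated dose, a noisy error-free measurement, and one perturbed
#' calculated dose per error kind (10 dose conditions per beam in total with
#' the default suite). Only the error-free conditions of train/validation
#' beams feed the VAE; the supervised CNN additionally consumes the error
#' conditions of all splits; gamma analysis uses the test conditions.
#'
#' @param n_beams total number of beams.
#' @param split named or positional vector `(train, validation, test)`;
#'   must not exceed `n_beams`.
#' @param seed master seed; the entire dataset regenerates bit-identically
#'   from `(arguments, seed)`.
#' @param geometry detector geometry.
#' @param noise measurement [noise_config()].
#' @param errors character vector of error kinds to simulate per beam.
#' @param keep_plane_grids splits for which fine in-plane calculated grids are
#'   stored per condition (needed later for gamma analysis).
#' @param plane_grid_step step of those grids, mm.
#' @param n_cp control points per plan.
#' @param ... further arguments to [compute_dose()].
#' @return A `qa_dataset`: `manifest` (one row per beam-condition),
#'   `beams` (per-beam plans, measurements and per-condition planar doses)
#'   and the generating configuration.
#' @examples
#' ds <- generate_dataset(n_beams = 3, split = c(1, 1, 1), seed = 1, n_cp = 4)
#' table(ds$manifest$split)
#' @export
generate_dataset <- function(n_beams = 161,
                             split = c(train = 100, validation = 25, test = 36),
                             seed = 1,
                             geometry = make_detector_geometry(),
                             noise = noise_config(),
                             errors = error_kinds(),
                             keep_plane_grids = "test",
                             plane_grid_step = 2.5,
                             n_cp = 20, ...) {
  if (length(split) != 3L) stop("split must have three entries")
  if (is.null(names(split)) || !all(nzchar(names(split))))
    names(split) <- c("train", "validation", "test")
  if (sum(split) > n_beams)
    stop(sprintf("split sizes (%d) exceed n_beams (%d)", sum(split), n_beams))

  split_labels <- with_seed(seed, {
    lab <- rep(NA_character_, n_beams)
    ord <- sample.int(n_beams)
    lab[ord[seq_len(split[["train"]])]] <- "train"
    lab[ord[split[["train"]] + seq_len(split[["validation"]])]] <- "validation"
    lab[ord[split[["train"]] + split[["validation"]] +
              seq_len(split[["test"]])]] <- "test"
    lab
  })
  seeds <- matrix(derive_seeds(seed, 3L * n_beams), ncol = 3L)
  colnames(seeds) <- c("plan", "meas", "mlc_random")

  beams <- vector("list", n_beams)
  manifest <- vector("list", n_beams)
  for (b in seq_len(n_beams)) {
    sp <- split_labels[b]
    if (is.na(sp)) next
    plan <- sample_plan(seeds[b, "plan"], n_cp = n_cp)
    dose0 <- compute_dose(plan, geometry, ...)
    measured <- simulate_measurement(dose0$planar, geometry, noise,
                                     seed = seeds[b, "meas"])
    keep_grids <- sp %in% keep_plane_grids
    conds <- list()
    kinds <- c("none", errors)
    for (kind in kinds) {
      spec <- error_spec(kind, seed = if (kind == "mlc_random")
        seeds[b, "mlc_random"] else NULL)
      pert <- inject_error(plan, dose0, spec, geometry, ...)
      cond <- list(planar = pert$dose$planar)
      if (keep_grids)
        cond$plane_grids <- lapply(1:2, function(k)
          sample_plane_grid(pert$dose$grid, geometry, k,
                            step = plane_grid_step))
      conds[[kind]] <- cond
    }
    beams[[b]] <- list(beam_id = b, split = sp,
                       plan_seed = seeds[b, "plan"],
                       meas_seed = seeds[b, "meas"],
                       measured = measured, conditions = conds)
    manifest[[b]] <- data.frame(beam_id = b, split = sp, error_kind = kinds,
                                plan_seed = unname(seeds[b, "plan"]),
                                meas_seed = unname(seeds[b, "meas"]),
                                stringsAsFactors = FALSE)
  }
  used <- !vapply(beams, is.null, logical(1))
  structure(list(manifest = do.call(rbind, manifest[used]),
                 beams = beams[used],
                 geometry = geometry, noise = noise, seed = seed,
                 split = split, errors = errors, n_cp = n_cp),
            class = "qa_dataset")
}

#' @export
print.qa_dataset <- function(x, ...) {
  cat(sprintf("Synthetic QA dataset: %d beams (%s), %d error kinds, seed %d\n",
              length(x$beams),
              paste(sprintf("%s=%d", names(x$split), x$split), collapse = ", "),
              length(x$errors), x$seed))
  invisible(x)
}

#' Write a dataset manifest to JSON
#' @param dataset a `qa_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  jsonlite::write_json(list(seed = dataset$seed,
                            split = as.list(dataset$split),
                            errors = dataset$errors,
                            manifest = dataset$manifest),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
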