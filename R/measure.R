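#' Measurement noise model configuration
#'
#' Error-free "measured" doses are the true planar dose times a daily output
#' factor times `(1 + correlated field + iid diode noise)`. The correlated
#' component emulates slowly varying delivery/modeling residuals; the iid
#' component emulates per-diode reading noise; the daily factor emulates
#' day-to-day machine output and is recorded so it can be corrected away, as
#' the daily 10 x 10 cm output calibration does for the real device.
#'
#' @param sd_diode per-diode relative noise sd.
#' @param sd_field relative sd of the spatially correlated field.
#' @param corr_length correlation length of the field, mm.
#' @param sd_daily sd of the daily output factor around 1.
#' @return A `noise_config` object.
#' @export
noise_config <- function(sd_diode = 0.007, sd_field = 0.005,
                         corr_length = 20, sd_daily = 0.003) {
  if (sd_diode < 0 || sd_field < 0 || sd_daily < 0)
    stop("noise standard deviations must be non-negative")
  if (corr_length <= 0) stop("correlation length must be positive")
  structure(list(sd_diode = sd_diode, sd_field = sd_field,
                 corr_length = corr_length, sd_daily = sd_daily),
            class = "noise_config")
}

# Gaussian random field on a plane with unit marginal sd: kernel-weighted sum
# of iid node weights on a lattice of spacing = corr_length, normalized
# pointwise.
correlated_field <- function(inplane, corr_length, extent) {
  nodes <- expand.grid(a = seq(-extent, extent, by = corr_length),
                       b = seq(-extent, extent, by = corr_length))
  w <- rnorm(nrow(nodes))
  da <- outer(inplane[, "a"], nodes$a, `-`)
  db <- outer(inplane[, "b"], nodes$b, `-`)
  k <- exp(-(da^2 + db^2) / (2 * corr_length^2))
  as.numeric((k %*% w) / sqrt(rowSums(k^2)))
}

#' Simulate a noisy measurement of a planar dose pair
#'
#' @param planar_pair list of two per-plane diode dose vectors (the true,
#'   error-free delivered dose).
#' @param geometry detector geometry (for diode positions).
#' @param noise a [noise_config()].
#' @param seed reproducibility seed.
#' @return list with `planes` (the raw measured pair, daily factor included)
#'   and `daily_factor` (the stored calibration factor; dividing the raw
#'   measurement by it applies the daily output correction, leaving no
#'   residual bias in expectation).
#' @examples
#' geo <- make_detector_geometry()
#' d <- compute_dose(sample_plan(1, n_cp = 4), geo)
#' m <- simulate_measurement(d$planar, geo, noise_config(), seed = 7)
#' @export
simulate_measurement <- function(planar_pair, geometry,
                                 noise = noise_config(), seed) {
  stopifnot(inherits(noise, "noise_config"))
  if (missing(seed)) stop("a seed is required")
  with_seed(seed, {
    f <- 1 + rnorm(1, 0, noise$sd_daily)
    planes <- lapply(1:2, function(k) {
      true <- planar_pair[[k]]
      corr <- if (noise$sd_field > 0)
        noise$sd_field * correlated_field(geometry$planes[[k]]$inplane,
                                          noise$corr_length, geometry$extent)
      else 0
      iid <- if (noise$sd_diode > 0) rnorm(length(true), 0, noise$sd_diode) else 0
      true * f * (1 + corr + iid)
    })
    list(planes = planes, daily_factor = f)
  })
}

#' Apply the stored daily output correction to a measurement
#' @param measurement result of [simulate_measurement()].
#' @return list of two corrected per-plane dose vectors.
#' @export
apply_daily_correction <- function(measurement) {
  lapply(measurement$planes, function(p) p / measurement$daily_factor)
}
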