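# Aliases for internal machinery exercised by the tests.
layer_conv2d <- vmatqa:::layer_conv2d
layer_conv2d_transpose <- vmatqa:::layer_conv2d_transpose
layer_batchnorm <- vmatqa:::layer_batchnorm
layer_relu <- vmatqa:::layer_relu
layer_maxpool2 <- vmatqa:::layer_maxpool2
layer_flatten <- vmatqa:::layer_flatten
layer_reshape <- vmatqa:::layer_reshape
layer_dense <- vmatqa:::layer_dense
layer_dropout <- vmatqa:::layer_dropout
net_forward <- vmatqa:::net_forward
net_backward <- vmatqa:::net_backward

# Fixtures shared across test files, built once on first use.
.fixtures <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A small but complete dataset: 3 train / 2 validation / 3 test beams,
# all 9 error kinds, plane grids kept for the test split.
tiny_dataset <- function() {
  fixture("tiny_dataset", function()
    generate_dataset(n_beams = 8, split = c(3, 2, 3), seed = 202,
                     n_cp = 12))
}

# A single beam's dose and corrected measurement.
tiny_beam <- function() {
  fixture("tiny_beam", function() {
    geo <- make_detector_geometry()
    plan <- sample_plan(77, n_cp = 12)
    dose <- compute_dose(plan, geo)
    meas <- simulate_measurement(dose$planar, geo, noise_config(), seed = 78)
    list(geo = geo, plan = plan, dose = dose, meas = meas)
  })
}

# Synthetic error-free-like maps (correlated blob + noise at the ~1% scale).
synthetic_maps <- function(n, seed = 9, size = 27) {
  with_seed <- vmatqa:::with_seed
  with_seed(seed, replicate(n, {
    m <- matrix(rnorm(size^2, sd = 0.004), size, size)
    b <- outer(dnorm(seq_len(size), runif(1, 5, size - 5), 4),
               dnorm(seq_len(size), runif(1, 5, size - 5), 4))
    m + b / max(b) * rnorm(1, 0, 0.006)
  }, simplify = FALSE))
}
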