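test_that("the reference model reproduces hand-computed mean and covariance", {
  v <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  ref <- fit_reference(v, ridge = 0)
  expect_equal(ref$xbar, c(1, 1))
  expect_equal(ref$Sigma, diag(c(4 / 3, 4 / 3)), ignore_attr = TRUE)
  expect_equal(ref$n_ref, 4L)
})

test_that("degenerate references are rejected without a ridge", {
  same <- matrix(1, 5, 3)
  expect_error(fit_reference(same, ridge = 0), "singular|positive definite")
  expect_no_error(fit_reference(same, ridge = 1e-6))
  # fewer vectors than dimensions
  few <- matrix(rnorm(4 * 6), 4, 6)
  expect_error(fit_reference(few, ridge = 0), "singular")
  expect_error(fit_reference(matrix(0, 1, 2)), "at least two")
})

test_that("a tiny ridge perturbs distances negligibly on well-conditioned data", {
  set.seed(31)
  v <- matrix(rnorm(200 * 5), 200, 5)
  x <- rnorm(5)
  md0 <- mahalanobis_distance(x, fit_reference(v, ridge = 0))
  md1 <- mahalanobis_distance(x, fit_reference(v, ridge = 1e-8))
  expect_equal(md0, md1, tolerance = 1e-4)
})

test_that("Mahalanobis distance matches hand values and brute force", {
  ref <- fit_reference(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)), ridge = 0)
  expect_equal(mahalanobis_distance(c(1, 1), ref), 0)
  # diag(4, 1) covariance, x = (2, 1): sqrt(4/4 + 1/1) = sqrt(2)
  ref2 <- structure(list(xbar = c(0, 0), Sigma = diag(c(4, 1)),
                         Sigma_inv = diag(c(1 / 4, 1)), ridge = 0,
                         n_ref = 100L), class = "md_reference")
  expect_equal(mahalanobis_distance(c(2, 1), ref2), sqrt(2))
  # identity covariance reduces to Euclidean distance
  set.seed(32)
  vi <- matrix(rnorm(5000 * 3), 5000, 3)
  refi <- fit_reference(vi, ridge = 0)
  refi$Sigma_inv <- diag(3)
  refi$xbar <- c(0, 0, 0)
  x <- c(1, -2, 2)
  expect_equal(mahalanobis_distance(x, refi), sqrt(sum(x^2)))
  # brute-force oracle on random 30-D instances
  v30 <- matrix(rnorm(200 * 30), 200, 30)
  ref30 <- fit_reference(v30, ridge = 0)
  for (i in 1:5) {
    x30 <- rnorm(30)
    expect_equal(mahalanobis_distance(x30, ref30),
                 oracle_md(x30, ref30$xbar, ref30$Sigma), tolerance = 1e-8)
    # cross-check against the standard library implementation
    expect_equal(mahalanobis_distance(x30, ref30)^2,
                 unname(stats::mahalanobis(matrix(x30, 1), ref30$xbar,
                                           ref30$Sigma)),
                 tolerance = 1e-6)
  }
  expect_error(mahalanobis_distance(rnorm(4), ref30), "dimension")
})

test_that("Mahalanobis distance is invariant under invertible linear maps", {
  set.seed(33)
  v <- matrix(rnorm(300 * 4), 300, 4)
  x <- rnorm(4)
  A <- matrix(rnorm(16), 4, 4) + diag(4) * 2
  md1 <- mahalanobis_distance(x, fit_reference(v, ridge = 0))
  md2 <- mahalanobis_distance(as.numeric(A %*% x),
                              fit_reference(t(A %*% t(v)), ridge = 0))
  expect_equal(md1, md2, tolerance = 1e-8)
})

test_that("mean squared distance over a Gaussian reference approaches the dimension", {
  set.seed(34)
  d <- 6
  v <- matrix(rnorm(4000 * d), 4000, d)
  ref <- fit_reference(v, ridge = 0)
  msq <- mean(mahalanobis_distance(v, ref)^2)
  expect_equal(msq, d, tolerance = 0.05)
})

test_that("case scoring averages the two planes symmetrically", {
  maps <- synthetic_maps(40, seed = 41)
  model <- train_vae(maps, config = vae_config(epochs = 2, batch_size = 20,
                                               seed = 5))
  ref <- fit_reference(encode_maps(model, maps)$mu)
  case_ab <- list(beam_id = 1L, error_kind = "none",
                  maps = maps[1:2])
  case_ba <- list(beam_id = 1L, error_kind = "none",
                  maps = maps[2:1])
  s_ab <- score_case(model, ref, case_ab)
  s_ba <- score_case(model, ref, case_ba)
  expect_equal(s_ab$md_mean, s_ba$md_mean)
  expect_equal(s_ab$md_plane1, s_ba$md_plane2)
  # identical planes: the mean equals the per-plane distance
  s_same <- score_case(model, ref, list(beam_id = 2L, error_kind = "none",
                                        maps = list(maps[[3]], maps[[3]])))
  expect_equal(s_same$md_mean, s_same$md_plane1)
  expect_true(all(c(s_ab$md_plane1, s_ab$md_plane2) >= 0))
  expect_error(score_case(model, ref, list(beam_id = 3L, maps = maps[1])),
               "two plane maps")
})

test_that("classification assigns the boundary to the error-free class", {
  expect_equal(classify_md(0, 1), "error-free")
  expect_equal(classify_md(1, 1), "error-free")
  expect_equal(classify_md(1.0001, 1), "any-error")
  expect_equal(classify_md(0.01, 0), "any-error")
  expect_error(classify_md(1, -1), "non-negative")
})
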