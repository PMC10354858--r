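test_that("detector geometry satisfies its invariants and rejects bad configs", {
  geo <- make_detector_geometry()
  expect_equal(geo$plane_angles, c(50, 40))
  expect_length(geo$planes, 2L)
  for (pl in geo$planes) {
    # all diodes inside the phantom cross-section (cylinder axis = y)
    r <- sqrt(pl$pos3d[, "x"]^2 + pl$pos3d[, "z"]^2)
    expect_true(all(r <= geo$phantom_radius + 1e-9))
    # central region pitch 5 mm, peripheral 10 mm
    central <- abs(pl$inplane[, "a"]) <= 30 & abs(pl$inplane[, "b"]) <= 30
    expect_true(all(pl$pitch_class[central] == 5))
    expect_true(all(pl$pitch_class[!central] == 10))
    a_central <- sort(unique(pl$inplane[central, "a"]))
    expect_equal(min(diff(a_central)), 5)
  }
  expect_error(make_detector_geometry(extent = 0), "extent")
  expect_error(make_detector_geometry(pitch_central = -1), "pitch")
  expect_error(make_detector_geometry(extent = 200, phantom_radius = 110),
               "exceeds")
})

test_that("sampled plans are reproducible, seed-sensitive and physical", {
  p1 <- sample_plan(101)
  p2 <- sample_plan(101)
  p3 <- sample_plan(102)
  expect_identical(p1, p2)
  expect_true(any(p1$leaf_a != p3$leaf_a))
  for (s in c(101, 102, 555)) {
    p <- sample_plan(s)
    expect_true(all(p$leaf_a <= p$leaf_b))
    expect_true(all(p$gantry >= 0 & p$gantry < 360))
    expect_true(all(p$mu_weight > 0))
  }
})

test_that("dose engine is linear in MU and matches an independent evaluation", {
  tb <- tiny_beam()
  plan2 <- tb$plan
  plan2$mu_weight <- plan2$mu_weight * 2
  d2 <- compute_dose(plan2, tb$geo)
  expect_equal(d2$grid$values, tb$dose$grid$values * 2, tolerance = 1e-12)
  expect_equal(d2$planar[[1]], tb$dose$planar[[1]] * 2, tolerance = 1e-12)

  # independent loop evaluation of the same dose model at probe points
  pts <- rbind(c(0, 0, 0), c(10, 5, -10), c(-30, 20, 15), c(50, -40, 5))
  expected <- oracle_dose_at(tb$plan, pts)
  got <- vmatqa:::cpp_trilinear(as.numeric(tb$dose$grid$values),
                                dim(tb$dose$grid$values),
                                tb$dose$grid$origin, tb$dose$grid$spacing,
                                pts)
  expect_equal(got, expected, tolerance = 0.02)
})

test_that("closed apertures leak at most the transmission level", {
  geo <- tiny_beam()$geo
  plan <- sample_plan(5, n_cp = 6)
  plan$leaf_b <- plan$leaf_a  # close every leaf pair
  d <- compute_dose(plan, geo)
  open <- compute_dose(sample_plan(5, n_cp = 6), geo)
  expect_lt(max(d$grid$values), 0.05 * max(open$grid$values))
})

test_that("a single open control point peaks on the beam axis", {
  geo <- make_detector_geometry()
  plan <- sample_plan(1, n_cp = 1)
  plan$gantry <- 0  # beam along the vertical axis
  plan$mu_weight <- 1
  plan$leaf_a[] <- -30
  plan$leaf_b[] <- 30
  n_rows <- ncol(plan$leaf_a)
  centers <- (plan$row_edges[-1] + plan$row_edges[-(n_rows + 1)]) / 2
  closed <- abs(centers) > 30
  plan$leaf_a[, closed] <- 0
  plan$leaf_b[, closed] <- 0
  d <- compute_dose(plan, geo)
  peak <- which(d$grid$values == max(d$grid$values), arr.ind = TRUE)[1, ]
  xs <- seq(d$grid$origin[1], by = d$grid$spacing[1],
            length.out = dim(d$grid$values)[1])
  # at gantry 0 the beam axis is x = 0; the maximum must sit within one cell
  expect_lte(abs(xs[peak[1]]), d$grid$spacing[1])
})

test_that("error injection matches its contracts", {
  tb <- tiny_beam()
  # identity
  e0 <- inject_error(tb$plan, tb$dose, error_spec("none"), tb$geo)
  expect_identical(e0$dose$grid$values, tb$dose$grid$values)
  # output scaling is exact
  ep <- inject_error(tb$plan, tb$dose, error_spec("output_plus"), tb$geo)
  expect_equal(ep$dose$grid$values, tb$dose$grid$values * 1.03,
               tolerance = 1e-12)
  em <- inject_error(tb$plan, tb$dose, error_spec("output_minus"), tb$geo)
  expect_equal(em$dose$planar[[2]], tb$dose$planar[[2]] * 0.97,
               tolerance = 1e-12)
  # systematic MLC: every leaf offset +2 mm, dose recomputed
  es <- inject_error(tb$plan, tb$dose, error_spec("mlc_systematic"), tb$geo)
  expect_equal(es$plan$leaf_a, tb$plan$leaf_a + 2)
  expect_equal(es$plan$leaf_b, tb$plan$leaf_b + 2)
  expect_false(identical(es$dose$grid$values, tb$dose$grid$values))
  # random MLC: reproducible per seed, Gaussian scale
  er1 <- inject_error(tb$plan, tb$dose, error_spec("mlc_random", seed = 3),
                      tb$geo)
  er2 <- inject_error(tb$plan, tb$dose, error_spec("mlc_random", seed = 3),
                      tb$geo)
  expect_identical(er1$plan, er2$plan)
  expect_true(all(er1$plan$leaf_a <= er1$plan$leaf_b))
  expect_error(inject_error(tb$plan, tb$dose,
                            structure(list(kind = "bogus", magnitude = 1),
                                      class = "error_spec"), tb$geo),
               "unknown")
  expect_error(error_spec("mlc_random"), "seed")
})

test_that("opposite gantry rotations compose to the identity within resampling error", {
  tb <- tiny_beam()
  cw <- inject_error(tb$plan, tb$dose, error_spec("gantry_cw"), tb$geo)
  back <- inject_error(tb$plan, cw$dose, error_spec("gantry_ccw"), tb$geo)
  # compare on an interior block, away from grid-edge clamping
  v0 <- tb$dose$grid$values
  v1 <- back$dose$grid$values
  d <- dim(v0)
  core <- list(8:(d[1] - 7), 8:(d[2] - 7), 8:(d[3] - 7))
  err <- max(abs(v1[core[[1]], core[[2]], core[[3]]] -
                   v0[core[[1]], core[[2]], core[[3]]]))
  # bound: 2x the single-resampling interpolation error on this smooth field
  single <- max(abs(cw$dose$grid$values - v0))
  expect_lt(err, 2 * single)
  expect_lt(err, 0.02 * max(v0))
})

test_that("measurement noise honors its configuration", {
  tb <- tiny_beam()
  # zero noise, unit factor reproduces the input exactly
  m0 <- simulate_measurement(tb$dose$planar, tb$geo,
                             noise_config(0, 0, 20, 0), seed = 1)
  expect_equal(m0$planes[[1]], tb$dose$planar[[1]], tolerance = 1e-15)
  expect_equal(m0$daily_factor, 1)
  # determinism
  m1 <- simulate_measurement(tb$dose$planar, tb$geo, noise_config(), seed = 5)
  m2 <- simulate_measurement(tb$dose$planar, tb$geo, noise_config(), seed = 5)
  expect_identical(m1, m2)
  # Monte-Carlo check of the per-diode relative sd (correlated field off)
  truth <- rep(1, 500)
  draws <- unlist(lapply(1:20, function(s)
    simulate_measurement(list(truth, truth), tb$geo,
                         noise_config(sd_diode = 0.007, sd_field = 0,
                                      sd_daily = 0),
                         seed = s)$planes[[1]]))
  expect_equal(sd(draws), 0.007, tolerance = 0.1)
  expect_error(noise_config(sd_diode = -1), "non-negative")
})

test_that("dataset generation respects the split and condition structure", {
  ds <- tiny_dataset()
  expect_equal(table(vapply(ds$beams, `[[`, "", "split")),
               table(c(rep("train", 3), rep("validation", 2),
                       rep("test", 3))))
  for (beam in ds$beams) {
    expect_length(beam$conditions, 10L)  # error-free + 9 errors
    expect_named(beam$conditions, c("none", error_kinds()),
                 ignore.order = FALSE)
    for (cond in beam$conditions)
      expect_length(cond$planar, 2L)  # two detector planes
    if (beam$split == "test")
      expect_length(beam$conditions$none$plane_grids, 2L)
    else
      expect_null(beam$conditions$none$plane_grids)
  }
  expect_error(generate_dataset(n_beams = 3, split = c(3, 2, 2), seed = 1),
               "exceed")
})

test_that("the dataset regenerates identically from the same seed", {
  ds1 <- generate_dataset(n_beams = 3, split = c(1, 1, 1), seed = 31,
                          n_cp = 8)
  ds2 <- generate_dataset(n_beams = 3, split = c(1, 1, 1), seed = 31,
                          n_cp = 8)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$beams, ds2$beams)
})

test_that("dose-difference amplitude grows with the output-error magnitude", {
  tb <- tiny_beam()
  iso <- vmatqa:::isocenter_dose_of(tb$dose$planar[[1]], tb$geo)
  amp <- vapply(c(0.01, 0.03, 0.05), function(m) {
    e <- inject_error(tb$plan, tb$dose,
                      error_spec("output_plus", magnitude = m), tb$geo)
    mean(abs(e$dose$planar[[1]] - tb$dose$planar[[1]])) / iso
  }, 0)
  expect_true(all(diff(amp) > 0))
})
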