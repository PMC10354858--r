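make_eval <- function(values, origin = c(-20, -20), step = 1)
  list(values = values, origin = origin, step = step)

test_that("identical distributions give gamma 0 and a 100% pass rate", {
  ev <- make_eval(matrix(1, 41, 41))
  pts <- as.matrix(expand.grid(a = seq(-10, 10, 5), b = seq(-10, 10, 5)))
  g <- gamma_index(pts, rep(1, nrow(pts)), ev, gamma_criteria(3, 2))
  expect_true(all(g == 0))
  expect_equal(gamma_pass_rate(g, rep(1, nrow(pts)),
                               gamma_criteria(3, 2))$pass_rate, 100)
})

test_that("a uniform 5% offset at 3%/2mm gives gamma 5/3 everywhere (DTA cannot help)", {
  ev <- make_eval(matrix(1, 41, 41))
  pts <- as.matrix(expand.grid(a = seq(-10, 10, 5), b = seq(-10, 10, 5)))
  g <- gamma_index(pts, rep(1.05, nrow(pts)), ev, gamma_criteria(3, 2),
                   norm_dose = 1)
  expect_equal(unique(round(g, 9)), 5 / 3)
  expect_equal(gamma_pass_rate(g, rep(1.05, nrow(pts)),
                               gamma_criteria(3, 2))$pass_rate, 0)
})

test_that("a 1 mm shift of a 1%/mm gradient gives gamma near 1/sqrt(13)", {
  xs <- seq(-20, 20, 1)
  ev <- make_eval(matrix(rep(1 + 0.01 * xs, 41), 41, 41))
  pts <- as.matrix(expand.grid(a = seq(-5, 5, 5), b = seq(-5, 5, 5)))
  refd <- 1 + 0.01 * (pts[, 1] + 1)  # measured = calculated shifted by 1 mm
  g <- gamma_index(pts, refd, ev, gamma_criteria(3, 2), norm_dose = 1)
  expect_equal(unique(round(g, 4)), round(1 / sqrt(13), 4), tolerance = 0.02)
})

test_that("the gamma search agrees with brute force on a finer lattice", {
  set.seed(51)
  xs <- seq(-20, 20, 1)
  smooth <- outer(xs, xs, function(x, y)
    1 + 0.3 * sin(x / 7) * cos(y / 9) + 0.1 * sin((x + y) / 11))
  ev <- make_eval(smooth)
  pts <- cbind(runif(12, -10, 10), runif(12, -10, 10))
  refd <- 1 + 0.3 * sin((pts[, 1] + 1.3) / 7) * cos(pts[, 2] / 9) +
    rnorm(12, 0, 0.01)
  cr <- gamma_criteria(3, 2)
  g <- gamma_index(pts, refd, ev, cr, norm_dose = 1)
  for (i in seq_len(nrow(pts))) {
    gb <- oracle_gamma(pts[i, 1], pts[i, 2], refd[i], ev,
                       dd_abs = 0.03, dta = 2)
    expect_lt(abs(g[i] - gb), 0.02)
  }
})

test_that("loosening the criteria never lowers a pass rate", {
  ds <- tiny_dataset()
  loose <- gamma_score_cases(ds, gamma_criteria(3, 2))
  strict <- gamma_score_cases(ds, gamma_criteria(2, 1))
  expect_equal(nrow(loose), 30L)  # 3 test beams x 10 conditions
  merged <- merge(loose, strict, by = c("beam_id", "error_kind"))
  expect_true(all(merged$pass_rate.x >= merged$pass_rate.y))
  expect_true(all(loose$pass_rate >= 0 & loose$pass_rate <= 100))
})

test_that("pass-rate bookkeeping honors the boundary and the low-dose cutoff", {
  cr <- gamma_criteria(3, 2)
  expect_equal(gamma_pass_rate(c(0.5, 0.5), c(1, 1), cr)$pass_rate, 100)
  # gamma exactly 1 passes
  expect_equal(gamma_pass_rate(c(0.5, 1, 1.5), c(1, 1, 1), cr)$pass_rate,
               2 / 3 * 100, tolerance = 1e-9)
  # the low-dose diode is excluded before counting
  r <- gamma_pass_rate(c(2, 2, 2), c(0.05, 0.5, 1), cr)
  expect_equal(r$n_evaluated, 2L)
  expect_equal(r$pass_rate, 0)
  expect_error(gamma_pass_rate(c(1, 1), c(0.01, 0.02), cr, max_dose = 1),
               "cutoff")
})

test_that("gamma classification assigns the boundary to any-error", {
  expect_equal(classify_gamma(100, 95), "error-free")
  expect_equal(classify_gamma(0, 95), "any-error")
  expect_equal(classify_gamma(95, 95), "any-error")
})

test_that("phantom-position optimization recovers a constructed shift", {
  ds <- tiny_dataset()
  geo <- ds$geometry
  beam <- ds$beams[[which(vapply(ds$beams, `[[`, "", "split") == "test")[1]]]
  plan <- sample_plan(beam$plan_seed, n_cp = 12)
  d <- compute_dose(plan, geo)
  # noise-free measurement taken with the phantom displaced 1 mm laterally
  shift_true <- c(1, 0, 0)
  meas <- lapply(geo$planes, function(pl)
    vmatqa:::cpp_trilinear(as.numeric(d$grid$values), dim(d$grid$values),
                           d$grid$origin, d$grid$spacing,
                           sweep(pl$pos3d, 2, shift_true, `+`)))
  opt <- optimize_phantom_position(meas, d$grid, geo)
  expect_lt(sqrt(sum((opt$shift - shift_true)^2)), 0.2)
  expect_equal(opt$pass_rate, 100)
})

test_that("aligned data yield a zero shift and a zero search space is the identity", {
  tb <- tiny_beam()
  opt0 <- optimize_phantom_position(tb$dose$planar, tb$dose$grid, tb$geo)
  expect_equal(unname(opt0$shift), c(0, 0, 0))
  optz <- optimize_phantom_position(tb$dose$planar, tb$dose$grid, tb$geo,
                                    search_mm = 0)
  expect_equal(unname(optz$shift), c(0, 0, 0))
})
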