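test_that("ROC curves honor their endpoint and separation contracts", {
  r <- roc_curve(c(1, 2), c(3, 4))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  # perfect separation passes through (0, 1)
  expect_true(any(r$curve$fpr == 0 & r$curve$tpr == 1))
  expect_equal(r$auc, 1)
  # identical score sets give the diagonal
  r2 <- roc_curve(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$auc, 0.5)
  expect_true(all(abs(r2$curve$fpr - r2$curve$tpr) < 1e-12))
  # single threshold reproduces the directly counted confusion matrix
  neg <- c(1, 2, 2, 5)
  pos <- c(1.5, 3, 4, 6)
  r3 <- roc_curve(neg, pos)
  i <- which(r3$curve$threshold == 2)
  expect_equal(r3$curve$fpr[i], mean(neg > 2))
  expect_equal(r3$curve$tpr[i], mean(pos > 2))
  expect_error(roc_curve(numeric(0), 1), "non-empty")
})

test_that("AUC equals Mann-Whitney pair counting and transforms correctly", {
  expect_equal(roc_curve(c(1, 2, 3), c(2.5, 4, 5))$auc, 8 / 9,
               tolerance = 1e-12)
  set.seed(71)
  for (i in 1:10) {
    neg <- round(rnorm(17), 1)  # rounding forces ties
    pos <- round(rnorm(23, 0.5), 1)
    auc <- roc_curve(neg, pos)$auc
    expect_equal(auc, oracle_auc(neg, pos), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(roc_curve(exp(neg), exp(pos))$auc, auc, tolerance = 1e-12)
    # reversing the orientation maps AUC to 1 - AUC
    expect_equal(roc_curve(neg, pos, orientation = "lower")$auc, 1 - auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC matches the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  neg <- rnorm(40)
  pos <- rnorm(40, 0.8)
  ours <- roc_curve(neg, pos)$auc
  theirs <- as.numeric(pROC::auc(rep(0:1, each = 40), c(neg, pos),
                                 direction = "<", quiet = TRUE))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the ideal threshold minimizes distance to (0,1) with stated tie-breaks", {
  # constructed curve: operating point (0.1, 0.9) is closest to (0, 1)
  neg <- c(rep(1, 9), 2)
  pos <- c(0, rep(2, 9))
  r <- roc_curve(neg, pos)
  opt <- ideal_threshold(r)
  i <- which(r$curve$threshold == opt$threshold)
  expect_equal(r$curve$fpr[i], 0.1)
  expect_equal(r$curve$tpr[i], 0.9)
  expect_equal(opt$sensitivity, 0.9)
  expect_equal(opt$specificity, 0.9)
  expect_equal(opt$accuracy, 0.9)
  # perfect separation: all metrics 1
  opt2 <- ideal_threshold(roc_curve(c(1, 2), c(3, 4)))
  expect_equal(opt2$sensitivity, 1)
  expect_equal(opt2$specificity, 1)
  expect_equal(opt2$accuracy, 1)
  # diagonal curve: the tie-break picks the higher-sensitivity point among
  # the equally close ones
  opt3 <- ideal_threshold(roc_curve(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(opt3$sensitivity, 2 / 3)
  expect_equal(opt3$specificity, 1 / 3)
})

test_that("the paired AUC test behaves at its boundary cases", {
  set.seed(73)
  labels <- rep(c(FALSE, TRUE), each = 36)
  x <- c(rnorm(36), rnorm(36, 1))
  same <- compare_auc(x, x, labels)
  expect_equal(same$p_value, 1)
  # perfect separation vs pure noise is detected
  perfect <- c(rep(0, 36), rep(1, 36))
  noise <- rnorm(72)
  expect_lt(compare_auc(perfect, noise, labels)$p_value, 0.05)
  # two-sided symmetry
  a <- rnorm(72)
  b <- rnorm(72) + labels * 0.8
  expect_equal(compare_auc(a, b, labels)$p_value,
               compare_auc(b, a, labels)$p_value, tolerance = 1e-12)
  expect_error(compare_auc(a, b[1:10], labels), "paired")
  expect_error(compare_auc(a, b, rep(TRUE, 72)), "both classes")
})

test_that("the paired AUC test matches the reference DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  labels <- rep(0:1, each = 30)
  a <- rnorm(60) + labels * 0.7
  b <- rnorm(60) + labels * 0.3
  ours <- compare_auc(a, b, labels)
  theirs <- pROC::roc.test(pROC::roc(labels, a, direction = "<",
                                     quiet = TRUE),
                           pROC::roc(labels, b, direction = "<",
                                     quiet = TRUE),
                           method = "delong", paired = TRUE)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-9)
})

test_that("evaluate_all produces the full method-by-error-type report", {
  set.seed(75)
  kinds <- error_kinds()
  mk_scores <- function(col, shift_fun) {
    rows <- lapply(c("none", kinds), function(k) {
      df <- data.frame(beam_id = 1:12, error_kind = k)
      df[[col]] <- rnorm(12) + shift_fun(k)
      df
    })
    do.call(rbind, rows)
  }
  md <- mk_scores("md_mean", function(k) if (k == "none") 0 else 2)
  pp <- mk_scores("p_error_mean", function(k) if (k == "none") 0 else 1)
  g1 <- mk_scores("pass_rate", function(k) if (k == "none") 5 else 0)
  ev <- evaluate_all(md, pp, list("gamma 2%/1mm" = g1))
  expect_equal(nrow(ev$report), 9 * 3)
  expect_equal(sort(unique(ev$report$method)),
               sort(c("VAE", "S-CNN", "gamma 2%/1mm")))
  expect_true(all(ev$report$auc >= 0 & ev$report$auc <= 1))
  expect_true(all(is.na(ev$report$p_value_vs_vae[ev$report$method ==
                                                   "VAE"])))
  expect_true(all(ev$metrics$accuracy >= 0 & ev$metrics$accuracy <= 1))
  # a method with constant scores is at chance for every error type
  const <- mk_scores("md_mean", function(k) 0)
  const$md_mean <- 1
  ev2 <- evaluate_all(const)
  expect_true(all(ev2$report$auc == 0.5))
  # missing cells are reported by (method, error) pair
  expect_error(evaluate_all(md, pp[pp$error_kind != "setup_lng", ]),
               "S-CNN, setup_lng")
})
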