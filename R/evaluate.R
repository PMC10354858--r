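#' ROC curve from negative- and positive-class scores
#'
#' Sweeps the decision threshold over all distinct scores; a case is called
#' positive (any-error) when its oriented score strictly exceeds the
#' threshold, matching [classify_md()]. Scores where lower means more
#' anomalous (gamma pass rates) are negated internally so one code path
#' serves both orientations.
#'
#' @param neg_scores scores of the negative (error-free) class.
#' @param pos_scores scores of the positive (any-error) class.
#' @param orientation `"higher"` if larger scores are more anomalous,
#'   `"lower"` otherwise.
#' @return A `roc_result`: `curve` data frame (`threshold` on the original
#'   scale, `fpr`, `tpr`), `auc`, class counts and the orientation.
#' @export
roc_curve <- function(neg_scores, pos_scores,
                      orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  if (length(neg_scores) == 0L || length(pos_scores) == 0L)
    stop("both score sets must be non-empty")
  sgn <- if (orientation == "lower") -1 else 1
  neg <- sgn * neg_scores
  pos <- sgn * pos_scores
  thr <- c(Inf, sort(unique(c(neg, pos)), decreasing = TRUE), -Inf)
  fpr <- vapply(thr, function(t) mean(neg > t), 0)
  tpr <- vapply(thr, function(t) mean(pos > t), 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(curve = data.frame(threshold = sgn * thr, fpr = fpr,
                                    tpr = tpr),
                 auc = auc, n_neg = length(neg_scores),
                 n_pos = length(pos_scores), orientation = orientation),
            class = "roc_result")
}

#' Area under a ROC curve
#'
#' Trapezoidal area; equal to the Mann-Whitney pair statistic
#' (#(pos > neg) + 0.5 #(ties)) / (n_pos * n_neg).
#'
#' @param x a `roc_result` from [roc_curve()].
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(x) {
  stopifnot(inherits(x, "roc_result"))
  x$auc
}

#' Ideal operating point of a ROC curve
#'
#' The threshold whose (FPR, TPR) point is closest to (0, 1); ties broken by
#' higher sensitivity, then by the threshold that calls more cases positive.
#'
#' @param x a `roc_result`.
#' @return list: `threshold` (original score scale), `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
ideal_threshold <- function(x) {
  stopifnot(inherits(x, "roc_result"))
  cv <- x$curve
  d2 <- cv$fpr^2 + (1 - cv$tpr)^2
  cand <- which(d2 == min(d2))
  # tie-break: higher sensitivity first, then lower oriented threshold
  sgn <- if (x$orientation == "lower") -1 else 1
  i <- cand[order(-cv$tpr[cand], sgn * cv$threshold[cand])][1]
  list(threshold = cv$threshold[i],
       accuracy = (cv$tpr[i] * x$n_pos + (1 - cv$fpr[i]) * x$n_neg) /
         (x$n_pos + x$n_neg),
       sensitivity = cv$tpr[i],
       specificity = 1 - cv$fpr[i])
}

#' Paired DeLong test for the difference of two AUCs
#'
#' Two-sided test comparing the ROC AUCs of two methods scored on the same
#' cases (DeLong, DeLong and Clarke-Pearson 1988). Scores must be oriented
#' so that higher means more anomalous.
#'
#' @param scores_a,scores_b per-case scores of the two methods, same order.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive (any-error).
#' @return list: `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores and labels must be paired (equal lengths)")
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  placements <- function(x) {
    pos <- x[labels]
    neg <- x[!labels]
    psi <- outer(pos, neg, function(p, q)
      (p > q) + 0.5 * (p == q))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  a <- placements(scores_a)
  b <- placements(scores_b)
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- cov(cbind(a$v10, b$v10))
  s01 <- cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- a$auc - b$auc
  if (v <= 0) {
    p <- if (abs(d) < .Machine$double.eps^0.5) 1 else 0
    return(list(p_value = p, auc_a = a$auc, auc_b = b$auc, z = NA_real_))
  }
  z <- d / sqrt(v)
  list(p_value = 2 * pnorm(-abs(z)), auc_a = a$auc, auc_b = b$auc, z = z)
}

#' Full ROC evaluation of all methods per error type
#'
#' For every error kind and method, builds the ROC curve (error-free cases
#' as negatives, that kind's cases as positives), the AUC and the
#' ideal-threshold metrics, plus the paired DeLong p-value of each method's
#' AUC against the VAE-based method.
#'
#' @param md_scores data frame from [score_cases()] (`md_mean` column).
#' @param scnn_probs data frame from [score_cases_scnn()]
#'   (`p_error_mean` column); optional.
#' @param gamma_rates named list of data frames from [gamma_score_cases()]
#'   (one per criteria, e.g. `"gamma 2%/1mm"`); optional.
#' @return list: `report` (error kind x method: AUC and p-value vs VAE),
#'   `metrics` (ideal-threshold accuracy/sensitivity/specificity),
#'   `curves` (nested list of `roc_result`s).
#' @export
evaluate_all <- function(md_scores, scnn_probs = NULL, gamma_rates = NULL) {
  methods <- list(VAE = list(df = md_scores, col = "md_mean",
                             orientation = "higher"))
  if (!is.null(scnn_probs))
    methods$`S-CNN` <- list(df = scnn_probs, col = "p_error_mean",
                            orientation = "higher")
  for (nm in names(gamma_rates))
    methods[[nm]] <- list(df = gamma_rates[[nm]], col = "pass_rate",
                          orientation = "lower")

  kinds <- setdiff(unique(md_scores$error_kind), "none")
  missing <- character(0)
  for (nm in names(methods)) {
    have <- unique(methods[[nm]]$df$error_kind)
    for (k in c("none", kinds))
      if (!k %in% have) missing <- c(missing, paste0("(", nm, ", ", k, ")"))
  }
  if (length(missing))
    stop("missing scores for: ", paste(missing, collapse = ", "))

  pull <- function(meth, kind) {
    df <- meth$df[meth$df$error_kind == kind, , drop = FALSE]
    if (!is.null(df$beam_id)) df <- df[order(df$beam_id), , drop = FALSE]
    df[[meth$col]]
  }
  report <- metrics <- list()
  curves <- list()
  for (k in kinds) {
    curves[[k]] <- list()
    vae_scores <- NULL
    for (nm in names(methods)) {
      meth <- methods[[nm]]
      neg <- pull(meth, "none")
      pos <- pull(meth, k)
      roc <- roc_curve(neg, pos, orientation = meth$orientation)
      curves[[k]][[nm]] <- roc
      opt <- ideal_threshold(roc)
      sgn <- if (meth$orientation == "lower") -1 else 1
      oriented <- sgn * c(neg, pos)
      if (nm == "VAE") vae_scores <- oriented
      pval <- if (nm == "VAE") NA_real_ else
        compare_auc(oriented, vae_scores,
                    labels = rep(c(FALSE, TRUE), c(length(neg),
                                                   length(pos))))$p_value
      report[[length(report) + 1L]] <- data.frame(
        error_kind = k, method = nm, auc = roc$auc, p_value_vs_vae = pval,
        n_neg = length(neg), n_pos = length(pos), stringsAsFactors = FALSE)
      metrics[[length(metrics) + 1L]] <- data.frame(
        error_kind = k, method = nm, threshold = opt$threshold,
        accuracy = opt$accuracy, sensitivity = opt$sensitivity,
        specificity = opt$specificity, stringsAsFactors = FALSE)
    }
  }
  list(report = do.call(rbind, report), metrics = do.call(rbind, metrics),
       curves = curves)
}

#' Write an evaluation report to CSV files
#' @param evaluation an [evaluate_all()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(evaluation$report, file.path(dir, "report.csv"),
            row.names = FALSE)
  write.csv(evaluation$metrics, file.path(dir, "metrics.csv"),
            row.names = FALSE)
  invisible(dir)
}
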