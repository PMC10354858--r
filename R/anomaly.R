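#' Fit the Mahalanobis reference model from training latent means
#'
#' The reference "normal" distribution is the sample mean and covariance
#' (denominator n-1) of the latent mean vectors obtained by encoding the
#' error-free training maps. A small ridge is added to the covariance before
#' inversion; the default scales with the mean eigenvalue so the
#' regularization is unit-free.
#'
#' @param train_mu matrix of reference latent means (`n x d`).
#' @param ridge non-negative ridge added as `ridge * I`; `NULL` (default)
#'   uses `1e-6 * trace(Sigma) / d`.
#' @return An `md_reference`: `xbar`, `Sigma`, `Sigma_inv`, `ridge`, `n_ref`.
#' @export
fit_reference <- function(train_mu, ridge = NULL) {
  train_mu <- as.matrix(train_mu)
  n <- nrow(train_mu)
  d <- ncol(train_mu)
  if (n < 2L) stop("at least two reference vectors are required")
  xbar <- colMeans(train_mu)
  Sigma <- cov(train_mu)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(Sigma)) / d
  if (ridge < 0) stop("ridge must be non-negative")
  if (ridge == 0 && n <= d)
    stop(sprintf(
      "covariance is singular (%d reference vectors for %d dimensions); supply ridge > 0",
      n, d))
  Sr <- Sigma + diag(ridge, d)
  Sigma_inv <- tryCatch(chol2inv(chol(Sr)), error = function(e)
    stop("covariance (plus ridge) is not positive definite: ",
         conditionMessage(e)))
  structure(list(xbar = xbar, Sigma = Sigma, Sigma_inv = Sigma_inv,
                 ridge = ridge, n_ref = n),
            class = "md_reference")
}

#' Mahalanobis distance of a latent vector from the reference
#'
#' `sqrt((x - xbar) %*% Sigma_inv %*% (x - xbar))`, covariance-scaled
#' distance from the error-free reference distribution; the anomaly score.
#'
#' @param x latent vector (or `n x d` matrix of vectors).
#' @param reference an [fit_reference()] result.
#' @return non-negative distance(s).
#' @export
mahalanobis_distance <- function(x, reference) {
  stopifnot(inherits(reference, "md_reference"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(reference$xbar))
    stop(sprintf("dimension mismatch: x has %d, reference has %d",
                 ncol(x), length(reference$xbar)))
  dx <- sweep(x, 2, reference$xbar)
  md2 <- rowSums((dx %*% reference$Sigma_inv) * dx)
  sqrt(pmax(md2, 0))
}

#' Score a beam case: per-plane and mean Mahalanobis distance
#'
#' Encodes both plane maps of the case and averages the two per-plane
#' distances into the case-level anomaly score.
#'
#' @param model trained `vae_model`.
#' @param reference an [fit_reference()] result.
#' @param beam_case list with `beam_id`, `error_kind` and `maps` (two maps).
#' @return A one-row data frame: `beam_id`, `error_kind`, `md_plane1`,
#'   `md_plane2`, `md_mean`.
#' @export
score_case <- function(model, reference, beam_case) {
  if (length(beam_case$maps) != 2L) stop("beam case must carry two plane maps")
  st <- encode_maps(model, beam_case$maps)
  md <- mahalanobis_distance(st$mu, reference)
  data.frame(beam_id = beam_case$beam_id %||% NA_integer_,
             error_kind = beam_case$error_kind %||% NA_character_,
             md_plane1 = md[1], md_plane2 = md[2],
             md_mean = mean(md), stringsAsFactors = FALSE)
}

#' Score all test cases
#'
#' @param model trained `vae_model`.
#' @param reference an [fit_reference()] result.
#' @param test_cases list of beam cases (from [assemble_vae_datasets()]).
#' @return data frame with one row per case.
#' @export
score_cases <- function(model, reference, test_cases) {
  # batch-encode all maps at once, then regroup in pairs
  maps <- unlist(lapply(test_cases, `[[`, "maps"), recursive = FALSE)
  st <- encode_maps(model, maps)
  md <- mahalanobis_distance(st$mu, reference)
  i1 <- seq(1L, length(md), by = 2L)
  data.frame(
    beam_id = vapply(test_cases, function(cs) as.integer(cs$beam_id), 1L),
    error_kind = vapply(test_cases, `[[`, "", "error_kind"),
    md_plane1 = md[i1], md_plane2 = md[i1 + 1L],
    md_mean = (md[i1] + md[i1 + 1L]) / 2, stringsAsFactors = FALSE)
}

#' Classify a case by its mean Mahalanobis distance
#'
#' At or below the threshold is "error-free"; above it is "any-error".
#'
#' @param md_mean case score(s).
#' @param threshold non-negative decision threshold.
#' @return character vector of labels.
#' @export
classify_md <- function(md_mean, threshold) {
  if (threshold < 0) stop("threshold must be non-negative")
  ifelse(md_mean > threshold, "any-error", "error-free")
}
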