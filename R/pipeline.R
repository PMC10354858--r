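#' Pipeline configuration
#'
#' One seed governs the whole run; every stage derives its own seed from it.
#'
#' @param seed master seed.
#' @param n_beams,split dataset size, passed to [generate_dataset()].
#' @param vae a [vae_config()] (its seed is overridden by the derived seed).
#' @param scnn an [scnn_config()] (idem), or `NULL` to skip the S-CNN arm.
#' @param gamma_criteria named list of [gamma_criteria()] (default: global
#'   2%/1 mm and 3%/2 mm), or `NULL` to skip gamma analysis.
#' @param out_dir directory for stage caches and reports; `NULL` disables
#'   persistence (everything stays in memory).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1, n_beams = 161,
                            split = c(train = 100, validation = 25,
                                      test = 36),
                            vae = vae_config(),
                            scnn = scnn_config(),
                            gamma_criteria = NULL,
                            out_dir = NULL) {
  if (missing(gamma_criteria))
    gamma_criteria <- list("gamma 2%/1mm" = vmatqa::gamma_criteria(2, 1),
                           "gamma 3%/2mm" = vmatqa::gamma_criteria(3, 2))
  structure(list(seed = seed, n_beams = n_beams, split = split, vae = vae,
                 scnn = scnn, gamma_criteria = gamma_criteria,
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # cheap content key for stage caching: fold the serialized config bytes
  raw <- serialize(config, NULL, version = 2)[-(1:14)]  # skip header
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %%
            .Machine$integer.max)
}

#' Run the full error-detection pipeline
#'
#' simulate -> dose-difference maps -> {VAE + Mahalanobis scoring, S-CNN,
#' gamma analysis} -> ROC evaluation. With an `out_dir`, each stage's result
#' is cached (keyed on the configuration) and reused on re-runs; reports are
#' written as CSV.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return list: `dataset`, `vae_model`, `reference`, `md_scores`,
#'   `scnn_model`, `scnn_scores`, `gamma_scores`, `evaluation`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  key <- config_hash(config)
  cache <- function(stage, expr) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(config$out_dir,
                        sprintf("stage-%s-%s.rds", stage, key))
      if (file.exists(path)) {
        if (verbose) message("[", stage, "] reusing cached result")
        return(readRDS(path))
      }
    }
    if (verbose) message("[", stage, "] running")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (verbose)
      message(sprintf("[%s] done in %.1f s", stage,
                      proc.time()[["elapsed"]] - t0))
    if (!is.null(config$out_dir)) saveRDS(out, path)
    out
  }
  seeds <- derive_seeds(config$seed, 3L)

  dataset <- cache("simulate", generate_dataset(
    n_beams = config$n_beams, split = config$split, seed = seeds[1],
    keep_plane_grids = if (is.null(config$gamma_criteria)) character(0)
    else "test"))

  maps <- cache("ddmap", assemble_vae_datasets(dataset))

  vae_fit <- cache("vae", {
    cfg <- config$vae
    cfg$seed <- seeds[2]
    model <- train_vae(maps$train, maps$validation, cfg)
    reference <- fit_reference(encode_maps(model, maps$train)$mu)
    list(model = model, reference = reference)
  })
  md_scores <- cache("score", score_cases(vae_fit$model, vae_fit$reference,
                                          maps$test_cases))

  scnn_model <- NULL
  scnn_scores <- NULL
  if (!is.null(config$scnn)) {
    scnn_model <- cache("scnn", {
      cfg <- config$scnn
      cfg$seed <- seeds[3]
      train_scnn(assemble_scnn_datasets(dataset), cfg)
    })
    scnn_scores <- cache("score-scnn",
                         score_cases_scnn(scnn_model, maps$test_cases))
  }

  gamma_scores <- NULL
  if (!is.null(config$gamma_criteria)) {
    gamma_scores <- cache("gamma", lapply(config$gamma_criteria, function(cr)
      gamma_score_cases(dataset, cr)))
  }

  evaluation <- cache("evaluate",
                      evaluate_all(md_scores, scnn_scores, gamma_scores))
  if (!is.null(config$out_dir)) write_report(evaluation, config$out_dir)

  list(dataset = dataset, vae_model = vae_fit$model,
       reference = vae_fit$reference, md_scores = md_scores,
       scnn_model = scnn_model, scnn_scores = scnn_scores,
       gamma_scores = gamma_scores, evaluation = evaluation)
}
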