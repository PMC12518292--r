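#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations for [run_pipeline()]: simulate (or
#' ingest) imagery, preprocess, train the compositional and baseline
#' autoencoders, extract latents, compute vegetation indices, and run the
#' disentanglement and yield evaluations. Every run writes its resolved
#' configuration next to its outputs so any report is reproducible from the
#' co-written config and seed.
#'
#' @param sim a [sim_config()] for synthetic data, or `NULL` when
#'   `data_dir` is given.
#' @param data_dir directory of an existing dataset written by
#'   [write_dataset()]; overrides `sim`.
#' @param latent a [latent_config()] (default 6-6-1).
#' @param training a [training_config()].
#' @param ae_epochs epochs for the baseline autoencoder (defaults to the
#'   compositional model's).
#' @param eval_disentanglement,eval_yield stage switches.
#' @param write_data also write the simulated dataset under the output
#'   directory.
#' @param seed master seed; stages derive their seeds from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), data_dir = NULL,
                            latent = latent_config(),
                            training = training_config(),
                            ae_epochs = NULL,
                            eval_disentanglement = TRUE, eval_yield = TRUE,
                            write_data = FALSE, seed = 1) {
  structure(list(sim = sim, data_dir = data_dir, latent = latent,
                 training = training,
                 ae_epochs = ae_epochs %||% training$epochs,
                 eval_disentanglement = eval_disentanglement,
                 eval_yield = eval_yield, write_data = write_data,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_stage <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  message(line)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) -> preprocess -> train compositional and vanilla
#' autoencoders -> extract latents -> vegetation indices -> disentanglement
#' report -> yield reports. Artifacts are written under `out_dir`:
#' `config.json`, `latents_cae.csv`, `latents_ae.csv`, `vis.csv`,
#' `loss_cae.csv`, `loss_ae.csv`, `disentanglement.json`, `yield_cv.csv`,
#' `rank_overlap.csv`, `unseen_env.csv`, and `run.log`. A stage failure
#' aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the dataset, fits, latent/VI tables and
#'   reports.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("cae_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  stage <- function(name, expr) {
    .log_stage(log_path, "stage ", name, " started")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  resolved <- list(
    seed = config$seed,
    sim = if (is.null(config$data_dir)) unclass(config$sim) else NULL,
    data_dir = config$data_dir,
    latent = unclass(config$latent)[c("zg", "ze", "zp")],
    training = unclass(config$training),
    ae_epochs = config$ae_epochs,
    eval_disentanglement = config$eval_disentanglement,
    eval_yield = config$eval_yield
  )
  jsonlite::write_json(resolved, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  dataset <- stage("data", {
    if (!is.null(config$data_dir)) read_dataset(config$data_dir)
    else simulate_dataset(config$sim)
  })
  if (config$write_data && is.null(config$data_dir)) {
    stage("write-data", write_dataset(dataset, file.path(out_dir, "dataset")))
  }

  pre <- stage("preprocess", preprocess(dataset))
  clipped <- stage("clip-for-vis", clip_outliers(dataset))

  vis <- stage("vegetation-indices", vi_table(clipped))
  readr::write_csv(vis, file.path(out_dir, "vis.csv"))

  fit_cae <- stage("train-cae",
                   train_cae(pre, latent = config$latent,
                             config = config$training))
  readr::write_csv(fit_cae$history, file.path(out_dir, "loss_cae.csv"))
  ae_cfg <- config$training
  ae_cfg$epochs <- config$ae_epochs
  fit_ae <- stage("train-ae",
                  train_ae(pre, latent = config$latent, config = ae_cfg))
  readr::write_csv(fit_ae$history, file.path(out_dir, "loss_ae.csv"))

  lat_cae <- stage("extract-cae", extract_latents(fit_cae, pre))
  lat_ae <- stage("extract-ae", extract_latents(fit_ae, pre))
  readr::write_csv(lat_cae, file.path(out_dir, "latents_cae.csv"))
  readr::write_csv(lat_ae, file.path(out_dir, "latents_ae.csv"))

  reports <- list()
  if (config$eval_disentanglement) {
    reports$disentanglement <- stage("eval-disentangle", {
      macro <- macro_env_silhouette(lat_cae)
      micro <- micro_env_silhouette(lat_cae)
      raw <- raw_baseline_silhouette(pre)
      list(
        macro_env_silhouette = macro$score,
        micro_env_silhouette = micro$score,
        raw_baseline_silhouette = raw$score,
        macro_variance_ratios = macro$projection$explained_variance_ratio,
        raw_variance_ratios = raw$projection$explained_variance_ratio
      )
    })
    jsonlite::write_json(reports$disentanglement,
                         file.path(out_dir, "disentanglement.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (config$eval_yield) {
    if (is.null(dataset$yields)) {
      .log_stage(log_path,
                 "yield stages skipped: dataset carries no yield table")
    } else {
      yt <- yield_table(dataset)
      feature_sets <- list(
        CAE = dplyr::select(lat_cae, "plot_id", dplyr::matches("^z[gep]_")),
        AE = dplyr::select(lat_ae, "plot_id", dplyr::starts_with("z_")),
        VIs = vis
      )
      reports$yield_cv <- stage("eval-yield-cv", {
        experiment1(feature_sets, yt, seed = config$seed,
                    regressor = xgb_regressor(seed = config$seed))
      })
      readr::write_csv(reports$yield_cv, file.path(out_dir, "yield_cv.csv"))
      reports$rank_overlap <- stage("eval-rank-overlap", {
        experiment2(feature_sets["CAE"], yt,
                    regressor = xgb_regressor(seed = config$seed))
      })
      readr::write_csv(reports$rank_overlap,
                       file.path(out_dir, "rank_overlap.csv"))
      reports$unseen_env <- stage("eval-unseen-env", {
        holdout <- sort(unique(yt$environment_id))[1]
        experiment3(feature_sets$CAE, yt, holdout,
                    regressor = xgb_regressor(seed = config$seed))
      })
      readr::write_csv(reports$unseen_env,
                       file.path(out_dir, "unseen_env.csv"))
    }
  }

  .log_stage(log_path, "pipeline complete")
  invisible(list(dataset = dataset, preprocessed = pre, fit_cae = fit_cae,
                 fit_ae = fit_ae, latents_cae = lat_cae, latents_ae = lat_ae,
                 vis = vis, reports = reports, out_dir = out_dir))
}

#' Sweep latent partition configurations
#'
#' Trains one compositional model per `(zg, ze, zp)` configuration and
#' tabulates the disentanglement scores and cross-validated yield accuracy
#' for each — the mechanism behind latent-dimension sensitivity analyses.
#'
#' @param dataset a [cae_dataset()] (preprocessed or raw).
#' @param configs a list of `c(zg, ze, zp)` triples or [latent_config()]s.
#' @param training a [training_config()].
#' @param seed seed for the evaluation folds.
#' @return a tibble with one row per configuration: `zg`, `ze`, `zp`,
#'   `macro_env_silhouette`, `micro_env_silhouette`, `cv_r2_mean`,
#'   `cv_rmse_mean`.
#' @export
sweep_latent_configs <- function(dataset, configs,
                                 training = training_config(), seed = 1) {
  if (length(configs) < 1) stop("need at least one configuration")
  if (!dataset$preprocessed) dataset <- preprocess(dataset)
  purrr::map_dfr(configs, function(cf) {
    lc <- if (inherits(cf, "latent_config")) cf
          else latent_config(cf[1], cf[2], cf[3])
    fit <- train_cae(dataset, latent = lc, config = training)
    lat <- extract_latents(fit, dataset)
    row <- tibble::tibble(
      zg = lc$zg, ze = lc$ze, zp = lc$zp,
      macro_env_silhouette = macro_env_silhouette(lat)$score,
      micro_env_silhouette = micro_env_silhouette(lat)$score,
      cv_r2_mean = NA_real_, cv_rmse_mean = NA_real_
    )
    if (!is.null(dataset$yields)) {
      cv <- experiment1(
        list(CAE = dplyr::select(lat, "plot_id", dplyr::matches("^z[gep]_"))),
        yield_table(dataset), seed = seed,
        regressor = xgb_regressor(seed = seed))
      row$cv_r2_mean <- mean(cv$r2)
      row$cv_rmse_mean <- mean(cv$rmse)
    }
    row
  })
}
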