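#' Pipeline configuration
#'
#' One configuration object drives the whole chain. Untouched defaults
#' reproduce the published settings: the per-label SVR hyperparameters, the
#' swarm coefficients (C1 = 0.4862, C2 = 2.5067, Omega = -0.2887), the
#' 80/20 split, and the 126-cell default missingness of the synthetic
#' generator.
#'
#' @param dataset Optional path to a formulation CSV; when \code{NULL} the
#'   synthetic generator supplies the data.
#' @param out_dir Optional output directory for stage artifacts.
#' @param synthetic A [synthetic_config()].
#' @param hyperparams Per-label SVR settings ([default_hyperparams()]).
#' @param split_seed,test_fraction 80/20 split control (default seed 42).
#' @param pso A [pso_config()].
#' @param lambda_nuclear,tol,max_iter SoftImpute settings (see
#'   [soft_impute()]).
#' @param log Logical; stage progress on stderr.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(dataset = NULL, out_dir = NULL,
                            synthetic = synthetic_config(),
                            hyperparams = default_hyperparams(),
                            split_seed = 42L, test_fraction = 0.2,
                            pso = pso_config(),
                            lambda_nuclear = NULL, tol = 1e-5,
                            max_iter = 500L, log = FALSE) {
  labs <- label_names()
  if (!setequal(names(hyperparams), labs))
    stop("config error: hyperparams must cover exactly the four labels",
         call. = FALSE)
  structure(list(dataset = dataset, out_dir = out_dir, synthetic = synthetic,
                 hyperparams = hyperparams, split_seed = as.integer(split_seed),
                 test_fraction = test_fraction, pso = pso,
                 lambda_nuclear = lambda_nuclear, tol = tol,
                 max_iter = as.integer(max_iter), log = isTRUE(log)),
            class = "pipeline_config")
}

stage_log <- function(cfg, fmt, ...) {
  if (cfg$log) message(sprintf(paste0("[fiberopt] ", fmt), ...))
}

#' Run the full inverse-design pipeline
#'
#' Executes the four stages in order — preprocessing, feature importance,
#' surrogate training/evaluation, swarm optimization — on either a loaded
#' CSV or a freshly generated synthetic dataset, and assembles the
#' [report_bundle()]. Fully deterministic given the configuration seeds.
#' Per-label swarm searches use \code{cfg$pso$seed} offset by the label
#' index so the four searches draw independent random streams.
#'
#' @param cfg A [pipeline_config()].
#' @return A [report_bundle()]; when \code{cfg$out_dir} is set, the dataset
#'   CSV, transform-state JSON, surrogate JSONs and report JSON are also
#'   written there.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stage_log(cfg, "%s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  ds <- run_stage("data", {
    if (!is.null(cfg$dataset)) load_dataset(cfg$dataset)
    else generate_dataset(cfg$synthetic)$dataset
  })

  prep <- run_stage("preprocess",
                    preprocess_pipeline(ds, lambda_nuclear = cfg$lambda_nuclear,
                                        tol = cfg$tol, max_iter = cfg$max_iter))

  labs <- label_names()
  importance <- run_stage("importance", {
    out <- lapply(labs, function(lab) importance_report(prep$dataset, lab))
    stats::setNames(out, labs)
  })

  fit <- run_stage("train",
                   fit_surrogates(prep, hyperparams = cfg$hyperparams,
                                  split_seed = cfg$split_seed,
                                  test_fraction = cfg$test_fraction,
                                  raw_labels = ds$labels))

  optima <- run_stage("optimize", {
    out <- lapply(seq_along(labs), function(i) {
      pcfg <- cfg$pso
      pcfg$seed <- cfg$pso$seed + i - 1L
      optimize_label(fit$models[[labs[i]]], cfg = pcfg)
    })
    stats::setNames(out, labs)
  })

  ranges <- run_stage("aggregate", aggregate_optimal_ranges(optima))

  bundle <- report_bundle(
    importance, fit$metrics, optima, ranges,
    meta = list(
      n_rows = nrow(ds$features),
      n_missing_cells = sum(ds$missing_mask),
      synthetic = is.null(cfg$dataset),
      synthetic_mode = if (is.null(cfg$dataset)) cfg$synthetic$mode,
      split_seed = cfg$split_seed,
      pso_seed = cfg$pso$seed,
      preprocessing = "box-cox -> soft-impute -> min-max; labels never imputed"
    ))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(ds, file.path(cfg$out_dir, "dataset.csv"))
    write_transform_state(prep$state,
                          file.path(cfg$out_dir, "transform_state.json"))
    for (lab in labs)
      write_surrogate(fit$models[[lab]],
                      file.path(cfg$out_dir, paste0("surrogate_", lab, ".json")))
    write_report(bundle, file.path(cfg$out_dir, "report.json"))
  }
  bundle
}
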