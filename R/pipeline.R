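# End-to-end experiment orchestration: a validated YAML/list
# configuration drives generate-data -> split -> train -> importance ->
# reduce/retrain (-> optional MD), writing every artifact plus a manifest
# with content hashes.

.configSchema <- list(
  name = "character", seed = "integer", output_dir = "character",
  dataset = c("path", "synthetic"),
  split = c("n_train", "n_valid", "n_test"),
  model = c("sigma", "sigma_grid", "lambda"),
  reduction = c("percentiles", "n_importance", "resigma"),
  md = c("run", "dt", "n_steps", "temperature", "friction",
         "external_force_pN", "pull_atoms", "sample_every"),
  synthetic = c("kind", "n_atoms", "temperature", "n_samples", "stride",
                "dt", "friction")
)

.configError <- function(...) {
  stop(structure(class = c("gdmlr_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list against the versioned schema: unknown keys
#' are rejected before any computation, mandatory keys (seed, dataset,
#' split) must be present, and all seeds must be explicit — there is no
#' silent nondeterminism.
#'
#' @param config a named list (e.g. from [yaml::read_yaml()]).
#' @return The normalized config list, invisibly on success; signals a
#'   condition of class `gdmlr_config_error` otherwise.
#' @export
validateConfig <- function(config) {
  if (!is.list(config)) .configError("config must be a named list")
  unknown <- setdiff(names(config), names(.configSchema))
  if (length(unknown))
    .configError("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("seed", "dataset", "split"))
    if (is.null(config[[key]])) .configError("missing config key: ", key)
  if (is.list(config$dataset)) {
    unknown <- setdiff(names(config$dataset), c("path", "synthetic"))
    if (length(unknown))
      .configError("unknown dataset key(s): ",
                   paste(unknown, collapse = ", "))
    if (is.list(config$dataset$synthetic)) {
      unknown <- setdiff(names(config$dataset$synthetic),
                         .configSchema$synthetic)
      if (length(unknown))
        .configError("unknown dataset.synthetic key(s): ",
                     paste(unknown, collapse = ", "))
    }
  }
  for (sect in c("split", "model", "reduction", "md")) {
    if (!is.null(config[[sect]])) {
      unknown <- setdiff(names(config[[sect]]), .configSchema[[sect]])
      if (length(unknown))
        .configError("unknown ", sect, " key(s): ",
                     paste(unknown, collapse = ", "))
    }
  }
  invisible(config)
}

.logmsg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full train/reduce/analyze pipeline from a configuration
#'
#' Executes, in order: dataset loading or synthetic generation, splitting,
#' reference-model training (with grid length-scale selection when a
#' `sigma_grid` is configured), masking-loss computation, reduction and
#' retraining at every configured percentile, and optionally a stability MD
#' run with the most reduced model.  Every artifact (dataset container,
#' model archives, importance TSV, masks, reduction-curve TSV, trajectory
#' log) is written under the output directory, and a JSON manifest lists
#' each file with its md5 content hash plus summary metrics.  Reruns with
#' an identical configuration reproduce all deterministic artifacts
#' bit-exactly.
#'
#' @param config configuration list or path to a YAML file (see the
#'   vignette for the schema).
#' @param outputDir overrides `output_dir` from the config.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validateConfig(config)
  out <- outputDir %||% config$output_dir %||% .configError(
    "no output directory configured")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  artifacts <- character(0)
  metrics <- list()

  .logmsg("pipeline start (seed ", seed, ") -> ", out)
  if (!is.null(config$dataset$path)) {
    dataset <- readDataset(config$dataset$path)
  } else if (!is.null(config$dataset$synthetic)) {
    sy <- config$dataset$synthetic
    topo <- buildToyMolecule(sy$kind %||% "chain",
                             sy$n_atoms %||% 10L, seed = seed)
    dataset <- generateDataset(topo,
                               temperature = sy$temperature %||% 300,
                               nSamples = sy$n_samples %||% 150L,
                               stride = sy$stride %||% 100L,
                               dt = sy$dt %||% 1,
                               friction = sy$friction %||% 0.02,
                               seed = seed)
  } else .configError("dataset must give a path or a synthetic spec")
  dsPath <- file.path(out, "dataset.rds")
  writeDataset(dataset, dsPath)
  artifacts <- c(artifacts, dsPath)
  .logmsg("dataset: ", nFrames(dataset), " frames of ", nAtoms(dataset),
          " atoms")

  splits <- splitDataset(dataset, config$split$n_train,
                         config$split$n_valid,
                         config$split$n_test %||% NA, seed = seed)
  spec <- descriptorSpec(nAtoms(dataset))
  lambda <- config$model$lambda %||% 1e-10

  if (!is.null(config$model$sigma_grid)) {
    sel <- selectSigma(dataset, splits, spec,
                       as.numeric(config$model$sigma_grid), lambda)
    model <- sel$model
  } else {
    model <- trainGDML(dataset, splits$train, spec,
                       sigma = config$model$sigma, lambda = lambda)
  }
  mPath <- file.path(out, "model_global.rds")
  saveGDMLModel(model, mPath)
  artifacts <- c(artifacts, mPath)
  rep0 <- evaluateModel(model, dataset, splits$test)
  metrics$global <- as.list(rep0)
  .logmsg(sprintf("global model: sigma=%.4g, test force RMSE %.4f",
                  model@sigma, rep0$forceRMSE))

  nImp <- config$reduction$n_importance %||% 30L
  impIdx <- splits$test
  if (length(impIdx) > nImp)
    impIdx <- impIdx[round(seq(1, length(impIdx), length.out = nImp))]
  imp <- featureImportance(model, dataset, impIdx)
  st <- featureDistanceStats(dataset, spec)
  impPath <- file.path(out, "importance.tsv")
  exportImportance(imp, spec, impPath, stats = st)
  artifacts <- c(artifacts, impPath)

  percentiles <- config$reduction$percentiles %||% c(0, 50)
  resigma <- config$reduction$resigma %||% TRUE
  curve <- data.frame()
  lastModel <- model
  for (p in percentiles) {
    if (p == 0) {
      row <- data.frame(percentile = 0, fractionKept = 1,
                        nFeatures = sum(spec@active),
                        energyRMSE = rep0$energyRMSE,
                        forceRMSE = rep0$forceRMSE,
                        nTrain = length(splits$train))
    } else {
      rr <- reduceAndRetrain(model, dataset, splits, p, importance = imp,
                             resigma = resigma, lambda = lambda)
      mp <- file.path(out, sprintf("model_p%02d.rds", as.integer(p)))
      saveGDMLModel(rr$model, mp)
      kp <- file.path(out, sprintf("mask_p%02d.json", as.integer(p)))
      writeMask(rr$model@spec, kp)
      artifacts <- c(artifacts, mp, kp)
      row <- data.frame(percentile = p,
                        fractionKept = length(rr$kept) / sum(spec@active),
                        nFeatures = length(rr$kept),
                        energyRMSE = rr$report$energyRMSE,
                        forceRMSE = rr$report$forceRMSE,
                        nTrain = length(splits$train))
      lastModel <- rr$model
      .logmsg(sprintf("p=%g: kept %d features, test force RMSE %.4f",
                      p, length(rr$kept), rr$report$forceRMSE))
    }
    curve <- rbind(curve, row)
  }
  cPath <- file.path(out, "reduction_curve.tsv")
  utils::write.table(curve, cPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts <- c(artifacts, cPath)
  metrics$curve <- curve

  if (isTRUE(config$md$run)) {
    if (!is.null(config$dataset$synthetic)) {
      topoMD <- buildToyMolecule(config$dataset$synthetic$kind %||% "chain",
                                 config$dataset$synthetic$n_atoms %||% 10L,
                                 seed = seed)
    } else topoMD <- NULL
    ext <- if (!is.null(config$md$external_force_pN))
      list(atoms = config$md$pull_atoms %||% c(1L, nAtoms(dataset)),
           pN = config$md$external_force_pN)
    traj <- runMD(lastModel, getConfig(dataset, splits$test[1]),
                  mode = "langevin", dt = config$md$dt %||% 0.5,
                  nSteps = config$md$n_steps %||% 10000L,
                  temperature = config$md$temperature %||% 300,
                  friction = config$md$friction %||% 0.01,
                  externalForce = ext, seed = seed,
                  sampleEvery = config$md$sample_every %||% 50L)
    tPath <- file.path(out, "trajectory.xyz")
    writeTrajectory(traj, tPath)
    artifacts <- c(artifacts, tPath, paste0(tPath, ".tsv"))
    if (!is.null(topoMD)) {
      ev <- detectInstability(traj, topoMD)
      metrics$md <- list(nSamples = length(traj@times),
                         nEvents = nrow(ev),
                         meanRg = mean(traj@rg))
    }
  }

  manifest <- list(
    schema = "gdmlr-manifest-1",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    rVersion = R.version.string,
    packageVersion = as.character(utils::packageVersion("gdmlr")),
    files = lapply(artifacts, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))),
    metrics = metrics)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .logmsg("pipeline complete: ", length(artifacts), " artifacts")
  invisible(manifest)
}
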