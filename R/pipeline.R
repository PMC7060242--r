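# End-to-end pipeline: simulate -> split -> train -> score -> evaluate
# (-> dose-response), driven by one config, with seed control and a
# machine-readable run log.

#' Build the parameter objects of a run configuration
#'
#' Accepts a nested list (or a YAML file path) and validates every stage's
#' parameters before any compute: simulator parameters, design table,
#' split fractions, model spec and training configuration. A configuration
#' that references an external manifest must point at an existing file.
#'
#' @param config list or YAML path.
#' @return list with validated \code{params}, \code{design},
#'   \code{splitSpec}, \code{spec}, \code{trainConfig}, \code{plateSize},
#'   and the raw config.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$sim) && is.null(config$manifest))
    stop("config error: neither a 'sim' block nor a 'manifest' path given")
  if (!is.null(config$manifest) && !file.exists(config$manifest))
    stop("config error: manifest path does not exist: ", config$manifest)
  params <- NULL
  design <- NULL
  if (!is.null(config$sim)) {
    params <- do.call(simParams, config$sim$params %||% list())
    validObject(params)
    if (is.null(config$sim$design))
      stop("config error: sim block lacks a design table")
    design <- do.call(rbind, lapply(config$sim$design, function(row)
      as.data.frame(row, stringsAsFactors = FALSE)))
  }
  sSpec <- do.call(splitSpec, config$split %||% list())
  mSpec <- do.call(modelSpec, lapply(config$model %||% list(), function(x)
    if (is.numeric(x)) as.integer(x) else x))
  tConf <- do.call(trainConfig, config$train %||% list())
  validObject(sSpec); validObject(mSpec); validObject(tConf)
  list(params = params, design = design, splitSpec = sSpec, spec = mSpec,
       trainConfig = tConf, plateSize = config$sim$plateSize %||% 16L,
       raw = config)
}

#' Run the full pipeline from one configuration
#'
#' Chains simulation, plate-stratified splitting, training, scoring and
#' evaluation (plus dose-response analysis when drug-treated wells exist)
#' into one reproducible artifact directory: \code{images/},
#' \code{manifests/}, \code{checkpoints/}, \code{reports/} and
#' \code{run_log.json} capturing the config hash, seed, package version
#' and stage timings. A failure in any stage aborts with the stage name
#' and cause. Identical (config, seed) reruns produce identical reports.
#'
#' @param config list or YAML path, see [validateRunConfig()].
#' @param outDir artifact directory.
#' @param seed global seed; every stochastic stage derives its own stream
#'   from it.
#' @return list with the trained model, variant summaries, evaluation
#'   report and (optionally) dose series; written artifacts under
#'   \code{outDir}.
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
  cfg <- validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = seed, config_hash = objectHash(cfg$raw),
              package_version = as.character(utils::packageVersion(
                "pathscore")),
              r_version = R.version.string, stages = list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2))
    res
  }

  ds <- stage("simulate", {
    if (!is.null(cfg$params)) {
      generateExperiment(cfg$design, cfg$params,
                         seed = deriveSeed(seed, 11L), outDir = outDir,
                         plateSize = cfg$plateSize)
    } else {
      wellDataset(cfg$raw$manifest)
    }
  })

  splits <- stage("split", {
    sSpec <- cfg$splitSpec
    sSpec@seed <- deriveSeed(seed, 22L)
    sp <- splitByPlate(ds, sSpec)
    dir.create(file.path(outDir, "manifests"), showWarnings = FALSE)
    writeSplit(sp, file.path(outDir, "manifests", "splits.csv"))
    sp
  })

  model <- stage("train", {
    tc <- cfg$trainConfig
    tc@seed <- deriveSeed(seed, 33L)
    # activation-head training uses only WT / activating wells
    tr <- splits$train; va <- splits$val
    if (cfg$spec@head == "activation") {
      keepCls <- c("WT", "activating")
      tr@manifest <- tr@manifest[
        tr@manifest$annotation_class %in% keepCls, , drop = FALSE]
      va@manifest <- va@manifest[
        va@manifest$annotation_class %in% keepCls, , drop = FALSE]
    }
    m <- trainModel(cfg$spec, tr, va, tc)
    saveModel(m, file.path(outDir, "checkpoints", "model.rds"))
    write.csv(m@history, file.path(outDir, "checkpoints", "history.csv"),
              row.names = FALSE)
    m
  })

  scored <- stage("score", {
    sc <- scoreImages(model, splits$test)
    summ <- summarizeVariants(sc, splits$test@manifest)
    dir.create(file.path(outDir, "reports"), showWarnings = FALSE)
    write.csv(summ, file.path(outDir, "reports", "variant_summary.csv"),
              row.names = FALSE)
    write.csv(classBreakdown(summ),
              file.path(outDir, "reports", "class_breakdown.csv"),
              row.names = FALSE)
    list(scores = sc, summaries = summ)
  })

  report <- stage("evaluate", {
    rep <- evalReport(scored$scores, splits$test@manifest)
    jsonlite::write_json(
      list(perGene = rep$perGene, meanAuc = rep$meanAuc,
           meanAccuracy = rep$meanAccuracy,
           confusion = as.data.frame(rep$confusion)),
      file.path(outDir, "reports", "evaluation.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(rep$perGene,
              file.path(outDir, "reports", "per_gene_metrics.csv"),
              row.names = FALSE)
    rep
  })

  doseSeries <- NULL
  man <- splits$test@manifest
  if (any(!is.na(man$drug) & nzchar(as.character(man$drug)))) {
    doseSeries <- stage("dose-response", {
      dsr <- buildDoseSeries(scored$scores, man)
      write.csv(dsr, file.path(outDir, "reports", "dose_response.csv"),
                row.names = FALSE)
      dsr
    })
  }

  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, summaries = scored$summaries,
                 report = report, doseSeries = doseSeries,
                 splits = splits))
}

#' A minimal smoke-test run configuration
#'
#' Sixteen tiny wells at 128 x 128 with a single-scale spec and two epochs:
#' exercises every pipeline stage in well under a minute.
#'
#' @return a nested config list for [runPipeline()].
#' @export
smokeRunConfig <- function() {
  list(
    sim = list(
      params = list(fovSize = 128L, meanCells = 15, sdCells = 2,
                    nucleusRadiusRange = c(4, 7)),
      plateSize = 4L,
      design = list(
        list(gene = "KRAS", variant = "WT", annotation_class = "WT",
             alpha = 0.05, n_wells = 8L),
        list(gene = "KRAS", variant = "G12D",
             annotation_class = "activating", alpha = 0.9, n_wells = 8L))),
    split = list(fractions = c(0.5, 0.25, 0.25)),
    model = list(scales = 128L, patch = 128L, filters = c(4L, 8L),
                 fcWidths = c(16L), nGenes = 2L),
    train = list(batchSize = 4L, maxEpochs = 2L))
}
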