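.pipelineStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = unique(c("PipelineError", setdiff(class(e), "condition")))))
  })
}

.specFromConfig <- function(p, seed, idx) {
  base <- silhouetteParams()
  num <- function(key, default)
    if (!is.null(p[[key]])) as.numeric(unlist(p[[key]])) else default
  params <- silhouetteParams(
    imageSize = num("image_size", base@imageSize),
    somaRadius = num("soma_radius", base@somaRadius),
    nPrimary = num("n_primary", base@nPrimary),
    branchProb = num("branch_prob", base@branchProb),
    segmentLength = num("segment_length", base@segmentLength),
    tortuosity = num("tortuosity", base@tortuosity),
    thickness = num("thickness", base@thickness))
  populationSpec(nCells = p$n_cells, params = params,
                 label = unlist(p$label), seed = .childSeed(seed, idx))
}

#' Run the full analysis pipeline
#'
#' Executes feature extraction, population distances, supervised
#' classification and classical inference in order, writing every artifact to
#' the configured output directory:
#' `features.csv`, `md_matrix.csv`, `emd_signed.csv`,
#' `classifier_report.json`, `confusion_matrix.csv`, `anova_tukey.csv` and an
#' append-only `run_log.txt` carrying the package version, the seed and an
#' MD5 hash of the configuration. The seed propagates to every stochastic
#' stage, so identical config + seed gives identical artifacts.
#'
#' @param config a named list or the path of a YAML file with entries:
#'   `seed`, `output_dir`, `grouping` (label column to analyze and predict),
#'   optional `normalize` (default `TRUE`), one input source — either
#'   `input: features_csv:` / `input: label_images: [...], metadata_csv:` or
#'   `simulate: populations: [...]` (each population: `n_cells`, `label:`
#'   map, and any [silhouetteParams()] field in snake_case) — plus optional
#'   `scheme:` (`repeats`, `train_fraction`), `oversampler:`
#'   (`balance_ratio`, `sd_max_fraction`), `forest:` (`num_trees`, `mtry`)
#'   and `importance` (logical, default `TRUE`).
#' @return Invisibly, a list with the computed objects (`features`, `md`,
#'   `report`, `importance`, `stats`) and `paths` of all written artifacts.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    cfgPath <- config
    config <- yaml::read_yaml(config)
  } else {
    cfgPath <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, cfgPath)
  }
  if (is.null(config$output_dir))
    .amStop("SchemaError", "config entry 'output_dir' is required")
  if (is.null(config$grouping))
    .amStop("SchemaError", "config entry 'grouping' is required")
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  outDir <- config$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- unname(tools::md5sum(cfgPath))
  grouping <- config$grouping
  normalize <- if (!is.null(config$normalize)) isTRUE(config$normalize) else TRUE

  ft <- .pipelineStage("features", {
    if (!is.null(config$input$features_csv)) {
      readFeatureTable(config$input$features_csv)
    } else if (!is.null(config$input$label_images)) {
      md <- if (!is.null(config$input$metadata_csv))
        read.csv(config$input$metadata_csv, stringsAsFactors = FALSE) else NULL
      masks <- unlist(lapply(config$input$label_images, function(pth)
        masksFromLabels(readLabelImage(pth),
                        imageId = tools::file_path_sans_ext(basename(pth)),
                        metadata = md)), recursive = FALSE)
      suppressWarnings(computeFeatureTable(masks))
    } else if (!is.null(config$simulate$populations)) {
      pops <- config$simulate$populations
      suppressWarnings(generatePopulations(
        lapply(seq_along(pops), function(i)
          .specFromConfig(pops[[i]], seed, i))))
    } else {
      .amStop("SchemaError",
              "config must provide input$features_csv, input$label_images or simulate$populations")
    }
  })
  if (!grouping %in% colnames(cellData(ft)))
    .amStop("SchemaError", "label column '%s' missing from the feature table",
            grouping)

  paths <- list(features = file.path(outDir, "features.csv"))
  writeFeatureTable(ft, paths$features)

  dist <- .pipelineStage("distance", {
    md <- suppressWarnings(mdMatrix(ft, grouping, normalize = normalize))
    emd <- suppressWarnings(signedEmdTable(ft, grouping, normalize = normalize))
    list(md = md, emd = emd)
  })
  paths$md_matrix <- file.path(outDir, "md_matrix.csv")
  write.csv(mdValues(dist$md), paths$md_matrix)
  paths$emd_signed <- file.path(outDir, "emd_signed.csv")
  write.csv(cbind(feature = rownames(dist$emd), dist$emd),
            paths$emd_signed, row.names = FALSE)

  scheme <- splitScheme(
    trainFraction = config$scheme$train_fraction %||% 0.7,
    repeats = config$scheme$repeats %||% 10L,
    seed = .childSeed(seed, 1001L))
  overs <- oversamplerConfig(
    balanceRatio = config$oversampler$balance_ratio %||% 0.9,
    sdMaxFraction = config$oversampler$sd_max_fraction %||% (1 / 3),
    seed = .childSeed(seed, 1002L))
  numTrees <- config$forest$num_trees %||% 500
  mtry <- config$forest$mtry
  cls <- .pipelineStage("classify", {
    report <- repeatedEvaluate(ft, grouping, scheme, overs,
                               numTrees = numTrees, mtry = mtry)
    imp <- if (config$importance %||% TRUE)
      mdaImportance(ft, grouping, scheme, overs, numTrees = numTrees,
                    mtry = mtry) else NULL
    list(report = report, importance = imp)
  })
  paths$classifier_report <- file.path(outDir, "classifier_report.json")
  rep <- cls$report
  jsonlite::write_json(list(
    grouping = grouping, seed = seed, config_md5 = cfgHash,
    accuracies = rep@accuracies,
    mean_accuracy = mean(rep@accuracies), sd_accuracy = sd(rep@accuracies),
    baseline_accuracy = mean(rep@baselineAccuracies),
    class_metrics = rep@classMetrics,
    importance = cls$importance
  ), paths$classifier_report, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths$confusion <- file.path(outDir, "confusion_matrix.csv")
  write.csv(pooledConfusion(rep), paths$confusion)

  st <- .pipelineStage("stats", anovaTukey(ft, grouping))
  paths$anova_tukey <- file.path(outDir, "anova_tukey.csv")
  writeAnovaTukey(st, paths$anova_tukey)

  paths$log <- file.path(outDir, "run_log.txt")
  cat(sprintf("[%s] astromorph %s seed=%d config_md5=%s grouping=%s cells=%d\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              as.character(utils::packageVersion("astromorph")), seed, cfgHash,
              grouping, ncol(ft)),
      file = paths$log, append = TRUE)
  invisible(list(features = ft, md = dist$md, emd = dist$emd,
                 report = cls$report, importance = cls$importance, stats = st,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
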