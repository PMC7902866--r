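.FEATURE_SETS <- c("mc", "gmv", "gmv_mc")
.THRESHOLDS <- c("laser", "cold", "score")
.CFG_KEYS <- c("simulate", "input", "threshold", "feature_set", "mode",
               "schedule", "metric", "pls", "seed", "out_dir")
.SIM_KEYS <- c("n_participants", "n_rois", "n_voxels", "subject_sd",
               "roi_mean_base", "roi_sigma_base", "n_planted_edges",
               "planted_r2", "noise_sd")
.PLS_KEYS <- c("l_max", "criterion", "target", "threshold")

#' Validate and default a pipeline run configuration
#'
#' Accepts a YAML/JSON file path or a list. Recognized keys: `simulate`
#' (synthetic-cohort parameters) or `input` (paths `samples_tsv`,
#' `phenotypes_csv`, `parcellation_csv`), `threshold` (one of laser, cold,
#' score), `feature_set` (mc, gmv, gmv_mc), `mode` (group_level, nested),
#' `schedule`, `metric`, `pls` (l_max, criterion, target, threshold),
#' `seed`, `out_dir`. Unknown keys are rejected; defaults are filled in.
#'
#' @param config file path or list
#' @return validated config list (class `"painMCRunConfig"`)
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  unknown <- setdiff(names(config), .CFG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- config
  cfg$threshold <- cfg$threshold %||% "laser"
  if (length(cfg$threshold) != 1 || !cfg$threshold %in% .THRESHOLDS)
    stop("threshold: exactly one of ", paste(.THRESHOLDS, collapse = ", "))
  cfg$feature_set <- cfg$feature_set %||% "mc"
  if (!cfg$feature_set %in% .FEATURE_SETS)
    stop("feature_set must be one of: ", paste(.FEATURE_SETS, collapse = ", "))
  cfg$mode <- cfg$mode %||% "group_level"
  if (!cfg$mode %in% c("group_level", "nested"))
    stop("mode must be group_level or nested")
  cfg$metric <- cfg$metric %||% "mae"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% tempfile("painmc_run_")
  if (!is.null(cfg$schedule)) {
    s <- as.integer(unlist(cfg$schedule))
    if (length(s) < 1 || any(diff(s) >= 0) || s[length(s)] != 1)
      stop("schedule must be strictly decreasing and end at 1")
    cfg$schedule <- s
  }
  pls <- cfg$pls %||% list()
  unknown <- setdiff(names(pls), .PLS_KEYS)
  if (length(unknown)) stop("unknown pls key(s): ", paste(unknown, collapse = ", "))
  pls$l_max <- pls$l_max %||% 10L
  pls$criterion <- pls$criterion %||% "r2target"
  pls$target <- pls$target %||% 0.95
  pls$threshold <- pls$threshold %||% 0.01
  cfg$pls <- pls
  if (is.null(cfg$input)) {
    sim <- cfg$simulate %||% list()
    unknown <- setdiff(names(sim), .SIM_KEYS)
    if (length(unknown))
      stop("unknown simulate key(s): ", paste(unknown, collapse = ", "))
    sim$n_participants <- sim$n_participants %||% 60L
    sim$n_rois <- sim$n_rois %||% 20L
    sim$n_voxels <- sim$n_voxels %||% 300L
    sim$n_planted_edges <- sim$n_planted_edges %||% 10L
    sim$planted_r2 <- sim$planted_r2 %||% 0.6
    cfg$simulate <- sim
  } else {
    need <- c("samples_tsv", "phenotypes_csv", "parcellation_csv")
    if (!all(need %in% names(cfg$input)))
      stop("input needs paths: ", paste(need, collapse = ", "))
    for (p in unlist(cfg$input[need]))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  class(cfg) <- "painMCRunConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(...) message("[painMC] ", ...)

.cohortFromConfig <- function(cfg) {
  if (!is.null(cfg$input)) {
    parc <- loadParcellation(cfg$input$parcellation_csv)
    samples <- readROISamplesTSV(cfg$input$samples_tsv, parc)
    phenotypes <- utils::read.csv(cfg$input$phenotypes_csv,
                                  stringsAsFactors = FALSE)
    return(list(samples = samples, phenotypes = phenotypes, truth = NULL,
                parc = parc))
  }
  sim <- cfg$simulate
  k <- as.integer(sim$n_planted_edges)
  spec <- cohortSpec(
    nParticipants = sim$n_participants, nRois = sim$n_rois,
    nVoxels = sim$n_voxels,
    roiMeanBase = sim$roi_mean_base %||% seq(0.35, 0.75,
                                             length.out = sim$n_rois),
    subjectSd = sim$subject_sd %||% 0.03,
    roiSigmaBase = sim$roi_sigma_base %||% seq(0.07, 0.13,
                                               length.out = sim$n_rois),
    plantedEdges = cbind(seq(1L, by = 2L, length.out = k),
                         seq(2L, by = 2L, length.out = k)),
    plantedR2 = sim$planted_r2,
    noiseSd = sim$noise_sd %||% c(1, 1),
    seed = .stageSeed(cfg$seed, "simulate"))
  gen <- generateCohort(spec)
  gen$parc <- parcellation(gen$samples)
  gen
}

#' Run the full prediction pipeline
#'
#' Stages: obtain the cohort (simulate or load) -> pain scores -> features
#' (GMV and/or MC) -> coefficient-ranked feature selection with the chosen
#' mode -> leave-one-out evaluation -> reports and a run manifest, all under
#' `config$out_dir`. Identical config + seed reproduces identical outputs.
#'
#' @param config a path/list accepted by [validateRunConfig()]
#' @return the evaluation report (invisibly also written to disk), with the
#'   manifest path in `$manifest`
#' @export
runPipeline <- function(config) {
  cfg <- if (inherits(config, "painMCRunConfig")) config
  else validateRunConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  data <- .cohortFromConfig(cfg)
  parc <- data$parc
  .log("cohort: ", length(participants(data$samples)), " participants x ",
       nRois(parc), " ROIs")
  ph <- computePainScores(data$phenotypes)
  y <- switch(cfg$threshold,
              laser = ph$laser_threshold_J,
              cold = ph$cold_threshold_s,
              score = ph$pain_sensitivity_score)
  names(y) <- ph$participant_id

  gmv <- computeGMV(data$samples)
  nMC <- 0L
  if (cfg$feature_set %in% c("mc", "gmv_mc")) {
    se <- buildCohortMC(data$samples, phenotypes = ph)
    mc <- mcFeatureMatrix(se)
    nMC <- ncol(mc)
  }
  X <- switch(cfg$feature_set,
              mc = mc,
              gmv = gmv,
              gmv_mc = cbind(gmv, mc))
  X <- X[ph$participant_id, , drop = FALSE]
  .log("feature set '", cfg$feature_set, "': ", ncol(X), " features")

  sel <- selectFeatures(X, y, mode = cfg$mode, schedule = cfg$schedule,
                        metric = cfg$metric, LMax = cfg$pls$l_max,
                        criterion = cfg$pls$criterion,
                        target = cfg$pls$target,
                        threshold = cfg$pls$threshold)
  .log("selection (", cfg$mode, "): m* = ", sel@mStar)
  rep <- evaluatePrediction(predictions(sel), y,
                            featureSet = cfg$feature_set,
                            thresholdType = cfg$threshold, mode = cfg$mode)
  .log(sprintf("MAE %.4g  MRAE %s  r %.3f", rep$mae,
               ifelse(is.na(rep$mrae), "NA", sprintf("%.4g", rep$mrae)),
               rep$pearson_r))

  od <- cfg$out_dir
  utils::write.csv(rep$per_participant,
                   file.path(od, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(rep[setdiff(names(rep), "per_participant")],
                       file.path(od, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeSelectionJSON(sel, file.path(od, "selection.json"))
  if (cfg$feature_set == "mc" && length(sel@indices)) {
    lp <- lobePairCounts(sel, parc)
    utils::write.csv(lp, file.path(od, "lobe_pairs.csv"), row.names = FALSE)
  }
  outs <- list.files(od, full.names = TRUE)
  outs <- outs[basename(outs) != "manifest.json"]
  manifest <- list(
    package = "painMC",
    version = as.character(utils::packageVersion("painMC")),
    seed = cfg$seed,
    config = unclass(cfg),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = as.list(tools::md5sum(sort(outs))))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  rep$selection <- sel
  rep$manifest <- file.path(od, "manifest.json")
  invisible(rep)
}

#' Sweep the 3 feature sets x 3 threshold types
#'
#' Runs [runPipeline()] for every combination of feature set (gmv, mc,
#' gmv_mc) and threshold (laser, cold, score), each in its own subdirectory
#' of `out_dir`, and writes a summary CSV of MAE/MRAE/r.
#'
#' @param config base config (feature_set/threshold are overridden)
#' @return data.frame summary, one row per combination
#' @export
runSweep <- function(config) {
  cfg <- if (inherits(config, "painMCRunConfig")) config
  else validateRunConfig(config)
  base <- cfg$out_dir
  rows <- list()
  for (fs in .FEATURE_SETS) for (th in .THRESHOLDS) {
    ci <- cfg
    ci$feature_set <- fs
    ci$threshold <- th
    ci$out_dir <- file.path(base, paste(fs, th, sep = "_"))
    rep <- runPipeline(ci)
    rows[[paste(fs, th)]] <- data.frame(
      feature_set = fs, threshold = th, mae = rep$mae, mrae = rep$mrae,
      pearson_r = rep$pearson_r, n = rep$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, file.path(base, "sweep_summary.csv"),
                   row.names = FALSE)
  out
}
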