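## End-to-end orchestration: simulate -> preprocess -> telomere -> clock ->
## associations (+ sensitivity) -> enrichment, with a deterministic manifest.

#' Configuration for an end-to-end pipeline run
#'
#' @param output_dir directory for all stage outputs
#' @param sim a [simConfig()] for fixture generation, or `NULL` when reading
#'   a previously written fixture directory
#' @param input_dir fixture directory (used when `sim` is `NULL`)
#' @param stages stages to execute, in dependency order
#' @param seed seed for imputation and clock fold assignment
#' @param folds CV folds for clock tuning
#' @param gmt optional path to a GMT collection for the enrichment stage
#' @param sensitivity run the sensitivity-analysis suite in the associate
#'   stage
#' @param covariates adjustment set for all association models
#' @return a validated list of class `"RunConfig"`
#' @export
runConfig <- function(output_dir,
                      sim = simConfig(),
                      input_dir = NULL,
                      stages = c("simulate", "preprocess", "telomere",
                                 "clock", "associate", "enrich"),
                      seed = 1L, folds = 10, gmt = NULL,
                      sensitivity = FALSE,
                      covariates = c("age", "sex", "ethnicity", "centre")) {
  stages <- match.arg(stages, several.ok = TRUE,
                      choices = c("simulate", "preprocess", "telomere",
                                  "clock", "associate", "enrich"))
  if (!"simulate" %in% stages) {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("stage 'simulate' disabled but no readable input_dir supplied")
  } else if (is.null(sim)) {
    stop("stage 'simulate' enabled but no sim config supplied")
  }
  if ("enrich" %in% stages && !is.null(gmt) && !file.exists(gmt))
    stop("gmt file does not exist: ", gmt)
  structure(list(output_dir = output_dir, sim = sim, input_dir = input_dir,
                 stages = stages, seed = as.integer(seed), folds = folds,
                 gmt = gmt, sensitivity = isTRUE(sensitivity),
                 covariates = covariates),
            class = "RunConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [runConfig()]; a `sim:` mapping is
#' passed to [simConfig()].
#'
#' @param path YAML file
#' @return a `"RunConfig"`
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$block_sizes)) y$sim$block_sizes <- unlist(y$sim$block_sizes)
    if (!is.null(y$sim$block_kinds)) y$sim$block_kinds <- unlist(y$sim$block_kinds)
    if (!is.null(y$sim$n_age_features))
      y$sim$n_age_features <- unlist(y$sim$n_age_features)
    if (!is.null(y$sim$delta_age_outcome_effects))
      y$sim$delta_age_outcome_effects <- unlist(y$sim$delta_age_outcome_effects)
    y$sim <- do.call(simConfig, y$sim)
  }
  do.call(runConfig, y)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order, writing per-stage
#' outputs under `output_dir`: fixtures, QC reports (JSON), the telomere
#' results CSV, the serialized clock and its predictions, the association
#' results (tidy CSV, one row per model) with BH q-values across the primary
#' family, a marker-by-outcome summary grid, optional enrichment results,
#' and a manifest (JSON; versions, seeds, row counts, selected alpha/lambda,
#' validation metrics). Any stage error halts the run naming the stage.
#'
#' @param config a [runConfig()] (or path to a YAML accepted by
#'   [readRunConfig()])
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("omicage")),
                   seed = config$seed, stages = config$stages)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\nreproduce with: runPipeline(<this config>) after fixing inputs",
           call. = FALSE)
    })
  }

  ## simulate or load
  study <- stage("simulate", {
    if ("simulate" %in% config$stages) {
      st <- generateStudy(config$sim)
      writeFixtures(st, file.path(config$output_dir, "fixtures"))
      manifest$simulate <- list(n_children = nrow(studyCohort(st)),
                                blocks = names(studyBlocks(st)),
                                sim_seed = config$sim$seed)
      st
    } else readStudy(config$input_dir)
  })
  cohort <- studyCohort(study)

  ## preprocess
  scaled <- scalers <- NULL
  if ("preprocess" %in% config$stages) {
    pp <- stage("preprocess", lapply(studyBlocks(study), preprocessBlock,
                                     impute_seed = config$seed))
    scaled <- lapply(pp, `[[`, "block")
    scalers <- lapply(pp, `[[`, "scaler")
    qc <- lapply(pp, function(z) z$qc)
    jsonlite::write_json(qc, file.path(config$output_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    manifest$preprocess <- lapply(scaled, function(b)
      list(features_kept = nrow(b), samples = ncol(b)))
  }

  ## telomere
  telo <- NULL
  if ("telomere" %in% config$stages) {
    telo <- stage("telomere", relativeTS(studyWells(study)))
    write.csv(telo, file.path(config$output_dir, "telomere.csv"),
              row.names = FALSE)
    manifest$telomere <- list(n = nrow(telo),
                              mean_relative_ts = mean(telo$relative_ts))
  }

  ## clock
  preds <- panel_preds <- NULL
  if ("clock" %in% config$stages) {
    if (is.null(scaled)) stop("pipeline stage 'clock' requires 'preprocess'")
    stage("clock", {
      x <- concatBlocks(scaled)
      model <- tuneClock(x, cohort$age, folds = config$folds,
                         seed = config$seed)
      preds <- predictAges(model, x, cohort$age)
      writeClockModel(model, file.path(config$output_dir, "clock_model.json"))
      write.csv(preds, file.path(config$output_dir, "predictions.csv"),
                row.names = FALSE)
      val <- NULL; prog <- NULL
      pc <- studyPanelCohort(study)
      if (nrow(pc)) {
        ppanel <- lapply(names(studyPanelBlocks(study)), function(lb)
          preprocessBlock(studyPanelBlocks(study)[[lb]],
                          impute_seed = config$seed,
                          scaler = scalers[[lb]])$block)
        names(ppanel) <- names(studyPanelBlocks(study))
        xp <- concatBlocks(ppanel)
        centres <- cohort$centre[match(pc$id, cohort$id)]
        val <- validateClock(model, xp, pc$age, groups = centres)
        panel_preds <- val$predictions
        write.csv(panel_preds,
                  file.path(config$output_dir, "predictions_panel.csv"),
                  row.names = FALSE)
        first <- preds[preds$sample_id %in% pc$id, ]
        prog <- progressionTest(first, panel_preds)
      }
      manifest$clock <- list(
        alpha = clockAlpha(model), lambda = clockLambda(model),
        nonzero = length(clockWeights(model)),
        block_composition = as.list(blockComposition(model)),
        test_r = if (!is.null(val)) val$pearson_r else NA,
        test_mae = if (!is.null(val)) val$mae else NA,
        progression = prog)
    })
  }

  ## associations
  if ("associate" %in% config$stages) {
    stage("associate", {
      deltas <- list()
      if (!is.null(preds)) deltas$immunometabolic <- preds
      if ("epigenetic_age" %in% colnames(cohort))
        deltas$epigenetic <- data.frame(
          sample_id = cohort$id,
          delta_age = cohort$epigenetic_age - cohort$age)
      dat <- prepareMarkers(cohort, telomere = telo, deltas = deltas)
      markers <- c(if (!is.null(telo)) "telomere_shortening",
                   paste0("delta_age_", names(deltas)))
      outcomes <- intersect(c("zBMI", "zHeight", "fat_pct", "dprime",
                              "hrt_se", "cpm", "cbcl_int", "cbcl_ext",
                              "fev1", "puberty"), colnames(dat))
      risks <- intersect(c("birthweight", "gestational_age",
                           "maternal_smoking", "passive_smoke", "kidmed",
                           "fas", "social_capital"), colnames(dat))
      specs <- list()
      for (mk in markers) {
        for (oc in outcomes)
          specs[[length(specs) + 1]] <- associationSpec(
            mk, oc, covariates = config$covariates,
            family = if (oc == "puberty") "logistic" else "linear")
        for (rf in risks)
          specs[[length(specs) + 1]] <- associationSpec(
            rf, mk, covariates = config$covariates)
      }
      res <- do.call(rbind, lapply(specs, runAssociation, data = dat))
      res <- fdrAdjust(res)
      write.csv(res, file.path(config$output_dir, "associations.csv"),
                row.names = FALSE)
      grid <- res[res$outcome %in% outcomes,
                  c("exposure", "outcome", "estimate", "ci_low", "ci_high",
                    "p", "q", "n")]
      write.csv(grid, file.path(config$output_dir, "summary_grid.csv"),
                row.names = FALSE)
      manifest$associate <- list(n_models = nrow(res),
                                  fdr_family_size = nrow(res),
                                  n_fdr_significant = sum(res$q < 0.05))
      if (config$sensitivity) {
        base <- specs[vapply(specs, function(s) s$outcome %in% outcomes,
                             TRUE)]
        sens <- sensitivitySuite(base, dat)
        write.csv(sens$results,
                  file.path(config$output_dir, "associations_sensitivity.csv"),
                  row.names = FALSE)
        manifest$associate$sensitivity_models <- nrow(sens$results)
        manifest$associate$sensitivity_skipped <- length(sens$skipped)
      }
    })
  }

  ## enrichment
  if ("enrich" %in% config$stages) {
    if (is.null(config$gmt)) {
      manifest$enrich <- list(skipped = "no GMT collection supplied")
    } else {
      stage("enrich", {
        collection <- readGmt(config$gmt)
        model <- readClockModel(file.path(config$output_dir,
                                          "clock_model.json"))
        universe <- model@features
        ora <- oraCollection(names(clockWeights(model)), collection, universe)
        write.csv(ora, file.path(config$output_dir, "enrichment.csv"),
                  row.names = FALSE)
        manifest$enrich <- list(n_sets = nrow(ora),
                                 n_significant = sum(ora$significant))
      })
    }
  }

  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
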