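#' OmicsBlock: one omic feature block with assay metadata
#'
#' A thin subclass of [SummarizedExperiment::SummarizedExperiment] holding one
#' samples-by-features omic block in Bioconductor orientation (features as
#' rows, samples as columns). The `"values"` assay carries measurements
#' (censored cells are `NA`); the `"censored"` assay carries integer flags
#' (0 in range, -1 below LOQ1, +1 above LOQ2). Per-feature assay metadata
#' (block label, kind, LOD, LOQ1, LOQ2, CV%, call rate) lives in `rowData`;
#' per-sample metadata (plate) in `colData`. `metadata(x)$log2` records
#' whether values (and LOQ bounds) are on the log2 scale.
#'
#' @seealso [OmicsBlock()] for the constructor, [omicsValues()],
#'   [featureMeta()], [censorFlags()]
#' @export
setClass("OmicsBlock", contains = "SummarizedExperiment")

setValidity("OmicsBlock", function(object) {
  msg <- character()
  if (!"values" %in% assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  need <- c("block", "kind", "lod", "loq1", "loq2", "cv_percent", "call_rate")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    msg <- c(msg, paste0("rowData misses column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  rd <- rowData(object)
  if (all(c("loq1", "loq2") %in% colnames(rd))) {
    bad <- !is.na(rd$loq1) & !is.na(rd$loq2) & rd$loq1 > rd$loq2
    if (any(bad)) msg <- c(msg, "LOQ1 > LOQ2 for some features")
  }
  if ("cv_percent" %in% colnames(rd) && any(rd$cv_percent < 0, na.rm = TRUE))
    msg <- c(msg, "negative cv_percent")
  if ("call_rate" %in% colnames(rd) &&
      any(rd$call_rate < 0 | rd$call_rate > 1, na.rm = TRUE))
    msg <- c(msg, "call_rate outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' ClockModel: fitted sparse linear age predictor
#'
#' Holds the elastic-net age clock: sparse weights on the training features,
#' intercept (years), the selected mixing parameter `alpha` and penalty
#' `lambda`, the feature scaler (training means/SDs, reapplied verbatim to any
#' test or follow-up data), the per-block count of nonzero predictors, and the
#' cross-validated MSE path over the (alpha, lambda) grid.
#'
#' @slot weights named numeric, nonzero coefficients only
#' @slot intercept numeric(1), years
#' @slot alpha numeric(1) in [0,1]
#' @slot lambda numeric(1), >= 0
#' @slot features character, all training feature names (model's input contract)
#' @slot scaler list with named numeric `center` and `scale`
#' @slot blockComposition named integer, nonzero predictors per block
#' @slot cvMsePath data.frame with columns alpha, lambda, cvm
#' @export
setClass("ClockModel",
  representation(
    weights = "numeric", intercept = "numeric", alpha = "numeric",
    lambda = "numeric", features = "character", scaler = "list",
    blockComposition = "integer", cvMsePath = "data.frame"))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (length(object@alpha) != 1 || object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be a single value in [0,1]")
  if (length(object@lambda) != 1 || object@lambda < 0)
    msg <- c(msg, "lambda must be a single non-negative value")
  if (!all(names(object@weights) %in% object@features))
    msg <- c(msg, "weights defined outside the training feature set")
  if (length(object@blockComposition) &&
      sum(object@blockComposition) != length(object@weights))
    msg <- c(msg, "blockComposition does not sum to the nonzero count")
  if (length(msg)) msg else TRUE
})

#' SyntheticStudy: a simulated cohort with recorded ground truth
#'
#' Container for one synthetic study: the cohort table (covariates, outcomes,
#' precomputed epigenetic age), the omic blocks, the qPCR well table, the
#' follow-up ("panel") blocks and table for the subset re-examined about half
#' a year later, and the ground truth used to generate everything.
#'
#' @slot cohort data.frame, one row per child
#' @slot blocks named list of [OmicsBlock-class] objects
#' @slot qpcr data.frame of qPCR wells
#' @slot panelBlocks named list of [OmicsBlock-class] (empty if no panel)
#' @slot panelCohort data.frame for the panel visit (ids, ages at follow-up)
#' @slot truth list: true age coefficients, true delta age, outcome effects,
#'   plate assignments, dilution factors, config echo
#' @export
setClass("SyntheticStudy",
  representation(
    cohort = "data.frame", blocks = "list", qpcr = "data.frame",
    panelBlocks = "list", panelCohort = "data.frame", truth = "list"))

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  ids <- object@cohort$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate child ids in cohort")
  for (nm in names(object@blocks)) {
    if (!identical(colnames(object@blocks[[nm]]), as.character(ids)))
      msg <- c(msg, paste0("block '", nm, "' sample ids differ from cohort"))
  }
  if (nrow(object@panelCohort) &&
      !all(object@panelCohort$id %in% ids))
    msg <- c(msg, "panel subset is not a subset of cohort ids")
  if (length(msg)) msg else TRUE
})
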