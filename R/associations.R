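## Covariate-adjusted association framework: marker preparation, linear /
## logistic models, BH FDR across the family, partial correlations, and the
## four sensitivity variants.

#' Assemble the marker/outcome analysis table
#'
#' Joins the biological-age markers onto the cohort table and applies the
#' analysis transforms: relative telomere length is multiplied by -1 (so
#' effects read as SD of telomere *shortening*, directionally consistent
#' with the clocks) and unit-SD scaled; delta-age columns pass through in
#' years; continuous outcomes are mean-centred and unit-scaled except the
#' BMI and height z-scores, which are already on a reference scale; CBCL
#' behaviour scores are log(x+1)-transformed before scaling (they contain
#' zeros).
#'
#' @param cohort cohort data.frame with an `id` column
#' @param telomere optional data.frame from [relativeTS()] (`sample_id`,
#'   `relative_ts`)
#' @param deltas optional named list of prediction data.frames from
#'   [predictAges()]; each adds a `delta_age_<name>` column
#' @param outcomes character vector of outcome columns to transform;
#'   defaults to the generator's outcome set intersected with `cohort`
#' @return data.frame ready for [runAssociation()]
#' @export
prepareMarkers <- function(cohort, telomere = NULL, deltas = NULL,
                           outcomes = NULL) {
  dat <- cohort
  if (!is.null(telomere)) {
    idx <- match(dat$id, telomere$sample_id)
    raw <- telomere$relative_ts[idx]
    s <- sd(raw, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("telomere SD is zero")
    dat$telomere_shortening <- (-1 * raw) / s
  }
  for (nm in names(deltas)) {
    idx <- match(dat$id, deltas[[nm]]$sample_id)
    dat[[paste0("delta_age_", nm)]] <- deltas[[nm]]$delta_age[idx]
  }
  if (is.null(outcomes))
    outcomes <- intersect(c("zBMI", "zHeight", "fat_pct", "dprime", "hrt_se",
                            "cpm", "cbcl_int", "cbcl_ext", "fev1", "puberty"),
                          colnames(dat))
  for (oc in outcomes) {
    if (oc %in% c("zBMI", "zHeight", "puberty")) next  # pass through
    x <- dat[[oc]]
    if (grepl("^cbcl", oc)) x <- log(x + 1)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("outcome '", oc, "' has zero SD")
    dat[[oc]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  dat
}

#' Specify one association model
#'
#' @param exposure name of the exposure column (a biological-age marker for
#'   outcome models; a risk factor when the marker is the dependent variable)
#' @param outcome name of the dependent-variable column
#' @param covariates adjustment set (default: chronological age, sex,
#'   ethnicity, study centre)
#' @param family `"linear"` or `"logistic"`
#' @param stratum optional named list, e.g. `list(sex = "female")`
#' @param extra_covariates optional further adjustment columns
#' @return an object of class `"AssociationSpec"`
#' @export
associationSpec <- function(exposure, outcome,
                            covariates = c("age", "sex", "ethnicity", "centre"),
                            family = c("linear", "logistic"),
                            stratum = NULL, extra_covariates = NULL) {
  family <- match.arg(family)
  if (exposure %in% c(covariates, extra_covariates))
    stop("exposure '", exposure, "' must not appear among the covariates")
  structure(list(exposure = exposure, outcome = outcome,
                 covariates = covariates, family = family,
                 stratum = stratum, extra_covariates = extra_covariates),
            class = "AssociationSpec")
}

#' Run one covariate-adjusted association
#'
#' Fits ordinary least squares (or maximum-likelihood logistic regression
#' for binary outcomes) of the outcome on the exposure plus the adjustment
#' covariates, on complete cases. Returns the exposure coefficient
#' (exponentiated to an odds ratio for logistic models), its Wald 95%
#' confidence interval, two-sided p-value and the analysis n. Perfect
#' separation in logistic models is flagged rather than fatal; collinear
#' covariates raise an error naming the aliased term.
#'
#' @param spec an [associationSpec()]
#' @param data analysis data.frame from [prepareMarkers()]
#' @return one-row data.frame: exposure, outcome, family, stratum, estimate,
#'   ci_low, ci_high, p, n, flagged
#' @export
runAssociation <- function(spec, data) {
  stopifnot(inherits(spec, "AssociationSpec"))
  strat_label <- ""
  if (!is.null(spec$stratum)) {
    for (nm in names(spec$stratum))
      data <- data[!is.na(data[[nm]]) & data[[nm]] == spec$stratum[[nm]], ,
                   drop = FALSE]
    # a stratifying variable is constant within the stratum; drop it
    spec$covariates <- setdiff(spec$covariates, names(spec$stratum))
    strat_label <- paste(names(spec$stratum), unlist(spec$stratum),
                         sep = "=", collapse = ",")
  }
  vars <- c(spec$outcome, spec$exposure, spec$covariates,
            spec$extra_covariates)
  miss <- setdiff(vars, colnames(data))
  if (length(miss))
    stop("column(s) absent from data: ", paste(miss, collapse = ", "))
  dat <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  rhs <- paste(c(spec$exposure, spec$covariates, spec$extra_covariates),
               collapse = " + ")
  # drop factor covariates that are constant on the analysis rows
  for (vv in c(spec$covariates, spec$extra_covariates)) {
    if (length(unique(dat[[vv]])) < 2) {
      rhs <- paste(setdiff(strsplit(rhs, " \\+ ")[[1]], vv), collapse = " + ")
    }
  }
  form <- stats::as.formula(paste(spec$outcome, "~", rhs))
  flagged <- FALSE
  if (spec$family == "logistic") {
    if (!all(dat[[spec$outcome]] %in% c(0, 1)))
      stop("logistic family requires a binary 0/1 outcome")
    fit <- withCallingHandlers(
      glm(form, data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
  } else {
    fit <- lm(form, data = dat)
  }
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased))
    stop("collinear covariates: aliased term(s) ",
         paste(aliased, collapse = ", "))
  sm <- summary(fit)$coefficients
  row <- grep(paste0("^", spec$exposure), rownames(sm))[1]
  if (is.na(row)) stop("exposure term not found in the fitted model")
  est <- sm[row, 1]; se <- sm[row, 2]; p <- sm[row, 4]
  lo <- est - 1.959964 * se; hi <- est + 1.959964 * se
  if (spec$family == "logistic") {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  data.frame(exposure = spec$exposure, outcome = spec$outcome,
             family = spec$family, stratum = strat_label,
             estimate = est, ci_low = lo, ci_high = hi, p = p,
             n = nrow(dat), flagged = flagged)
}

#' Benjamini-Hochberg adjustment across the association family
#'
#' Fills the `q` column with step-up BH q-values computed across the whole
#' family of supplied results (the primary associations pooled together;
#' sensitivity variants are excluded by convention).
#'
#' @param results data.frame of stacked [runAssociation()] rows
#' @return the same data.frame with a `q` column
#' @export
fdrAdjust <- function(results) {
  if (!nrow(results)) stop("empty association family")
  results$q <- p.adjust(results$p, method = "BH")
  results
}

#' Partial correlation with covariate adjustment
#'
#' Residualises `x` and `y` on the covariate model matrix (categorical
#' covariates become indicator columns) and reports the Pearson correlation
#' of the residuals, with a t-based p-value on `n - 2 - k` degrees of
#' freedom where `k` is the number of covariate model columns.
#'
#' @param x,y numeric vectors
#' @param covariates data.frame of adjustment variables (may be empty)
#' @return list: `r`, `p`, `n`, `df`
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- 0L
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
    mm <- model.matrix(~ ., data = covariates)
    k <- ncol(mm) - 1L
    if (n <= k + 2) stop("need n > covariate count + 2")
    x <- resid(lm.fit(mm, x))
    y <- resid(lm.fit(mm, y))
  }
  if (sd(x) == 0 || sd(y) == 0) stop("zero residual variance")
  r <- cor(x, y)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), n = n, df = df)
}

#' Run the sensitivity-analysis suite
#'
#' Re-runs every base association under the four variants: stratification by
#' sex, adjustment for estimated cell-count fractions, adjustment for
#' associated health risk factors, and stratification by study centre.
#' Stratified fits retain the remaining covariates; extended fits append
#' covariates. Strata with too few rows for the model are skipped with a
#' log entry.
#'
#' @param base_specs list of [associationSpec()] objects
#' @param data analysis data.frame
#' @param cell_columns columns holding cell fractions
#' @param risk_columns risk-factor adjustment columns
#' @param variants which variants to run
#' @return list: `results` (data.frame keyed by spec and variant) and
#'   `skipped` (character log)
#' @export
sensitivitySuite <- function(base_specs, data,
                             cell_columns = grep("^cell_", colnames(data),
                                                 value = TRUE),
                             risk_columns = c("fas", "social_capital",
                                              "birthweight",
                                              "maternal_smoking",
                                              "passive_smoke"),
                             variants = c("sex_stratified", "cell_adjusted",
                                          "risk_adjusted",
                                          "centre_stratified")) {
  out <- list(); skipped <- character()
  tryRun <- function(spec, variant) {
    res <- tryCatch(runAssociation(spec, data), error = function(e) e)
    if (inherits(res, "error")) {
      skipped <<- c(skipped, paste0(variant, " [", spec$exposure, " -> ",
                                    spec$outcome, "]: ", conditionMessage(res)))
      return(NULL)
    }
    res$variant <- variant
    out[[length(out) + 1]] <<- res
  }
  for (spec in base_specs) {
    if ("sex_stratified" %in% variants) {
      for (sx in levels(factor(data$sex))) {
        s <- spec; s$stratum <- list(sex = sx)
        tryRun(s, paste0("sex=", sx))
      }
    }
    if ("cell_adjusted" %in% variants && length(cell_columns)) {
      s <- spec
      s$extra_covariates <- union(s$extra_covariates, cell_columns)
      tryRun(s, "cell_adjusted")
    }
    if ("risk_adjusted" %in% variants) {
      s <- spec
      s$extra_covariates <- union(s$extra_covariates,
                                  setdiff(risk_columns, s$exposure))
      tryRun(s, "risk_adjusted")
    }
    if ("centre_stratified" %in% variants) {
      for (ct in levels(factor(data$centre))) {
        s <- spec; s$stratum <- list(centre = ct)
        tryRun(s, paste0("centre=", ct))
      }
    }
  }
  list(results = if (length(out)) do.call(rbind, out) else NULL,
       skipped = skipped)
}
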