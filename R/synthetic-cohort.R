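#' Configuration for the synthetic study generator
#'
#' Defines the study conditions emulated by [generateStudy()]: a cohort of
#' school-age children (ages uniform on 5-12 years across six study centres),
#' multi-block omics with a sparse linear age signal plus noise and plate
#' effects, assay censoring at the limits of quantification for the protein
#' block, urinary dilution factors, a follow-up ("panel") visit about half a
#' year later for a subset, and developmental outcomes with configurable
#' dependence on the child's true biological-age deviation (delta age).
#'
#' Defaults mirror the assays the package targets: 36 plasma proteins, 177
#' serum metabolites and 44 urinary metabolites. A minority of features per
#' block (8/30/10) carries a true age signal; a fitted clock typically
#' selects these plus further correlated-noise features, so the *selected*
#' predictor count exceeds the true-signal count, as in real clocks.
#'
#' @param n_children number of children
#' @param age_range ages are uniform on this interval (years)
#' @param n_centres number of study centres
#' @param block_sizes named integer vector, features per block
#' @param block_kinds named character vector mapping block label to one of
#'   `"protein"`, `"serum_metabolite"`, `"urinary_metabolite"`, `"transcript"`
#' @param n_age_features named integer vector, truly age-associated features
#'   per block (must not exceed `block_sizes`)
#' @param age_effect_scale absolute per-feature slope, log2-units per year
#' @param noise_sd residual SD of each feature on the log2 scale
#' @param plate_count number of assay plates
#' @param plate_effect_sd SD of per-(plate, feature) shifts, log2 units
#' @param censor_quantiles lower/upper quantiles at which protein values are
#'   censored against LOQ1/LOQ2
#' @param urine_dilution_log_sd SD of log urinary dilution factors
#' @param panel_fraction fraction of children re-examined at follow-up
#' @param panel_gap_years years between the two visits
#' @param delta_age_outcome_effects named numeric: SD of outcome per year of
#'   true delta age (log odds per year for `puberty`)
#' @param covariate_missing_rate completely-at-random missingness applied to
#'   risk-factor covariates
#' @param poor_feature_rate fraction of non-age features per block given poor
#'   assay quality (heavy censoring for proteins; high CV and below-LOD
#'   fraction for serum metabolites) so the QC filters have work to do
#' @param delta_age_sd SD of the true delta age across children (years)
#' @param seed master seed; every stream of randomness derives from it
#' @return a validated list of class `"SimConfig"`
#' @examples
#' cfg <- simConfig(n_children = 50, seed = 7)
#' cfg$block_sizes
#' @export
simConfig <- function(n_children = 1000,
                      age_range = c(5, 12),
                      n_centres = 6,
                      block_sizes = c(proteins = 36, serum = 177, urine = 44),
                      block_kinds = c(proteins = "protein",
                                      serum = "serum_metabolite",
                                      urine = "urinary_metabolite"),
                      n_age_features = c(proteins = 8, serum = 30, urine = 10),
                      age_effect_scale = 0.3,
                      noise_sd = 1,
                      plate_count = 10,
                      plate_effect_sd = 0.2,
                      censor_quantiles = c(0.02, 0.98),
                      urine_dilution_log_sd = 0.6,
                      panel_fraction = 0.15,
                      panel_gap_years = 0.5,
                      delta_age_outcome_effects = c(zBMI = 0.3, zHeight = 0.2,
                                                    fat_pct = 0.2, dprime = 0.15,
                                                    hrt_se = -0.15, puberty = 0.3),
                      covariate_missing_rate = 0.01,
                      poor_feature_rate = 0.05,
                      delta_age_sd = 1,
                      seed = 1L) {
  cfg <- as.list(environment())
  chkCount <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x <= 0 || x != round(x))
      stop("invalid SimConfig field '", nm, "': must be a positive count")
  }
  chkProb <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1))
      stop("invalid SimConfig field '", nm, "': must lie in [0,1]")
  }
  chkCount(cfg$n_children, "n_children")
  chkCount(cfg$n_centres, "n_centres")
  chkCount(cfg$plate_count, "plate_count")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    stop("invalid SimConfig field 'age_range': lower must be < upper")
  if (is.null(names(cfg$block_sizes)) || any(cfg$block_sizes <= 0))
    stop("invalid SimConfig field 'block_sizes': named positive counts required")
  if (!all(names(cfg$n_age_features) %in% names(cfg$block_sizes)))
    stop("invalid SimConfig field 'n_age_features': unknown block label")
  full <- setNames(rep(0L, length(cfg$block_sizes)), names(cfg$block_sizes))
  full[names(cfg$n_age_features)] <- cfg$n_age_features
  cfg$n_age_features <- full
  if (any(cfg$n_age_features > cfg$block_sizes))
    stop("invalid SimConfig field 'n_age_features': exceeds block_sizes")
  if (!all(names(cfg$block_sizes) %in% names(cfg$block_kinds)))
    stop("invalid SimConfig field 'block_kinds': every block needs a kind")
  kinds <- c("protein", "serum_metabolite", "urinary_metabolite", "transcript")
  if (!all(cfg$block_kinds %in% kinds))
    stop("invalid SimConfig field 'block_kinds': must be one of ",
         paste(kinds, collapse = ", "))
  chkProb(cfg$censor_quantiles, "censor_quantiles")
  if (cfg$censor_quantiles[1] >= cfg$censor_quantiles[2])
    stop("invalid SimConfig field 'censor_quantiles': lower must be < upper")
  chkProb(cfg$panel_fraction, "panel_fraction")
  chkProb(cfg$covariate_missing_rate, "covariate_missing_rate")
  chkProb(cfg$poor_feature_rate, "poor_feature_rate")
  for (nm in c("age_effect_scale", "noise_sd", "plate_effect_sd",
               "urine_dilution_log_sd", "panel_gap_years", "delta_age_sd")) {
    if (length(cfg[[nm]]) != 1 || !is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("invalid SimConfig field '", nm, "': must be a non-negative number")
  }
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed))
    stop("invalid SimConfig field 'seed'")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "SimConfig"
  cfg
}

# one pseudo-random sub-seed per generator component, split from the master
# seed, so adding a block or component never perturbs the others' draws
.streamSeeds <- function(seed, labels) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(labels)), labels)
}

#' Generate a full synthetic study
#'
#' Simulates the cohort table, omic blocks, qPCR wells, follow-up blocks and
#' records the ground truth. Each age-associated feature follows
#' `baseline + slope * biological age + plate effect + noise` on the log2
#' scale, where biological age is chronological age plus the child's true
#' delta age, so an age clock trained on the features can in principle
#' recover delta age. Values are exponentiated to the raw assay scale;
#' urinary metabolites are additionally multiplied by a per-sample dilution
#' factor; protein values outside their per-feature quantification limits are
#' masked and flagged. Outcomes are a linear predictor in covariates plus the
#' configured delta-age effects plus noise. Deterministic given the seed.
#'
#' @param config a [simConfig()] object
#' @return a [SyntheticStudy-class]
#' @examples
#' study <- generateStudy(simConfig(n_children = 40, seed = 1))
#' study
#' @export
generateStudy <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  n <- config$n_children
  seeds <- .streamSeeds(config$seed,
                        c("cohort", "delta", "features", "qpcr",
                          "outcomes", "panel", "missing"))

  ## --- cohort covariates -------------------------------------------------
  set.seed(seeds["cohort"])
  ids <- sprintf("child_%04d", seq_len(n))
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- factor(sample(c("male", "female"), n, TRUE, prob = c(0.55, 0.45)),
                levels = c("male", "female"))
  ethnicity <- factor(sample(c("white", "asian", "other"), n, TRUE,
                             prob = c(0.89, 0.08, 0.03)),
                      levels = c("white", "asian", "other"))
  centre <- factor(sample(paste0("centre_", LETTERS[seq_len(config$n_centres)]),
                          n, TRUE))
  birthweight <- rnorm(n, 3.37, 0.5)
  gestational_age <- rnorm(n, 39.6, 1.7)
  maternal_smoking <- factor(sample(c("non_smoker", "smoker"), n, TRUE,
                                    prob = c(0.85, 0.15)),
                             levels = c("non_smoker", "smoker"))
  passive_smoke <- factor(sample(c("unexposed", "exposed"), n, TRUE,
                                 prob = c(0.64, 0.36)),
                          levels = c("unexposed", "exposed"))
  kidmed <- pmin(11L, pmax(-4L, as.integer(round(rnorm(n, 2.8, 1.8)))))
  fas <- factor(sample(c("low", "medium", "high"), n, TRUE,
                       prob = c(0.11, 0.39, 0.50)),
                levels = c("low", "medium", "high"))
  social_capital <- factor(sample(c("low", "medium", "high"), n, TRUE,
                                  prob = c(0.47, 0.25, 0.28)),
                           levels = c("low", "medium", "high"))
  # white-cell fractions as covariates for the cell-adjusted sensitivity runs
  cellnames <- c("CD4T", "CD8T", "mono", "bcell", "nk", "neutro", "eosino")
  shape <- c(8, 5, 3, 3, 2, 20, 1)
  cells <- vapply(shape, function(s) stats::rgamma(n, s, 1), numeric(n))
  cells <- cells / rowSums(cells)
  colnames(cells) <- paste0("cell_", cellnames)
  plate <- sample(sprintf("plate_%02d", seq_len(config$plate_count)), n, TRUE)

  set.seed(seeds["delta"])
  true_delta <- rnorm(n, 0, config$delta_age_sd)
  bio_age <- age + true_delta
  # precomputed epigenetic age column (a marker input, not modelled here)
  epigenetic_age <- age + 0.3 * true_delta + rnorm(n, 0, 0.8)

  ## --- omic blocks -------------------------------------------------------
  set.seed(seeds["features"])
  block_seeds <- .streamSeeds(sample.int(.Machine$integer.max - 1L, 1),
                              names(config$block_sizes))
  blocks <- list(); coef_truth <- list(); dilution <- NULL
  for (label in names(config$block_sizes)) {
    sim <- .simulateBlock(label, config, bio_age, plate, block_seeds[label])
    blocks[[label]] <- sim$block
    coef_truth[[label]] <- sim$coefs
    if (identical(config$block_kinds[[label]], "urinary_metabolite"))
      dilution <- setNames(sim$dilution, ids)
    block_seeds_keep <- block_seeds   # reused for the panel re-simulation
  }
  blocks <- lapply(blocks, function(b) { colnames(b) <- ids; b })

  ## --- qPCR wells --------------------------------------------------------
  set.seed(seeds["qpcr"])
  true_ts <- exp(-0.01 * (age - mean(age)) + rnorm(n, 0, 0.2))
  qpcr <- .simulateWells(ids, true_ts)

  ## --- outcomes ----------------------------------------------------------
  set.seed(seeds["outcomes"])
  eff <- config$delta_age_outcome_effects
  effOf <- function(nm) if (nm %in% names(eff)) eff[[nm]] else 0
  ce <- matrix(rnorm(config$n_centres * 9, 0, 0.15), config$n_centres, 9)
  ci <- as.integer(centre)
  female <- as.numeric(sex == "female")
  agec <- age - mean(age)
  out <- data.frame(
    zBMI = ce[ci, 1] + effOf("zBMI") * true_delta + rnorm(n, 0.4, 1.1),
    zHeight = ce[ci, 2] + effOf("zHeight") * true_delta + rnorm(n, 0.4, 0.95),
    fat_pct = ce[ci, 3] + 0.1 * agec + effOf("fat_pct") * true_delta + rnorm(n, 6.8, 1),
    dprime = ce[ci, 4] + 0.25 * agec + effOf("dprime") * true_delta + rnorm(n, 1.1, 0.9),
    hrt_se = ce[ci, 5] - 0.2 * agec + effOf("hrt_se") * true_delta + rnorm(n, 3, 0.9),
    cpm = ce[ci, 6] + 0.3 * agec + effOf("cpm") * true_delta + rnorm(n, 0, 0.95),
    fev1 = ce[ci, 7] + effOf("fev1") * true_delta + rnorm(n, 99, 1))
  lat_int <- 1.4 + ce[ci, 8] + effOf("cbcl_int") * true_delta + rnorm(n, 0, 0.8)
  lat_ext <- 1.45 + ce[ci, 9] + effOf("cbcl_ext") * true_delta + rnorm(n, 0, 0.8)
  out$cbcl_int <- pmax(0, round(exp(lat_int)) - 1)
  out$cbcl_ext <- pmax(0, round(exp(lat_ext)) - 1)
  logit <- -2 + 0.9 * (age - 8) + 0.5 * female + effOf("puberty") * true_delta
  puberty <- ifelse(age >= 8, rbinom(n, 1, 1 / (1 + exp(-logit))), NA_integer_)
  out$puberty <- puberty

  cohort <- data.frame(id = ids, age = age, sex = sex, ethnicity = ethnicity,
                       centre = centre, birthweight = birthweight,
                       gestational_age = gestational_age,
                       maternal_smoking = maternal_smoking,
                       passive_smoke = passive_smoke, kidmed = kidmed,
                       fas = fas, social_capital = social_capital,
                       epigenetic_age = epigenetic_age,
                       cells, out, stringsAsFactors = FALSE)

  ## --- covariate missingness (MCAR) --------------------------------------
  set.seed(seeds["missing"])
  if (config$covariate_missing_rate > 0) {
    miss_cols <- c("birthweight", "gestational_age", "maternal_smoking",
                   "passive_smoke", "kidmed", "fas", "social_capital")
    for (cc in miss_cols) {
      hit <- runif(n) < config$covariate_missing_rate
      cohort[[cc]][hit] <- NA
    }
  }

  ## --- panel follow-up ---------------------------------------------------
  set.seed(seeds["panel"])
  n_panel <- round(config$panel_fraction * n)
  panelBlocks <- list()
  panelCohort <- data.frame(id = character(), age = numeric())
  if (n_panel >= 1) {
    panel_idx <- sort(sample.int(n, n_panel))
    panel_age <- age[panel_idx] + config$panel_gap_years
    panel_bio <- panel_age + true_delta[panel_idx]
    panel_seeds <- .streamSeeds(sample.int(.Machine$integer.max - 1L, 1),
                                names(config$block_sizes))
    for (label in names(config$block_sizes)) {
      sim <- .simulateBlock(label, config, panel_bio, plate[panel_idx],
                            panel_seeds[label],
                            coefs = coef_truth[[label]],
                            baseline = attr(coef_truth[[label]], "baseline"),
                            plate_eff = attr(coef_truth[[label]], "plate_eff"),
                            loq = attr(coef_truth[[label]], "loq"))
      b <- sim$block; colnames(b) <- ids[panel_idx]
      panelBlocks[[label]] <- b
    }
    panelCohort <- data.frame(id = ids[panel_idx], age = panel_age,
                              stringsAsFactors = FALSE)
  }

  truth <- list(
    true_age_coefficients = lapply(coef_truth, function(x) {
      y <- as.numeric(x); names(y) <- names(x); y }),
    true_delta_age = setNames(true_delta, ids),
    true_outcome_effects = as.list(eff),
    plate_assignments = setNames(plate, ids),
    dilution_factors = dilution,
    true_ts = setNames(true_ts, ids),
    panel_ids = panelCohort$id,
    config = unclass(config))

  new("SyntheticStudy", cohort = cohort, blocks = blocks, qpcr = qpcr,
      panelBlocks = panelBlocks, panelCohort = panelCohort, truth = truth)
}

# simulate one block; when coefs/baseline/plate_eff/loq are supplied the same
# generating model is reused (the panel re-simulation), only the noise is new
.simulateBlock <- function(label, config, bio_age, plate, seed,
                           coefs = NULL, baseline = NULL, plate_eff = NULL,
                           loq = NULL) {
  set.seed(seed)
  p <- config$block_sizes[[label]]
  kind <- config$block_kinds[[label]]
  n <- length(bio_age)
  feat <- sprintf("%s_%03d", label, seq_len(p))
  mu0 <- switch(kind, protein = 10, serum_metabolite = 5,
                urinary_metabolite = 5, transcript = 7)
  fresh <- is.null(coefs)
  if (fresh) {
    baseline <- rnorm(p, mu0, 1)
    coefs <- setNames(numeric(p), feat)
    n_age <- config$n_age_features[[label]]
    age_idx <- if (n_age > 0) sample.int(p, n_age) else integer()
    coefs[age_idx] <- sample(c(-1, 1), length(age_idx), TRUE) *
      config$age_effect_scale
    plate_eff <- matrix(rnorm(config$plate_count * p, 0, config$plate_effect_sd),
                        config$plate_count, p)
  } else {
    age_idx <- which(coefs != 0)
  }
  plate_i <- as.integer(factor(plate, levels = sprintf("plate_%02d",
                                                       seq_len(config$plate_count))))
  log2val <- matrix(baseline, n, p, byrow = TRUE) +
    outer(bio_age, unname(coefs)) + plate_eff[plate_i, , drop = FALSE] +
    matrix(rnorm(n * p, 0, config$noise_sd), n, p)
  raw <- 2^log2val
  dimnames(raw) <- list(NULL, feat)

  dilution <- NULL
  if (kind == "urinary_metabolite") {
    dilution <- exp(rnorm(n, 0, config$urine_dilution_log_sd))
    raw <- raw * dilution
  }

  # assay-quality metadata and censoring
  n_poor <- round(config$poor_feature_rate * p)
  non_age <- setdiff(seq_len(p), age_idx)
  poor <- if (fresh) sort(sample(non_age, min(n_poor, length(non_age))))
          else attr(coefs, "poor")
  cv <- runif(p, 3, 25)
  lod <- loq1 <- loq2 <- rep(NA_real_, p)
  flags <- matrix(0L, n, p, dimnames = dimnames(raw))
  if (kind == "protein") {
    if (fresh) {
      loq1 <- apply(raw, 2, quantile, config$censor_quantiles[1])
      loq2 <- apply(raw, 2, quantile, config$censor_quantiles[2])
      loq1[poor] <- apply(raw[, poor, drop = FALSE], 2, quantile, 0.8)
      lod <- 0.8 * loq1
    } else {
      lod <- loq$lod; loq1 <- loq$loq1; loq2 <- loq$loq2
    }
    below <- sweep(raw, 2, loq1, "<")
    above <- sweep(raw, 2, loq2, ">")
    flags[below] <- -1L; flags[above] <- 1L
    raw[flags != 0L] <- NA_real_
  } else if (kind == "serum_metabolite") {
    if (fresh) {
      lod <- apply(raw, 2, quantile, 0.01)
      if (length(poor)) {
        lod[poor] <- apply(raw[, poor, drop = FALSE], 2, quantile, 0.4)
      }
    } else {
      lod <- loq$lod
    }
    cv[poor] <- runif(length(poor), 35, 60)
  }
  call_rate <- if (kind == "transcript") stats::rbeta(p, 20, 1) else rep(1, p)

  fm <- data.frame(block = label, kind = kind, lod = lod, loq1 = loq1,
                   loq2 = loq2, cv_percent = cv, call_rate = call_rate,
                   row.names = feat)
  rownames(raw) <- paste0("s", seq_len(n))
  block <- OmicsBlock(raw, fm, sample_meta = data.frame(plate = plate),
                      censored = flags, log2 = FALSE)
  attr(coefs, "baseline") <- baseline
  attr(coefs, "plate_eff") <- plate_eff
  attr(coefs, "poor") <- poor
  attr(coefs, "loq") <- list(lod = lod, loq1 = loq1, loq2 = loq2)
  list(block = block, coefs = coefs, dilution = dilution)
}

# triplicate telomere/single-copy wells with per-run calibrators + standards
.simulateWells <- function(ids, true_ts, run_size = 40, cq_sd = 0.05,
                           eff = c(T = 0.95, S = 0.90),
                           intercept = c(T = 25, S = 28)) {
  n <- length(ids)
  runs <- sprintf("run_%02d", ((seq_len(n) - 1) %/% run_size) + 1)
  run_levels <- unique(runs)
  run_shift <- setNames(rnorm(length(run_levels), 0, 0.3), run_levels)
  s_quant <- exp(rnorm(n, 0, 0.15))
  # triplicate sample wells for both targets
  sdf <- data.frame(
    sample_id = rep(ids, each = 6),
    target = rep(rep(c("T", "S"), each = 3), n),
    run_id = rep(runs, each = 6),
    replicate = rep(1:3, 2 * n),
    cq = NA_real_, role = "sample", input_quantity = NA_real_)
  ix <- match(sdf$sample_id, ids)
  q <- ifelse(sdf$target == "T", true_ts[ix] * s_quant[ix], s_quant[ix])
  sdf$cq <- intercept[sdf$target] + run_shift[sdf$run_id] -
    log(q) / log(1 + eff[sdf$target]) + rnorm(nrow(sdf), 0, cq_sd)
  # eight inter-run calibrators (pooled DNA, quantity 1) per run and target
  cdf <- expand.grid(sample_id = sprintf("cal_%02d", 1:8),
                     target = c("T", "S"), run_id = run_levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cdf$replicate <- 1L
  cdf$cq <- intercept[cdf$target] + run_shift[cdf$run_id] +
    rnorm(nrow(cdf), 0, cq_sd)
  cdf$role <- "inter_run_calibrator"; cdf$input_quantity <- NA_real_
  # six-point serial dilution standards per run and target
  quant <- 50 / 2^(0:5)
  ddf <- expand.grid(sample_id = sprintf("std_%d", 1:6),
                     target = c("T", "S"), run_id = run_levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ddf$replicate <- 1L
  ddf$input_quantity <- quant[match(ddf$sample_id, sprintf("std_%d", 1:6))]
  ddf$cq <- intercept[ddf$target] + run_shift[ddf$run_id] -
    log(ddf$input_quantity) / log(1 + eff[ddf$target]) +
    rnorm(nrow(ddf), 0, cq_sd)
  ddf$role <- "dilution_standard"
  cols <- c("sample_id", "target", "run_id", "replicate", "cq", "role",
            "input_quantity")
  rbind(sdf[, cols], cdf[, cols], ddf[, cols])
}

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy: ", nrow(object@cohort), " children, ",
      length(object@blocks), " omic block(s) [",
      paste(names(object@blocks), collapse = ", "), "]\n", sep = "")
  cat("  qPCR wells: ", nrow(object@qpcr),
      "; panel subset: ", nrow(object@panelCohort), " children\n", sep = "")
})

#' Accessors for SyntheticStudy components
#' @param x a [SyntheticStudy-class]
#' @return the corresponding component
#' @export
studyCohort <- function(x) x@cohort
#' @rdname studyCohort
#' @export
studyBlocks <- function(x) x@blocks
#' @rdname studyCohort
#' @export
studyWells <- function(x) x@qpcr
#' @rdname studyCohort
#' @export
studyPanelBlocks <- function(x) x@panelBlocks
#' @rdname studyCohort
#' @export
studyPanelCohort <- function(x) x@panelCohort
#' @rdname studyCohort
#' @export
groundTruth <- function(x) x@truth
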