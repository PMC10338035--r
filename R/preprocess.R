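## Assay preprocessing: quantifiability filters, log2, plate centering,
## truncated-normal imputation of censored cells, median-fold-change
## normalization of urinary dilution, and feature scaling.
##
## Canonical order per block kind (applied by preprocessBlock):
##   protein / serum / transcript: filter -> log2 -> plate centre ->
##     impute (proteins) -> scale
##   urinary metabolites: filter -> median-fold-change normalize
##     (raw scale; includes half-minimum offset and log2) -> scale

.emptyQC <- function(params = list()) {
  list(dropped_features = data.frame(feature = character(),
                                     reason = character()),
       dropped_samples = data.frame(sample = character(),
                                    reason = character()),
       imputed_cell_count = 0L, params = params)
}

.dropFeat <- function(qc, feats, reason) {
  if (length(feats))
    qc$dropped_features <- rbind(
      qc$dropped_features, data.frame(feature = feats, reason = reason))
  qc
}

#' Filter features (and samples) to the quantifiable set
#'
#' Applies the assay-specific quality rule: proteins are kept only if more
#' than 30% of their measurements fall within the linear range of
#' quantification (between LOQ1 and LOQ2); serum metabolites are dropped only
#' when *both* their CV exceeds 30% *and* more than 30% of values lie below
#' the LOD; transcripts with a call rate below 1% are dropped, after samples
#' with a call rate below 40% are removed.
#'
#' @param block an [OmicsBlock-class]
#' @param kind one of `"protein"`, `"serum_metabolite"`, `"transcript"`;
#'   defaults to the kind recorded in the feature metadata
#' @return list with elements `block` (filtered) and `qc` (a QC report:
#'   dropped features/samples with reason codes, parameters used)
#' @export
filterQuantifiable <- function(block, kind = NULL) {
  fm <- featureMeta(block)
  if (is.null(kind)) kind <- fm$kind[1]
  kind <- match.arg(kind, c("protein", "serum_metabolite", "transcript",
                            "urinary_metabolite"))
  qc <- .emptyQC(list(rule = kind, threshold = 0.30))
  v <- assay(block, "values")     # features x samples
  fl <- assay(block, "censored")
  if (kind == "protein") {
    for (cc in c("loq1", "loq2"))
      if (all(is.na(fm[[cc]])))
        stop("missing required metadata column '", cc, "' for the protein rule")
    in_range <- rowMeans(fl == 0L, na.rm = FALSE)
    drop <- which(!(in_range > 0.30))
    qc <- .dropFeat(qc, rownames(block)[drop], "linear_range_le_30pct")
  } else if (kind == "serum_metabolite") {
    if (all(is.na(fm$lod)))
      stop("missing required metadata column 'lod' for the serum metabolite rule")
    if (all(is.na(fm$cv_percent)))
      stop("missing required metadata column 'cv_percent' for the serum metabolite rule")
    below_lod <- rowMeans(fl == -1L | (fl == 0L & v < fm$lod), na.rm = TRUE)
    drop <- which(fm$cv_percent > 30 & below_lod > 0.30)
    qc <- .dropFeat(qc, rownames(block)[drop], "cv_gt_30_and_below_lod_gt_30")
  } else if (kind == "transcript") {
    if (all(is.na(fm$call_rate)))
      stop("missing required metadata column 'call_rate' for the transcript rule")
    sample_call <- colMeans(!is.na(v))
    bad_samples <- which(sample_call < 0.40)
    if (length(bad_samples)) {
      qc$dropped_samples <- rbind(
        qc$dropped_samples,
        data.frame(sample = colnames(block)[bad_samples],
                   reason = "sample_call_rate_lt_40pct"))
      block <- block[, -bad_samples, drop = FALSE]
    }
    drop <- which(fm$call_rate < 0.01)
    qc <- .dropFeat(qc, rownames(block)[drop], "call_rate_lt_1pct")
  } else {
    drop <- integer()
  }
  if (length(qc$dropped_features$feature))
    block <- block[!rownames(block) %in% qc$dropped_features$feature, ,
                   drop = FALSE]
  list(block = block, qc = qc)
}

#' Log2-transform an OmicsBlock
#'
#' Transforms values and the LOD/LOQ bounds; errors on non-positive values.
#'
#' @param block an [OmicsBlock-class] on the raw scale
#' @return the block on the log2 scale
#' @export
log2Transform <- function(block) {
  if (isLog2(block)) return(block)
  v <- assay(block, "values")
  if (any(v <= 0, na.rm = TRUE))
    stop("non-positive values; cannot log2-transform")
  assay(block, "values") <- log2(v)
  for (cc in c("lod", "loq1", "loq2"))
    rowData(block)[[cc]] <- log2(rowData(block)[[cc]])
  metadata(block)$log2 <- TRUE
  block
}

#' Centre out plate effects
#'
#' For each feature and plate, subtracts the plate-specific mean minus the
#' feature's grand mean, so all per-plate feature means equal the grand mean
#' afterwards. A feature entirely missing on a plate is left untouched on
#' that plate (with a warning); the operation is idempotent and preserves
#' each feature's grand mean.
#'
#' @param block an [OmicsBlock-class] on the log2 scale with a `plate` column
#'   in its sample metadata
#' @return the plate-centred block
#' @export
plateCenter <- function(block) {
  plate <- colData(block)$plate
  if (is.null(plate)) stop("no 'plate' column in sample metadata")
  v <- assay(block, "values")
  plates <- unique(plate)
  if (length(plates) <= 1) return(block)
  grand <- rowMeans(v, na.rm = TRUE)
  skipped <- 0L
  for (p in plates) {
    idx <- which(plate == p)
    pm <- rowMeans(v[, idx, drop = FALSE], na.rm = TRUE)
    empty <- is.nan(pm)
    skipped <- skipped + sum(empty)
    shift <- ifelse(empty, 0, pm - grand)
    v[, idx] <- v[, idx, drop = FALSE] - shift
  }
  if (skipped > 0)
    warning(skipped, " feature-plate cell(s) had no data; left untouched")
  assay(block, "values") <- v
  block
}

# inverse-CDF draws from a normal truncated to (-Inf, b] or [a, Inf)
.rtruncnorm <- function(n, mu, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mu, sd)
  phi <- pnorm(upper, mu, sd)
  qnorm(plo + runif(n) * (phi - plo), mu, sd)
}

#' Impute censored cells from a truncated normal
#'
#' Per feature, the mean and SD are estimated from the in-range (uncensored)
#' values; cells flagged below LOQ1 are drawn from the fitted normal
#' truncated to (-Inf, LOQ1], cells above LOQ2 from [LOQ2, Inf). Values and
#' bounds must be on the same (log2) scale. Features with fewer than 3
#' in-range values are dropped as un-imputable. Deterministic given the seed;
#' uncensored cells are never altered.
#'
#' @param block an [OmicsBlock-class] with censoring flags
#' @param seed integer seed for the imputation draws
#' @return list with elements `block` and `qc`
#' @export
imputeTruncated <- function(block, seed = 1L) {
  set.seed(seed)
  v <- assay(block, "values")
  fl <- assay(block, "censored")
  fm <- featureMeta(block)
  qc <- .emptyQC(list(stage = "impute_truncated", seed = seed))
  unimputable <- character()
  for (i in seq_len(nrow(v))) {
    cens <- which(fl[i, ] != 0L)
    if (!length(cens)) next
    obs <- v[i, fl[i, ] == 0L]
    obs <- obs[!is.na(obs)]
    if (length(obs) < 3 || sd(obs) == 0) {
      unimputable <- c(unimputable, rownames(v)[i])
      next
    }
    mu <- mean(obs); s <- sd(obs)
    lo <- which(fl[i, ] == -1L); hi <- which(fl[i, ] == 1L)
    if (length(lo))
      v[i, lo] <- .rtruncnorm(length(lo), mu, s, upper = fm$loq1[i])
    if (length(hi))
      v[i, hi] <- .rtruncnorm(length(hi), mu, s, lower = fm$loq2[i])
    fl[i, cens] <- 0L   # cells are filled now; record kept in metadata
    qc$imputed_cell_count <- qc$imputed_cell_count + length(lo) + length(hi)
  }
  qc <- .dropFeat(qc, unimputable, "lt_3_in_range_values")
  metadata(block)$imputed_cells <- qc$imputed_cell_count
  assay(block, "values") <- v
  assay(block, "censored") <- fl
  if (length(unimputable))
    block <- block[!rownames(block) %in% unimputable, , drop = FALSE]
  list(block = block, qc = qc)
}

#' Median-fold-change (probabilistic quotient) normalization
#'
#' Corrects per-sample urinary dilution: each sample's dilution factor is the
#' median, over features, of its ratio to a reference profile (by default the
#' feature-wise median sample); values are divided by the factor, offset by
#' half the minimal positive value of the normalized block, and expressed as
#' log2. Scale-equivariant: multiplying a sample by `c` multiplies its
#' estimated factor by `c`.
#'
#' @param block an [OmicsBlock-class] on the raw positive scale
#' @param reference optional numeric vector of reference feature levels
#' @return list with `block` (log2, normalized) and `dilution_factors`
#'   (named per sample)
#' @export
medianFoldChangeNormalize <- function(block, reference = NULL) {
  if (isLog2(block)) stop("median-fold-change normalization needs raw-scale data")
  v <- assay(block, "values")   # features x samples
  if (is.null(reference)) reference <- apply(v, 1, median, na.rm = TRUE)
  if (any(!is.finite(reference) | reference <= 0))
    stop("non-positive reference entry")
  allzero <- colSums(v != 0, na.rm = TRUE) == 0
  if (any(allzero))
    stop("all-zero sample(s): ", paste(colnames(v)[allzero], collapse = ", "))
  d <- apply(v / reference, 2, median, na.rm = TRUE)
  vn <- sweep(v, 2, d, "/")
  offset <- 0.5 * min(vn[vn > 0], na.rm = TRUE)
  assay(block, "values") <- log2(vn + offset)
  for (cc in c("lod", "loq1", "loq2"))
    rowData(block)[[cc]] <- log2(rowData(block)[[cc]] + offset)
  metadata(block)$log2 <- TRUE
  metadata(block)$mfc_offset <- offset
  list(block = block, dilution_factors = setNames(d, colnames(v)))
}

#' Mean-centre and unit-scale features
#'
#' Each feature is centred to mean 0 and scaled to sample SD 1 (n-1
#' convention). Zero-variance features are dropped with a reason code. The
#' returned scaler must be re-applied (never re-estimated) to test or
#' follow-up data via [applyScaler()].
#'
#' @param block an [OmicsBlock-class] with no censored cells remaining
#' @return list with `block` (scaled), `scaler` (named `center`/`scale`
#'   vectors), and `qc`
#' @export
scaleFeatures <- function(block) {
  fl <- assay(block, "censored")
  if (any(fl != 0L, na.rm = TRUE))
    stop("censored cells remain; impute before scaling")
  v <- assay(block, "values")
  ctr <- rowMeans(v, na.rm = TRUE)
  sds <- apply(v, 1, sd, na.rm = TRUE)
  qc <- .emptyQC(list(stage = "scale_features", sd = "sample (n-1)"))
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad)) {
    qc <- .dropFeat(qc, rownames(v)[bad], "zero_variance")
    block <- block[-bad, , drop = FALSE]
    v <- v[-bad, , drop = FALSE]; ctr <- ctr[-bad]; sds <- sds[-bad]
  }
  assay(block, "values") <- (v - ctr) / sds
  scaler <- list(center = setNames(ctr, rownames(v)),
                 scale = setNames(sds, rownames(v)))
  list(block = block, scaler = scaler, qc = qc)
}

#' Apply a stored feature scaler
#'
#' @param block an [OmicsBlock-class] containing at least the scaler's
#'   features
#' @param scaler a scaler from [scaleFeatures()]
#' @return the block restricted to the scaler's features, scaled with the
#'   stored training means and SDs
#' @export
applyScaler <- function(block, scaler) {
  feats <- names(scaler$center)
  missing <- setdiff(feats, rownames(block))
  if (length(missing))
    stop("features absent from block: ", paste(head(missing, 5), collapse = ", "))
  block <- keepFeatures(block, feats)
  v <- assay(block, "values")
  assay(block, "values") <- (v - scaler$center) / scaler$scale
  block
}

#' Preprocess one block end to end
#'
#' Runs the canonical per-kind pipeline (see the module header) and returns
#' the scaled block together with the scaler, any dilution factors, and the
#' combined QC report.
#'
#' @param block an [OmicsBlock-class] on the raw scale
#' @param kind assay kind; defaults to the recorded feature metadata
#' @param impute_seed seed for truncated-normal imputation
#' @param scaler optional stored scaler from a training run; when supplied,
#'   filtering keeps exactly the scaler's features and the training
#'   means/SDs are applied instead of re-estimated
#' @return list with `block`, `scaler`, `dilution_factors` (urine only),
#'   and `qc` (list of per-stage reports)
#' @export
preprocessBlock <- function(block, kind = NULL, impute_seed = 1L,
                            scaler = NULL) {
  if (is.null(kind)) kind <- featureMeta(block)$kind[1]
  qc <- list()
  dil <- NULL
  if (kind == "urinary_metabolite") {
    norm <- medianFoldChangeNormalize(block)
    block <- norm$block
    dil <- norm$dilution_factors
  } else {
    if (is.null(scaler)) {
      filt <- filterQuantifiable(block, kind)
      block <- filt$block
      qc$filter <- filt$qc
    } else {
      block <- keepFeatures(block, names(scaler$center))
    }
    block <- log2Transform(block)
    if (!is.null(colData(block)$plate)) block <- plateCenter(block)
    if (kind == "protein") {
      imp <- imputeTruncated(block, seed = impute_seed)
      block <- imp$block
      qc$impute <- imp$qc
    }
  }
  if (is.null(scaler)) {
    sc <- scaleFeatures(block)
    block <- sc$block
    scaler <- sc$scaler
    qc$scale <- sc$qc
  } else {
    block <- applyScaler(block, scaler)
  }
  list(block = block, scaler = scaler, dilution_factors = dil, qc = qc)
}
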