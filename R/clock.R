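## Sparse linear age clocks: elastic-net training with an alpha line search
## and cross-validated lambda selection, prediction, delta age, validation,
## and the paired progression test between visits.

#' Concatenate scaled omic blocks column-wise
#'
#' @param blocks named list of [OmicsBlock-class] sharing sample order
#' @return samples-by-features numeric matrix with a `"feature_blocks"`
#'   attribute naming each feature's block
#' @export
concatBlocks <- function(blocks) {
  ids <- colnames(blocks[[1]])
  for (b in blocks)
    if (!identical(colnames(b), ids))
      stop("blocks do not share sample ordering")
  mats <- lapply(blocks, omicsValues)
  x <- do.call(cbind, mats)
  rownames(x) <- ids
  attr(x, "feature_blocks") <-
    setNames(rep(names(blocks), vapply(mats, ncol, 1L)), colnames(x))
  x
}

# age-decile-stratified fold assignment, seed-controlled
.makeFolds <- function(ages, folds, seed) {
  set.seed(seed)
  br <- unique(quantile(ages, 0:10 / 10))
  strata <- cut(ages, br, include.lowest = TRUE)
  foldid <- integer(length(ages))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- rep_len(sample.int(folds), length(idx))
  }
  foldid
}

#' Tune and fit an elastic-net age clock
#'
#' Performs a line search for the mixing parameter alpha over
#' `{0, 0.1, ..., 1}`; for each alpha the penalty lambda is chosen by
#' minimisation of K-fold cross-validated mean squared error along the
#' lambda path, with folds stratified by age decile and shared across
#' alphas. The (alpha, lambda) pair with the smallest CV MSE wins (ties go
#' to the larger lambda, then the larger alpha, i.e. the sparser model) and
#' the final model is refit on all data at that pair. Features are assumed
#' pre-scaled, so the solver does not re-standardise.
#'
#' @param x samples-by-features matrix of scaled features (e.g. from
#'   [concatBlocks()]), or a named list of scaled [OmicsBlock-class]
#' @param ages chronological ages in years
#' @param folds number of CV folds (default 10)
#' @param seed seed controlling the fold assignment
#' @param alphas the alpha grid
#' @param scaler optional feature scaler to store with the model
#' @return a [ClockModel-class]
#' @export
tuneClock <- function(x, ages, folds = 10, seed = 1L,
                      alphas = seq(0, 1, by = 0.1), scaler = list()) {
  if (is.list(x) && !is.matrix(x)) x <- concatBlocks(x)
  fb <- attr(x, "feature_blocks")
  if (nrow(x) != length(ages)) stop("ages must match the sample count")
  if (length(ages) < folds) stop("need at least as many samples as folds")
  bad <- colnames(x)[!apply(is.finite(x), 2, all)]
  if (length(bad))
    stop("non-finite values in feature(s): ", paste(head(bad, 5), collapse = ", "))
  foldid <- .makeFolds(ages, folds, seed)

  path <- list()
  for (a in alphas) {
    cv <- glmnet::cv.glmnet(x, ages, alpha = a, foldid = foldid,
                            standardize = FALSE, family = "gaussian")
    path[[length(path) + 1]] <- data.frame(alpha = a, lambda = cv$lambda,
                                           cvm = cv$cvm)
  }
  path <- do.call(rbind, path)
  pick <- path[order(path$cvm, -path$lambda, -path$alpha), ][1, ]

  fit <- glmnet::glmnet(x, ages, alpha = pick$alpha,
                        lambda = path$lambda[path$alpha == pick$alpha],
                        standardize = FALSE, family = "gaussian")
  cf <- as.numeric(coef(fit, s = pick$lambda))
  names(cf) <- c("(Intercept)", colnames(x))
  w <- cf[-1][cf[-1] != 0]
  comp <- if (is.null(fb)) setNames(length(w), "all")
          else table(factor(fb[names(w)], levels = unique(fb)))
  new("ClockModel", weights = w, intercept = unname(cf[1]),
      alpha = pick$alpha, lambda = pick$lambda, features = colnames(x),
      scaler = scaler,
      blockComposition = setNames(as.integer(comp), names(comp)),
      cvMsePath = path)
}

#' Accessors for ClockModel components
#' @param x a [ClockModel-class]
#' @return the corresponding component
#' @export
clockWeights <- function(x) x@weights
#' @rdname clockWeights
#' @export
clockAlpha <- function(x) x@alpha
#' @rdname clockWeights
#' @export
clockLambda <- function(x) x@lambda
#' @rdname clockWeights
#' @export
clockScaler <- function(x) x@scaler
#' @rdname clockWeights
#' @export
blockComposition <- function(x) x@blockComposition
#' @rdname clockWeights
#' @export
cvMsePath <- function(x) x@cvMsePath

setMethod("show", "ClockModel", function(object) {
  cat("ClockModel: ", length(object@weights), " nonzero predictor(s) of ",
      length(object@features), " features\n", sep = "")
  cat("  alpha = ", object@alpha, ", lambda = ",
      signif(object@lambda, 4), "\n", sep = "")
  if (length(object@blockComposition)) {
    cat("  block composition: ",
        paste(names(object@blockComposition), object@blockComposition,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
})

#' Predict ages and delta age
#'
#' Computes `predicted_age = intercept + sum(w_f * x_f)` over the model's
#' features and `delta_age = predicted - chronological`. Input features must
#' already carry the training scaling ([applyScaler()]); model features
#' absent from the input raise an error (no silent zero-fill).
#'
#' @param model a [ClockModel-class]
#' @param x scaled samples-by-features matrix or list of scaled blocks
#' @param chronological_ages ages in years, aligned to rows of `x`
#' @return data.frame: `sample_id`, `predicted_age`, `chronological_age`,
#'   `delta_age`
#' @export
predictAges <- function(model, x, chronological_ages) {
  if (is.list(x) && !is.matrix(x)) x <- concatBlocks(x)
  need <- names(clockWeights(model))
  missing <- setdiff(need, colnames(x))
  if (length(missing))
    stop("model features absent from input: ",
         paste(head(missing, 10), collapse = ", "))
  pred <- model@intercept +
    as.numeric(x[, need, drop = FALSE] %*% clockWeights(model))
  data.frame(sample_id = rownames(x), predicted_age = pred,
             chronological_age = chronological_ages,
             delta_age = pred - chronological_ages)
}

#' Validate clock predictions against chronological age
#'
#' @param model a [ClockModel-class]
#' @param x scaled test features (matrix or list of blocks), disjoint from
#'   training (caller-asserted)
#' @param ages test chronological ages
#' @param groups optional factor (e.g. study centre) for per-group
#'   correlations
#' @return list: `pearson_r`, `mae` (years), `n`, `constant_predictions`
#'   flag, `per_group` (data.frame of group, r, p, n), and the predictions
#' @export
validateClock <- function(model, x, ages, groups = NULL) {
  pred <- predictAges(model, x, ages)
  if (nrow(pred) < 3) stop("need at least 3 test samples")
  constant <- sd(pred$predicted_age) == 0
  r <- if (constant) NA_real_ else cor(pred$predicted_age, ages)
  mae <- mean(abs(pred$predicted_age - ages))
  per_group <- NULL
  if (!is.null(groups)) {
    groups <- factor(groups)
    per_group <- do.call(rbind, lapply(levels(groups), function(g) {
      sel <- groups == g
      if (sum(sel) < 3 || sd(pred$predicted_age[sel]) == 0 || sd(ages[sel]) == 0)
        return(data.frame(group = g, r = NA_real_, p = NA_real_,
                          n = sum(sel)))
      ct <- cor.test(pred$predicted_age[sel], ages[sel])
      data.frame(group = g, r = unname(ct$estimate), p = ct$p.value,
                 n = sum(sel))
    }))
  }
  list(pearson_r = r, mae = mae, n = nrow(pred),
       constant_predictions = constant, per_group = per_group,
       predictions = pred)
}

#' Paired one-sided progression test between visits
#'
#' Tests whether predicted biological age increased between the first and
#' second clinical examinations: paired differences (second minus first
#' predicted age), one-sided alternative mean > 0.
#'
#' @param first,second prediction data.frames from [predictAges()], paired
#'   by `sample_id`
#' @return list: `mean_increase` (years), `sd`, `t`, `one_sided_p`,
#'   `n_pairs`
#' @export
progressionTest <- function(first, second) {
  m <- merge(first[, c("sample_id", "predicted_age")],
             second[, c("sample_id", "predicted_age")],
             by = "sample_id", suffixes = c("_first", "_second"))
  if (nrow(m) < 2) stop("need at least 2 paired samples")
  d <- m$predicted_age_second - m$predicted_age_first
  if (sd(d) == 0) stop("zero-variance paired differences")
  tt <- t.test(d, alternative = "greater", mu = 0)
  list(mean_increase = mean(d), sd = sd(d), t = unname(tt$statistic),
       one_sided_p = tt$p.value, n_pairs = nrow(m))
}

#' Serialize / restore a ClockModel as JSON
#'
#' @param model a [ClockModel-class]
#' @param path output file
#' @return `writeClockModel` returns the path invisibly; `readClockModel`
#'   the restored model
#' @export
writeClockModel <- function(model, path) {
  obj <- list(weights = as.list(clockWeights(model)),
              intercept = model@intercept, alpha = model@alpha,
              lambda = model@lambda, features = model@features,
              scaler = lapply(model@scaler, as.list),
              block_composition = as.list(model@blockComposition))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeClockModel
#' @export
readClockModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ClockModel", weights = unlist(obj$weights), intercept = obj$intercept,
      alpha = obj$alpha, lambda = obj$lambda, features = obj$features,
      scaler = lapply(obj$scaler, unlist),
      blockComposition = setNames(as.integer(unlist(obj$block_composition)),
                                  names(obj$block_composition)),
      cvMsePath = data.frame())
}
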