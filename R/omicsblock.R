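#' Construct an OmicsBlock
#'
#' Builds an [OmicsBlock-class] from a samples-by-features matrix (the
#' orientation of the on-disk TSVs) plus feature and sample metadata. The
#' matrix is transposed internally to the Bioconductor features-by-samples
#' convention.
#'
#' @param values numeric matrix, samples in rows, features in columns; row
#'   names are sample ids, column names feature ids
#' @param feature_meta data.frame with one row per feature; any of the
#'   columns `block`, `kind`, `lod`, `loq1`, `loq2`, `cv_percent`,
#'   `call_rate` that are absent are filled with `NA`
#' @param sample_meta optional data.frame with one row per sample (e.g. a
#'   `plate` column)
#' @param censored optional integer matrix of the same shape as `values`:
#'   0 in range, -1 below LOQ1, +1 above LOQ2
#' @param log2 logical(1), whether `values` (and LOQ bounds) are already on
#'   the log2 scale
#' @return an [OmicsBlock-class]
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'   dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
#' b <- OmicsBlock(m, data.frame(block = "demo", row.names = colnames(m)))
#' dim(b)
#' @export
OmicsBlock <- function(values, feature_meta = NULL, sample_meta = NULL,
                       censored = NULL, log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs sample row names and feature column names")
  nfeat <- ncol(values)
  fm <- if (is.null(feature_meta)) data.frame(row.names = colnames(values))
        else as.data.frame(feature_meta)
  if (nrow(fm) != nfeat) stop("feature_meta rows must match feature count")
  defaults <- list(block = NA_character_, kind = NA_character_,
                   lod = NA_real_, loq1 = NA_real_, loq2 = NA_real_,
                   cv_percent = NA_real_, call_rate = NA_real_)
  for (nm in names(defaults))
    if (!nm %in% colnames(fm)) fm[[nm]] <- rep(defaults[[nm]], nfeat)
  rownames(fm) <- colnames(values)
  if (is.null(censored)) {
    censored <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
    censored[is.na(values)] <- NA_integer_
  }
  cd <- if (is.null(sample_meta)) DataFrame(row.names = rownames(values))
        else DataFrame(sample_meta, row.names = rownames(values))
  se <- SummarizedExperiment(
    assays = list(values = t(values), censored = t(censored)),
    rowData = DataFrame(fm), colData = cd)
  metadata(se)$log2 <- isTRUE(log2)
  new("OmicsBlock", se)
}

#' Accessors for OmicsBlock components
#'
#' `omicsValues()` returns the measurement matrix in samples-by-features
#' orientation (censored cells `NA`); `censorFlags()` the matching flag
#' matrix; `featureMeta()` the per-feature metadata as a data.frame;
#' `isLog2()` whether values are on the log2 scale.
#'
#' @param x an [OmicsBlock-class]
#' @return see description
#' @export
omicsValues <- function(x) t(assay(x, "values"))

#' @rdname omicsValues
#' @export
censorFlags <- function(x) t(assay(x, "censored"))

#' @rdname omicsValues
#' @export
featureMeta <- function(x) as.data.frame(rowData(x))

#' @rdname omicsValues
#' @export
isLog2 <- function(x) isTRUE(metadata(x)$log2)

setMethod("show", "OmicsBlock", function(object) {
  flags <- assay(object, "censored")
  cat("OmicsBlock: ", ncol(object), " samples x ", nrow(object), " features",
      " [", unique(rowData(object)$block)[1], "]\n", sep = "")
  cat("  scale: ", if (isLog2(object)) "log2" else "raw",
      "; censored cells: ", sum(flags != 0, na.rm = TRUE), "\n", sep = "")
  callNextMethod()
})

# replace the values assay keeping everything else; used by processing steps
setValues <- function(x, values_t) {
  assay(x, "values") <- values_t
  x
}

# subset to a feature id set, preserving order of `keep`
keepFeatures <- function(x, keep) x[match(keep, rownames(x)), , drop = FALSE]
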