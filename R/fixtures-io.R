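## Plain-text fixture writers/readers. Numeric matrices are written with 17
## significant digits so doubles round-trip exactly through the TSVs.

.fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.writeMatrixTSV <- function(m, path) {
  # samples x features with a leading sample_id column
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  body <- cbind(rownames(m), matrix(.fmtNum(m), nrow(m)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

.readMatrixTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic study to plain-text fixtures
#'
#' Emits `cohort.csv`, one `block_<label>.tsv` (samples x features) and
#' `features_<label>.tsv` per omic block, per-sample plate assignments in
#' `samples.csv`, censoring flags (`censor_<label>.tsv`) for blocks with any
#' censored cells, `qpcr.csv`, panel-visit files when a panel subset exists,
#' and the ground truth as `truth.json`. Matrices round-trip losslessly
#' through [readStudy()].
#'
#' @param study a [SyntheticStudy-class]
#' @param directory output directory, created if needed
#' @return invisibly, a manifest data.frame (file, rows, cols)
#' @export
writeFixtures <- function(study, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  manifest <- list()
  note <- function(file, rows, cols)
    manifest[[length(manifest) + 1]] <<- data.frame(file = file, rows = rows,
                                                    cols = cols)
  co <- studyCohort(study)
  write.csv(co, file.path(directory, "cohort.csv"), row.names = FALSE)
  note("cohort.csv", nrow(co), ncol(co))

  plates <- groundTruth(study)$plate_assignments
  sm <- data.frame(id = names(plates), plate = unname(plates))
  write.csv(sm, file.path(directory, "samples.csv"), row.names = FALSE)
  note("samples.csv", nrow(sm), ncol(sm))

  writeBlockSet <- function(blocks, suffix = "") {
    for (label in names(blocks)) {
      b <- blocks[[label]]
      v <- omicsValues(b)
      f <- paste0("block_", label, suffix, ".tsv")
      .writeMatrixTSV(v, file.path(directory, f))
      note(f, nrow(v), ncol(v))
      fl <- censorFlags(b)
      if (any(fl != 0, na.rm = TRUE)) {
        cf <- paste0("censor_", label, suffix, ".tsv")
        .writeMatrixTSV(fl, file.path(directory, cf))
        note(cf, nrow(fl), ncol(fl))
      }
      if (suffix == "") {
        fm <- featureMeta(b)
        fm <- data.frame(feature_id = rownames(fm), block = fm$block,
                         kind = fm$kind, lod = .fmtNum(fm$lod),
                         loq1 = .fmtNum(fm$loq1), loq2 = .fmtNum(fm$loq2),
                         plate = NA, cv_percent = .fmtNum(fm$cv_percent),
                         call_rate = .fmtNum(fm$call_rate))
        ff <- paste0("features_", label, ".tsv")
        write.table(fm, file.path(directory, ff), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        note(ff, nrow(fm), ncol(fm))
      }
    }
  }
  writeBlockSet(studyBlocks(study))
  qp <- studyWells(study)
  write.csv(qp, file.path(directory, "qpcr.csv"), row.names = FALSE)
  note("qpcr.csv", nrow(qp), ncol(qp))

  pc <- studyPanelCohort(study)
  if (nrow(pc)) {
    write.csv(pc, file.path(directory, "panel_cohort.csv"), row.names = FALSE)
    note("panel_cohort.csv", nrow(pc), ncol(pc))
    writeBlockSet(studyPanelBlocks(study), suffix = "_panel")
  } else {
    note("panel: absent (panel_fraction = 0)", 0, 0)
  }

  # named atomic vectors become JSON objects so names survive the round trip
  namedToList <- function(x) {
    if (is.list(x)) lapply(x, namedToList)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(namedToList(groundTruth(study)),
                       file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  note("truth.json", NA, NA)
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(directory, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read one omic block back from fixtures
#'
#' @param directory fixture directory written by [writeFixtures()]
#' @param label block label
#' @param panel read the panel-visit matrix instead of the main one
#' @return an [OmicsBlock-class]
#' @export
readOmicsBlock <- function(directory, label, panel = FALSE) {
  suffix <- if (panel) "_panel" else ""
  vpath <- file.path(directory, paste0("block_", label, suffix, ".tsv"))
  if (!file.exists(vpath)) stop("no such block file: ", vpath)
  v <- .readMatrixTSV(vpath)
  fm <- read.delim(file.path(directory, paste0("features_", label, ".tsv")))
  rownames(fm) <- fm$feature_id
  fm <- fm[colnames(v), c("block", "kind", "lod", "loq1", "loq2",
                          "cv_percent", "call_rate")]
  cpath <- file.path(directory, paste0("censor_", label, suffix, ".tsv"))
  flags <- NULL
  if (file.exists(cpath)) {
    flags <- .readMatrixTSV(cpath)
    storage.mode(flags) <- "integer"
  }
  sm <- read.csv(file.path(directory, "samples.csv"))
  plate <- setNames(sm$plate, sm$id)[rownames(v)]
  OmicsBlock(v, fm, sample_meta = data.frame(plate = unname(plate)),
             censored = flags, log2 = FALSE)
}

#' Read a full study back from fixtures
#'
#' Reconstructs a [SyntheticStudy-class] from a directory written by
#' [writeFixtures()]; matrices are restored to full precision.
#'
#' @param directory fixture directory
#' @return a [SyntheticStudy-class]
#' @export
readStudy <- function(directory) {
  co <- read.csv(file.path(directory, "cohort.csv"))
  for (cc in list(c("sex", "male", "female"),
                  c("ethnicity", "white", "asian", "other"),
                  c("maternal_smoking", "non_smoker", "smoker"),
                  c("passive_smoke", "unexposed", "exposed"),
                  c("fas", "low", "medium", "high"),
                  c("social_capital", "low", "medium", "high")))
    co[[cc[1]]] <- factor(co[[cc[1]]], levels = cc[-1])
  co$centre <- factor(co$centre)
  labels <- sub("^features_(.*)\\.tsv$", "\\1",
                list.files(directory, pattern = "^features_.*\\.tsv$"))
  blocks <- setNames(lapply(labels, readOmicsBlock, directory = directory),
                     labels)
  qp <- read.csv(file.path(directory, "qpcr.csv"))
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  pcov <- file.path(directory, "panel_cohort.csv")
  panelBlocks <- list()
  panelCohort <- data.frame(id = character(), age = numeric())
  if (file.exists(pcov)) {
    panelCohort <- read.csv(pcov)
    panelBlocks <- setNames(
      lapply(labels, readOmicsBlock, directory = directory, panel = TRUE),
      labels)
  }
  new("SyntheticStudy", cohort = co, blocks = blocks, qpcr = qp,
      panelBlocks = panelBlocks, panelCohort = panelCohort,
      truth = as.list(truth))
}
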