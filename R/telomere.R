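## Relative telomere length (T/S) from triplicate qPCR Cq values with
## standard-curve efficiency estimation and inter-run calibration.

.checkWells <- function(wells) {
  need <- c("sample_id", "target", "run_id", "replicate", "cq", "role")
  miss <- setdiff(need, colnames(wells))
  if (length(miss))
    stop("well table misses column(s): ", paste(miss, collapse = ", "))
  if (any(wells$cq <= 0, na.rm = TRUE)) stop("non-positive Cq values")
  wells
}

#' Estimate PCR efficiency from a serial-dilution standard curve
#'
#' Fits Cq against log10(input quantity) by least squares; the amplification
#' efficiency is `E = 10^(-1/slope) - 1` (a perfectly doubling reaction has
#' slope -3.3219 and E = 1).
#'
#' @param standards well table rows with `role == "dilution_standard"` (or
#'   any rows carrying `input_quantity`)
#' @param target `"T"` (telomere) or `"S"` (single-copy gene)
#' @return list with `efficiency`, `slope`, and `r_squared`
#' @examples
#' std <- data.frame(sample_id = "std", target = "T", run_id = "r1",
#'   replicate = 1, cq = 30 - log2(c(1, 2, 4, 8, 16, 32)),
#'   role = "dilution_standard", input_quantity = c(1, 2, 4, 8, 16, 32))
#' estimateEfficiency(std, "T")$efficiency   # 1 (100%)
#' @export
estimateEfficiency <- function(standards, target) {
  standards <- .checkWells(standards)
  std <- standards[standards$target == target &
                     !is.na(standards$input_quantity), , drop = FALSE]
  if (any(std$input_quantity <= 0)) stop("non-positive input quantity")
  pts <- unique(std$input_quantity)
  if (length(pts) < 3)
    stop("need >= 3 dilution points for target ", target,
         " (got ", length(pts), ")")
  fit <- lm(cq ~ log10(input_quantity), data = std)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("standard curve for target ", target,
         " is not monotone decreasing in input quantity")
  # R^2 computed directly; summary.lm warns on noiseless curves
  r2 <- 1 - sum(resid(fit)^2) / sum((std$cq - mean(std$cq))^2)
  list(efficiency = 10^(-1 / slope) - 1, slope = slope, r_squared = r2)
}

#' Relative telomere length (T/S) per sample
#'
#' For every replicate well, the relative quantity is
#' `Q = (1+E)^(Cq_ref - Cq)` with `Cq_ref` the run's inter-run-calibrator
#' mean Cq for that target. Replicate quantities are averaged per sample and
#' target, the T/S ratio is formed, each run's ratios are divided by the
#' geometric mean of that run's calibrator T/S values, and finally every
#' ratio is divided by the cohort mean so the sample-set average is exactly
#' 1. Replicate CVs (SD/mean of replicate quantities, percent) are reported
#' on the quantity scale.
#'
#' @param wells a well table (see [generateStudy()] output for the layout)
#' @param efficiencies optional named numeric `c(T=, S=)`; estimated from the
#'   dilution standards in `wells` when absent
#' @return data.frame with one row per sample: `ts_ratio` (calibrated),
#'   `relative_ts` (cohort-mean referenced), replicate CVs, efficiencies,
#'   and a `flagged` column for samples with fewer than 2 usable replicates
#' @export
relativeTS <- function(wells, efficiencies = NULL) {
  wells <- .checkWells(wells)
  if (is.null(efficiencies)) {
    efficiencies <- c(
      T = estimateEfficiency(wells, "T")$efficiency,
      S = estimateEfficiency(wells, "S")$efficiency)
  }
  runs <- unique(wells$run_id[wells$role == "sample"])
  cal <- wells[wells$role == "inter_run_calibrator", , drop = FALSE]
  samp <- wells[wells$role == "sample", , drop = FALSE]
  # per-run, per-target calibrator mean Cq
  calref <- list()
  for (run in runs) {
    for (target in c("T", "S")) {
      cc <- cal$cq[cal$run_id == run & cal$target == target]
      if (!length(cc))
        stop("no inter-run calibrators for target ", target, " on run ", run)
      calref[[paste(run, target)]] <- mean(cc)
    }
  }
  qOf <- function(cq, run, target)
    (1 + efficiencies[[target]])^(calref[[paste(run, target)]] - cq)

  ids <- unique(samp$sample_id)
  res <- data.frame(sample_id = ids, run_id = NA_character_,
                    ts_ratio = NA_real_, relative_ts = NA_real_,
                    replicate_cv_t = NA_real_, replicate_cv_s = NA_real_,
                    efficiency_t = unname(efficiencies["T"]),
                    efficiency_s = unname(efficiencies["S"]),
                    flagged = FALSE)
  cvp <- function(x) if (mean(x) == 0) 0 else 100 * sd(x) / mean(x)
  for (k in seq_along(ids)) {
    w <- samp[samp$sample_id == ids[k], , drop = FALSE]
    run <- w$run_id[1]
    res$run_id[k] <- run
    qt <- qOf(w$cq[w$target == "T"], run, "T")
    qs <- qOf(w$cq[w$target == "S"], run, "S")
    if (length(qt) < 2 || length(qs) < 2) res$flagged[k] <- TRUE
    if (!length(qt) || !length(qs)) next
    res$ts_ratio[k] <- mean(qt) / mean(qs)
    res$replicate_cv_t[k] <- cvp(qt)
    res$replicate_cv_s[k] <- cvp(qs)
  }
  # inter-run calibration: divide by the geometric mean calibrator T/S per run
  for (run in runs) {
    crun <- cal[cal$run_id == run, , drop = FALSE]
    by_cal <- split(crun, crun$sample_id)
    cal_ts <- vapply(by_cal, function(w) {
      qt <- qOf(w$cq[w$target == "T"], run, "T")
      qs <- qOf(w$cq[w$target == "S"], run, "S")
      mean(qt) / mean(qs)
    }, numeric(1))
    gm <- exp(mean(log(cal_ts)))
    sel <- res$run_id == run
    res$ts_ratio[sel] <- res$ts_ratio[sel] / gm
  }
  res$relative_ts <- res$ts_ratio / mean(res$ts_ratio, na.rm = TRUE)
  res$cv_ts <- NA_real_
  ok <- !is.na(res$replicate_cv_t) & !is.na(res$replicate_cv_s)
  res$cv_ts[ok] <- sqrt(res$replicate_cv_t[ok]^2 + res$replicate_cv_s[ok]^2)
  res
}
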