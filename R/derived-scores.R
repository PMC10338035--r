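## Questionnaire and cognitive score derivations used to build the cohort
## table from item-level inputs.

#' Mediterranean diet quality (KIDMED) score
#'
#' Eleven items positively associated with the Mediterranean diet pattern
#' score +1 when endorsed, four negatively associated items score -1; the
#' fifteen item scores are summed, giving a total between -4 and 11.
#'
#' @param positive logical vector of length 11 (endorsed positive items)
#' @param negative logical vector of length 4 (endorsed negative items)
#' @return integer score in [-4, 11]
#' @examples
#' kidmedScore(rep(TRUE, 11), rep(FALSE, 4))   # 11
#' kidmedScore(rep(FALSE, 11), rep(TRUE, 4))   # -4
#' @export
kidmedScore <- function(positive, negative) {
  if (length(positive) != 11 || length(negative) != 4)
    stop("KIDMED needs 11 positive and 4 negative item indicators")
  if (anyNA(positive) || anyNA(negative)) stop("missing item responses")
  as.integer(sum(positive) - sum(negative))
}

#' Family Affluence Scale category
#'
#' Maps the composite score (0-9) to the three-level category: low (0-2),
#' medium (3-5), high (6-9).
#'
#' @param score integer 0-9
#' @return factor level among `"low"`, `"medium"`, `"high"`
#' @export
fasCategory <- function(score) {
  if (any(is.na(score)) || any(score != round(score)) ||
      any(score < 0 | score > 9))
    stop("FAS composite score must be an integer in 0-9")
  cut(score, c(-1, 2, 5, 9), labels = c("low", "medium", "high"))
}

#' Pubertal Development Scale mean and onset indicator
#'
#' Item ratings (1 = no development ... 4 = completed) are averaged into an
#' overall physical-maturation score; for girls the menarche yes/no item
#' enters at its 1/4 coding. Puberty is classed as started when the mean
#' exceeds 1 (all-ones means not started).
#'
#' @param items numeric item scores, each in 1-4
#' @param menarche optional girls' menarche item coded 1 (no) or 4 (yes)
#' @return list: `pds_mean`, `started`
#' @examples
#' pubertyOnset(c(1, 1, 1, 2, 1))   # mean 1.2, started
#' @export
pubertyOnset <- function(items, menarche = NULL) {
  all_items <- c(items, menarche)
  if (any(is.na(all_items)) || any(all_items < 1 | all_items > 4))
    stop("PDS items must lie in 1-4")
  if (!is.null(menarche) && !menarche %in% c(1, 4))
    stop("menarche item must be coded 1 (no) or 4 (yes)")
  m <- mean(all_items)
  list(pds_mean = m, started = m > 1)
}

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`. Rates of exactly 0 or
#' 1 are undefined on the probit scale; when the trial count is supplied
#' they are clamped to `[1/(2n), 1 - 1/(2n)]`, otherwise an error is
#' raised.
#'
#' @param hit_rate,fa_rate rates in (0, 1)
#' @param n_trials optional trial count enabling the extreme-rate correction
#' @return numeric d'
#' @examples
#' dprime(0.8413, 0.1587)   # ~2
#' @export
dprime <- function(hit_rate, fa_rate, n_trials = NULL) {
  rates <- c(hit_rate, fa_rate)
  if (any(is.na(rates)) || any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]")
  if (any(rates %in% c(0, 1))) {
    if (is.null(n_trials))
      stop("rate of exactly 0 or 1: supply n_trials for the correction")
    clamp <- function(r) min(max(r, 1 / (2 * n_trials)), 1 - 1 / (2 * n_trials))
    hit_rate <- clamp(hit_rate); fa_rate <- clamp(fa_rate)
  }
  qnorm(hit_rate) - qnorm(fa_rate)
}

#' Hit reaction time standard error (HRT-SE)
#'
#' The standard error of the hit reaction times, `SD / sqrt(n)`; a higher
#' value indicates less consistent response speed (inattentiveness).
#'
#' @param reaction_times hit reaction times in ms (>= 2 values)
#' @return standard error in ms
#' @examples
#' hrtSe(c(300, 340))   # 20
#' @export
hrtSe <- function(reaction_times) {
  reaction_times <- reaction_times[!is.na(reaction_times)]
  if (length(reaction_times) < 2) stop("need at least 2 hit reaction times")
  sd(reaction_times) / sqrt(length(reaction_times))
}
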