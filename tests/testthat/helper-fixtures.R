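# Small fixtures built in code.

# an OmicsBlock with explicit values/flags; defaults give an uncensored
# 6-sample x 3-feature protein-style block
makeBlock <- function(values = NULL, kind = "protein", lod = NULL,
                      loq1 = NULL, loq2 = NULL, cv = NULL, call_rate = NULL,
                      plate = NULL, censored = NULL, log2 = FALSE) {
  if (is.null(values)) {
    set.seed(99)
    values <- matrix(2^rnorm(18, 8), 6, 3,
                     dimnames = list(paste0("s", 1:6), paste0("f", 1:3)))
  }
  p <- ncol(values)
  fm <- data.frame(
    block = "test", kind = kind,
    lod = if (is.null(lod)) rep(NA_real_, p) else lod,
    loq1 = if (is.null(loq1)) rep(NA_real_, p) else loq1,
    loq2 = if (is.null(loq2)) rep(NA_real_, p) else loq2,
    cv_percent = if (is.null(cv)) rep(10, p) else cv,
    call_rate = if (is.null(call_rate)) rep(1, p) else call_rate,
    row.names = colnames(values))
  sm <- if (is.null(plate)) NULL else data.frame(plate = plate)
  OmicsBlock(values, fm, sample_meta = sm, censored = censored, log2 = log2)
}

# noiseless qPCR wells generated from known relative quantities: with
# efficiency E, Cq = cq0 - log(q)/log(1+E); calibrators have quantity 1
makeNoiselessWells <- function(qt, qs, run_size = 4,
                               eff = c(T = 1, S = 1),
                               cq0 = c(T = 24, S = 27)) {
  n <- length(qt)
  ids <- sprintf("kid_%02d", seq_len(n))
  runs <- sprintf("run_%d", ((seq_len(n) - 1) %/% run_size) + 1)
  rows <- list()
  add <- function(id, target, run, q, role, iq = NA_real_, nrep = 3) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = id, target = target, run_id = run,
      replicate = seq_len(nrep),
      cq = cq0[[target]] - log(q) / log(1 + eff[[target]]),
      role = role, input_quantity = iq)
  }
  for (i in seq_len(n)) {
    add(ids[i], "T", runs[i], qt[i], "sample")
    add(ids[i], "S", runs[i], qs[i], "sample")
  }
  for (run in unique(runs)) {
    for (target in c("T", "S")) {
      for (j in 1:8) add(sprintf("cal_%02d", j), target, run, 1,
                         "inter_run_calibrator", nrep = 1)
      for (q in 2^(0:3)) add(sprintf("std_%g", q), target, run, q,
                             "dilution_standard", iq = q, nrep = 1)
    }
  }
  do.call(rbind, rows)
}

# a small cohort-like data.frame with covariates and a planted linear effect
# of `x` on `y`
makeAssocData <- function(n, beta, seed, binary = FALSE) {
  set.seed(seed)
  age <- runif(n, 5, 12)
  sex <- factor(sample(c("male", "female"), n, TRUE))
  centre <- factor(sample(paste0("c", 1:4), n, TRUE))
  x <- rnorm(n)
  if (binary) {
    lp <- -0.5 + beta * x + 0.1 * (age - 8)
    y <- rbinom(n, 1, 1 / (1 + exp(-lp)))
  } else {
    y <- 0.2 * (age - 8) + 0.3 * (sex == "female") + beta * x + rnorm(n)
  }
  data.frame(y = y, x = x, age = age, sex = sex, centre = centre)
}

# tiny but fully featured simulation config for fast end-to-end runs
tinySim <- function(seed, n = 250, effects = c(zBMI = 0.3),
                    n_age = c(proteins = 2, serum = 2, urine = 2), ...) {
  simConfig(n_children = n,
            block_sizes = c(proteins = 6, serum = 6, urine = 6),
            n_age_features = n_age,
            delta_age_outcome_effects = effects,
            seed = seed, ...)
}
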