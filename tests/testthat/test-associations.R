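test_that("marker preparation applies the documented transforms", {
  set.seed(24)
  n <- 50
  cohort <- data.frame(id = paste0("k", 1:n), age = runif(n, 5, 12),
                       zBMI = rnorm(n, 0.4, 1.2),
                       fat_pct = rnorm(n, 7, 4),
                       cbcl_ext = rpois(n, 6))
  telo <- data.frame(sample_id = cohort$id,
                     relative_ts = exp(rnorm(n, 0, 0.2)))
  deltas <- list(immuno = data.frame(sample_id = cohort$id,
                                     delta_age = rnorm(n)))
  dat <- prepareMarkers(cohort, telomere = telo, deltas = deltas)
  # telomere: sign-flipped, unit SD
  expect_equal(sd(dat$telomere_shortening), 1)
  expect_equal(cor(dat$telomere_shortening, telo$relative_ts), -1)
  # delta age passes through in years
  expect_equal(dat$delta_age_immuno, deltas$immuno$delta_age)
  # BMI z-score passes through unscaled
  expect_equal(dat$zBMI, cohort$zBMI)
  # other continuous outcomes are centred/scaled
  expect_equal(mean(dat$fat_pct), 0)
  expect_equal(sd(dat$fat_pct), 1)
  # CBCL is log(x+1)-transformed before scaling (zeros map to log1p 0)
  lg <- log(cohort$cbcl_ext + 1)
  expect_equal(dat$cbcl_ext, (lg - mean(lg)) / sd(lg))
})

test_that("a planted linear effect is recovered with a covering Wald CI", {
  dat <- makeAssocData(500, beta = 0.5, seed = 25)
  spec <- associationSpec("x", "y", covariates = c("age", "sex", "centre"))
  res <- runAssociation(spec, dat)
  expect_equal(res$estimate, 0.5, tolerance = 0.15)
  expect_true(res$ci_low <= 0.5 && res$ci_high >= 0.5)
  expect_lt(res$p, 1e-10)
  expect_equal(res$n, 500)
})

test_that("listwise deletion and logistic odds ratios work as specified", {
  dat <- makeAssocData(800, beta = 0.7, seed = 26, binary = TRUE)
  dat$age[1:10] <- NA
  spec <- associationSpec("x", "y", covariates = c("age", "sex"),
                          family = "logistic")
  res <- runAssociation(spec, dat)
  expect_equal(res$n, 790)
  expect_equal(log(res$estimate), 0.7, tolerance = 0.25)
  expect_true(res$ci_low > 0)   # OR scale
  # non-binary outcome refuses the logistic family
  expect_error(runAssociation(associationSpec("x", "fake",
                                              covariates = c("age", "sex"),
                                              family = "logistic"),
                              transform(dat, fake = rnorm(790 + 10))),
               "binary")
})

test_that("invariant: with a scaled outcome and no covariates the slope is r * SD ratio", {
  set.seed(27)
  x <- rnorm(120); y <- 0.4 * x + rnorm(120)
  dat <- data.frame(y = y, x = x)
  res <- runAssociation(associationSpec("x", "y", covariates = character(0)),
                        dat)
  expect_equal(res$estimate, cor(x, y) * sd(y) / sd(x), tolerance = 1e-10)
})

test_that("invariant: a constant shift of the exposure leaves the slope unchanged", {
  dat <- makeAssocData(300, beta = 0.4, seed = 28)
  spec <- associationSpec("x", "y", covariates = c("age", "sex", "centre"))
  base <- runAssociation(spec, dat)
  shifted <- runAssociation(spec, transform(dat, x = x + 5))
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-10)
  expect_equal(shifted$p, base$p, tolerance = 1e-10)
})

test_that("degenerate model inputs are rejected informatively", {
  dat <- makeAssocData(100, beta = 0, seed = 29)
  expect_error(associationSpec("x", "y", covariates = c("x", "age")),
               "must not appear")
  dat$x2 <- dat$x
  expect_error(runAssociation(associationSpec("x", "y",
                                              covariates = c("age", "x2")),
                              transform(dat, x2 = x)),
               "collinear|aliased")
  expect_error(runAssociation(associationSpec("x", "missing_col"), dat),
               "absent")
})

test_that("BH q-values match the hand-computed step-up on the worked example", {
  res <- data.frame(p = c(0.01, 0.02, 0.03, 0.04))
  out <- fdrAdjust(res)
  expect_equal(out$q, rep(0.04, 4))
  expect_equal(fdrAdjust(data.frame(p = 0.37))$q, 0.37)
  set.seed(30)
  p <- runif(25)
  q <- fdrAdjust(data.frame(p = p))$q
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p
  expect_equal(q, bhBruteForce(p))
  expect_error(fdrAdjust(data.frame(p = numeric(0))), "empty")
})

test_that("partial correlation removes exactly the covariate-shared signal", {
  set.seed(31)
  n <- 1500
  z <- rnorm(n)
  x <- z + rnorm(n); y <- z + rnorm(n)
  marg <- cor(x, y)
  pc <- partialCorrelation(x, y, data.frame(z = z))
  expect_gt(marg, 0.3)
  expect_lt(abs(pc$r), 0.08)
  expect_equal(pc$df, n - 3L)
  # identity case
  expect_equal(partialCorrelation(x, x + 0, data.frame(u = rnorm(n)))$r, 1)
  # categorical covariates are expanded to indicators
  g <- factor(sample(letters[1:4], n, TRUE))
  xg <- rnorm(n) + as.integer(g); yg <- rnorm(n) + as.integer(g)
  pcg <- partialCorrelation(xg, yg, data.frame(g = g))
  expect_lt(abs(pcg$r), 0.08)
  expect_equal(pcg$df, n - 2L - 3L)
  expect_error(partialCorrelation(rep(1, 50), rnorm(50)), "variance")
})

test_that("sensitivity variants reduce to the base fit when they add nothing", {
  dat <- makeAssocData(400, beta = 0.3, seed = 32)
  dat$sex <- factor(rep("female", 400))   # single stratum == base rows
  spec <- associationSpec("x", "y", covariates = c("age", "centre"))
  base <- runAssociation(spec, dat)
  sens <- sensitivitySuite(list(spec), dat, cell_columns = character(0),
                           risk_columns = character(0),
                           variants = c("sex_stratified", "risk_adjusted"))
  res <- sens$results
  strat <- res[res$variant == "sex=female", ]
  expect_equal(strat$estimate, base$estimate, tolerance = 1e-12)
  noop <- res[res$variant == "risk_adjusted", ]
  expect_equal(noop$estimate, base$estimate, tolerance = 1e-12)
  expect_equal(noop$p, base$p, tolerance = 1e-12)
})

test_that("a sex-specific planted effect appears only in that stratum", {
  set.seed(33)
  n <- 2000
  sex <- factor(sample(c("male", "female"), n, TRUE))
  age <- runif(n, 5, 12)
  centre <- factor(sample(paste0("c", 1:3), n, TRUE))
  x <- rnorm(n)
  y <- 0.1 * (age - 8) + ifelse(sex == "female", 0.5, 0) * x + rnorm(n)
  dat <- data.frame(y, x, age, sex, centre)
  sens <- sensitivitySuite(list(associationSpec("x", "y", covariates = c("age", "sex", "centre"))), dat,
                           cell_columns = character(0),
                           variants = "sex_stratified")
  res <- sens$results
  girls <- res[res$variant == "sex=female", ]
  boys <- res[res$variant == "sex=male", ]
  expect_equal(girls$estimate, 0.5, tolerance = 0.15)
  expect_lt(abs(boys$estimate), 0.12)
})

test_that("a homogeneous effect keeps a consistent sign across centres", {
  set.seed(34)
  n <- 1800
  centre <- factor(sample(paste0("c", 1:6), n, TRUE))
  age <- runif(n, 5, 12)
  sex <- factor(sample(c("male", "female"), n, TRUE))
  x <- rnorm(n)
  y <- 0.5 * x + 0.1 * (age - 8) + rnorm(n)
  dat <- data.frame(y, x, age, sex, centre)
  sens <- sensitivitySuite(list(associationSpec("x", "y", covariates = c("age", "sex", "centre"))), dat,
                           cell_columns = character(0),
                           variants = "centre_stratified")
  expect_equal(nrow(sens$results), 6)
  expect_true(all(sens$results$estimate > 0))
})

test_that("undersized strata are skipped with a log entry, not an error", {
  dat <- makeAssocData(60, beta = 0.3, seed = 35)
  dat$centre <- factor(c(rep("big", 58), rep("tiny", 2)))
  sens <- sensitivitySuite(list(associationSpec("x", "y", covariates = c("age", "sex", "centre"))), dat,
                           cell_columns = character(0),
                           variants = "centre_stratified")
  expect_true(any(grepl("tiny", sens$skipped)) ||
                !"centre=tiny" %in% sens$results$variant)
  expect_true("centre=big" %in% sens$results$variant)
})
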