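scaledMatrix <- function(n, p, seed) {
  set.seed(seed)
  x <- scale(matrix(rnorm(n * p), n, p))
  matrix(as.numeric(x), n, p,
         dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(p))))
}

test_that("a pure noiseless linear signal is fit essentially perfectly", {
  x <- scaledMatrix(60, 4, 16)
  ages <- as.numeric(8 + x %*% c(1.5, -1, 0.5, 0.2))
  model <- tuneClock(x, ages, folds = 5, seed = 1)
  preds <- predictAges(model, x, ages)
  expect_gte(cor(preds$predicted_age, ages), 0.999)
})

test_that("pure-noise response shrinks to the empty model with mean intercept", {
  x <- scaledMatrix(80, 3, 17)
  set.seed(170)
  ages <- rnorm(80, 8, 2)   # unrelated to x
  model <- tuneClock(x, ages, folds = 10, seed = 2, alphas = 1)
  expect_length(clockWeights(model), 0)
  expect_equal(model@intercept, mean(ages), tolerance = 1e-8)
  preds <- predictAges(model, x, ages)
  expect_equal(preds$predicted_age, rep(mean(ages), 80), tolerance = 1e-8)
})

test_that("fold assignment and selection are deterministic given the seed", {
  x <- scaledMatrix(50, 6, 18)
  set.seed(180)
  ages <- as.numeric(8 + x %*% rnorm(6, 0, 0.3) + rnorm(50))
  m1 <- tuneClock(x, ages, seed = 5)
  m2 <- tuneClock(x, ages, seed = 5)
  expect_identical(clockAlpha(m1), clockAlpha(m2))
  expect_identical(clockLambda(m1), clockLambda(m2))
  expect_identical(clockWeights(m1), clockWeights(m2))
  expect_identical(omicage:::.makeFolds(ages, 10, 5),
                   omicage:::.makeFolds(ages, 10, 5))
})


test_that("delta age is predicted minus chronological, with strict features", {
  model <- new("ClockModel", weights = c(f1 = 0.5), intercept = 8,
               alpha = 0.5, lambda = 0.1, features = c("f1", "f2"),
               scaler = list(), blockComposition = c(all = 1L),
               cvMsePath = data.frame())
  x <- cbind(f1 = c(1, 0, -1), f2 = c(0, 0, 0))
  rownames(x) <- paste0("s", 1:3)
  preds <- predictAges(model, x, c(8, 8, 8))
  expect_equal(preds$predicted_age, c(8.5, 8, 7.5))
  expect_equal(preds$delta_age, c(0.5, 0, -0.5))
  # all-zero input predicts the intercept
  x0 <- x; x0[] <- 0
  expect_equal(predictAges(model, x0, c(7, 7, 7))$predicted_age, rep(8, 3))
  # missing model features must not be zero-filled silently
  expect_error(predictAges(model, x[, "f2", drop = FALSE], rep(8, 3)),
               "absent")
})

test_that("validation metrics behave for exact and shifted predictions", {
  model <- new("ClockModel", weights = c(f1 = 1), intercept = 0,
               alpha = 1, lambda = 0, features = "f1", scaler = list(),
               blockComposition = c(all = 1L), cvMsePath = data.frame())
  ages <- c(5, 6, 7, 9, 11)
  x <- cbind(f1 = ages); rownames(x) <- paste0("s", 1:5)
  val <- validateClock(model, x, ages)
  expect_equal(val$pearson_r, 1)
  expect_equal(val$mae, 0)
  shifted <- new("ClockModel", weights = c(f1 = 1), intercept = 1,
                 alpha = 1, lambda = 0, features = "f1", scaler = list(),
                 blockComposition = c(all = 1L), cvMsePath = data.frame())
  val2 <- validateClock(shifted, x, ages)
  expect_equal(val2$pearson_r, 1)
  expect_equal(val2$mae, 1)
  expect_error(validateClock(model, x[1:2, , drop = FALSE], ages[1:2]),
               "3 test samples")
  # constant predictions are reported as undefined correlation, not a crash
  const <- new("ClockModel", weights = setNames(numeric(0), character(0)),
               intercept = 8, alpha = 1, lambda = 99, features = "f1",
               scaler = list(), blockComposition = setNames(0L, "all")[0],
               cvMsePath = data.frame())
  val3 <- validateClock(const, x, ages)
  expect_true(val3$constant_predictions)
  expect_true(is.na(val3$pearson_r))
})

test_that("per-group validation returns centre-wise correlations", {
  set.seed(19)
  ages <- runif(60, 5, 12)
  x <- cbind(f1 = ages + rnorm(60, 0, 0.5)); rownames(x) <- paste0("s", 1:60)
  model <- new("ClockModel", weights = c(f1 = 1), intercept = 0, alpha = 1,
               lambda = 0, features = "f1", scaler = list(),
               blockComposition = c(all = 1L), cvMsePath = data.frame())
  groups <- rep(c("A", "B", "C"), each = 20)
  val <- validateClock(model, x, ages, groups = groups)
  expect_equal(nrow(val$per_group), 3)
  expect_true(all(val$per_group$r > 0.8))
  expect_true(all(val$per_group$p < 0.05))
})

test_that("the progression test detects a planted half-year-scale increase", {
  set.seed(20)
  n <- 100
  first <- data.frame(sample_id = paste0("s", 1:n),
                      predicted_age = runif(n, 5, 12))
  second <- first
  second$predicted_age <- first$predicted_age + rnorm(n, 0.3, 0.1)
  res <- progressionTest(first, second)
  expect_lt(res$one_sided_p, 1e-10)
  expect_equal(res$mean_increase, 0.3, tolerance = 0.1)
  expect_equal(res$n_pairs, n)
  expect_error(progressionTest(first[1, ], second[1, ]), "2 paired")
  expect_error(progressionTest(first, transform(first,
                                                predicted_age = predicted_age + 1)),
               "variance")
})


test_that("clock models serialize to JSON and back", {
  x <- scaledMatrix(50, 4, 22)
  set.seed(220)
  ages <- as.numeric(8 + x %*% c(1, -0.5, 0, 0) + rnorm(50, 0, 0.5))
  model <- tuneClock(x, ages, folds = 5, seed = 3,
                     scaler = list(center = setNames(rep(0, 4), colnames(x)),
                                   scale = setNames(rep(1, 4), colnames(x))))
  path <- withr::local_tempfile(fileext = ".json")
  writeClockModel(model, path)
  back <- readClockModel(path)
  expect_equal(clockWeights(back), clockWeights(model))
  expect_equal(back@intercept, model@intercept)
  expect_equal(clockAlpha(back), clockAlpha(model))
  expect_equal(predictAges(back, x, ages)$predicted_age,
               predictAges(model, x, ages)$predicted_age)
})

test_that("adding a pure-noise block barely moves test performance", {
  set.seed(23)
  n <- 200
  ages <- runif(n, 5, 12)
  signal <- sapply(1:10, function(i) 0.4 * ages + rnorm(n))
  signal <- scale(signal)
  colnames(signal) <- paste0("sig_", 1:10)
  noise <- scale(matrix(rnorm(n * 10), n, 10))
  colnames(noise) <- paste0("noi_", 1:10)
  rownames(signal) <- rownames(noise) <- paste0("s", 1:n)
  tr <- 1:150; te <- 151:200
  m1 <- tuneClock(signal[tr, ], ages[tr], seed = 4)
  m2 <- tuneClock(cbind(signal, noise)[tr, ], ages[tr], seed = 4)
  r1 <- validateClock(m1, signal[te, ], ages[te])$pearson_r
  r2 <- validateClock(m2, cbind(signal, noise)[te, ], ages[te])$pearson_r
  expect_lt(abs(r1 - r2), 0.1)
})
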