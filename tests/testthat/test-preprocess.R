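test_that("protein linear-range rule keeps only features with >30% quantifiable", {
  # f1: 2/8 in range (25%) -> dropped; f2: 3/8 (37.5%) -> kept; f3: all in range
  flags <- cbind(f1 = c(-1L, -1L, -1L, -1L, 1L, 1L, 0L, 0L),
                 f2 = c(-1L, -1L, -1L, -1L, -1L, 0L, 0L, 0L),
                 f3 = rep(0L, 8))
  vals <- matrix(2^rnorm(24, 8), 8, 3,
                 dimnames = list(paste0("s", 1:8), colnames(flags)))
  vals[flags != 0L] <- NA
  b <- makeBlock(vals, loq1 = rep(2, 3), loq2 = rep(2000, 3),
                 censored = flags)
  out <- filterQuantifiable(b, "protein")
  expect_setequal(rownames(out$block), c("f2", "f3"))
  expect_equal(out$qc$dropped_features$feature, "f1")
  expect_match(out$qc$dropped_features$reason, "linear_range")
})

test_that("serum rule drops only when CV > 30 AND below-LOD fraction > 30%", {
  set.seed(4)
  vals <- matrix(2^rnorm(40, 8), 10, 4,
                 dimnames = list(paste0("s", 1:10), paste0("f", 1:4)))
  # f1: high CV, 10% below LOD -> retained; f2: high CV, 40% below -> dropped
  # f3: low CV, 90% below -> retained; f4: clean -> retained
  lods <- c(quantile(vals[, 1], 0.10), quantile(vals[, 2], 0.45),
            quantile(vals[, 3], 0.95), min(vals[, 4]) / 2)
  b <- makeBlock(vals, kind = "serum_metabolite", lod = unname(lods),
                 cv = c(35, 35, 10, 10))
  out <- filterQuantifiable(b, "serum_metabolite")
  expect_setequal(rownames(out$block), c("f1", "f3", "f4"))
  expect_equal(out$qc$dropped_features$feature, "f2")
})

test_that("transcript rule drops low-call samples before low-call features", {
  set.seed(5)
  vals <- matrix(rnorm(50, 7), 10, 5,
                 dimnames = list(paste0("s", 1:10), paste0("f", 1:5)))
  vals[1, 1:4] <- NA                  # sample s1: 20% call rate
  b <- makeBlock(vals, kind = "transcript",
                 call_rate = c(0.005, 0.5, 1, 1, 1))
  out <- filterQuantifiable(b, "transcript")
  expect_false("s1" %in% colnames(out$block))
  expect_false("f1" %in% rownames(out$block))
  expect_equal(dim(out$block), c(4L, 9L))
})

test_that("a block passing all rules comes through identical with empty drops", {
  b <- makeBlock(loq1 = rep(1, 3), loq2 = rep(1e6, 3))
  out <- filterQuantifiable(b, "protein")
  expect_identical(omicsValues(out$block), omicsValues(b))
  expect_equal(nrow(out$qc$dropped_features), 0)
})

test_that("feature drops are insensitive to feature order", {
  set.seed(6)
  vals <- matrix(2^rnorm(60, 6), 10, 6,
                 dimnames = list(paste0("s", 1:10), paste0("f", 1:6)))
  lod <- apply(vals, 2, quantile, 0.5)
  cv <- c(40, 40, 10, 40, 10, 40)
  b1 <- makeBlock(vals, kind = "serum_metabolite", lod = lod, cv = cv)
  perm <- c(4, 1, 6, 2, 5, 3)
  b2 <- makeBlock(vals[, perm], kind = "serum_metabolite", lod = lod[perm],
                  cv = cv[perm])
  d1 <- filterQuantifiable(b1, "serum_metabolite")$qc$dropped_features$feature
  d2 <- filterQuantifiable(b2, "serum_metabolite")$qc$dropped_features$feature
  expect_setequal(d1, d2)
})

test_that("plate centering forces per-plate means to the grand mean", {
  # one feature, two plates with means 5 and 7 -> both centred to 6
  vals <- matrix(c(4, 6, 6, 8), 4, 1, dimnames = list(paste0("s", 1:4), "f1"))
  b <- makeBlock(vals, plate = c("p1", "p1", "p2", "p2"), log2 = TRUE)
  out <- plateCenter(b)
  v <- omicsValues(out)
  expect_equal(mean(v[1:2, 1]), 6)
  expect_equal(mean(v[3:4, 1]), 6)
  expect_equal(mean(v), mean(vals))          # grand mean preserved
  # idempotence
  expect_equal(omicsValues(plateCenter(out)), v)
  # single plate: identity
  b1 <- makeBlock(vals, plate = rep("p1", 4), log2 = TRUE)
  expect_equal(omicsValues(plateCenter(b1)), vals)
})

test_that("imputed values respect their censoring bounds and nothing else moves", {
  set.seed(8)
  n <- 30
  vals <- matrix(rnorm(n * 2, 10), n, 2,
                 dimnames = list(paste0("s", 1:n), c("f1", "f2")))
  flags <- matrix(0L, n, 2, dimnames = dimnames(vals))
  flags[1:5, 1] <- -1L; flags[6:8, 1] <- 1L
  vals[flags != 0L] <- NA
  orig <- vals
  b <- makeBlock(vals, loq1 = c(8.5, NA), loq2 = c(11.5, NA),
                 censored = flags, log2 = TRUE)
  out <- imputeTruncated(b, seed = 42)
  v <- omicsValues(out$block)
  expect_true(all(v[1:5, 1] <= 8.5))
  expect_true(all(v[6:8, 1] >= 11.5))
  expect_false(anyNA(v))
  untouched <- !is.na(orig)
  expect_identical(v[untouched], orig[untouched])
  expect_equal(out$qc$imputed_cell_count, 8L)
  # deterministic given the seed
  out2 <- imputeTruncated(b, seed = 42)
  expect_identical(omicsValues(out2$block), v)
  # identity when nothing is censored
  b0 <- makeBlock(log2 = TRUE)
  expect_identical(omicsValues(imputeTruncated(b0, 1)$block), omicsValues(b0))
})

test_that("lower-tail imputation matches the closed-form truncated-normal mean", {
  # in-range values crafted to have sample mean exactly LOQ1 and SD exactly 1
  loq1 <- 10
  inr <- loq1 + scale(seq_len(50))[, 1]
  n_cens <- 4000
  vals <- matrix(c(inr, rep(NA, n_cens)), ncol = 1,
                 dimnames = list(paste0("s", 1:(50 + n_cens)), "f1"))
  flags <- matrix(c(rep(0L, 50), rep(-1L, n_cens)), ncol = 1,
                  dimnames = dimnames(vals))
  b <- makeBlock(vals, loq1 = loq1, loq2 = 1e6, censored = flags, log2 = TRUE)
  out <- imputeTruncated(b, seed = 9)
  imp <- omicsValues(out$block)[51:(50 + n_cens), 1]
  # E[X | X <= mu] = mu - sd * dnorm(0)/pnorm(0) for X ~ N(mu, sd)
  expected <- loq1 - dnorm(0) / pnorm(0)
  expect_equal(mean(imp), expected, tolerance = 0.01)
})

test_that("features with too few in-range values are dropped as un-imputable", {
  vals <- matrix(c(1, 2, NA, NA, NA, NA, 5, 6, 7, 8, 9, 10), 6, 2,
                 dimnames = list(paste0("s", 1:6), c("bad", "good")))
  flags <- matrix(0L, 6, 2, dimnames = dimnames(vals))
  flags[3:6, 1] <- -1L
  b <- makeBlock(vals, loq1 = c(0.5, 0.5), loq2 = c(1e3, 1e3),
                 censored = flags, log2 = TRUE)
  out <- imputeTruncated(b, 1)
  expect_equal(out$qc$dropped_features$feature, "bad")
  expect_equal(rownames(out$block), "good")
})

test_that("median fold change recovers exact and simulated dilution factors", {
  set.seed(10)
  ref <- 2^rnorm(20, 5)
  m <- rbind(ref * 2, ref, ref * 0.25)
  dimnames(m) <- list(c("a", "b", "c"), paste0("f", 1:20))
  b <- makeBlock(m, kind = "urinary_metabolite")
  out <- medianFoldChangeNormalize(b, reference = ref)
  expect_equal(unname(out$dilution_factors), c(2, 1, 0.25))
  # pre-offset, the doubled sample normalizes back onto the reference
  expect_equal(2^omicsValues(out$block)["a", ] -
                 metadata(out$block)$mfc_offset,
               ref, tolerance = 1e-12, ignore_attr = TRUE)
  # scale equivariance: scaling one sample scales its factor
  m2 <- m; m2["c", ] <- m2["c", ] * 10
  out2 <- medianFoldChangeNormalize(makeBlock(m2, kind = "urinary_metabolite"),
                                    reference = ref)
  expect_equal(unname(out2$dilution_factors["c"]),
               unname(out$dilution_factors["c"]) * 10)
  expect_error(medianFoldChangeNormalize(b, reference = rep(0, 20)),
               "reference")
})

test_that("estimated urinary dilutions track the simulated ground truth", {
  st <- generateStudy(simConfig(seed = 11))
  out <- preprocessBlock(studyBlocks(st)$urine)
  truth <- unlist(groundTruth(st)$dilution_factors)
  expect_gt(cor(out$dilution_factors, truth), 0.95)
})

test_that("feature scaling gives mean 0 / SD 1 and a reusable scaler", {
  vals <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(2, 4, 9))
  rownames(vals) <- paste0("s", 1:3)
  b <- makeBlock(vals, log2 = TRUE)
  out <- scaleFeatures(b)
  v <- omicsValues(out$block)
  expect_equal(unname(colMeans(v)), c(0, 0))
  expect_equal(unname(apply(v, 2, sd)), c(1, 1))
  expect_equal(out$qc$dropped_features$feature, "f2")   # constant: dropped
  # reapplying the stored scaler reproduces the scaled matrix
  b2 <- makeBlock(vals[, c("f1", "f3")], log2 = TRUE)
  expect_equal(omicsValues(applyScaler(b2, out$scaler)), v)
  expect_error(applyScaler(makeBlock(vals[, "f1", drop = FALSE], log2 = TRUE),
                           out$scaler), "absent")
})
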