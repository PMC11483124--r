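test_that("dataset construction encodes targets and splits reproducibly", {
  tab <- syntheticFeatureTable()
  expect_equal(unique((tab$wEnd / tab$wStart)[tab$wEnd == 2]), 2.0)
  tab2 <- data.frame(tab[1, ])
  tab2$wStart <- 2.5; tab2$wEnd <- 1
  expect_equal(repool:::.targetColumn(tab2, "weight_ratio"), 0.4)
  ds1 <- buildRegressionDataset(tab, "inhibition", splitSeed = 5L)
  ds2 <- buildRegressionDataset(tab, "inhibition", splitSeed = 5L)
  expect_identical(ds1$train, ds2$train)
  expect_length(intersect(ds1$train, ds1$test), 0)
  expect_equal(length(ds1$train) + length(ds1$test), nrow(tab))
  expect_equal(length(ds1$train) / nrow(tab), 0.7, tolerance = 0.05)
  # standardized on the training split
  expect_equal(unname(colMeans(ds1$x[ds1$train, ])), rep(0, 7),
               tolerance = 1e-10)
})

test_that("constant features are dropped with a warning", {
  tab <- syntheticFeatureTable()
  tab$tRange <- 3
  expect_warning(ds <- buildRegressionDataset(tab, "inhibition"),
                 "constant")
  expect_false("tRange" %in% ds$features)
  tab$gIn <- 0
  expect_error(buildRegressionDataset(tab, "inhibition"), "zero variance")
})

test_that("an exactly linear target is recovered perfectly and noise is not", {
  set.seed(2)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("tRec", "tDrec", "deltaF",
                                      "braceHeight")))
  tab <- data.frame(x, wStart = 1, wEnd = rep(c(1, 2), n / 2))
  tab$gIn <- 2 * x[, "deltaF"] - x[, "tRec"] + 0.5
  ds <- buildRegressionDataset(tab, "inhibition",
                               features = colnames(x))
  fits <- fitRegressionModels(ds, models = c("ols", "ridge"))
  expect_equal(fits$r2Test[fits$model == "ols"], 1, tolerance = 1e-6)
  tab$gIn <- rnorm(n)
  dsn <- buildRegressionDataset(tab, "inhibition", features = colnames(x))
  fitn <- fitRegressionModels(dsn, models = "ols")
  expect_lt(abs(fitn$r2Test), 0.35)
})

test_that("the stepwise F ranking finds the informative feature and nests MSE", {
  set.seed(3)
  n <- 150
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("f1", "f2", "f3", "f4", "f5")))
  tab <- data.frame(x, wStart = 1, wEnd = 1)
  tab$gIn <- 3 * x[, "f3"] + rnorm(n, 0, 0.3)
  ds <- buildRegressionDataset(tab, "inhibition", features = colnames(x))
  sw <- stepwiseFRanking(ds, models = "ols")
  expect_equal(sw$ranking$feature[1], "f3")
  # training MSE of nested least squares never increases
  expect_true(all(diff(sw$mse$ols) <= 1e-10))
  # the curve plateaus after the informative feature enters
  expect_lt(sw$mse$ols[1], 0.2 * var(ds$y[ds$train]))
  expect_equal(nrow(sw$mse), 5)
})

test_that("mutual information ranks dependence and vanishes for shuffled data", {
  set.seed(4)
  y <- runif(150)
  self <- knnMutualInformation(y, y)
  noisy <- knnMutualInformation(y + rnorm(150, 0, 0.3), y)
  shuffled <- knnMutualInformation(sample(y), y)
  expect_gt(self, noisy)
  expect_gt(noisy, shuffled)
  expect_lt(shuffled, 0.2)
  tab <- data.frame(tRec = y, tDrec = sample(y), wStart = 1, wEnd = 1,
                    gIn = y)
  ds <- buildRegressionDataset(tab, "inhibition",
                               features = c("tRec", "tDrec"))
  mi <- mutualInfoRanking(ds)
  expect_equal(mi$feature[1], "tRec")
})

test_that("known smooth maps from inputs to features are recovered out of sample", {
  tab <- syntheticFeatureTable()
  for (tg in c("inhibition", "neuromodulation", "weight_ratio")) {
    rep <- regressionReport(tab, tg)
    expect_gt(max(rep@r2), 0.9)
    expect_true(all(rep@r2 <= 1))
    expect_equal(nrow(rep@stepwise), 7)
  }
})

test_that("regression reports are reproducible run to run", {
  tab <- syntheticFeatureTable()
  r1 <- regressionReport(tab, "inhibition")
  r2 <- regressionReport(tab, "inhibition")
  expect_identical(r1@r2, r2@r2)
  expect_identical(r1@miRanking, r2@miRanking)
  expect_identical(r1@stepwise, r2@stepwise)
})
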