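test_that("recruitment and de-recruitment timing are read off the raw train", {
  expect_equal(recruitmentTime(c(2.1, 2.3, 5)), 2.1)
  expect_true(is.na(recruitmentTime(numeric(0))))
  expect_equal(derecruitmentTime(c(2.1, 19.4)), 19.4)
  expect_equal(activationDuration(2.5, 19.5), 17)
  expect_equal(activationDuration(5, 5), 0)
  expect_error(activationDuration(6, 5), "precede")
  expect_equal(recruitmentRange(c(1.8, 2.4, 5.0)), 3.2)
  expect_equal(recruitmentRange(c(1.8, NA, 5.0)), 3.2)
})

test_that("saturation is the smoothed-rate slope from 1 s post-recruitment to the peak", {
  tt <- seq(0, 22, by = 0.005)
  # hand case: f(3) = 10, f(11) = 14, tRec = 2 -> slope 0.5
  r <- approx(c(0, 3, 11, 22), c(10 - 3 * 0.5, 10, 14, 14), xout = tt)$y
  expect_equal(saturation(r, 2, tt), 0.5, tolerance = 1e-6)
  # a perfectly linear rise returns its slope
  lin <- 1.5 * tt
  expect_equal(saturation(lin, 4, tt), 1.5, tolerance = 1e-9)
  # a plateaued rate gives a slope near zero, below its initial-phase slope
  plat <- pmin(8 * tt, 12)
  expect_lt(saturation(plat, 1, tt), 0.4)
  expect_lt(saturation(plat, 1, tt), 8)
  expect_true(is.na(saturation(lin, 10.5, tt)))
})

test_that("delta-F implements the reporter-pair rule", {
  tt <- seq(0, 22, by = 0.005)
  rep_rate <- approx(c(0, 5, 15, 22), c(0, 12, 8, 0), xout = tt)$y
  # f0 at test recruitment (5 s) = 12, f1 at de-recruitment (15 s) = 8
  expect_equal(deltaF(rep_rate, 5, 15, 2, tt), 4, tolerance = 1e-9)
  # symmetric reporter rate and symmetric test on/off window give 0
  sym <- 10 - abs(tt - 11)
  expect_equal(deltaF(sym, 8, 14, 2, tt), 0, tolerance = 1e-9)
  # recruitment difference of 0.5 s excludes the pair
  expect_true(is.na(deltaF(rep_rate, 2.5, 15, 2, tt)))
})

test_that("brace-height matches the analytic point-to-line distance", {
  tt <- seq(0, 22, by = 0.005)
  # exactly linear rise: zero
  expect_equal(braceHeight(2 * tt, 1, tt), 0, tolerance = 1e-9)
  # quadratic bulge: f = chord + a*(t - t0)*(t1 - t) with known apex
  t0 <- 2; t1 <- 11; a <- 0.3
  chord <- 1 + 0.8 * tt
  f <- chord + ifelse(tt >= t0 & tt <= t1, a * (tt - t0) * (t1 - tt), 0)
  # apex vertical deviation a*(t1-t0)^2/4; perpendicular = vertical * cos
  # of the chord angle with slope 0.8
  expected <- a * (t1 - t0)^2 / 4 / sqrt(1 + 0.8^2)
  expect_equal(braceHeight(f, t0, tt), expected, tolerance = 1e-3)
  # normalization divides by the chord peak rate
  expect_equal(braceHeight(f, t0, tt, normalize = TRUE),
               expected / (1 + 0.8 * 11), tolerance = 1e-3)
  expect_true(is.na(braceHeight(f, 11, tt)))
})

test_that("pool feature extraction matches hand computation on a two-neuron fixture", {
  res <- handBuiltResult()
  f <- extractPoolFeatures(res, normalizeBrace = FALSE)
  expect_equal(f$tRec, mean(c(2, 5)))
  expect_equal(f$tDrec, mean(c(20, 15)))
  expect_equal(f$tDur, mean(c(18, 10)))
  expect_equal(f$tRange, 3)
  expect_equal(f$nRecruited, 2L)
  # only the (reporter = neuron 1, test = neuron 2) pair is admissible;
  # reporter rate at 5 s is 8 + 4*(1 - 6/9), at 15 s is 8 + 4*(1 - 4/9)
  expect_equal(f$nPairs, 1L)
  expect_equal(f$deltaF, (8 + 4 * (1 - 6 / 9)) - (8 + 4 * (1 - 4 / 9)),
               tolerance = 1e-9)
  # neuron 2's rate is flat at 10: saturation 0, brace-height 0
  bh2 <- braceHeight(res@rates[, 2], 5, res@time)
  expect_equal(bh2, 0, tolerance = 1e-9)
})

test_that("identical trains collapse pool means to the single-neuron value", {
  res <- handBuiltResult()
  res@rates <- cbind(res@rates[, 1], res@rates[, 1])
  res@spikes <- list(res@spikes[[1]], res@spikes[[1]])
  f <- extractPoolFeatures(res)
  expect_equal(f$tRange, 0)
  expect_equal(f$tRec, 2)
  expect_equal(f$nPairs, 0L)  # no pair separated by more than 1 s
})

test_that("seed aggregation is the average of per-run averages", {
  r1 <- data.frame(rMod = 1, gIn = 0, wStart = 1, wEnd = 1, seed = 1,
                   converged = TRUE, mse = 0.5, tRec = 2, tDrec = 18,
                   tDur = 16, tRange = 6, alphaSat = 1, deltaF = 4,
                   braceHeight = 0.1, nRecruited = 20, nPairs = 50)
  r2 <- r1; r2$seed <- 2; r2$deltaF <- 6; r2$tRec <- 4
  agg <- aggregateFeatures(rbind(r1, r2))
  expect_equal(nrow(agg), 1)
  expect_equal(agg$deltaF, 5)
  expect_equal(agg$tRec, 3)
  expect_equal(agg$nSeeds, 2)
})

test_that("delta-F from the pipeline equals a brute-force re-read of the rates", {
  res <- cachedRun(1, 0, 1, 1, 1L)
  f <- extractPoolFeatures(res)
  tt <- res@time
  tRec <- vapply(res@spikes, recruitmentTime, numeric(1))
  tDrec <- vapply(res@spikes, derecruitmentTime, numeric(1))
  vals <- c()
  for (i in seq_along(res@spikes)) for (j in seq_along(res@spikes)) {
    if (i == j || is.na(tRec[i]) || is.na(tRec[j])) next
    if (tRec[j] - tRec[i] <= 1) next
    f0 <- approx(tt, res@rates[, i], xout = tRec[j])$y
    f1 <- approx(tt, res@rates[, i], xout = tDrec[j])$y
    vals <- c(vals, f0 - f1)
  }
  expect_equal(f$deltaF, mean(vals), tolerance = 1e-9)
  expect_equal(f$nPairs, length(vals))
})

test_that("spike CSV round-trips through the standard format", {
  sp <- list(c(1.5, 2.25), numeric(0), c(0.5))
  path <- tempfile(fileext = ".csv")
  writeSpikeCSV(sp, path)
  back <- readSpikeCSV(path, N = 3)
  expect_equal(back, sp)
})
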