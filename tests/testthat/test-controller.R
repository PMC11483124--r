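test_that("the triangular reference has the standard geometry", {
  ref <- makeReference()
  tt <- attr(ref, "time")
  at <- function(x) ref[match(x, tt)]
  expect_equal(at(1.0), 0)
  expect_equal(at(11.0), 16)
  expect_equal(at(6.0), 8)
  expect_equal(at(21.0), 0)
  expect_true(all(ref[tt < 1] == 0))
  expect_true(all(ref[tt > 21] == 0))
  expect_equal(max(ref), 16)
  expect_equal(tt[which.max(ref)], 11)
})

test_that("the inhibitory bias follows its quadratic coupling to neuromodulation", {
  expect_equal(computeBin(1.0), 4.0)
  expect_equal(computeBin(0.8), 2.0)
  expect_equal(computeBin(1.2), 6.5)
})

test_that("the inhibitory command couples to excitation through gain and bias", {
  iEx <- seq(0, 16, length.out = 100)
  expect_equal(computeIin(iEx, 0, 1.0), rep(4, 100))
  expect_equal(computeIin(numeric(100), -0.7, 1.0), rep(4, 100))
  down <- computeIin(iEx, -0.7, 1.0)
  expect_true(all(diff(down) < 0))
})

test_that("rate smoothing conserves unit area and recovers a periodic rate", {
  expect_identical(smoothRate(numeric(0), 10), numeric(2001))
  one <- smoothRate(5, 10)
  expect_equal(sum(one) * 0.005, 1, tolerance = 1e-6)
  # periodic 10 imp/s train: interior plateau equals the rate
  sp <- seq(0.05, 30, by = 0.1)
  r <- smoothRate(sp, 30)
  tt <- seq(0, 30, by = 0.005)
  expect_equal(mean(r[tt > 5 & tt < 25]), 10, tolerance = 1e-3)
  expect_lt(diff(range(r[tt > 5 & tt < 25])), 0.2)
  expect_error(smoothRate(c(1, 31), 30), "within")
})

test_that("the CST is the mean over neurons with silent neurons as zero", {
  z <- replicate(20, numeric(100), simplify = FALSE)
  expect_identical(computeCST(z), numeric(100))
  allsame <- replicate(20, rep(16, 100), simplify = FALSE)
  expect_identical(computeCST(allsame), rep(16, 100))
  one <- c(list(rep(20, 100)), replicate(19, numeric(100),
                                         simplify = FALSE))
  expect_identical(computeCST(one), rep(1, 100))
  expect_error(computeCST(list(1:5, 1:4)), "equal length")
})

test_that("the command update reproduces hand-computed values", {
  cfg <- controllerConfig()
  expect_equal(updateCommand(10, 5, cfg), 11)
  cst <- rep(7, 50)
  expect_equal(updateCommand(cst, 0 * cst, cfg), cst)   # e = 0 fixed point
  ref <- rep(10, 50)
  expect_equal(updateCommand(0 * ref, ref, cfg), 0.2 * ref)
  expect_equal(updateCommand(1, -10, cfg), 0)           # floored at zero
})

test_that("a zero reference is matched immediately by the zero command", {
  ref0 <- numeric(length(makeReference()))
  attr(ref0, "time") <- attr(makeReference(), "time")
  res <- runClosedLoop(seed = 1L, reference = ref0)
  expect_true(res@converged)
  expect_equal(res@nIterations, 1L)
  expect_equal(finalMSE(res), 0)
  expect_true(all(res@command == 0))
})

test_that("the closed loop converges at the default combination with monotone error", {
  res <- cachedRun(1, 0, 1, 1, 1L)
  expect_true(res@converged)
  expect_lt(finalMSE(res), 1)
  expect_true(all(diff(res@mse) < 0))
  expect_equal(res@cst, computeCST(res@rates))
  # converged CST tracks the triangular reference closely at the peak
  expect_equal(max(res@cst), 16, tolerance = 0.15)
})

test_that("converged commands reflect the PIC economy of the inputs", {
  area <- function(res) sum(res@command) * 0.005
  aLow <- mean(sapply(1:2, function(s) area(cachedRun(0.8, 0, 1, 1, s))))
  aHigh <- mean(sapply(1:2, function(s) area(cachedRun(1.2, 0, 1, 1, s))))
  expect_lt(aHigh, aLow)   # high neuromodulation needs less excitation
  aPP <- area(cachedRun(1.0, -0.7, 1, 1, 1L))
  aBal <- area(cachedRun(1.0, 0.7, 1, 1, 1L))
  expect_lt(aPP, aBal)     # push-pull is cheaper than balanced
})

test_that("the rising-phase command is non-monotone at high neuromodulation only", {
  # count derivative sign changes of the heavily smoothed command on the
  # rising phase: the PIC dip appears at rMod = 1.2, not at 0.8
  signChanges <- function(res) {
    tt <- res@time
    sel <- tt > 1.5 & tt < 10.5
    sm <- stats::filter(res@command, rep(1 / 201, 201), sides = 2)
    d <- diff(sm[sel])
    d <- d[!is.na(d) & abs(d) > 2e-4]
    sum(diff(sign(d)) != 0)
  }
  s12 <- mean(sapply(1:2, function(s) signChanges(cachedRun(1.2, 0, 1, 1, s))))
  s08 <- mean(sapply(1:2, function(s) signChanges(cachedRun(0.8, 0, 1, 1, s))))
  expect_gt(s12, 0)
  expect_gte(s12, s08)
})
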