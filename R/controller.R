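## Closed-loop controller: triangular reference generation, the
## inhibition-excitation coupling, Hanning-window rate smoothing, the
## cumulative spike train (CST), and the iterative feedback loop that finds
## the excitatory command reproducing the reference.

#' Controller configuration constructor
#'
#' @param gain proportional gain K (default 0.2)
#' @param maxIterations iteration cap (default 20)
#' @param mseTolerance convergence tolerance, (imp/s)^2 (default 1)
#' @param window rate-smoothing window, s (default 2)
#' @param rateToExc,rateToInh rate-to-conductance scales, uS per imp/s
#' @param dt integrator step, ms
#' @param dtCmd command/rate sampling interval, s
#' @return a [`ControllerConfig`]
#' @export
controllerConfig <- function(gain = 0.2, maxIterations = 20L,
                             mseTolerance = 1, window = 2,
                             rateToExc = 0.06, rateToInh = 0.02,
                             dt = 0.1, dtCmd = 0.005) {
  new("ControllerConfig", gain = gain,
      maxIterations = as.integer(maxIterations),
      mseTolerance = mseTolerance, window = window,
      rateToExc = rateToExc, rateToInh = rateToInh, dt = dt, dtCmd = dtCmd)
}

#' Triangular reference command
#'
#' 22 s trace: zero for the first `delay` seconds, linear rise to `peak`
#' imp/s over `rise` seconds, linear fall back to zero over `fall` seconds,
#' zero afterwards.
#'
#' @param dtCmd sampling interval, s
#' @param duration,delay,rise,fall segment lengths, s
#' @param peak peak value, imp/s (default 16)
#' @return numeric trace with attribute `"time"` (s)
#' @export
makeReference <- function(dtCmd = 0.005, duration = 22, delay = 1,
                          rise = 10, fall = 10, peak = 16) {
  if (dtCmd <= 0) stop("dtCmd must be positive")
  t <- seq(0, duration, by = dtCmd)
  up <- peak * (t - delay) / rise
  down <- peak * (1 - (t - delay - rise) / fall)
  ref <- pmin(pmax(0, up), pmax(0, down))
  ref[t > delay + rise + fall] <- 0
  attr(ref, "time") <- t
  ref
}

#' Inhibitory bias as a function of neuromodulation
#'
#' `bIn = 6.25 rMod^2 - 1.25 rMod - 1`: the baseline of the inhibitory
#' command is coupled to the neuromodulation level so that it is just
#' sufficient to deactivate the PIC at the end of the command.
#'
#' @param rMod neuromodulation gain
#' @return bias, in the rate units of the command traces
#' @export
computeBin <- function(rMod) {
  6.25 * rMod^2 - 1.25 * rMod - 1
}

#' Inhibitory command coupled to the excitatory command
#'
#' `iIn = gIn * iEx + bIn(rMod)`, pointwise.  Negative gains implement
#' push-pull (reciprocal) inhibition, positive gains balanced inhibition.
#' The trace is not clipped here; clipping at zero happens when the command
#' is mapped to a conductance.
#'
#' @param iEx excitatory command trace (rate units)
#' @param gIn inhibitory coupling gain (nominal range -0.7..0.7)
#' @param rMod neuromodulation gain
#' @return inhibitory command trace
#' @export
computeIin <- function(iEx, gIn, rMod) {
  gIn * iEx + computeBin(rMod)
}

#' Unit-area Hanning kernel
#' @noRd
.hanningKernel <- function(window, dtCmd) {
  m <- round(window / dtCmd)
  if (m %% 2 == 1) m <- m + 1
  j <- 0:m
  h <- 0.5 * (1 - cos(2 * pi * j / m))
  h / (sum(h) * dtCmd)
}

#' Smoothed firing rate of one spike train
#'
#' Convolution of the spike impulse train with a unit-area Hanning window
#' (default 2 s), evaluated on a regular grid; ends are zero-padded.
#'
#' @param spikeTimes spike times, s
#' @param duration trace length, s
#' @param dtCmd sampling interval, s
#' @param window window length, s
#' @return numeric rate trace, imp/s
#' @export
smoothRate <- function(spikeTimes, duration = 22, dtCmd = 0.005,
                       window = 2) {
  n <- length(seq(0, duration, by = dtCmd))
  counts <- numeric(n)
  if (length(spikeTimes)) {
    if (any(spikeTimes < 0 | spikeTimes > duration))
      stop("spike times must lie within [0, duration]")
    idx <- pmin(n, floor(spikeTimes / dtCmd) + 1L)
    tb <- tabulate(idx, nbins = n)
    counts <- tb
  }
  h <- .hanningKernel(window, dtCmd)
  .convSame(counts, h)
}

# centred, zero-padded convolution
.convSame <- function(x, k) {
  nk <- length(k)
  full <- stats::convolve(x, rev(k), type = "open")
  half <- (nk - 1) %/% 2
  full[(half + 1):(half + length(x))]
}

#' Cumulative spike train of the pool
#'
#' Arithmetic mean of the smoothed per-neuron rates; silent neurons count
#' as zero.
#'
#' @param rates matrix (time x neuron) or list of equal-length rate traces
#' @return numeric CST trace, imp/s
#' @export
computeCST <- function(rates) {
  if (is.list(rates)) {
    len <- vapply(rates, length, integer(1))
    if (length(unique(len)) != 1)
      stop("rate traces must have equal length")
    rates <- do.call(cbind, rates)
  }
  rowMeans(rates)
}

#' Proportional-feedback command update
#'
#' Next excitatory command (rate units) is the base trace plus `gain`
#' times the error, floored at zero; the rate-to-conductance mapping is
#' applied separately when the command is played into the pool.  Because
#' the pool is calibrated to near-unity gain (a command of x imp/s yields a
#' CST near x imp/s), the measured CST and the command that produced it are
#' interchangeable as the base when the loop is close to the solution; the
#' closed loop uses the current command, which makes the error contract
#' geometrically across iterations for any plant with bounded positive
#' gain.
#'
#' @param base trace the correction is applied to (the current command, or
#'   equivalently the measured CST near convergence), imp/s
#' @param error reference minus CST, imp/s
#' @param cfg a [`ControllerConfig`] (supplies the gain)
#' @return next command trace, rate units
#' @export
updateCommand <- function(base, error, cfg = controllerConfig()) {
  pmax(0, base + cfg@gain * error)
}

#' Run the closed-loop input-matching procedure for one input combination
#'
#' Starting from a scaled copy of the reference (`0.6 * Ref`), iterates:
#' derive the inhibitory command from the excitatory one, add the shared
#' conductance noise, simulate the pool, smooth each spike train with a
#' unit-area 2 s Hanning window, average into the CST, and update the
#' command with proportional feedback until the mean squared error against
#' the triangular reference drops below tolerance (or the iteration cap is
#' reached; non-convergence is flagged, not an error).  The noise
#' realization is frozen per (combination, seed) so each loop optimizes a
#' deterministic objective.
#'
#' @param rMod neuromodulation gain
#' @param gIn inhibitory coupling gain
#' @param wcfg a [`WeightConfig`]
#' @param seed integer noise seed for this combination
#' @param cfg a [`ControllerConfig`]
#' @param poolCfg a [`PoolConfig`]
#' @param noiseCfg a [`NoiseConfig`] (its seed slot is ignored; `seed` is
#'   used)
#' @param reference optional reference trace (defaults to
#'   [makeReference()] at `cfg@dtCmd`)
#' @return a [`SimulationResult`]
#' @export
runClosedLoop <- function(rMod = 1, gIn = 0, wcfg = weightConfig(1, 1),
                          seed = 1L, cfg = controllerConfig(),
                          poolCfg = new("PoolConfig"),
                          noiseCfg = new("NoiseConfig"),
                          reference = NULL, globals = mnGlobals()) {
  validObject(cfg)
  ref <- if (is.null(reference)) makeReference(cfg@dtCmd) else reference
  tt <- attr(ref, "time")
  if (is.null(tt)) tt <- (seq_along(ref) - 1L) * cfg@dtCmd
  duration <- tt[length(tt)]
  n <- length(ref)

  pool <- buildPool(poolCfg, wcfg)
  P <- .paramMatrix(pool)
  bin <- computeBin(rMod)

  # frozen unit-variance OU paths for the excitatory and inhibitory noise
  unitCfg <- new("NoiseConfig", tau = noiseCfg@tau, c = 1, seed = 1L)
  uE <- generateNoise(rep(1, n), unitCfg, dt = cfg@dtCmd, seed = 2 * seed)
  uI <- generateNoise(rep(1, n), unitCfg, dt = cfg@dtCmd,
                      seed = 2 * seed + 1)

  iEx <- 0.6 * as.numeric(ref)
  mseLog <- numeric(0)
  converged <- FALSE
  iIn <- cst <- rep(0, n)
  rates <- matrix(0, n, nrow(P))
  spikes <- vector("list", nrow(P))

  for (it in seq_len(cfg@maxIterations)) {
    iIn <- computeIin(iEx, gIn, rMod)
    gExcCmd <- pmax(0, cfg@rateToExc *
                      (iEx + noiseCfg@c * sqrt(iEx) * uE))
    iInPos <- pmax(0, iIn)
    gInhCmd <- pmax(0, cfg@rateToInh *
                      (iInPos + noiseCfg@c * sqrt(iInPos) * uI))
    out <- .simulate_pool_cpp(P, unname(globals), rMod, gExcCmd, gInhCmd,
                              dt = cfg@dt, dt_cmd = cfg@dtCmd * 1000,
                              T_ms = duration * 1000,
                              record_every = 1L, record_v = FALSE,
                              state0_ = NULL)
    spikes <- lapply(out$spikes, function(s) s / 1000)
    rates <- vapply(spikes, smoothRate, numeric(n), duration = duration,
                    dtCmd = cfg@dtCmd, window = cfg@window)
    cst <- computeCST(rates)
    err <- as.numeric(ref) - cst
    mseLog <- c(mseLog, mean(err^2))
    if (mseLog[it] < cfg@mseTolerance) {
      converged <- TRUE
      break
    }
    if (it < cfg@maxIterations)
      iEx <- updateCommand(iEx, err, cfg)
  }

  new("SimulationResult",
      converged = converged, mse = mseLog, nIterations = length(mseLog),
      time = tt, reference = as.numeric(ref), command = iEx,
      inhibition = iIn, cst = cst, rates = rates, spikes = spikes,
      pars = list(rMod = rMod, gIn = gIn, wStart = wcfg@wStart,
                  wEnd = wcfg@wEnd, seed = seed))
}

#' Final mean squared error of a simulation result
#' @param result a [`SimulationResult`]
#' @return numeric, (imp/s)^2
#' @export
finalMSE <- function(result) {
  result@mse[length(result@mse)]
}
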