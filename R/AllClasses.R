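#' @useDynLib repool, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Excitatory weight distribution across the pool
#'
#' The excitatory synaptic conductance is distributed across the pool on a
#' quadratic profile from `wStart` (lowest-threshold neuron) to `wEnd`
#' (highest-threshold neuron), mirroring the skew of intrinsic excitability
#' toward low-threshold units.
#'
#' @slot wStart weight of the lowest-threshold motoneuron (dimensionless, > 0)
#' @slot wEnd weight of the highest-threshold motoneuron (dimensionless, > 0)
#' @export
setClass("WeightConfig",
  representation(wStart = "numeric", wEnd = "numeric"),
  prototype(wStart = 1, wEnd = 1),
  validity = function(object) {
    if (length(object@wStart) != 1 || length(object@wEnd) != 1)
      return("wStart and wEnd must be scalars")
    if (!is.finite(object@wStart) || !is.finite(object@wEnd))
      return("weights must be finite")
    if (object@wStart <= 0 || object@wEnd <= 0)
      return("weights must be positive")
    TRUE
  })

#' Shared synaptic noise configuration
#'
#' Ornstein-Uhlenbeck conductance noise with a pointwise standard deviation
#' proportional to the square root of the local mean command.  A single
#' realization is shared by the whole pool (common drive); per-neuron
#' scaling happens through the excitatory weights.
#'
#' @slot tau decay time constant (ms)
#' @slot c amplitude coefficient: sd(t) = c * sqrt(mean(t)), in the units of
#'   the command trace
#' @slot seed integer seed for the realization
#' @export
setClass("NoiseConfig",
  representation(tau = "numeric", c = "numeric", seed = "integer"),
  prototype(tau = 20, c = 0.45, seed = 1L),
  validity = function(object) {
    if (object@tau <= 0) return("tau must be positive")
    if (object@c < 0) return("c must be non-negative")
    TRUE
  })

#' Motoneuron pool configuration
#'
#' Gradients across the pool: `tauCaRange` (ms) sets the calcium-removal
#' time constant of the AHP from neuron 1 to neuron N, `vHalfRange` (mV)
#' the PIC activation half-voltage, and `sizeRange` the multiplicative
#' scaling of all membrane conductances and capacitances (the electrical
#' "size" that creates orderly recruitment).  Size is spaced quadratically
#' so the pool holds a greater proportion of low-threshold units.
#'
#' @slot N neuron count (default 20)
#' @slot tauCaRange length-2 numeric, ms (default c(90, 57))
#' @slot vHalfRange length-2 numeric, mV (default c(-42, -40.4))
#' @slot sizeRange length-2 numeric, dimensionless (default c(1, 2));
#'   synaptic conductances are densities, so the absolute conductance a
#'   neuron receives scales with its size factor
#' @slot thresholdRange length-2 numeric, mV (default c(0, 17)): somatic
#'   spike-threshold shift from the lowest- to the highest-threshold
#'   neuron, spaced quadratically so low-threshold units predominate
#' @slot excitabilityRange length-2 numeric, dimensionless (default
#'   c(1, 4)): multiplier on the specific leak density, spaced
#'   quadratically; leakier membranes need more synaptic density to reach
#'   both spike threshold and PIC activation, which spreads recruitment
#'   across the ramp
#' @slot picDensityExponent scalar in [0, 1] (default 0.55): the PIC
#'   maximal conductance scales with the leak multiplier raised to this
#'   power, so high-threshold units keep a real but relatively weaker PIC
#' @export
setClass("PoolConfig",
  representation(N = "integer", tauCaRange = "numeric",
                 vHalfRange = "numeric", sizeRange = "numeric",
                 thresholdRange = "numeric", excitabilityRange = "numeric",
                 picDensityExponent = "numeric"),
  prototype(N = 20L, tauCaRange = c(90, 57), vHalfRange = c(-42, -40.4),
            sizeRange = c(1, 2), thresholdRange = c(0, 17),
            excitabilityRange = c(1, 4), picDensityExponent = 0.55),
  validity = function(object) {
    if (object@N < 2) return("N must be >= 2")
    for (nm in c("tauCaRange", "vHalfRange", "sizeRange",
                 "thresholdRange", "excitabilityRange")) {
      v <- slot(object, nm)
      if (length(v) != 2 || any(!is.finite(v)))
        return(sprintf("%s must be a finite length-2 numeric", nm))
    }
    if (any(object@sizeRange <= 0)) return("sizeRange must be positive")
    if (any(object@excitabilityRange <= 0))
      return("excitabilityRange must be positive")
    if (object@picDensityExponent < 0 || object@picDensityExponent > 1)
      return("picDensityExponent must lie in [0, 1]")
    TRUE
  })

#' Closed-loop controller configuration
#'
#' @slot gain proportional gain K on the error term (default 0.2)
#' @slot maxIterations iteration cap (default 20)
#' @slot mseTolerance convergence tolerance on the mean squared error
#'   between CST and reference, in (imp/s)^2 (default 1)
#' @slot window smoothing window length for firing rates, s (default 2,
#'   Hanning, unit area)
#' @slot rateToExc excitatory rate-to-conductance scale, uS per imp/s
#' @slot rateToInh inhibitory rate-to-conductance scale, uS per imp/s
#' @slot dt integrator time step, ms (must be in (0, 0.1])
#' @slot dtCmd sampling interval of command and rate traces, s
#' @export
setClass("ControllerConfig",
  representation(gain = "numeric", maxIterations = "integer",
                 mseTolerance = "numeric", window = "numeric",
                 rateToExc = "numeric", rateToInh = "numeric",
                 dt = "numeric", dtCmd = "numeric"),
  prototype(gain = 0.2, maxIterations = 20L, mseTolerance = 1,
            window = 2, rateToExc = 0.06, rateToInh = 0.02,
            dt = 0.1, dtCmd = 0.005),
  validity = function(object) {
    if (object@gain <= 0) return("gain must be positive")
    if (object@mseTolerance <= 0) return("mseTolerance must be positive")
    if (object@maxIterations < 1) return("maxIterations must be >= 1")
    if (object@dt <= 0 || object@dt > 0.1)
      return("dt must be in (0, 0.1] ms")
    if (object@dtCmd <= 0) return("dtCmd must be positive")
    if (object@window <= 0) return("window must be positive")
    if (object@rateToExc <= 0 || object@rateToInh <= 0)
      return("rate-to-conductance scales must be positive")
    TRUE
  })

#' Result of one closed-loop pool simulation
#'
#' @slot converged logical: final MSE below tolerance
#' @slot mse per-iteration mean squared error, (imp/s)^2
#' @slot nIterations iterations executed
#' @slot time trace time axis, s
#' @slot reference reference CST trace, imp/s
#' @slot command converged excitatory command, imp/s (rate units, before
#'   conductance mapping)
#' @slot inhibition inhibitory command derived from the converged command,
#'   rate units
#' @slot cst cumulative spike train of the final iteration, imp/s
#' @slot rates matrix (time x neuron) of smoothed firing rates, imp/s
#' @slot spikes list of per-neuron spike-time vectors, s
#' @slot pars the input combination: named list (rMod, gIn, wStart, wEnd,
#'   seed)
#' @export
setClass("SimulationResult",
  representation(converged = "logical", mse = "numeric",
                 nIterations = "integer", time = "numeric",
                 reference = "numeric", command = "numeric",
                 inhibition = "numeric", cst = "numeric",
                 rates = "matrix", spikes = "list", pars = "list"),
  validity = function(object) {
    n <- length(object@time)
    for (nm in c("reference", "command", "inhibition", "cst")) {
      if (length(slot(object, nm)) != n)
        return(sprintf("%s must match the time axis", nm))
    }
    if (nrow(object@rates) != n)
      return("rates must have one row per time sample")
    if (length(object@spikes) != ncol(object@rates))
      return("spikes and rates must cover the same neurons")
    TRUE
  })

#' Ensemble grid specification
#'
#' Cartesian product of neuromodulation levels, inhibitory gains, weight
#' configurations and noise seeds.
#'
#' @slot rMod neuromodulation levels (default seq(0.8, 1.2, by = 0.1))
#' @slot gIn inhibitory coupling gains (default seq(-0.7, 0.7, by = 0.1))
#' @slot weights list of [`WeightConfig`] objects (default the seven
#'   standard configurations)
#' @slot seeds integer noise seeds (default 1:30)
#' @export
setClass("GridSpec",
  representation(rMod = "numeric", gIn = "numeric", weights = "list",
                 seeds = "integer"),
  validity = function(object) {
    if (length(object@rMod) == 0 || length(object@gIn) == 0 ||
        length(object@weights) == 0 || length(object@seeds) == 0)
      return("all grid dimensions must be non-empty")
    if (anyDuplicated(object@rMod) || anyDuplicated(object@gIn) ||
        anyDuplicated(object@seeds))
      return("grid dimension values must be unique")
    if (!all(vapply(object@weights, is, logical(1), "WeightConfig")))
      return("weights must be a list of WeightConfig objects")
    TRUE
  })

#' Regression report: how well firing-pattern features predict the inputs
#'
#' @slot target name of the predicted input ("inhibition", "neuromodulation"
#'   or "weight_ratio")
#' @slot r2 named numeric: held-out R-squared per model
#' @slot r2Train named numeric: training R-squared per model
#' @slot bestModel name of the best model on the held-out split
#' @slot stepwise data.frame of cumulative-MSE curves (feature order by
#'   F-statistic; one column per model)
#' @slot miRanking data.frame of features with mutual-information scores,
#'   descending
#' @export
setClass("RegressionReport",
  representation(target = "character", r2 = "numeric", r2Train = "numeric",
                 bestModel = "character", stepwise = "data.frame",
                 miRanking = "data.frame"),
  validity = function(object) {
    if (any(object@r2 > 1 + 1e-9)) return("R-squared cannot exceed 1")
    TRUE
  })

setMethod("show", "SimulationResult", function(object) {
  p <- object@pars
  cat("SimulationResult:",
      sprintf("rMod=%.2f gIn=%.2f w=[%g,%g] seed=%s",
              p$rMod, p$gIn, p$wStart, p$wEnd, p$seed), "\n")
  cat(sprintf("  %s after %d iteration(s); final MSE = %.4g (imp/s)^2\n",
              if (object@converged) "converged" else "NOT converged",
              object@nIterations, object@mse[length(object@mse)]))
  nrec <- sum(vapply(object@spikes, length, integer(1)) > 0)
  cat(sprintf("  %d/%d neurons recruited; CST peak = %.2f imp/s\n",
              nrec, length(object@spikes), max(object@cst)))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d rMod x %d gIn x %d weights x %d seeds = %d combinations\n",
    length(object@rMod), length(object@gIn), length(object@weights),
    length(object@seeds), gridSize(object)))
})

setMethod("show", "WeightConfig", function(object) {
  cat(sprintf("WeightConfig [wStart, wEnd] = [%g, %g]\n",
              object@wStart, object@wEnd))
})
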