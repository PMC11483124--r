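## Single-motoneuron compartmental model: construction of the per-neuron
## parameter set and direct simulation of one neuron from conductance
## traces.  The heavy integration lives in src/integrator.cpp.

# Column order must match the enum in src/integrator.cpp.
.PAR_COLS <- c("cSoma", "cDend", "gLeakSoma", "gLeakDend", "gCouple",
               "gNa", "gK", "gAHP", "caStep", "tauCa",
               "gCaLBar", "vHalf", "gHCNSoma", "gHCNDend", "weight",
               "vShift", "synScale")

.STATE_COLS <- c(paste0("v", 0:4), "mNa", "hNa", "nK", "ca",
                 paste0("mCaL", 1:4), paste0("hHCN", 0:4))

#' Global biophysical constants shared by all motoneurons
#'
#' Reversal potentials (mV), PIC activation slope and time constant, spike
#' detection threshold and absolute refractory period, AHP calcium
#' half-saturation, and HCN activation curve.  Values can be overridden by
#' name.
#'
#' @param ... named overrides, e.g. `eCaL = 45`
#' @return named numeric vector
#' @export
mnGlobals <- function(...) {
  g <- c(eLeak = -72, eNa = 50, eK = -80, eExc = 0, eInh = -85,
         eHCN = -43, eCaL = 40, kCaL = 5, tauCaL = 300,
         vSpike = -10, refractory = 2, kCa = 2,
         tauHCN = 50, vHCNHalf = -80, kHCN = 6)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(g))
    if (length(bad)) stop("unknown global parameter(s): ",
                          paste(bad, collapse = ", "))
    g[names(ov)] <- unlist(ov)
  }
  g
}

# Base (smallest-neuron) membrane parameters; every conductance and
# capacitance scales with the neuron's size factor.
.mnBase <- function() {
  c(cSoma = 0.25, cDend = 0.30,        # nF
    gLeakSoma = 0.08, gLeakDend = 0.03, # uS
    gCouple = 0.10,                     # uS, soma<->each dendrite
    gNa = 30, gK = 6,                   # uS, somatic spike conductances
    gAHP = 3.5, caStep = 0.35,          # uS; Ca increment per spike (a.u.)
    gCaLBar = 0.052,                    # uS per dendritic compartment
    gHCNSoma = 0.01, gHCNDend = 0.01)   # uS
}

#' Build the parameter set for one motoneuron
#'
#' Neuron `index` (0-based) of a pool of `N`.  The electrical size factor
#' follows a quadratic profile across the pool so recruitment thresholds
#' are skewed toward low-threshold units; the AHP calcium-removal time
#' constant and the PIC half-activation voltage follow linear gradients.
#'
#' @param index 0-based neuron index
#' @param N pool size
#' @param cfg a [`PoolConfig`] supplying the gradients
#' @param weight excitatory synaptic weight for this neuron
#' @param base named vector of base membrane parameters (the smallest
#'   neuron); override entries to explore variants
#' @return named numeric vector of per-neuron parameters
#' @export
mnParams <- function(index, N = 20L, cfg = new("PoolConfig"), weight = 1,
                     base = .mnBase()) {
  if (index < 0 || index > N - 1) stop("index must be in 0..N-1")
  frac <- index / (N - 1)
  size <- cfg@sizeRange[1] +
    frac^2 * (cfg@sizeRange[2] - cfg@sizeRange[1])
  excit <- cfg@excitabilityRange[1] +
    frac^2 * (cfg@excitabilityRange[2] - cfg@excitabilityRange[1])
  b <- base
  scaled <- b * size
  scaled[["caStep"]] <- b[["caStep"]]  # per-spike Ca increment is intensive
  scaled[["gLeakSoma"]] <- scaled[["gLeakSoma"]] * excit
  scaled[["gLeakDend"]] <- scaled[["gLeakDend"]] * excit
  scaled[["gCaLBar"]] <- scaled[["gCaLBar"]] * excit^cfg@picDensityExponent
  p <- c(scaled[c("cSoma", "cDend", "gLeakSoma", "gLeakDend", "gCouple",
                  "gNa", "gK", "gAHP", "caStep")],
         tauCa = cfg@tauCaRange[1] +
           frac * (cfg@tauCaRange[2] - cfg@tauCaRange[1]),
         gCaLBar = scaled[["gCaLBar"]],
         vHalf = cfg@vHalfRange[1] +
           frac * (cfg@vHalfRange[2] - cfg@vHalfRange[1]),
         gHCNSoma = scaled[["gHCNSoma"]],
         gHCNDend = scaled[["gHCNDend"]],
         weight = weight,
         vShift = cfg@thresholdRange[1] +
           frac^2 * (cfg@thresholdRange[2] - cfg@thresholdRange[1]),
         synScale = size)
  names(p) <- .PAR_COLS
  p
}

.paramMatrix <- function(params) {
  if (is.numeric(params) && is.null(dim(params)))
    params <- matrix(params, nrow = 1,
                     dimnames = list(NULL, names(params)))
  if (is.data.frame(params)) params <- as.matrix(params[.PAR_COLS])
  storage.mode(params) <- "double"
  if (!all(.PAR_COLS %in% colnames(params)))
    stop("parameter set is missing columns: ",
         paste(setdiff(.PAR_COLS, colnames(params)), collapse = ", "))
  params[, .PAR_COLS, drop = FALSE]
}

#' Resting state for a set of motoneurons
#'
#' All compartments at the leak reversal, gates at their steady-state
#' values, calcium at zero.  (The true resting potential differs slightly
#' because of the HCN and subthreshold currents; a short settling period or
#' the 1 s zero-input delay of the reference command absorbs the
#' difference.)
#'
#' @param params parameter vector, matrix or data.frame (one row per neuron)
#' @param globals global constants from [mnGlobals()]
#' @return matrix (neuron x state variable)
#' @export
mnRestingState <- function(params, globals = mnGlobals()) {
  P <- .paramMatrix(params)
  out <- .simulate_pool_cpp(P, unname(globals), 0,
                            numeric(1), numeric(1),
                            dt = 0.1, dt_cmd = 1, T_ms = 0.1,
                            record_every = 1L, record_v = FALSE,
                            state0_ = NULL)
  st <- out$state
  colnames(st) <- .STATE_COLS
  st
}

#' Dendritic persistent-inward-current (PIC) for a given state
#'
#' The L-type Ca current per dendritic compartment,
#' `I = rMod * gCaLBar * mCaL * (V - eCaL)` (nA); the soma carries no PIC
#' channels, so its contribution is zero.  The current is exactly linear in
#' the neuromodulation gain `rMod`, which rescales the maximal conductance.
#'
#' @param state named state vector or one-row state matrix (see
#'   [mnRestingState()])
#' @param params per-neuron parameter vector from [mnParams()]
#' @param rMod neuromodulation gain (nominal range 0.8 to 1.2; values
#'   outside trigger a warning)
#' @param globals global constants
#' @return numeric length 5: current per compartment (soma first), nA
#' @export
picCurrent <- function(state, params, rMod, globals = mnGlobals()) {
  if (rMod < 0.8 || rMod > 1.2)
    warning("rMod = ", rMod, " is outside the nominal range [0.8, 1.2]")
  st <- if (is.matrix(state)) state[1, ] else state
  v <- st[paste0("v", 1:4)]
  m <- st[paste0("mCaL", 1:4)]
  g <- rMod * params[["gCaLBar"]]
  c(soma = 0, g * m * (v - globals[["eCaL"]]))
}

#' Advance one or more motoneurons a single time step
#'
#' @param state matrix (neuron x state variable)
#' @param gExc,gInh total synaptic conductances at this instant (uS);
#'   excitation is multiplied by the per-neuron weight and both are split
#'   equally over the four dendritic compartments
#' @param params per-neuron parameters (vector or matrix)
#' @param rMod neuromodulation gain
#' @param dt time step, ms (must be in (0, 0.1])
#' @param globals global constants
#' @return list with `state` (updated matrix) and `spiked` (logical per
#'   neuron: somatic threshold crossed on this step)
#' @export
mnStep <- function(state, gExc, gInh, params, rMod, dt = 0.1,
                   globals = mnGlobals()) {
  if (gExc < 0 || gInh < 0) stop("synaptic conductances must be >= 0")
  P <- .paramMatrix(params)
  st <- if (is.null(dim(state)))
    matrix(state, nrow = 1, dimnames = list(NULL, names(state))) else state
  out <- .simulate_pool_cpp(P, unname(globals), rMod,
                            rep(gExc, 2L), rep(gInh, 2L),
                            dt = dt, dt_cmd = dt, T_ms = dt,
                            record_every = 1L, record_v = FALSE,
                            state0_ = unname(st[, .STATE_COLS, drop = FALSE]))
  ns <- out$state
  colnames(ns) <- .STATE_COLS
  list(state = ns,
       spiked = vapply(out$spikes, function(s) length(s) > 0, logical(1)))
}

#' Simulate one motoneuron from conductance traces
#'
#' @param params per-neuron parameter vector from [mnParams()]
#' @param rMod neuromodulation gain
#' @param gExcTrace,gInhTrace synaptic conductance traces (uS) sampled at
#'   `dtCmd`
#' @param duration simulated time, s
#' @param dt integrator step, ms
#' @param dtCmd sampling interval of the traces (and of the recorded
#'   voltage), s
#' @param recordVoltage record the somatic and first-dendrite voltage
#' @param state0 optional initial state (defaults to rest)
#' @return list with `spikeTimes` (s), `voltage` (matrix time x 2:
#'   soma and dendrite, mV; NULL unless requested), `time` (s) and `state`
#'   (final state matrix)
#' @export
simulateNeuron <- function(params, rMod, gExcTrace, gInhTrace,
                           duration = 22, dt = 0.1, dtCmd = 0.005,
                           recordVoltage = FALSE, state0 = NULL,
                           globals = mnGlobals()) {
  if (rMod < 0.8 || rMod > 1.2)
    warning("rMod = ", rMod, " is outside the nominal range [0.8, 1.2]")
  if (any(gExcTrace < 0) || any(gInhTrace < 0))
    stop("conductance traces must be non-negative")
  P <- .paramMatrix(params)
  if (is.null(state0)) state0 <- mnRestingState(P, globals)
  recEvery <- max(1L, as.integer(round(dtCmd * 1000 / dt)))
  out <- .simulate_pool_cpp(P, unname(globals), rMod,
                            as.numeric(gExcTrace), as.numeric(gInhTrace),
                            dt = dt, dt_cmd = dtCmd * 1000,
                            T_ms = duration * 1000,
                            record_every = recEvery,
                            record_v = recordVoltage,
                            state0_ = unname(state0[, .STATE_COLS,
                                                    drop = FALSE]))
  v <- NULL
  tv <- NULL
  if (recordVoltage) {
    v <- t(out$v[[1]])
    colnames(v) <- c("soma", "dendrite")
    tv <- (seq_len(nrow(v)) - 1L) * dtCmd
  }
  st <- out$state
  colnames(st) <- .STATE_COLS
  list(spikeTimes = out$spikes[[1]] / 1000, voltage = v, time = tv,
       state = st)
}
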