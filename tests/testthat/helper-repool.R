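# Shared helpers: a session-level cache of closed-loop runs so the slower
# phenomenology checks reuse simulations across test files.

.runCache <- new.env(parent = emptyenv())

cachedRun <- function(rMod = 1, gIn = 0, wStart = 1, wEnd = 1, seed = 1L) {
  key <- paste(rMod, gIn, wStart, wEnd, seed, sep = "|")
  if (is.null(.runCache[[key]]))
    .runCache[[key]] <- runClosedLoop(rMod, gIn,
                                      weightConfig(wStart, wEnd), seed)
  .runCache[[key]]
}

# reduced study grid: 3 neuromodulation levels x 5 inhibitory gains x
# equal weights x 3 noise seeds, seed-averaged
phenoGrid <- function() {
  if (is.null(.runCache[["phenoGrid"]])) {
    rows <- list()
    for (rm in c(0.8, 1.0, 1.2))
      for (gi in c(-0.6, -0.3, 0, 0.3, 0.6))
        for (sd in 1:3) {
          res <- cachedRun(rm, gi, 1, 1, sd)
          f <- extractPoolFeatures(res)
          f$area <- sum(res@command) * 0.005
          rows[[length(rows) + 1]] <- f
        }
    .runCache[["phenoGrid"]] <- do.call(rbind, rows)
  }
  .runCache[["phenoGrid"]]
}

ensembleFixture <- function() {
  path <- system.file("extdata", "ensemble_features.csv",
                      package = "repool")
  read.csv(path)
}

# two-neuron SimulationResult with hand-built rates and spikes, for
# feature-extraction oracles
handBuiltResult <- function() {
  dt <- 0.005
  tt <- seq(0, 22, by = dt)
  n <- length(tt)
  # neuron 1 (reporter): fires 2..20 s, symmetric triangular rate 8..12..8
  # neuron 2 (test): fires 5..15 s, constant rate 10
  rate1 <- ifelse(tt >= 2 & tt <= 20, 8 + 4 * (1 - abs(tt - 11) / 9), 0)
  rate2 <- ifelse(tt >= 5 & tt <= 15, 10, 0)
  sp1 <- seq(2, 20, by = 0.1)
  sp2 <- seq(5, 15, by = 0.1)
  new("SimulationResult", converged = TRUE, mse = 0.5, nIterations = 1L,
      time = tt, reference = makeReference(dt), command = numeric(n),
      inhibition = numeric(n), cst = (rate1 + rate2) / 2,
      rates = cbind(rate1, rate2), spikes = list(sp1, sp2),
      pars = list(rMod = 1, gIn = 0, wStart = 1, wEnd = 1, seed = 1L))
}
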