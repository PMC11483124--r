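## Ensemble grid: enumeration of the neuromodulation x inhibition x weight
## x seed Cartesian product, embarrassingly parallel execution with a
## per-combination seed discipline, and a persistent on-disk layout (one
## directory per combination plus a top-level index CSV).

#' Construct a GridSpec
#'
#' Defaults reproduce the full ensemble: 5 neuromodulation levels x 15
#' inhibitory gains x 7 weight configurations x 30 noise seeds = 15,750
#' combinations.
#'
#' @param rMod neuromodulation levels
#' @param gIn inhibitory coupling gains
#' @param weights list of [`WeightConfig`] objects
#' @param seeds integer noise seeds
#' @return a [`GridSpec`]
#' @export
gridSpec <- function(rMod = seq(0.8, 1.2, by = 0.1),
                     gIn = seq(-0.7, 0.7, by = 0.1),
                     weights = standardWeightConfigs(),
                     seeds = 1:30) {
  new("GridSpec", rMod = rMod, gIn = round(gIn, 10), weights = weights,
      seeds = as.integer(seeds))
}

#' Number of combinations in a grid
#' @param spec a [`GridSpec`]
#' @return integer
#' @export
gridSize <- function(spec) {
  length(spec@rMod) * length(spec@gIn) * length(spec@weights) *
    length(spec@seeds)
}

#' Enumerate the grid combinations
#'
#' Deterministic lexicographic order (seed fastest, then weight
#' configuration, inhibition, neuromodulation).
#'
#' @param spec a [`GridSpec`]
#' @return data.frame with columns `rMod`, `gIn`, `wStart`, `wEnd`, `seed`
#'   and `comboId` (stable identifier string)
#' @export
enumerateGrid <- function(spec) {
  validObject(spec)
  w <- do.call(rbind, lapply(spec@weights, function(x)
    data.frame(wStart = x@wStart, wEnd = x@wEnd)))
  g <- expand.grid(seed = spec@seeds, wi = seq_len(nrow(w)),
                   gIn = spec@gIn, rMod = spec@rMod,
                   KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(rMod = g$rMod, gIn = g$gIn,
                    wStart = w$wStart[g$wi], wEnd = w$wEnd[g$wi],
                    seed = g$seed)
  out <- out[order(out$rMod, out$gIn, out$wStart, out$wEnd, out$seed), ]
  rownames(out) <- NULL
  out$comboId <- sprintf("r%03d_g%+04d_w%g-%g_s%03d",
                         round(out$rMod * 100), round(out$gIn * 100),
                         out$wStart, out$wEnd, out$seed)
  out
}

# master seed -> per-combination seed, counter-based so extending the grid
# never reshuffles existing combinations
.comboSeed <- function(masterSeed, seed) {
  as.integer((as.numeric(masterSeed) * 10007 + as.numeric(seed)) %%
               .Machine$integer.max)
}

.runOneCombo <- function(row, cfg, poolCfg, noiseCfg, masterSeed, outDir,
                         globals) {
  sd <- .comboSeed(masterSeed, row$seed)
  res <- runClosedLoop(rMod = row$rMod, gIn = row$gIn,
                       wcfg = weightConfig(row$wStart, row$wEnd),
                       seed = sd, cfg = cfg, poolCfg = poolCfg,
                       noiseCfg = noiseCfg, globals = globals)
  feat <- extractPoolFeatures(res)
  feat$rMod <- row$rMod; feat$gIn <- row$gIn
  feat$wStart <- row$wStart; feat$wEnd <- row$wEnd
  feat$seed <- row$seed
  feat$comboId <- row$comboId
  feat$nIter <- res@nIterations
  if (!is.null(outDir)) {
    d <- file.path(outDir, row$comboId)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    writeSpikeCSV(res@spikes, file.path(d, "spikes.csv"))
    utils::write.csv(data.frame(t = res@time, i_ex = res@command,
                                i_in = res@inhibition, cst = res@cst),
                     file.path(d, "command.csv"), row.names = FALSE)
    # full float precision so a re-run reproduces the stored MSE exactly
    utils::write.csv(data.frame(iteration = seq_along(res@mse),
                                mse = sprintf("%.17g", res@mse)),
                     file.path(d, "iterations.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  feat
}

#' Run a grid of closed-loop simulations
#'
#' Each combination is executed independently (process-parallel map over
#' combinations); all randomness derives from the per-combination seed, so
#' the result is identical for any worker count.  Individual failures are
#' recorded per combination and never abort the sweep.
#'
#' @param spec a [`GridSpec`]
#' @param cfg a [`ControllerConfig`]
#' @param workers parallel worker count (forked processes; 1 = serial)
#' @param outDir optional directory: per-combination artifacts (spike CSV,
#'   command traces, iteration log) plus a top-level `index.csv`
#' @param masterSeed master seed combined with each combination's seed
#' @param poolCfg,noiseCfg,globals pool, noise and biophysics settings
#' @return data.frame: one row per combination with the extracted features,
#'   convergence metadata and (if a failure occurred) an `error` message
#' @export
runGrid <- function(spec, cfg = controllerConfig(), workers = 1L,
                    outDir = NULL, masterSeed = 1L,
                    poolCfg = new("PoolConfig"),
                    noiseCfg = new("NoiseConfig"), globals = mnGlobals()) {
  stopifnot(workers >= 1)
  combos <- enumerateGrid(spec)
  rows <- split(combos, seq_len(nrow(combos)))
  runOne <- function(row) {
    tryCatch(.runOneCombo(row, cfg, poolCfg, noiseCfg, masterSeed, outDir,
                          globals),
             error = function(e) {
               data.frame(rMod = row$rMod, gIn = row$gIn,
                          wStart = row$wStart, wEnd = row$wEnd,
                          seed = row$seed, comboId = row$comboId,
                          error = conditionMessage(e))
             })
  }
  feats <- if (workers > 1L) {
    parallel::mclapply(rows, runOne, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(rows, runOne)
  }
  out <- do.call(rbind, lapply(feats, function(f) {
    if (is.null(f$error)) f$error <- NA_character_
    f
  }))
  rownames(out) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(outDir, "index.csv"),
                     row.names = FALSE)
  }
  out
}

#' Load a grid dataset written by runGrid
#'
#' Reads the top-level index; combinations whose artifact directory is
#' missing (an interrupted sweep) are flagged in the `complete` column.
#'
#' @param path directory previously passed to [runGrid()] as `outDir`
#' @return data.frame as returned by [runGrid()], plus `complete`
#' @export
loadGridDataset <- function(path) {
  idx <- file.path(path, "index.csv")
  if (!dir.exists(path) || !file.exists(idx))
    stop("no grid dataset found at '", path, "'")
  d <- utils::read.csv(idx)
  need <- c("rMod", "gIn", "wStart", "wEnd", "seed", "comboId")
  if (!all(need %in% names(d)))
    stop("index.csv has an unexpected schema; missing: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d$complete <- vapply(d$comboId, function(id)
    dir.exists(file.path(path, id)), logical(1))
  d
}
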