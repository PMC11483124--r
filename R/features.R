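## Firing-pattern feature extraction: recruitment/de-recruitment timing,
## firing-rate saturation, delta-F hysteresis, and brace-height, computed
## per motoneuron from raw spike times and 2 s Hanning-smoothed rates, then
## aggregated per input combination.

#' Recruitment time of a spike train
#'
#' Time of the first instantaneous discharge.  An empty train returns the
#' not-recruited sentinel `NA` (excluded from pool aggregation).
#'
#' @param spikeTimes numeric spike times, s
#' @return time in s, or `NA_real_` if never recruited
#' @export
recruitmentTime <- function(spikeTimes) {
  if (length(spikeTimes) == 0) return(NA_real_)
  min(spikeTimes)
}

#' De-recruitment time of a spike train
#'
#' Time of the last instantaneous discharge; `NA` for an empty train.
#'
#' @param spikeTimes numeric spike times, s
#' @return time in s, or `NA_real_`
#' @export
derecruitmentTime <- function(spikeTimes) {
  if (length(spikeTimes) == 0) return(NA_real_)
  max(spikeTimes)
}

#' Activation duration
#'
#' `tDur = tDrec - tRec`.
#'
#' @param tRec,tDrec recruitment and de-recruitment times, s
#' @return duration, s
#' @export
activationDuration <- function(tRec, tDrec) {
  if (any(tDrec < tRec, na.rm = TRUE))
    stop("de-recruitment must not precede recruitment")
  tDrec - tRec
}

#' Recruitment range of the pool
#'
#' Difference between the recruitment times of the last and the first
#' motoneuron recruited in the pool.
#'
#' @param tRecs per-neuron recruitment times (NA for silent neurons)
#' @return range, s (NA if fewer than one neuron recruited)
#' @export
recruitmentRange <- function(tRecs) {
  v <- tRecs[!is.na(tRecs)]
  if (length(v) == 0) return(NA_real_)
  max(v) - min(v)
}

#' Firing-rate saturation
#'
#' Rate of firing-rate increase from 1 s after recruitment to the time of
#' the target peak (default 11 s), measured on the smoothed rate:
#' `(f(t3) - f(tRec + 1)) / (t3 - (tRec + 1))`.  A strongly saturating
#' (PIC-attenuated) rate gives values near zero.  Neurons recruited within
#' 1 s of the peak return `NA`.
#'
#' @param rate smoothed rate trace, imp/s
#' @param tRec recruitment time, s
#' @param time time axis of `rate`, s (default assumes 5 ms sampling)
#' @param tPeak time of the reference peak, s
#' @return slope in imp/s per s, or `NA_real_`
#' @export
saturation <- function(rate, tRec, time = NULL, tPeak = 11) {
  if (is.null(time)) time <- (seq_along(rate) - 1) * 0.005
  if (is.na(tRec) || tRec + 1 >= tPeak) return(NA_real_)
  f2 <- stats::approx(time, rate, xout = tRec + 1)$y
  f3 <- stats::approx(time, rate, xout = tPeak)$y
  (f3 - f2) / (tPeak - (tRec + 1))
}

#' Delta-F of one reporter/test motoneuron pair
#'
#' The drop in the smoothed firing rate of a lower-threshold reporter unit
#' between the recruitment (`f0`) and de-recruitment (`f1`) of a
#' higher-threshold test unit: `deltaF = f0 - f1`, the standard index of
#' PIC-mediated hysteresis.  Pairs whose recruitment times differ by 1 s or
#' less are excluded (return `NA`): the reporter's PIC must have reached
#' near steady state so its rate mainly tracks synaptic drive.
#'
#' @param reporterRate smoothed rate trace of the reporter, imp/s
#' @param tRecTest,tDrecTest recruitment and de-recruitment times of the
#'   test unit, s
#' @param tRecReporter recruitment time of the reporter, s
#' @param time time axis, s
#' @return delta-F in imp/s, or `NA_real_` for an inadmissible pair
#' @export
deltaF <- function(reporterRate, tRecTest, tDrecTest, tRecReporter,
                   time = NULL) {
  if (is.null(time)) time <- (seq_along(reporterRate) - 1) * 0.005
  if (any(is.na(c(tRecTest, tDrecTest, tRecReporter)))) return(NA_real_)
  if (tRecTest - tRecReporter <= 1) return(NA_real_)
  f0 <- stats::approx(time, reporterRate, xout = tRecTest)$y
  f1 <- stats::approx(time, reporterRate, xout = tDrecTest)$y
  f0 - f1
}

#' Brace-height of a rising-phase firing rate
#'
#' Maximum perpendicular distance between the smoothed rate on the rising
#' phase and the chord joining `(tRec, f(tRec))` to `(tPeak, f(tPeak))`,
#' signed positive when the rate bulges above the chord (PIC acceleration).
#' With `normalize = TRUE` the distance is divided by the larger chord
#' endpoint rate, giving a dimensionless index insensitive to the absolute
#' firing level.
#'
#' @param rate smoothed rate trace, imp/s
#' @param tRec recruitment time, s
#' @param time time axis, s
#' @param tPeak end of the rising phase, s (11: reference peak time)
#' @param normalize divide by the peak chord rate (default FALSE)
#' @return signed distance (imp/s, or dimensionless when normalized);
#'   `NA_real_` for a degenerate chord
#' @export
braceHeight <- function(rate, tRec, time = NULL, tPeak = 11,
                        normalize = FALSE) {
  if (is.null(time)) time <- (seq_along(rate) - 1) * 0.005
  if (is.na(tRec) || tRec >= tPeak) return(NA_real_)
  sel <- time >= tRec & time <= tPeak
  ts <- time[sel]; fs <- rate[sel]
  if (length(ts) < 2) return(NA_real_)
  p0 <- c(ts[1], fs[1]); p1 <- c(ts[length(ts)], fs[length(fs)])
  d <- p1 - p0
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) return(NA_real_)
  # signed perpendicular distance of each point from the chord; positive
  # above the chord (cross product orientation)
  dist <- (d[1] * (fs - p0[2]) - d[2] * (ts - p0[1])) / nrm
  bh <- max(dist)
  if (normalize) {
    peak <- max(abs(c(p0[2], p1[2])))
    if (peak == 0) return(NA_real_)
    bh <- bh / peak
  }
  bh
}

#' Extract the seven pool-level firing-pattern features from one run
#'
#' Per-neuron recruitment/de-recruitment times and activation duration come
#' from the raw spike times; saturation, delta-F and brace-height are
#' measured on the 2 s Hanning-smoothed rates.  Per-neuron features are
#' averaged across recruited neurons; delta-F is averaged over all ordered
#' reporter/test pairs whose recruitment times differ by more than 1 s; the
#' recruitment range is a single pool-level value.
#'
#' @param result a [`SimulationResult`]
#' @param normalizeBrace use the normalized brace-height (default TRUE,
#'   the variant fed to the inference stage)
#' @return one-row data.frame with columns `tRec`, `tDrec`, `tDur`,
#'   `tRange`, `alphaSat`, `deltaF`, `braceHeight`, `nRecruited`,
#'   `nPairs`, plus the input combination columns `rMod`, `gIn`, `wStart`,
#'   `wEnd`, `seed`, `converged`, `mse`
#' @export
extractPoolFeatures <- function(result, normalizeBrace = TRUE) {
  stopifnot(is(result, "SimulationResult"))
  tt <- result@time
  sp <- result@spikes
  nn <- length(sp)
  tRec <- vapply(sp, recruitmentTime, numeric(1))
  tDrec <- vapply(sp, derecruitmentTime, numeric(1))
  tDur <- activationDuration(tRec, tDrec)
  rec <- which(!is.na(tRec))
  aSat <- vapply(seq_len(nn), function(i)
    saturation(result@rates[, i], tRec[i], tt), numeric(1))
  bh <- vapply(seq_len(nn), function(i)
    braceHeight(result@rates[, i], tRec[i], tt,
                normalize = normalizeBrace), numeric(1))
  # delta-F over admissible ordered pairs (reporter recruited earlier)
  dfs <- c()
  if (length(rec) >= 2) {
    for (rep_i in rec) for (test_i in rec) {
      if (rep_i == test_i) next
      if (tRec[test_i] - tRec[rep_i] <= 1) next
      dfs <- c(dfs, deltaF(result@rates[, rep_i], tRec[test_i],
                           tDrec[test_i], tRec[rep_i], tt))
    }
  }
  dfs <- dfs[!is.na(dfs)]
  p <- result@pars
  data.frame(
    rMod = p$rMod, gIn = p$gIn, wStart = p$wStart, wEnd = p$wEnd,
    seed = p$seed, converged = result@converged, mse = finalMSE(result),
    tRec = mean(tRec, na.rm = TRUE), tDrec = mean(tDrec, na.rm = TRUE),
    tDur = mean(tDur, na.rm = TRUE), tRange = recruitmentRange(tRec),
    alphaSat = mean(aSat, na.rm = TRUE),
    deltaF = if (length(dfs)) mean(dfs) else NA_real_,
    braceHeight = mean(bh, na.rm = TRUE),
    nRecruited = length(rec), nPairs = length(dfs))
}

#' Seed-averaged feature table
#'
#' Aggregates per-run features into one row per (rMod, gIn, weight
#' configuration): first the features are averaged within each run (done by
#' [extractPoolFeatures()]), then these averages are averaged over the
#' noise seeds.
#'
#' @param runFeatures data.frame of per-run rows from
#'   [extractPoolFeatures()] (rows from several seeds)
#' @return data.frame keyed by (rMod, gIn, wStart, wEnd) with seed-averaged
#'   feature columns and `nSeeds`
#' @export
aggregateFeatures <- function(runFeatures) {
  key <- interaction(runFeatures$rMod, runFeatures$gIn,
                     runFeatures$wStart, runFeatures$wEnd, drop = TRUE)
  featCols <- c("tRec", "tDrec", "tDur", "tRange", "alphaSat", "deltaF",
                "braceHeight")
  out <- do.call(rbind, lapply(split(runFeatures, key), function(d) {
    cbind(d[1, c("rMod", "gIn", "wStart", "wEnd")],
          as.data.frame(lapply(d[featCols], mean, na.rm = TRUE)),
          nSeeds = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$rMod, out$gIn, out$wStart, out$wEnd), ]
}

#' Read spike trains from the standard spike CSV
#'
#' Columns `neuron_index` (0-based) and `spike_time_s`.  Returns a list of
#' per-neuron spike-time vectors so externally recorded motor-unit trains
#' can enter the feature pipeline.
#'
#' @param path CSV file path
#' @param N pool size (default: one past the largest index present)
#' @return list of numeric vectors, one per neuron
#' @export
readSpikeCSV <- function(path, N = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("neuron_index", "spike_time_s") %in% names(d)))
    stop("spike CSV must have columns neuron_index, spike_time_s")
  if (is.null(N)) N <- max(d$neuron_index) + 1L
  lapply(seq_len(N) - 1L, function(i)
    sort(d$spike_time_s[d$neuron_index == i]))
}

#' Write spike trains to the standard spike CSV
#' @param spikes list of per-neuron spike-time vectors, s
#' @param path output CSV path
#' @export
writeSpikeCSV <- function(spikes, path) {
  d <- data.frame(
    neuron_index = rep(seq_along(spikes) - 1L,
                       vapply(spikes, length, integer(1))),
    spike_time_s = unlist(spikes))
  utils::write.csv(d, path, row.names = FALSE)
}
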