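## Pool construction: parameter gradients across the 20 motoneurons,
## quadratic excitatory weight profile, and the shared ("common drive")
## synaptic conductance noise.

#' Quadratic excitatory weight profile across the pool
#'
#' `w[k] = wStart + (k/(N-1))^2 * (wEnd - wStart)` for 0-based neuron index
#' `k`, so the endpoints equal `wStart` and `wEnd` exactly.  The quadratic
#' spacing mirrors the skew of the pool toward low-threshold units.
#'
#' @param cfg a [`WeightConfig`]
#' @param N pool size (>= 2)
#' @return numeric weight vector of length `N`
#' @examples
#' assignWeights(weightConfig(1, 2.5), 20)
#' @export
assignWeights <- function(cfg, N = 20L) {
  stopifnot(is(cfg, "WeightConfig"))
  if (N < 2) stop("invalid configuration: N must be >= 2")
  k <- seq_len(N) - 1
  cfg@wStart + (k / (N - 1))^2 * (cfg@wEnd - cfg@wStart)
}

#' Construct a WeightConfig
#' @param wStart,wEnd weights at the low- and high-threshold end of the pool
#' @export
weightConfig <- function(wStart = 1, wEnd = 1) {
  new("WeightConfig", wStart = as.numeric(wStart), wEnd = as.numeric(wEnd))
}

#' The seven standard weight configurations
#'
#' The standard set of `[wStart, wEnd]` pairs:
#' `[1,1], [1.5,1], [2,1], [2.5,1], [1,1.5], [1,2], [2.5,1]`.  The printed
#' list contains `[2.5,1]` twice and no `[1,2.5]`, although the surrounding
#' description covers symmetric ranges in both directions; with
#' `fixDuplicate = TRUE` the seventh entry is replaced by `[1, 2.5]`.
#'
#' @param fixDuplicate substitute `[1, 2.5]` for the duplicated seventh
#'   entry (default FALSE: keep the list as printed)
#' @return list of seven [`WeightConfig`] objects
#' @export
standardWeightConfigs <- function(fixDuplicate = FALSE) {
  pairs <- list(c(1, 1), c(1.5, 1), c(2, 1), c(2.5, 1),
                c(1, 1.5), c(1, 2), c(2.5, 1))
  if (fixDuplicate) pairs[[7]] <- c(1, 2.5)
  lapply(pairs, function(p) weightConfig(p[1], p[2]))
}

#' Shared Ornstein-Uhlenbeck conductance noise
#'
#' Low-pass-filtered Gaussian noise with decay time constant `cfg@tau` and
#' a pointwise standard deviation `cfg@c * sqrt(meanTrace)`, i.e. variance
#' proportional to the local mean command.  One realization is generated
#' per call and shared by every neuron of the pool; the seed is taken from
#' `cfg@seed` unless overridden.
#'
#' @param meanTrace non-negative mean command trace (any units; the noise
#'   comes out in the same units)
#' @param cfg a [`NoiseConfig`]
#' @param dt sampling interval of `meanTrace`, s
#' @param seed optional integer overriding `cfg@seed`
#' @return numeric noise trace, same length as `meanTrace`
#' @export
generateNoise <- function(meanTrace, cfg = new("NoiseConfig"), dt = 0.005,
                          seed = NULL) {
  stopifnot(is(cfg, "NoiseConfig"))
  if (any(meanTrace < 0)) stop("meanTrace must be non-negative")
  n <- length(meanTrace)
  if (is.null(seed)) seed <- cfg@seed
  s <- cfg@c * sqrt(meanTrace)
  a <- exp(-dt * 1000 / cfg@tau)
  b <- sqrt(1 - a^2)
  x <- numeric(n)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  z <- stats::rnorm(n)
  # OU recursion with slowly varying target sd: x_k ~ N(0, s_k^2) pointwise
  x[1] <- s[1] * z[1]
  for (k in seq_len(n - 1)) {
    x[k + 1] <- a * x[k] + b * s[k + 1] * z[k + 1]
  }
  x
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build the motoneuron pool
#'
#' Applies the pool gradients (electrical size, AHP calcium-removal time
#' constant, PIC half-activation voltage) and attaches the excitatory
#' weight profile.
#'
#' @param cfg a [`PoolConfig`]
#' @param wcfg a [`WeightConfig`]
#' @return data.frame with one row per neuron (column order matches the
#'   integrator); attribute `"neuronIndex"` gives the 0-based indices
#' @export
buildPool <- function(cfg = new("PoolConfig"), wcfg = weightConfig(1, 1)) {
  stopifnot(is(cfg, "PoolConfig"), is(wcfg, "WeightConfig"))
  validObject(cfg); validObject(wcfg)
  w <- assignWeights(wcfg, cfg@N)
  rows <- lapply(seq_len(cfg@N) - 1L, function(i)
    mnParams(i, N = cfg@N, cfg = cfg, weight = w[i + 1]))
  pool <- as.data.frame(do.call(rbind, rows))
  attr(pool, "neuronIndex") <- seq_len(cfg@N) - 1L
  pool
}
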