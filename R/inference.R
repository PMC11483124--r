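## Regression stage: map seed-averaged firing-pattern features back onto
## the synaptic input organization (inhibitory gain, neuromodulation
## level, excitatory weight ratio), rank features by univariate F
## statistic and by nonparametric mutual information.

.FEATURES7 <- c("tRec", "tDrec", "tDur", "tRange", "alphaSat", "deltaF",
                "braceHeight")

.targetColumn <- function(table, target) {
  switch(target,
         inhibition = table$gIn,
         neuromodulation = table$rMod,
         weight_ratio = table$wEnd / table$wStart,
         stop("unknown target '", target, "'"))
}

#' Build a train/test regression dataset from a feature table
#'
#' Features are standardized to zero mean and unit variance using the
#' training split only; the split is random 70/30, stratified by weight
#' configuration, and reproducible under `splitSeed`.  Constant feature
#' columns are dropped with a warning; rows with missing feature values
#' are removed.
#'
#' @param table seed-averaged feature table from [aggregateFeatures()] (or
#'   per-run rows; any data.frame with the feature and key columns)
#' @param target one of `"inhibition"`, `"neuromodulation"`,
#'   `"weight_ratio"`
#' @param features feature column names (default the seven firing-pattern
#'   features; drop `"tDur"` to reproduce the six-feature variant)
#' @param trainFraction fraction of rows in the training split (default 0.7)
#' @param splitSeed integer seed for the split
#' @return list with elements `x` (standardized feature matrix), `y`
#'   (numeric target), `train`/`test` (row indices), `target`, `features`,
#'   `center`, `scale`
#' @export
buildRegressionDataset <- function(table,
                                   target = c("inhibition",
                                              "neuromodulation",
                                              "weight_ratio"),
                                   features = .FEATURES7,
                                   trainFraction = 0.7, splitSeed = 1L) {
  target <- match.arg(target)
  miss <- setdiff(features, names(table))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  y <- .targetColumn(table, target)
  x <- as.matrix(table[features])
  keep <- stats::complete.cases(x) & is.finite(y)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with missing values removed")
    x <- x[keep, , drop = FALSE]; y <- y[keep]
    table <- table[keep, , drop = FALSE]
  }
  if (stats::var(y) == 0) stop("degenerate target: zero variance")
  strat <- interaction(table$wStart, table$wEnd, drop = TRUE)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(as.integer(splitSeed))
  train <- unlist(lapply(split(seq_along(y), strat), function(idx) {
    ntr <- max(1L, round(trainFraction * length(idx)))
    sample(idx, ntr)
  }), use.names = FALSE)
  train <- sort(train)
  test <- setdiff(seq_along(y), train)
  ctr <- colMeans(x[train, , drop = FALSE])
  scl <- apply(x[train, , drop = FALSE], 2, stats::sd)
  const <- scl == 0 | !is.finite(scl)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(x = xs, y = y, train = train, test = test, target = target,
       features = colnames(xs), center = ctr, scale = scl)
}

.r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

.fitOne <- function(model, xtr, ytr, seed) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  switch(model,
    ols = {
      d <- data.frame(y = ytr, xtr)
      fit <- stats::lm(y ~ ., data = d)
      function(x) as.numeric(stats::predict(fit, data.frame(x)))
    },
    lasso = .glmnetFit(xtr, ytr, alpha = 1),
    ridge = .glmnetFit(xtr, ytr, alpha = 0),
    elasticnet = .glmnetFit(xtr, ytr, alpha = 0.5),
    svmLinear = {
      fit <- .svmTune(xtr, ytr, kernel = "linear")
      function(x) as.numeric(stats::predict(fit, x))
    },
    svmRBF = {
      fit <- .svmTune(xtr, ytr, kernel = "radial")
      function(x) as.numeric(stats::predict(fit, x))
    },
    stop("unknown model"))
}

.glmnetFit <- function(xtr, ytr, alpha) {
  if (ncol(xtr) < 2) {
    # glmnet needs >= 2 columns; fall back to ordinary least squares
    d <- data.frame(y = ytr, xtr)
    fit <- stats::lm(y ~ ., data = d)
    return(function(x) as.numeric(stats::predict(fit, data.frame(x))))
  }
  nf <- max(3L, min(10L, floor(nrow(xtr) / 3)))
  cv <- glmnet::cv.glmnet(xtr, ytr, alpha = alpha, nfolds = nf)
  function(x) as.numeric(stats::predict(cv, x, s = "lambda.min"))
}

# small fixed hyperparameter grid selected by cross-validation on the
# training split (the shrinkage strengths and kernel width are not tied to
# any externally fixed values)
.svmTune <- function(xtr, ytr, kernel) {
  costs <- c(1, 10, 100)
  gammas <- if (kernel == "radial") c(0.25, 1, 4) / ncol(xtr) else 1
  best <- NULL; bestErr <- Inf
  n <- nrow(xtr)
  folds <- rep_len(1:3, n)[sample.int(n)]
  for (co in costs) for (ga in gammas) {
    err <- 0
    for (f in 1:3) {
      tr <- folds != f
      fit <- e1071::svm(xtr[tr, , drop = FALSE], ytr[tr], kernel = kernel,
                        cost = co, gamma = ga, type = "eps-regression")
      pr <- stats::predict(fit, xtr[!tr, , drop = FALSE])
      err <- err + sum((ytr[!tr] - pr)^2)
    }
    if (err < bestErr) { bestErr <- err; best <- c(cost = co, gamma = ga) }
  }
  e1071::svm(xtr, ytr, kernel = kernel, cost = best[["cost"]],
             gamma = best[["gamma"]], type = "eps-regression")
}

.MODELS <- c("ols", "lasso", "ridge", "elasticnet", "svmLinear", "svmRBF")

#' Fit the six regression families and score them on the held-out split
#'
#' Ordinary least squares, lasso (L1), ridge (L2), elastic net, and
#' support-vector regression with linear and radial-basis kernels, all
#' minimizing squared error; shrinkage strengths and kernel parameters are
#' chosen by cross-validation on the training split.
#'
#' @param ds dataset from [buildRegressionDataset()]
#' @param models subset of model names (default all six)
#' @param seed seed for the internal cross-validation folds
#' @return data.frame with columns `model`, `r2Test`, `r2Train`
#' @export
fitRegressionModels <- function(ds, models = .MODELS, seed = 1L) {
  xtr <- ds$x[ds$train, , drop = FALSE]; ytr <- ds$y[ds$train]
  xte <- ds$x[ds$test, , drop = FALSE]; yte <- ds$y[ds$test]
  rows <- lapply(models, function(m) {
    pred <- .fitOne(m, xtr, ytr, seed)
    data.frame(model = m,
               r2Test = .r2(yte, pred(xte)),
               r2Train = .r2(ytr, pred(xtr)))
  })
  do.call(rbind, rows)
}

#' Rank features by univariate F statistic and trace cumulative MSE
#'
#' Features are ordered by the F statistic of the single-feature linear
#' regression on the training split (a greedy forward ordering); each model
#' family is then refitted on the growing feature set and its mean squared
#' error recorded at each step.
#'
#' @param ds dataset from [buildRegressionDataset()]
#' @param models model names (default all six)
#' @param seed internal cross-validation seed
#' @return list with `ranking` (features in decreasing F order, with
#'   scores) and `mse` (data.frame: step, feature, one column per model
#'   with the training-split MSE, and matching `<model>_test` columns)
#' @export
stepwiseFRanking <- function(ds, models = .MODELS, seed = 1L) {
  xtr <- ds$x[ds$train, , drop = FALSE]; ytr <- ds$y[ds$train]
  xte <- ds$x[ds$test, , drop = FALSE]; yte <- ds$y[ds$test]
  fstat <- vapply(seq_len(ncol(xtr)), function(j) {
    fit <- stats::lm(ytr ~ xtr[, j])
    summary(fit)$fstatistic[["value"]]
  }, numeric(1))
  ord <- order(fstat, decreasing = TRUE)
  ranking <- data.frame(feature = colnames(xtr)[ord], fStat = fstat[ord])
  steps <- lapply(seq_along(ord), function(k) {
    cols <- ord[seq_len(k)]
    row <- list(step = k, feature = colnames(xtr)[ord[k]])
    for (m in models) {
      pred <- .fitOne(m, xtr[, cols, drop = FALSE], ytr, seed)
      row[[m]] <- mean((ytr - pred(xtr[, cols, drop = FALSE]))^2)
      row[[paste0(m, "_test")]] <-
        mean((yte - pred(xte[, cols, drop = FALSE]))^2)
    }
    as.data.frame(row)
  })
  list(ranking = ranking, mse = do.call(rbind, steps))
}

#' Nearest-neighbour mutual information between two continuous variables
#'
#' Kraskov-Stoegbauer-Grassberger estimator (variant 1) with `k`
#' neighbours; a tiny deterministic jitter breaks ties.
#'
#' @param x,y numeric vectors
#' @param k neighbour count (default 3)
#' @return MI estimate in nats (clamped at 0)
#' @export
knnMutualInformation <- function(x, y, k = 3L) {
  n <- length(x)
  stopifnot(length(y) == n, n > k + 1)
  # deterministic tie-breaking jitter scaled to the data
  jx <- diff(range(x)); jy <- diff(range(y))
  if (jx == 0 || jy == 0) return(0)
  x <- x + jx * 1e-10 * sin(seq_len(n) * 1.7)
  y <- y + jy * 1e-10 * cos(seq_len(n) * 2.3)
  dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  eps <- apply(dz, 1, function(r) sort(r)[k])
  nx <- vapply(seq_len(n), function(i)
    sum(dx[i, -i] < eps[i]), numeric(1))
  ny <- vapply(seq_len(n), function(i)
    sum(dy[i, -i] < eps[i]), numeric(1))
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(0, mi)
}

#' Rank features by mutual information with the target
#'
#' @param ds dataset from [buildRegressionDataset()]
#' @param k neighbour count for the estimator (default 3)
#' @return data.frame `feature`, `mi`, sorted descending
#' @export
mutualInfoRanking <- function(ds, k = 3L) {
  mi <- vapply(seq_len(ncol(ds$x)), function(j)
    knnMutualInformation(ds$x[, j], ds$y, k), numeric(1))
  out <- data.frame(feature = colnames(ds$x), mi = mi)
  out[order(-out$mi), ]
}

#' Full regression report for one target
#'
#' Fits the six models, ranks features by F statistic (with stepwise MSE
#' curves) and by mutual information.
#'
#' @param table feature table (see [buildRegressionDataset()])
#' @param target one of `"inhibition"`, `"neuromodulation"`,
#'   `"weight_ratio"`
#' @param ... passed to [buildRegressionDataset()]
#' @return a [`RegressionReport`]
#' @export
regressionReport <- function(table, target, ...) {
  ds <- buildRegressionDataset(table, target, ...)
  fits <- fitRegressionModels(ds)
  sw <- stepwiseFRanking(ds)
  mi <- mutualInfoRanking(ds)
  r2 <- stats::setNames(fits$r2Test, fits$model)
  new("RegressionReport", target = ds$target, r2 = pmin(r2, 1),
      r2Train = stats::setNames(fits$r2Train, fits$model),
      bestModel = fits$model[which.max(fits$r2Test)],
      stepwise = sw$mse, miRanking = mi)
}

setMethod("show", "RegressionReport", function(object) {
  cat("RegressionReport for target:", object@target, "\n")
  cat("  held-out R-squared:\n")
  for (m in names(object@r2))
    cat(sprintf("    %-10s %6.3f%s\n", m, object@r2[m],
                if (m == object@bestModel) "  <- best" else ""))
  cat("  MI ranking:", paste(object@miRanking$feature, collapse = " > "),
      "\n")
})

#' Synthetic feature table with a known generative map
#'
#' Builds a feature table over a parameter grid from smooth closed-form
#' maps (linear trends plus mild interactions and curvature) with additive
#' Gaussian noise.  Because the generative map is known, held-out
#' predictability of the inputs is a property of the inference machinery
#' alone, not of the biophysics; it is the scaled-down stand-in for a full
#' ensemble when testing parameter recovery.
#'
#' @param rMod,gIn grid values
#' @param ratios weight-ratio values
#' @param seeds number of pseudo-seeds averaged per combination
#' @param noiseSd relative noise amplitude (default 0.05)
#' @param seed RNG seed
#' @return data.frame shaped like [aggregateFeatures()] output
#' @export
syntheticFeatureTable <- function(rMod = seq(0.8, 1.2, by = 0.1),
                                  gIn = seq(-0.7, 0.7, by = 0.2),
                                  ratios = c(0.5, 1, 2),
                                  seeds = 3L, noiseSd = 0.05, seed = 1L) {
  g <- expand.grid(rMod = rMod, gIn = gIn, ratio = ratios)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  n <- nrow(g)
  noise <- function(scale) stats::rnorm(n, 0, noiseSd * scale) / sqrt(seeds)
  r <- g$rMod; i <- g$gIn; w <- g$ratio
  data.frame(
    rMod = r, gIn = i, wStart = 1, wEnd = w,
    tRec = 3 - 1.2 * log(w) + 0.3 * i - 0.5 * (r - 1) + noise(1),
    tDrec = 18 + 2 * (r - 1) - 1.5 * i + 0.4 * log(w) + noise(1),
    tDur = 15 + 2.5 * (r - 1) - 1.8 * i + 1.6 * log(w) + noise(1),
    tRange = 8 - 2.5 * log(w) + 0.5 * i + noise(1),
    alphaSat = 1.8 - 1.2 * (r - 1) + 0.4 * i + 0.1 * i^2 + noise(0.3),
    deltaF = 4 + 10 * (r - 1) - 3 * i - 4 * (r - 1) * i + noise(0.6),
    braceHeight = 0.06 + 0.1 * (r - 1) - 0.005 * i + noise(0.02),
    nSeeds = seeds)
}
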