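#' Average per-fold PLSR coefficient vectors
#'
#' Element-wise arithmetic mean of the coefficient vectors produced by the
#' leave-one-out folds (the deterministic SIMPLS sign convention makes this
#' average meaningful).
#'
#' @param perFoldAlphas matrix (folds x K) or list of length-K vectors
#' @return length-K mean coefficient vector
#' @export
averageFoldCoefficients <- function(perFoldAlphas) {
  if (is.list(perFoldAlphas)) {
    len <- unique(lengths(perFoldAlphas))
    if (length(len) != 1) stop("coefficient vectors differ in length")
    perFoldAlphas <- do.call(rbind, perFoldAlphas)
  }
  if (!is.matrix(perFoldAlphas)) stop("need a matrix or list of vectors")
  colMeans(perFoldAlphas)
}

#' Rank features by coefficient magnitude
#'
#' Indices in descending order of `|alpha|`; ties are broken by ascending
#' feature index (deterministic).
#'
#' @param alpha coefficient vector (finite)
#' @return integer permutation of `seq_along(alpha)`, with `alpha` attached
#'   as attribute `"alpha"`
#' @export
rankFeatures <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) < 1) stop("alpha must be numeric")
  if (any(!is.finite(alpha))) stop("non-finite coefficient in alpha")
  structure(order(-abs(alpha), seq_along(alpha)), alpha = alpha)
}

#' Coarse-to-fine search for the best subset size
#'
#' Stage 1 evaluates subset sizes m = 1, 1+s, 1+2s, ... (plus K itself) for
#' the first interval s; each later, finer stage spans the previous best
#' +/- the previous interval, clipped to `[1, K]`. The evaluator receives the
#' top-m feature indices of the ranking and returns a cross-validated error;
#' ties in the minimal error go to the smallest m (parsimony).
#'
#' @param ranking integer permutation from [rankFeatures()]
#' @param schedule strictly decreasing intervals ending at 1,
#'   e.g. `c(100, 10, 1)`
#' @param evaluator `function(indices) -> error` (smaller is better)
#' @param K number of features (default `length(ranking)`)
#' @return list: `mStar`, `indices` (top-mStar of the ranking), `trace`
#'   (data.frame stage/m/error), `stageBest` (best m per stage)
#' @export
coarseToFineSearch <- function(ranking, schedule, evaluator,
                               K = length(ranking)) {
  schedule <- as.integer(schedule)
  if (length(schedule) < 1 || schedule[length(schedule)] != 1 ||
      any(diff(schedule) >= 0) || any(schedule < 1))
    stop("schedule must be strictly decreasing and end at 1")
  if (K < 1) stop("empty candidate set")
  cache <- new.env(parent = emptyenv())
  trace <- list()
  evalM <- function(m, stage) {
    key <- as.character(m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    e <- evaluator(ranking[seq_len(m)])
    cache[[key]] <- e
    trace[[length(trace) + 1]] <<- data.frame(stage = stage, m = m, error = e)
    e
  }
  best <- NA_integer_
  for (t in seq_along(schedule)) {
    s <- schedule[t]
    cand <- if (t == 1) unique(c(seq(1L, K, by = s), K))
    else {
      prev <- schedule[t - 1]
      lo <- max(1L, best - prev); hi <- min(K, best + prev)
      sort(unique(c(seq(lo, hi, by = s), best)))
    }
    errs <- vapply(cand, evalM, numeric(1), stage = s)
    best <- cand[which.min(errs)]  # which.min takes the first (smallest m)
  }
  trace <- do.call(rbind, trace)
  winners <- trace$m[trace$error <= min(trace$error)]
  mStar <- min(winners)
  list(mStar = as.integer(mStar),
       indices = ranking[seq_len(mStar)],
       trace = trace,
       stageBest = best)
}

## Default search schedule: the (100, 10, 1) ladder, dropping any interval
## wider than a quarter of the feature count (a coarse grid must subdivide
## the size range into several cells to bracket the optimum). Gives
## (100, 10, 1) for full-scale MC problems (K = 4005), (10, 1) for GMV-sized
## ones (K = 90), and exhaustive search for small K.
.defaultSchedule <- function(K) {
  s <- c(100L, 10L, 1L)
  s <- s[s <= K / 4]
  if (!length(s) || s[length(s)] != 1L) s <- c(s, 1L)
  s
}

.errorMetric <- function(metric) {
  switch(metric,
         mae = function(p, y) mean(abs(p - y)),
         mrae = function(p, y) mean(abs((p - y) / y)),
         cor = function(p, y) 1 - stats::cor(p, y),
         stop("unknown metric: ", metric))
}

#' Coefficient-ranked feature selection with coarse-to-fine subset search
#'
#' Two modes. `"group_level"` follows the reference procedure: one full
#' leave-one-out pass with all features yields per-fold coefficient vectors,
#' their average is ranked, and the subset size minimizing the
#' leave-one-out error of the re-fitted model over the whole cohort is found
#' by [coarseToFineSearch()]. Because the subset is chosen using all folds
#' and the error is then reported on the same cohort, this estimate is
#' optimistic. `"nested"` repeats ranking and search inside every training
#' fold only and predicts the held-out participant with that fold's own
#' subset: an unbiased cross-validated estimate. Nested results carry the
#' per-fold subsets and their consensus (features kept in >= 50% of folds).
#'
#' @param X numeric matrix, N x K
#' @param y response, length N
#' @param mode `"group_level"` or `"nested"`
#' @param schedule search intervals (default: `(100, 10, 1)` trimmed to
#'   intervals below K)
#' @param metric search error metric: `"mae"` (default), `"mrae"` or
#'   `"cor"` (1 - Pearson r)
#' @param LMax,criterion,target,threshold component-count rule per fit, as in
#'   [loocv()]; the component count is re-selected for every candidate subset
#' @return a [SelectionResult-class]; `predictions(x)` gives the
#'   leave-one-out predictions of the selected model
#' @export
selectFeatures <- function(X, y, mode = c("group_level", "nested"),
                           schedule = NULL, metric = "mae",
                           LMax = NULL, criterion = "r2target",
                           target = 0.95, threshold = 0.01) {
  mode <- match.arg(mode)
  X <- .asTrainingMatrix(X, y)
  K <- ncol(X); N <- nrow(X)
  if (is.null(schedule)) schedule <- .defaultSchedule(K)
  mfun <- .errorMetric(metric)
  looPred <- function(Xs, ys, idx) {
    loocv(Xs[, idx, drop = FALSE], ys, LMax = LMax, criterion = criterion,
          target = target, threshold = threshold)$pred
  }
  if (mode == "group_level") {
    full <- loocv(X, y, LMax = LMax, criterion = criterion, target = target,
                  threshold = threshold, returnAlphas = TRUE)
    avg <- averageFoldCoefficients(full$alphas)
    ranking <- rankFeatures(avg)
    sr <- coarseToFineSearch(ranking, schedule,
                             function(idx) mfun(looPred(X, y, idx), y), K = K)
    pred <- looPred(X, y, sr$indices)
    new("SelectionResult",
        indices = as.integer(sr$indices),
        names = colnames(X)[sr$indices],
        mStar = sr$mStar, trace = sr$trace, mode = "group_level",
        ranking = as.integer(ranking), avgAlpha = as.numeric(avg),
        perFold = list(), consensus = integer(0), pred = pred)
  } else {
    pred <- stats::setNames(numeric(N), rownames(X))
    perFold <- vector("list", N)
    hits <- integer(K)
    for (i in seq_len(N)) {
      Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
      inner <- loocv(Xi, yi, LMax = LMax, criterion = criterion,
                     target = target, threshold = threshold,
                     returnAlphas = TRUE)
      ranking <- rankFeatures(averageFoldCoefficients(inner$alphas))
      sr <- coarseToFineSearch(ranking, schedule,
                               function(idx) mfun(looPred(Xi, yi, idx), yi),
                               K = K)
      idx <- sr$indices
      perFold[[i]] <- as.integer(idx)
      hits[idx] <- hits[idx] + 1L
      Lsub <- selectNComponents(Xi[, idx, drop = FALSE], yi,
                                LMax = min(if (is.null(LMax)) 10L else LMax,
                                           length(idx), N - 3L),
                                criterion = criterion, target = target,
                                threshold = threshold)
      fit <- simplsFit(Xi[, idx, drop = FALSE], yi, L = Lsub)
      pred[i] <- predict(fit, X[i, idx, drop = FALSE])
    }
    consensus <- which(hits >= N / 2)
    new("SelectionResult",
        indices = as.integer(consensus),
        names = colnames(X)[consensus],
        mStar = length(consensus),
        trace = data.frame(stage = integer(0), m = integer(0),
                           error = numeric(0)),
        mode = "nested", ranking = integer(0), avgAlpha = numeric(0),
        perFold = perFold, consensus = as.integer(consensus), pred = pred)
  }
}

#' @describeIn selectFeatures leave-one-out predictions of the selected model
#' @param x a [SelectionResult-class]
#' @export
predictions <- function(x) x@pred

#' @describeIn SelectionResult selected feature indices
#' @param x a SelectionResult
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@indices)

#' @describeIn SelectionResult search trace (stage, m, error)
#' @export
setMethod("searchTrace", "SelectionResult", function(x) x@trace)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@mode, "): ", object@mStar,
      " features selected\n", sep = "")
  if (length(object@perFold))
    cat("  per-fold subset sizes:",
        paste(range(lengths(object@perFold)), collapse = "-"),
        "; consensus size", length(object@consensus), "\n")
})

#' Export a selection result as JSON / edge-list TSV
#'
#' @param x a [SelectionResult-class]
#' @param path output file
#' @export
writeSelectionJSON <- function(x, path) {
  jsonlite::write_json(list(mode = x@mode, mStar = x@mStar,
                            indices = x@indices, names = x@names,
                            trace = x@trace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
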