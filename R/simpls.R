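.asTrainingMatrix <- function(X, y) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || !all(is.finite(X)))
    stop("X must be a finite numeric matrix with no missing values")
  if (!is.numeric(y) || anyNA(y) || !all(is.finite(y)))
    stop("y must be finite with no missing values")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (nrow(X) < 3) stop("need at least 3 participants")
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Fit a PLSR model with the SIMPLS algorithm
#'
#' Deterministic SIMPLS (de Jong) on column-centered features and centered
#' response; no variance scaling is applied by default since MC features
#' share a scale (set `standardize = TRUE` when mixing GMV and MC scales).
#' With `L = min(K, N-1)` on full-rank data the fit reproduces ordinary least
#' squares. The sign of each basis weight vector is fixed (first
#' non-negligible entry positive) so coefficient vectors from different folds
#' can be averaged.
#'
#' @param X numeric matrix, N participants x K features
#' @param y numeric response, length N
#' @param L number of latent components, 1 <= L <= min(K, N-1)
#' @param standardize also scale columns to unit variance before fitting
#'   (coefficients are mapped back to the original scale)
#' @return a [PLSRModel-class]
#' @export
simplsFit <- function(X, y, L, standardize = FALSE) {
  X <- .asTrainingMatrix(X, y)
  N <- nrow(X); K <- ncol(X)
  L <- as.integer(L)
  if (L < 1 || L > min(K, N - 1))
    stop("L must be between 1 and min(K, N-1) = ", min(K, N - 1))
  sdx <- rep(1, K)
  Xf <- X
  if (standardize) {
    sdx <- apply(X, 2, stats::sd)
    if (any(sdx == 0)) stop("zero-variance feature; cannot standardize")
    Xf <- sweep(X, 2, sdx, "/")
  }
  fit <- cpp_simpls(Xf, as.numeric(y), L)
  A <- fit$ncomp
  if (A < 1) stop("SIMPLS could not extract a component")
  Luse <- min(L, A)
  W <- fit$weights[, seq_len(Luse), drop = FALSE]
  q <- fit$q[seq_len(Luse)]
  alpha <- as.numeric(W %*% q) / sdx
  xMean <- as.numeric(fit$xMean) * sdx  # mean on the original scale
  new("PLSRModel",
      alpha = alpha,
      intercept = fit$yMean - sum(xMean * alpha),
      L = as.integer(Luse),
      xMean = xMean, yMean = fit$yMean,
      weights = W, q = as.numeric(q),
      r2 = as.numeric(fit$r2[seq_len(Luse)]),
      featureNames = colnames(X))
}

#' @describeIn simplsFit coefficient vector (named by feature)
#' @param object a [PLSRModel-class]
#' @param ... unused
#' @export
setMethod("coef", "PLSRModel", function(object, ...) {
  stats::setNames(object@alpha, object@featureNames)
})

#' Predict from a fitted PLSR model
#'
#' yhat = (X_new - xMean) alpha + yMean.
#'
#' @param object a [PLSRModel-class]
#' @param newdata matrix with K columns in training feature order
#' @param ... unused
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object@alpha))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object@alpha))
  as.numeric(sweep(X, 2, object@xMean) %*% object@alpha) + object@yMean
})

setMethod("show", "PLSRModel", function(object) {
  cat("PLSRModel (SIMPLS):", length(object@alpha), "features,",
      object@L, "components, training R^2",
      signif(object@r2[object@L], 4), "\n")
})

#' Choose the number of latent components
#'
#' Computes the cumulative training R^2 of the SIMPLS fit for L = 1..LMax
#' (non-decreasing by construction, since latent scores are orthonormal) and
#' applies one of two rules: `"r2target"` returns the smallest L whose R^2
#' reaches `target` (default 0.95; falls back to the best available L);
#' `"elbow"` returns the smallest L beyond which the next increment of R^2
#' falls below `threshold`.
#'
#' @param X,y training data
#' @param LMax largest component count considered, <= min(K, N-1)
#' @param criterion `"r2target"` or `"elbow"`
#' @param target R^2 target for `"r2target"`
#' @param threshold increment threshold for `"elbow"`
#' @return the chosen L (integer), with the R^2 sequence in attribute `"r2"`
#' @export
selectNComponents <- function(X, y, LMax = NULL,
                              criterion = c("r2target", "elbow"),
                              target = 0.95, threshold = 0.01) {
  criterion <- match.arg(criterion)
  X <- .asTrainingMatrix(X, y)
  cap <- min(ncol(X), nrow(X) - 1)
  if (is.null(LMax)) LMax <- cap
  if (LMax > cap) stop("LMax must be <= min(K, N-1) = ", cap)
  fit <- cpp_simpls(X, as.numeric(y), as.integer(LMax))
  A <- fit$ncomp
  r2 <- fit$r2[seq_len(A)]
  L <- if (criterion == "r2target") {
    hit <- which(r2 >= target - 1e-12)
    if (length(hit)) hit[1] else A
  } else {
    if (A == 1) 1L else {
      inc <- diff(r2)
      small <- which(inc < threshold)
      if (length(small)) small[1] else A
    }
  }
  structure(as.integer(L), r2 = r2)
}
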