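#' Leave-one-participant-out cross-validation of a SIMPLS model
#'
#' Exactly N folds: fold i fits on every participant but i (the component
#' count is re-selected on each training fold, see [selectNComponents()]) and
#' predicts participant i. Predictions are assembled in the input row order,
#' which is keyed to participants, so file ordering upstream is irrelevant.
#' The per-fold coefficient vectors are returned for group-level feature
#' selection.
#'
#' @param X numeric matrix, N x K (rownames = participant ids)
#' @param y response, length N
#' @param LMax largest component count per fold (default
#'   `min(10, K, N - 2)`; capped at `min(K, N - 2)`)
#' @param criterion,target,threshold component rule, as in
#'   [selectNComponents()]
#' @param returnAlphas also return the N x K matrix of per-fold coefficients
#' @return list: `pred` (length N, named), `ncomp` (per-fold L), and
#'   `alphas` when requested
#' @export
loocv <- function(X, y, LMax = NULL, criterion = c("r2target", "elbow"),
                  target = 0.95, threshold = 0.01, returnAlphas = FALSE) {
  criterion <- match.arg(criterion)
  X <- .asTrainingMatrix(X, y)
  N <- nrow(X)
  cap <- max(1L, min(ncol(X), N - 2L))
  if (is.null(LMax)) LMax <- min(10L, cap)
  LMax <- min(as.integer(LMax), cap)
  res <- cpp_loo(X, as.numeric(y), LMax,
                 if (criterion == "r2target") 0L else 1L,
                 target, threshold, isTRUE(returnAlphas))
  ids <- rownames(X)
  out <- list(pred = stats::setNames(as.numeric(res$pred), ids),
              ncomp = as.integer(res$ncomp))
  if (isTRUE(returnAlphas)) {
    a <- res$alphas
    dimnames(a) <- list(ids, colnames(X))
    out$alphas <- a
  }
  out
}
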