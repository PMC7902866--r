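#' Composite pain sensitivity score
#'
#' Min-max normalizes the laser and cold thresholds over the cohort (cohort
#' minimum -> 0, maximum -> 1; the score range 0-1 pins the normalization to
#' min-max up to the affine choice) and takes their arithmetic mean. A higher
#' score means a less pain-sensitive participant. A z-score variant is
#' available for sensitivity analyses.
#'
#' @param phenotypes data.frame with `participant_id`, `laser_threshold_J`,
#'   `cold_threshold_s`
#' @param normalization `"minmax"` (default) or `"zscore"`
#' @return the phenotype table with added columns `laser_norm`, `cold_norm`,
#'   `pain_sensitivity_score`
#' @export
computePainScores <- function(phenotypes, normalization = c("minmax", "zscore")) {
  normalization <- match.arg(normalization)
  need <- c("participant_id", "laser_threshold_J", "cold_threshold_s")
  if (!all(need %in% names(phenotypes)))
    stop("phenotypes needs columns: ", paste(need, collapse = ", "))
  if (nrow(phenotypes) < 2) stop("need at least 2 participants")
  if (anyDuplicated(phenotypes$participant_id))
    stop("duplicate participant ids")
  la <- phenotypes$laser_threshold_J
  co <- phenotypes$cold_threshold_s
  if (any(!is.finite(la)) || any(!is.finite(co)) || any(la <= 0) || any(co <= 0))
    stop("thresholds must be finite and > 0")
  norm <- if (normalization == "minmax") .minmax
  else function(x) {
    if (stats::sd(x) == 0) stop("normalization undefined for a constant vector")
    (x - mean(x)) / stats::sd(x)
  }
  out <- phenotypes
  out$laser_norm <- norm(la)
  out$cold_norm <- norm(co)
  out$pain_sensitivity_score <- (out$laser_norm + out$cold_norm) / 2
  out
}

#' Prediction error and correlation metrics
#'
#' `mae` is the mean absolute error, `mrae` the mean of absolute errors
#' divided by the true values (refused when any true value is 0, since
#' near-zero targets make it explode), `pearsonR` the Pearson correlation
#' between predicted and true values.
#'
#' @param yHat predicted values
#' @param y true values
#' @return scalar metric; per-participant terms in attribute `"per"` for
#'   `mae`/`mrae`
#' @export
mae <- function(yHat, y) {
  .checkPair(yHat, y)
  per <- abs(yHat - y)
  structure(mean(per), per = per)
}

#' @rdname mae
#' @export
mrae <- function(yHat, y) {
  .checkPair(yHat, y)
  if (any(y == 0)) stop("mrae undefined: zero true value")
  per <- abs((yHat - y) / y)
  structure(mean(per), per = per)
}

#' @rdname mae
#' @export
pearsonR <- function(yHat, y) {
  .checkPair(yHat, y)
  stats::cor(yHat, y)
}

.checkPair <- function(yHat, y) {
  if (length(yHat) != length(y)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 values")
  if (any(!is.finite(yHat)) || any(!is.finite(y))) stop("non-finite values")
  invisible(NULL)
}

#' Assemble an evaluation report from leave-one-out predictions
#'
#' @param yHat predictions aligned to `y` (named by participant if available)
#' @param y true values
#' @param featureSet,thresholdType labels recorded in the report
#' @param mode selection mode label (`"group_level"` estimates are optimistic
#'   by construction; see [selectFeatures()])
#' @return list with per-participant table, `mae`, `mrae` (NA when a true
#'   value is 0), `pearson_r`, `n`
#' @export
evaluatePrediction <- function(yHat, y, featureSet = "mc",
                               thresholdType = "laser", mode = "nested") {
  .checkPair(yHat, y)
  ids <- names(yHat)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  m <- mae(yHat, y)
  r <- pearsonR(yHat, y)
  mr <- if (any(y == 0)) NA_real_ else as.numeric(mrae(yHat, y))
  per <- data.frame(participant_id = ids, y = y, y_hat = as.numeric(yHat),
                    abs_error = abs(yHat - y),
                    rel_abs_error = if (any(y == 0)) NA_real_
                    else abs((yHat - y) / y),
                    stringsAsFactors = FALSE)
  list(per_participant = per, mae = as.numeric(m), mrae = mr,
       pearson_r = r, feature_set = featureSet,
       threshold_type = thresholdType, mode = mode, n = length(y))
}

#' Compare two models' absolute-error samples (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test on the per-participant
#' absolute errors of two models, using the normal approximation with tie
#' correction.
#'
#' @param errorsA,errorsB per-participant absolute errors
#' @return list: `statistic` (Mann-Whitney U of sample A), `p` (two-sided),
#'   `type = "errors"`
#' @export
compareErrorSets <- function(errorsA, errorsB) {
  if (!length(errorsA) || !length(errorsB)) stop("empty error sample")
  wt <- stats::wilcox.test(errorsA, errorsB, alternative = "two.sided",
                           exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value, type = "errors")
}

#' Compare two models' prediction-truth correlations (participant bootstrap)
#'
#' The reference analysis reports p-values for differences between
#' correlation coefficients without naming a test; here the default is a
#' participant bootstrap: resample participants with replacement, recompute
#' r_A - r_B, and return a two-sided percentile p-value for a zero
#' difference. A dependent-correlation z-test (Steiger-type, using the
#' correlation between the two predictors) is available as an alternative.
#'
#' @param predA,predB two prediction vectors for the same participants
#' @param y true values
#' @param B bootstrap replicates (default 2000; must be > 0)
#' @param seed RNG seed for the resampling
#' @param method `"bootstrap"` or `"ztest"`
#' @return list: `statistic` (observed r_A - r_B), `p`,
#'   `type = "correlations"`, `method`
#' @export
compareCorrelations <- function(predA, predB, y, B = 2000, seed = 1,
                                method = c("bootstrap", "ztest")) {
  method <- match.arg(method)
  .checkPair(predA, y); .checkPair(predB, y)
  if (stats::sd(y) == 0) stop("degenerate y")
  d0 <- stats::cor(predA, y) - stats::cor(predB, y)
  if (method == "ztest") {
    n <- length(y)
    rA <- stats::cor(predA, y); rB <- stats::cor(predB, y)
    rAB <- stats::cor(predA, predB)
    zA <- atanh(rA); zB <- atanh(rB)
    # Steiger's approximation for dependent correlations sharing y
    rbar2 <- ((rA + rB) / 2)^2
    cov <- rAB * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - rAB^2)
    cov <- cov / (1 - rbar2)^2
    z <- (zA - zB) * sqrt((n - 3) / (2 - 2 * cov))
    return(list(statistic = d0, p = 2 * stats::pnorm(-abs(z)),
                type = "correlations", method = "ztest"))
  }
  B <- as.integer(B)
  if (B <= 0) stop("B must be > 0")
  n <- length(y)
  dstar <- .withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(y[idx]) == 0 || stats::sd(predA[idx]) == 0 ||
          stats::sd(predB[idx]) == 0) return(NA_real_)
      stats::cor(predA[idx], y[idx]) - stats::cor(predB[idx], y[idx])
    }, numeric(1))
  })
  dstar <- dstar[is.finite(dstar)]
  Bok <- length(dstar)
  pLo <- (sum(dstar <= 0) + 1) / (Bok + 1)
  pHi <- (sum(dstar >= 0) + 1) / (Bok + 1)
  list(statistic = d0, p = min(1, 2 * min(pLo, pHi)),
       type = "correlations", method = "bootstrap", B = Bok)
}

#' Count selected MC features per lobe pair
#'
#' Maps each selected ROI-pair feature to the unordered pair of
#' hemisphere-specific lobes of its two ROIs and counts features per lobe
#' pair, ranked descending (ties at the top-k boundary are included).
#'
#' @param selected a [SelectionResult-class] whose feature indices refer to
#'   the lower-triangle MC feature order of `parc`, or an integer vector of
#'   such indices
#' @param parc the [Parcellation-class]
#' @param topK how many top pairs to flag (default 5)
#' @return data.frame (lobe_a, lobe_b, n, top) sorted by decreasing n; the
#'   counts sum to the number of selected features
#' @export
lobePairCounts <- function(selected, parc, topK = 5) {
  idx <- if (is(selected, "SelectionResult")) selected@indices else
    as.integer(selected)
  n <- nRois(parc)
  nf <- n * (n - 1) / 2
  if (any(idx < 1 | idx > nf))
    stop("selected indices outside the MC feature range 1..", nf)
  lob <- lobeLabels(parc)
  if (any(is.na(lob) | lob == "")) stop("ROI without lobe assignment")
  ij <- .lowerPairs(n)[idx, , drop = FALSE]
  a <- lob[ij[, 1]]; b <- lob[ij[, 2]]
  pair <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  tab <- sort(table(pair), decreasing = TRUE)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(lobe_a = vapply(parts, `[`, "", 1),
                    lobe_b = vapply(parts, `[`, "", 2),
                    n = as.integer(tab), stringsAsFactors = FALSE)
  if (nrow(out)) {
    cut <- if (nrow(out) <= topK) min(out$n) else out$n[topK]
    out$top <- out$n >= cut
  }
  rownames(out) <- NULL
  out
}

#' Common and distinct lobe pairs between two selections
#'
#' Set algebra over the top lobe pairs of two summaries (e.g. the laser and
#' cold models): pairs predictive of both, and pairs specific to each.
#'
#' @param countsA,countsB data.frames from [lobePairCounts()]
#' @param topOnly compare only the flagged top pairs (default) or all pairs
#' @return list of data.frames `common`, `onlyA`, `onlyB`
#' @export
lobePairSetOps <- function(countsA, countsB, topOnly = TRUE) {
  keys <- function(d) {
    if (topOnly && "top" %in% names(d)) d <- d[d$top, , drop = FALSE]
    paste(d$lobe_a, d$lobe_b, sep = "|")
  }
  ka <- keys(countsA); kb <- keys(countsB)
  split2 <- function(k) {
    if (!length(k)) return(data.frame(lobe_a = character(0),
                                      lobe_b = character(0)))
    p <- strsplit(k, "|", fixed = TRUE)
    data.frame(lobe_a = vapply(p, `[`, "", 1), lobe_b = vapply(p, `[`, "", 2),
               stringsAsFactors = FALSE)
  }
  list(common = split2(intersect(ka, kb)),
       onlyA = split2(setdiff(ka, kb)),
       onlyB = split2(setdiff(kb, ka)))
}

#' Cross-participant correlation between MC and GMV features
#'
#' Pearson correlation, across participants, of every (MC feature, GMV
#' feature) pair, with Benjamini-Hochberg adjusted p-values. Constant
#' features yield NA entries (flagged, not an error).
#'
#' @param mcFeatures participants x MC-features matrix
#' @param gmv participants x ROIs GMV matrix (same participant order)
#' @return list: `r` (MC x GMV correlation matrix), `p` (raw p-values),
#'   `q` (BH-adjusted), `significant` (logical, q < alpha), `alpha`
#' @param alpha BH significance level (default 0.05)
#' @export
mcGmvCorrelation <- function(mcFeatures, gmv, alpha = 0.05) {
  mcFeatures <- as.matrix(mcFeatures); gmv <- as.matrix(gmv)
  if (nrow(mcFeatures) != nrow(gmv))
    stop("participant mismatch between MC and GMV tables")
  n <- nrow(mcFeatures)
  if (n < 4) stop("need at least 4 participants")
  sdm <- apply(mcFeatures, 2, stats::sd)
  sdg <- apply(gmv, 2, stats::sd)
  r <- suppressWarnings(stats::cor(mcFeatures, gmv))
  r[sdm == 0, ] <- NA_real_
  r[, sdg == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
              dimnames = dimnames(p))
  list(r = r, p = p, q = q, significant = q < alpha, alpha = alpha)
}
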