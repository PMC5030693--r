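## DNA-RNA fold-change integration: OLS of RNA log2FC on DNA log2FC across
## features, per-observation 95% prediction intervals, and classification of
## significant features falling outside the band as "responsive" — features
## whose transcription changed beyond what their copy-number change predicts.

#' Pair DNA and RNA differential results per feature
#'
#' Merges two [fitDifferential()] outputs (one per assay) on feature id,
#' keeping the features present in both.
#'
#' @param dnaRes,rnaRes differential result `data.frame`s.
#' @param features optional feature universe restriction (e.g. the jointly
#'   detected set from [detectFilter()]).
#' @return `data.frame` with columns `feature_id`, `dna_log2fc`,
#'   `rna_log2fc`, `dna_significant`, `rna_significant`.
#' @export
foldChangePairs <- function(dnaRes, rnaRes, features = NULL) {
  shared <- intersect(dnaRes$feature_id, rnaRes$feature_id)
  if (!is.null(features)) shared <- intersect(shared, features)
  if (!length(shared)) stop("no shared features between DNA and RNA results")
  di <- match(shared, dnaRes$feature_id)
  ri <- match(shared, rnaRes$feature_id)
  out <- data.frame(feature_id = shared,
                    dna_log2fc = dnaRes$log2fc[di],
                    rna_log2fc = rnaRes$log2fc[ri],
                    dna_significant = dnaRes$significant[di],
                    rna_significant = rnaRes$significant[ri],
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$dna_log2fc)) || any(!is.finite(out$rna_log2fc)))
    stop("non-finite fold changes")
  out
}

#' OLS regression of RNA fold change on DNA fold change
#'
#' @param pairs output of [foldChangePairs()] (or any data frame with
#'   `dna_log2fc` and `rna_log2fc` columns); needs at least 3 rows and a
#'   non-constant predictor.
#' @return an [FcRegression-class] with `s^2 = SSE / (n - 2)`.
#' @export
fitFcRegression <- function(pairs) {
  x <- pairs$dna_log2fc
  y <- pairs$rna_log2fc
  n <- length(x)
  if (n < 3) stop("need at least 3 points to fit the fold-change regression")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate predictor: all DNA fold changes are equal")
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  new("FcRegression",
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      residualSd = sqrt(sse / (n - 2)),
      n = n, xMean = mean(x), sxx = sxx,
      rSquared = if (sst > 0) 1 - sse / sst else NA_real_)
}

#' Per-observation prediction interval of the fold-change regression
#'
#' `yhat +/- t_{1-(1-level)/2, n-2} * s * sqrt(1 + 1/n + (x0 - xbar)^2/Sxx)`.
#'
#' @param fit an [FcRegression-class].
#' @param x0 predictor value(s).
#' @param level coverage level in (0, 1), default 0.95.
#' @return `data.frame` with columns `fit`, `lwr`, `upr`.
#' @export
predictionInterval <- function(fit, x0, level = 0.95) {
  stopifnot(is(fit, "FcRegression"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  yhat <- fit@intercept + fit@slope * x0
  tq <- stats::qt(1 - (1 - level) / 2, df = fit@n - 2)
  half <- tq * fit@residualSd *
    sqrt(1 + 1 / fit@n + (x0 - fit@xMean)^2 / fit@sxx)
  data.frame(fit = yhat, lwr = yhat - half, upr = yhat + half)
}

#' Classify responsive features from fold-change pairs
#'
#' A feature is called responsive when (a) it is significant under the chosen
#' rule — differentially abundant at the DNA **or** RNA level (default), or at
#' the RNA level only — and (b) its RNA fold change lies outside the
#' per-observation prediction interval of the DNA-RNA fold-change regression.
#' Direction is by the side of the interval: above the upper bound is
#' `up_responsive`, below the lower bound `down_responsive` (set
#' `direction = "sign"` to use the sign of the RNA fold change instead).
#'
#' @param pairs output of [foldChangePairs()].
#' @param fit an [FcRegression-class] computed on these pairs.
#' @param level prediction-interval level, default 0.95.
#' @param rule `"dna_or_rna"` (default) or `"rna_only"`.
#' @param direction `"pi_side"` (default) or `"sign"`.
#' @return `pairs` with added columns `predicted`, `pi_low`, `pi_high`,
#'   `class` (`up_responsive` / `down_responsive` / `none`).
#' @export
classifyResponsive <- function(pairs, fit, level = 0.95,
                               rule = c("dna_or_rna", "rna_only"),
                               direction = c("pi_side", "sign")) {
  rule <- match.arg(rule)
  direction <- match.arg(direction)
  pi <- predictionInterval(fit, pairs$dna_log2fc, level = level)
  sig <- if (rule == "dna_or_rna")
    pairs$dna_significant | pairs$rna_significant else pairs$rna_significant
  above <- pairs$rna_log2fc > pi$upr
  below <- pairs$rna_log2fc < pi$lwr
  cls <- rep("none", nrow(pairs))
  if (direction == "pi_side") {
    cls[sig & above] <- "up_responsive"
    cls[sig & below] <- "down_responsive"
  } else {
    out <- sig & (above | below)
    cls[out & pairs$rna_log2fc >= 0] <- "up_responsive"
    cls[out & pairs$rna_log2fc < 0] <- "down_responsive"
  }
  pairs$predicted <- pi$fit
  pairs$pi_low <- pi$lwr
  pairs$pi_high <- pi$upr
  pairs$class <- cls
  pairs
}
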