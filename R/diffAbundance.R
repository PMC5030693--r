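## Two-group differential abundance on CSS-normalized counts: per-feature
## OLS group coefficient on log2(value + 1), empirical-Bayes variance
## moderation, moderated t, BH adjustment.  This stands in for the
## zero-inflated Gaussian of metagenomeSeq while keeping its key ingredients
## (CSS scaling, variance shrinkage, BH control) fully specified.

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_(i) -> min over j >= i of p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummin((p[o] * m / seq_len(m))[m:1])[m:1])
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Moderated-t differential abundance between two conditions
#'
#' For every feature of a CSS-normalized matrix: `y = log2(value + 1)` is
#' regressed on the group indicator (contrast condition minus reference), the
#' residual variance `s_g^2` on `d_g = n - 2` degrees of freedom is shrunk
#' towards a prior `(d0, s0^2)` estimated across features by the
#' method-of-moments fit of a scaled F distribution to the sample variances
#' (via [limma::squeezeVar()]), and the moderated statistic
#' `t = coef / (s_tilde * sqrt(1/n1 + 1/n2))` is referred to a t distribution
#' on `d0 + d_g` degrees of freedom.  P-values are BH-adjusted across
#' features.
#'
#' @param norm a [NormalizedMatrix-class] (tagged `"css"`; `"rpm"` is allowed
#'   but unusual).
#' @param contrast `c(test, reference)` condition names; the log2 fold change
#'   is test minus reference.  Default `c("Hh_aIL10R", "steady_state")`.
#' @param alpha BH significance level, default 0.05.
#' @param minFc optional minimum fold change (natural scale, e.g. 2); when
#'   set, significance additionally requires `|log2fc| > log2(minFc)`.
#' @param prior optional `list(d0 = , s0sq = )` overriding the estimated
#'   moderation prior (use `d0` near 0 to recover the ordinary t-test).
#' @param features optional character vector restricting the analysis (e.g.
#'   the output of [detectFilter()]).
#' @return `data.frame` with columns `feature_id`, `log2fc`,
#'   `mean_abundance`, `raw_p`, `adjusted_p`, `significant`; attributes
#'   `d0` and `s0sq` record the moderation prior used.
#' @export
fitDifferential <- function(norm, contrast = c("Hh_aIL10R", "steady_state"),
                            alpha = 0.05, minFc = NULL, prior = NULL,
                            features = NULL) {
  stopifnot(is(norm, "NormalizedMatrix"), length(contrast) == 2L)
  cond <- sampleConditions(norm)
  missing <- setdiff(contrast, unique(cond))
  if (length(missing))
    stop("condition(s) absent from the data: ", paste(missing, collapse = ", "))
  vals <- normValues(norm)
  if (!is.null(features)) {
    unknown <- setdiff(features, rownames(vals))
    if (length(unknown))
      stop("unknown feature(s): ", paste(utils::head(unknown, 3), collapse = ", "))
    vals <- vals[features, , drop = FALSE]
  }
  test <- cond == contrast[1L]
  ref <- cond == contrast[2L]
  n1 <- sum(ref); n2 <- sum(test)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples (got ", n1, " and ", n2, ")")
  y <- log2(vals[, test | ref, drop = FALSE] + 1)
  g <- test[test | ref]
  m1 <- rowMeans(y[, !g, drop = FALSE])
  m2 <- rowMeans(y[, g, drop = FALSE])
  coef <- m2 - m1
  ss <- rowSums((y[, !g, drop = FALSE] - m1)^2) +
        rowSums((y[, g, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- ss / df
  if (is.null(prior)) {
    sq <- limma::squeezeVar(s2, df)
    d0 <- sq$df.prior
    s0sq <- sq$var.prior
    varPost <- sq$var.post
  } else {
    d0 <- prior$d0
    s0sq <- prior$s0sq
    varPost <- (d0 * s0sq + df * s2) / (d0 + df)
  }
  se <- sqrt(varPost * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, coef / se, 0)
  dfTotal <- d0 + df
  rawP <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  res <- data.frame(feature_id = rownames(y), log2fc = unname(coef),
                    mean_abundance = unname(rowMeans(y)),
                    raw_p = unname(rawP),
                    adjusted_p = bhAdjust(unname(rawP)),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- callSignificant(res, alpha = alpha, minFc = minFc)
  attr(res, "d0") <- unname(d0)
  attr(res, "s0sq") <- unname(s0sq)
  attr(res, "contrast") <- contrast
  res
}

#' Apply a significance rule to differential results
#'
#' Flags features with `adjusted_p < alpha`, and, when `minFc` is given,
#' additionally `2^|log2fc| > minFc` (i.e. a fold change beyond `minFc` in
#' either direction) — the usual replication rule "adjusted p < 0.05 and fold
#' change > 2".
#'
#' @param results output of [fitDifferential()].
#' @param alpha BH level, default 0.05.
#' @param minFc optional minimum fold change on the natural scale.
#' @return `results` with its `significant` column (re)set.
#' @export
callSignificant <- function(results, alpha = 0.05, minFc = NULL) {
  sig <- results$adjusted_p < alpha
  if (!is.null(minFc))
    sig <- sig & (2^abs(results$log2fc) > minFc)
  results$significant <- sig
  results
}
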