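## Normalization and community summaries: reads-per-million scaling, the
## joint DNA/RNA detection filter, cumulative sum scaling (CSS), Shannon
## diversity and exact expected rarefaction richness.

.newNormalized <- function(template, values, normalization,
                           cssQuantile = NA_real_, cssScale = NA_real_) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    colData = SummarizedExperiment::colData(template))
  new("NormalizedMatrix", se, normalization = normalization,
      cssQuantile = cssQuantile, cssScale = cssScale,
      featureKind = featureKind(template))
}

#' Reads-per-million scaling
#'
#' `value = count / library_size * 1e6`, where the library size is the total
#' number of aligned reads recorded in the sample metadata (not the column
#' sum: unassignable reads still count towards the denominator).
#'
#' @param m a [CountMatrix-class].
#' @return a [NormalizedMatrix-class] tagged `"rpm"`.
#' @export
rpmNormalize <- function(m) {
  stopifnot(is(m, "CountMatrix"))
  ls <- librarySizes(m)
  if (any(is.na(ls)) || any(ls <= 0))
    stop("every sample needs a positive library_size")
  vals <- sweep(counts(m), 2L, ls, "/") * 1e6
  .newNormalized(m, vals, "rpm")
}

#' Joint DNA/RNA detection filter
#'
#' Features whose mean RPM across samples is strictly greater than the
#' threshold in **both** the DNA and the RNA matrix.  This reproduces the
#' usual "detected at >0.1 RPM in both data sets" rule used to define the
#' jointly observed feature universe.
#'
#' @param dna,rna [NormalizedMatrix-class] objects tagged `"rpm"` sharing a
#'   feature universe.
#' @param threshold detection threshold in RPM, default 0.1 (strict
#'   inequality).
#' @param statistic `"mean"` (default) or `"all_samples"`: whether the
#'   threshold applies to the mean across samples or to every sample.
#' @return character vector of retained feature ids.
#' @export
detectFilter <- function(dna, rna, threshold = 0.1,
                         statistic = c("mean", "all_samples")) {
  statistic <- match.arg(statistic)
  stopifnot(normMethod(dna) == "rpm", normMethod(rna) == "rpm")
  shared <- intersect(rownames(dna), rownames(rna))
  if (!length(shared))
    stop("DNA and RNA matrices share no features")
  stat <- function(x) if (statistic == "mean") rowMeans(x) else
    apply(x, 1L, min)
  d <- stat(normValues(dna)[shared, , drop = FALSE])
  r <- stat(normValues(rna)[shared, , drop = FALSE])
  shared[d > threshold & r > threshold]
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Per sample: `q` is the linear-interpolation `p`-quantile of the sample's
#' positive counts; the scaling factor `s` is the sum of all counts less than
#' or equal to `q`; values are `count / s * scale`.  Computing the quantile
#' over positive counts only keeps the factor from collapsing to zero on the
#' sparse matrices typical of microbiome data.
#'
#' @param m a [CountMatrix-class]; every sample needs at least one positive
#'   count.
#' @param p quantile in (0, 1), default 0.5.
#' @param scale output scale constant, default 1000.
#' @return a [NormalizedMatrix-class] tagged `"css"`.
#' @examples
#' m <- CountMatrix(matrix(c(0L, 1L, 2L, 3L, 10L), 5, 1,
#'                         dimnames = list(paste0("f", 1:5), "s1")),
#'                  condition = "steady_state", assayType = "DNA",
#'                  librarySize = 16, featureKind = "NOG")
#' normValues(cssNormalize(m))["f4", ]  # 3 / (1 + 2) * 1000 = 1000
#' @export
cssNormalize <- function(m, p = 0.5, scale = 1000) {
  stopifnot(is(m, "CountMatrix"), p > 0, p < 1, scale > 0)
  cts <- counts(m)
  s <- vapply(seq_len(ncol(cts)), function(j) {
    x <- cts[, j]
    pos <- x[x > 0]
    if (!length(pos))
      stop("sample '", colnames(cts)[j], "' has no positive counts")
    q <- stats::quantile(pos, p, names = FALSE, type = 7)
    sum(x[x <= q])
  }, numeric(1))
  vals <- sweep(cts, 2L, s, "/") * scale
  .newNormalized(m, vals, "css", cssQuantile = p, cssScale = scale)
}

#' Shannon diversity of one sample
#'
#' `H = -sum(p_i * log(p_i))` (natural log) over the positive proportions of
#' a count vector.
#'
#' @param x non-negative count vector with positive sum.
#' @return H in nats.
#' @export
shannonIndex <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  tot <- sum(x)
  if (tot <= 0) stop("all-zero sample: Shannon diversity undefined")
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Expected rarefied richness
#'
#' The exact hypergeometric expectation of the number of features observed in
#' a random subsample of `n` reads drawn without replacement:
#' `E[S_n] = sum_i (1 - choose(T - c_i, n) / choose(T, n))` with `T` the
#' total count.  No resampling is performed.
#'
#' @param x non-negative integer count vector.
#' @param n subsample size, `0 <= n <= sum(x)`.
#' @return expected number of features observed.
#' @export
rarefyRichness <- function(x, n) {
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  total <- sum(x)
  if (n > total) stop("subsample size n exceeds the total count")
  if (n < 0) stop("n must be >= 0")
  x <- x[x > 0]
  sum(1 - exp(lchoose(total - x, n) - lchoose(total, n)))
}
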