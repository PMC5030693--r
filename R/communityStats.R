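## Ordination and the remaining inferential statistics: PCA on normalized
## abundances, Bray-Curtis distances, PERMANOVA with a label-permutation
## null, hypergeometric category/overlap enrichment, genus-per-NOG
## contribution matrices, dominance flags and Kolmogorov-Smirnov
## distribution comparisons.

#' PCA of normalized abundances
#'
#' Samples are projected onto the principal components of the feature-centred
#' (by default unscaled) normalized abundance matrix.
#'
#' @param norm a [NormalizedMatrix-class].
#' @param scale. scale features to unit variance, default FALSE.
#' @param nComponents number of components to return (default all).
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components) and `varianceExplained` (fractions, summing to
#'   at most 1).
#' @export
pcaOrdination <- function(norm, scale. = FALSE, nComponents = NULL) {
  vals <- normValues(norm)
  if (nrow(vals) < 2L || ncol(vals) < 2L)
    stop("PCA needs at least 2 features and 2 samples")
  keep <- apply(vals, 1L, function(r) stats::var(r) > 0)
  if (!any(keep)) stop("constant matrix: PCA undefined")
  if (scale.) vals <- vals[keep, , drop = FALSE]
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(nComponents)) length(ve) else min(nComponents, length(ve))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       varianceExplained = ve[seq_len(k)])
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` over features, computed with
#' [vegan::vegdist()].
#'
#' @param norm a [NormalizedMatrix-class] (or a samples-in-columns matrix of
#'   non-negative values).
#' @return a `dist` over samples.
#' @export
brayCurtis <- function(norm) {
  vals <- if (is(norm, "NormalizedMatrix")) normValues(norm) else as.matrix(norm)
  if (any(vals < 0)) stop("Bray-Curtis needs non-negative values")
  zero <- colSums(vals) == 0
  if (any(zero))
    stop("all-zero sample(s): Bray-Curtis undefined for ",
         paste(colnames(vals)[zero], collapse = ", "))
  vegan::vegdist(t(vals), method = "bray")
}

#' PERMANOVA (one-factor, label-permutation null)
#'
#' Partitions the pairwise squared distances: `SS_T = sum_{i<j} d_ij^2 / N`,
#' `SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g`, and
#' `F = ((SS_T - SS_W)/(a - 1)) / (SS_W/(N - a))` for `a` groups.  The
#' p-value is the add-one proportion of label permutations with `F* >= F`.
#'
#' @param d a `dist` over samples (e.g. from [brayCurtis()]).
#' @param labels group label per sample (>= 2 groups, each >= 2 samples).
#' @param nPerm number of permutations, default 999.
#' @param seed integer seed.
#' @return list with `F`, `p`, `ssTotal`, `ssWithin`, `df`.
#' @export
permanova <- function(d, labels, nPerm = 999, seed = 1) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required")
  tab <- table(labels)
  if (length(tab) < 2L) stop("PERMANOVA needs >= 2 groups")
  if (any(tab < 2L)) stop("every group needs >= 2 samples")
  a <- length(tab)
  ssTotal <- sum(dm[upper.tri(dm)]) / n
  within <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      s <- s + sum(dm[idx, idx][upper.tri(dm[idx, idx])]) / length(idx)
    }
    s
  }
  ssW <- within(labels)
  if (ssW == 0)
    stop("within-group sum of squares is zero: F undefined")
  fstat <- function(ssw) ((ssTotal - ssw) / (a - 1)) / (ssw / (n - a))
  f <- fstat(ssW)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    ssWp <- within(labels[sample.int(n)])
    if (ssWp > 0 && fstat(ssWp) >= f) exceed <- exceed + 1L
  }
  list(F = f, p = (1 + exceed) / (1 + nPerm),
       ssTotal = ssTotal, ssWithin = ssW, df = c(a - 1L, n - a))
}

#' Hypergeometric category enrichment
#'
#' For every category: with `N` the universe size, `K` the category size,
#' `n` the query size and `k` the query/category overlap, the raw p is the
#' upper-tail hypergeometric probability `P(X >= k)`, the fold enrichment is
#' `(k/n) / (K/N)`, and p-values are BH-adjusted across categories.
#'
#' @param query character vector, a subset of `universe`.
#' @param categories named character vector mapping feature id -> category id
#'   (features without a category are simply in no category).
#' @param universe character vector of all features.
#' @return `data.frame` with columns `category`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `raw_p`, `adjusted_p`, ordered by raw p.
#' @export
hypergeomEnrichment <- function(query, categories, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(setdiff(query, universe)))
    stop("query is not a subset of the universe")
  categories <- categories[names(categories) %in% universe]
  cats <- sort(unique(unname(categories)))
  n <- length(query)
  N <- length(universe)
  rows <- lapply(cats, function(cc) {
    members <- names(categories)[categories == cc]
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(category = cc, k = k, K = K, n = n, N = N,
               fold_enrichment = if (n > 0 && K > 0) (k / n) / (K / N) else 0,
               raw_p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bhAdjust(out$raw_p)
  out[order(out$raw_p, out$category), , drop = FALSE]
}

#' Significance of the overlap of two feature sets
#'
#' Upper-tail hypergeometric probability of observing an overlap of at least
#' `k` between two sets of the given sizes drawn from a common universe.
#'
#' @param k observed overlap.
#' @param set1Size,set2Size set sizes.
#' @param universeSize universe size.
#' @return the raw p-value `P(X >= k)`.
#' @examples
#' overlapSignificance(331, 1221, 669, 14211)  # far below 0.01
#' @export
overlapSignificance <- function(k, set1Size, set2Size, universeSize) {
  if (k > min(set1Size, set2Size) || max(set1Size, set2Size) > universeSize)
    stop("inconsistent sizes: need k <= min(set sizes) <= universe")
  stats::phyper(k - 1, set1Size, universeSize - set1Size, set2Size,
                lower.tail = FALSE)
}

#' Genus-per-NOG contribution matrix
#'
#' From a joint genus-by-NOG count matrix (RNA reads assignable to both a
#' genus and a NOG; rownames `"genus|NOG"`), sums reads over samples and
#' column-normalizes to the proportion of each NOG's reads contributed by
#' each genus.  NOGs with zero total are dropped with a warning.  The
#' `>1%`-style display filter belongs to output time: see [topContributors()].
#'
#' @param joint a [CountMatrix-class] with `featureKind = "genus_by_NOG"` and
#'   rownames of the form `genus|NOG`, or a genus x NOG count matrix.
#' @param sep separator in the pair rownames, default `"|"`.
#' @return genus x NOG matrix of proportions; every column sums to 1.
#' @export
genusNogContributions <- function(joint, sep = "|") {
  if (is(joint, "CountMatrix")) {
    stopifnot(featureKind(joint) == "genus_by_NOG")
    tot <- rowSums(counts(joint))
    parts <- strsplit(rownames(joint), sep, fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("genus_by_NOG rownames must be 'genus", sep, "NOG'")
    genus <- vapply(parts, `[`, character(1), 1L)
    nog <- vapply(parts, `[`, character(1), 2L)
    m <- matrix(0, length(unique(genus)), length(unique(nog)),
                dimnames = list(unique(genus), unique(nog)))
    m[cbind(genus, nog)] <- tot
  } else {
    m <- as.matrix(joint)
  }
  colTot <- colSums(m)
  if (any(colTot == 0)) {
    warning("dropping ", sum(colTot == 0), " NOG(s) with zero total reads")
    m <- m[, colTot > 0, drop = FALSE]
    colTot <- colTot[colTot > 0]
  }
  sweep(m, 2L, colTot, "/")
}

#' Display filter for contribution matrices
#'
#' Zeroes out entries below `minContribution` (default 1%), the conventional
#' display rule "only genera contributing >1% of reads are shown".  Purely a
#' reporting filter: column sums are no longer 1 afterwards.
#'
#' @param contrib output of [genusNogContributions()].
#' @param minContribution threshold proportion, default 0.01.
#' @return filtered matrix.
#' @export
topContributors <- function(contrib, minContribution = 0.01) {
  contrib[contrib <= minContribution] <- 0
  contrib[rowSums(contrib) > 0, , drop = FALSE]
}

#' Dominance flags and KS comparison of contribution distributions
#'
#' A NOG is dominantly expressed when its maximum genus contribution exceeds
#' 0.5.  For each labelled NOG set, the distribution of per-NOG maximum
#' contributions is compared against the reference set with a two-sample
#' Kolmogorov-Smirnov test (asymptotic p).
#'
#' @param contrib output of [genusNogContributions()].
#' @param nogSets named list of character vectors (NOG ids, subsets of the
#'   contribution columns); must include `reference`.
#' @param reference name of the reference set, default `"none"`.
#' @param dominanceThreshold default 0.5.
#' @return list with `maxContribution` (named numeric per NOG), `dominant`
#'   (named logical per NOG) and `ks` (`data.frame`: set, D, p vs reference).
#' @export
dominanceAndKs <- function(contrib, nogSets, reference = "none",
                           dominanceThreshold = 0.5) {
  unknown <- setdiff(unique(unlist(nogSets)), colnames(contrib))
  if (length(unknown))
    stop("NOG set member(s) absent from the contribution matrix: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  if (!reference %in% names(nogSets))
    stop("reference set '", reference, "' not in nogSets")
  maxC <- apply(contrib, 2L, max)
  refVals <- maxC[nogSets[[reference]]]
  others <- setdiff(names(nogSets), reference)
  ks <- lapply(others, function(s) {
    vals <- maxC[nogSets[[s]]]
    if (length(vals) < 2L || length(refVals) < 2L)
      stop("KS undefined: set '", s, "' or reference has fewer than 2 NOGs")
    kt <- suppressWarnings(stats::ks.test(vals, refVals))
    data.frame(set = s, D = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  list(maxContribution = maxC,
       dominant = maxC > dominanceThreshold,
       ks = do.call(rbind, ks))
}
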