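# Shared fixtures and independent oracles, built in code.

# Small two-phylum taxonomy: Clostridium (2 species) under Firmicutes,
# Escherichia (1 species) under Proteobacteria.
smallTaxonomy <- function() {
  loadTaxonomy(c(
    "1\t1\troot\troot",
    "2\t1\tsuperkingdom\tBacteria",
    "3\t2\tphylum\tFirmicutes",
    "4\t2\tphylum\tProteobacteria",
    "5\t3\tgenus\tClostridium",
    "6\t4\tgenus\tEscherichia",
    "7\t5\tspecies\tC. difficile",
    "8\t5\tspecies\tC. perfringens",
    "9\t6\tspecies\tE. coli"))
}

makeCounts <- function(m, condition = rep(c("steady_state", "Hh_aIL10R"),
                                          length.out = ncol(m)),
                       assayType = "DNA",
                       librarySize = pmax(colSums(m), 1),
                       featureKind = "NOG") {
  if (is.null(dimnames(m)))
    dimnames(m) <- list(paste0("f", seq_len(nrow(m))),
                        paste0("s", seq_len(ncol(m))))
  CountMatrix(m, condition = condition, assayType = assayType,
              librarySize = librarySize, featureKind = featureKind)
}

randomCountMatrix <- function(nf = 6, ns = 4) {
  m <- matrix(rpois(nf * ns, 20), nf, ns,
              dimnames = list(paste0("f", seq_len(nf)),
                              paste0("s", seq_len(ns))))
  makeCounts(m, librarySize = colSums(m) + rpois(ns, 50))
}

# independent brute-force step-up BH: min over j >= i of p_(j) * m / j
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(sorted[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# naive loop re-implementation of the running-sum enrichment score
naiveES <- function(metric, isHit, weight = 1) {
  n <- length(metric)
  nr <- sum(abs(metric[isHit])^weight)
  nmiss <- n - sum(isHit)
  run <- 0
  sums <- numeric(n)
  for (i in seq_len(n)) {
    if (isHit[i]) run <- run + abs(metric[i])^weight / nr
    else run <- run - 1 / nmiss
    sums[i] <- run
  }
  bestPos <- which(abs(sums) >= max(abs(sums)) - 1e-12)[1L]
  list(es = sums[bestPos], position = bestPos, runningSum = sums)
}

# exhaustive hypergeometric upper tail by enumerating all size-n draws
enumHyperP <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inCat <- seq_len(K)  # first K elements form the category
  mean(apply(draws, 2, function(d) sum(d %in% inCat) >= k))
}

# Monte-Carlo rarefaction oracle: mean observed richness over subsamples
mcRarefy <- function(x, n, reps = 10000) {
  pool <- rep(seq_along(x), x)
  vals <- replicate(reps, length(unique(sample(pool, n))))
  c(mean = mean(vals), se = stats::sd(vals) / sqrt(reps))
}
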