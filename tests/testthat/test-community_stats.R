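rpmFixture <- function(m, assayType = "DNA") {
  rpmNormalize(makeCounts(m, assayType = assayType,
                          librarySize = rep(1e6, ncol(m))))
}

test_that("PCA separates duplicated sample groups on PC1", {
  m <- cbind(s1 = c(100L, 0L, 5L), s2 = c(98L, 2L, 5L),
             s3 = c(0L, 100L, 5L), s4 = c(2L, 98L, 5L))
  rownames(m) <- paste0("f", 1:3)
  pca <- pcaOrdination(rpmFixture(m))
  expect_gt(pca$varianceExplained[1], 0.95)
  pc1 <- pca$scores[, 1]
  expect_true(all(sign(pc1[c("s1", "s2")]) == -sign(pc1[c("s3", "s4")])))
  # variance explained non-increasing; scores sign-invariant to row order
  expect_true(all(diff(pca$varianceExplained) <= 1e-12))
  perm <- sample(nrow(m))
  pca2 <- pcaOrdination(rpmFixture(m[perm, , drop = FALSE]))
  expect_equal(abs(pca2$scores[, 1]), abs(pca$scores[, 1]))
})

test_that("bray-curtis matches hand-computed dissimilarities", {
  m <- cbind(s1 = c(1, 0), s2 = c(0, 1), s3 = c(2, 2), s4 = c(1, 1))
  rownames(m) <- c("f1", "f2")
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["s1", "s2"], 1)
  expect_equal(d["s3", "s4"], 1 / 3)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  mz <- cbind(s1 = c(1, 1), s2 = c(0, 0))
  expect_error(brayCurtis(mz), "all-zero")
})

test_that("permanova reproduces the 1-D euclidean toy decomposition", {
  d <- dist(c(0, 1, 10, 11))
  res <- permanova(d, c("A", "A", "B", "B"), nPerm = 99, seed = 1)
  expect_equal(res$ssTotal, 101)
  expect_equal(res$ssWithin, 1)
  expect_equal(res$F, 200)
  # invariance to label names and sample order
  res2 <- permanova(d, c("x", "x", "y", "y"), nPerm = 99, seed = 1)
  expect_equal(res2$F, res$F)
  o <- c(3, 1, 4, 2)
  d2 <- dist(c(0, 1, 10, 11)[o])
  res3 <- permanova(d2, c("A", "A", "B", "B")[o], nPerm = 99, seed = 1)
  expect_equal(res3$F, res$F)
  # degenerate all-identical configuration is signalled
  expect_error(permanova(dist(rep(0, 4)), c("A", "A", "B", "B")),
               "undefined")
  expect_error(permanova(d, c("A", "B", "B", "B")), ">= 2 samples")
})

test_that("permanova F agrees with vegan::adonis2 on random data", {
  set.seed(71)
  for (i in 1:5) {
    x <- matrix(abs(rnorm(10 * 12)), 12, 10)
    grp <- rep(c("A", "B", "C"), each = 4)
    d <- vegan::vegdist(x, method = "bray")
    mine <- permanova(d, grp, nPerm = 49, seed = 1)
    ref <- vegan::adonis2(d ~ grp, permutations = 49)
    expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # worked example: N=10, K=5, n=4, k=4 -> 5/210
  universe <- sprintf("u%02d", 1:10)
  cats <- setNames(rep(c("cat", "other"), each = 5), universe)
  res <- hypergeomEnrichment(universe[c(1:4)], cats, universe)
  row <- res[res$category == "cat", ]
  expect_equal(row$raw_p, 5 / 210)
  expect_equal(row$fold_enrichment, (4 / 4) / (5 / 10))
  # k=0 -> fold enrichment 0, p near 1
  res0 <- hypergeomEnrichment(universe[6:7], cats, universe)
  row0 <- res0[res0$category == "cat", ]
  expect_equal(row0$fold_enrichment, 0)
  expect_gt(row0$raw_p, 0.7)
  # query = universe -> P(X >= K) = 1
  resAll <- hypergeomEnrichment(universe, cats, universe)
  expect_true(all(resAll$raw_p == 1))
  expect_error(hypergeomEnrichment("zz", cats, universe), "subset")
  # random instances vs enumeration over all C(N, n) draws
  set.seed(72)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    u <- sprintf("e%02d", 1:N)
    cmap <- setNames(c(rep("inC", K), rep("out", N - K)), u)
    q <- sample(u, n)
    k <- sum(q %in% u[1:K])
    got <- hypergeomEnrichment(q, cmap, u)
    expect_equal(got$raw_p[got$category == "inC"], enumHyperP(N, K, n, k))
  }
})

test_that("overlap significance reproduces the in-paper configuration", {
  expect_lt(overlapSignificance(331, 1221, 669, 14211), 0.01)
  expect_equal(overlapSignificance(0, 5, 5, 20), 1)
  # complete forced overlap: both sets equal the universe
  expect_equal(overlapSignificance(10, 10, 10, 10), 1)
  expect_error(overlapSignificance(6, 5, 5, 20), "inconsistent")
})

test_that("contribution matrices column-normalize and filter at display time", {
  joint <- matrix(c(3L, 0L, 1L,
                    0L, 4L, 0L,
                    1L, 0L, 199L), 3, 3, byrow = TRUE,
                  dimnames = list(c("G1", "G2", "G3"),
                                  c("nogA", "nogB", "nogC")))
  contrib <- genusNogContributions(joint)
  expect_equal(unname(colSums(contrib)), rep(1, 3))
  expect_equal(contrib["G1", "nogA"], 0.75)
  expect_equal(contrib["G3", "nogA"], 0.25)
  expect_equal(contrib["G2", "nogB"], 1)
  # 0.5% contributor removed only by the display filter
  expect_equal(contrib["G1", "nogC"], 0.005)
  shown <- topContributors(contrib, 0.01)
  expect_equal(shown["G1", "nogC"], 0)
  expect_equal(shown["G3", "nogC"], 0.995)
  # genus_by_NOG CountMatrix entry point
  cm <- makeCounts(matrix(c(3L, 1L), 2, 1,
                          dimnames = list(c("G1|nogA", "G2|nogA"), "s1")),
                   condition = "Hh_aIL10R", assayType = "RNA",
                   featureKind = "genus_by_NOG")
  c2 <- genusNogContributions(cm)
  expect_equal(unname(c2[, "nogA"]), c(0.75, 0.25))
  # zero-total NOG dropped with a warning
  jz <- cbind(joint, nogZ = 0L)
  expect_warning(cz <- genusNogContributions(jz), "zero total")
  expect_false("nogZ" %in% colnames(cz))
})

test_that("dominance flags and KS comparisons behave on planted shifts", {
  set.seed(73)
  nog <- function(maxc) c(maxc, (1 - maxc) / 2, (1 - maxc) / 2)
  shifted <- vapply(pmin(runif(100, 0.35, 0.65) + 0.3, 0.99), nog,
                    numeric(3))
  ref <- vapply(runif(100, 0.35, 0.65), nog, numeric(3))
  contrib <- cbind(shifted, ref)
  rownames(contrib) <- c("G1", "G2", "G3")
  colnames(contrib) <- sprintf("n%03d", 1:200)
  sets <- list(up = colnames(contrib)[1:100],
               none = colnames(contrib)[101:200])
  res <- dominanceAndKs(contrib, sets, reference = "none")
  expect_gt(res$ks$D[res$ks$set == "up"], 0.3)
  expect_lt(res$ks$p[res$ks$set == "up"], 1e-6)
  expect_equal(unname(res$dominant), unname(apply(contrib, 2, max) > 0.5))
  # identical distributions: D = 0, p = 1
  same <- dominanceAndKs(contrib, list(a = sets$none, none = sets$none),
                         reference = "none")
  expect_equal(same$ks$D, 0)
  expect_equal(same$ks$p, 1)
  expect_error(dominanceAndKs(contrib, list(tiny = colnames(contrib)[1],
                                            none = sets$none)),
               "fewer than 2")
})
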