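hitRow <- function(read = "r1", subject = "s1", score = 100, e = 1e-10,
                   taxon = NA_character_, nog = NA_character_) {
  data.frame(read_id = read, subject_id = subject, bit_score = score,
             e_value = e, taxon_id = taxon, nog_id = nog,
             stringsAsFactors = FALSE)
}

test_that("hit filtering applies ms, me and the top-percent window in order", {
  hits <- rbind(hitRow(subject = "a", score = 100),
                hitRow(subject = "b", score = 60),
                hitRow(subject = "c", score = 45))
  kept <- filterHits(hits, assignmentParams())
  expect_equal(kept$subject_id, c("a", "b"))  # threshold max(50, 100*0.5)
  # single hit below ms -> empty
  expect_equal(nrow(filterHits(hitRow(score = 49), assignmentParams())), 0L)
  # ties at the best are kept even for tiny top-percent windows
  ties <- rbind(hitRow(subject = "a", score = 100),
                hitRow(subject = "b", score = 100))
  expect_equal(nrow(filterHits(ties, assignmentParams(topPercent = 1))), 2L)
  # best score is computed after the ms/me filter
  withBadBest <- rbind(hitRow(subject = "a", score = 200, e = 1),  # fails me
                       hitRow(subject = "b", score = 80),
                       hitRow(subject = "c", score = 50))
  expect_equal(filterHits(withBadBest, assignmentParams())$subject_id,
               c("b", "c"))
  # idempotence on random hit sets
  set.seed(1)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    hs <- hitRow(subject = letters[1:n], score = runif(n, 30, 150),
                 e = 10^runif(n, -30, 0))
    once <- filterHits(hs, assignmentParams())
    expect_identical(filterHits(once, assignmentParams()), once)
  }
})

test_that("lca returns the deepest common ancestor", {
  tr <- smallTaxonomy()
  expect_equal(lca("5", tr), "5")                 # identity
  expect_equal(lca(c("5", "6"), tr), "2")         # across phyla -> Bacteria
  expect_equal(lca(c("7", "5"), tr), "5")         # ancestor-of
  expect_equal(lca(c("7", "8"), tr), "5")         # two species, same genus
  expect_error(lca(c("5", "99"), tr), "unknown")
})

test_that("assignReads combines LCA taxonomy with best-hit NOG annotation", {
  tr <- smallTaxonomy()
  ht <- new("HitTable", hits = rbind(
    # r1: one retained hit at an Escherichia leaf
    hitRow("r1", "s1", 120, 1e-12, taxon = "9", nog = "COG0783"),
    # r2: retained hits spanning two phyla -> LCA Bacteria; best hit NOG wins
    hitRow("r2", "s2", 100, 1e-10, taxon = "7", nog = "COG1"),
    hitRow("r2", "s3", 90, 1e-10, taxon = "9", nog = "COG2"),
    # r3: all hits below ms -> unassigned
    hitRow("r3", "s4", 30, 1e-10, taxon = "7", nog = "COG1"),
    # r4: taxon-less hit still eligible as NOG best hit
    hitRow("r4", "s5", 110, 1e-10, taxon = NA, nog = "COG9"),
    hitRow("r4", "s6", 80, 1e-10, taxon = "8", nog = "COG1")))
  asg <- assignReads(ht, tr)
  expect_equal(asg$read_id, c("r1", "r2", "r3", "r4"))
  expect_equal(asg$node_id, c("9", "2", NA, "8"))
  expect_equal(asg$nog_id, c("COG0783", "COG1", NA, "COG9"))
  # best-hit ties break by smallest subject_id
  tie <- new("HitTable", hits = rbind(
    hitRow("t", "zz", 100, 1e-10, nog = "COGZ"),
    hitRow("t", "aa", 100, 1e-10, nog = "COGA")))
  expect_equal(assignReads(tie, tr)$nog_id, "COGA")
})

test_that("rank projection counts reads at or below the rank only", {
  tr <- smallTaxonomy()
  asg <- data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    node_id = c("7", "5", "5", "2", "3", NA),  # species, genus x2, above-genus, phylum, unassigned
    nog_id = NA_character_, stringsAsFactors = FALSE)
  cm <- projectToRank(asg, tr, rank = "genus")
  expect_equal(unname(counts(cm)["Clostridium", "all"]), 3L)
  expect_equal(unname(counts(cm)["Escherichia", "all"]), 0L)
  # conservation: assigned-at-genus <= reads
  expect_lte(sum(counts(cm)), nrow(asg))
  # per-sample split
  cm2 <- projectToRank(asg, tr, rank = "genus",
                       samples = setNames(rep(c("a", "b"), 3), asg$read_id))
  expect_equal(dim(counts(cm2)), c(2L, 2L))
  expect_equal(sum(counts(cm2)), 3L)
})

test_that("LCA on the decoy fixture recovers the planted genus", {
  tr <- smallTaxonomy()
  sh <- simulateHitTable(tr, 300, decoyProb = 1, scoreGap = 60, seed = 8)
  asg <- assignReads(sh$hits, tr)
  nd <- taxNodes(tr)
  parent <- setNames(nd$parent, nd$id)
  rankOf <- setNames(nd$rank, nd$id)
  toGenus <- function(id) {
    while (!is.na(id) && rankOf[[id]] != "genus") {
      nxt <- parent[[id]]
      if (nxt == id) return(NA_character_)
      id <- nxt
    }
    id
  }
  got <- vapply(asg$node_id, toGenus, character(1))
  expect_equal(unname(got), unname(sh$truth[asg$read_id]))
})

test_that("annotation concordance counts strict alternative-hit majorities", {
  tr <- smallTaxonomy()
  mk <- function(read, nogs, scores = c(100, rep(90, length(nogs) - 1))) {
    do.call(rbind, lapply(seq_along(nogs), function(i)
      hitRow(read, sprintf("%s_s%d", read, i), scores[i], 1e-10,
             nog = nogs[i])))
  }
  # r1: best X, alternatives X X Y -> 2/3 > 0.5 concordant
  # r2: best X, alternatives Y Z -> not concordant
  # r3: single retained hit -> excluded from the denominator
  ht <- new("HitTable", hits = rbind(
    mk("r1", c("X", "X", "X", "Y")),
    mk("r2", c("X", "Y", "Z")),
    mk("r3", "X")))
  expect_equal(annotationConcordance(ht), 0.5)
  # exactly half matching is NOT concordant (strict majority)
  htHalf <- new("HitTable", hits = mk("r4", c("X", "X", "Y")))
  expect_equal(annotationConcordance(htHalf), 0)
  # no eligible reads -> NA with a warning, never 0
  expect_warning(val <- annotationConcordance(
    new("HitTable", hits = mk("r5", "X"))), "undefined")
  expect_true(is.na(val))
})
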