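test_that("tabular alignment parsing maps fields and annotation channels", {
  line <- "r1\ts1\t99\t50\t0\t0\t1\t50\t1\t50\t1e-20\t100.5"
  ht <- parseTabularAlignment(line, taxonMap = c(s1 = "7"),
                              nogMap = c(s1 = "COG0783"))
  h <- hitRecords(ht)
  expect_equal(nrow(h), 1L)
  expect_equal(h$read_id, "r1")
  expect_equal(h$subject_id, "s1")
  expect_equal(h$e_value, 1e-20)
  expect_equal(h$bit_score, 100.5)
  expect_equal(h$taxon_id, "7")
  expect_equal(h$nog_id, "COG0783")
  # unmapped subject -> NA channels
  h2 <- hitRecords(parseTabularAlignment(line, taxonMap = c(other = "9")))
  expect_true(is.na(h2$taxon_id) && is.na(h2$nog_id))
})

test_that("tabular parser handles empty input and rejects malformed lines", {
  expect_equal(nReads(parseTabularAlignment(character(0))), 0L)
  bad11 <- "r1\ts1\t99\t50\t0\t0\t1\t50\t1\t50\t1e-20"
  expect_error(parseTabularAlignment(bad11), "line 1")
  badNum <- "r1\ts1\t99\t50\t0\t0\t1\t50\t1\t50\tNOTANUMBER\t100"
  expect_error(parseTabularAlignment(badNum), "non-numeric")
})

test_that("parser preserves within-read order and total line count", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    reads <- sort(sample(sprintf("r%d", 1:5), n, replace = TRUE))
    lines <- sprintf("%s\tsub%d\t90\t40\t0\t0\t1\t40\t1\t40\t%g\t%g",
                     reads, seq_len(n), runif(n, 1e-30, 1e-5),
                     runif(n, 40, 200))
    h <- hitRecords(parseTabularAlignment(lines))
    expect_equal(nrow(h), n)
    expect_equal(h$subject_id, sprintf("sub%d", seq_len(n)))
  }
})

test_that("taxonomy loading validates structure", {
  tr <- loadTaxonomy(c("1\t1\troot\troot", "2\t1\tgenus\tClostridium"))
  expect_s4_class(tr, "TaxonomyTree")
  expect_equal(nrow(taxNodes(tr)), 2L)
  expect_equal(taxRoot(tr), "1")
  # cycle without a self-parent root
  expect_error(loadTaxonomy(c("1\t2\tgenus\ta", "2\t1\tgenus\tb")), "root")
  # cycle off the root
  expect_error(
    loadTaxonomy(c("1\t1\troot\troot", "2\t3\tgenus\ta", "3\t2\tgenus\tb")),
    "cycle")
  # orphan parent
  expect_error(loadTaxonomy(c("1\t1\troot\troot", "2\t99\tgenus\ta")),
               "orphan")
})

test_that("ncbi_dmp dialect reads nodes.dmp/names.dmp conventions", {
  nodes <- c("1\t|\t1\t|\tno rank\t|\t",
             "2\t|\t1\t|\tgenus\t|\t")
  names <- c("1\t|\tall\t|\t\t|\tsynonym\t|",
             "1\t|\troot\t|\t\t|\tscientific name\t|",
             "2\t|\tClostridium\t|\t\t|\tscientific name\t|")
  tr <- loadTaxonomy(nodes, dialect = "ncbi_dmp", namesFile = names)
  nd <- taxNodes(tr)
  expect_equal(nd$name[nd$id == "2"], "Clostridium")
  expect_equal(nd$rank[nd$id == "1"], "no_rank")
})

test_that("count matrix TSV round-trip is an identity", {
  set.seed(7)
  for (rep in 1:5) {
    m <- randomCountMatrix(nf = sample(2:8, 1), ns = sample(2:5, 1))
    cf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
    writeCounts(m, cf, mf)
    back <- readCounts(cf, mf, featureKind = featureKind(m))
    expect_identical(unname(counts(back)), unname(counts(m)))
    expect_equal(rownames(back), rownames(m))
    expect_equal(colnames(back), colnames(m))
    expect_equal(librarySizes(back), librarySizes(m))
    expect_equal(sampleConditions(back), sampleConditions(m))
  }
})

test_that("count reading rejects bad inputs", {
  cf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "f1\t-1"), cf)
  writeLines(c("sample_id\tcondition\tassay\tlibrary_size",
               "s1\tsteady_state\tDNA\t10"), mf)
  expect_error(readCounts(cf, mf), "non-negative")
  writeLines(c("feature_id\ts1", "f1\t1", "f1\t2"), cf)
  expect_error(readCounts(cf, mf), "duplicate")
  writeLines(c("feature_id\ts1", "f1\t1"), cf)
  writeLines(c("sample_id\tcondition\tassay\tlibrary_size",
               "s1\tsteady_state\tDNA\t10",
               "s2\tHh_aIL10R\tDNA\t10"), mf)
  expect_error(readCounts(cf, mf), "missing from count header")
})

test_that("CountMatrix enforces its invariants", {
  m <- matrix(c(1.5, 1, 1, 1), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(CountMatrix(m, c("steady_state", "Hh"), "DNA", c(2, 2), "NOG"),
               "integral")
  m2 <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(CountMatrix(m2, c("bogus", "Hh"), "DNA", c(2, 2), "NOG"),
               "condition")
  expect_error(CountMatrix(m2, c("Hh", "Hh"), "DNA", c(0, 2), "NOG"),
               "library_size")
})
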