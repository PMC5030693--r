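test_that("OLS fold-change regression matches closed forms", {
  exact <- fitFcRegression(data.frame(dna_log2fc = c(0, 1, 2),
                                      rna_log2fc = c(0, 1, 2)))
  expect_equal(exact@slope, 1)
  expect_equal(exact@intercept, 0)
  expect_equal(exact@residualSd, 0)
  hand <- fitFcRegression(data.frame(dna_log2fc = c(0, 1, 2),
                                     rna_log2fc = c(0, 2, 2)))
  expect_equal(hand@slope, 1)
  expect_equal(hand@intercept, 1 / 3)
  expect_equal(hand@residualSd^2, 2 / 3)
  expect_error(fitFcRegression(data.frame(dna_log2fc = c(1, 1, 1),
                                          rna_log2fc = 1:3)), "degenerate")
  expect_error(fitFcRegression(data.frame(dna_log2fc = 1:2,
                                          rna_log2fc = 1:2)), "3 points")
})

test_that("prediction intervals match predict.lm and widen away from the mean", {
  set.seed(51)
  x <- rnorm(40); y <- 0.5 + 1.2 * x + rnorm(40, 0, 0.7)
  fit <- fitFcRegression(data.frame(dna_log2fc = x, rna_log2fc = y))
  x0 <- c(-2, 0, mean(x), 1, 3)
  mine <- predictionInterval(fit, x0)
  ref <- predict(lm(y ~ x), newdata = data.frame(x = x0),
                 interval = "prediction", level = 0.95)
  expect_equal(as.matrix(mine), unname(ref), ignore_attr = TRUE)
  # width minimal at the predictor mean, monotone in |x0 - xbar|
  off <- seq(0, 4, by = 0.5)
  w <- with(predictionInterval(fit, fit@xMean + off), upr - lwr)
  expect_true(all(diff(w) > 0))
  wNeg <- with(predictionInterval(fit, fit@xMean - off), upr - lwr)
  expect_equal(w, wNeg)
  expect_error(predictionInterval(fit, 0, level = 1.2), "level")
})

test_that("zero residual variance gives a zero-width interval", {
  fit <- fitFcRegression(data.frame(dna_log2fc = c(0, 1, 2, 3),
                                    rna_log2fc = c(0, 1, 2, 3)))
  pi <- predictionInterval(fit, 5)
  expect_equal(pi$lwr, pi$upr)
  expect_equal(pi$fit, 5)
})

test_that("responsive classification needs both significance and PI excess", {
  pairs <- data.frame(
    feature_id = c("above_sig", "inside_sig", "above_notsig", "below_sig"),
    dna_log2fc = c(0, 0.5, 0, 0),
    rna_log2fc = c(5, 0.5, 5, -5),
    dna_significant = c(FALSE, TRUE, FALSE, FALSE),
    rna_significant = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  # steep-noise-free fit from auxiliary points: y = x
  fit <- fitFcRegression(data.frame(dna_log2fc = seq(-2, 2, 0.5),
                                    rna_log2fc = seq(-2, 2, 0.5) +
                                      rnorm(9, 0, 1e-3)))
  calls <- classifyResponsive(pairs, fit)
  expect_equal(calls$class,
               c("up_responsive", "none", "none", "down_responsive"))
  # rna_only rule drops DNA-only significance
  pairs2 <- pairs
  pairs2$rna_significant <- FALSE
  pairs2$dna_significant <- TRUE
  calls2 <- classifyResponsive(pairs2, fit, rule = "rna_only")
  expect_true(all(calls2$class == "none"))
  calls3 <- classifyResponsive(pairs2, fit, rule = "dna_or_rna")
  expect_equal(sum(calls3$class != "none"), 3L)  # all outside-PI rows qualify
})

test_that("classification is invariant to feature order", {
  set.seed(52)
  n <- 60
  pairs <- data.frame(feature_id = sprintf("f%02d", 1:n),
                      dna_log2fc = rnorm(n),
                      rna_log2fc = rnorm(n),
                      dna_significant = runif(n) < 0.3,
                      rna_significant = runif(n) < 0.3,
                      stringsAsFactors = FALSE)
  fit <- fitFcRegression(pairs)
  calls <- classifyResponsive(pairs, fit)
  perm <- sample(n)
  fitP <- fitFcRegression(pairs[perm, ])
  callsP <- classifyResponsive(pairs[perm, ], fitP)
  expect_equal(fitP@slope, fit@slope)
  expect_equal(callsP$class[order(callsP$feature_id)],
               calls$class[order(calls$feature_id)])
})

test_that("foldChangePairs merges on shared features and honours the universe", {
  dna <- data.frame(feature_id = c("a", "b", "c"), log2fc = 1:3,
                    significant = c(TRUE, FALSE, TRUE))
  rna <- data.frame(feature_id = c("b", "c", "d"), log2fc = c(5, 6, 7),
                    significant = c(TRUE, TRUE, FALSE))
  pairs <- foldChangePairs(dna, rna)
  expect_equal(pairs$feature_id, c("b", "c"))
  expect_equal(pairs$dna_log2fc, c(2, 3))
  expect_equal(pairs$rna_log2fc, c(5, 6))
  restricted <- foldChangePairs(dna, rna, features = "c")
  expect_equal(restricted$feature_id, "c")
  expect_error(foldChangePairs(dna, rna, features = "zz"), "no shared")
})
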