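# Simulation oracles for the discriminants, cross-checked against MASS.

simClouds <- function(n = 50, d = 2, delta = 6, seed = 1,
                      sd1 = 1, sd2 = 1, mu2 = NULL) {
  set.seed(seed)
  if (is.null(mu2)) mu2 <- c(delta, rep(0, d - 1))
  X1 <- matrix(rnorm(n * d, sd = sd1), n, d)
  X2 <- matrix(rnorm(n * d, sd = sd2), n, d, byrow = TRUE) +
    matrix(mu2, n, d, byrow = TRUE)
  df <- as.data.frame(rbind(X1, X2))
  names(df) <- paste0("f", seq_len(d))
  df$label <- rep(c("A", "B"), each = n)
  df
}

accuracy <- function(rep) {
  sum(diag(rep$counts)) / sum(rep$counts)
}

test_that("Fisher discriminant separates well-separated clouds and matches lda", {
  df <- simClouds(n = 50, d = 2, delta = 6, seed = 100)
  m <- fitFisherLinear(df, c("f1", "f2"))
  rep <- evaluateClassifier(m, df)
  expect_gte(accuracy(rep), 0.99)

  skip_if_not_installed("MASS")
  ld <- MASS::lda(label ~ f1 + f2, df, prior = c(0.5, 0.5))
  predLda <- as.character(predict(ld, df)$class)
  expect_identical(predict(m, df), predLda)
})

test_that("identical class distributions classify at chance", {
  df <- simClouds(n = 200, d = 2, delta = 0, seed = 101)
  m <- fitFisherLinear(df, c("f1", "f2"))
  rep <- evaluateClassifier(m, df)
  # binomial 95% band around 0.5 for n = 400
  expect_lt(abs(accuracy(rep) - 0.5), 1.96 * sqrt(0.25 / 400) + 0.05)
})

test_that("Fisher assignments are invariant under affine feature maps", {
  # well-separated clouds: no point sits within the tiny ridge-induced
  # wobble of the boundary, so invariance holds exactly
  df <- simClouds(n = 40, d = 3, delta = 6, seed = 102)
  m0 <- fitFisherLinear(df, c("f1", "f2", "f3"))
  p0 <- predict(m0, df)
  # per-feature rescaling (units independence)
  df2 <- df
  df2$f1 <- df$f1 * 1000; df2$f2 <- df$f2 / 50; df2$f3 <- df$f3 * 3
  expect_identical(predict(fitFisherLinear(df2, c("f1", "f2", "f3")), df2), p0)
  # general invertible affine map
  A <- matrix(c(2, 0.5, 0, -1, 1.5, 0.3, 0.2, 0, 1), 3, 3)
  Xt <- as.matrix(df[, 1:3]) %*% A
  df3 <- data.frame(f1 = Xt[, 1] + 5, f2 = Xt[, 2] - 2, f3 = Xt[, 3],
                    label = df$label)
  expect_identical(predict(fitFisherLinear(df3, c("f1", "f2", "f3")), df3), p0)
})

test_that("quadratic discriminant reduces to linear for equal covariances", {
  df <- simClouds(n = 150, d = 2, delta = 2.5, seed = 103)
  lin <- fitFisherLinear(df, c("f1", "f2"))
  quad <- fitQuadratic(df, c("f1", "f2"))
  agree <- mean(predict(lin, df) == predict(quad, df))
  expect_gte(agree, 0.95)
  # determinism
  expect_identical(predict(quad, df),
                   predict(fitQuadratic(df, c("f1", "f2")), df))

  skip_if_not_installed("MASS")
  qd <- MASS::qda(label ~ f1 + f2, df, prior = c(0.5, 0.5))
  expect_gte(mean(predict(quad, df) ==
                    as.character(predict(qd, df)$class)), 0.99)
})

test_that("quadratic discriminant separates concentric classes where linear cannot", {
  df <- simClouds(n = 150, d = 2, delta = 0, seed = 104, sd1 = 0.5, sd2 = 3)
  lin <- evaluateClassifier(fitFisherLinear(df, c("f1", "f2")), df)
  quad <- evaluateClassifier(fitQuadratic(df, c("f1", "f2")), df)
  expect_lt(accuracy(lin), 0.65)
  expect_gt(accuracy(quad), 0.8)
})

test_that("confusion arithmetic reproduces the printed per-class reports", {
  # linear classifier, 2 features
  expect_equal(confusionStats(27, 28)$pct_rounded, 96L)
  expect_equal(confusionStats(27, 28)$se_pct_rounded, 4L)
  expect_equal(confusionStats(18, 21)$pct_rounded, 86L)
  expect_equal(confusionStats(18, 21)$se_pct_rounded, 8L)
  # quadratic, 2 features
  expect_equal(confusionStats(26, 28)$pct_rounded, 93L)
  expect_equal(confusionStats(26, 28)$se_pct_rounded, 5L)
  expect_equal(confusionStats(3, 21)$pct_rounded, 14L)
  expect_equal(confusionStats(3, 21)$se_pct_rounded, 8L)
  # linear, 3 features
  expect_equal(confusionStats(5, 21)$pct_rounded, 24L)
  expect_equal(confusionStats(5, 21)$se_pct_rounded, 9L)
  expect_equal(confusionStats(16, 21)$pct_rounded, 76L)
  # quadratic, 3 features
  expect_equal(confusionStats(25, 28)$pct_rounded, 89L)
  expect_equal(confusionStats(25, 28)$se_pct_rounded, 6L)
  expect_equal(confusionStats(1, 21)$pct_rounded, 5L)
  expect_equal(confusionStats(1, 21)$se_pct_rounded, 5L)
  expect_equal(confusionStats(20, 21)$pct_rounded, 95L)
  expect_equal(confusionStats(20, 21)$se_pct_rounded, 5L)
  # SE vanishes at perfect classification
  expect_equal(confusionStats(10, 10)$pct_rounded, 100L)
  expect_equal(confusionStats(10, 10)$se_pct_rounded, 0L)
  # one-sided binomial significance is exact
  expect_equal(confusionStats(27, 28)$p_value,
               stats::binom.test(27, 28, 0.5, "greater")$p.value)
})

test_that("confusion report columns sum to the class sizes", {
  df <- simClouds(n = 30, d = 2, delta = 1.5, seed = 105)
  rep <- evaluateClassifier(fitFisherLinear(df, c("f1", "f2")), df)
  expect_equal(unname(colSums(rep$counts)), c(30, 30))
  # leave-one-out runs and reports the same structure
  loo <- suppressMessages(
    evaluateClassifier(fitFisherLinear(df, c("f1", "f2")), df, mode = "loo"))
  expect_equal(unname(colSums(loo$counts)), c(30, 30))
})

test_that("decision-boundary plot is written and separates separable data", {
  df <- simClouds(n = 25, d = 2, delta = 8, seed = 106)
  m <- fitFisherLinear(df, c("f1", "f2"))
  path <- tempfile(fileext = ".png")
  scatterWithBoundary(df, m, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  # every point of class A on the positive side, class B negative
  sc <- as.matrix(df[, c("f1", "f2")]) %*% m$w + m$b
  expect_true(all(sc[df$label == "A"] > 0))
  expect_true(all(sc[df$label == "B"] < 0))
  m3 <- fitFisherLinear(simClouds(n = 20, d = 3, seed = 107),
                        c("f1", "f2", "f3"))
  expect_error(scatterWithBoundary(df, m3, path), "2-feature")
})
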