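# Stage classifier, coefficient standardization, two-round reduction,
# evaluation and the random-signature null.

test_that("classifier separates a separable toy and is deterministic", {
  X <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1L,
              dimnames = list(NULL, "f1"))
  y <- rep(c("lo", "hi"), each = 3L)
  fit <- trainClassifier(X, y)
  expect_equal(as.character(predict(fit, X)), y)
  fit2 <- trainClassifier(X, y)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-8)
  p <- predict(fit, X, type = "prob")
  expect_equal(rowSums(p), rep(1, 6L))
})

test_that("classifier validates its inputs", {
  X <- matrix(rnorm(20), ncol = 2L)
  expect_error(trainClassifier(X, rep("a", 10L)), "two classes")
  expect_error(trainClassifier(X, c(rep("a", 9L), "b")), ">= 2 samples")
  Xbad <- X; Xbad[1L] <- NA
  expect_error(trainClassifier(Xbad, rep(c("a", "b"), 5L)), "non-finite")
})

test_that("strong ridge shrinks towards the majority-class solution", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40L)
  y <- rep(c("a", "a", "a", "b"), 10L)   # class a has frequency 0.75
  fit <- trainClassifier(X, y, l2 = 1e6)
  expect_lt(max(abs(fit$beta)), 1e-3)
  acc <- mean(predict(fit, X) == y)
  expect_equal(acc, 0.75, tolerance = 1e-9)
})

test_that("fitted probabilities agree with glmnet ridge multinomial", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  n <- 60L; p <- 5L
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  y <- factor(rep(c("a", "b", "c"), each = 20L))
  X[y == "b", 2L] <- X[y == "b", 2L] + 1.5
  X[y == "c", 4L] <- X[y == "c", 4L] - 1.5
  l2 <- 2
  mine <- trainClassifier(X, y, l2 = l2)
  gfit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                         lambda = l2 / n, standardize = FALSE,
                         thresh = 1e-12)
  gp <- drop(predict(gfit, X, type = "response", s = l2 / n))
  expect_lt(max(abs(predict(mine, X, type = "prob") - gp)), 1e-3)
})

test_that("coefficient standardization matches the hand computation", {
  z <- standardizeCoefficients(matrix(c(1, 2, 3, 4), nrow = 1L))
  expect_equal(as.vector(z), c(-1.3416408, -0.4472136, 0.4472136,
                               1.3416408), tolerance = 1e-6)
  # exact zero mean / unit population sd
  set.seed(9)
  b <- matrix(rnorm(40, 3, 2), nrow = 4L)
  zz <- standardizeCoefficients(b)
  expect_lt(abs(mean(zz)), 1e-9)
  expect_lt(abs(sqrt(mean((zz - mean(zz))^2)) - 1), 1e-9)
  # symmetry of a symmetric pool
  zs <- standardizeCoefficients(matrix(rep(c(-1, 0, 1), 4L), nrow = 2L))
  expect_equal(sort(unique(round(as.vector(zs), 9))),
               round(c(-sqrt(1.5), 0, sqrt(1.5)), 9))
  expect_error(standardizeCoefficients(matrix(2, 2L, 2L)), "degenerate")
})

test_that("feature selection is strict, max-over-classes, and monotone", {
  z <- rbind(c(0.5, 0.78, 0.9), c(-0.1, -0.5, 0.2))
  colnames(z) <- c("g1", "g2", "g3")
  sel <- selectFeatures(z, 0.78)
  expect_equal(sel$selected, "g3")       # 0.78 is not beyond 0.78
  expect_equal(unname(sel$max_abs_z), c(0.5, 0.78, 0.9))
  expect_length(selectFeatures(matrix(0, 2L, 3L))$selected, 0L)
  z2 <- matrix(rnorm(40), 4L, dimnames = list(NULL, paste0("g", 1:10)))
  lo <- selectFeatures(z2, 0.2)$selected
  hi <- selectFeatures(z2, 1.0)$selected
  expect_true(all(hi %in% lo))
  expect_setequal(selectFeatures(abs(z2) + 0.01, 0)$selected,
                  colnames(z2))
})

test_that("two-round reduction honors its contracts", {
  set.seed(5)
  X <- matrix(rnorm(40 * 8), 40L, dimnames = list(NULL, paste0("g", 1:8)))
  y <- rep(c("a", "b"), each = 20L)
  X[y == "b", 1L] <- X[y == "b", 1L] + 3
  all_in <- twoRoundReduction(X, y, threshold = -Inf)
  expect_setequal(signatureGenes(all_in, 1L), colnames(X))
  expect_setequal(signatureGenes(all_in, 2L), colnames(X))
  sig <- twoRoundReduction(X, y, threshold = 0.78, seed = 3L)
  expect_true(all(signatureGenes(sig, 2L) %in% signatureGenes(sig, 1L)))
  sig2 <- twoRoundReduction(X, y, threshold = 0.78, seed = 3L)
  expect_identical(signatureGenes(sig, 1L), signatureGenes(sig2, 1L))
  expect_error(twoRoundReduction(X, y, threshold = 1e6), "no features")
})

test_that("classification report matches direct counting", {
  perfect <- evaluateClassifier(c("a", "b"), c("a", "b"))
  expect_equal(accuracy(perfect), 1)
  expect_equal(macroJaccard(perfect), 1)

  rep4 <- evaluateClassifier(c("a", "a", "b", "b"),
                             c("a", "b", "b", "b"))
  expect_equal(accuracy(rep4), 0.75)
  expect_equal(unname(rep4@perClassJaccard), c(1 / 2, 2 / 3))
  expect_equal(macroJaccard(rep4), 7 / 12)
  expect_equal(sum(confusionMatrix(rep4)), 4L)
  expect_equal(unname(rowSums(confusionMatrix(rep4))), c(2L, 2L))

  # everything predicted as the wrong single class
  wrong <- evaluateClassifier(c("a", "a", "b", "b"), rep("b", 4L))
  expect_equal(accuracy(wrong), 0.5)
  expect_equal(unname(wrong@perClassJaccard), c(0, 1 / 2))
  expect_error(evaluateClassifier(c("a", "b"), c("a", "x"),
                                  levels = c("a", "b")),
               "unknown labels")
})

test_that("random-signature null is reproducible and bounded", {
  se <- simulateStageExpression(
    stageSimConfig(n_genes = 120L, n_signature = 10L,
                   samples_per_stage = rep(6L, 8L), effect_size = 2,
                   seed = 4L))
  X <- t(SummarizedExperiment::assay(se))
  y <- SummarizedExperiment::colData(se)$stage
  planted <- groundTruth(se)$signature_genes
  n1 <- randomSignatureNull(X, y, planted, nSets = 12L, seed = 31L)
  n2 <- randomSignatureNull(X, y, planted, nSets = 12L, seed = 31L)
  expect_identical(nullValues(n1), nullValues(n2))
  expect_true(all(nullValues(n1) >= 0 & nullValues(n1) <= 1))
  expect_gt(empiricalP(n1), 0)
  # strong planted signal: observed beats every random set
  expect_gt(observedJaccard(n1), max(nullValues(n1)))
  expect_equal(empiricalP(n1), 1 / 13)
  expect_error(randomSignatureNull(X, y, planted, k = 1000L), "exceeds")
})

test_that("ranking standardized coefficients recovers the planted signature", {
  # The 0.78 threshold only prunes heavy-tailed coefficient pools; on a
  # Gaussian synthetic world the transferable signal is the coefficient
  # RANKING, which cleanly separates planted from background genes.
  hits <- vapply(1:2, function(s) {
    se <- simulateStageExpression(stageSimConfig(seed = s))
    X <- standardizeFeatures(t(SummarizedExperiment::assay(se)))
    y <- SummarizedExperiment::colData(se)$stage
    fit <- trainClassifier(X, y, l2 = 1)
    mz <- apply(abs(standardizeCoefficients(fit)), 2L, max)
    top <- names(sort(mz, decreasing = TRUE))[1:15]
    sum(top %in% groundTruth(se)$signature_genes)
  }, numeric(1))
  expect_true(all(hits >= 13L))   # precision and recall >= 0.85
})
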