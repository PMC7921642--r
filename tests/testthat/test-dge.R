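# Differential expression: pooled/moderated t, BH adjustment, filtering
# and merging, with limma and p.adjust as independent cross-checks.

test_that("ordinary pooled t matches the hand-computed toy", {
  se <- make_se(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1L),
                stages = rep(c("control", "case"), each = 3L),
                stage_order = c("control", "case"),
                control_stages = "control")
  tab <- fitContrast(se, "case", moderated = FALSE)
  expect_equal(tab$mean_stage - tab$mean_control, 3)
  expect_equal(tab$t, 3 / sqrt(2 / 3), tolerance = 1e-12)  # 3.674
  expect_equal(attr(tab, "df_residual"), 4L)
  expect_equal(tab$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(tab$signed_fc, 2^3)
})

test_that("identical groups give t = 0 and p = 1; down-regulation is < -1", {
  vals <- matrix(rep(c(5, 7, 6, 5, 7, 6), each = 3L), nrow = 3L)
  se <- make_se(vals, stages = rep(c("a", "b"), each = 3L),
                stage_order = c("a", "b"), control_stages = "a")
  tab <- fitContrast(se, "b", moderated = FALSE)
  expect_equal(tab$t, rep(0, 3L))
  expect_equal(tab$p, rep(1, 3L))
  # signed convention: stage below control reads as a negative ratio
  vals2 <- rbind(c(8, 8.1, 7.9, 6, 6.1, 5.9))
  se2 <- make_se(vals2, stages = rep(c("a", "b"), each = 3L),
                 stage_order = c("a", "b"), control_stages = "a")
  fc <- fitContrast(se2, "b", moderated = FALSE)$signed_fc
  expect_lt(fc, -1)
  expect_equal(fc, -2^2, tolerance = 1e-12)
})

test_that("contrast preconditions are enforced", {
  se <- make_se(matrix(1:12, nrow = 2L),
                stages = c("a", "a", "b", "b", "b", "c"),
                stage_order = c("a", "b", "c"), control_stages = "a")
  expect_error(fitContrast(se, "c"), ">= 2 samples")
  expect_error(fitContrast(se, "a"), "control")
  expect_error(fitContrast(se, "zz"), "unknown stage")
  flat <- make_se(matrix(5, nrow = 3L, ncol = 6L),
                  stages = rep(c("a", "b"), each = 3L),
                  stage_order = c("a", "b"), control_stages = "a")
  expect_error(fitContrast(flat, "b", moderated = FALSE),
               "zero variance")
})

test_that("variance moderation agrees with limma on the same data", {
  skip_if_not_installed("limma")
  set.seed(7)
  n1 <- 8L; n0 <- 10L
  vals <- matrix(rnorm(400 * (n1 + n0), sd = rep(runif(400, 0.5, 2),
                                                 n1 + n0)),
                 nrow = 400L)
  se <- make_se(vals, stages = rep(c("ctrl", "case"), c(n0, n1)),
                stage_order = c("ctrl", "case"), control_stages = "ctrl")
  tab <- fitContrast(se, "case", moderated = TRUE)

  # Route 1: prior fit against limma::squeezeVar on identical variances
  x1 <- vals[, (n0 + 1):(n0 + n1)]; x0 <- vals[, 1:n0]
  s2 <- ((n1 - 1) * apply(x1, 1, var) + (n0 - 1) * apply(x0, 1, var)) /
    (n1 + n0 - 2)
  sq <- limma::squeezeVar(s2, df = n1 + n0 - 2)
  expect_equal(attr(tab, "d0"), sq$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "s02"), sq$var.prior, tolerance = 1e-6)

  # Route 2: full moderated t against lmFit + eBayes
  design <- cbind(1, rep(c(0, 1), c(n0, n1)))
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(tab$t, fit$t[, 2L], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tab$p, fit$p.value[, 2L], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("BH step-up matches the worked example and p.adjust", {
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(rep(1, 5L)), rep(1, 5L))
  expect_equal(bhAdjust(0.123), 0.123)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1L))
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
  }
})

test_that("filter thresholds apply jointly and the merge deduplicates", {
  mk <- function(genes, fc, p) {
    data.frame(gene = genes, mean_stage = 0, mean_control = 0,
               signed_fc = fc, t = 0, p = p, adj_p = p)
  }
  t1 <- mk(c("g1", "g2", "g3"), c(2.0, -1.2, -1.8), c(0.01, 0.01, 0.2))
  out <- filterAndMerge(list(c1 = t1))
  expect_equal(out$gene, "g1")   # g2 fails FC, g3 fails p
  t2 <- mk(c("g1", "g2", "g3"), c(1.7, 1.1, 1.0), c(0.001, 0.5, 0.9))
  both <- filterAndMerge(list(c1 = t1, c2 = t2))
  expect_equal(both$gene, "g1")
  expect_equal(both$contrasts, "c1,c2")
  expect_equal(both$n_contrasts, 2L)
  none <- filterAndMerge(list(c1 = mk("g1", 1.0, 0.9)))
  expect_equal(nrow(none), 0L)
  expect_error(filterAndMerge(list()), "non-empty")
  # monotonicity: stricter thresholds never add genes
  set.seed(3)
  tabs <- list(a = mk(paste0("g", 1:50), runif(50, -3, 3), runif(50)),
               b = mk(paste0("g", 1:50), runif(50, -3, 3), runif(50)))
  loose <- filterAndMerge(tabs, p_thresh = 0.2, fc_thresh = 1.2)
  tight_fc <- filterAndMerge(tabs, p_thresh = 0.2, fc_thresh = 2)
  tight_p <- filterAndMerge(tabs, p_thresh = 0.01, fc_thresh = 1.2)
  expect_true(all(tight_fc$gene %in% loose$gene))
  expect_true(all(tight_p$gene %in% loose$gene))
})

test_that("planted signature is recovered by filter-and-merge", {
  # Monte-Carlo-frozen bounds: sensitivity is complete at this effect
  # size; the union of six BH-filtered contrasts admits a bounded number
  # of false positives (union FDR is not controlled at the per-contrast
  # level).
  for (s in 1:3) {
    se <- simulateStageExpression(
      stageSimConfig(n_genes = 1000L, n_signature = 50L,
                     samples_per_stage = rep(15L, 8L), effect_size = 2,
                     noise_sd = 1, seed = s))
    merged <- filterAndMerge(fitAllContrasts(se))
    planted <- groundTruth(se)$signature_genes
    tp <- length(intersect(merged$gene, planted))
    expect_gte(tp, 45L)
    expect_lte(nrow(merged) - tp, 25L)
  }
})

test_that("probe collapse keeps the strongest probe per symbol", {
  map <- c(p1 = "A", p2 = "A", p3 = "B", p4 = "")
  map <- map[map != ""]
  stat <- c(p1 = 1.2, p2 = 5.0, p3 = 2.0)
  out <- collapseToSymbols(c("p1", "p2", "p3", "px"), map, stat)
  expect_equal(out$probe[out$symbol == "A"], "p2")
  expect_equal(attr(out, "unmapped"), "px")
  expect_equal(nrow(out), 2L)
})
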