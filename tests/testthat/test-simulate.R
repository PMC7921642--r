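# Synthetic-data generators: dimensions, determinism, planted structure
# and null behavior.

test_that("expression simulator obeys its dimension and labeling contract", {
  cfg <- stageSimConfig(n_genes = 1000L, samples_per_stage = rep(15L, 8L),
                        seed = 3L)
  se <- simulateStageExpression(cfg)
  expect_equal(dim(se), c(1000L, 120L))
  expect_equal(as.vector(table(SummarizedExperiment::colData(se)$stage)),
               rep(15L, 8L))
  expect_length(groundTruth(se)$signature_genes, 15L)
  expect_equal(sum(SummarizedExperiment::rowData(se)$planted), 15L)
  expect_setequal(
    rownames(se)[SummarizedExperiment::rowData(se)$planted],
    groundTruth(se)$signature_genes)
  # control pooling: first two stages flagged (15 samples each here)
  cd <- SummarizedExperiment::colData(se)
  expect_equal(sum(cd$is_control), 30L)
  # the default design carries the historical per-stage counts
  expect_equal(sum(stageSimConfig()$samples_per_stage), 107L)
})

test_that("planted genes follow the configured stage-mean profile", {
  cfg <- stageSimConfig(n_genes = 200L, n_signature = 5L,
                        samples_per_stage = rep(50L, 8L),
                        effect_size = 2, noise_sd = 0.5, seed = 11L)
  se <- simulateStageExpression(cfg)
  m <- SummarizedExperiment::assay(se)
  stage_idx <- as.integer(SummarizedExperiment::colData(se)$stage) - 1L
  planted <- groundTruth(se)$signature_genes
  for (j in c(0L, 3L, 7L)) {
    mu_hat <- rowMeans(m[planted, stage_idx == j, drop = FALSE])
    expect_equal(unname(mu_hat), rep(8 + 2 * j, 5L), tolerance = 0.2)
  }
  # non-planted genes are stage-independent
  other <- setdiff(rownames(se), planted)[1:5]
  expect_equal(unname(rowMeans(m[other, stage_idx == 7, drop = FALSE])),
               rep(8, 5L), tolerance = 0.2)
  # step profile switches on at step_stage
  se2 <- simulateStageExpression(
    stageSimConfig(n_genes = 200L, n_signature = 5L,
                   samples_per_stage = rep(50L, 8L), effect_size = 2,
                   effect_profile = "step", step_stage = 5L,
                   noise_sd = 0.5, seed = 11L))
  m2 <- SummarizedExperiment::assay(se2)
  p2 <- groundTruth(se2)$signature_genes
  expect_equal(mean(m2[p2, stage_idx == 2]), 8, tolerance = 0.1)
  expect_equal(mean(m2[p2, stage_idx == 6]), 10, tolerance = 0.1)
})

test_that("identical config and seed reproduce identical outputs", {
  cfg <- stageSimConfig(n_genes = 300L, seed = 42L)
  expect_identical(SummarizedExperiment::assay(simulateStageExpression(cfg)),
                   SummarizedExperiment::assay(simulateStageExpression(cfg)))
  ncfg <- networkSimConfig(n_nodes = 150L, seed = 42L)
  g1 <- simulateInteractome(ncfg)
  g2 <- simulateInteractome(ncfg)
  expect_identical(igraph::as_edgelist(g1$network),
                   igraph::as_edgelist(g2$network))
  expect_identical(g1$ground_truth, g2$ground_truth)
})

test_that("configuration errors name the violated field", {
  expect_error(stageSimConfig(n_signature = 50L, n_genes = 10L),
               "n_signature")
  expect_error(stageSimConfig(noise_sd = 0), "noise_sd")
  expect_error(stageSimConfig(samples_per_stage = rep(15L, 3L)),
               "samples_per_stage")
  expect_error(networkSimConfig(n_hubs = 1L, n_gatekeepers = 2L), "n_hubs")
  expect_error(networkSimConfig(n_nodes = 5L, n_hubs = 4L,
                                n_gatekeepers = 3L), "n_nodes")
})

test_that("network simulator honors its planted-structure contract", {
  sim <- simulateInteractome(networkSimConfig(n_nodes = 100L, n_hubs = 5L,
                                              hub_degree = 20L,
                                              n_gatekeepers = 3L,
                                              seed = 9L))
  g <- sim$network
  expect_true(igraph::is_simple(g))
  expect_false(igraph::is_directed(g))
  truth <- sim$ground_truth
  # every planted hub reaches the guaranteed minimum degree
  expect_true(all(igraph::degree(g, truth$hub_nodes) >= 20L))
  # planted gatekeepers: few neighbors, all of them hubs, C exactly 1
  cc <- clusteringCentrality(g)
  gk <- cc[cc$node %in% truth$gatekeeper_nodes, ]
  expect_true(all(gk$C == 1))
  expect_true(all(gk$k >= 2L))
  for (v in truth$gatekeeper_nodes) {
    expect_true(all(igraph::neighbors(g, v)$name %in% truth$hub_nodes))
  }
  # no gatekeepers requested -> none planted
  sim0 <- simulateInteractome(networkSimConfig(n_nodes = 100L,
                                               n_gatekeepers = 0L))
  expect_length(sim0$ground_truth$gatekeeper_nodes, 0L)
})

test_that("null world: no effect means uniform p-values and no planted calls", {
  cfg <- stageSimConfig(n_genes = 6000L, n_signature = 50L,
                        effect_size = 0, seed = 5L)
  se <- simulateStageExpression(cfg)
  tab <- fitContrast(se, "squamous.cell.carcinoma")
  nonplanted <- !(tab$gene %in% groundTruth(se)$signature_genes)
  ks <- stats::ks.test(tab$p[nonplanted], "punif")
  expect_gt(ks$p.value, 0.001)
  merged <- filterAndMerge(fitAllContrasts(se))
  hits <- sum(merged$gene %in% groundTruth(se)$signature_genes)
  # planted genes carry no signal: flagged at most at the nominal rate
  expect_lte(hits, qbinom(0.99, 50L, 0.05))
})

test_that("plain-text writers round-trip through their readers", {
  se <- simulateStageExpression(stageSimConfig(n_genes = 50L, seed = 2L))
  tmp <- withr::local_tempdir()
  writeExpressionTSV(se, file.path(tmp, "e.tsv"))
  writeDesignTSV(se, file.path(tmp, "d.tsv"))
  m <- readExpressionTSV(file.path(tmp, "e.tsv"))
  expect_equal(m, SummarizedExperiment::assay(se), tolerance = 1e-12)
  se2 <- readDesignTSV(file.path(tmp, "d.tsv"),
                       stage_order = defaultStageLabels(),
                       control_stages = defaultStageLabels()[1:2],
                       expr = m)
  expect_equal(as.character(SummarizedExperiment::colData(se2)$stage),
               as.character(SummarizedExperiment::colData(se)$stage))
  sim <- simulateInteractome(networkSimConfig(n_nodes = 60L, seed = 2L))
  writeEdgeListTSV(sim$network, file.path(tmp, "n.tsv"))
  back <- cleanNetwork(file.path(tmp, "n.tsv"))
  expect_equal(back$report$n_duplicates, 0L)
  expect_equal(igraph::ecount(back$network), igraph::ecount(sim$network))
})
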