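# Pipeline driver binding the modules together: simulate (optional) ->
# differential expression -> network/gatekeepers -> two-round signature
# reduction -> evaluation -> random-signature null -> enrichment
# (optional), with every intermediate written to the output directory
# and a JSON manifest of parameters and file hashes.

#' Pipeline configuration
#'
#' All of the thresholds of the analysis are exposed here so each one can
#' be varied for sensitivity analysis. Defaults follow the study design
#' the package emulates: filter at adjusted p < 0.05 and |signed fold
#' change| > 1.5, gatekeepers at clustering centrality 1 with degree
#' >= 2, signature selection beyond 0.78 standardized-coefficient units
#' over two rounds, and a 500-set random-signature null.
#'
#' @param outdir Output directory (created if absent).
#' @param expression,design,edge_list,gmt,annotation Input file paths
#'   (TSV / GMT); `expression`, `design` and `edge_list` may be omitted
#'   when `simulate = TRUE`.
#' @param simulate Generate synthetic inputs instead of reading files.
#' @param sim_expression A [stageSimConfig()] (used when simulating).
#' @param sim_network A [networkSimConfig()] (used when simulating; node
#'   ids are drawn from the simulated gene ids so the expression and
#'   interactome share a namespace).
#' @param p_thresh,fc_thresh Differential-expression filter thresholds.
#' @param use_adjusted Filter on BH-adjusted p-values (default) or raw.
#' @param moderated Use variance-moderated t statistics (default).
#' @param z_threshold Standardized-coefficient selection threshold.
#' @param fdr_thresh Enrichment significance threshold.
#' @param min_degree Minimum degree for a gatekeeper call.
#' @param expand_network Induce the subnetwork on the merged gene list
#'   only (default) or expand it by the genes' first interactome
#'   neighbors.
#' @param l2_strength Ridge penalty of the stage classifier.
#' @param n_null_sets Random sets in the null (default 500).
#' @param signature_k Cap on the size of the final reported signature:
#'   when the two-round threshold rule keeps more genes, the top
#'   `signature_k` by standardized-coefficient magnitude are reported
#'   and carried into the evaluation and the null.
#' @param seed Root seed; per-stage seeds are derived from it
#'   deterministically.
#' @return A validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outdir,
                           expression = NULL, design = NULL,
                           edge_list = NULL, gmt = NULL,
                           annotation = NULL,
                           simulate = is.null(expression),
                           sim_expression = stageSimConfig(),
                           sim_network = networkSimConfig(),
                           p_thresh = 0.05, fc_thresh = 1.5,
                           use_adjusted = TRUE, moderated = TRUE,
                           z_threshold = 0.78, fdr_thresh = 0.05,
                           min_degree = 2L, expand_network = FALSE,
                           l2_strength = 1,
                           n_null_sets = 500L, signature_k = 15L,
                           seed = 1L) {
  check_prob(p_thresh, "p_thresh")
  check_prob(fdr_thresh, "fdr_thresh")
  if (fc_thresh < 1) stop_config("fc_thresh", "must be >= 1")
  if (l2_strength < 0) stop_config("l2_strength", "must be >= 0")
  check_count(min_degree, "min_degree")
  check_count(n_null_sets, "n_null_sets")
  check_count(signature_k, "signature_k")
  check_count(seed, "seed", min = 0L)
  if (!simulate) {
    for (f in c(expression, design, edge_list)) {
      if (is.null(f) || !file.exists(f)) {
        stop_config("inputs", paste0("file not found: ",
                                     if (is.null(f)) "<missing>" else f))
      }
    }
  }
  for (f in c(gmt, annotation)) {
    if (!is.null(f) && !file.exists(f)) {
      stop_config("inputs", paste0("file not found: ", f))
    }
  }
  structure(list(outdir = outdir, expression = expression,
                 design = design, edge_list = edge_list, gmt = gmt,
                 annotation = annotation, simulate = simulate,
                 sim_expression = sim_expression,
                 sim_network = sim_network,
                 p_thresh = p_thresh, fc_thresh = fc_thresh,
                 use_adjusted = use_adjusted, moderated = moderated,
                 z_threshold = z_threshold, fdr_thresh = fdr_thresh,
                 min_degree = as.integer(min_degree),
                 expand_network = isTRUE(expand_network),
                 l2_strength = l2_strength,
                 n_null_sets = as.integer(n_null_sets),
                 signature_k = as.integer(signature_k),
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a probe-to-symbol annotation map
#'
#' Two-column TSV (probe, symbol). Many probes may map to one symbol;
#' exact duplicate rows are deduplicated silently; probes with an empty
#' symbol are dropped and counted; a probe mapping to two different
#' symbols is an error.
#'
#' @param path Annotation TSV path.
#' @return Named character vector probe -> symbol, with attribute
#'   `n_empty` (probes dropped for empty symbols).
#' @export
readAnnotation <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("annotation file must have rows and two columns", call. = FALSE)
  }
  probe <- df[[1L]]; symbol <- df[[2L]]
  empty <- is.na(symbol) | !nzchar(symbol)
  n_empty <- sum(empty)
  probe <- probe[!empty]; symbol <- symbol[!empty]
  dup <- duplicated(paste(probe, symbol, sep = "\r"))
  probe <- probe[!dup]; symbol <- symbol[!dup]
  conflict <- unique(probe[duplicated(probe)])
  if (length(conflict)) {
    stop("probes mapped to conflicting symbols: ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }
  map <- stats::setNames(symbol, probe)
  attr(map, "n_empty") <- n_empty
  map
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the whole stage-signature discovery pipeline
#'
#' Executes (optional simulation ->) per-stage differential expression,
#' filtering and merging, probe-to-symbol collapse, interactome cleaning
#' and induction, clustering centrality and gatekeeper detection,
#' two-round classifier reduction, evaluation of the reduced signature,
#' the random-signature null, and (when a GMT is supplied) Fisher
#' enrichment of the gatekeeper list. Every intermediate artifact is
#' written as TSV under `config$outdir` together with `manifest.json`
#' recording the package version, parameters, seed and an MD5 hash of
#' every output; rerunning with an identical config reproduces identical
#' hashes.
#'
#' @param config A [pipelineConfig()].
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  say <- function(...) if (!quiet) message("[stageSigNet] ", ...)
  files <- character(0)

  # -- inputs -------------------------------------------------------------
  if (config$simulate) {
    say("simulating expression and interactome")
    sim_cfg <- config$sim_expression
    sim_cfg$seed <- split_seed(config$seed, 1L)
    se <- simulateStageExpression(sim_cfg)
    net_cfg <- config$sim_network
    net_cfg$seed <- split_seed(config$seed, 2L)
    net_cfg$n_nodes <- min(net_cfg$n_nodes, nrow(se))
    planted <- groundTruth(se)$signature_genes
    n_roles <- net_cfg$n_gatekeepers + net_cfg$n_hubs
    if (length(planted) < n_roles) {
      stop("simulated network roles need n_signature >= n_gatekeepers + ",
           "n_hubs", call. = FALSE)
    }
    # Network roles live on planted (differentially expressed) genes so
    # the induced DGE subnetwork downstream actually contains them.
    node_ids <- with_seed(split_seed(config$seed, 5L), {
      pool <- setdiff(rownames(se), planted)
      sort(c(planted,
             sample(pool, max(net_cfg$n_nodes - length(planted), 0L))))
    })
    net_cfg$n_nodes <- length(node_ids)
    roleset <- with_seed(split_seed(config$seed, 6L), sample(planted))
    sim_net <- simulateInteractome(
      net_cfg, node_ids = node_ids,
      gatekeepers = roleset[seq_len(net_cfg$n_gatekeepers)],
      hubs = roleset[net_cfg$n_gatekeepers + seq_len(net_cfg$n_hubs)])
    interactome <- sim_net$network
    truth <- list(
      signature_genes = groundTruth(se)$signature_genes,
      gatekeeper_nodes = sim_net$ground_truth$gatekeeper_nodes,
      hub_nodes = sim_net$ground_truth$hub_nodes)
    files["expression"] <- writeExpressionTSV(se, out("expression.tsv"))
    files["design"] <- writeDesignTSV(se, out("design.tsv"))
    files["edge_list"] <- writeEdgeListTSV(interactome,
                                           out("edge_list.tsv"))
    files["ground_truth"] <- writeGroundTruthJSON(truth,
                                                  out("ground_truth.json"))
    clean_report <- list(simulated = TRUE)
    map <- NULL
  } else {
    say("reading inputs")
    expr <- readExpressionTSV(config$expression)
    hdr <- read.table(config$design, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    stage_order <- unique(hdr$stage)
    se <- readDesignTSV(config$design, stage_order = stage_order,
                        control_stages = stage_order[1:2], expr = expr)
    cleaned <- cleanNetwork(config$edge_list)
    interactome <- cleaned$network
    clean_report <- cleaned$report
    truth <- NULL
    map <- if (!is.null(config$annotation)) {
      readAnnotation(config$annotation)
    }
  }
  m <- SummarizedExperiment::assay(se, "exprs")

  # -- differential expression -------------------------------------------
  say("fitting stage-versus-control contrasts")
  tabs <- fitAllContrasts(se, moderated = config$moderated)
  for (nm in names(tabs)) {
    files[paste0("dge_", nm)] <-
      write_tsv(tabs[[nm]], out(sprintf("dge_%s.tsv", nm)))
  }
  merged <- filterAndMerge(tabs, config$p_thresh, config$fc_thresh,
                           config$use_adjusted)
  files["merged"] <- write_tsv(merged, out("dge_merged.tsv"))
  say(nrow(merged), " genes pass the filter in >= 1 contrast")

  # -- symbol collapse at the network boundary ----------------------------
  max_t <- apply(do.call(cbind, lapply(tabs, function(tt) abs(tt$t))),
                 1L, max)
  names(max_t) <- tabs[[1L]]$gene
  if (!is.null(map)) {
    collapsed <- collapseToSymbols(merged$gene, map, stat = max_t)
    gene_symbols <- collapsed$symbol
  } else {
    gene_symbols <- merged$gene
  }

  # -- network ------------------------------------------------------------
  say("inducing subnetwork and scoring clustering centrality")
  induced <- induceSubnetwork(interactome, gene_symbols,
                              expand = config$expand_network)
  cc <- clusteringCentrality(induced$network)
  gatekeepers <- findGatekeepers(cc, min_degree = config$min_degree)
  comp <- largestComponent(induced$network)
  closure <- if (length(gatekeepers)) {
    neighborEdgeClosure(induced$network, gatekeepers, order = 2L)
  } else {
    list(edges = data.frame(node_a = character(0),
                            node_b = character(0)), coverage = 0)
  }
  files["centrality"] <- writeCentralityTSV(cc, out("centrality.tsv"))
  files["gatekeepers"] <- write_tsv(
    data.frame(gatekeeper = gatekeepers), out("gatekeepers.tsv"))
  files["component"] <- write_tsv(
    data.frame(node = sort(igraph::V(comp)$name)),
    out("big_component.tsv"))
  files["closure"] <- write_tsv(closure$edges, out("edge_closure.tsv"))
  say(length(gatekeepers), " gatekeepers; big component has ",
      igraph::vcount(comp), " nodes")

  # -- signature ----------------------------------------------------------
  say("two-round signature reduction")
  X <- t(m)
  y <- SummarizedExperiment::colData(se)$stage
  sig <- twoRoundReduction(X, y, threshold = config$z_threshold,
                           l2 = config$l2_strength,
                           seed = split_seed(config$seed, 3L))
  s2 <- signatureGenes(sig, 2L)
  if (length(s2) == 0L) s2 <- signatureGenes(sig, 1L)
  # The threshold rule only prunes hard when the coefficient pool is
  # heavy-tailed; cap the reported signature at signature_k genes by
  # standardized-coefficient magnitude so downstream steps always see a
  # compact signature.
  files["signature_round2"] <- write_tsv(
    data.frame(gene = s2), out("signature_round2.tsv"))
  if (length(s2) > config$signature_k) {
    mz2 <- apply(abs(sig@zscores$round2), 2L, max)[s2]
    s2 <- sort(names(sort(mz2, decreasing = TRUE))[
      seq_len(config$signature_k)])
  }
  Xz <- standardizeFeatures(X)
  final_fit <- trainClassifier(Xz[, s2, drop = FALSE], y,
                               l2 = config$l2_strength)
  report <- evaluateClassifier(y, predict(final_fit,
                                          Xz[, s2, drop = FALSE]))
  files["signature_round1"] <- write_tsv(
    data.frame(gene = signatureGenes(sig, 1L)), out("signature_round1.tsv"))
  files["signature"] <- write_tsv(
    data.frame(gene = s2), out("signature.tsv"))
  zz <- sig@zscores$round1
  files["zscores"] <- write_tsv(
    data.frame(gene = colnames(zz),
               max_abs_z = apply(abs(zz), 2L, max)),
    out("zscores_round1.tsv"))
  conf <- as.data.frame.matrix(confusionMatrix(report))
  files["confusion"] <- write_tsv(
    cbind(data.frame(true = rownames(conf)), conf), out("confusion.tsv"))
  say(sprintf("signature of %d genes; accuracy %.3f, macro Jaccard %.3f",
              length(s2), accuracy(report), macroJaccard(report)))

  # -- random-signature null ---------------------------------------------
  say("random-signature null (", config$n_null_sets, " sets)")
  null <- randomSignatureNull(X, y, signature = s2,
                              k = max(length(s2), 1L),
                              nSets = config$n_null_sets,
                              l2 = config$l2_strength,
                              seed = split_seed(config$seed, 4L))
  files["null"] <- write_tsv(
    data.frame(jaccard = nullValues(null)), out("null_jaccard.tsv"))

  # -- enrichment ---------------------------------------------------------
  enrich_summary <- NULL
  if (!is.null(config$gmt) && length(gatekeepers) > 0L) {
    say("Fisher enrichment of the gatekeeper list")
    collection <- readGMT(config$gmt)
    enr <- fisherEnrichment(gatekeepers, collection,
                            fdr_thresh = config$fdr_thresh)
    files["enrichment"] <- write_tsv(enr, out("enrichment.tsv"))
    enrich_summary <- list(n_sets = nrow(enr),
                           n_significant = sum(enr$significant))
  }

  # -- manifest -----------------------------------------------------------
  params <- config[c("p_thresh", "fc_thresh", "use_adjusted", "moderated",
                     "z_threshold", "fdr_thresh", "min_degree",
                     "expand_network", "l2_strength", "n_null_sets",
                     "signature_k", "seed")]
  manifest <- list(
    package = "stageSigNet",
    version = as.character(packageVersion("stageSigNet")),
    parameters = params,
    network_cleaning = clean_report,
    n_merged_genes = nrow(merged),
    gatekeepers = gatekeepers,
    signature = s2,
    scores = list(accuracy = accuracy(report),
                  macro_jaccard = macroJaccard(report),
                  null_max = max(nullValues(null)),
                  null_mean = mean(nullValues(null)),
                  empirical_p = empiricalP(null)),
    enrichment = enrich_summary,
    outputs = lapply(files[order(names(files))], function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("wrote ", out("manifest.json"))
  invisible(manifest)
}
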