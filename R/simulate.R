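# Synthetic-data module: seeded expression matrices with planted stage
# signatures and interactomes with planted hubs/gatekeepers.
#
# Expression is generated on a log2-like additive scale, so a fold-change
# filter downstream is a difference of group means; no attempt is made to
# emulate probe-level array artifacts.

#' Default ordered stage labels of the eight-stage carcinogenesis series
#'
#' Two normal groups (normo- and hypo-fluorescent, pooled as the control),
#' then metaplasia, three grades of dysplasia, carcinoma in situ and
#' invasive squamous-cell carcinoma.
#'
#' @return Character vector of length 8, ordered from normal to carcinoma.
#' @export
defaultStageLabels <- function() {
  c("normal.normofluorescent", "normal.hypofluorescent", "metaplasia",
    "mild.dysplasia", "moderate.dysplasia", "severe.dysplasia",
    "carcinoma.in.situ", "squamous.cell.carcinoma")
}

#' Configuration for the synthetic stage-expression generator
#'
#' The defaults mirror the bronchial-biopsy series the package emulates:
#' eight ordered histological stages with per-stage sample counts
#' (13, 14, 15, 13, 13, 12, 13, 14), the first two stages pooled as the
#' control group, and log2-scale intensities around a baseline of 8.
#'
#' @param n_genes Number of genes (rows) to simulate.
#' @param n_signature Number of planted stage-discriminative genes.
#' @param stage_labels Ordered character vector of 8 stage labels.
#' @param samples_per_stage Integer vector of per-stage sample counts
#'   (same length as `stage_labels`).
#' @param n_control_stages How many leading stages are pooled as control.
#' @param effect_size Additive per-stage shift (log2 units) for planted
#'   genes; with `effect_profile = "linear"` the mean of a planted gene at
#'   stage index j (0-based) is `baseline_mean + j * effect_size`.
#' @param effect_profile `"linear"` (monotone ramp across the ordered
#'   stages, the default) or `"step"` (shift applied from `step_stage` on).
#' @param step_stage 1-based stage index at which the `"step"` profile
#'   turns on.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise.
#' @param baseline_mean Baseline log2 expression.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated list of class `stageSimConfig`.
#' @export
stageSimConfig <- function(n_genes = 2000L,
                           n_signature = 15L,
                           stage_labels = defaultStageLabels(),
                           samples_per_stage = c(13L, 14L, 15L, 13L, 13L,
                                                 12L, 13L, 14L),
                           n_control_stages = 2L,
                           effect_size = 1,
                           effect_profile = c("linear", "step"),
                           step_stage = 5L,
                           noise_sd = 1,
                           baseline_mean = 8,
                           seed = 1L) {
  effect_profile <- match.arg(effect_profile)
  check_count(n_genes, "n_genes")
  check_count(n_signature, "n_signature", min = 0L)
  if (n_signature > n_genes) {
    stop_config("n_signature", "must not exceed n_genes")
  }
  if (!is.character(stage_labels) || anyDuplicated(stage_labels)) {
    stop_config("stage_labels", "must be unique labels")
  }
  if (length(samples_per_stage) != length(stage_labels)) {
    stop_config("samples_per_stage", "must match stage_labels in length")
  }
  for (k in samples_per_stage) check_count(k, "samples_per_stage")
  check_count(n_control_stages, "n_control_stages")
  if (n_control_stages >= length(stage_labels)) {
    stop_config("n_control_stages", "must leave at least one test stage")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop_config("noise_sd", "must be a positive number")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      !is.finite(effect_size)) {
    stop_config("effect_size", "must be a finite number")
  }
  check_count(step_stage, "step_stage")
  check_count(seed, "seed", min = 0L)
  structure(list(n_genes = as.integer(n_genes),
                 n_signature = as.integer(n_signature),
                 stage_labels = stage_labels,
                 samples_per_stage = as.integer(samples_per_stage),
                 n_control_stages = as.integer(n_control_stages),
                 effect_size = as.numeric(effect_size),
                 effect_profile = effect_profile,
                 step_stage = as.integer(step_stage),
                 noise_sd = as.numeric(noise_sd),
                 baseline_mean = as.numeric(baseline_mean),
                 seed = as.integer(seed)),
            class = "stageSimConfig")
}

#' Simulate a stage-structured expression experiment
#'
#' Generates a genes-by-samples log2 expression matrix with
#' `config$n_signature` planted stage-discriminative genes. Planted genes
#' follow an additive stage effect (linear ramp or step, see
#' [stageSimConfig()]); all other genes have a stage-independent mean.
#' Noise is i.i.d. Gaussian.
#'
#' @param config A [stageSimConfig()] object.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"exprs"`, `colData` columns `stage` (ordered factor) and
#'   `is_control`, `rowData` column `planted`, and
#'   `metadata(x)$ground_truth$signature_genes` holding the planted gene
#'   ids.
#' @seealso [stageDesign()], [simulateInteractome()]
#' @export
simulateStageExpression <- function(config = stageSimConfig()) {
  if (!inherits(config, "stageSimConfig")) {
    config <- do.call(stageSimConfig, config)
  }
  n_stage <- length(config$stage_labels)
  n_samp <- sum(config$samples_per_stage)
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  stage <- factor(rep(config$stage_labels, config$samples_per_stage),
                  levels = config$stage_labels)

  with_seed(config$seed, {
    planted <- sort(sample.int(config$n_genes, config$n_signature))
    mu <- matrix(config$baseline_mean, nrow = config$n_genes, ncol = n_samp)
    stage_index <- as.integer(stage) - 1L    # 0-based index along the series
    shift <- switch(config$effect_profile,
      linear = stage_index * config$effect_size,
      step   = ifelse(stage_index >= (config$step_stage - 1L),
                      config$effect_size, 0))
    if (length(planted) > 0L) {
      mu[planted, ] <- mu[planted, , drop = FALSE] +
        matrix(shift, nrow = length(planted), ncol = n_samp, byrow = TRUE)
    }
    values <- mu + matrix(rnorm(config$n_genes * n_samp, 0, config$noise_sd),
                          nrow = config$n_genes)
  })

  dimnames(values) <- list(gene_ids, sample_ids)
  is_planted <- seq_len(config$n_genes) %in% planted
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    rowData = S4Vectors::DataFrame(planted = is_planted,
                                   row.names = gene_ids),
    colData = S4Vectors::DataFrame(
      stage = stage,
      is_control = as.integer(stage) <= config$n_control_stages,
      row.names = sample_ids))
  S4Vectors::metadata(se)$stage_order <- config$stage_labels
  S4Vectors::metadata(se)$control_stages <-
    config$stage_labels[seq_len(config$n_control_stages)]
  S4Vectors::metadata(se)$ground_truth <-
    list(signature_genes = gene_ids[is_planted],
         gatekeeper_nodes = character(0),
         hub_nodes = character(0))
  S4Vectors::metadata(se)$sim_config <- config
  se
}

#' Extract the stage design of an expression experiment
#'
#' @param se A `SummarizedExperiment` produced by
#'   [simulateStageExpression()] or [readExpressionTSV()] +
#'   [readDesignTSV()].
#' @return A list with `assignment` (named character, sample -> stage),
#'   `stage_order` and `control_stages`.
#' @export
stageDesign <- function(se) {
  stage <- as.character(SummarizedExperiment::colData(se)$stage)
  names(stage) <- colnames(se)
  list(assignment = stage,
       stage_order = S4Vectors::metadata(se)$stage_order,
       control_stages = S4Vectors::metadata(se)$control_stages)
}

#' Planted ground truth of a simulated object
#'
#' @param x A simulated `SummarizedExperiment` or the list returned by
#'   [simulateInteractome()].
#' @return List with `signature_genes`, `gatekeeper_nodes`, `hub_nodes`.
#' @export
groundTruth <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    return(S4Vectors::metadata(x)$ground_truth)
  }
  if (is.list(x) && !is.null(x$ground_truth)) return(x$ground_truth)
  if (inherits(x, "igraph")) {
    return(igraph::graph_attr(x, "ground_truth"))
  }
  stop("no ground truth attached to this object", call. = FALSE)
}

#' Configuration for the synthetic interactome generator
#'
#' The generated graph has a heavy-tailed (preferential-attachment)
#' background, a set of planted mutually-connected hubs, and a set of
#' planted gatekeepers: low-degree nodes attached only to 2-3 of the hubs,
#' so that their clustering centrality is exactly 1.
#'
#' @param n_nodes Total number of nodes.
#' @param n_hubs Number of planted hubs (>= 2 when gatekeepers are
#'   requested, because a gatekeeper must bridge at least two
#'   interconnected hubs).
#' @param hub_degree Minimum degree guaranteed for every planted hub.
#' @param n_gatekeepers Number of planted gatekeepers.
#' @param attachment Background edge rule; `"preferential"` (scale-free,
#'   default) or `"uniform"` (Erdos-Renyi with the same edge budget).
#' @param edges_per_node Edges added per background node.
#' @param seed Integer seed.
#' @return A validated list of class `networkSimConfig`.
#' @export
networkSimConfig <- function(n_nodes = 500L,
                             n_hubs = 5L,
                             hub_degree = 20L,
                             n_gatekeepers = 3L,
                             attachment = c("preferential", "uniform"),
                             edges_per_node = 2L,
                             seed = 1L) {
  attachment <- match.arg(attachment)
  check_count(n_nodes, "n_nodes")
  check_count(n_hubs, "n_hubs", min = 0L)
  check_count(n_gatekeepers, "n_gatekeepers", min = 0L)
  check_count(hub_degree, "hub_degree")
  check_count(edges_per_node, "edges_per_node")
  check_count(seed, "seed", min = 0L)
  if (n_gatekeepers >= 1L && n_hubs < 2L) {
    stop_config("n_hubs", "must be >= 2 when gatekeepers are requested")
  }
  if (n_gatekeepers + n_hubs > n_nodes) {
    stop_config("n_nodes", "must be >= n_hubs + n_gatekeepers")
  }
  if (n_nodes - n_gatekeepers < max(hub_degree + 1L, 10L)) {
    stop_config("n_nodes", "leaves too few background nodes for hub_degree")
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 n_hubs = as.integer(n_hubs),
                 hub_degree = as.integer(hub_degree),
                 n_gatekeepers = as.integer(n_gatekeepers),
                 attachment = attachment,
                 edges_per_node = as.integer(edges_per_node),
                 seed = as.integer(seed)),
            class = "networkSimConfig")
}

#' Simulate an interactome with planted hubs and gatekeepers
#'
#' Planted gatekeepers are connected to exactly 2-3 planted hubs that are
#' pairwise connected (so the gatekeeper's clustering centrality is 1 by
#' construction); planted hubs additionally receive background edges until
#' their degree reaches `hub_degree`. After generation the graph is
#' checked and repaired so that *only* the planted gatekeepers have
#' clustering centrality 1 at degree >= 2: any spurious such node gains
#' one extra edge to a node sharing none of its neighbors, which lowers
#' its centrality below 1 without touching any planted gatekeeper's
#' neighborhood.
#'
#' @param config A [networkSimConfig()] object.
#' @param node_ids Optional character vector of node names (length
#'   `n_nodes`); defaults to `N0001`, `N0002`, ...
#' @param gatekeepers,hubs Optional explicit role assignment (disjoint
#'   subsets of `node_ids` of sizes `n_gatekeepers` and `n_hubs`); by
#'   default roles are placed at random. Assigning roles to known
#'   differentially expressed genes couples the simulated interactome to
#'   a simulated expression experiment.
#' @return A list with `network` (a simple undirected `igraph`) and
#'   `ground_truth` (list with `gatekeeper_nodes`, `hub_nodes`,
#'   `signature_genes = character(0)`); the ground truth is also attached
#'   as a graph attribute.
#' @export
simulateInteractome <- function(config = networkSimConfig(),
                                node_ids = NULL, gatekeepers = NULL,
                                hubs = NULL) {
  if (!inherits(config, "networkSimConfig")) {
    config <- do.call(networkSimConfig, config)
  }
  if (is.null(node_ids)) {
    node_ids <- sprintf("N%05d", seq_len(config$n_nodes))
  }
  if (length(node_ids) != config$n_nodes || anyDuplicated(node_ids)) {
    stop_config("node_ids", "must be n_nodes unique names")
  }
  if (!is.null(gatekeepers) || !is.null(hubs)) {
    if (length(gatekeepers) != config$n_gatekeepers ||
        length(hubs) != config$n_hubs ||
        !all(c(gatekeepers, hubs) %in% node_ids) ||
        length(intersect(gatekeepers, hubs)) > 0L) {
      stop_config("gatekeepers/hubs",
                  "must be disjoint node_ids subsets of the configured sizes")
    }
  }

  with_seed(config$seed, {
    if (is.null(gatekeepers)) {
      roles <- sample(node_ids)   # random placement of planted roles
      gatekeepers <- sort(roles[seq_len(config$n_gatekeepers)])
      hubs <- sort(roles[config$n_gatekeepers + seq_len(config$n_hubs)])
    } else {
      gatekeepers <- sort(gatekeepers)
      hubs <- sort(hubs)
    }
    background <- setdiff(node_ids, gatekeepers)

    # Heavy-tailed background over everything except the gatekeepers.
    n_bg <- length(background)
    bg <- if (config$attachment == "preferential") {
      igraph::sample_pa(n_bg, power = 1, m = config$edges_per_node,
                        directed = FALSE)
    } else {
      igraph::sample_gnm(n_bg, m = config$edges_per_node * n_bg)
    }
    igraph::V(bg)$name <- sample(background)
    g <- igraph::simplify(bg)

    # Hub clique, then top hubs up to the guaranteed minimum degree.
    if (config$n_hubs >= 2L) {
      hub_pairs <- t(utils::combn(hubs, 2L))
      g <- igraph::add_edges(g, as.vector(t(hub_pairs)))
    }
    g <- igraph::simplify(g)
    for (h in hubs) {
      deg <- igraph::degree(g, h)
      if (deg < config$hub_degree) {
        nbrs <- igraph::neighbors(g, h)$name
        pool <- setdiff(background, c(h, nbrs))
        extra <- sample(pool, config$hub_degree - deg)
        g <- igraph::add_edges(g, as.vector(rbind(h, extra)))
      }
    }

    # Each gatekeeper bridges 2-3 pairwise-connected hubs and nothing else.
    for (gk in gatekeepers) {
      g <- igraph::add_vertices(g, 1L, name = gk)
      m_gk <- if (config$n_hubs >= 3L) sample(2:3, 1L) else 2L
      to <- sample(hubs, m_gk)
      g <- igraph::add_edges(g, as.vector(rbind(gk, to)))
    }
    g <- igraph::simplify(g)

    # Repair pass: break clustering centrality 1 for non-planted nodes.
    # Adding an edge between a spurious node s and a node v that shares no
    # neighbor with s (and is not a gatekeeper) lowers C(s) and C(v) below
    # 1 and changes no third node's neighborhood edge count.
    for (pass in seq_len(25L)) {
      cc <- clusteringCentrality(g)
      spurious <- setdiff(cc$node[cc$k >= 2L & cc$C == 1], gatekeepers)
      if (length(spurious) == 0L) break
      for (s in spurious) {
        nb_s <- igraph::neighbors(g, s)$name
        second <- unique(unlist(lapply(nb_s, function(u) {
          igraph::neighbors(g, u)$name
        })))
        cand <- setdiff(node_ids, c(s, nb_s, second, gatekeepers))
        if (length(cand) == 0L) {
          cand <- setdiff(node_ids, c(s, nb_s, gatekeepers))
        }
        g <- igraph::add_edges(g, c(s, sample(cand, 1L)))
      }
      g <- igraph::simplify(g)
    }
  })

  truth <- list(signature_genes = character(0),
                gatekeeper_nodes = gatekeepers,
                hub_nodes = hubs)
  g <- igraph::set_graph_attr(g, "ground_truth", truth)
  list(network = g, ground_truth = truth)
}

## ---- plain-text writers / readers -------------------------------------

#' Write / read an expression matrix as TSV
#'
#' The format is one header row of sample ids and a first column of gene
#' ids (column name `gene`).
#'
#' @param se A `SummarizedExperiment` with an `"exprs"` assay.
#' @param path Output/input file path.
#' @return `writeExpressionTSV()` returns `path` invisibly;
#'   `readExpressionTSV()` returns a numeric matrix with gene rownames.
#' @export
writeExpressionTSV <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "exprs")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene ids in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (anyNA(m)) stop("missing values in expression matrix ", path,
                     call. = FALSE)
  m
}

#' Write / read a stage design as two-column TSV (sample_id, stage)
#'
#' @param se A `SummarizedExperiment` carrying a `stage` column.
#' @param path File path.
#' @param stage_order,control_stages For `readDesignTSV()`: the ordered
#'   stage labels and the subset pooled as control.
#' @param expr For `readDesignTSV()`: optional expression matrix whose
#'   columns the design must cover.
#' @return `readDesignTSV()` returns a `SummarizedExperiment` when `expr`
#'   is supplied, otherwise a design list as from [stageDesign()].
#' @export
writeDesignTSV <- function(se, path) {
  df <- data.frame(sample_id = colnames(se),
                   stage = as.character(
                     SummarizedExperiment::colData(se)$stage))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignTSV
#' @export
readDesignTSV <- function(path, stage_order, control_stages, expr = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "stage") %in% names(df))) {
    stop("design file must have columns sample_id and stage", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  bad <- setdiff(unique(df$stage), stage_order)
  if (length(bad)) {
    stop("unknown stage labels in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(control_stages %in% stage_order)) {
    stop("control_stages must be a subset of stage_order", call. = FALSE)
  }
  if (is.null(expr)) {
    assignment <- df$stage
    names(assignment) <- df$sample_id
    return(list(assignment = assignment, stage_order = stage_order,
                control_stages = control_stages))
  }
  missing <- setdiff(colnames(expr), df$sample_id)
  if (length(missing)) {
    stop("samples missing from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[match(colnames(expr), df$sample_id), ]
  stage <- factor(df$stage, levels = stage_order)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr),
    colData = S4Vectors::DataFrame(
      stage = stage,
      is_control = df$stage %in% control_stages,
      row.names = colnames(expr)))
  S4Vectors::metadata(se)$stage_order <- stage_order
  S4Vectors::metadata(se)$control_stages <- control_stages
  se
}

#' Write a network as a two-column edge-list TSV
#'
#' @param net An `igraph` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeEdgeListTSV <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param truth A ground-truth list (see [groundTruth()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeGroundTruthJSON <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
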