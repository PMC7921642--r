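# Interactome handling: edge-list cleaning, subnetwork induction,
# clustering centrality (C_i = 2 E_i / (k_i (k_i - 1))), gatekeeper
# detection, neighborhood edge closures and connected components.

#' Clean a raw interaction edge list into a simple undirected graph
#'
#' Collapses duplicated interactions (including reversed pairs), removes
#' self-loops and, when a third taxon column is present, drops rows whose
#' taxon does not match `taxon`.
#'
#' @param edges A two-column `data.frame`/matrix of node pairs (an
#'   optional third column is read as a taxon id), or a path to a TSV
#'   file with those columns.
#' @param taxon Optional taxon identifier; rows with a non-matching third
#'   column are removed. Ignored when the input has two columns.
#' @param header Does a file input carry a header row?
#' @return A list with `network` (simple undirected `igraph`) and
#'   `report` (`n_input`, `n_self_loops`, `n_duplicates`,
#'   `n_cross_species`, `n_edges`, `n_nodes`).
#' @export
cleanNetwork <- function(edges, taxon = NULL, header = TRUE) {
  if (is.character(edges) && length(edges) == 1L) {
    lines <- readLines(edges)
    if (header && length(lines) > 0L) lines <- lines[-1L]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      stop("malformed edge-list row at line ",
           bad[1L] + if (header) 1L else 0L, call. = FALSE)
    }
    edges <- data.frame(a = vapply(parts, `[[`, "", 1L),
                        b = vapply(parts, `[[`, "", 2L),
                        stringsAsFactors = FALSE)
    if (all(lengths(parts) >= 3L)) {
      edges$taxon <- vapply(parts, `[[`, "", 3L)
    }
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    return(list(network = igraph::make_empty_graph(0, directed = FALSE),
                report = list(n_input = 0L, n_self_loops = 0L,
                              n_duplicates = 0L, n_cross_species = 0L,
                              n_edges = 0L, n_nodes = 0L)))
  }
  if (ncol(edges) < 2L) {
    stop("edge list needs at least two columns", call. = FALSE)
  }
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    stop("malformed edge-list row: empty node identifier at row ",
         which(!nzchar(a) | !nzchar(b) | is.na(a) | is.na(b))[1L],
         call. = FALSE)
  }
  n_input <- length(a)
  n_cross <- 0L
  if (!is.null(taxon) && ncol(edges) >= 3L) {
    keep <- as.character(edges[[3L]]) == as.character(taxon)
    n_cross <- sum(!keep)
    a <- a[keep]; b <- b[keep]
  }
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup]), directed = FALSE)
  list(network = g,
       report = list(n_input = n_input,
                     n_self_loops = n_self,
                     n_duplicates = n_dup,
                     n_cross_species = n_cross,
                     n_edges = igraph::ecount(g),
                     n_nodes = igraph::vcount(g)))
}

#' Induce the subnetwork on a gene list
#'
#' @param net An `igraph` network.
#' @param genes Character vector of node ids (e.g. a merged
#'   differential-expression list mapped to symbols).
#' @param expand Also include the first neighbors of the mapped genes
#'   (default `FALSE`: the subgraph is induced on the gene list only).
#' @return A list with `network` (induced subgraph on `genes` present in
#'   the interactome, plus their first neighbors when `expand`) and
#'   `unmapped` (genes absent from the interactome, reported rather than
#'   silently dropped).
#' @export
induceSubnetwork <- function(net, genes, expand = FALSE) {
  present <- intersect(genes, igraph::V(net)$name)
  keep <- present
  if (expand && length(present)) {
    nb <- unique(unlist(lapply(present, function(s) {
      igraph::neighbors(net, s)$name
    })))
    keep <- union(present, nb)
  }
  list(network = igraph::induced_subgraph(net, keep),
       unmapped = setdiff(genes, present))
}

#' Clustering centrality of every node
#'
#' For node i with degree k_i and E_i edges among its neighbors,
#' C_i = 2 E_i / (k_i (k_i - 1)). Nodes of degree < 2 have no defined
#' value (the denominator vanishes) and are assigned C = 0 by convention;
#' they are excluded from gatekeeper calls via `min_degree`.
#'
#' Neighbor-edge counts are obtained from the diagonal of A^3 (twice the
#' per-node triangle count) on the sparse adjacency matrix, and are exact
#' integers.
#'
#' @param net A simple undirected `igraph`.
#' @return `data.frame` with columns `node`, `k` (degree), `E`
#'   (neighbor-edge count) and `C` in \[0, 1\].
#' @export
clusteringCentrality <- function(net) {
  n <- igraph::vcount(net)
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (n == 0L) {
    return(data.frame(node = character(0), k = integer(0), E = integer(0),
                      C = numeric(0), stringsAsFactors = FALSE))
  }
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- methods::as(A, "generalMatrix")
  k <- as.integer(Matrix::rowSums(A))
  E <- as.integer(round(Matrix::diag(A %*% A %*% A) / 2))
  C <- ifelse(k >= 2L, 2 * E / (k * (k - 1)), 0)
  data.frame(node = nodes, k = k, E = E, C = C,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gatekeeper detection: nodes whose clustering centrality is exactly 1
#'
#' A gatekeeper has few neighbors that are all pairwise connected
#' (typically interconnected hubs). Equality is tested in integer
#' arithmetic, 2 E == k (k - 1), so no floating-point tolerance is
#' involved; degree < `min_degree` nodes are excluded.
#'
#' @param records Output of [clusteringCentrality()] (or an `igraph`, in
#'   which case centralities are computed first).
#' @param min_degree Minimum degree for a gatekeeper call (default 2: a
#'   gatekeeper must bridge at least two interconnected neighbors).
#' @return Sorted character vector of gatekeeper node ids.
#' @export
findGatekeepers <- function(records, min_degree = 2L) {
  if (inherits(records, "igraph")) records <- clusteringCentrality(records)
  stopifnot(all(c("node", "k", "E") %in% names(records)))
  keep <- records$k >= min_degree &
    (2L * records$E) == (records$k * (records$k - 1L))
  sort(records$node[keep])
}

#' Edges covered by a seed set and (optionally) its first neighbors
#'
#' Order 1 returns every edge incident to a seed node; order 2 returns
#' every edge incident to the seeds or their first neighbors — the "red
#' edges" view of how much of a network a small seed set reaches.
#'
#' @param net An `igraph` network.
#' @param seeds Character vector of seed node ids (must exist in `net`).
#' @param order 1 or 2.
#' @return List with `edges` (two-column `data.frame`) and `coverage`
#'   (fraction of all network edges returned).
#' @export
neighborEdgeClosure <- function(net, seeds, order = 1L) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  unknown <- setdiff(seeds, igraph::V(net)$name)
  if (length(unknown)) {
    stop("unknown seed nodes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  front <- seeds
  if (order == 2L && length(seeds)) {
    nb <- unique(unlist(lapply(seeds, function(s) {
      igraph::neighbors(net, s)$name
    })))
    front <- union(seeds, nb)
  }
  el <- igraph::as_edgelist(net)
  m <- nrow(el)
  if (length(front) == 0L || m == 0L) {
    return(list(edges = data.frame(node_a = character(0),
                                   node_b = character(0)),
                coverage = 0))
  }
  hit <- el[, 1L] %in% front | el[, 2L] %in% front
  list(edges = data.frame(node_a = el[hit, 1L], node_b = el[hit, 2L],
                          stringsAsFactors = FALSE),
       coverage = sum(hit) / m)
}

#' Largest connected component
#'
#' Ties between equally large components are broken towards the one
#' containing the lexicographically smallest node id, so the result is
#' deterministic.
#'
#' @param net An `igraph` network.
#' @return The induced subgraph on the largest component (an empty graph
#'   for an empty input).
#' @export
largestComponent <- function(net) {
  if (igraph::vcount(net) == 0L) return(net)
  comp <- igraph::components(net)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    anchor <- vapply(big, function(i) {
      min(igraph::V(net)$name[comp$membership == i])
    }, character(1))
    big <- big[order(anchor)[1L]]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}

#' Write a centrality table as TSV
#'
#' @param records Output of [clusteringCentrality()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeCentralityTSV <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
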