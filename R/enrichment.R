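# Fisher exact over/under-representation of a gene list against a
# gene-set collection, with BH false-discovery-rate control across the
# sets actually tested.

#' Construct a gene-set collection against a reference universe
#'
#' Members outside the universe are trimmed with a warning (counted per
#' set), mirroring the harmonization a web over-representation tool
#' applies against its reference list. Symbol matching is exact and
#' case-sensitive.
#'
#' @param sets Named list of character vectors (set id -> member genes).
#' @param universe Character vector: the reference gene list.
#' @param names Optional named character vector of set descriptions.
#' @return A list of class `geneSetCollection` with elements `sets`,
#'   `set_names`, `universe`.
#' @export
geneSetCollection <- function(sets, universe, names = NULL) {
  if (!is.list(sets) || is.null(base::names(sets)) ||
      anyDuplicated(base::names(sets))) {
    stop("sets must be a uniquely named list", call. = FALSE)
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  trimmed <- 0L
  sets <- lapply(sets, function(g) {
    g <- unique(as.character(g))
    keep <- g %in% universe
    trimmed <<- trimmed + sum(!keep)
    g[keep]
  })
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) empty after harmonization; dropped")
    sets <- sets[!empty]
  }
  if (trimmed > 0L) {
    warning(trimmed, " set member(s) outside the universe were dropped")
  }
  if (is.null(names)) {
    names <- stats::setNames(base::names(sets), base::names(sets))
  }
  structure(list(sets = sets,
                 set_names = names[base::names(sets)],
                 universe = universe),
            class = "geneSetCollection")
}

#' Read a GMT gene-set file
#'
#' One set per line: id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @param universe Reference universe for [geneSetCollection()]; defaults
#'   to the union of all set members.
#' @return A `geneSetCollection`.
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1L], " (need id, description, genes)",
         call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- ids
  if (is.null(universe)) universe <- unique(unlist(sets))
  geneSetCollection(sets, universe, stats::setNames(desc, ids))
}

#' Fisher exact over/under-representation test
#'
#' For each gene set, builds the 2x2 table of set membership against
#' input membership over the universe and computes the two-sided Fisher
#' exact p-value (sum of the probabilities of all tables at most as
#' likely as the observed one). Direction is `over` when the observed
#' overlap exceeds its hypergeometric expectation
#' `input_size * category_size / universe_size`, `under` when below,
#' `none` on an exact tie. FDR is BH across exactly the sets in the
#' collection.
#'
#' @param input_genes Character vector of query genes; members outside
#'   the universe are dropped with a warning.
#' @param collection A [geneSetCollection()].
#' @param fdr_thresh Significance threshold on the BH-adjusted p
#'   (default 0.05).
#' @param alternative `"two.sided"` (default), `"greater"` (over only)
#'   or `"less"`.
#' @return `data.frame` with one row per set: `set_id`, `set_name`,
#'   `universe_size`, `category_size`, `input_size`, `observed`,
#'   `expected`, `direction`, `raw_p`, `fdr`, `significant`.
#' @export
fisherEnrichment <- function(input_genes, collection, fdr_thresh = 0.05,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  if (!inherits(collection, "geneSetCollection")) {
    stop("collection must be a geneSetCollection", call. = FALSE)
  }
  check_prob(fdr_thresh, "fdr_thresh")
  universe <- collection$universe
  input_genes <- unique(as.character(input_genes))
  if (length(input_genes) == 0L) stop("empty input gene list",
                                      call. = FALSE)
  dropped <- setdiff(input_genes, universe)
  if (length(dropped)) {
    warning(length(dropped),
            " input gene(s) outside the universe were dropped")
    input_genes <- intersect(input_genes, universe)
  }
  if (length(input_genes) == 0L) {
    stop("no input genes left after harmonization", call. = FALSE)
  }
  N <- length(universe)
  n_in <- length(input_genes)
  rows <- lapply(names(collection$sets), function(id) {
    members <- collection$sets[[id]]
    K <- length(members)
    obs <- length(intersect(members, input_genes))
    expected <- n_in * K / N
    tab <- matrix(c(obs, K - obs, n_in - obs, N - K - n_in + obs), 2L, 2L)
    p <- fisher.test(tab, alternative = alternative)$p.value
    data.frame(set_id = id,
               set_name = unname(collection$set_names[id]),
               universe_size = N,
               category_size = K,
               input_size = n_in,
               observed = obs,
               expected = expected,
               direction = if (obs > expected) "over" else
                 if (obs < expected) "under" else "none",
               raw_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$raw_p)
  out$significant <- out$fdr < fdr_thresh
  out[order(out$raw_p, out$set_id), , drop = FALSE]
}
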