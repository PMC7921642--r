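# Differential expression: each non-control stage versus the pooled
# control group, with optional empirical-Bayes variance moderation.

#' Benjamini-Hochberg step-up adjustment
#'
#' Plain step-up false-discovery-rate adjustment with monotonicity
#' enforcement, returned in the input order.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(pvals[o] * m / (m:1)))
  adj[ro]
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior
# from per-gene sample variances s2 on df degrees of freedom. Works on
# z = log(s2), whose marginal moments under the hierarchy are those of a
# log-F distribution. Returns prior df d0 (possibly Inf) and prior
# variance s02.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    stop("degenerate data: need at least two positive gene variances",
         call. = FALSE)
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated (or ordinary) two-group contrast of one stage versus control
#'
#' Compares the samples of `stage` against the pooled control group. The
#' per-gene statistic is a two-sample pooled-variance t; with
#' `moderated = TRUE` (default) the gene variances are squeezed towards a
#' common prior fitted across genes by method of moments on the log
#' variances, s2_tilde = (d0 * s02 + df * s2) / (d0 + df), and the t
#' statistic is referred to a t distribution on d0 + df degrees of
#' freedom. With `moderated = FALSE` (equivalently d0 = 0) this is the
#' ordinary pooled t-test. Fold changes are signed linear-scale ratios:
#' with log2 input, FC = 2^d for d >= 0 and -2^(-d) for d < 0, where d is
#' the difference of group means, so down-regulation reads as < -1.
#'
#' @param se A `SummarizedExperiment` with assay `"exprs"`, a `stage`
#'   column and `control_stages` metadata (see [readDesignTSV()]).
#' @param stage Stage label to contrast against the control pool; must
#'   not itself be a control stage.
#' @param moderated Squeeze gene variances towards the fitted prior?
#' @return A `data.frame` with one row per gene: `gene`, `mean_stage`,
#'   `mean_control`, `signed_fc`, `t`, `p`, `adj_p`; attributes `d0`,
#'   `s02`, `df_residual` and `contrast` carry the fitted moderation
#'   hyperparameters.
#' @export
fitContrast <- function(se, stage, moderated = TRUE) {
  design <- stageDesign(se)
  if (!stage %in% design$stage_order) {
    stop("unknown stage: ", stage, call. = FALSE)
  }
  if (stage %in% design$control_stages) {
    stop("stage '", stage, "' is part of the control pool", call. = FALSE)
  }
  m <- SummarizedExperiment::assay(se, "exprs")
  grp1 <- design$assignment == stage
  grp0 <- design$assignment %in% design$control_stages
  n1 <- sum(grp1); n0 <- sum(grp0)
  if (n1 < 2L || n0 < 2L) {
    stop("each group needs >= 2 samples (stage: ", n1, ", control: ", n0,
         ")", call. = FALSE)
  }
  x1 <- m[, grp1, drop = FALSE]
  x0 <- m[, grp0, drop = FALSE]
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  v1 <- apply(x1, 1L, var)
  v0 <- apply(x0, 1L, var)
  df <- n1 + n0 - 2L
  s2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / df
  if (all(s2 == 0)) {
    stop("degenerate data: zero variance for every gene", call. = FALSE)
  }

  if (moderated) {
    prior <- fit_variance_prior(s2, df)
    d0 <- prior$d0; s02 <- prior$s02
    s2_tilde <- if (is.finite(d0)) {
      (d0 * s02 + df * s2) / (d0 + df)
    } else {
      rep(s02, length(s2))
    }
    df_total <- d0 + df
  } else {
    d0 <- 0; s02 <- NA_real_
    s2_tilde <- s2
    df_total <- df
  }

  d <- m1 - m0
  se_d <- sqrt(s2_tilde * (1 / n1 + 1 / n0))
  tt <- ifelse(se_d > 0, d / se_d, 0)
  p <- if (is.finite(df_total)) 2 * pt(-abs(tt), df = df_total) else
    2 * pnorm(-abs(tt))
  fc <- ifelse(d >= 0, 2^d, -2^(-d))
  out <- data.frame(gene = rownames(m),
                    mean_stage = m1,
                    mean_control = m0,
                    signed_fc = fc,
                    t = tt,
                    p = p,
                    adj_p = bhAdjust(p),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- stage
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_residual") <- df
  out
}

#' Fit all stage-versus-control contrasts
#'
#' @param se As in [fitContrast()].
#' @param moderated Passed to [fitContrast()].
#' @return Named list of per-contrast `data.frame`s, one per non-control
#'   stage in stage order.
#' @export
fitAllContrasts <- function(se, moderated = TRUE) {
  design <- stageDesign(se)
  stages <- setdiff(design$stage_order, design$control_stages)
  tabs <- lapply(stages, function(s) fitContrast(se, s, moderated))
  names(tabs) <- stages
  tabs
}

#' Filter per-contrast tables and merge significant genes across contrasts
#'
#' Within each contrast, keeps genes with adjusted (or raw) p below
#' `p_thresh` and a signed fold change strictly beyond `+/- fc_thresh`;
#' the union across contrasts is returned deduplicated with provenance.
#'
#' @param tables Named list of tables from [fitContrast()], all over the
#'   same gene universe.
#' @param p_thresh Significance threshold (default 0.05).
#' @param fc_thresh Signed fold-change magnitude threshold (default 1.5).
#' @param use_adjusted Filter on BH-adjusted p (default) or raw p.
#' @return `data.frame` with columns `gene`, `n_contrasts`, `contrasts`
#'   (comma-separated provenance), sorted by gene id.
#' @export
filterAndMerge <- function(tables, p_thresh = 0.05, fc_thresh = 1.5,
                           use_adjusted = TRUE) {
  if (!is.list(tables) || length(tables) == 0L) {
    stop("need a non-empty list of contrast tables", call. = FALSE)
  }
  check_prob(p_thresh, "p_thresh")
  universe <- tables[[1L]]$gene
  hits <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!identical(sort(tab$gene), sort(universe))) {
      stop("contrast tables must share one gene universe", call. = FALSE)
    }
    pcol <- if (use_adjusted) tab$adj_p else tab$p
    keep <- pcol < p_thresh & abs(tab$signed_fc) > fc_thresh
    hits[[nm]] <- tab$gene[keep]
  }
  genes <- sort(unique(unlist(hits)))
  prov <- vapply(genes, function(g) {
    paste(names(hits)[vapply(hits, function(h) g %in% h, logical(1))],
          collapse = ",")
  }, character(1))
  data.frame(gene = genes,
             n_contrasts = lengths(regmatches(prov,
               gregexpr(",", prov))) + 1L,
             contrasts = unname(prov),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Collapse probe-level hits to gene symbols at the network boundary
#'
#' Probe-level rows are kept throughout the differential-expression step;
#' only when the gene list meets the interactome are probes collapsed to
#' symbols, keeping per symbol the probe with the largest absolute
#' t-statistic across contrasts.
#'
#' @param probes Character vector of probe ids (e.g. the `gene` column of
#'   [filterAndMerge()] output).
#' @param map Named character vector probe -> symbol (see
#'   [readAnnotation()]).
#' @param stat Optional named numeric (per probe) used to break
#'   multi-probe ties, typically max |t|; defaults to keeping the first
#'   probe per symbol.
#' @return A `data.frame` with columns `symbol` and `probe` (one row per
#'   retained symbol); attribute `unmapped` lists probes absent from the
#'   map.
#' @export
collapseToSymbols <- function(probes, map, stat = NULL) {
  unmapped <- setdiff(probes, names(map))
  probes <- intersect(probes, names(map))
  sym <- map[probes]
  if (is.null(stat)) stat <- stats::setNames(rep(0, length(probes)), probes)
  ord <- order(sym, -abs(stat[probes]), probes)
  probes <- probes[ord]; sym <- sym[ord]
  keep <- !duplicated(sym)
  out <- data.frame(symbol = unname(sym[keep]), probe = probes[keep],
                    stringsAsFactors = FALSE)
  attr(out, "unmapped") <- unmapped
  out
}

#' Write one differential-expression table as TSV
#'
#' @param tab A table from [fitContrast()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeDGETSV <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
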