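# S4 result containers for the classifier-based signature discovery.

#' Multiclass classification report
#'
#' Confusion matrix (rows = true class, columns = predicted; the figure
#' convention puts the true class on the x-axis), overall accuracy, and
#' the per-class and macro-averaged Jaccard index
#' TP / (TP + FP + FN). The macro Jaccard is the score used for the
#' random-signature null.
#'
#' @slot confusion Integer matrix, true classes in rows.
#' @slot accuracy Proportion of correctly classified samples.
#' @slot macroJaccard Mean of the per-class Jaccard indices.
#' @slot perClassJaccard Named numeric vector.
#' @export
setClass("ClassificationReport",
  representation(confusion = "matrix",
                 accuracy = "numeric",
                 macroJaccard = "numeric",
                 perClassJaccard = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@accuracy < 0 || object@accuracy > 1) {
      msg <- c(msg, "accuracy must be in [0, 1]")
    }
    if (object@macroJaccard < 0 || object@macroJaccard > 1) {
      msg <- c(msg, "macroJaccard must be in [0, 1]")
    }
    if (nrow(object@confusion) != ncol(object@confusion)) {
      msg <- c(msg, "confusion matrix must be square")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Two-round signature-reduction result
#'
#' Holds the gene subsets selected in each standardized-coefficient
#' reduction round, the fitted multinomial models, and the standardized
#' coefficient matrices the selections were made from.
#'
#' @slot round1 Features selected after the first train-and-threshold
#'   round.
#' @slot round2 Features selected after retraining on `round1` (the
#'   signature); always a subset of `round1`.
#' @slot models List of the two fitted classifiers.
#' @slot zscores List of the two standardized coefficient matrices
#'   (classes x features).
#' @slot threshold Standardized-coefficient selection threshold.
#' @slot l2 Ridge penalty used for both fits.
#' @slot seed Seed recorded for reproducibility.
#' @export
setClass("StageSignature",
  representation(round1 = "character",
                 round2 = "character",
                 models = "list",
                 zscores = "list",
                 threshold = "numeric",
                 l2 = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (!all(object@round2 %in% object@round1)) {
      return("round2 must be a subset of round1")
    }
    TRUE
  })

#' Random-signature null distribution
#'
#' Jaccard indices of classifiers trained on random gene sets of the same
#' size as the observed signature, the observed signature's Jaccard, and
#' the add-one empirical p-value (1 + #\{null >= observed\}) /
#' (n_sets + 1).
#'
#' @slot jaccard Numeric vector of null macro-Jaccard values.
#' @slot observed Observed signature macro-Jaccard.
#' @slot empiricalP Add-one empirical p-value in (0, 1].
#' @slot k Signature size drawn per null set.
#' @slot seed Seed used to draw the null sets.
#' @export
setClass("SignatureNull",
  representation(jaccard = "numeric",
                 observed = "numeric",
                 empiricalP = "numeric",
                 k = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@jaccard < 0 | object@jaccard > 1)) {
      msg <- c(msg, "null Jaccard values must be in [0, 1]")
    }
    if (length(object@empiricalP) == 1L &&
        (object@empiricalP <= 0 || object@empiricalP > 1)) {
      msg <- c(msg, "empirical p must be in (0, 1]")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn ClassificationReport-class Compact display.
#' @param object A `ClassificationReport`.
#' @export
setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport:", sum(object@confusion), "samples,",
      nrow(object@confusion), "classes\n")
  cat(sprintf("  accuracy      %.4f\n", object@accuracy))
  cat(sprintf("  macro Jaccard %.4f\n", object@macroJaccard))
})

#' @describeIn StageSignature-class Compact display.
#' @param object A `StageSignature`.
#' @export
setMethod("show", "StageSignature", function(object) {
  cat("StageSignature: two-round standardized-coefficient reduction\n")
  cat(sprintf("  threshold |z| > %.2f, ridge l2 = %g\n",
              object@threshold, object@l2))
  cat(sprintf("  round 1: %d features; round 2 (signature): %d features\n",
              length(object@round1), length(object@round2)))
  if (length(object@round2)) {
    cat("  signature:", paste(utils::head(object@round2, 10L),
                              collapse = ", "),
        if (length(object@round2) > 10L) "..." else "", "\n")
  }
})

#' @describeIn SignatureNull-class Compact display.
#' @param object A `SignatureNull`.
#' @export
setMethod("show", "SignatureNull", function(object) {
  cat(sprintf(
    "SignatureNull: %d random sets of %d genes\n  observed Jaccard %.4f;",
    length(object@jaccard), object@k, object@observed))
  cat(sprintf(" null max %.4f; empirical p = %.4g\n",
              max(object@jaccard), object@empiricalP))
})

## ---- accessors --------------------------------------------------------

#' Accessors for signature and null results
#'
#' @param x A [StageSignature-class] or [SignatureNull-class] object.
#' @param round For `signatureGenes()`: reduction round (1 or 2; default
#'   the final round 2).
#' @return `signatureGenes()`: character vector of selected features;
#'   `signatureModels()`: list of fitted classifiers; `nullValues()`:
#'   numeric vector of null Jaccard indices; `observedJaccard()` and
#'   `empiricalP()`: single numbers.
#' @name signature-accessors
NULL

#' @rdname signature-accessors
#' @export
signatureGenes <- function(x, round = 2L) {
  stopifnot(is(x, "StageSignature"), round %in% c(1L, 2L))
  if (round == 1L) x@round1 else x@round2
}

#' @rdname signature-accessors
#' @export
signatureModels <- function(x) {
  stopifnot(is(x, "StageSignature"))
  x@models
}

#' @rdname signature-accessors
#' @export
nullValues <- function(x) {
  stopifnot(is(x, "SignatureNull"))
  x@jaccard
}

#' @rdname signature-accessors
#' @export
observedJaccard <- function(x) {
  stopifnot(is(x, "SignatureNull"))
  x@observed
}

#' @rdname signature-accessors
#' @export
empiricalP <- function(x) {
  stopifnot(is(x, "SignatureNull"))
  x@empiricalP
}

#' @rdname signature-accessors
#' @export
accuracy <- function(x) {
  stopifnot(is(x, "ClassificationReport"))
  x@accuracy
}

#' @rdname signature-accessors
#' @export
macroJaccard <- function(x) {
  stopifnot(is(x, "ClassificationReport"))
  x@macroJaccard
}

#' @rdname signature-accessors
#' @export
confusionMatrix <- function(x) {
  stopifnot(is(x, "ClassificationReport"))
  x@confusion
}
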