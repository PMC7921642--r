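# Multinomial logistic stage classifier and the two-round
# standardized-coefficient parameter reduction, with its random-signature
# null control.
#
# The fit is a softmax (true multinomial, not one-vs-rest) with an L2
# ridge penalty on the non-intercept coefficients, minimized by L-BFGS
# with an analytic gradient from an all-zero start, so it is a
# deterministic convex optimization: identical inputs give identical
# coefficients to optimizer tolerance.

softmax_prob <- function(X1, B) {
  eta <- X1 %*% B
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Z-score features (columns) of a sample-by-feature matrix
#'
#' Coefficient magnitudes are only comparable across genes when the genes
#' are on one scale, so features are standardized before training; a
#' zero-variance feature is left at zero.
#'
#' @param X Numeric matrix, samples in rows.
#' @return Matrix of the same shape with columns centered and scaled to
#'   unit standard deviation.
#' @export
standardizeFeatures <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2L, mu, "-"), 2L, s, "/")
}

#' Train a ridge-penalized multinomial (softmax) stage classifier
#'
#' Minimizes the summed negative log-likelihood plus `l2 / 2` times the
#' squared norm of the non-intercept coefficients. Intercepts are
#' unpenalized. The optimization is convex and started from zero, so the
#' result is deterministic for fixed inputs; `seed` is recorded for
#' provenance but no randomness is consumed.
#'
#' @param X Numeric matrix, samples x features (features should be
#'   z-scored, see [standardizeFeatures()]).
#' @param y Factor (or coercible) of class labels, >= 2 classes, each
#'   with >= 2 samples.
#' @param l2 Ridge penalty (default 1).
#' @param seed Integer, recorded in the fit.
#' @param maxit Maximum L-BFGS iterations.
#' @return An object of class `stageClassifier`: list with `beta`
#'   (features x classes), `intercept`, `classes`, `features`, `l2`,
#'   `value` (objective at optimum) and `convergence`.
#' @export
trainClassifier <- function(X, y, l2 = 1, seed = 1L, maxit = 2000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in X", call. = FALSE)
  y <- factor(y)
  K <- nlevels(y)
  if (K < 2L) stop("need at least two classes", call. = FALSE)
  if (any(table(y) < 2L)) {
    stop("every class needs >= 2 samples", call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (l2 < 0) stop("l2 must be non-negative", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(p))
  X1 <- cbind(`(Intercept)` = 1, X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  pen_mask <- c(0, rep(1, p))   # intercept row unpenalized

  obj <- function(par) {
    B <- matrix(par, p + 1L, K)
    eta <- X1 %*% B
    mx <- apply(eta, 1L, max)
    lse <- mx + log(rowSums(exp(eta - mx)))
    nll <- sum(lse) - sum(eta[Y == 1])
    nll + 0.5 * l2 * sum((pen_mask * B)^2)
  }
  grad <- function(par) {
    B <- matrix(par, p + 1L, K)
    P <- softmax_prob(X1, B)
    G <- crossprod(X1, P - Y) + l2 * (pen_mask * B)
    as.vector(G)
  }
  fit <- optim(rep(0, (p + 1L) * K), obj, grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  B <- matrix(fit$par, p + 1L, K,
              dimnames = list(c("(Intercept)", colnames(X)), levels(y)))
  structure(list(beta = B[-1L, , drop = FALSE],
                 intercept = B[1L, ],
                 classes = levels(y),
                 features = colnames(X),
                 l2 = l2,
                 seed = as.integer(seed),
                 value = fit$value,
                 convergence = fit$convergence),
            class = "stageClassifier")
}

#' @export
print.stageClassifier <- function(x, ...) {
  cat("stageClassifier:", length(x$classes), "classes,",
      length(x$features), "features, ridge l2 =", x$l2, "\n")
  invisible(x)
}

#' Predict stage labels (or class probabilities)
#'
#' @param object A `stageClassifier` fit.
#' @param newdata Samples x features matrix with the training features.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or a samples x classes
#'   probability matrix.
#' @export
predict.stageClassifier <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$features)) {
      stop("newdata has no feature names and the wrong column count",
           call. = FALSE)
    }
    colnames(newdata) <- object$features
  }
  newdata <- newdata[, object$features, drop = FALSE]
  B <- rbind(object$intercept, object$beta)
  P <- softmax_prob(cbind(1, newdata), B)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Standardize model coefficients to z-scores
#'
#' All class-by-feature coefficients (intercepts excluded) are pooled and
#' transformed to z = (beta - mean) / sd with the population (1/N)
#' standard deviation, so the standardized parameters have exactly zero
#' mean and unit standard deviation.
#'
#' @param beta A `stageClassifier` fit or a classes x features numeric
#'   matrix.
#' @return Classes x features matrix of standardized coefficients.
#' @export
standardizeCoefficients <- function(beta) {
  if (inherits(beta, "stageClassifier")) beta <- t(beta$beta)
  beta <- as.matrix(beta)
  mu <- mean(beta)
  s <- sqrt(mean((beta - mu)^2))
  if (s == 0) {
    stop("degenerate coefficients: all entries are equal", call. = FALSE)
  }
  (beta - mu) / s
}

#' Select features whose standardized coefficient is beyond a threshold
#'
#' A feature is selected when the largest absolute standardized
#' coefficient over the classes strictly exceeds `threshold` (default
#' 0.78 standard deviations from the mean).
#'
#' @param z Classes x features standardized coefficient matrix.
#' @param threshold Selection threshold; `-Inf` selects everything.
#' @return List with `selected` (feature names), `mask` (named logical)
#'   and `max_abs_z` (named numeric).
#' @export
selectFeatures <- function(z, threshold = 0.78) {
  z <- as.matrix(z)
  max_abs <- apply(abs(z), 2L, max)
  mask <- max_abs > threshold
  list(selected = names(max_abs)[mask], mask = mask, max_abs_z = max_abs)
}

#' Two-round standardized-coefficient signature reduction
#'
#' Round 1 trains the multinomial classifier on all (z-scored) features
#' and keeps those whose standardized coefficient magnitude exceeds
#' `threshold`; round 2 retrains on the kept features and applies the
#' same selection again, yielding the final signature (a subset of round
#' 1).
#'
#' @param X Samples x features matrix.
#' @param y Stage labels.
#' @param threshold Standardized-coefficient threshold (default 0.78).
#' @param l2 Ridge penalty for both fits.
#' @param seed Recorded seed.
#' @param standardize Z-score the features first (default TRUE).
#' @return A [StageSignature-class] object.
#' @export
twoRoundReduction <- function(X, y, threshold = 0.78, l2 = 1, seed = 1L,
                              standardize = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  if (standardize) X <- standardizeFeatures(X)
  fit1 <- trainClassifier(X, y, l2 = l2, seed = seed)
  z1 <- standardizeCoefficients(fit1)
  s1 <- selectFeatures(z1, threshold)$selected
  if (length(s1) == 0L) {
    stop("round 1 selected no features; lower the threshold",
         call. = FALSE)
  }
  fit2 <- trainClassifier(X[, s1, drop = FALSE], y, l2 = l2, seed = seed)
  z2 <- standardizeCoefficients(fit2)
  s2 <- selectFeatures(z2, threshold)$selected
  new("StageSignature",
      round1 = s1, round2 = s2,
      models = list(round1 = fit1, round2 = fit2),
      zscores = list(round1 = z1, round2 = z2),
      threshold = threshold, l2 = l2, seed = as.integer(seed))
}

#' Evaluate predictions against true labels
#'
#' Builds the confusion matrix (true classes in rows), overall accuracy
#' and per-class / macro-averaged Jaccard indices TP / (TP + FP + FN).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param levels Optional class set; defaults to the union of labels in
#'   `y_true` and `y_pred` (in order of appearance in `y_true` first).
#' @return A [ClassificationReport-class] object.
#' @export
evaluateClassifier <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- if (is.factor(y_true)) base::levels(y_true) else
      unique(c(as.character(y_true), as.character(y_pred)))
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  unknown <- setdiff(unique(c(y_true, y_pred)), levels)
  if (length(unknown)) {
    stop("unknown labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  conf <- table(factor(y_true, levels = levels),
                factor(y_pred, levels = levels))
  conf <- unclass(conf)
  storage.mode(conf) <- "integer"
  names(dimnames(conf)) <- c("true", "predicted")
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  denom <- tp + fp + fn
  jac <- ifelse(denom > 0, tp / denom, 1)  # class absent on both sides
  names(jac) <- levels
  new("ClassificationReport",
      confusion = conf,
      accuracy = sum(tp) / length(y_true),
      macroJaccard = mean(jac),
      perClassJaccard = jac)
}

#' Random-signature null distribution of the classification Jaccard
#'
#' Draws `nSets` random feature subsets of size `k`, trains one
#' classifier per subset with the same protocol as the observed
#' signature (train and evaluate on the same records), and records the
#' macro-Jaccard of each. The observed signature's Jaccard and its
#' add-one empirical p-value against the null are returned with the
#' distribution.
#'
#' @param X Samples x features matrix (z-scored internally with the same
#'   rule as the observed fit).
#' @param y Stage labels.
#' @param signature Character vector of observed signature features.
#' @param k Random-set size; defaults to `length(signature)`.
#' @param nSets Number of random sets (default 500).
#' @param l2 Ridge penalty.
#' @param seed Seed governing the random draws.
#' @param standardize Z-score features first (default TRUE).
#' @return A [SignatureNull-class] object.
#' @export
randomSignatureNull <- function(X, y, signature, k = length(signature),
                                nSets = 500L, l2 = 1, seed = 1L,
                                standardize = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  check_count(k, "k")
  check_count(nSets, "nSets")
  if (k > ncol(X)) {
    stop("k exceeds the number of available features", call. = FALSE)
  }
  missing <- setdiff(signature, colnames(X))
  if (length(missing)) {
    stop("signature features not in X: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (standardize) X <- standardizeFeatures(X)
  score <- function(feats) {
    fit <- trainClassifier(X[, feats, drop = FALSE], y, l2 = l2)
    report <- evaluateClassifier(y, predict(fit, X[, feats, drop = FALSE]))
    macroJaccard(report)
  }
  observed <- score(signature)
  jac <- with_seed(seed, {
    vapply(seq_len(nSets), function(i) {
      score(sample(colnames(X), k))
    }, numeric(1))
  })
  new("SignatureNull",
      jaccard = jac,
      observed = observed,
      empiricalP = (1 + sum(jac >= observed)) / (nSets + 1),
      k = as.integer(k),
      seed = as.integer(seed))
}
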