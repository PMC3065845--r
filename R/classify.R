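## Fisher linear and Gaussian quadratic discriminants over the three-feature
## space (i_average, i_skewness, K_naaGc), with resubstitution confusion
## reports and exact one-sided binomial significance.

.checkFeatureTable <- function(table, features) {
  stopifnot(is.data.frame(table))
  if (!"label" %in% names(table)) stop("feature table needs a 'label' column")
  if (anyNA(table[, features])) stop("missing feature values")
  lv <- sort(unique(as.character(table$label)))
  if (length(lv) != 2) stop("exactly two class labels required")
  if (any(tabulate(factor(table$label, levels = lv)) < 2))
    stop("need >= 2 rows per class")
  lv
}

## Ridge regularization for (near-)singular scatter matrices.
.ridge <- function(S, eps = 1e-6) S + diag(eps * sum(diag(S)) / nrow(S) +
                                           1e-12, nrow(S))

#' Fit a Fisher linear discriminant
#'
#' Weight direction proportional to Sw^-1 (mu1 - mu2) with Sw the pooled
#' within-class scatter; the offset places the boundary at the midpoint of
#' the projected class means (equal priors). Deterministic; a small ridge
#' term (1e-6 * trace/d) keeps near-singular scatters invertible. Class
#' assignments are invariant under invertible affine transforms of the
#' features, in particular per-feature rescaling.
#'
#' @param table data.frame with a \code{label} column (two classes) and the
#'   feature columns.
#' @param features character vector of 2 or 3 feature column names.
#' @return A classifier model (list, class \code{"laminaClassifier"}) with
#'   elements kind, features, levels, w, b.
#' @export
fitFisherLinear <- function(table,
                            features = c("K_naaGc", "i_average")) {
  lv <- .checkFeatureTable(table, features)
  X <- as.matrix(table[, features, drop = FALSE])
  g <- as.character(table$label)
  m1 <- colMeans(X[g == lv[1], , drop = FALSE])
  m2 <- colMeans(X[g == lv[2], , drop = FALSE])
  Sw <- matrix(0, length(features), length(features))
  for (l in lv) {
    Xc <- sweep(X[g == l, , drop = FALSE], 2,
                colMeans(X[g == l, , drop = FALSE]))
    Sw <- Sw + crossprod(Xc)
  }
  w <- solve(.ridge(Sw), m1 - m2)
  b <- -sum(w * (m1 + m2)) / 2
  structure(list(kind = "fisher_linear", features = features, levels = lv,
                 w = as.numeric(w), b = b),
            class = "laminaClassifier")
}

#' Fit a Gaussian quadratic discriminant
#'
#' Gaussian class-conditional model with per-class mean and covariance
#' (ridge-regularized) and equal priors.
#'
#' @inheritParams fitFisherLinear
#' @return A classifier model (list, class \code{"laminaClassifier"}).
#' @export
fitQuadratic <- function(table, features = c("K_naaGc", "i_average")) {
  lv <- .checkFeatureTable(table, features)
  X <- as.matrix(table[, features, drop = FALSE])
  g <- as.character(table$label)
  if (any(base::table(g) <= length(features)))
    stop("need more rows than features per class for a quadratic fit")
  pars <- lapply(lv, function(l) {
    Xl <- X[g == l, , drop = FALSE]
    S <- .ridge(stats::cov(Xl))
    list(mean = colMeans(Xl), cov = S, covInv = solve(S),
         logDet = determinant(S, logarithm = TRUE)$modulus)
  })
  names(pars) <- lv
  structure(list(kind = "quadratic", features = features, levels = lv,
                 pars = pars),
            class = "laminaClassifier")
}

#' Predict class labels
#'
#' @param object a model from [fitFisherLinear()] or [fitQuadratic()].
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.laminaClassifier <- function(object, newdata, ...) {
  if (!all(object$features %in% names(newdata)))
    stop("feature mismatch between model and table")
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (object$kind == "fisher_linear") {
    sc <- as.vector(X %*% object$w) + object$b
    ifelse(sc > 0, object$levels[1], object$levels[2])
  } else {
    d <- vapply(object$levels, function(l) {
      p <- object$pars[[l]]
      Xc <- sweep(X, 2, p$mean)
      -0.5 * rowSums((Xc %*% p$covInv) * Xc) - 0.5 * as.numeric(p$logDet)
    }, numeric(nrow(X)))
    d <- matrix(d, nrow = nrow(X))
    object$levels[max.col(d, ties.method = "first")]
  }
}

#' Per-class percent correct with binomial standard error and significance
#'
#' The arithmetic behind a confusion-matrix cell: percent correct
#' p = k/N (reported rounded to integer percent, half away from zero),
#' standard error sqrt(p (1 - p) / N) in percent (same rounding), and the
#' one-sided exact binomial p-value of k successes in N trials against
#' chance (0.5).
#'
#' @param correct number of correctly classified cells k.
#' @param n class size N.
#' @return list: pct, se_pct, pct_rounded, se_pct_rounded, p_value.
#' @export
confusionStats <- function(correct, n) {
  if (n <= 0 || correct < 0 || correct > n) stop("invalid counts")
  p <- correct / n
  se <- sqrt(p * (1 - p) / n)
  list(pct = 100 * p, se_pct = 100 * se,
       pct_rounded = as.integer(.roundHalfAway(100 * p)),
       se_pct_rounded = as.integer(.roundHalfAway(100 * se)),
       p_value = stats::binom.test(correct, n, 0.5,
                                   alternative = "greater")$p.value)
}

#' Evaluate a classifier into a confusion report
#'
#' Resubstitution by default (evaluating on the training rows, as when a
#' decision line is drawn through the measured cells themselves);
#' leave-one-out refitting is available as an extension and logged as such.
#'
#' @param model a fitted classifier.
#' @param table the feature table with labels.
#' @param mode "resubstitution" or "loo".
#' @return list of class \code{"confusionReport"}: \code{counts} (predicted
#'   x true), \code{per_class} (list of [confusionStats()] results), and
#'   \code{mode}.
#' @export
evaluateClassifier <- function(model, table,
                               mode = c("resubstitution", "loo")) {
  mode <- match.arg(mode)
  lv <- model$levels
  truth <- as.character(table$label)
  if (mode == "resubstitution") {
    pred <- predict(model, table)
  } else {
    message("leave-one-out evaluation: departs from the resubstitution default")
    refit <- if (model$kind == "fisher_linear") fitFisherLinear else fitQuadratic
    pred <- vapply(seq_len(nrow(table)), function(i)
      predict(refit(table[-i, , drop = FALSE], model$features),
              table[i, , drop = FALSE]),
      character(1))
  }
  counts <- base::table(factor(pred, levels = lv), factor(truth, levels = lv))
  perClass <- lapply(lv, function(l)
    confusionStats(counts[l, l], sum(counts[, l])))
  names(perClass) <- lv
  structure(list(counts = unclass(counts), per_class = perClass, mode = mode),
            class = "confusionReport")
}

#' @export
print.confusionReport <- function(x, ...) {
  cat("Confusion matrix (rows: predicted, cols: true;", x$mode, "):\n")
  print(x$counts)
  for (l in names(x$per_class)) {
    s <- x$per_class[[l]]
    cat(sprintf("  %s: %d%% +/- %d%% correct (exact one-sided binomial p = %.3g)\n",
                l, s$pct_rounded, s$se_pct_rounded, s$p_value))
  }
  invisible(x)
}

#' Scatter plot of two features with the linear decision line
#'
#' @param table feature table with labels.
#' @param model a 2-feature Fisher linear model.
#' @param path output file (png/pdf/svg decided by extension).
#' @return \code{path}, invisibly; the ggplot object as attribute "plot".
#' @export
scatterWithBoundary <- function(table, model, path) {
  if (model$kind != "fisher_linear" || length(model$features) != 2)
    stop("decision line requires a 2-feature linear model")
  f <- model$features
  df <- data.frame(x = table[[f[1]]], y = table[[f[2]]],
                   label = as.character(table$label))
  w <- model$w; b <- model$b
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$label,
                                        shape = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = f[1], y = f[2]) +
    ggplot2::theme_bw()
  if (abs(w[2]) > 1e-12 * max(abs(w), 1e-300)) {
    p <- p + ggplot2::geom_abline(intercept = -b / w[2], slope = -w[1] / w[2])
  } else {
    p <- p + ggplot2::geom_vline(xintercept = -b / w[1])
  }
  ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 150)
  out <- path
  attr(out, "plot") <- p
  invisible(out)
}

#' @importFrom ggplot2 .data
NULL
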