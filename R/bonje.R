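#' Greedy feature selection by neighborhood joint entropy
#'
#' Fits a feature-selection model to a decision table: starting from the
#' empty subset, each step scores every remaining attribute by the
#' neighborhood joint entropy of the enlarged subset and adds the best one,
#' stopping at the first step whose best candidate no longer strictly
#' improves the current entropy. Because the criterion is non-monotonic in
#' the subset, this stop rule (no strict improvement) replaces the usual
#' saturation test of monotone reducts.
#'
#' @param x A [decision_table], a numeric matrix/data frame of condition
#'   attributes, or a formula (see the formula method).
#' @param labels Decision labels (when `x` is a matrix or data frame).
#' @param delta Neighborhood radius in the normalized `[0, 1]` feature space.
#' @param p Minkowski order (`2` = Euclidean).
#' @param log_base Base of the entropy logarithm.
#' @param normalize Min-max normalize the condition attributes first?
#'   (Normalization statistics come from the full table.)
#' @param tol Absolute tolerance for the strict-improvement comparison; the
#'   stop rule hinges on equality of two floating-point entropy pipelines.
#' @param data Data frame holding the variables of the formula.
#' @param ... Passed between methods.
#'
#' @return An object of class `bonje`: list with
#'   \describe{
#'     \item{selected}{Integer indices of the chosen features, in selection
#'       order.}
#'     \item{feature_names}{Names of the chosen features, in order.}
#'     \item{trace}{Data frame of the greedy steps: `step`, `candidate`
#'       (feature name), `score` (joint entropy if added), `chosen`.}
#'     \item{final_H}{Joint entropy of the selected subset.}
#'     \item{nds}{The underlying [neighborhood_system()].}
#'   }
#'
#' @examples
#' fit <- bonje(toy_decision_table(), delta = 0.3)
#' fit                   # selects c then a, H = 0.345
#' coef(fit)
#' summary(fit)
#' @seealso [verify_feature_subset()], [neighborhood_joint_entropy()]
#' @export
bonje <- function(x, ...) UseMethod("bonje")

#' @rdname bonje
#' @export
bonje.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.fail)
  labels <- stats::model.response(mf)
  feats <- mf[, -1L, drop = FALSE]
  bonje(decision_table(feats, labels), ...)
}

#' @rdname bonje
#' @export
bonje.default <- function(x, labels, ...) {
  bonje(decision_table(x, labels), ...)
}

#' @rdname bonje
#' @export
bonje.decision_table <- function(x, delta = 0.3, p = 2, log_base = 10,
                                 normalize = TRUE, tol = 1e-12, ...) {
  nds <- neighborhood_system(x, delta = delta, p = p, normalize = normalize)
  bonje(nds, log_base = log_base, tol = tol)
}

#' @rdname bonje
#' @export
bonje.nds <- function(x, log_base = 10, tol = 1e-12, ...) {
  nds <- x
  n_feat <- ncol(nds$table$values)
  if (n_feat == 0L) stop("decision table has no condition attributes", call. = FALSE)
  if (n_samples(nds) < 2L) stop("need at least 2 samples", call. = FALSE)
  feat_names <- colnames(nds$table$values)

  one_class <- nlevels(droplevels(nds$table$labels)) < 2L
  if (one_class) {
    warning("decision attribute has a single class; nothing to select",
            call. = FALSE)
  }

  selected <- integer(0)
  H_cur <- 0
  trace <- list()
  step <- 0L
  while (!one_class && length(selected) < n_feat) {
    step <- step + 1L
    cand <- setdiff(seq_len(n_feat), selected)
    scores <- vapply(cand, function(b) {
      neighborhood_joint_entropy(nds, c(selected, b), log_base)
    }, numeric(1))
    best <- which.max(scores)  # ties: lowest feature index (cand is ascending)
    accept <- scores[best] - H_cur > tol
    trace[[step]] <- data.frame(
      step = step,
      candidate = feat_names[cand],
      score = scores,
      chosen = accept & (cand == cand[best]),
      stringsAsFactors = FALSE
    )
    if (!accept) break
    selected <- c(selected, cand[best])
    H_cur <- scores[best]
  }

  structure(
    list(selected = selected,
         feature_names = feat_names[selected],
         trace = if (length(trace)) do.call(rbind, trace) else
           data.frame(step = integer(), candidate = character(),
                      score = numeric(), chosen = logical()),
         final_H = H_cur,
         nds = nds),
    class = "bonje"
  )
}

#' @export
print.bonje <- function(x, digits = 4, ...) {
  cat("Neighborhood joint-entropy feature selection\n")
  cat(sprintf("  delta = %g, p = %g, %d samples, %d features\n",
              x$nds$delta, x$nds$p, n_samples(x$nds),
              ncol(x$nds$table$values)))
  if (length(x$selected) == 0L) {
    cat("  no features selected\n")
  } else {
    cat("  selected (in order): ", paste(x$feature_names, collapse = ", "),
        "\n", sep = "")
    cat(sprintf("  H(D,B) = %.*g\n", digits, x$final_H))
  }
  invisible(x)
}

#' @export
coef.bonje <- function(object, ...) {
  # per-feature entropy gain at the step it was accepted
  if (length(object$selected) == 0L) return(numeric(0))
  steps <- object$trace[object$trace$chosen, , drop = FALSE]
  gains <- diff(c(0, steps$score))
  stats::setNames(gains, steps$candidate)
}

#' @export
summary.bonje <- function(object, ...) {
  steps <- object$trace[object$trace$chosen, , drop = FALSE]
  structure(
    list(fit = object,
         step_table = if (nrow(steps)) {
           data.frame(step = steps$step, feature = steps$candidate,
                      H_after = steps$score, gain = diff(c(0, steps$score)))
         } else NULL,
         verification = if (length(object$selected)) {
           verify_feature_subset(object$nds, object$selected)
         } else NULL),
    class = "summary.bonje"
  )
}

#' @export
print.summary.bonje <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$step_table)) {
    cat("\nGreedy steps:\n")
    print(x$step_table, digits = digits, row.names = FALSE)
  }
  if (!is.null(x$verification)) {
    v <- x$verification
    cat(sprintf("\nReduct check: preserves full-set entropy: %s; no redundant member: %s\n",
                v$cond1, v$cond2))
    if (length(v$offending)) {
      cat("  redundant: ", paste(v$offending, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
plot.bonje <- function(x, ...) {
  steps <- x$trace[x$trace$chosen, , drop = FALSE]
  if (nrow(steps) == 0L) {
    stop("no accepted steps to plot", call. = FALSE)
  }
  graphics::plot(c(0, steps$step), c(0, steps$score), type = "b", pch = 19,
                 xlab = "greedy step", ylab = "H(D,B)",
                 main = "Joint entropy along the greedy path", ...)
  graphics::text(steps$step, steps$score, labels = steps$candidate,
                 pos = 3, cex = 0.8)
  invisible(x)
}

#' Predict decision labels with the selected features
#'
#' Classifies new samples by the built-in 3-nearest-neighbor rule on the
#' selected features. New data are scaled with the min-max statistics of
#' the training table.
#'
#' @param object A fitted [bonje] model with at least one selected feature.
#' @param newdata Numeric matrix or data frame with the training features as
#'   columns; defaults to the training table (resubstitution).
#' @param k Number of neighbors.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.bonje <- function(object, newdata = NULL, k = 3, ...) {
  if (length(object$selected) == 0L) {
    stop("no features were selected; cannot predict", call. = FALSE)
  }
  train <- object$nds$table$values[, object$selected, drop = FALSE]
  labels <- object$nds$table$labels
  if (is.null(newdata)) {
    test <- train
  } else {
    if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
    test <- newdata[, object$feature_names, drop = FALSE]
  }
  knn_predict(train, labels, test, k = k)
}

#' Check a subset against the reduct conditions
#'
#' A subset `B` is a reduct when (1) its joint entropy is at least that of
#' the full attribute set, and (2) removing any single member strictly
#' decreases the joint entropy (no redundant member). The greedy search does
#' not enforce condition (1) -- non-monotonicity means its result may fall
#' short of the full set -- so this report is diagnostic.
#'
#' @inheritParams classic_neighborhood_entropy
#' @param tol Absolute tolerance for the entropy comparisons.
#' @return List with logicals `cond1`, `cond2`, character `offending`
#'   (members whose removal does not strictly decrease the entropy), and the
#'   entropies `H_B`, `H_C`.
#' @examples
#' nds <- neighborhood_system(toy_decision_table(), 0.3)
#' verify_feature_subset(nds, c("a", "c"))
#' @export
verify_feature_subset <- function(nds, B, log_base = 10, tol = 1e-12) {
  stopifnot(inherits(nds, "nds"))
  B <- resolve_features(nds, B)
  C <- seq_len(ncol(nds$table$values))
  H_B <- neighborhood_joint_entropy(nds, B, log_base)
  H_C <- neighborhood_joint_entropy(nds, C, log_base)
  cond1 <- H_B >= H_C - tol
  drops <- vapply(seq_along(B), function(k) {
    if (length(B) == 1L) 0 else
      neighborhood_joint_entropy(nds, B[-k], log_base)
  }, numeric(1))
  redundant <- !(H_B - drops > tol)
  list(cond1 = cond1, cond2 = !any(redundant),
       offending = colnames(nds$table$values)[B[redundant]],
       H_B = H_B, H_C = H_C)
}
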