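#' Empirical ROC curve and AUC
#'
#' Builds the threshold ROC from continuous scores and computes the AUC
#' by the trapezoid rule, which for this construction equals the
#' Mann-Whitney U statistic with ties counted one half (midranks).
#'
#' @param scores numeric risk scores (larger = more positive).
#' @param labels 0/1 vector; both classes must be present.
#' @param class optional class tag stored on the result.
#' @return object of class `roc_result`: `fpr`, `tpr` (curve vertices,
#'   from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`, `class`.
#' @export
roc_curve <- function(scores, labels, class = NA_character_) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: one of the classes is absent")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- c(diff(s) != 0, TRUE)           # one vertex per distinct score
  fpr <- c(0, fp[last] / n_neg)
  tpr <- c(0, tp[last] / n_pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(fpr = fpr, tpr = tpr, auc = auc, n_pos = n_pos,
                 n_neg = n_neg, class = class),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result%s: AUC %.4f (%d pos / %d neg)\n",
              if (is.na(x$class)) "" else paste0(" [", x$class, "]"),
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# one-sided limits of a ROC polyline at each grid point: a curve with a
# vertical jump at x has distinct left/right TPR limits there, and keeping
# both makes the trapezoid integral of the averaged curve exact
.roc_limits <- function(curve, grid) {
  f <- curve$fpr; t <- curve$tpr
  xs <- unique(f)
  tL <- t[match(xs, f)]                          # first occurrence
  tR <- t[length(f) + 1L - match(xs, rev(f))]    # last occurrence
  j <- findInterval(grid, xs)
  at_bp <- grid == xs[j]
  left <- right <- numeric(length(grid))
  left[at_bp] <- tL[j[at_bp]]
  right[at_bp] <- tR[j[at_bp]]
  mid <- !at_bp
  if (any(mid)) {
    jm <- j[mid]
    v <- tR[jm] + (tL[jm + 1L] - tR[jm]) *
      (grid[mid] - xs[jm]) / (xs[jm + 1L] - xs[jm])
    left[mid] <- v; right[mid] <- v
  }
  list(left = left, right = right)
}

#' Macro-average ROC over one-vs-rest class curves
#'
#' Evaluates every class curve on the union of their observed FPR
#' breakpoints, averages the TPR at each grid point (keeping one-sided
#' limits at vertical jumps), and integrates the averaged curve by the
#' trapezoid rule — exact for the input step curves, so the macro of
#' identical curves reproduces their AUC to machine precision.
#'
#' @param curves list of `roc_result`s (>= 2).
#' @return `roc_result` with `class = "macro"`.
#' @export
macro_roc <- function(curves) {
  if (length(curves) < 2L) stop("need >= 2 class curves")
  grid <- sort(unique(unlist(lapply(curves, `[[`, "fpr"))))
  lims <- lapply(curves, .roc_limits, grid = grid)
  left <- rowMeans(vapply(lims, `[[`, numeric(length(grid)), "left"))
  right <- rowMeans(vapply(lims, `[[`, numeric(length(grid)), "right"))
  k <- length(grid)
  auc <- sum(diff(grid) * (right[-k] + left[-1]) / 2)
  # emit vertical jumps as duplicated vertices, like the input curves
  fpr <- rep(grid, each = 2L)
  tpr <- as.vector(rbind(left, right))
  keep <- !duplicated(cbind(fpr, tpr))
  structure(list(fpr = fpr[keep], tpr = tpr[keep], auc = auc,
                 n_pos = NA_integer_, n_neg = NA_integer_,
                 class = "macro"),
            class = "roc_result")
}

#' Confusion matrix and per-class accuracy from class scores
#'
#' The predicted class is the argmax of the per-class scores (ties go to
#' the lowest class index).  Rows are ground truth, columns predictions;
#' the per-class accuracy is the diagonal over the row sum.
#'
#' @param scores n x K score matrix with class column names.
#' @param labels true class labels.
#' @return list: `table` (K x K), `per_class_accuracy`, `overall_accuracy`.
#' @export
confusion <- function(scores, labels) {
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  pred <- classes[max.col(scores, ties.method = "first")]
  tab <- table(truth = factor(as.character(labels), levels = classes),
               predicted = factor(pred, levels = classes))
  rs <- rowSums(tab)
  acc <- ifelse(rs > 0, diag(tab) / rs, NA_real_)
  list(table = tab, per_class_accuracy = acc,
       overall_accuracy = sum(diag(tab)) / sum(tab))
}

# midrank structural components of the AUC (positives and negatives)
.delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc, m = m, n = n)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two models scored on the same patients using the
#' DeLong structural-components covariance estimator (midrank, O(n log n)
#' formulation); the z statistic is the AUC difference over its standard
#' error with a two-sided normal p value.  Identical (or perfectly
#' monotone-related) score vectors have zero variance and are reported as
#' a degenerate comparison with p = 1.
#'
#' @param scores_1,scores_2 paired score vectors.
#' @param labels 0/1 vector; both classes required.
#' @return object of class `delong_result`: `auc1`, `auc2`, `delta`
#'   (= auc1 - auc2 exactly), `var_delta`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  labels <- as.integer(labels)
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels))
    stop("the two models must score the same patients")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("both classes must be present")
  c1 <- .delong_components(scores_1, labels)
  c2 <- .delong_components(scores_2, labels)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  v <- s10 / c1$m + s01 / c1$n
  var_delta <- v[1, 1] + v[2, 2] - 2 * v[1, 2]
  delta <- c1$auc - c2$auc
  if (!is.finite(var_delta) || var_delta < 1e-15) {
    z <- 0; p <- 1; degenerate <- TRUE
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
    degenerate <- FALSE
  }
  structure(list(auc1 = c1$auc, auc2 = c2$auc, delta = delta,
                 var_delta = var_delta, z = z, p = p,
                 degenerate = degenerate),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("delong_result: AUC %.4f vs %.4f, delta %.4f, z %.3f, p %.4g%s\n",
              x$auc1, x$auc2, x$delta, x$z, x$p,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
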