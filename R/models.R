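#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that every class is
#' spread as evenly as possible across folds.  Uses the current RNG
#' state.  Errors if any class has fewer members than folds (a fold would
#' be missing the class).
#'
#' @param labels class labels.
#' @param k number of folds.
#' @return integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k = 5L) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf("class '%s' has %d members, fewer than %d folds: %s",
                   cl, length(idx), k, "stratification impossible"))
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Spearman redundancy filter
#'
#' Among any group of features whose pairwise |Spearman rho| exceeds the
#' threshold, only one is retained.  The survivor is the feature with the
#' largest |Spearman rho| against the task label (for a multiclass label,
#' the maximum over one-vs-rest indicators), ties broken by column order;
#' elimination is greedy from the most label-relevant feature down.
#' Constant columns have no defined rank correlation and are dropped with
#' a warning.  After filtering, no surviving pair exceeds the threshold.
#'
#' @param features numeric matrix (rows = patients).
#' @param labels optional task labels driving the survivor rule; without
#'   labels, earlier columns win.
#' @param threshold redundancy cut on |rho| (default 0.8, strict).
#' @return the reduced matrix; `attr(,"dropped")` lists removed columns.
#' @export
spearman_filter <- function(features, labels = NULL, threshold = 0.8) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need >= 2 rows")
  const <- apply(features, 2, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(features)[const], collapse = ", "))
  }
  keep_cols <- which(!const)
  x <- features[, keep_cols, drop = FALSE]
  p <- ncol(x)
  if (p == 0L) stop("no non-constant features left")
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0
  relevance <- if (is.null(labels)) rev(seq_len(p)) else {
    labs <- as.character(labels)
    cls <- unique(labs)
    sapply(seq_len(p), function(j) {
      max(vapply(cls, function(cl)
        abs(suppressWarnings(stats::cor(x[, j], as.integer(labs == cl),
                                        method = "spearman"))),
        numeric(1)), na.rm = TRUE)
    })
  }
  relevance[!is.finite(relevance)] <- 0
  ord <- order(-relevance, seq_len(p))
  alive <- rep(TRUE, p)
  kept <- logical(p)
  for (j in ord) {
    if (!alive[j]) next
    kept[j] <- TRUE
    drop <- alive & abs(rho[j, ]) > threshold
    drop[j] <- FALSE
    alive[drop] <- FALSE
  }
  out <- x[, sort(which(kept)), drop = FALSE]
  attr(out, "dropped") <- setdiff(colnames(features), colnames(out))
  attr(out, "provenance") <- attr(features, "provenance")
  out
}

.is_binary_col <- function(x) all(x %in% c(0, 1))

.standardize_fit <- function(x) {
  bin <- apply(x, 2, .is_binary_col)
  center <- ifelse(bin, 0, colMeans(x))
  scale <- ifelse(bin, 1, apply(x, 2, stats::sd))
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

.standardize_apply <- function(x, st)
  sweep(sweep(x, 2, st$center), 2, st$scale, "/")

#' Macro-averaged F1 score
#' @param pred,truth vectors of class labels.
#' @param classes class set (defaults to classes in `truth`).
#' @return mean per-class F1 (classes with no predictions and no members
#'   contribute 0).
#' @export
macro_f1 <- function(pred, truth, classes = sort(unique(as.character(truth)))) {
  pred <- as.character(pred); truth <- as.character(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Fit an L1-penalized logistic task model with CV grid search
#'
#' Fits a lasso logistic regression (multinomial softmax for the 3-class
#' etiology task, binomial for prognosis) over a grid of 13 log-spaced
#' inverse penalty strengths C in \[1e-2, 1e2\].  The penalty is chosen by
#' stratified k-fold cross-validation maximizing the mean (macro) F1 of
#' the argmax prediction; ties prefer the sparser model.  Out-of-fold
#' class probabilities at the chosen penalty are retained for fusion and
#' ROC; the final model is refit on all rows.
#'
#' @param features numeric matrix, rows named by patient id.
#' @param labels class labels (3 classes for etiology, 2 for prognosis).
#' @param task `"etiology"` or `"prognosis"` (controls the family and F1
#'   flavor; inferred from the class count if missing).
#' @param folds number of CV folds.
#' @param seed integer seed (fold assignment).
#' @param C_grid inverse penalty strengths (mapped to glmnet lambda =
#'   1/(n C)).
#' @return object of class `model_report`: `oof_scores` (n x K matrix,
#'   rows sum to 1), `weights` (features x K signed coefficients),
#'   `lambda`, `C`, `cv` (grid summary), `fold_id`, standardization
#'   constants, the refit glmnet object, `classes`, `seed`.
#' @export
fit_task_model <- function(features, labels, task = NULL, folds = 5L,
                           seed = 1L,
                           C_grid = 10^seq(-2, 2, length.out = 13)) {
  features <- as.matrix(features)
  labels <- factor(labels)
  classes <- levels(labels)
  K <- length(classes)
  if (is.null(task)) task <- if (K == 3L) "etiology" else "prognosis"
  if (task == "etiology" && K != 3L)
    stop("the etiology task needs exactly 3 classes")
  if (task == "prognosis" && K != 2L)
    stop("the prognosis task needs exactly 2 classes")
  if (ncol(features) < 2L)
    stop("need >= 2 feature columns")
  n <- nrow(features)
  family <- if (K == 2L) "binomial" else "multinomial"
  lam_of <- function(C, m) 1 / (m * C)

  set.seed(as.integer(seed))
  fold_id <- stratified_folds(labels, folds)

  # CV: out-of-fold probabilities for every C
  oof <- array(NA_real_, c(n, K, length(C_grid)))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    st <- .standardize_fit(features[tr, , drop = FALSE])
    xtr <- .standardize_apply(features[tr, , drop = FALSE], st)
    xte <- .standardize_apply(features[!tr, , drop = FALSE], st)
    lams <- sort(unique(lam_of(C_grid, sum(tr))), decreasing = TRUE)
    fit <- glmnet::glmnet(xtr, labels[tr], family = family, alpha = 1,
                          standardize = FALSE, lambda = lams)
    for (ci in seq_along(C_grid)) {
      pr <- stats::predict(fit, xte, s = lam_of(C_grid[ci], sum(tr)),
                           type = "response", exact = FALSE)
      oof[!tr, , ci] <- if (family == "binomial")
        cbind(1 - pr[, 1], pr[, 1]) else pr[, , 1]
    }
  }
  cv_f1 <- vapply(seq_along(C_grid), function(ci) {
    mean(vapply(seq_len(folds), function(f) {
      idx <- fold_id == f
      sc <- matrix(oof[idx, , ci], ncol = K)
      pred <- classes[max.col(sc, ties.method = "first")]
      if (K == 2L) {
        truth <- as.character(labels[idx])
        tp <- sum(pred == classes[2] & truth == classes[2])
        fp <- sum(pred == classes[2] & truth != classes[2])
        fn <- sum(pred != classes[2] & truth == classes[2])
        if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      } else macro_f1(pred, labels[idx], classes)
    }, numeric(1)))
  }, numeric(1))
  best <- which(cv_f1 >= max(cv_f1) - 1e-12)
  ci <- best[which.min(C_grid[best])]          # sparser model on ties

  st <- .standardize_fit(features)
  xall <- .standardize_apply(features, st)
  lams <- sort(unique(lam_of(C_grid, n)), decreasing = TRUE)
  fit <- glmnet::glmnet(xall, labels, family = family, alpha = 1,
                        standardize = FALSE, lambda = lams)
  lam <- lam_of(C_grid[ci], n)
  co <- stats::coef(fit, s = lam)
  weights <- if (family == "binomial") {
    w <- as.matrix(co)[-1, 1, drop = FALSE]
    colnames(w) <- classes[2]
    w
  } else {
    w <- do.call(cbind, lapply(co, function(cc) as.matrix(cc)[-1, 1]))
    colnames(w) <- classes
    w
  }
  oof_best <- oof[, , ci]
  dimnames(oof_best) <- list(rownames(features), classes)
  structure(list(task = task, classes = classes, lambda = lam,
                 C = C_grid[ci],
                 cv = data.frame(C = C_grid, mean_f1 = cv_f1),
                 oof_scores = oof_best / rowSums(oof_best),
                 fold_id = fold_id, weights = weights,
                 feature_names = colnames(features),
                 standardization = st, fit = fit,
                 seed = as.integer(seed)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(paste0("model_report (%s): %d features, C = %.3g, ",
                     "%d nonzero weights, CV F1 = %.3f\n"),
              x$task, length(x$feature_names), x$C,
              sum(rowSums(abs(x$weights)) > 0),
              max(x$cv$mean_f1)))
  invisible(x)
}

#' Predict class probabilities from a fitted task model
#'
#' @param object a `model_report`.
#' @param newdata matrix with the model's feature columns.
#' @param ... unused.
#' @return n x K probability matrix (rows sum to 1).
#' @export
predict.model_report <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  x <- .standardize_apply(newdata, object$standardization)
  pr <- stats::predict(object$fit, x, s = object$lambda, type = "response")
  out <- if (length(object$classes) == 2L)
    cbind(1 - pr[, 1], pr[, 1]) else pr[, , 1]
  dimnames(out) <- list(rownames(newdata), object$classes)
  out / rowSums(out)
}

#' Score-averaging model fusion
#'
#' The fused score of a patient for a class is the arithmetic mean of the
#' component models' scores, renormalized so each patient's fused scores
#' sum to 1 over classes.  When `model_report`s are fused their
#' out-of-fold scores are used and patients, classes and fold assignments
#' must agree.
#'
#' @param reports list of `model_report`s, or of n x K score matrices with
#'   matching dimnames.
#' @return fused n x K score matrix.
#' @export
fuse <- function(reports) {
  if (length(reports) < 1L) stop("nothing to fuse")
  mats <- lapply(reports, function(r)
    if (inherits(r, "model_report")) r$oof_scores else as.matrix(r))
  ref <- mats[[1]]
  for (i in seq_along(mats)[-1]) {
    if (!identical(rownames(mats[[i]]), rownames(ref)) ||
        !identical(colnames(mats[[i]]), colnames(ref)))
      stop("score matrices are not aligned on the same patients/classes")
  }
  if (all(vapply(reports, inherits, logical(1), "model_report"))) {
    fids <- lapply(reports, `[[`, "fold_id")
    if (!all(vapply(fids, identical, logical(1), fids[[1]])))
      stop("models were cross-validated with different fold assignments")
  }
  fused <- Reduce(`+`, mats) / length(mats)
  fused / rowSums(fused)
}

# --- full study protocol --------------------------------------------------

#' Clinical feature matrix from the cohort's clinical table
#'
#' @param clinical the `clinical` data.frame of an `ich_cohort`.
#' @return numeric matrix (age, female, hypertension_history, diabetes,
#'   smoking, gcs), rows named by patient id, provenance `"clinical"`.
#' @export
clinical_features <- function(clinical) {
  m <- as.matrix(clinical[, c("age", "female", "hypertension_history",
                              "diabetes", "smoking", "gcs")])
  rownames(m) <- clinical$patient_id
  attr(m, "provenance") <- "clinical"
  m
}

#' Run the full etiology + prognosis modeling study on a cohort
#'
#' Implements the multicenter protocol: models are developed on the
#' center-1 subset (Spearman redundancy filter at 0.8, L1 logistic
#' regression with 5-fold CV grid search on F1, score-averaging fusion of
#' the component models) and evaluated frozen on centers 2 and 3.  The
#' etiology task (3 classes; patients with unknown etiology excluded)
#' uses clinical, location and fused clinical+location models; the
#' prognosis task (poor outcome = mRS 3-6) adds the attention-pooled
#' radiomics model and the three-way fusion.
#'
#' @param cohort an `ich_cohort`.
#' @param tasks subset of `c("etiology", "prognosis")`.
#' @param folds CV folds on the development set.
#' @param seed integer seed (folds, pooler training).
#' @param spearman_threshold redundancy cut (default 0.8).
#' @param involvement_threshold strict region-involvement cut (default 0.20).
#' @param bin_width radiomics discretization width.
#' @param C_grid penalty grid, see [fit_task_model()].
#' @return object of class `ich_study`: per task, the fitted
#'   `model_report`s, fused development scores, and per-dataset
#'   evaluations (AUC, confusion, DeLong fusion-vs-component).
#' @export
run_study <- function(cohort, tasks = c("etiology", "prognosis"),
                      folds = 5L, seed = 1L, spearman_threshold = 0.8,
                      involvement_threshold = 0.20, bin_width = 5,
                      C_grid = 10^seq(-2, 2, length.out = 13)) {
  stopifnot(inherits(cohort, "ich_cohort"))
  clin <- cohort$clinical
  if (!"center" %in% names(clin)) stop("clinical table lacks a center id")
  small <- table(clin$center)
  if (any(small < 20))
    warning("center(s) with < 20 patients: ",
            paste(names(small)[small < 20], collapse = ", "))

  loc_all <- location_features(cohort, threshold = involvement_threshold)
  rownames(loc_all) <- clin$patient_id
  cli_all <- clinical_features(clin)
  dev <- clin$center == 1
  study <- list(seed = as.integer(seed), tasks = list())

  run_task <- function(task) {
    if (task == "etiology") {
      keep <- clin$etiology != "unknown"
      n_excl <- sum(!keep)
      if (n_excl > 0)
        message(n_excl, " patients with unknown etiology excluded")
      labels <- factor(clin$etiology[keep])
      sets <- list(clinical = cli_all[keep, , drop = FALSE],
                   location = loc_all[keep, , drop = FALSE])
      use_dev <- dev[keep]
    } else {
      keep <- rep(TRUE, nrow(clin))
      labels <- factor(ifelse(clin$poor_outcome == 1, "poor", "good"),
                       levels = c("good", "poor"))
      sets <- list(clinical = cli_all, location = loc_all)
      use_dev <- dev
      # radiomics: pooler trained on development-set prognosis labels
      lf <- extract_radiomics(cohort, bin_width = bin_width)
      ok <- vapply(lf[, setdiff(names(lf), c("patient_id", "lesion_id"))],
                   function(x) all(is.finite(x)), logical(1))
      lf <- lf[, c("patient_id", "lesion_id",
                   names(ok)[ok]), drop = FALSE]
      bags <- lesion_bags(lf, patient_ids = clin$patient_id)
      pooler <- train_pooler(bags[clin$patient_id[dev]],
                             clin$poor_outcome[dev], folds = folds,
                             seed = seed)
      rad <- pool_cohort(bags, pooler)[clin$patient_id, , drop = FALSE]
      sets$radiomics <- rad
      study$pooler <<- pooler
    }
    ids <- clin$patient_id[keep]

    reports <- lapply(sets, function(x) {
      xd <- spearman_filter(x[use_dev, , drop = FALSE],
                            labels = labels[use_dev],
                            threshold = spearman_threshold)
      fit_task_model(xd, labels[use_dev], task = task, folds = folds,
                     seed = seed, C_grid = C_grid)
    })
    fused_dev <- fuse(reports)

    eval_scores <- function(comp, truth) {
      aucs <- vapply(comp, function(m) score_auc(m, truth), numeric(1))
      dl <- lapply(names(reports), function(nm)
        score_delong(comp$fusion, comp[[nm]], truth))
      names(dl) <- paste0("fusion_vs_", names(reports))
      list(n = length(truth), auc = aucs,
           confusion = confusion(comp$fusion, truth),
           delong = dl, scores = comp)
    }
    # dataset 1: internal CV (out-of-fold scores of the development set)
    comp_dev <- lapply(reports, `[[`, "oof_scores")
    comp_dev$fusion <- fused_dev
    evals <- list(dataset1 = eval_scores(comp_dev, labels[use_dev]))
    # datasets 2 and 3: frozen models on held-out centers
    for (ct in c(2, 3)) {
      sel <- clin$center[keep] == ct
      if (sum(sel) > 0) {
        comp <- lapply(names(sets), function(nm)
          predict(reports[[nm]], sets[[nm]][sel, , drop = FALSE]))
        names(comp) <- names(sets)
        comp$fusion <- fuse(comp)
        evals[[paste0("dataset", ct)]] <- eval_scores(comp, labels[sel])
      }
    }
    list(task = task, labels = labels, patient_ids = ids,
         models = reports, fused_dev = fused_dev, evaluation = evals)
  }

  for (task in tasks) study$tasks[[task]] <- run_task(task)
  class(study) <- "ich_study"
  study
}

# macro one-vs-rest AUC for K >= 3, plain AUC for binary score matrices
score_auc <- function(scores, truth) {
  K <- ncol(scores)
  if (K == 2L) {
    roc_curve(scores[, 2], as.integer(truth == colnames(scores)[2]))$auc
  } else {
    curves <- lapply(colnames(scores), function(cl)
      roc_curve(scores[, cl], as.integer(truth == cl)))
    macro_roc(curves)$auc
  }
}

# DeLong comparison; for 3 classes, per one-vs-rest class
score_delong <- function(s1, s2, truth) {
  K <- ncol(s1)
  if (K == 2L) {
    delong_test(s1[, 2], s2[, 2],
                as.integer(truth == colnames(s1)[2]))
  } else {
    out <- lapply(colnames(s1), function(cl)
      delong_test(s1[, cl], s2[, cl], as.integer(truth == cl)))
    names(out) <- colnames(s1)
    out
  }
}

#' Signed feature weights of a fitted model as a tidy table
#' @param report a `model_report`.
#' @return data.frame with `feature`, `class`, `weight` (nonzero only).
#' @export
report_weights <- function(report) {
  w <- report$weights
  out <- data.frame(feature = rep(rownames(w), ncol(w)),
                    class = rep(colnames(w), each = nrow(w)),
                    weight = as.vector(w), stringsAsFactors = FALSE)
  out <- out[out$weight != 0, ]
  rownames(out) <- NULL
  out[order(out$class, -abs(out$weight)), ]
}
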