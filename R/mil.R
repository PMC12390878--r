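# Gated-attention multiple-instance pooling.
#
# Per lesion l with standardized feature row h_l:
#   score  e_l = w' ( tanh(V h_l) * sigmoid(U h_l) )
#   weight a_l = softmax over the lesions of the same patient (bag)
#   pooled z_b = sum_l a_l x_l          (x_l = raw feature row)
# A logistic head on z (computed on standardized pooled features) gives a
# poor-outcome probability; training minimizes the mean cross-entropy by
# full-batch BFGS with analytic gradients, so runs are reproducible.

.mil_unpack <- function(theta, d, H) {
  i <- 0L
  V <- matrix(theta[i + seq_len(H * d)], H, d); i <- i + H * d
  U <- matrix(theta[i + seq_len(H * d)], H, d); i <- i + H * d
  w <- theta[i + seq_len(H)]; i <- i + H
  beta <- theta[i + seq_len(d)]; i <- i + d
  b0 <- theta[i + 1L]
  list(V = V, U = U, w = w, beta = beta, b0 = b0)
}

.mil_nparam <- function(d, H) 2L * H * d + H + d + 1L

# forward pass on standardized lesion matrix X (L x d), bag ids g
.mil_forward <- function(par, X, g) {
  A1 <- X %*% t(par$V)                 # L x H
  A2 <- X %*% t(par$U)
  H1 <- tanh(A1)
  H2 <- stats::plogis(A2)
  G <- H1 * H2
  e <- as.vector(G %*% par$w)
  emax <- stats::ave(e, g, FUN = max)
  ex <- exp(e - emax)
  den <- rowsum(ex, g)
  gi <- match(g, rownames(den))
  a <- ex / den[gi]
  Z <- rowsum(a * X, g)                # B x d (bag order = sorted unique g)
  logit <- as.vector(Z %*% par$beta) + par$b0
  list(H1 = H1, H2 = H2, G = G, e = e, a = a, gi = gi, Z = Z,
       logit = logit, bag_ids = rownames(den))
}

# loss + gradient; y ordered like sorted unique bag ids
.mil_loss_grad <- function(theta, X, g, y, lambda, d, H) {
  par <- .mil_unpack(theta, d, H)
  fw <- .mil_forward(par, X, g)
  p <- stats::plogis(fw$logit)
  B <- length(y)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)) +
    lambda / 2 * (sum(par$V^2) + sum(par$U^2) + sum(par$w^2) +
                    sum(par$beta^2))
  dlogit <- (p - y) / B                          # B
  dbeta <- as.vector(t(fw$Z) %*% dlogit) + lambda * par$beta
  db0 <- sum(dlogit)
  # dz_b = dlogit_b * beta ; da_l = x_l . dz_{bag(l)}
  da <- dlogit[fw$gi] * as.vector(X %*% par$beta)
  sum_ada <- rowsum(fw$a * da, g)
  de <- fw$a * (da - sum_ada[fw$gi])
  dw <- as.vector(t(fw$G) %*% de) + lambda * par$w
  dG <- outer(de, par$w)                         # L x H
  dA1 <- dG * fw$H2 * (1 - fw$H1^2)
  dA2 <- dG * fw$H1 * fw$H2 * (1 - fw$H2)
  dV <- t(dA1) %*% X + lambda * par$V
  dU <- t(dA2) %*% X + lambda * par$U
  # attention acts on standardized X; pooled Z also uses standardized X here
  list(loss = loss, grad = c(as.vector(dV), as.vector(dU), dw, dbeta, db0))
}

.mil_fit <- function(theta0, X, g, y, lambda, d, H, maxit) {
  fn <- function(th) .mil_loss_grad(th, X, g, y, lambda, d, H)$loss
  gr <- function(th) .mil_loss_grad(th, X, g, y, lambda, d, H)$grad
  stats::optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
}

.bag_stack <- function(bags) {
  X <- do.call(rbind, bags)
  g <- rep(sprintf("B%06d", seq_along(bags)),
           vapply(bags, nrow, integer(1)))
  list(X = X, g = g)
}

.bag_loss <- function(par, bags, y, center, scale) {
  st <- .bag_stack(bags)
  Xs <- sweep(sweep(st$X, 2, center), 2, scale, "/")
  fw <- .mil_forward(par, Xs, st$g)
  p <- stats::plogis(fw$logit)
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train an attention-based multiple-instance pooler
#'
#' Learns gated-attention weights over each patient's lesions by
#' minimizing the cross-entropy of a logistic head on the pooled vectors
#' against the (binary) prognosis label.  Features are standardized on
#' the training bags; the weight-decay strength is chosen from a small
#' grid by stratified 5-fold cross-validated loss and the pooler is refit
#' on all bags at the chosen value.  Deterministic given `seed`.
#'
#' @param bags list of numeric matrices (lesions x features), one per
#'   patient; all with the same (named) columns.
#' @param labels 0/1 outcome per bag; both classes required.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed (initialization and fold assignment).
#' @param hidden attention hidden width (default 16).
#' @param lambda_grid weight-decay candidates.
#' @param maxit BFGS iteration cap per fit.
#' @return object of class `attention_pooler`: parameters, `center`/
#'   `scale`, `feature_names`, chosen `lambda`, `cv` summary, `folds`
#'   assignment, final training `loss`.
#' @export
train_pooler <- function(bags, labels, folds = 5L, seed = 1L, hidden = 16L,
                         lambda_grid = c(1e-3, 1e-2, 1e-1), maxit = 150L) {
  if (length(bags) < 20L) stop("need >= 20 bags to train the pooler")
  if (length(labels) != length(bags)) stop("one label per bag required")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present to train")
  d <- ncol(bags[[1]])
  if (any(vapply(bags, ncol, integer(1)) != d))
    stop("all bags must share the feature dimension")
  X_all <- do.call(rbind, bags)
  center <- colMeans(X_all)
  scale <- apply(X_all, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  std <- function(bs) lapply(bs, function(b)
    sweep(sweep(b, 2, center), 2, scale, "/"))
  bags_s <- std(bags)

  set.seed(as.integer(seed))
  theta0 <- stats::rnorm(.mil_nparam(d, hidden), 0, 0.1)
  fold_id <- stratified_folds(labels, folds)

  cv <- sapply(lambda_grid, function(lam) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      st <- .bag_stack(bags_s[tr])
      yb <- labels[tr][order(sprintf("B%06d", seq_len(sum(tr))))]
      fit <- .mil_fit(theta0, st$X, st$g, yb, lam, d, hidden, maxit)
      par <- .mil_unpack(fit$par, d, hidden)
      .bag_loss(par, bags[!tr], labels[!tr], center, scale)
    }, numeric(1)))
  })
  lambda <- lambda_grid[which.min(cv)]

  st <- .bag_stack(bags_s)
  y_sorted <- labels[order(sprintf("B%06d", seq_along(bags)))]
  fit <- .mil_fit(theta0, st$X, st$g, y_sorted, lambda, d, hidden, maxit)
  par <- .mil_unpack(fit$par, d, hidden)
  structure(c(par,
              list(hidden = hidden, center = center, scale = scale,
                   feature_names = colnames(bags[[1]]), lambda = lambda,
                   cv = data.frame(lambda = lambda_grid, cv_loss = cv),
                   folds = fold_id, loss = fit$value,
                   seed = as.integer(seed))),
            class = "attention_pooler")
}

#' Attention weights for one bag
#'
#' Nonnegative weights over the bag's lesions, summing to 1, computed
#' from the pooler's gated-attention score on standardized features.
#'
#' @param bag lesions-x-features matrix.
#' @param pooler a trained [train_pooler()] result.
#' @return numeric vector, one weight per lesion.
#' @export
attention_weights <- function(bag, pooler) {
  stopifnot(inherits(pooler, "attention_pooler"))
  bag <- as.matrix(bag)
  if (ncol(bag) != length(pooler$beta))
    stop(sprintf("bag has %d features but the pooler expects %d",
                 ncol(bag), length(pooler$beta)))
  Xs <- sweep(sweep(bag, 2, pooler$center), 2, pooler$scale, "/")
  e <- as.vector((tanh(Xs %*% t(pooler$V)) *
                    stats::plogis(Xs %*% t(pooler$U))) %*% pooler$w)
  ex <- exp(e - max(e))
  ex / sum(ex)
}

#' Pool a bag of lesion vectors into one patient-level vector
#'
#' The pooled vector is the attention-weighted sum of the raw per-lesion
#' feature rows — a convex combination, so a single-lesion bag pools to
#' exactly that lesion's vector whatever the pooler's state.
#'
#' @param bag lesions-x-features matrix.
#' @param pooler a trained [train_pooler()] result.
#' @return named numeric vector of patient-level features.
#' @export
pool <- function(bag, pooler) {
  bag <- as.matrix(bag)
  a <- attention_weights(bag, pooler)
  out <- as.vector(t(bag) %*% a)
  names(out) <- colnames(bag)
  out
}

#' Per-patient bags from a per-lesion radiomics table
#'
#' @param lesion_features data.frame from [extract_radiomics()].
#' @param patient_ids optional vector fixing the bag order (defaults to
#'   order of first appearance).
#' @return named list of matrices, one bag per patient.
#' @export
lesion_bags <- function(lesion_features, patient_ids = NULL) {
  featcols <- setdiff(names(lesion_features), c("patient_id", "lesion_id"))
  ids <- patient_ids %||% unique(lesion_features$patient_id)
  out <- lapply(ids, function(p) {
    as.matrix(lesion_features[lesion_features$patient_id == p, featcols,
                              drop = FALSE])
  })
  names(out) <- ids
  out[vapply(out, nrow, integer(1)) > 0L]
}

#' Patient-level radiomics matrix via attention pooling
#'
#' @param bags named list of per-patient lesion matrices.
#' @param pooler a trained [train_pooler()] result.
#' @return patients x features matrix with
#'   `attr(,"provenance") = "radiomics"`.
#' @export
pool_cohort <- function(bags, pooler) {
  m <- t(vapply(bags, pool, numeric(length(pooler$beta)), pooler = pooler))
  rownames(m) <- names(bags)
  colnames(m) <- pooler$feature_names
  attr(m, "provenance") <- "radiomics"
  m
}

#' @export
print.attention_pooler <- function(x, ...) {
  cat(sprintf(paste0("attention_pooler: %d features, hidden %d, ",
                     "lambda %.3g, training loss %.4f\n"),
              length(x$beta), x$hidden, x$lambda, x$loss))
  invisible(x)
}
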