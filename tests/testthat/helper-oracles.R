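# independent brute-force / closed-form oracles shared across test files

brute_glcm_matrix <- function(lev) {
  dm <- dim(lev)
  L <- max(lev, na.rm = TRUE)
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  acc <- matrix(0, L, L); used <- 0L
  half <- dirs[dirs[, 1] > 0 | (dirs[, 1] == 0 & dirs[, 2] > 0) |
                 (dirs[, 1] == 0 & dirs[, 2] == 0 & dirs[, 3] > 0), ,
               drop = FALSE]
  for (d in seq_len(nrow(half))) {
    m <- matrix(0, L, L)
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
      for (k in seq_len(dm[3])) {
        a <- lev[i, j, k]
        ii <- i + half[d, 1]; jj <- j + half[d, 2]; kk <- k + half[d, 3]
        if (is.na(a) || ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
            kk < 1 || kk > dm[3]) next
        b <- lev[ii, jj, kk]
        if (is.na(b)) next
        m[a, b] <- m[a, b] + 1
        m[b, a] <- m[b, a] + 1
      }
    if (sum(m) > 0) { acc <- acc + m / sum(m); used <- used + 1L }
  }
  acc / used
}

glcm_from_matrix <- function(p) {
  i <- row(p); j <- col(p)
  L <- nrow(p)
  pi_ <- rowSums(p)
  mu <- sum(seq_len(L) * pi_)
  sig2 <- sum((seq_len(L) - mu)^2 * pi_)
  nz <- p[p > 0]
  c(contrast = sum((i - j)^2 * p),
    correlation = if (sig2 > 1e-12) sum((i - mu) * (j - mu) * p) / sig2 else 1,
    joint_entropy = -sum(nz * log2(nz)),
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    dissimilarity = sum(abs(i - j) * p))
}

brute_dependence <- function(lev) {
  dm <- dim(lev)
  out <- c()
  lv <- c()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      if (is.na(lev[i, j, k])) next
      dep <- 0L
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
            kk < 1 || kk > dm[3]) next
        if (!is.na(lev[ii, jj, kk]) && lev[ii, jj, kk] == lev[i, j, k])
          dep <- dep + 1L
      }
      out <- c(out, dep); lv <- c(lv, lev[i, j, k])
    }
  list(level = lv, dep = out)
}

gldm_from_counts <- function(level, dep) {
  nz <- length(level)
  m <- table(level = level, dependence = dep + 1L)
  jj <- as.integer(colnames(m))
  p <- as.vector(m) / nz
  pm <- matrix(p, nrow(m), ncol(m))
  c(small_dependence_emphasis = sum(sweep(pm, 2, jj^2, "/")),
    large_dependence_emphasis = sum(sweep(pm, 2, jj^2, "*")),
    gray_level_nonuniformity = sum(rowSums(m)^2) / nz,
    dependence_nonuniformity = sum(colSums(m)^2) / nz,
    dependence_entropy = { q <- p[p > 0]; -sum(q * log2(q)) })
}

make_planted_bags <- function(n_bags, d = 5L, signal = 3, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n_bags)
  bags <- vector("list", n_bags)
  informative <- integer(n_bags)
  for (b in seq_len(n_bags)) {
    m <- matrix(rnorm(3 * d), 3, d)
    informative[b] <- sample(3, 1)
    # feature 1 of the informative lesion carries the label signal
    m[informative[b], 1] <- signal * (2 * labels[b] - 1) + rnorm(1, 0, 0.5)
    # decoys carry an off-signal marker in feature 2 so attention can
    # tell lesion types apart
    m[-informative[b], 2] <- m[-informative[b], 2] + 2
    colnames(m) <- paste0("f", seq_len(d))
    bags[[b]] <- m
  }
  list(bags = bags, labels = labels, informative = informative)
}

greedy_filter_oracle <- function(x, relevance, threshold = 0.8) {
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0
  alive <- rep(TRUE, ncol(x))
  kept <- c()
  ord <- order(-relevance, seq_len(ncol(x)))
  for (j in ord) {
    if (!alive[j]) next
    kept <- c(kept, j)
    for (k in which(alive)) {
      if (k != j && abs(rho[j, k]) > threshold) alive[k] <- FALSE
    }
  }
  sort(kept)
}

all_pairs_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
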