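# 13 unique direction pairs at Chebyshev distance 1 (half of the 26
# neighbors, lexicographically positive representatives)
.dirs13 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  unname(g[keep, , drop = FALSE])
})

.dirs26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
})

#' Fixed-bin-width gray-level discretization
#'
#' Maps intensities to integer levels `floor((x - min(x))/bin_width) + 1`,
#' anchored at the lesion minimum, the recommended scheme for CT-like
#' calibrated intensities.  The level range starts at 1; a constant lesion
#' occupies the single level 1.
#'
#' @param x numeric vector of in-mask intensities.
#' @param bin_width positive bin width (same units as `x`).
#' @return integer vector of gray levels; `attr(,"n_levels")` records the
#'   number of levels, `attr(,"bin_width")` the width used.
#' @export
discretize <- function(x, bin_width = 5) {
  if (length(x) == 0L) stop("empty lesion: no intensities to discretize")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0")
  lev <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  attr(lev, "n_levels") <- max(lev)
  attr(lev, "bin_width") <- bin_width
  lev
}

#' First-order intensity statistics of a lesion
#'
#' Moments use population (n-denominator) definitions; skewness and
#' kurtosis (non-excess) are reported as 0 for constant lesions; entropy
#' is computed on the fixed-bin-width histogram in bits.
#'
#' @param x numeric vector of in-mask intensities (>= 1 voxel).
#' @param bin_width histogram bin width for the entropy term.
#' @return named numeric vector:
#'   mean, variance, skewness, kurtosis, energy, entropy, min, max,
#'   range, p10, p90.
#' @export
first_order <- function(x, bin_width = 5) {
  if (length(x) == 0L) stop("empty lesion")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  lev <- discretize(x, bin_width)
  p <- tabulate(lev) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  c(mean = mu, variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(x^2), entropy = -sum(p * log2(p)),
    min = min(x), max = max(x), range = max(x) - min(x),
    p10 = q[1], p90 = q[2])
}

# bounding-box array of per-voxel values with NA outside the mask
.les_array <- function(voxels, values, dm) {
  co <- arrayInd(voxels, dm)
  lo <- apply(co, 2, min); hi <- apply(co, 2, max)
  bb <- hi - lo + 1L
  a <- array(NA_real_, bb)
  a[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L,
          co[, 3] - lo[3] + 1L)] <- values
  a
}

# subarray index ranges for an offset pair (source, shifted)
.shift_ranges <- function(dm, o) {
  src <- vector("list", 3); dst <- vector("list", 3)
  for (i in 1:3) {
    if (o[i] >= 0) { src[[i]] <- 1:(dm[i] - o[i]); dst[[i]] <- (1 + o[i]):dm[i] }
    else           { src[[i]] <- (1 - o[i]):dm[i]; dst[[i]] <- 1:(dm[i] + o[i]) }
    if (dm[i] - abs(o[i]) < 1) return(NULL)
  }
  list(src = src, dst = dst)
}

#' Gray-level co-occurrence features
#'
#' Co-occurrences are counted over the 13 unique 3D directions at
#' distance 1, symmetrized, each direction's matrix normalized, and the
#' normalized matrices averaged; features are computed on the averaged
#' matrix.  A single-level image has correlation 1 by convention.
#'
#' @param lev 3D array of integer gray levels with `NA` outside the mask,
#'   or a list as produced internally by [extract_radiomics()].
#' @return named numeric vector: contrast, correlation, joint_entropy,
#'   energy, homogeneity, dissimilarity.
#' @export
glcm_features <- function(lev) {
  dm <- dim(lev)
  L <- max(lev, na.rm = TRUE)
  acc <- matrix(0, L, L)
  used <- 0L
  for (d in seq_len(nrow(.dirs13))) {
    rg <- .shift_ranges(dm, .dirs13[d, ])
    if (is.null(rg)) next
    v1 <- lev[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
    v2 <- lev[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]]
    ok <- !is.na(v1) & !is.na(v2)
    if (!any(ok)) next
    cnt <- tabulate((v1[ok] - 1L) * L + v2[ok], nbins = L * L)
    m <- matrix(cnt, L, L, byrow = TRUE)
    m <- m + t(m)                               # symmetrize
    acc <- acc + m / sum(m)
    used <- used + 1L
  }
  if (used == 0L) stop("lesion too small for co-occurrence counting")
  p <- acc / used
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p)
  mu <- sum(seq_len(L) * pi_)
  sig2 <- sum((seq_len(L) - mu)^2 * pi_)
  corr <- if (sig2 > 1e-12) sum((i - mu) * (j - mu) * p) / sig2 else 1
  nz <- p[p > 0]
  c(contrast = sum((i - j)^2 * p),
    correlation = corr,
    joint_entropy = -sum(nz * log2(nz)),
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    dissimilarity = sum(abs(i - j) * p))
}

# per-voxel count of 26-neighbors satisfying pred (in-mask & level match)
.neighbor_stats <- function(lev) {
  dm <- dim(lev)
  nsum <- array(0, dm); ncnt <- array(0L, dm); ndep <- array(0L, dm)
  for (d in seq_len(nrow(.dirs26))) {
    rg <- .shift_ranges(dm, .dirs26[d, ])
    if (is.null(rg)) next
    nb <- array(NA_real_, dm)
    nb[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
      lev[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
    ok <- !is.na(nb)
    nsum[ok] <- nsum[ok] + nb[ok]
    ncnt[ok] <- ncnt[ok] + 1L
    same <- ok & !is.na(lev) & nb == lev
    ndep[same] <- ndep[same] + 1L
  }
  list(sum = nsum, count = ncnt, dep = ndep)
}

#' Gray-level dependence matrix features
#'
#' The dependence of a voxel is the number of its 26-neighbors (inside
#' the mask) whose gray level differs by at most `alpha`; the matrix
#' counts voxels by (level, dependence + 1) and the five IBSI statistics
#' are computed from it.
#'
#' @param lev 3D gray-level array with `NA` outside the mask.
#' @param alpha dependence tolerance in gray levels (default 0).
#' @return named numeric vector: small_dependence_emphasis,
#'   large_dependence_emphasis, gray_level_nonuniformity,
#'   dependence_nonuniformity, dependence_entropy.
#' @export
gldm_features <- function(lev, alpha = 0) {
  inm <- which(!is.na(lev))
  if (length(inm) == 0L) stop("empty lesion")
  if (alpha == 0) {
    ns <- .neighbor_stats(lev)
    dep <- ns$dep[inm]
  } else {
    dm <- dim(lev)
    dep <- integer(length(inm))
    depa <- array(0L, dm)
    for (d in seq_len(nrow(.dirs26))) {
      rg <- .shift_ranges(dm, .dirs26[d, ])
      if (is.null(rg)) next
      nb <- array(NA_real_, dm)
      nb[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
        lev[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
      ok <- !is.na(nb) & !is.na(lev) & abs(nb - lev) <= alpha
      depa[ok] <- depa[ok] + 1L
    }
    dep <- depa[inm]
  }
  g <- lev[inm]
  nz <- length(inm)
  m <- table(level = g, dependence = dep + 1L)
  jj <- as.integer(colnames(m))
  p <- as.vector(m) / nz
  pm <- matrix(p, nrow(m), ncol(m))
  c(small_dependence_emphasis =
      sum(sweep(pm, 2, jj^2, "/")),
    large_dependence_emphasis =
      sum(sweep(pm, 2, jj^2, "*")),
    gray_level_nonuniformity = sum(rowSums(m)^2) / nz,
    dependence_nonuniformity = sum(colSums(m)^2) / nz,
    dependence_entropy = { q <- p[p > 0]; -sum(q * log2(q)) })
}

#' Neighborhood gray-tone difference features
#'
#' For every in-mask voxel the absolute difference between its level and
#' the mean level of its valid 26-neighborhood is accumulated per level
#' (the s-vector); the five IBSI statistics follow.  A lesion occupying a
#' single gray level has contrast 0 by convention.
#'
#' @param lev 3D gray-level array with `NA` outside the mask.
#' @return named numeric vector: coarseness, contrast, busyness,
#'   complexity, strength.
#' @export
ngtdm_features <- function(lev) {
  inm <- which(!is.na(lev))
  if (length(inm) < 2L) stop("need >= 2 voxels")
  ns <- .neighbor_stats(lev)
  ok <- inm[ns$count[inm] > 0L]
  g <- lev[ok]
  abar <- ns$sum[ok] / ns$count[ok]
  L <- max(lev, na.rm = TRUE)
  n_i <- tabulate(g, nbins = L)
  s_i <- vapply(seq_len(L), function(i)
    sum(abs(i - abar[g == i])), numeric(1))
  N <- length(ok)
  p_i <- n_i / N
  pres <- which(p_i > 0)
  ngp <- length(pres)
  ii <- pres
  coarse_den <- sum(p_i[pres] * s_i[pres])
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[pres], p_i[pres]) * outer(ii, ii, "-")^2) /
       (ngp * (ngp - 1))) * (sum(s_i) / N)
  } else 0
  busy_den <- sum(abs(outer(ii * p_i[pres], ii * p_i[pres], "-")))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  pij <- outer(p_i[pres], p_i[pres], "+")
  sij <- outer(p_i[pres] * s_i[pres], p_i[pres] * s_i[pres], "+")
  complexity <- sum(abs(outer(ii, ii, "-")) * sij / pij) / N
  s_sum <- sum(s_i)
  strength <- if (s_sum > 0)
    sum(pij * outer(ii, ii, "-")^2) / s_sum else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' Shape features of a binary lesion
#'
#' Mesh volume and surface area come from a marching-tetrahedra
#' triangulation of the 0.5 isosurface (see [mesh_volume_area()]);
#' sphericity is \eqn{(36\pi V^2)^{1/3} / A}; the maximum 3D diameter is
#' the largest pairwise distance between surface voxel centers.  Lesions
#' with fewer than 8 voxels are not meshed: their mesh volume falls back
#' to the voxel-count volume (flagged via `meshed = 0`).
#'
#' @param voxels linear voxel indices of the lesion.
#' @param dm grid dimensions.
#' @param voxel_size edge length of a voxel (default 1; volumes scale with
#'   its cube).
#' @return named numeric vector: voxel_volume, mesh_volume, surface_area,
#'   sphericity, max_diameter3d, meshed.
#' @export
shape_features <- function(voxels, dm, voxel_size = 1) {
  n <- length(voxels)
  if (n == 0L) stop("empty lesion")
  co <- arrayInd(voxels, dm)
  lo <- apply(co, 2, min); bb <- apply(co, 2, max) - lo + 1L
  m <- array(0L, bb)
  m[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L,
          co[, 3] - lo[3] + 1L)] <- 1L
  vv <- n * voxel_size^3
  if (n >= 8L) {
    ms <- mesh_volume_area(m)
    mv <- ms$volume * voxel_size^3
    sa <- ms$area * voxel_size^2
    meshed <- 1
  } else {
    mv <- vv
    # exposed-face surface as the unmeshed fallback
    faces <- 0L
    for (d in 1:3) {
      o <- c(0L, 0L, 0L); o[d] <- 1L
      rg <- .shift_ranges(bb, o)
      inner <- if (is.null(rg)) 0L else
        sum(m[rg$src[[1]], rg$src[[2]], rg$src[[3]]] *
              m[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]])
      faces <- faces + 2L * n - 2L * inner
    }
    sa <- faces * voxel_size^2
    meshed <- 0
  }
  # surface voxels: at least one 6-neighbor outside
  surf <- rep(FALSE, n)
  idx <- cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L,
               co[, 3] - lo[3] + 1L)
  for (d in 1:3) for (sgn in c(-1L, 1L)) {
    nb <- idx; nb[, d] <- nb[, d] + sgn
    out <- nb[, d] < 1L | nb[, d] > bb[d]
    inside <- !out
    val <- rep(0L, n)
    val[inside] <- m[nb[inside, , drop = FALSE]]
    surf <- surf | val == 0L
  }
  sc <- co[surf, , drop = FALSE]
  maxd <- if (nrow(sc) >= 2) max(stats::dist(sc)) * voxel_size else 0
  c(voxel_volume = vv, mesh_volume = mv, surface_area = sa,
    sphericity = if (sa > 0) (36 * pi * mv^2)^(1 / 3) / sa else 1,
    max_diameter3d = maxd, meshed = meshed)
}

#' Connected components of a sparse voxel set (26-connectivity)
#'
#' @param voxels linear voxel indices.
#' @param dm grid dimensions.
#' @return list of integer index vectors, one per component, in order of
#'   smallest member index.
#' @export
connected_components <- function(voxels, dm) {
  voxels <- sort(unique(voxels))
  n <- length(voxels)
  if (n == 0L) return(list())
  co <- arrayInd(voxels, dm)
  comp <- integer(n)                     # 0 = unvisited
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      base <- co[cur, ]
      nb <- sweep(.dirs26, 2, base, "+")
      okb <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nbi <- nb[okb, 1] + dm[1] * (nb[okb, 2] - 1L) +
        dm[1] * dm[2] * (nb[okb, 3] - 1L)
      hit <- match(nbi, voxels)
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  lapply(seq_len(ncomp), function(k) voxels[comp == k])
}

#' Extract the full per-lesion radiomics feature set for a cohort
#'
#' Decomposes each patient's hemorrhage into 26-connected components and
#' computes, per component, the first-order, shape, GLCM, GLDM and NGTDM
#' families on fixed-bin-width discretized intensities.  Patients without
#' lesion voxels are excluded with a warning.
#'
#' @param cohort an `ich_cohort`, or a list of `lesion_set`s.
#' @param bin_width discretization bin width (HU-like units, default 5).
#' @return data.frame: `patient_id`, `lesion_id`, then one column per
#'   feature (family-prefixed names); `attr(,"provenance")="radiomics"`,
#'   `attr(,"bin_width")` records the discretization.
#' @export
extract_radiomics <- function(cohort, bin_width = 5) {
  lesions <- if (inherits(cohort, "ich_cohort")) cohort$lesions else cohort
  rows <- list()
  for (ls in lesions) {
    vox <- lesion_voxels(ls)
    if (length(vox) == 0L) {
      warning("patient ", ls$patient_id, " has no lesion voxels; excluded")
      next
    }
    val <- numeric(length(vox))
    for (les in ls$lesions)                       # later lesion wins overlap
      val[match(les$voxels, vox)] <- les$intensity
    comps <- connected_components(vox, ls$dim)
    for (k in seq_along(comps)) {
      cv <- comps[[k]]
      ints <- val[match(cv, vox)]
      lev_vec <- discretize(ints, bin_width)
      lev <- .les_array(cv, as.numeric(lev_vec), ls$dim)
      fo <- first_order(ints, bin_width)
      sh <- shape_features(cv, ls$dim)
      feat <- c(stats::setNames(fo, paste0("fo_", names(fo))),
                stats::setNames(sh, paste0("shape_", names(sh))))
      if (length(cv) >= 2) {
        gl <- glcm_features(lev)
        gd <- gldm_features(lev)
        ng <- ngtdm_features(lev)
        feat <- c(feat,
                  stats::setNames(gl, paste0("glcm_", names(gl))),
                  stats::setNames(gd, paste0("gldm_", names(gd))),
                  stats::setNames(ng, paste0("ngtdm_", names(ng))))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = ls$patient_id, lesion_id = k,
                   as.list(feat), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no lesions to extract features from")
  # single-voxel components lack texture columns; align on the union
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    miss <- setdiff(all_cols, names(r))
    for (mcol in miss) r[[mcol]] <- 0
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- "radiomics"
  attr(out, "bin_width") <- bin_width
  out
}
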