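# brute-force texture oracles (independent loop implementations)

test_that("discretization follows the fixed-bin-width formula", {
  expect_identical(as.integer(discretize(rep(42, 5), 5)), rep(1L, 5))
  expect_identical(as.integer(discretize(c(0, 5, 10), 5)), c(1L, 2L, 3L))
  expect_error(discretize(numeric(0), 5), "empty")
  expect_error(discretize(1:3, 0), "bin_width")
  set.seed(41)
  x <- stats::rnorm(200, 60, 10)
  lev <- discretize(x, 2.5)
  brute <- vapply(x, function(v) floor((v - min(x)) / 2.5) + 1, numeric(1))
  expect_equal(as.numeric(lev), brute)
  expect_equal(attr(lev, "n_levels"), max(brute))
})

test_that("first-order statistics match hand arithmetic", {
  f <- first_order(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 1.25)           # population variance
  expect_equal(f[["energy"]], 1 + 4 + 9 + 16)
  expect_equal(f[["range"]], 3)
  fc <- first_order(rep(7, 10))
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["skewness"]], 0)
  fs <- first_order(c(-3, -1, 0, 1, 3))          # symmetric sample
  expect_equal(fs[["skewness"]], 0)
})

test_that("mesh volume of a digitized sphere approaches the analytic value", {
  sph <- digitized_sphere(10)
  ms <- mesh_volume_area(sph)
  analytic <- 4 / 3 * pi * 1000
  expect_lt(abs(ms$volume - analytic) / analytic, 0.05)
  # mesh volume sits between voxel volume minus a surface layer and
  # the voxel volume itself (spheres r = 5..15)
  for (r in c(5, 8, 12, 15)) {
    s <- digitized_sphere(r)
    m <- mesh_volume_area(s)
    expect_lte(m$volume, sum(s))
    expect_gte(m$volume, sum(s) - m$area)
    expect_gte(m$volume, 0)
  }
})

test_that("sphere shape features behave isoperimetrically", {
  sph <- digitized_sphere(10)
  f <- shape_features(which(sph == 1L), dim(sph))
  expect_equal(f[["voxel_volume"]], sum(sph))
  expect_equal(f[["meshed"]], 1)
  # equal-volume 1-voxel-thick slab has lower sphericity
  n <- sum(sph)
  side <- ceiling(sqrt(n))
  dm2 <- c(side + 2L, side + 2L, 5L)
  slab <- array(0L, dm2)
  slab[2:(side + 1), 2:(side + 1), 3][seq_len(n)] <- 1L
  fs <- shape_features(which(slab == 1L), dm2)
  expect_gt(f[["sphericity"]], fs[["sphericity"]])
  # max 3D diameter of the sphere is close to its true diameter
  expect_gt(f[["max_diameter3d"]], 18)
  expect_lt(f[["max_diameter3d"]], 22)
})

test_that("tiny lesions fall back to voxel counting with a flag", {
  dm <- c(10L, 10L, 10L)
  f <- shape_features(55L, dm)                   # single voxel
  expect_equal(f[["voxel_volume"]], 1)
  expect_equal(f[["mesh_volume"]], 1)
  expect_equal(f[["meshed"]], 0)
  expect_equal(f[["surface_area"]], 6)           # exposed faces of a cube
})

test_that("co-occurrence features match exhaustive neighbor enumeration", {
  # 2x2x1 toy with levels [[1,2],[1,2]]
  lev <- array(c(1, 1, 2, 2), c(2, 2, 1))
  got <- glcm_features(lev)
  want <- glcm_from_matrix(brute_glcm_matrix(lev))
  expect_equal(got, want, tolerance = 1e-12)
  # random masked toys
  set.seed(43)
  for (rep in 1:5) {
    lv <- array(sample(1:3, 27, replace = TRUE), c(3, 3, 3))
    lv[sample(27, 6)] <- NA
    expect_equal(glcm_features(lv),
                 glcm_from_matrix(brute_glcm_matrix(lv)),
                 tolerance = 1e-12)
  }
  # constant image: zero contrast, correlation 1 by convention
  const <- array(1, c(3, 3, 3))
  gc <- glcm_features(const)
  expect_equal(gc[["contrast"]], 0)
  expect_equal(gc[["correlation"]], 1)
})

test_that("difference-based GLCM features are level-shift invariant", {
  set.seed(47)
  lv <- array(sample(1:4, 27, replace = TRUE), c(3, 3, 3))
  a <- glcm_features(lv)
  b <- glcm_features(lv + 1)
  for (nm in c("contrast", "dissimilarity", "energy", "joint_entropy",
               "homogeneity"))
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-12)
})

test_that("gray-level dependence features match brute-force enumeration", {
  set.seed(53)
  for (rep in 1:5) {
    lv <- array(sample(1:2, 8, replace = TRUE), c(2, 2, 2))
    got <- gldm_features(lv)
    br <- brute_dependence(lv)
    expect_equal(got, gldm_from_counts(br$level, br$dep), tolerance = 1e-12)
  }
  # constant cube: interior voxel has all 26 neighbors at the same level
  const <- array(1, c(3, 3, 3))
  br <- brute_dependence(const)
  expect_equal(max(br$dep), 26L)
  expect_equal(gldm_features(const),
               gldm_from_counts(br$level, br$dep), tolerance = 1e-12)
  # single voxel: dependence 0, all mass at one cell
  single <- array(NA_real_, c(3, 3, 3)); single[2, 2, 2] <- 1
  g <- gldm_features(single)
  expect_equal(g[["small_dependence_emphasis"]], 1)
  expect_equal(g[["large_dependence_emphasis"]], 1)
  expect_equal(g[["dependence_entropy"]], 0)
})

test_that("NGTDM s-vector matches hand neighborhood means", {
  # 3x3x1 with a bright center: level 2 at (2,2,1), level 1 elsewhere
  lev <- array(1, c(3, 3, 1)); lev[2, 2, 1] <- 2
  # center: 8 valid neighbors, all level 1 -> s_2 = |2 - 1| = 1
  # each corner: 3 neighbors {1,1,2}(corners see center? corner (1,1) sees
  # (1,2),(2,1),(2,2) = 1,1,2 -> mean 4/3, |1 - 4/3| = 1/3
  # each edge: 5 neighbors {1,1,1,1,2} -> mean 6/5, |1 - 6/5| = 1/5
  s1 <- 4 * (1 / 3) + 4 * (1 / 5)
  s2 <- 1
  n <- 9
  p <- c(8, 1) / n
  f <- ngtdm_features(lev)
  expect_equal(f[["coarseness"]], 1 / (p[1] * s1 + p[2] * s2),
               tolerance = 1e-12)
  # ordered double sum over (i, j) counts both (1,2) and (2,1)
  contrast <- (2 * p[1] * p[2] * (1 - 2)^2 / (2 * 1)) * ((s1 + s2) / n)
  expect_equal(f[["contrast"]], contrast, tolerance = 1e-12)
  # constant image has zero contrast
  expect_equal(ngtdm_features(array(1, c(3, 3, 3)))[["contrast"]], 0)
})

test_that("coarseness drops as spatial frequency rises", {
  dm <- c(8L, 8L, 1L)
  ix <- arrayInd(seq_len(prod(dm)), dm)
  fine <- array(1 + (ix[, 1] + ix[, 2]) %% 2, dm)      # checkerboard, period 1
  coarse <- array(1 + (ix[, 1] > 4), dm)               # two half-plane blocks
  expect_gt(ngtdm_features(coarse)[["coarseness"]],
            ngtdm_features(fine)[["coarseness"]])
})

test_that("all features are invariant to integer translation", {
  set.seed(59)
  dm <- c(20L, 20L, 20L)
  base <- as.matrix(expand.grid(3:7, 4:8, 5:9))
  keep <- stats::runif(nrow(base)) < 0.7
  co1 <- base[keep, ]
  co2 <- sweep(co1, 2, c(6L, 4L, 5L), "+")
  to_idx <- function(co) co[, 1] + dm[1] * (co[, 2] - 1) +
    dm[1] * dm[2] * (co[, 3] - 1)
  ints <- stats::rnorm(nrow(co1), 60, 10)
  ls1 <- make_lesion_set(list(to_idx(co1)), dm, intensities = list(ints))
  ls2 <- make_lesion_set(list(to_idx(co2)), dm, intensities = list(ints))
  f1 <- extract_radiomics(list(ls1))
  f2 <- extract_radiomics(list(ls2))
  expect_equal(f1[, -(1:2)], f2[, -(1:2)], tolerance = 1e-12)
})

test_that("texture families are invariant to a global intensity shift", {
  set.seed(61)
  dm <- c(15L, 15L, 15L)
  vox <- which(digitized_sphere(4, pad = 3) == 1L)
  ints <- stats::rnorm(length(vox), 60, 8)
  ls1 <- make_lesion_set(list(vox), dm, intensities = list(ints))
  ls2 <- make_lesion_set(list(vox), dm, intensities = list(ints + 100))
  f1 <- extract_radiomics(list(ls1))
  f2 <- extract_radiomics(list(ls2))
  tex <- grep("^(glcm|gldm|ngtdm)_", names(f1), value = TRUE)
  expect_equal(f1[, tex], f2[, tex], tolerance = 1e-10)
})

test_that("extraction is per connected lesion and deterministic", {
  at <- small_atlas()
  co <- sample_cohort(10, atlas = at, seed = 67)
  f1 <- extract_radiomics(co)
  f2 <- extract_radiomics(co)
  expect_identical(f1, f2)
  expect_equal(ncol(f1) - 2L, 33L)               # documented catalogue size
  # 3 well-separated lesions -> 3 rows with the shared patient id
  dm <- c(30L, 30L, 30L)
  sph <- digitized_sphere(2, pad = 1)                  # 7^3 stamp
  stamp <- arrayInd(which(sph == 1L), dim(sph))
  mk <- function(zofs) {
    co <- stamp; co[, 3] <- co[, 3] + zofs
    co[, 1] + dm[1] * (co[, 2] - 1L) + dm[1] * dm[2] * (co[, 3] - 1L)
  }
  ls <- make_lesion_set(list(mk(0L), mk(10L), mk(20L)),
                        dm, patient_id = "P9",
                        intensities = NULL)
  # give nonconstant intensities
  ls$lesions <- lapply(ls$lesions, function(l) {
    l$intensity <- stats::rnorm(length(l$voxels), 60, 5); l
  })
  f3 <- extract_radiomics(list(ls))
  expect_equal(nrow(f3), 3L)
  expect_true(all(f3$patient_id == "P9"))
  # patient with no voxels is excluded with a warning
  empty <- make_lesion_set(list(), dm, patient_id = "E")
  expect_warning(f4 <- extract_radiomics(list(ls, empty)), "excluded")
  expect_equal(nrow(f4), 3L)
})

test_that("connected components split and merge correctly", {
  dm <- c(10L, 10L, 10L)
  a <- c(1L, 2L, 11L)          # touching voxels
  b <- c(555L, 556L)           # (5,6,6) and (6,6,6)
  cc <- connected_components(c(a, b), dm)
  expect_length(cc, 2L)
  expect_setequal(cc[[1]], a)
  expect_setequal(cc[[2]], b)
  # diagonal touch counts under 26-connectivity
  d1 <- 1L
  d2 <- 1L + 1L + 10L + 100L   # (2,2,2)
  expect_length(connected_components(c(d1, d2), dm), 1L)
})
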