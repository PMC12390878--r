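test_that("probability map counts patients per voxel", {
  dm <- c(8L, 8L, 8L)
  masks <- replicate(4, array(0L, dm), simplify = FALSE)
  masks[[2]][3, 3, 3] <- 1L
  pm <- probability_map(masks)
  expect_equal(pm$volume[3, 3, 3], 0.25)
  expect_equal(sum(pm$volume), 0.25)
  # all-empty group
  empty <- probability_map(replicate(3, array(0L, dm), simplify = FALSE))
  expect_true(all(empty$volume == 0))
})

test_that("probability map equals the brute-force voxel tally", {
  set.seed(5)
  dm <- c(16L, 16L, 16L)
  masks <- replicate(50, random_mask(dm, 0.15), simplify = FALSE)
  pm <- probability_map(masks)
  brute <- array(0, dm)
  for (i in seq_len(prod(dm))) {
    brute[i] <- sum(vapply(masks, function(m) m[i] != 0L, logical(1))) / 50
  }
  expect_equal(pm$volume, brute)
  # every voxel value times n is an integer count <= n
  cnt <- pm$volume * pm$n_patients
  expect_true(all(abs(cnt - round(cnt)) < 1e-9))
  expect_true(all(cnt <= pm$n_patients))
  # invariant to patient permutation
  pm2 <- probability_map(masks[sample(50)])
  expect_equal(pm$volume, pm2$volume)
})

test_that("probability map rejects mismatched grids, naming the patient", {
  masks <- list(array(0L, c(8, 8, 8)), array(0L, c(9, 8, 8)))
  expect_error(probability_map(masks), "index 2")
})

test_that("involvement fractions equal a brute-force per-voxel tally", {
  set.seed(17)
  for (rep in 1:50) {
    dm <- c(12L, 12L, 12L)
    at <- random_atlas(dm, n_regions = 5L)
    mask <- random_mask(dm, stats::runif(1, 0.05, 0.4))
    inv <- involvement(mask, at)
    for (lab in 1:5) {
      brute_hit <- 0L; brute_tot <- 0L
      for (i in seq_len(prod(dm))) {
        if (at$volume[i] == lab) {
          brute_tot <- brute_tot + 1L
          if (mask[i] != 0L) brute_hit <- brute_hit + 1L
        }
      }
      expect_identical(inv$fraction[inv$label == lab],
                       brute_hit / brute_tot)
      expect_identical(inv$flag[inv$label == lab],
                       as.integer(brute_hit / brute_tot > 0.2))
    }
  }
})

test_that("the 20% involvement rule is strict", {
  dm <- c(24L, 24L, 24L)
  vol <- array(0L, dm)
  vol[1:10] <- 1L                    # region 1: exactly 10 voxels
  vol[11:30] <- 2L
  rt <- data.frame(label = 1:2, name = c("A", "B"),
                   structure = c("subcortical", "subcortical"))
  at <- labeled_atlas(vol, rt)
  mask <- array(0L, dm); mask[1:2] <- 1L     # 2 of 10 voxels: exactly 20%
  inv <- involvement(mask, at)
  expect_equal(inv$fraction[1], 0.2)
  expect_identical(inv$flag[1], 0L)
  mask[3] <- 1L                              # 30% — now flagged
  inv <- involvement(mask, at)
  expect_identical(inv$flag[1], 1L)
  # full coverage
  mask2 <- array(0L, dm); mask2[11:30] <- 1L
  inv2 <- involvement(mask2, at)
  expect_equal(inv2$fraction[2], 1.0)
  expect_identical(inv2$flag[2], 1L)
})

test_that("involvement uses union semantics over overlapping lesions", {
  at <- small_atlas()
  dm <- dim(at$volume)
  vox <- which(at$volume == 3L)[1:40]
  one <- make_lesion_set(list(vox), dm)
  split2 <- make_lesion_set(list(vox[1:25], vox[10:40]), dm)  # overlap
  expect_equal(involvement(one, at)$fraction,
               involvement(split2, at)$fraction)
})

test_that("location feature matrix matches per-patient recounts", {
  at <- small_atlas()
  set.seed(3)
  co <- sample_cohort(30, atlas = at, seed = 3)
  feat <- location_features(co)
  expect_identical(dim(feat), c(30L, 20L))
  expect_true(all(feat %in% c(0, 1)))
  recount <- vapply(seq_len(20), function(j) {
    sum(vapply(co$lesions, function(ls)
      involvement(ls, at)$flag[j] == 1L, logical(1)))
  }, numeric(1))
  expect_equal(unname(colSums(feat)), recount)
  # a patient with no lesions gives an all-zero row
  empty <- make_lesion_set(list(), dim(at$volume), patient_id = "E")
  f2 <- location_features(list(empty), atlas = at)
  expect_true(all(f2 == 0))
})

test_that("repeated-measures ANOVA matches the aov decomposition", {
  set.seed(23)
  x <- matrix(stats::runif(18), 6, 3)          # 6 regions x 3 etiologies
  res <- repeated_anova(x)
  df <- data.frame(y = as.vector(x),
                   treat = factor(rep(1:3, each = 6)),
                   subj = factor(rep(1:6, 3)))
  a <- summary(stats::aov(y ~ treat + subj, data = df))[[1]]
  expect_equal(res$F, a["treat", "F value"], tolerance = 1e-10)
  expect_equal(res$p, a["treat", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 10L)
})

test_that("identical involvement profiles give F = 0, p = 1", {
  x <- matrix(rep(c(0.1, 0.4, 0.2, 0.8, 0.3), 3), 5, 3)
  res <- repeated_anova(x)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("a uniform etiology shift is detected by the structure ANOVA", {
  base <- c(0.15, 0.25, 0.10, 0.30, 0.20)
  x <- cbind(base, base + 0.3, base)           # one etiology +0.3
  res <- repeated_anova(x)
  expect_lt(res$p, 0.01)
})

test_that("etiology_region_anova wires rates correctly per structure", {
  at <- small_atlas()
  set.seed(29)
  n <- 60
  eti <- rep(c("hypertension", "aneurysm", "malformation"), each = 20)
  feat <- matrix(rbinom(n * 20, 1, 0.3), n, 20,
                 dimnames = list(NULL, at$region_table$name))
  res <- etiology_region_anova(feat, eti, at$region_table)
  expect_setequal(res$structure, ICH_STRUCTURES)
  # recompute one structure by hand
  regs <- at$region_table$name[at$region_table$structure == "cortical"]
  rates <- sapply(sort(unique(eti)), function(e)
    colMeans(feat[eti == e, regs]))
  expect_equal(res$F[res$structure == "cortical"], repeated_anova(rates)$F)
  # fewer than 2 regions is a degrees-of-freedom error
  rt_bad <- at$region_table[c(1, 5:20), ]
  expect_error(etiology_region_anova(feat[, c(1, 5:20)], eti, rt_bad),
               "< 2 regions")
})

test_that("Pearson chi-square matches the hand formula and chisq.test", {
  expect_equal(pearson_chisq(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(pearson_chisq(matrix(c(10, 10, 10, 10), 2))$p, 1)
  tab <- matrix(c(30, 5, 5, 30), 2)
  res <- pearson_chisq(tab)
  # N (ad-bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$statistic, 70 * (30 * 30 - 5 * 5)^2 / 35^4)
  expect_equal(res$statistic, 35.714285714, tolerance = 1e-9)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, unname(ref$p.value))
})

test_that("per-region chi-square ranking is stable under column order", {
  set.seed(31)
  n <- 80
  feat <- matrix(rbinom(n * 6, 1, 0.4), n, 6,
                 dimnames = list(NULL, paste0("R", 1:6)))
  out <- rbinom(n, 1, 0.5)
  r1 <- prognosis_region_chisq(feat, out)
  r2 <- prognosis_region_chisq(feat[, sample(6)], out)
  expect_equal(r1[order(r1$region), ], r2[order(r2$region), ],
               ignore_attr = TRUE)
  expect_true(all(diff(r1$statistic) <= 1e-12))
  # region never involved: statistic 0 by convention
  feat[, 1] <- 0
  r3 <- prognosis_region_chisq(feat, out)
  expect_equal(r3$statistic[r3$region == "R1"], 0)
  expect_equal(r3$p[r3$region == "R1"], 1)
  expect_error(prognosis_region_chisq(feat, rep(1, n)), "both outcome")
})

test_that("degenerate placement puts the map peak inside that structure", {
  at <- small_atlas()
  pm <- placement_model(c(ventricle = 0, subcortical = 1, white_matter = 0,
                          cortical = 0, subarachnoid = 0),
                        lesion_count_probs = 1, radius_mean = 2.5,
                        radius_sd = 0.5)
  set.seed(37)
  masks <- lapply(1:30, function(i) sample_patient(at, pm, "hypertension"))
  prob <- probability_map(masks, group = "hypertension")
  peak <- which.max(prob$volume)
  lab <- at$volume[peak]
  expect_equal(at$region_table$structure[match(lab, at$region_table$label)],
               "subcortical")
})
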