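# shared fixtures: a small 20-region atlas, random masks, sparse lesion sets

small_region_table <- function() {
  default_region_table(c(ventricle = 4L, subcortical = 4L,
                         white_matter = 4L, cortical = 4L,
                         subarachnoid = 4L))
}

# built once per test run; 32^3 is cheap
small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_toy_atlas(toy_atlas_spec(c(32L, 32L, 32L),
                                               small_region_table(),
                                               seed = 42L))
    cache
  }
})

full_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_toy_atlas(toy_atlas_spec(seed = 11L))
    cache
  }
})

random_mask <- function(dm, p = 0.2) {
  array(as.integer(stats::runif(prod(dm)) < p), dm)
}

# a labeled atlas with random (possibly disconnected) regions — fine for
# oracle tests that only use the label lookup
random_atlas <- function(dm, n_regions = 5L) {
  vol <- array(sample.int(n_regions + 1L, prod(dm), replace = TRUE) - 1L, dm)
  rt <- data.frame(label = seq_len(n_regions),
                   name = paste0("R", seq_len(n_regions)),
                   structure = rep_len(ICH_STRUCTURES, n_regions),
                   stringsAsFactors = FALSE)
  labeled_atlas(vol, rt)
}

make_lesion_set <- function(voxel_list, dm, patient_id = "P1",
                            intensities = NULL) {
  lesions <- lapply(seq_along(voxel_list), function(i) {
    v <- as.integer(voxel_list[[i]])
    list(voxels = v,
         intensity = if (is.null(intensities)) rep(50, length(v))
                     else intensities[[i]])
  })
  structure(list(patient_id = patient_id, dim = as.integer(dm),
                 etiology = NA, lesions = lesions),
            class = "lesion_set")
}

digitized_sphere <- function(r, pad = 3L) {
  n <- 2L * (r + pad) + 1L
  ctr <- rep(r + pad + 1, 3)
  ix <- arrayInd(seq_len(n^3), rep(n, 3))
  array(as.integer(sqrt(rowSums(sweep(ix, 2, ctr)^2)) <= r), rep(n, 3))
}

# random parameter set shaped like a trained pooler (for contract tests)
random_pooler <- function(d, hidden = 4L, seed = 1L) {
  set.seed(seed)
  structure(list(V = matrix(rnorm(hidden * d), hidden, d),
                 U = matrix(rnorm(hidden * d), hidden, d),
                 w = rnorm(hidden), beta = rnorm(d), b0 = rnorm(1),
                 hidden = hidden, center = rnorm(d),
                 scale = abs(rnorm(d)) + 0.5,
                 feature_names = paste0("f", seq_len(d)),
                 lambda = 0.01, folds = NULL, loss = NA, seed = seed),
            class = "attention_pooler")
}
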