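#' The five intracranial structure groups
#'
#' Region labels partition into five structures: ventricle, subcortical
#' (deep gray nuclei), white matter, cortical ribbon, and subarachnoid
#' space.  All region tables in the package use these names.
#'
#' @export
ICH_STRUCTURES <- c("ventricle", "subcortical", "white_matter",
                    "cortical", "subarachnoid")

#' Default region table for the toy atlas
#'
#' Mirrors the cardinality of a full template parcellation: 4 ventricle
#' regions, 60 deep-nuclei regions, 68 white-matter regions, 50 cortical
#' regions and 10 subarachnoid regions (192 in total).  Smaller tables
#' (e.g. 4 regions per structure) are convenient for tests.
#'
#' @param n named integer vector of region counts per structure; names must
#'   be the five entries of [ICH_STRUCTURES] and every count must be >= 2.
#' @return data.frame with columns `label`, `name`, `structure`.
#' @export
default_region_table <- function(n = c(ventricle = 4L, subcortical = 60L,
                                       white_matter = 68L, cortical = 50L,
                                       subarachnoid = 10L)) {
  if (!setequal(names(n), ICH_STRUCTURES))
    stop("`n` must be named by the five intracranial structures")
  if (any(n < 2L))
    stop("every structure needs at least 2 regions")
  n <- n[ICH_STRUCTURES]
  abbr <- c(ventricle = "VEN", subcortical = "SC", white_matter = "WM",
            cortical = "CTX", subarachnoid = "SAS")
  tabs <- lapply(ICH_STRUCTURES, function(s) {
    data.frame(name = sprintf("%s_%02d", abbr[[s]], seq_len(n[[s]])),
               structure = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  out <- data.frame(label = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Specification of a toy labeled atlas
#'
#' @param grid_shape integer triple of voxel dimensions, each >= 24.
#' @param regions data.frame with columns `label` (unique positive
#'   integers), `name`, `structure` (one of [ICH_STRUCTURES]); every
#'   structure present must have at least two regions.
#' @param seed integer seed controlling the (deterministic) angular offsets
#'   of the sector partition.
#' @return object of class `toy_atlas_spec`.
#' @seealso [build_toy_atlas()]
#' @export
toy_atlas_spec <- function(grid_shape = c(64L, 64L, 64L),
                           regions = default_region_table(),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)))
    stop("`grid_shape` must be an integer triple")
  if (any(grid_shape < 24L))
    stop("grid too small: every dimension must be >= 24 voxels")
  if (!all(c("label", "name", "structure") %in% names(regions)))
    stop("`regions` needs columns label, name, structure")
  lab <- as.integer(regions$label)
  if (anyDuplicated(lab) || any(lab <= 0L))
    stop("region labels must be unique positive integers (0 is background)")
  if (!all(regions$structure %in% ICH_STRUCTURES))
    stop("unknown structure name in region table")
  cnt <- table(regions$structure)
  if (any(cnt < 2L))
    stop("every structure must be represented by >= 2 regions")
  structure(list(grid_shape = grid_shape, regions = regions,
                 seed = as.integer(seed)),
            class = "toy_atlas_spec")
}

# radial zone boundaries (fractions of the brain radius), inside out;
# chosen to keep per-region voxel volumes of the default 192-region table
# roughly comparable across structures
.zone_frac <- c(ventricle = 0.24, subcortical = 0.60, white_matter = 0.80,
                cortical = 0.93, subarachnoid = 1.00)

#' Build a deterministic toy labeled atlas
#'
#' Constructs a nested-compartment parcellation on a regular grid: a
#' central ventricular core, surrounded by concentric shells for the
#' subcortical nuclei, white matter, cortical ribbon and outer
#' subarachnoid space.  Each shell is partitioned into the requested
#' number of regions by elevation bands and equal-count azimuthal
#' sectors, so every region is a connected wedge-shaped blob.  The result
#' is a pure function of the spec (including its seed).
#'
#' @param spec a [toy_atlas_spec()].
#' @return object of class `labeled_atlas`: list with `volume` (3D integer
#'   array, 0 = background), `region_table`, `voxel_counts` (named by label).
#' @export
build_toy_atlas <- function(spec) {
  stopifnot(inherits(spec, "toy_atlas_spec"))
  dm <- spec$grid_shape
  ctr <- (dm + 1) / 2
  R <- 0.45 * min(dm)

  ix <- arrayInd(seq_len(prod(dm)), dm)
  dx <- ix[, 1] - ctr[1]; dy <- ix[, 2] - ctr[2]; dz <- ix[, 3] - ctr[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)

  vol <- integer(prod(dm))
  set.seed(spec$seed)
  lo <- 0
  for (s in ICH_STRUCTURES) {
    hi <- .zone_frac[[s]] * R
    labs <- spec$regions$label[spec$regions$structure == s]
    k <- length(labs)
    if (k == 0L) { lo <- hi; next }
    in_zone <- if (s == "ventricle") which(r <= hi) else which(r > lo & r <= hi)
    if (length(in_zone) < k)
      stop(sprintf("grid too small to host %d regions in structure '%s'",
                   k, s))
    vol[in_zone] <- labs[.sector_partition(dx[in_zone], dy[in_zone],
                                           dz[in_zone], k)]
    lo <- hi
  }
  vol <- array(vol, dm)

  counts <- tabulate(vol, nbins = max(spec$regions$label))
  names(counts) <- as.character(seq_along(counts))
  counts <- counts[as.character(spec$regions$label)]
  if (any(counts == 0L))
    stop(sprintf("grid too small: region(s) %s ended up empty",
                 paste(spec$regions$name[counts == 0L], collapse = ", ")))
  new_labeled_atlas(vol, spec$regions)
}

# Partition zone voxels into k connected sectors: elevation bands (equal
# voxel counts) then equal-count azimuth wedges; random azimuth origin per
# zone keeps different seeds distinguishable while staying deterministic.
.sector_partition <- function(dx, dy, dz, k) {
  m <- length(dx)
  n_bands <- max(1L, min(k, as.integer(floor(sqrt(k / 2)))))
  # sectors per band, proportional to band size, each >= 1
  band <- if (n_bands == 1L) rep(1L, m) else {
    br <- stats::quantile(dz, probs = seq(0, 1, length.out = n_bands + 1),
                          type = 1)
    findInterval(dz, br[-c(1, n_bands + 1)]) + 1L
  }
  bsz <- tabulate(band, n_bands)
  alloc <- pmax(1L, as.integer(round(k * bsz / sum(bsz))))
  while (sum(alloc) != k) {          # largest-remainder style fixup
    i <- if (sum(alloc) > k) which.max(alloc) else which.max(bsz / alloc)
    alloc[i] <- alloc[i] + sign(k - sum(alloc))
  }
  off <- stats::runif(1, 0, 2 * pi)
  theta <- (atan2(dy, dx) + off) %% (2 * pi)
  sec <- integer(m)
  base <- 0L
  for (b in seq_len(n_bands)) {
    idx <- which(band == b)
    kk <- alloc[b]
    if (length(idx) < kk)
      stop("grid too small: an elevation band has fewer voxels than sectors")
    qs <- stats::quantile(theta[idx], probs = seq(0, 1, length.out = kk + 1),
                          type = 1)
    sec[idx] <- base + pmin(kk, findInterval(theta[idx], qs[-c(1, kk + 1)]) + 1L)
    base <- base + kk
  }
  sec
}

new_labeled_atlas <- function(volume, region_table) {
  storage.mode(volume) <- "integer"
  counts <- tabulate(volume, nbins = max(region_table$label))
  vc <- counts[region_table$label]
  names(vc) <- as.character(region_table$label)
  structure(list(volume = volume, region_table = region_table,
                 voxel_counts = vc),
            class = "labeled_atlas")
}

#' Construct a labeled atlas from a volume and region table
#'
#' @param volume 3D integer array of region labels (0 = background).
#' @param region_table data.frame with columns `label`, `name`, `structure`.
#' @return `labeled_atlas` object.
#' @export
labeled_atlas <- function(volume, region_table) {
  labs <- sort(unique(as.vector(volume)))
  labs <- labs[labs != 0]
  if (!all(labs %in% region_table$label))
    stop("volume contains labels absent from the region table")
  new_labeled_atlas(volume, region_table)
}

#' @export
print.labeled_atlas <- function(x, ...) {
  cat(sprintf("labeled_atlas: %s grid, %d regions (%s)\n",
              paste(dim(x$volume), collapse = "x"),
              nrow(x$region_table),
              paste(sprintf("%s=%d", names(table(x$region_table$structure)),
                            table(x$region_table$structure)),
                    collapse = ", ")))
  invisible(x)
}

#' Labels belonging to one structure
#' @param atlas a `labeled_atlas`.
#' @param structure one of [ICH_STRUCTURES].
#' @return integer vector of region labels.
#' @export
structure_labels <- function(atlas, structure) {
  atlas$region_table$label[atlas$region_table$structure == structure]
}
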