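#' Etiology-conditional lesion placement model
#'
#' Describes how lesions of one etiology are placed: a categorical
#' distribution over the five intracranial structures, a distribution of
#' the per-patient lesion count, a (truncated normal) lesion radius in
#' voxels, and Hounsfield-like intensity parameters for lesion and
#' background tissue.
#'
#' @param structure_probs named numeric vector over [ICH_STRUCTURES],
#'   nonnegative, summing to 1 (renormalized if slightly off).
#' @param lesion_count_probs probabilities of 1, 2, ... lesions per patient.
#' @param radius_mean,radius_sd lesion radius distribution, voxels;
#'   `radius_mean` must be positive.
#' @param intensity list with `lesion_mean`, `lesion_sd`,
#'   `background_mean`, `background_sd` (HU-like units).
#' @return object of class `placement_model`.
#' @export
placement_model <- function(structure_probs,
                            lesion_count_probs = c(0.8, 0.15, 0.05),
                            radius_mean = 4, radius_sd = 1.2,
                            intensity = list(lesion_mean = 65, lesion_sd = 8,
                                             background_mean = 30,
                                             background_sd = 5)) {
  if (!setequal(names(structure_probs), ICH_STRUCTURES))
    stop("`structure_probs` must be named by the five structures")
  structure_probs <- structure_probs[ICH_STRUCTURES]
  if (any(structure_probs < 0) || any(structure_probs > 1 + 1e-8))
    stop("structure probabilities must lie in [0, 1]")
  s <- sum(structure_probs)
  if (abs(s - 1) > 1e-6) stop("structure probabilities must sum to 1")
  structure_probs <- structure_probs / s
  if (any(lesion_count_probs < 0) ||
      abs(sum(lesion_count_probs) - 1) > 1e-6)
    stop("`lesion_count_probs` must be a probability vector")
  if (radius_mean <= 0) stop("`radius_mean` must be > 0")
  structure(list(structure_probs = structure_probs,
                 lesion_count_probs = lesion_count_probs / sum(lesion_count_probs),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 intensity = intensity),
            class = "placement_model")
}

#' Default per-etiology placement models
#'
#' Encodes the qualitative spatial signatures of the three etiologies:
#' hypertensive hemorrhage in the deep nuclei, aneurysmal hemorrhage in
#' the subarachnoid space, malformation-related hemorrhage predominantly
#' cortical with a broad spread.  `strength`, if given, overrides the
#' weight on each etiology's signature structure (remaining mass is
#' redistributed proportionally) — a separability dial for experiments.
#'
#' Lesion radii differ by cause: aneurysmal subarachnoid hemorrhage
#' spreads widely along the cisterns, so its blobs are the largest;
#' hypertensive deep bleeds are the most compact.
#'
#' @param strength optional numeric in (0, 1]: weight on the signature
#'   structure of each etiology.
#' @param ... passed on to [placement_model()] (counts, intensity);
#'   radii are set per etiology unless overridden here.
#' @return named list of three `placement_model`s
#'   (`hypertension`, `aneurysm`, `malformation`).
#' @export
default_placement_models <- function(strength = NULL, ...) {
  radii <- list(hypertension = c(4.5, 1.2), aneurysm = c(6.5, 1.5),
                malformation = c(5.5, 1.5))
  base <- list(
    hypertension = c(ventricle = 0.05, subcortical = 0.70,
                     white_matter = 0.15, cortical = 0.05,
                     subarachnoid = 0.05),
    aneurysm     = c(ventricle = 0.07, subcortical = 0.03,
                     white_matter = 0.02, cortical = 0.08,
                     subarachnoid = 0.80),
    malformation = c(ventricle = 0.15, subcortical = 0.08,
                     white_matter = 0.20, cortical = 0.45,
                     subarachnoid = 0.12))
  signature <- c(hypertension = "subcortical", aneurysm = "subarachnoid",
                 malformation = "cortical")
  dots <- list(...)
  out <- lapply(names(base), function(e) {
    p <- base[[e]]
    if (!is.null(strength)) {
      sig <- signature[[e]]
      rest <- p[names(p) != sig]
      p[names(p) != sig] <- (1 - strength) * rest / sum(rest)
      p[sig] <- strength
    }
    args <- c(list(structure_probs = p), dots)
    if (is.null(args$radius_mean)) args$radius_mean <- radii[[e]][1]
    if (is.null(args$radius_sd)) args$radius_sd <- radii[[e]][2]
    do.call(placement_model, args)
  })
  names(out) <- names(base)
  out
}

#' Logistic outcome model for the dichotomized mRS
#'
#' Linear predictor on centered admission GCS, log total lesion volume,
#' age, and per-structure involvement indicators; the poor-outcome
#' (mRS 3-6) probability is the logistic transform.  Defaults make low
#' GCS, large volume and ventricular extension the dominant risks.
#'
#' @param intercept scalar.
#' @param gcs coefficient on (GCS - 12).
#' @param log_volume coefficient on (log1p(total voxels) - 6.5).
#' @param age coefficient on (age - 57).
#' @param structures named coefficients on involvement indicators
#'   (default: ventricular extension harmful, subarachnoid-only relatively
#'   benign).
#' @return object of class `outcome_model`.
#' @export
outcome_model <- function(intercept = -1.0, gcs = -0.40, log_volume = 0.80,
                          age = 0.02,
                          structures = c(ventricle = 0.9, subcortical = 0,
                                         white_matter = 0, cortical = 0,
                                         subarachnoid = -0.5)) {
  if (!setequal(names(structures), ICH_STRUCTURES))
    stop("`structures` must be named by the five structures")
  structure(list(intercept = intercept, gcs = gcs, log_volume = log_volume,
                 age = age, structures = structures[ICH_STRUCTURES]),
            class = "outcome_model")
}

#' Etiology-conditional clinical covariate priors
#'
#' Defaults encode the qualitative associations seen clinically:
#' hypertension history most frequent in hypertensive sICH, female excess
#' among aneurysm ruptures, youngest ages for vascular malformations.
#'
#' @return data.frame, one row per etiology, with prior parameters.
#' @export
default_clinical_priors <- function() {
  data.frame(
    etiology  = c("hypertension", "aneurysm", "malformation"),
    age_mean  = c(62, 56, 40),
    age_sd    = c(11, 11, 13),
    female_p  = c(0.40, 0.60, 0.42),
    htn_p     = c(0.88, 0.35, 0.25),
    diabetes_p = c(0.12, 0.08, 0.06),
    smoking_p = c(0.22, 0.20, 0.15),
    stringsAsFactors = FALSE)
}

# --- lesion sampling ------------------------------------------------------

# one Gaussian-deformed sphere of radius r0 centered at voxel `ctr`,
# clipped to nonzero atlas labels; returns integer voxel indices.
# `spread_region`: voxel indices of the target region — blood in thin
# CSF-filled compartments (cisterns, ventricles) conforms to the
# compartment, so the blob is widened tangentially inside that region.
.sample_blob <- function(atlas, ctr, r0, spread_region = NULL,
                         spread_factor = 1.8) {
  dm <- dim(atlas$volume)
  a <- stats::rnorm(3, 0, 0.08)
  b <- matrix(stats::rnorm(9, 0, 0.04), 3, 3); b <- (b + t(b)) / 2
  rmax <- ceiling(r0 * 1.6) + 1L
  rng <- lapply(1:3, function(i) max(1L, ctr[i] - rmax):min(dm[i], ctr[i] + rmax))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d <- sweep(g, 2, ctr)
  dist <- sqrt(rowSums(d^2))
  u <- d / pmax(dist, 1e-9)
  rad <- r0 * (1 + u %*% a + rowSums((u %*% b) * u))
  keep <- dist <= pmax(as.vector(rad), 0.6)
  vox <- g[keep, , drop = FALSE]
  idx <- vox[, 1] + dm[1] * (vox[, 2] - 1L) + dm[1] * dm[2] * (vox[, 3] - 1L)
  idx <- idx[atlas$volume[idx] != 0L]            # clip to brain
  ctr_idx <- ctr[1] + dm[1] * (ctr[2] - 1L) + dm[1] * dm[2] * (ctr[3] - 1L)
  idx <- c(as.integer(idx), as.integer(ctr_idx))
  if (!is.null(spread_region)) {
    co <- arrayInd(spread_region, dm)
    d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2
    idx <- c(idx, as.integer(spread_region[d2 <= (spread_factor * r0)^2]))
  }
  sort(unique(idx))
}

#' Sample one patient's lesion set
#'
#' Draws the lesion count, then for each lesion a target structure from
#' the etiology's structure distribution, a uniformly chosen region of
#' that structure, a center voxel inside it, and a Gaussian-deformed
#' sphere clipped to the brain.  Lesion voxels carry intensities from the
#' lesion intensity distribution.  Uses the current RNG state; seed at
#' the call site for reproducibility.
#'
#' @param atlas a `labeled_atlas`.
#' @param placement a [placement_model()].
#' @param etiology one of `"hypertension"`, `"aneurysm"`, `"malformation"`.
#' @param patient_id optional identifier carried on the result.
#' @return object of class `lesion_set`: `dim`, `patient_id`, `etiology`,
#'   and `lesions` — a list of `list(voxels = <int>, intensity = <num>)`
#'   in sparse voxel-index form (see [as_mask()]).
#' @export
sample_patient <- function(atlas, placement, etiology, patient_id = NA) {
  stopifnot(inherits(atlas, "labeled_atlas"),
            inherits(placement, "placement_model"))
  if (!etiology %in% c("hypertension", "aneurysm", "malformation"))
    stop("unknown etiology: ", etiology)
  dm <- dim(atlas$volume)
  k <- sample.int(length(placement$lesion_count_probs), 1,
                  prob = placement$lesion_count_probs)
  lesions <- vector("list", k)
  for (j in seq_len(k)) {
    s <- sample(ICH_STRUCTURES, 1, prob = placement$structure_probs)
    labs <- structure_labels(atlas, s)
    if (length(labs) == 0L)
      stop(sprintf("atlas has no regions for structure '%s'", s))
    lab <- if (length(labs) == 1L) labs else sample(labs, 1)
    cand <- which(atlas$volume == lab)
    if (length(cand) == 0L)
      stop(sprintf("structure '%s' (region %d) is empty in the atlas", s, lab))
    ctr <- arrayInd(cand[sample.int(length(cand), 1)], dm)[1, ]
    r0 <- max(1.5, stats::rnorm(1, placement$radius_mean, placement$radius_sd))
    vox <- .sample_blob(atlas, as.integer(ctr), r0,
                        spread_region = if (s %in% c("subarachnoid",
                                                     "ventricle")) cand)
    lesions[[j]] <- list(
      voxels = vox,
      intensity = stats::rnorm(length(vox), placement$intensity$lesion_mean,
                               placement$intensity$lesion_sd),
      center = as.integer(ctr), target_label = lab, target_structure = s)
  }
  structure(list(patient_id = patient_id, dim = dm, etiology = etiology,
                 lesions = lesions),
            class = "lesion_set")
}

#' Dense binary mask of a lesion set
#' @param x a `lesion_set`.
#' @return 3D integer array (1 = hemorrhage).
#' @export
as_mask <- function(x) {
  stopifnot(inherits(x, "lesion_set"))
  m <- array(0L, x$dim)
  m[unique(unlist(lapply(x$lesions, `[[`, "voxels")))] <- 1L
  m
}

#' Union of lesion voxel indices
#' @param x a `lesion_set`.
#' @return sorted integer vector of linear voxel indices.
#' @export
lesion_voxels <- function(x) {
  sort(unique(unlist(lapply(x$lesions, `[[`, "voxels"))))
}

#' Total hemorrhage volume in voxels (union of lesions)
#' @param x a `lesion_set`.
#' @export
total_volume <- function(x) length(lesion_voxels(x))

#' Sample a labeled synthetic cohort
#'
#' Draws etiology labels from `mix`, lesions from the per-etiology
#' placement models, clinical covariates from etiology-conditional priors,
#' and the dichotomized mRS outcome from the logistic [outcome_model()].
#' Patients with etiology `"unknown"` (if `mix` includes that class) are
#' placed according to a uniformly chosen hidden etiology; downstream
#' etiology modeling excludes them.  Fully deterministic given `seed`.
#'
#' @param n number of patients (>= 10).
#' @param mix named etiology proportions (subset of
#'   `c("hypertension","aneurysm","malformation","unknown")`), summing to 1.
#' @param placement named list of [placement_model()]s for the three causes.
#' @param outcome an [outcome_model()].
#' @param priors clinical priors table, see [default_clinical_priors()].
#' @param atlas a prebuilt `labeled_atlas` (built from `atlas_spec` if NULL).
#' @param atlas_spec used when `atlas` is NULL.
#' @param center_probs sampling probabilities of the three centers.
#' @param seed integer seed.
#' @return object of class `ich_cohort`: `atlas`, `lesions` (list of
#'   `lesion_set`), `clinical` (data.frame; one row per patient), and
#'   `truth` (the generating parameters).
#' @export
sample_cohort <- function(n,
                          mix = c(hypertension = 0.485, aneurysm = 0.374,
                                  malformation = 0.095, unknown = 0.046),
                          placement = default_placement_models(),
                          outcome = outcome_model(),
                          priors = default_clinical_priors(),
                          atlas = NULL,
                          atlas_spec = toy_atlas_spec(),
                          center_probs = c(0.5, 0.3, 0.2),
                          seed = 1L) {
  if (n < 10) stop("`n` must be >= 10")
  if (abs(sum(mix) - 1) > 1e-6) stop("`mix` must sum to 1")
  if (!all(names(mix) %in% c("hypertension", "aneurysm", "malformation",
                             "unknown")))
    stop("unknown etiology name in `mix`")
  if (is.null(atlas)) atlas <- build_toy_atlas(atlas_spec)
  set.seed(as.integer(seed))

  eti <- sample(names(mix), n, replace = TRUE, prob = mix)
  center <- sample(1:3, n, replace = TRUE, prob = center_probs)

  lesions <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    true_eti <- if (eti[i] == "unknown")
      sample(c("hypertension", "aneurysm", "malformation"), 1) else eti[i]
    ls <- sample_patient(atlas, placement[[true_eti]], true_eti,
                         patient_id = sprintf("P%04d", i))
    lesions[[i]] <- ls

    pr <- priors[priors$etiology == true_eti, ]
    age <- round(max(18, stats::rnorm(1, pr$age_mean, pr$age_sd)))
    female <- stats::rbinom(1, 1, pr$female_p)
    htn <- stats::rbinom(1, 1, pr$htn_p)
    diabetes <- stats::rbinom(1, 1, pr$diabetes_p)
    smoking <- stats::rbinom(1, 1, pr$smoking_p)

    vol <- total_volume(ls)
    gcs <- round(stats::rnorm(1, 16.5 - 0.9 * log1p(vol), 1.8))
    gcs <- min(15L, max(3L, gcs))

    involved <- unique(atlas$region_table$structure[
      match(atlas$volume[lesion_voxels(ls)], atlas$region_table$label)])
    lp <- outcome$intercept + outcome$gcs * (gcs - 12) +
      outcome$log_volume * (log1p(vol) - 6.5) + outcome$age * (age - 57) +
      sum(outcome$structures[involved])
    poor <- stats::rbinom(1, 1, stats::plogis(lp))
    mrs <- if (poor == 1L) sample(3:6, 1) else sample(0:2, 1)

    rows[[i]] <- data.frame(
      patient_id = ls$patient_id, center = center[i], etiology = eti[i],
      age = age, female = female, hypertension_history = htn,
      diabetes = diabetes, smoking = smoking, gcs = gcs,
      n_lesions = length(ls$lesions), total_volume = vol,
      mrs = mrs, poor_outcome = poor, stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, rows)
  rownames(clinical) <- NULL
  structure(list(atlas = atlas, lesions = lesions, clinical = clinical,
                 truth = list(mix = as.list(mix),
                              placement = placement, outcome = outcome,
                              priors = priors, seed = as.integer(seed))),
            class = "ich_cohort")
}

#' @export
print.ich_cohort <- function(x, ...) {
  cat(sprintf("ich_cohort: %d patients, %s grid, %d regions\n",
              nrow(x$clinical), paste(dim(x$atlas$volume), collapse = "x"),
              nrow(x$atlas$region_table)))
  print(table(x$clinical$etiology))
  invisible(x)
}
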