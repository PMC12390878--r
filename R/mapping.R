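#' Voxel-wise hemorrhage probability map
#'
#' For a group of patients, the value at each voxel is the fraction of
#' patients whose hemorrhage covers that voxel (the per-voxel frequency
#' of hematoma occurrence).
#'
#' @param masks list of binary 3D arrays and/or `lesion_set` objects, all
#'   on the same grid.
#' @param group label stored on the result (e.g. `"hypertension"`).
#' @return object of class `probability_map`: `volume` (3D array in
#'   \[0, 1\]), `group`, `n_patients`.
#' @export
probability_map <- function(masks, group = "all") {
  n <- length(masks)
  if (n == 0L) stop("no masks supplied")
  dm <- if (inherits(masks[[1]], "lesion_set")) masks[[1]]$dim
        else dim(masks[[1]])
  counts <- array(0, dm)
  for (i in seq_len(n)) {
    m <- masks[[i]]
    if (inherits(m, "lesion_set")) {
      if (!identical(m$dim, dm))
        stop(sprintf("patient %s (index %d): grid %s does not match %s",
                     m$patient_id, i, paste(m$dim, collapse = "x"),
                     paste(dm, collapse = "x")))
      v <- lesion_voxels(m)
      counts[v] <- counts[v] + 1
    } else {
      if (!identical(dim(m), dm))
        stop(sprintf("mask at index %d: grid %s does not match %s", i,
                     paste(dim(m), collapse = "x"),
                     paste(dm, collapse = "x")))
      counts <- counts + (m != 0)
    }
  }
  structure(list(volume = counts / n, group = group, n_patients = n),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("probability_map '%s': n=%d, max voxel frequency %.3f\n",
              x$group, x$n_patients, max(x$volume)))
  invisible(x)
}

#' Write a probability map as NIfTI-1
#' @param pm a `probability_map`.
#' @param file output path.
#' @export
write_probability_map <- function(pm, file) {
  RNifti::writeNifti(pm$volume, file)
  invisible(file)
}

#' Per-region hemorrhage involvement of one patient
#'
#' The involvement fraction of a region is the share of its voxels
#' covered by the union of the patient's lesions; the binary involvement
#' flag is 1 iff the fraction strictly exceeds the threshold (a
#' hemorrhagic event is recorded only when more than 20% of a region's
#' voxels are hemorrhagic).  Overlapping lesions count once (union
#' semantics).
#'
#' @param mask_set a `lesion_set` or a binary 3D array on the atlas grid.
#' @param atlas a `labeled_atlas`.
#' @param threshold strict involvement cut-point (default 0.20).
#' @return data.frame with one row per region: `label`, `name`,
#'   `structure`, `fraction`, `flag`; patient id kept as attribute
#'   `patient_id`.
#' @export
involvement <- function(mask_set, atlas, threshold = 0.20) {
  stopifnot(inherits(atlas, "labeled_atlas"))
  dm <- dim(atlas$volume)
  if (inherits(mask_set, "lesion_set")) {
    if (!identical(mask_set$dim, dm))
      stop("mask grid does not match the atlas grid")
    vox <- lesion_voxels(mask_set)
    pid <- mask_set$patient_id
  } else {
    if (!identical(dim(mask_set), dm))
      stop("mask grid does not match the atlas grid")
    vox <- which(mask_set != 0)
    pid <- NA
  }
  labs_in <- atlas$volume[vox]
  labs_in <- labs_in[labs_in != 0L]
  if (length(labs_in) &&
      !all(unique(labs_in) %in% atlas$region_table$label))
    stop("mask overlaps labels absent from the region table")
  hit <- tabulate(labs_in, nbins = max(atlas$region_table$label))
  rt <- atlas$region_table
  frac <- hit[rt$label] / as.numeric(atlas$voxel_counts[as.character(rt$label)])
  out <- data.frame(label = rt$label, name = rt$name,
                    structure = rt$structure, fraction = frac,
                    flag = as.integer(frac > threshold),
                    stringsAsFactors = FALSE)
  attr(out, "patient_id") <- pid
  out
}

#' Binary location feature matrix for a cohort
#'
#' One binary column per atlas region (involvement flag under the strict
#' 20% rule), one row per patient, row order matching the clinical table.
#'
#' @param cohort an `ich_cohort`, or a list of `lesion_set`s with an
#'   `atlas` supplied.
#' @param atlas required when `cohort` is a bare list.
#' @param threshold strict involvement cut-point.
#' @return numeric 0/1 matrix, `dimnames` = (patient ids, region names),
#'   with `attr(,"provenance") = "location"`.
#' @export
location_features <- function(cohort, atlas = NULL, threshold = 0.20) {
  if (inherits(cohort, "ich_cohort")) {
    atlas <- cohort$atlas
    lesions <- cohort$lesions
  } else lesions <- cohort
  if (is.null(atlas)) stop("an atlas is required")
  rows <- lapply(lesions, function(ls) involvement(ls, atlas, threshold)$flag)
  m <- do.call(rbind, rows)
  colnames(m) <- atlas$region_table$name
  rownames(m) <- vapply(lesions, function(ls)
    as.character(ls$patient_id %||% NA), character(1))
  attr(m, "provenance") <- "location"
  m
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a

#' Repeated-measures one-way ANOVA on a subjects-by-treatments table
#'
#' Classical within-subjects decomposition: SS_total splits into
#' subject, treatment and residual parts; F = MS_treatment / MS_residual
#' with (k-1) and (k-1)(n-1) degrees of freedom.  If the treatment sum of
#' squares is zero (identical treatment profiles) the test reports F = 0,
#' p = 1 even when the residual variance is also zero.
#'
#' @param x numeric matrix, rows = subjects (matched units), columns =
#'   treatments.
#' @return list with `F`, `p`, `df1`, `df2` and the sums of squares.
#' @export
repeated_anova <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop("need >= 2 subjects (rows) for the repeated-measures test")
  if (k < 2L) stop("need >= 2 treatments (columns)")
  gm <- mean(x)
  ss_treat <- n * sum((colMeans(x) - gm)^2)
  ss_subj <- k * sum((rowMeans(x) - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ss_err <- max(0, ss_tot - ss_treat - ss_subj)
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  if (ss_treat <= 1e-14) {
    f <- 0; p <- 1
  } else if (ss_err <= 1e-14) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_treat / df1) / (ss_err / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, p = p, df1 = df1, df2 = df2,
       ss_treatment = ss_treat, ss_subject = ss_subj, ss_error = ss_err)
}

#' Per-structure etiology comparison of regional involvement rates
#'
#' Within each intracranial structure the regions are treated as matched
#' subjects and etiology as the repeated factor: for each region and
#' etiology the involvement rate (share of that etiology's patients with
#' the region flagged) is computed, and the three rate profiles are
#' compared with a repeated-measures one-way ANOVA.
#'
#' @param features binary location matrix from [location_features()].
#' @param etiologies vector of per-patient etiology labels (3 classes
#'   present; `"unknown"` rows should be excluded by the caller).
#' @param region_table data.frame mapping region `name` to `structure`.
#' @return data.frame, one row per structure: `structure`, `n_regions`,
#'   `F`, `p`.
#' @export
etiology_region_anova <- function(features, etiologies, region_table) {
  etiologies <- as.character(etiologies)
  cls <- sort(unique(etiologies))
  if (length(cls) != 3L)
    stop("exactly 3 etiology groups are required, got ", length(cls))
  out <- lapply(unique(region_table$structure), function(s) {
    regs <- region_table$name[region_table$structure == s]
    regs <- intersect(regs, colnames(features))
    if (length(regs) < 2L)
      stop(sprintf("structure '%s' has < 2 regions: repeated-measures df = 0",
                   s))
    rates <- sapply(cls, function(e)
      colMeans(features[etiologies == e, regs, drop = FALSE]))
    a <- repeated_anova(rates)
    data.frame(structure = s, n_regions = length(regs), F = a$F, p = a$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square statistic for a contingency table
#'
#' Plain Pearson \eqn{\sum (O-E)^2/E} without continuity correction.  A
#' table with a zero margin (so that some expected count is zero) is
#' reported as statistic 0 with p = 1 — the convention used for regions
#' with no involvement in either outcome class.
#'
#' @param tab integer matrix of observed counts.
#' @return list with `statistic`, `p`, `df`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  if (n == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = 0, p = 1, df = df))
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df)
}

#' Per-region chi-square comparison of involvement by outcome
#'
#' For every region, the 2x2 table of involvement flag against binary
#' outcome is tested with an uncorrected Pearson chi-square; regions are
#' returned ranked by the statistic (largest first), the ordering used to
#' display the most outcome-associated regions.
#'
#' @param features binary location matrix from [location_features()].
#' @param outcome 0/1 vector (1 = poor outcome), both classes present.
#' @param region_table optional data.frame adding a `structure` column.
#' @return data.frame: `region`, `structure` (if available), `statistic`,
#'   `p`, sorted by decreasing statistic.
#' @export
prognosis_region_chisq <- function(features, outcome, region_table = NULL) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present")
  res <- lapply(colnames(features), function(rg) {
    tab <- table(factor(features[, rg], levels = 0:1),
                 factor(outcome, levels = 0:1))
    ch <- pearson_chisq(tab)
    data.frame(region = rg, statistic = ch$statistic, p = ch$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(region_table))
    out$structure <- region_table$structure[match(out$region,
                                                  region_table$name)]
  out <- out[order(-out$statistic, out$region), ]
  rownames(out) <- NULL
  out
}
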