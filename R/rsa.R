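# Representational similarity analysis: RDM construction, category-level
# statistics, classical MDS, model comparison with Kendall tau-a and noise
# ceilings, and fMRI-MEG fusion.

#' Compute a 1 - Spearman RDM from a pattern matrix
#'
#' Dissimilarity between items i and j is one minus the Spearman rank
#' correlation of their feature vectors.
#'
#' @param patterns a [pattern_matrix()] (>= 2 items, >= 2 features).
#' @return an [rdm()] with metric `"one_minus_spearman"`.
#' @export
compute_rdm <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_matrix"))
  x <- patterns$values
  if (nrow(x) < 2 || ncol(x) < 2) stopf("need >= 2 items and >= 2 features")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stopf("constant feature vector (correlation undefined) for item(s): %s",
          paste(patterns$item_labels[sds == 0], collapse = ", "))
  }
  m <- 1 - stats::cor(t(x), method = "spearman")
  diag(m) <- 0
  rdm(m, patterns$item_labels, metric = "one_minus_spearman")
}

#' Per-timepoint RDM timecourse
#'
#' Applies [stimulus_patterns()] then [compute_rdm()] at every epoch
#' timepoint.
#'
#' @param epochs a [sensor_epochs()] (one subject).
#' @return an `rdm_timecourse`: list with `array` (items x items x
#'   timepoints), `labels`, `times_ms`.
#' @export
rdm_timecourse <- function(epochs) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  times <- epochs$times_ms
  first <- compute_rdm(stimulus_patterns(epochs, times[1]))
  arr <- array(NA_real_, c(length(first$labels), length(first$labels),
                           length(times)))
  arr[, , 1] <- first$matrix
  for (ti in seq_along(times)[-1]) {
    arr[, , ti] <- compute_rdm(stimulus_patterns(epochs, times[ti]))$matrix
  }
  structure(list(array = arr, labels = first$labels, times_ms = times),
            class = "rdm_timecourse")
}

#' @export
print.rdm_timecourse <- function(x, ...) {
  cat(sprintf("<rdm_timecourse> %d x %d items x %d timepoints\n",
              length(x$labels), length(x$labels), length(x$times_ms)))
  invisible(x)
}

#' Extract one timepoint of an RDM timecourse as an [rdm()]
#' @param x an `rdm_timecourse`.
#' @param time_ms latency (nearest timepoint is used).
#' @return an [rdm()].
#' @export
rdm_at <- function(x, time_ms) {
  ti <- which.min(abs(x$times_ms - time_ms))
  rdm(x$array[, , ti], x$labels, metric = "one_minus_spearman")
}

#' Average RDM timecourses across subjects
#' @param tcs list of `rdm_timecourse` objects with identical labels/times.
#' @return an `rdm_timecourse` (the group mean; arithmetic mean of subject
#'   RDMs, no rank transform).
#' @export
group_rdm_timecourse <- function(tcs) {
  arr <- tcs[[1]]$array
  for (s in seq_along(tcs)[-1]) arr <- arr + tcs[[s]]$array
  structure(list(array = arr / length(tcs), labels = tcs[[1]]$labels,
                 times_ms = tcs[[1]]$times_ms), class = "rdm_timecourse")
}

#' Category-averaged RDM
#'
#' Averages an item-level RDM into a category-by-category matrix:
#' between-category cells average all item pairs of the two categories;
#' within-category cells average all distinct item pairs, excluding the
#' diagonal.
#'
#' @param x an [rdm()].
#' @param categories named character vector mapping every RDM label to its
#'   category.
#' @return an [rdm()] over the categories (metric `"custom"`; note the
#'   within-category diagonal cells are returned in `attr(, "within")`
#'   since an RDM's diagonal is zero by construction).
#' @export
category_average <- function(x, categories) {
  stopifnot(inherits(x, "rdm"))
  miss <- setdiff(x$labels, names(categories))
  if (length(miss)) stopf("unlabeled items: %s", paste(miss, collapse = ", "))
  cats <- unname(categories[x$labels])
  lev <- intersect(CATEGORIES, unique(cats))
  if (!length(lev)) lev <- sort(unique(cats))
  k <- length(lev)
  out <- matrix(0, k, k, dimnames = list(lev, lev))
  within <- stats::setNames(numeric(k), lev)
  for (a in seq_len(k)) {
    ia <- which(cats == lev[a])
    if (length(ia) < 2) {
      stopf("category '%s' has < 2 items; within-category cell undefined",
            lev[a])
    }
    sub <- x$matrix[ia, ia, drop = FALSE]
    within[a] <- mean(sub[lower.tri(sub)])
    for (b in seq_len(k)) {
      if (b == a) next
      ib <- which(cats == lev[b])
      out[a, b] <- mean(x$matrix[ia, ib])
    }
  }
  res <- rdm(out, lev, metric = "custom")
  attr(res, "within") <- within
  res
}

#' Category-cell lookup including within-category cells
#' @keywords internal
category_cell <- function(cat_rdm, a, b) {
  if (a == b) attr(cat_rdm, "within")[[a]] else cat_rdm$matrix[a, b]
}

#' Permutation test for a category-averaged RDM contrast
#'
#' The contrast is a difference of two cells of the category-averaged RDM,
#' e.g. (illusory vs human) minus (matched vs human). The null distribution
#' is built by permuting the item-to-category assignment (rows and columns
#' of the item RDM jointly) and recomputing the contrast. The observed
#' statistic is included in the null (+1/+1 convention), so p is never 0.
#'
#' @param x an item-level [rdm()].
#' @param categories named label-to-category vector.
#' @param cell_a,cell_b each a length-2 character vector naming the two
#'   categories of a cell (equal entries denote a within-category cell).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list with `observed` (cell_a - cell_b), `p` (two-sided),
#'   `null` (the permuted statistics).
#' @export
category_contrast_perm <- function(x, categories, cell_a, cell_b,
                                   n_perm = 1000, seed = 1) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  stat <- function(cat_map) {
    ca <- category_average(x, cat_map)
    category_cell(ca, cell_a[1], cell_a[2]) -
      category_cell(ca, cell_b[1], cell_b[2])
  }
  observed <- stat(categories)
  labs <- x$labels
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- stats::setNames(unname(categories[labs])[sample.int(length(labs))],
                              labs)
      stat(perm)
    }, 0)
  })
  p <- (1 + sum(abs(null) >= abs(observed) - 1e-12)) / (1 + n_perm)
  list(observed = observed, p = p, null = null)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities, eigendecomposes, and returns
#' coordinates from the top-k nonnegative eigenvalues. Axis signs are fixed
#' deterministically: the first nonzero loading of each axis is positive.
#' If fewer than `k` positive eigenvalues exist, fewer dimensions are
#' returned and a warning record is attached.
#'
#' @param x an [rdm()].
#' @param k number of dimensions (default 2).
#' @return list with `coordinates` (items x <= k), `eigenvalues` (all n),
#'   and optionally `warning`.
#' @export
classical_mds <- function(x, k = 2) {
  stopifnot(inherits(x, "rdm"))
  b <- double_center(x$matrix^2)
  eg <- eigen(b, symmetric = TRUE)
  ev <- eg$values
  tol <- 1e-9 * max(abs(ev), 1)
  npos <- sum(ev > tol)
  kk <- min(k, npos)
  warning_rec <- NULL
  if (kk < k) {
    warning_rec <- sprintf(
      "only %d positive eigenvalue(s); returning %d dimension(s)", npos, kk)
  }
  if (kk == 0) {
    coords <- matrix(0, nrow(x$matrix), 0)
  } else {
    coords <- eg$vectors[, seq_len(kk), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(kk)]), kk)
    for (j in seq_len(kk)) {
      nz <- which(abs(coords[, j]) > 1e-12)
      if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- x$labels
  out <- list(coordinates = coords, eigenvalues = ev)
  if (!is.null(warning_rec)) out$warning <- warning_rec
  out
}

#' Kendall's tau-a rank correlation
#'
#' `tau_a = (concordant - discordant) / (n (n - 1) / 2)`; tied pairs count
#' as neither concordant nor discordant. This is the recommended statistic
#' for comparing RDMs against categorical model RDMs, which are full of
#' ties.
#'
#' @param x,y numeric vectors of equal length (>= 2); conventionally the
#'   strict lower triangles of two RDMs (diagonal excluded).
#' @return tau-a in `[-1, 1]`.
#' @export
kendall_tau_a <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("need n >= 2")
  check_no_na(x, "x"); check_no_na(y, "y")
  tau_a_cpp(as.numeric(x), as.numeric(y))
}

# tau-a between two RDMs restricted to shared labels, canonical
# lower-triangle vectorization
rdm_tau_a <- function(m1, m2) {
  kendall_tau_a(lower_tri_vec(m1), lower_tri_vec(m2))
}

#' Correlate a model RDM with subject RDM timecourses
#'
#' Computes Kendall tau-a between the model RDM and each subject's RDM at
#' every timepoint, after removing the excluded categories (by default the
#' human faces, whose strong neural response would otherwise dominate the
#' correlation) from both sides.
#'
#' @param subject_tcs list of `rdm_timecourse` objects (one per subject).
#' @param model_rdm an [rdm()] whose labels cover the retained items.
#' @param stimuli the [stimulus_set()] (category lookup).
#' @param exclude_categories categories removed from both model and neural
#'   RDMs (default `"human_face"`).
#' @return list with `tau` (subjects x timepoints), `times_ms`, `mean`,
#'   `sem`, and the retained `labels`.
#' @export
model_correlation_timecourse <- function(subject_tcs, model_rdm, stimuli,
                                         exclude_categories = "human_face") {
  cat_of <- stats::setNames(stimuli$category, stimuli$id)
  keep_labels <- subject_tcs[[1]]$labels
  keep_labels <- keep_labels[!cat_of[keep_labels] %in% exclude_categories]
  miss <- setdiff(keep_labels, model_rdm$labels)
  if (length(miss)) {
    stopf("model RDM is missing items: %s", paste(miss, collapse = ", "))
  }
  mm <- rdm_subset(model_rdm, keep_labels)$matrix
  times <- subject_tcs[[1]]$times_ms
  tau <- matrix(NA_real_, length(subject_tcs), length(times))
  for (s in seq_along(subject_tcs)) {
    tc <- subject_tcs[[s]]
    idx <- match(keep_labels, tc$labels)
    for (ti in seq_along(times)) {
      tau[s, ti] <- rdm_tau_a(tc$array[idx, idx, ti], mm)
    }
  }
  list(tau = tau, times_ms = times, mean = colMeans(tau),
       sem = apply(tau, 2, stats::sd) / sqrt(nrow(tau)),
       labels = keep_labels)
}

#' Noise ceiling for RDM-model correlations
#'
#' Upper bound: mean over subjects of tau-a between each subject's RDM and
#' the all-subject mean RDM. Lower bound: the same with the subject's own
#' RDM left out of the mean.
#'
#' @param subject_rdms list of [rdm()] objects (>= 2 subjects, same labels).
#' @return named numeric vector `c(lower =, upper =)`.
#' @export
noise_ceiling <- function(subject_rdms) {
  n <- length(subject_rdms)
  if (n < 2) stopf("noise ceiling needs >= 2 subjects")
  mats <- lapply(subject_rdms, function(r) r$matrix)
  total <- Reduce(`+`, mats)
  upper <- mean(vapply(seq_len(n), function(s) {
    rdm_tau_a(mats[[s]], total / n)
  }, 0))
  lower <- mean(vapply(seq_len(n), function(s) {
    rdm_tau_a(mats[[s]], (total - mats[[s]]) / (n - 1))
  }, 0))
  c(lower = lower, upper = upper)
}

#' fMRI-MEG representational fusion
#'
#' Correlates a group-average fMRI RDM for each region of interest with the
#' time-varying MEG RDM of every MEG subject (the two cohorts are different
#' individuals, so the pairing is group-fMRI against each MEG subject).
#' Human faces are removed by default, so significant correlations reflect
#' the representation of objects with and without an illusory face.
#'
#' @param fmri_rdms named list of [rdm()] objects, one per ROI (group
#'   averages at the stimulus level).
#' @param subject_tcs list of MEG `rdm_timecourse` objects.
#' @param stimuli the [stimulus_set()].
#' @param exclude_categories categories removed from both sides (default
#'   `"human_face"`).
#' @return list with `tau` (subjects x timepoints x ROIs), `times_ms`,
#'   `mean` and `sem` (timepoints x ROIs), `rois`.
#' @export
fusion_timecourse <- function(fmri_rdms, subject_tcs, stimuli,
                              exclude_categories = "human_face") {
  rois <- names(fmri_rdms)
  times <- subject_tcs[[1]]$times_ms
  tau <- array(NA_real_, c(length(subject_tcs), length(times), length(rois)),
               dimnames = list(NULL, NULL, rois))
  for (ri in seq_along(rois)) {
    mc <- model_correlation_timecourse(subject_tcs, fmri_rdms[[ri]], stimuli,
                                       exclude_categories)
    tau[, , ri] <- mc$tau
  }
  mean_mat <- apply(tau, c(2, 3), mean)
  sem_mat <- apply(tau, c(2, 3), stats::sd) / sqrt(dim(tau)[1])
  list(tau = tau, times_ms = times, mean = mean_mat, sem = sem_mat,
       rois = rois)
}
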