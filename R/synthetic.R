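# Synthetic-data generators. These define the study conditions used by every
# test: a 3-category stimulus design (human faces / illusory faces / matched
# objects) whose representational geometry follows a configurable,
# time-varying category-distance trajectory.

# --- trajectory -------------------------------------------------------------

#' Build a time-varying category-geometry trajectory
#'
#' A trajectory specifies, at a set of keyframe latencies, the 3 x 3 matrix of
#' target category-centroid distances `delta(t)` (rows/columns in the order
#' human_face, illusory_face, matched_object) and the within-category exemplar
#' spread `sigma_ex(t)`. Between keyframes both interpolate piecewise-linearly;
#' before `onset_ms` both are zero (no stimulus-driven signal before the
#' response onset); between `onset_ms` and the first keyframe they ramp
#' linearly from zero; after the last keyframe they are held constant.
#'
#' Each keyframe distance matrix must be symmetric, zero-diagonal,
#' nonnegative, and embeddable as three points in the plane (i.e. satisfy the
#' triangle inequality); convex combinations of such matrices remain
#' embeddable, so the whole trajectory is realizable in a 2-D latent space.
#'
#' @param keyframes list of keyframes, each `list(time_ms =, delta = 3x3
#'   matrix, sigma_ex = scalar >= 0)`, with strictly increasing times all
#'   at or after `onset_ms`.
#' @param onset_ms latency (ms) before which all signal is zero.
#' @return a `trajectory` object; query it with [trajectory_delta()] and
#'   [trajectory_sigma()].
#' @export
build_trajectory <- function(keyframes, onset_ms = 60) {
  if (!length(keyframes)) stopf("at least one keyframe is required")
  times <- vapply(keyframes, function(k) as.numeric(k$time_ms), 0)
  if (any(diff(times) <= 0)) stopf("keyframe times must be strictly increasing")
  if (any(times < onset_ms)) stopf("keyframe times must be >= onset_ms")
  deltas <- lapply(seq_along(keyframes), function(i) {
    d <- as.matrix(keyframes[[i]]$delta)
    check_distance_matrix(d, what = sprintf("delta@%gms", times[i]))
    if (nrow(d) != 3) stopf("delta@%gms must be 3 x 3", times[i])
    # triangle inequality guarantees a planar 3-point embedding
    tri <- c(d[1, 2] + d[2, 3] - d[1, 3], d[1, 2] + d[1, 3] - d[2, 3],
             d[1, 3] + d[2, 3] - d[1, 2])
    if (any(tri < -1e-8)) {
      stopf("delta@%gms is not embeddable (triangle inequality violated)",
            times[i])
    }
    ev <- eigen(double_center(d^2), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev), 1)) {
      stopf("delta@%gms is not embeddable (negative Gram eigenvalue %g)",
            times[i], min(ev))
    }
    dimnames(d) <- list(CATEGORIES, CATEGORIES)
    d
  })
  sigmas <- vapply(keyframes, function(k) as.numeric(k$sigma_ex), 0)
  if (any(sigmas < 0)) stopf("sigma_ex must be nonnegative")
  structure(list(times = times, deltas = deltas, sigmas = sigmas,
                 onset_ms = onset_ms),
            class = "trajectory")
}

# shared piecewise-linear interpolation of keyframe weights at time t:
# returns the keyframe mixing weights (a vector summing to <= 1; all zero
# before onset, ramping into the first keyframe).
traj_weights <- function(traj, t) {
  times <- traj$times
  w <- numeric(length(times))
  if (t < traj$onset_ms) return(w)
  if (t <= times[1]) {
    span <- times[1] - traj$onset_ms
    w[1] <- if (span <= 0) 1 else (t - traj$onset_ms) / span
    return(w)
  }
  if (t >= times[length(times)]) {
    w[length(times)] <- 1
    return(w)
  }
  i <- findInterval(t, times)
  frac <- (t - times[i]) / (times[i + 1] - times[i])
  w[i] <- 1 - frac
  w[i + 1] <- frac
  w
}

#' Evaluate a trajectory's category-distance matrix at a latency
#' @param traj a [build_trajectory()] object.
#' @param time_ms latency in ms.
#' @return 3 x 3 distance matrix.
#' @export
trajectory_delta <- function(traj, time_ms) {
  stopifnot(inherits(traj, "trajectory"))
  w <- traj_weights(traj, time_ms)
  out <- matrix(0, 3, 3, dimnames = list(CATEGORIES, CATEGORIES))
  for (i in seq_along(w)) if (w[i] != 0) out <- out + w[i] * traj$deltas[[i]]
  out
}

#' Evaluate a trajectory's exemplar spread at latencies
#' @param traj a [build_trajectory()] object.
#' @param time_ms vector of latencies in ms.
#' @return numeric vector of `sigma_ex(t)`.
#' @export
trajectory_sigma <- function(traj, time_ms) {
  stopifnot(inherits(traj, "trajectory"))
  vapply(time_ms, function(t) sum(traj_weights(traj, t) * traj$sigmas), 0)
}

#' Default category-geometry trajectory
#'
#' Encodes the canonical representational dynamics of the illusory-face
#' response: by 130 ms all three categories are separable, with illusory
#' faces lying closer to human faces than the matched objects do; at the
#' ~160 ms peak the separation is maximal (still with the illusory faces
#' intermediate); by ~260 ms the illusory faces have regrouped with the
#' matched objects (their mutual distance collapses) while human faces
#' remain maximally distinct from both object categories.
#'
#' @param onset_ms response onset latency (default 60 ms).
#' @param sigma_ex exemplar spread at every keyframe (default 0.4).
#' @return a `trajectory`.
#' @export
default_trajectory <- function(onset_ms = 60, sigma_ex = 0.4) {
  d3 <- function(hi, hm, im) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- hi
    m[1, 3] <- m[3, 1] <- hm
    m[2, 3] <- m[3, 2] <- im
    m
  }
  build_trajectory(list(
    list(time_ms = 130, delta = d3(0.8, 1.0, 0.40), sigma_ex = sigma_ex),
    list(time_ms = 160, delta = d3(1.2, 1.6, 0.80), sigma_ex = sigma_ex),
    list(time_ms = 260, delta = d3(1.6, 1.7, 0.15), sigma_ex = sigma_ex)
  ), onset_ms = onset_ms)
}

# --- configs ----------------------------------------------------------------

#' Synthetic MEG configuration
#'
#' Defaults reproduce the full recording design: 22 subjects, 160 axial
#' gradiometer channels, 96 stimuli (32 per category), 6 runs with 4 repeats
#' of every stimulus per run (2304 trials, 24 repeats per stimulus), epochs
#' from -100 to 1000 ms sampled at 1000 Hz.
#'
#' @param n_subjects,n_channels,n_exemplars_per_category,n_runs,repeats_per_run
#'   design counts (all positive integers).
#' @param sample_rate_hz sampling rate in Hz.
#' @param epoch_ms length-2 epoch window (must contain 0).
#' @param sensor_noise_sd i.i.d. Gaussian sensor noise SD.
#' @param signal_gain multiplier on the mixed latent signal (0 = pure noise).
#' @param exemplar_dim dimensionality of the per-exemplar offset subspace.
#' @param yoke_cor correlation between the offsets of each yoked
#'   illusory/matched pair (visual similarity of yokes).
#' @param seed integer seed; fully determines the generated data.
#' @return a `synthetic_meg_config` list.
#' @export
synthetic_meg_config <- function(n_subjects = 22, n_channels = 160,
                                 n_exemplars_per_category = 32, n_runs = 6,
                                 repeats_per_run = 4, sample_rate_hz = 1000,
                                 epoch_ms = c(-100, 1000),
                                 sensor_noise_sd = 1, signal_gain = 1,
                                 exemplar_dim = 4, yoke_cor = 0.5, seed = 1) {
  counts <- c(n_subjects, n_channels, n_exemplars_per_category, n_runs,
              repeats_per_run, sample_rate_hz, exemplar_dim)
  if (any(counts < 1)) stopf("all design counts must be positive")
  if (length(epoch_ms) != 2 || epoch_ms[1] > 0 || epoch_ms[2] < 0) {
    stopf("epoch window must contain 0 ms")
  }
  if (sensor_noise_sd < 0) stopf("sensor_noise_sd must be nonnegative")
  if (abs(yoke_cor) > 1) stopf("yoke_cor must lie in [-1, 1]")
  structure(list(n_subjects = n_subjects, n_channels = n_channels,
                 n_exemplars_per_category = n_exemplars_per_category,
                 n_runs = n_runs, repeats_per_run = repeats_per_run,
                 sample_rate_hz = sample_rate_hz, epoch_ms = epoch_ms,
                 sensor_noise_sd = sensor_noise_sd,
                 signal_gain = signal_gain, exemplar_dim = exemplar_dim,
                 yoke_cor = yoke_cor, seed = as.integer(seed)),
            class = "synthetic_meg_config")
}

#' Epoch dimensions implied by a synthetic MEG configuration
#' @param cfg a [synthetic_meg_config()].
#' @return named vector: trials, channels, timepoints per subject.
#' @export
meg_dims <- function(cfg) {
  n_stim <- 3L * cfg$n_exemplars_per_category
  c(trials = n_stim * cfg$n_runs * cfg$repeats_per_run,
    channels = cfg$n_channels,
    timepoints = length(seq(cfg$epoch_ms[1], cfg$epoch_ms[2],
                            by = 1000 / cfg$sample_rate_hz)))
}

#' ROI response profile for the synthetic fMRI generator
#'
#' @param roi_name label, e.g. `"FFA"`.
#' @param delta 3 x 3 category-distance matrix (order: human_face,
#'   illusory_face, matched_object). Face-selective profiles carry
#'   `delta[illusory, matched] > 0`; object/scene profiles set it to 0.
#' @param exemplar_spread within-category spread.
#' @param voxel_range length-2 integer range the ROI's voxel count is drawn
#'   from (per subject).
#' @return an `roi_profile`.
#' @export
roi_profile <- function(roi_name, delta, exemplar_spread = 0.4,
                        voxel_range = c(40, 80)) {
  delta <- as.matrix(delta)
  check_distance_matrix(delta, what = sprintf("delta_%s", roi_name))
  if (nrow(delta) != 3) stopf("delta must be 3 x 3")
  if (voxel_range[1] < 1) stopf("an ROI needs at least 1 voxel")
  dimnames(delta) <- list(CATEGORIES, CATEGORIES)
  structure(list(roi_name = roi_name, delta = delta,
                 exemplar_spread = exemplar_spread,
                 voxel_range = as.integer(voxel_range)),
            class = "roi_profile")
}

#' Default ROI profiles
#'
#' Four regions with differing illusory-face sensitivity: the face-selective
#' profiles (FFA, OFA) separate illusory faces from their matched objects,
#' while the object- and scene-selective profiles (LO, PPA) carry no
#' illusory-vs-matched distance at all (the two object categories share a
#' centroid). All four separate human faces from objects.
#'
#' @param voxel_range voxel-count range applied to every profile (the
#'   desk-scale default keeps ROIs small; pass e.g. `c(86, 577)` for
#'   realistically sized regions).
#' @return named list of [roi_profile()] objects.
#' @export
default_roi_profiles <- function(voxel_range = c(40, 80)) {
  d3 <- function(hi, hm, im) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- hi
    m[1, 3] <- m[3, 1] <- hm
    m[2, 3] <- m[3, 2] <- im
    m
  }
  list(
    FFA = roi_profile("FFA", d3(0.8, 1.1, 0.6), voxel_range = voxel_range),
    OFA = roi_profile("OFA", d3(0.85, 1.0, 0.5), voxel_range = voxel_range),
    LO  = roi_profile("LO",  d3(1.0, 1.0, 0.0), voxel_range = voxel_range),
    PPA = roi_profile("PPA", d3(0.7, 0.7, 0.0), voxel_range = voxel_range)
  )
}

#' Behavioral rating configuration
#'
#' Defaults follow the face-ness rating norms of the stimulus set: on the
#' 0-10 scale ("Rate how easily can you can see a face in this image"),
#' human faces average 9.96 (SD 0.10) across items, illusory faces 6.27
#' (SD 0.79), and matched objects 0.70 (SD 0.36).
#'
#' @param means,sds per-category item-mean and item-SD (order: human,
#'   illusory, matched).
#' @param n_raters raters (default 20).
#' @param rater_sd within-item across-rater SD (capped per item at 90% of
#'   the maximum SD the bounded scale admits).
#' @param bounds rating scale bounds.
#' @param n_per_category items per category.
#' @param seed integer seed.
#' @return a `rating_config`.
#' @export
rating_config <- function(means = c(9.96, 6.27, 0.70),
                          sds = c(0.10, 0.79, 0.36), n_raters = 20,
                          rater_sd = 0.5, bounds = c(0, 10),
                          n_per_category = 32, seed = 1) {
  if (any(means < bounds[1]) || any(means > bounds[2])) {
    stopf("category means must lie within the rating bounds")
  }
  if (any(sds < 0) || rater_sd < 0) stopf("SDs must be nonnegative")
  if (n_raters < 1) stopf("need at least one rater")
  structure(list(means = means, sds = sds, n_raters = n_raters,
                 rater_sd = rater_sd, bounds = bounds,
                 n_per_category = n_per_category, seed = as.integer(seed)),
            class = "rating_config")
}

# --- shared latent-geometry machinery --------------------------------------

# Embed a 3x3 category-distance matrix as 3 centered points in the plane.
embed_centroids <- function(delta) {
  if (max(delta) == 0) return(matrix(0, 3, 2))
  emb <- classical_mds(rdm(delta, CATEGORIES, metric = "custom"), k = 2)
  coords <- emb$coordinates
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  sweep(coords, 2, colMeans(coords))
}

# Per-exemplar latent offsets (n_stim x exemplar_dim), fixed across time and
# subjects. Yoked illusory/matched pairs get correlated offsets.
draw_exemplar_offsets <- function(stimuli, exemplar_dim, yoke_cor, seed) {
  n <- nrow(stimuli)
  with_seed(seed, {
    off <- matrix(stats::rnorm(n * exemplar_dim), n, exemplar_dim)
    rownames(off) <- stimuli$id
    ill <- stimuli$id[stimuli$category == "illusory_face"]
    for (id in ill) {
      yoke <- stimuli$yoke_id[stimuli$id == id]
      off[yoke, ] <- yoke_cor * off[id, ] +
        sqrt(1 - yoke_cor^2) * stats::rnorm(exemplar_dim)
    }
    off
  })
}

# --- MEG generator ----------------------------------------------------------

#' Generate a synthetic MEG dataset
#'
#' For every timepoint the three category centroids are embedded in a 2-D
#' latent space whose pairwise distances equal the trajectory's `delta(t)`;
#' each stimulus adds a fixed per-exemplar offset (orthogonal latent
#' subspace) scaled by `sigma_ex(t)`; each subject observes a random linear
#' sensor mixing of the latent vector, times `signal_gain`, plus i.i.d.
#' Gaussian sensor noise. Everything is reproducible from `cfg$seed`.
#'
#' @param cfg a [synthetic_meg_config()].
#' @param traj a [build_trajectory()] trajectory (default
#'   [default_trajectory()]).
#' @return list with one [sensor_epochs()] per subject; the generating
#'   [stimulus_set()] is attached as `attr(, "stimuli")`.
#' @export
generate_meg_dataset <- function(cfg, traj = default_trajectory()) {
  stopifnot(inherits(cfg, "synthetic_meg_config"),
            inherits(traj, "trajectory"))
  stimuli <- make_stimulus_set(cfg$n_exemplars_per_category)
  n_stim <- nrow(stimuli)
  times <- seq(cfg$epoch_ms[1], cfg$epoch_ms[2], by = 1000 / cfg$sample_rate_hz)
  n_t <- length(times)
  cat_idx <- match(stimuli$category, CATEGORIES)
  offsets <- draw_exemplar_offsets(stimuli, cfg$exemplar_dim, cfg$yoke_cor,
                                   derive_seed(cfg$seed, 1L))
  centroids <- lapply(times, function(t) embed_centroids(trajectory_delta(traj, t)))
  sigmas <- trajectory_sigma(traj, times)
  latent_dim <- 2L + cfg$exemplar_dim
  n_trials <- n_stim * cfg$n_runs * cfg$repeats_per_run

  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    subjects[[s]] <- with_seed(derive_seed(cfg$seed, 1000L + s), {
      mixing <- matrix(stats::rnorm(cfg$n_channels * latent_dim),
                       cfg$n_channels, latent_dim) / sqrt(latent_dim)
      stim_rows <- integer(0)
      run_col <- integer(0)
      rep_col <- integer(0)
      for (r in seq_len(cfg$n_runs)) {
        for (k in seq_len(cfg$repeats_per_run)) {
          stim_rows <- c(stim_rows, sample.int(n_stim))
          run_col <- c(run_col, rep(r, n_stim))
          rep_col <- c(rep_col, rep(k, n_stim))
        }
      }
      data <- array(stats::rnorm(n_trials * cfg$n_channels * n_t,
                                 sd = cfg$sensor_noise_sd),
                    dim = c(n_trials, cfg$n_channels, n_t))
      if (cfg$signal_gain != 0) {
        for (ti in seq_len(n_t)) {
          latent <- cbind(centroids[[ti]][cat_idx, , drop = FALSE],
                          offsets * sigmas[ti])
          sig <- cfg$signal_gain * (latent %*% t(mixing))
          data[, , ti] <- data[, , ti] + sig[stim_rows, , drop = FALSE]
        }
      }
      trials <- data.frame(stimulus_id = stimuli$id[stim_rows],
                           category = stimuli$category[stim_rows],
                           run = run_col, repeat_idx = rep_col,
                           stringsAsFactors = FALSE)
      sensor_epochs(data, times, trials, cfg$sample_rate_hz)
    })
  }
  attr(subjects, "stimuli") <- stimuli
  subjects
}

# --- fMRI generator ---------------------------------------------------------

#' Generate a synthetic fMRI beta dataset
#'
#' Per subject and ROI, betas are an ROI-specific random voxel projection of
#' (category centroid per the ROI's distance profile + fixed exemplar
#' offset), replicated over runs with independent run-level noise.
#'
#' @param n_subjects number of subjects (default 16).
#' @param n_runs number of runs (>= 2, default 7: one presentation of every
#'   stimulus per run).
#' @param profiles named list of [roi_profile()] objects.
#' @param n_exemplars_per_category exemplars per category (default 32).
#' @param noise_sd run-level beta noise SD.
#' @param signal_gain signal multiplier (0 = pure noise).
#' @param exemplar_dim latent offset dimensionality.
#' @param yoke_cor yoked-offset correlation.
#' @param seed integer seed.
#' @return list (one element per subject) of named lists (one per ROI) of
#'   stimuli x runs x voxels arrays; generating [stimulus_set()] attached as
#'   `attr(, "stimuli")`.
#' @export
generate_fmri_dataset <- function(n_subjects = 16, n_runs = 7,
                                  profiles = default_roi_profiles(),
                                  n_exemplars_per_category = 32,
                                  noise_sd = 1, signal_gain = 1,
                                  exemplar_dim = 4, yoke_cor = 0.5,
                                  seed = 1) {
  if (n_runs < 2) stopf("need >= 2 runs for run-wise cross-validation")
  stimuli <- make_stimulus_set(n_exemplars_per_category)
  n_stim <- nrow(stimuli)
  cat_idx <- match(stimuli$category, CATEGORIES)
  offsets <- draw_exemplar_offsets(stimuli, exemplar_dim, yoke_cor,
                                   derive_seed(seed, 2L))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subjects[[s]] <- with_seed(derive_seed(seed, 5000L + s), {
      rois <- lapply(profiles, function(p) {
        v <- sample(seq(p$voxel_range[1], p$voxel_range[2]), 1)
        centroids <- embed_centroids(p$delta)
        latent <- cbind(centroids[cat_idx, , drop = FALSE],
                        offsets * p$exemplar_spread)
        proj <- matrix(stats::rnorm(v * ncol(latent)), v, ncol(latent)) /
          sqrt(ncol(latent))
        sig <- signal_gain * (latent %*% t(proj))
        betas <- array(stats::rnorm(n_stim * n_runs * v, sd = noise_sd),
                       dim = c(n_stim, n_runs, v),
                       dimnames = list(stimuli$id, NULL, NULL))
        for (r in seq_len(n_runs)) betas[, r, ] <- betas[, r, ] + sig
        betas
      })
      names(rois) <- vapply(profiles, function(p) p$roi_name, "")
      rois
    })
  }
  attr(subjects, "stimuli") <- stimuli
  subjects
}

# --- ratings ----------------------------------------------------------------

# Bounded draw with exact mean/SD via a scaled Beta distribution
# (method-of-moments); sd = 0 degenerates to the mean.
rbeta_bounded <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  m <- (mean - lo) / (hi - lo)
  v <- (sd / (hi - lo))^2
  if (v >= m * (1 - m)) {
    stopf("sd %g is infeasible for a bounded scale with mean %g", sd, mean)
  }
  nu <- m * (1 - m) / v - 1
  lo + (hi - lo) * stats::rbeta(n, m * nu, (1 - m) * nu)
}

#' Generate behavioral face-ness ratings
#'
#' Per-image latent means are drawn on the bounded rating scale to match the
#' configured per-category mean and SD exactly in expectation (scaled Beta,
#' so no clipping bias near the scale ends); each rater's rating is a
#' bounded draw around the image's latent mean.
#'
#' @param cfg a [rating_config()].
#' @return matrix raters x images (colnames = stimulus ids), with the
#'   generating [stimulus_set()] as `attr(, "stimuli")` and the latent item
#'   means as `attr(, "item_means")`.
#' @export
generate_ratings <- function(cfg) {
  stopifnot(inherits(cfg, "rating_config"))
  stimuli <- make_stimulus_set(cfg$n_per_category)
  lo <- cfg$bounds[1]; hi <- cfg$bounds[2]
  with_seed(cfg$seed, {
    item_means <- numeric(nrow(stimuli))
    for (ci in seq_along(CATEGORIES)) {
      idx <- which(stimuli$category == CATEGORIES[ci])
      item_means[idx] <- rbeta_bounded(length(idx), cfg$means[ci],
                                       cfg$sds[ci], lo, hi)
    }
    ratings <- matrix(0, cfg$n_raters, nrow(stimuli),
                      dimnames = list(NULL, stimuli$id))
    for (j in seq_len(nrow(stimuli))) {
      m <- item_means[j]
      max_sd <- 0.9 * sqrt((m - lo) * (hi - m))
      ratings[, j] <- rbeta_bounded(cfg$n_raters, m,
                                    min(cfg$rater_sd, max_sd), lo, hi)
    }
    attr(ratings, "stimuli") <- stimuli
    attr(ratings, "item_means") <- stats::setNames(item_means, stimuli$id)
    ratings
  })
}
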