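# Temporal downsampling, per-subject PCA dimensionality reduction, and
# trial-to-pattern aggregation.

#' Downsample sensor epochs by bin averaging
#'
#' Each output sample is the mean of the source samples nearest to it: the
#' output grid keeps the first input latency and steps by
#' `1000 / target_rate_hz` ms, and every source sample is averaged into the
#' nearest output gridpoint. For an exact integer rate ratio this is
#' non-overlapping bin-mean downsampling (anti-aliasing by averaging); the
#' first and last bins may be partial. The trial table is unchanged.
#'
#' @param epochs a [sensor_epochs()].
#' @param target_rate_hz target rate; must divide the source rate.
#' @return downsampled [sensor_epochs()].
#' @export
downsample <- function(epochs, target_rate_hz) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  src <- epochs$sample_rate_hz
  ratio <- src / target_rate_hz
  if (abs(ratio - round(ratio)) > 1e-8) {
    divisors <- which(src %% seq_len(src) == 0)
    nearest <- divisors[which.min(abs(src / divisors - target_rate_hz))]
    stopf(paste0("source rate %g Hz is not divisible by target %g Hz; ",
                 "nearest valid target is %g Hz"),
          src, target_rate_hz, src / nearest)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(epochs)
  step_out <- 1000 / target_rate_hz
  t0 <- epochs$times_ms[1]
  grp <- as.integer(round((epochs$times_ms - t0) / step_out))
  times_out <- t0 + sort(unique(grp)) * step_out
  d <- dim(epochs$data)
  n_out <- length(times_out)
  out <- array(0, dim = c(d[1], d[2], n_out))
  counts <- tabulate(grp + 1L, nbins = max(grp) + 1L)
  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    sl <- epochs$data[, , idx, drop = FALSE]
    out[, , g + 1L] <- rowSums(sl, dims = 2) / length(idx)
  }
  sensor_epochs(out, times_out, epochs$trials, target_rate_hz,
                feature_space = epochs$feature_space)
}

#' Reduce channel dimensionality with PCA
#'
#' Fits PCA once per dataset on all trial-timepoints concatenated
#' (observations = trials x timepoints, variables = channels), retains the
#' smallest number of components whose cumulative explained variance reaches
#' `var_retained`, and returns the epochs in component space. Component signs
#' are fixed (largest-magnitude loading positive) for determinism.
#'
#' @param epochs a [sensor_epochs()] (>= 2 trials).
#' @param var_retained fraction of variance to retain, in `(0, 1]`
#'   (default 0.99).
#' @return [sensor_epochs()] with `feature_space = "components"`; loadings,
#'   channel means, and per-component explained variance are attached as
#'   attributes `loadings`, `center`, `explained`.
#' @export
pca_reduce <- function(epochs, var_retained = 0.99) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  if (var_retained <= 0 || var_retained > 1) {
    stopf("var_retained must lie in (0, 1]")
  }
  d <- dim(epochs$data)
  if (d[1] < 2) stopf("PCA needs at least 2 trials")
  # observations x channels
  x <- matrix(aperm(epochs$data, c(1, 3, 2)), d[1] * d[3], d[2])
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  cv <- crossprod(xc) / (nrow(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  if (total <= 0) stopf("data have zero variance; PCA undefined")
  cum <- cumsum(ev) / total
  k <- which(cum >= var_retained - 1e-12)[1]
  if (var_retained == 1) k <- min(d[2], nrow(xc))
  load <- eg$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| positive in each component
  for (j in seq_len(k)) {
    pivot <- which.max(abs(load[, j]))
    if (load[pivot, j] < 0) load[, j] <- -load[, j]
  }
  scores <- xc %*% load
  out <- aperm(array(scores, dim = c(d[1], d[3], k)), c(1, 3, 2))
  res <- sensor_epochs(out, epochs$times_ms, epochs$trials,
                       epochs$sample_rate_hz, feature_space = "components")
  attr(res, "loadings") <- load
  attr(res, "center") <- center
  attr(res, "explained") <- ev / total
  res
}

#' Extract one pattern per stimulus at a timepoint
#'
#' Averages all trials of each stimulus at the epoch timepoint nearest to
#' `time_ms` (which must lie within half a sample step of the grid).
#'
#' @param epochs a [sensor_epochs()].
#' @param time_ms requested latency in ms.
#' @return a [pattern_matrix()] (items = stimuli sorted by id), with the
#'   matched grid latency as attribute `time_ms`.
#' @export
stimulus_patterns <- function(epochs, time_ms) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  diffs <- abs(epochs$times_ms - time_ms)
  ti <- which.min(diffs)
  step <- 1000 / epochs$sample_rate_hz
  if (diffs[ti] > step / 2 + 1e-9) {
    stopf("time %g ms is not on the epoch grid (nearest: %g ms)",
          time_ms, epochs$times_ms[ti])
  }
  ids <- sort(unique(epochs$trials$stimulus_id))
  slab <- epochs$data[, , ti, drop = FALSE]
  dim(slab) <- dim(epochs$data)[1:2]
  grp <- factor(epochs$trials$stimulus_id, levels = ids)
  if (any(tabulate(grp, nbins = length(ids)) == 0)) {
    stopf("stimulus without trials: %s",
          paste(ids[tabulate(grp, nbins = length(ids)) == 0], collapse = ", "))
  }
  vals <- rowsum(slab, grp) / as.vector(table(grp))
  fs <- if (epochs$feature_space == "components") "components" else "channels"
  pm <- pattern_matrix(vals, ids, feature_space = fs)
  attr(pm, "time_ms") <- epochs$times_ms[ti]
  pm
}
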