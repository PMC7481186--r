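# Shared fixtures and independent oracles, built in code at test time.

# small high-SNR MEG dataset: 50-timepoint grid covering the 130/160/260 ms
# keyframes
tiny_meg <- function(n_subjects = 2, n_exemplars = 4, n_channels = 8,
                     signal_gain = 3, sensor_noise_sd = 0.5, seed = 7,
                     traj = default_trajectory()) {
  cfg <- synthetic_meg_config(
    n_subjects = n_subjects, n_channels = n_channels,
    n_exemplars_per_category = n_exemplars, n_runs = 2, repeats_per_run = 2,
    sample_rate_hz = 100, epoch_ms = c(-100, 390),
    sensor_noise_sd = sensor_noise_sd, signal_gain = signal_gain,
    seed = seed)
  generate_meg_dataset(cfg, traj)
}

cat_lookup <- function(stimuli) {
  stats::setNames(stimuli$category, stimuli$id)
}

# brute-force Kendall tau-a: explicit pair loop, ties count as neither
tau_a_brute <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx != 0 && dy != 0) s <- s + sign(dx) * sign(dy)
    }
  }
  s / (n * (n - 1) / 2)
}

# brute-force 1 - Spearman dissimilarity: rank explicitly, then Pearson
spearman_dissim_brute <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  1 - sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# brute-force 1-D TFCE by explicit height/cluster loops (independent of the
# compiled path)
tfce_brute <- function(m, E = 0.5, H = 2, dh = 0.1) {
  enhance <- function(v) {
    out <- numeric(length(v))
    if (max(v) <= 0) return(out)
    for (h in dh * seq_len(floor(max(v) / dh + 1e-9))) {
      above <- v >= h - 1e-12
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        idx <- starts[k]:ends[k]
        out[idx] <- out[idx] + length(idx)^E * h^H * dh
      }
    }
    out
  }
  enhance(pmax(m, 0)) - enhance(pmax(-m, 0))
}

# random valid RDM from random patterns
random_rdm <- function(n_items, n_features = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_items * n_features), n_items)
  compute_rdm(pattern_matrix(x, sprintf("it%02d", seq_len(n_items))))
}

# all permutations of 1..n as an n! x n matrix (exhaustive-null oracle)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

expect_rdm_valid <- function(x) {
  expect_s3_class(x, "rdm")
  expect_equal(x$matrix, t(x$matrix), tolerance = 1e-12)
  expect_equal(unname(diag(x$matrix)), rep(0, nrow(x$matrix)))
}
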