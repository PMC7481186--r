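test_that("trajectory interpolation is exact at keyframes, linear between,
           and silent before onset", {
  # valid 3-point metric with d12 = d13 = ab and d23 = 0
  d3 <- function(ab) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- ab
    m[1, 3] <- m[3, 1] <- ab
    m
  }
  # null trajectory: single zero keyframe
  tnull <- build_trajectory(list(list(time_ms = 100, delta = matrix(0, 3, 3),
                                      sigma_ex = 0)), onset_ms = 0)
  for (t in c(-50, 0, 100, 500)) {
    expect_equal(unname(trajectory_delta(tnull, t)), matrix(0, 3, 3))
  }
  # linear interpolation midpoint: delta12 goes 0 -> 2 between 100 and 200 ms
  tr <- build_trajectory(list(
    list(time_ms = 100, delta = d3(0), sigma_ex = 0),
    list(time_ms = 200, delta = d3(2), sigma_ex = 1)), onset_ms = 0)
  expect_equal(trajectory_delta(tr, 150)[1, 2], 1)
  expect_equal(trajectory_delta(tr, 100)[1, 2], 0)
  expect_equal(trajectory_delta(tr, 200)[1, 2], 2)
  expect_equal(trajectory_sigma(tr, c(-10, 150, 300)), c(0, 0.5, 1))

  # the default trajectory regroups illusory faces with matched objects:
  # their distance at 260 ms is below its 160 ms peak
  def <- default_trajectory()
  expect_lt(trajectory_delta(def, 260)["illusory_face", "matched_object"],
            trajectory_delta(def, 160)["illusory_face", "matched_object"])
  # and illusory faces stay closer to human faces than matched objects are
  expect_lt(trajectory_delta(def, 160)["human_face", "illusory_face"],
            trajectory_delta(def, 160)["human_face", "matched_object"])
})

test_that("invalid trajectory matrices are rejected naming the cell", {
  bad <- matrix(c(0, 1, 2, 1, 0, 1, 1, 1, 0), 3, 3)  # asymmetric
  expect_error(build_trajectory(list(list(time_ms = 100, delta = bad,
                                          sigma_ex = 0))),
               "delta@100ms\\[1,3\\]")
  neg <- matrix(0, 3, 3); neg[1, 2] <- neg[2, 1] <- -1
  expect_error(build_trajectory(list(list(time_ms = 100, delta = neg,
                                          sigma_ex = 0))), "negative")
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1; tri[1, 3] <- tri[3, 1] <- 5
  tri[2, 3] <- tri[3, 2] <- 1
  expect_error(build_trajectory(list(list(time_ms = 100, delta = tri,
                                          sigma_ex = 0))), "embeddable")
  expect_error(build_trajectory(list(
    list(time_ms = 200, delta = matrix(0, 3, 3), sigma_ex = 0),
    list(time_ms = 100, delta = matrix(0, 3, 3), sigma_ex = 0))),
    "increasing")
})

test_that("MEG generator produces the configured design and is seed-deterministic", {
  # full-design arithmetic: 2304 trials, 160 channels, 1101 samples
  expect_equal(unname(meg_dims(synthetic_meg_config())),
               c(2304, 160, 1101))

  meg <- tiny_meg(n_subjects = 2, n_exemplars = 4)
  ep <- meg[[1]]
  expect_equal(dim(ep$data), c(4 * 3 * 2 * 2, 8, 50))
  expect_equal(nrow(attr(meg, "stimuli")), 12)
  expect_equal(sort(unique(ep$trials$run)), 1:2)
  expect_equal(as.integer(table(ep$trials$stimulus_id)), rep(4L, 12))

  # byte-identical under the same seed; different under another
  meg2 <- tiny_meg(n_subjects = 2, n_exemplars = 4)
  expect_identical(meg[[2]]$data, meg2[[2]]$data)
  meg3 <- tiny_meg(n_subjects = 2, n_exemplars = 4, seed = 8)
  expect_false(identical(meg[[1]]$data, meg3[[1]]$data))
})

test_that("noise-free, zero-spread MEG collapses to identical
           within-category trials", {
  meg <- tiny_meg(n_subjects = 1, n_exemplars = 2, sensor_noise_sd = 0,
                  traj = default_trajectory(sigma_ex = 0))
  ep <- meg[[1]]
  for (ti in c(1, 25, 40)) {
    for (cat in unique(ep$trials$category)) {
      rows <- which(ep$trials$category == cat)
      slab <- ep$data[rows, , ti]
      expect_lt(max(abs(sweep(slab, 2, slab[1, ]))), 1e-12)
    }
  }
  # pre-onset everything is zero signal
  expect_equal(max(abs(ep$data[, , ep$times_ms < 60])), 0)
})

test_that("fMRI generator matches the run design and its degenerate cases", {
  fm <- generate_fmri_dataset(n_subjects = 1, n_runs = 7,
                              n_exemplars_per_category = 32, seed = 2)
  arr <- fm[[1]]$FFA
  expect_equal(dim(arr)[1:2], c(96L, 7L))
  expect_gte(dim(arr)[3], 40)
  expect_equal(names(fm[[1]]), c("FFA", "OFA", "LO", "PPA"))

  # zero noise: all run betas identical per stimulus
  fm0 <- generate_fmri_dataset(n_subjects = 1, n_runs = 3, noise_sd = 0,
                               n_exemplars_per_category = 2, seed = 2)
  a <- fm0[[1]]$FFA
  expect_equal(a[, 1, ], a[, 2, ])
  expect_equal(a[, 1, ], a[, 3, ])

  expect_error(generate_fmri_dataset(n_runs = 1), "2 runs")
  expect_error(roi_profile("X", matrix(0, 3, 3), voxel_range = c(0, 0)),
               "voxel")
})

test_that("ratings generator hits the configured category statistics", {
  # sigma = 0 everywhere: every rating equals its category mean
  r0 <- generate_ratings(rating_config(sds = c(0, 0, 0), rater_sd = 0,
                                       n_per_category = 4, n_raters = 3))
  stim <- attr(r0, "stimuli")
  expect_equal(unname(colMeans(r0)[stim$category == "human_face"]),
               rep(9.96, 4))
  expect_equal(unname(unique(as.vector(r0[, stim$category ==
                                            "matched_object"]))), 0.70)

  # defaults at large n_items: sample category means within 2 SE
  rl <- generate_ratings(rating_config(n_per_category = 400, n_raters = 5,
                                       seed = 11))
  sl <- attr(rl, "stimuli")
  im <- colMeans(rl)
  for (k in 1:3) {
    cat <- c("human_face", "illusory_face", "matched_object")[k]
    mu <- c(9.96, 6.27, 0.70)[k]
    # SE of the sample category mean: item variance plus rater noise on
    # each item's mean (5 raters), over 400 items
    se <- sqrt(c(0.10, 0.79, 0.36)[k]^2 + 0.5^2 / 5) / sqrt(400)
    expect_lt(abs(mean(im[sl$category == cat]) - mu), 2 * se)
  }
  # ratings never leave the bounded scale
  expect_gte(min(rl), 0)
  expect_lte(max(rl), 10)

  # yoked paired t: illusory faces rated far above their matched objects
  rd <- generate_ratings(rating_config(seed = 5))
  sd_ <- attr(rd, "stimuli")
  ill <- colMeans(rd)[sd_$id[sd_$category == "illusory_face"]]
  mat <- colMeans(rd)[sd_$yoke_id[sd_$category == "illusory_face"]]
  tt <- paired_ttest(ill, mat, tail = "one", bonferroni_k = 3)
  expect_gt(tt$t, 10)
  expect_lt(tt$p, 0.001)
})

test_that("high-SNR synthetic geometry is recovered in category RDMs", {
  meg <- tiny_meg(n_subjects = 2, n_exemplars = 6)
  stim <- attr(meg, "stimuli")
  tcs <- lapply(meg, rdm_timecourse)
  grp <- group_rdm_timecourse(tcs)
  traj <- default_trajectory()
  for (t in c(130, 160, 260)) {
    ca <- category_average(rdm_at(grp, t), cat_lookup(stim))
    inj <- trajectory_delta(traj, t)
    rho <- cor(ca$matrix[lower.tri(ca$matrix)], inj[lower.tri(inj)],
               method = "spearman")
    expect_gt(rho, 0.9)
  }
})
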