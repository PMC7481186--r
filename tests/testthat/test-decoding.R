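test_that("fold plans have the right counts, disjointness, and coverage", {
  set32 <- make_stimulus_set(32)
  pair <- c("illusory_face", "matched_object")

  paired <- make_folds(set32, pair, "paired_exemplar")
  expect_length(paired$folds, 32)
  expect_equal(nrow(paired$folds[[1]]$train), 62)
  expect_equal(nrow(paired$folds[[1]]$test), 2)
  # yoked partners held out together
  f1 <- paired$folds[[1]]$test$stimulus_id
  expect_equal(set32$yoke_id[set32$id == f1[1]], f1[2])

  exh <- make_folds(set32, pair, "exhaustive_exemplar")
  expect_length(exh$folds, 1024)

  set2 <- make_stimulus_set(2)
  rbe <- make_folds(set2, pair, "run_by_exemplar", runs = 1:3)
  expect_length(rbe$folds, 6)
  for (f in rbe$folds) {
    expect_length(intersect(f$train$stimulus_id, f$test$stimulus_id), 0)
  }
  expect_error(make_folds(set2, pair, "run_by_exemplar"), "run index")

  # property: disjointness and coverage over schemes and pairs
  for (scheme in c("paired_exemplar", "exhaustive_exemplar")) {
    for (p in list(c("human_face", "illusory_face"),
                   c("human_face", "matched_object"))) {
      plan <- make_folds(make_stimulus_set(4), p, scheme)
      tested <- character(0)
      for (f in plan$folds) {
        expect_length(intersect(f$train$stimulus_id, f$test$stimulus_id), 0)
        tested <- union(tested, f$test$stimulus_id)
      }
      expect_length(tested, 8)
    }
  }
})

test_that("regularized LDA matches its closed forms", {
  set.seed(31)
  # well-separated clouds: centroid test points are classified correctly
  x1 <- matrix(rnorm(20 * 3, 0), 20, 3)
  x2 <- matrix(rnorm(20 * 3, 5), 20, 3)
  tr <- rbind(x1, x2); y <- rep(c("a", "b"), each = 20)
  expect_equal(fit_predict_lda(tr, y, rbind(colMeans(x1), colMeans(x2))),
               c("a", "b"))

  # shrinkage = 1 is exactly nearest centroid
  te <- matrix(rnorm(40 * 3, 2.5, 4), 40, 3)
  pred <- fit_predict_lda(tr, y, te, shrinkage = 1)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  nearest <- ifelse(rowSums(sweep(te, 2, m1)^2) <
                    rowSums(sweep(te, 2, m2)^2), "a", "b")
  # ties toward the lexicographically first label
  d1 <- rowSums(sweep(te, 2, m1)^2); d2 <- rowSums(sweep(te, 2, m2)^2)
  nearest[d1 == d2] <- "a"
  expect_equal(pred, nearest)

  # weight vector solves S^-1 (mu2 - mu1): direct matrix-algebra oracle
  pooled <- (crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))) /
    (nrow(tr) - 2)
  w <- solve(pooled, m2 - m1)
  score <- te %*% w - sum(w * (m1 + m2)) / 2
  expect_equal(fit_predict_lda(tr, y, te, shrinkage = 0),
               ifelse(score > 0, "b", "a")[, 1])

  # MASS::lda as an independent implementation (equal priors, no shrinkage)
  fit <- MASS::lda(tr, grouping = factor(y), prior = c(0.5, 0.5))
  expect_equal(fit_predict_lda(tr, y, te, shrinkage = 0),
               as.character(predict(fit, te)$class))

  # singular covariance without shrinkage advises shrinkage
  xs <- cbind(rep(c(0, 1), 4), rep(c(0, 1), 4))
  expect_error(fit_predict_lda(xs, rep(c("a", "b"), 4), xs, shrinkage = 0),
               "shrinkage")
})

test_that("linear SVM separates separable data and is duplication-invariant", {
  set.seed(32)
  x <- rbind(matrix(rnorm(10 * 2, -3), 10, 2), matrix(rnorm(10 * 2, 3), 10, 2))
  y <- rep(c("a", "b"), each = 10)
  expect_equal(fit_predict_svm(x, y, x), y)
  pred1 <- fit_predict_svm(x, y, matrix(rnorm(20), 10, 2))
  pred2 <- fit_predict_svm(rbind(x, x), c(y, y), matrix(rnorm(20), 10, 2))
  set.seed(33); te <- matrix(rnorm(20), 10, 2)
  expect_equal(fit_predict_svm(x, y, te),
               fit_predict_svm(rbind(x, x), c(y, y), te))
})

test_that("LDA and SVM agree on high-SNR synthetic data", {
  meg <- tiny_meg(n_subjects = 1, n_exemplars = 4, signal_gain = 5,
                  sensor_noise_sd = 0.25)
  stim <- attr(meg, "stimuli")
  pair <- c("human_face", "matched_object")
  a_lda <- decode_timecourse(meg, stim, pair, "paired_exemplar", "lda")
  a_svm <- decode_timecourse(meg, stim, pair, "paired_exemplar", "svm")
  post <- a_lda$unit_values >= 130 & a_lda$unit_values <= 260
  expect_lt(mean(abs(a_lda$accuracy[, post] - a_svm$accuracy[, post])), 2)
})

test_that("noise-free separable epochs decode perfectly after onset", {
  meg <- tiny_meg(n_subjects = 1, n_exemplars = 2, sensor_noise_sd = 0,
                  traj = default_trajectory(sigma_ex = 0))
  stim <- attr(meg, "stimuli")
  res <- decode_timecourse(meg, stim, c("human_face", "matched_object"),
                           "paired_exemplar")
  post <- res$unit_values >= 130
  expect_equal(unname(res$accuracy[1, post]),
               rep(100, sum(post)))
})

test_that("paired and exhaustive schemes agree on high-SNR data", {
  meg <- tiny_meg(n_subjects = 2, n_exemplars = 4, signal_gain = 5,
                  sensor_noise_sd = 0.25)
  stim <- attr(meg, "stimuli")
  pair <- c("human_face", "matched_object")
  p <- decode_timecourse(meg, stim, pair, "paired_exemplar")
  e <- decode_timecourse(meg, stim, pair, "exhaustive_exemplar")
  post <- p$unit_values >= 130 & p$unit_values <= 260
  expect_lt(mean(abs(p$accuracy[, post] - e$accuracy[, post])), 2)
})

test_that("exemplar-wise label permutation keeps decoding at chance", {
  # permute category labels within yoked pairs (exemplar-wise) and check the
  # mean accuracy stays inside the binomial interval around 50%
  base <- tiny_meg(n_subjects = 1, n_exemplars = 4, signal_gain = 2)[[1]]
  stim <- make_stimulus_set(4)
  # restrict to the signal window so the permutation has something to destroy
  keep_t <- which(base$times_ms >= 130 & base$times_ms <= 260)
  base <- sensor_epochs(base$data[, , keep_t], base$times_ms[keep_t],
                        base$trials, base$sample_rate_hz)
  set.seed(41)
  draw_means <- vapply(1:20, function(draw) {
    ep <- base
    tr <- ep$trials
    for (i in which(stim$category == "illusory_face")) {
      if (runif(1) < 0.5) {   # swap this yoked pair's category labels
        a <- stim$id[i]; b <- stim$yoke_id[i]
        tr$category[tr$stimulus_id == a] <- "matched_object"
        tr$category[tr$stimulus_id == b] <- "illusory_face"
      }
    }
    ep$trials <- tr
    mean(decode_timecourse(ep, stim, c("illusory_face", "matched_object"),
                           "paired_exemplar")$accuracy)
  }, 0)
  # the permutation distribution of mean accuracy covers 50%
  expect_lt(abs(mean(draw_means) - 50),
            3 * stats::sd(draw_means) / sqrt(length(draw_means)) + 1)
})

test_that("ROI decoding recovers a single informative voxel perfectly", {
  stim <- make_stimulus_set(4)
  ids <- stim$id
  signal <- ifelse(stim$category == "illusory_face", 1,
                   ifelse(stim$category == "matched_object", -1, 0))
  betas <- array(rep(signal, 3), c(12, 3, 1), dimnames = list(ids, NULL, NULL))
  fm <- list(list(ROI = betas))
  res <- decode_roi(fm, stim, c("illusory_face", "matched_object"))
  expect_equal(unname(res$accuracy[1, 1]), 100)
  expect_equal(res$n_folds, 4 * 3)
})

test_that("searchlight spheres have the right size and reduce to single
           voxels", {
  expect_equal(nrow(sphere_offsets(3)), 123)
  expect_equal(nrow(sphere_offsets(1)), 7)
  expect_error(sphere_offsets(0.5), ">= 1")

  # single-voxel mask: searchlight equals decoding that voxel alone
  stim <- make_stimulus_set(3)
  set.seed(51)
  vol <- array(rnorm(9 * 3 * 3 * 3), c(9, 3, 3, 3),
               dimnames = list(stim$id, NULL, NULL, NULL))
  sig <- ifelse(stim$category == "human_face", 2, -2)
  vol[, 2, 2, 2] <- vol[, 2, 2, 2] + sig
  mask1 <- array(FALSE, c(3, 3, 3)); mask1[2, 2, 2] <- TRUE
  pair <- c("human_face", "matched_object")
  map1 <- searchlight_decode(vol, mask1, stim, pair, radius_voxels = 1)
  single <- decode_roi(
    list(list(V = array(vol[, 2, 2, 2], c(9, 1, 1),
                        dimnames = list(stim$id, NULL, NULL)))),
    stim, pair, scheme = "paired_exemplar")
  expect_equal(map1[2, 2, 2], unname(single$accuracy[1, 1]))
  expect_true(all(is.na(map1[-14])))
})

test_that("searchlight localizes an implanted signal blob", {
  stim <- make_stimulus_set(4)
  set.seed(52)
  dims <- c(7, 7, 3)
  vol <- array(rnorm(12 * prod(dims), sd = 0.5), c(12, dims),
               dimnames = list(stim$id, NULL, NULL, NULL))
  sig <- ifelse(stim$category == "illusory_face", 1.5,
                ifelse(stim$category == "matched_object", -1.5, 0))
  blob <- rbind(c(2, 2, 2), c(3, 2, 2), c(2, 3, 2), c(3, 3, 2), c(2, 2, 1))
  for (b in seq_len(nrow(blob))) {
    vol[, blob[b, 1], blob[b, 2], blob[b, 3]] <-
      vol[, blob[b, 1], blob[b, 2], blob[b, 3]] + sig
  }
  mask <- array(TRUE, dims)
  accmap <- searchlight_decode(vol, mask, stim,
                               c("illusory_face", "matched_object"),
                               radius_voxels = 1.5)
  # spheres overlapping the blob decode far better than distant ones
  centers <- which(mask, arr.ind = TRUE)
  dist_to_blob <- apply(centers, 1, function(cc) {
    min(sqrt(colSums((t(blob) - as.numeric(cc))^2)))
  })
  acc <- accmap[centers]
  expect_gt(mean(acc[dist_to_blob <= 1.5]), mean(acc[dist_to_blob > 2.5]) + 15)
  # and the global argmax lies on a sphere touching the blob
  top <- which(accmap == max(accmap), arr.ind = TRUE)
  top_d <- apply(top, 1, function(cc) {
    min(sqrt(colSums((t(blob) - as.numeric(cc))^2)))
  })
  expect_lte(min(top_d), 1.5)
})
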