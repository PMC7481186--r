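test_that("compute_rdm matches brute-force rank-then-Pearson dissimilarity", {
  # identical patterns: dissimilarity 0
  pm <- pattern_matrix(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)),
                       c("a", "b", "c"))
  r <- compute_rdm(pm)
  expect_rdm_valid(r)
  expect_equal(r$matrix["a", "b"], 0)
  # rank reversal: 1 - (-1) = 2
  expect_equal(r$matrix["a", "c"], 2)

  set.seed(61)
  x <- matrix(rnorm(30), 3, 10)
  rr <- compute_rdm(pattern_matrix(x, c("p", "q", "s")))
  for (i in 2:3) for (j in 1:(i - 1)) {
    expect_equal(rr$matrix[i, j], spearman_dissim_brute(x[i, ], x[j, ]),
                 tolerance = 1e-12)
  }

  # constant feature vector names the offending item
  bad <- pattern_matrix(rbind(c(1, 1, 1), c(1, 2, 3)), c("flat", "ok"))
  expect_error(compute_rdm(bad), "flat")
})

test_that("rdm timecourses have one valid RDM per timepoint", {
  ep <- pca_reduce(tiny_meg(n_subjects = 1, n_exemplars = 2)[[1]])
  tc <- rdm_timecourse(ep)
  expect_equal(dim(tc$array), c(6, 6, 50))
  expect_equal(tc$times_ms, ep$times_ms)
  for (ti in c(1, 30)) {
    expect_rdm_valid(rdm(tc$array[, , ti], tc$labels))
  }
})

test_that("category averaging matches hand computation and is symmetric", {
  # constant off-diagonal RDM: all cells equal that constant
  m <- matrix(0.7, 4, 4); diag(m) <- 0
  cats <- c(a1 = "human_face", a2 = "human_face",
            b1 = "illusory_face", b2 = "illusory_face")
  ca <- category_average(rdm(m, names(cats)), cats)
  expect_equal(unname(ca$matrix[1, 2]), 0.7)
  expect_equal(unname(attr(ca, "within")), c(0.7, 0.7))

  # 4-item toy RDM against brute-force averaging
  mm <- matrix(0, 4, 4)
  mm[lower.tri(mm)] <- c(1, 2, 3, 4, 5, 6)
  mm <- mm + t(mm)
  ca2 <- category_average(rdm(mm, names(cats)), cats)
  expect_equal(unname(ca2$matrix["human_face", "illusory_face"]),
               mean(c(mm[3, 1], mm[3, 2], mm[4, 1], mm[4, 2])))
  expect_equal(unname(attr(ca2, "within")["human_face"]), mm[2, 1])
  expect_equal(ca2$matrix, t(ca2$matrix))

  # a singleton category cannot fill its within-category cell
  cats_bad <- c(a1 = "human_face", a2 = "human_face",
                b1 = "illusory_face", b2 = "matched_object")
  expect_error(category_average(rdm(mm, names(cats_bad)), cats_bad), "< 2")
})

test_that("category contrast permutation test matches exhaustive enumeration", {
  # label-invariant RDM: observed 0, p = 1
  m <- matrix(0.5, 6, 6); diag(m) <- 0
  cats <- setNames(rep(c("human_face", "illusory_face", "matched_object"),
                       each = 2), paste0("i", 1:6))
  flat <- category_contrast_perm(rdm(m, names(cats)), cats,
                                 c("illusory_face", "human_face"),
                                 c("matched_object", "human_face"),
                                 n_perm = 50, seed = 2)
  expect_equal(flat$observed, 0)
  expect_equal(flat$p, 1)

  # Monte-Carlo p within 3 SE of the exhaustive permutation p
  r6 <- random_rdm(6, seed = 63)
  r6 <- rdm(r6$matrix, names(cats))
  res <- category_contrast_perm(r6, cats,
                                c("illusory_face", "human_face"),
                                c("matched_object", "human_face"),
                                n_perm = 400, seed = 3)
  perms <- combinat_perms(6)
  stat_of <- function(ord) {
    pc <- setNames(unname(cats)[ord], names(cats))
    ca <- category_average(r6, pc)
    ca$matrix["illusory_face", "human_face"] -
      ca$matrix["matched_object", "human_face"]
  }
  null_all <- apply(perms, 1, stat_of)
  p_exact <- mean(abs(null_all) >= abs(res$observed) - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 400)
  expect_lt(abs(res$p - p_exact), 3 * se + 2 / 400)
})

test_that("classical MDS reproduces forced and constructed geometries", {
  # equilateral 3-point RDM: all embedded distances 1
  eq <- rdm(matrix(1, 3, 3) - diag(3), c("a", "b", "c"))
  co <- classical_mds(eq, k = 2)$coordinates
  expect_equal(as.vector(dist(co)), rep(1, 3), tolerance = 1e-10)

  # Euclidean RDM from random 2-D points: exact reconstruction
  set.seed(64)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  emb <- classical_mds(rdm(d, paste0("p", 1:6)), k = 2)
  expect_equal(as.matrix(dist(emb$coordinates)), unname(d),
               tolerance = 1e-8, ignore_attr = TRUE)

  # zero RDM: all coordinates zero (returned with a warning record)
  z <- classical_mds(rdm(matrix(0, 3, 3), c("a", "b", "c")), k = 2)
  expect_equal(unname(z$coordinates), matrix(0, 3, 0))
  expect_match(z$warning, "positive eigenvalue")

  # agreement with stats::cmdscale as an independent implementation
  cm <- stats::cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(emb$coordinates), abs(cm$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(emb$eigenvalues, cm$eig, tolerance = 1e-8)

  # full-dimension MDS reconstructs any Euclidean-embeddable RDM
  pts5 <- matrix(rnorm(20), 5, 4)
  d5 <- as.matrix(dist(pts5))
  emb5 <- classical_mds(rdm(d5, paste0("q", 1:5)), k = 4)
  expect_equal(as.matrix(dist(emb5$coordinates)), unname(d5),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Kendall tau-a matches exhaustive pair counting", {
  expect_equal(kendall_tau_a(1:3, 1:3), 1)
  expect_equal(kendall_tau_a(1:3, 3:1), -1)
  # one tied pair in x out of three pairs: (C - D) / 3 = 2/3
  expect_equal(kendall_tau_a(c(1, 2, 2), c(1, 2, 3)), 2 / 3)
  expect_error(kendall_tau_a(1:3, 1:4), "equal length")

  set.seed(65)
  for (n in c(5, 17, 50)) {
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- rnorm(n)
    expect_equal(kendall_tau_a(x, y), tau_a_brute(x, y), tolerance = 1e-12)
    # and on tie-free data tau-a equals stats::cor's tau-b
    x2 <- rnorm(n); y2 <- rnorm(n)
    expect_equal(kendall_tau_a(x2, y2),
                 cor(x2, y2, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("model correlation timecourse peaks where model equals data", {
  meg <- tiny_meg(n_subjects = 2, n_exemplars = 4)
  stim <- attr(meg, "stimuli")
  tcs <- lapply(lapply(meg, pca_reduce), rdm_timecourse)
  grp <- group_rdm_timecourse(tcs)
  model <- rdm_at(grp, 160)
  mc <- model_correlation_timecourse(tcs, model, stim)
  expect_equal(length(mc$labels), 8)   # human faces excluded
  expect_equal(dim(mc$tau), c(2, 50))
  # the group curve is maximal at (or adjacent to) the matching timepoint
  peak_t <- mc$times_ms[which.max(mc$mean)]
  expect_lte(abs(peak_t - 160), 10)

  # label mismatch is reported
  bad <- rdm(matrix(0, 3, 3), c("x", "y", "z"))
  expect_error(model_correlation_timecourse(tcs, bad, stim), "missing items")
})

test_that("noise ceiling brackets behave and match brute force", {
  # identical subject RDMs with distinct entries: lower = upper
  r <- random_rdm(5, seed = 66)
  nc <- noise_ceiling(list(r, r, r))
  expect_equal(nc[["lower"]], nc[["upper"]])

  # brute-force oracle on 3 small subject RDMs
  rs <- lapply(1:3, function(s) random_rdm(4, seed = 70 + s))
  nc3 <- noise_ceiling(rs)
  mats <- lapply(rs, function(x) x$matrix)
  lt <- function(m) m[lower.tri(m)]
  up_b <- mean(sapply(1:3, function(s)
    tau_a_brute(lt(mats[[s]]), lt((mats[[1]] + mats[[2]] + mats[[3]]) / 3))))
  lo_b <- mean(sapply(1:3, function(s)
    tau_a_brute(lt(mats[[s]]), lt(Reduce(`+`, mats[-s]) / 2))))
  expect_equal(unname(nc3), c(lo_b, up_b), tolerance = 1e-12)

  # property: lower <= upper across random draws
  for (rep in 1:50) {
    rs <- lapply(1:4, function(s) random_rdm(5, seed = 100 * rep + s))
    nc <- noise_ceiling(rs)
    expect_lte(nc[["lower"]], nc[["upper"]] + 1e-12)
  }
  expect_error(noise_ceiling(list(r)), ">= 2 subjects")
})

test_that("fusion is maximal for an ROI RDM matching the MEG geometry", {
  meg <- tiny_meg(n_subjects = 2, n_exemplars = 4)
  stim <- attr(meg, "stimuli")
  tcs <- lapply(lapply(meg, pca_reduce), rdm_timecourse)
  grp <- group_rdm_timecourse(tcs)
  roi_rdm <- rdm_at(grp, 160)
  fu <- fusion_timecourse(list(FFA = roi_rdm), tcs, stim)
  expect_equal(dim(fu$tau), c(2, 50, 1))
  peak_t <- fu$times_ms[which.max(fu$mean[, "FFA"])]
  expect_lte(abs(peak_t - 160), 10)
})
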