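# Pairwise category cross-decoding with exemplar-generalizing
# cross-validation: MEG timepoints, fMRI ROIs, and volumetric searchlights.
# The defining constraint is that no stimulus ever appears in both the
# training and the test set of a fold, so above-chance accuracy requires
# generalization across exemplars rather than image-specific memorization.

#' Build an exemplar-generalizing cross-validation plan
#'
#' @param stimuli a [stimulus_set()].
#' @param pair character of length 2: the category pair to decode.
#' @param scheme fold scheme:
#'   * `"paired_exemplar"` - N folds; exemplar i of each category held out
#'     together. For the illusory/matched pair the yoked partner is held out
#'     with its yoke, preventing leakage through visually similar yokes.
#'   * `"exhaustive_exemplar"` - N^2 folds; every cross-category exemplar
#'     combination serves as test data once.
#'   * `"run_by_exemplar"` - N x n_runs folds; the held-out exemplar pair is
#'     tested only on the held-out run (combined leave-one-run-out and
#'     leave-one-exemplar-out).
#' @param runs run indices, required for `"run_by_exemplar"`.
#' @return a `fold_plan`: list of folds, each with `train` and `test`
#'   data.frames (`stimulus_id`, `run`; `run` is `NA` for non-run schemes).
#' @export
make_folds <- function(stimuli, pair,
                       scheme = c("paired_exemplar", "exhaustive_exemplar",
                                  "run_by_exemplar"), runs = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(stimuli, "stimulus_set"), length(pair) == 2)
  bad <- setdiff(pair, CATEGORIES)
  if (length(bad)) stopf("unknown categories: %s", paste(bad, collapse = ", "))
  a_ids <- sort(stimuli$id[stimuli$category == pair[1]])
  b_ids <- sort(stimuli$id[stimuli$category == pair[2]])
  n <- length(a_ids)
  if (n < 2 || length(b_ids) < 2) stopf("need >= 2 exemplars per category")
  if (length(b_ids) != n) stopf("category exemplar counts differ")
  # pair exemplars across categories: by yoke where the pair is yoked,
  # otherwise by sorted index
  if (setequal(pair, c("illusory_face", "matched_object"))) {
    yoke <- stats::setNames(stimuli$yoke_id, stimuli$id)
    b_of_a <- unname(yoke[a_ids])
  } else {
    b_of_a <- b_ids
  }
  all_ids <- c(a_ids, b_ids)
  fold <- function(test_ids, test_run = NA_integer_) {
    train_ids <- setdiff(all_ids, test_ids)
    train_run <- if (is.na(test_run)) NA_integer_ else test_run
    list(
      train = data.frame(stimulus_id = train_ids,
                         run = if (is.na(test_run)) NA_integer_ else -test_run,
                         stringsAsFactors = FALSE),
      test = data.frame(stimulus_id = test_ids, run = test_run,
                        stringsAsFactors = FALSE)
    )
  }
  folds <- switch(scheme,
    paired_exemplar = lapply(seq_len(n), function(i) {
      fold(c(a_ids[i], b_of_a[i]))
    }),
    exhaustive_exemplar = {
      out <- vector("list", n * length(b_ids))
      k <- 0L
      for (i in seq_len(n)) for (j in seq_along(b_ids)) {
        k <- k + 1L
        out[[k]] <- fold(c(a_ids[i], b_ids[j]))
      }
      out
    },
    run_by_exemplar = {
      if (is.null(runs)) {
        stopf("scheme 'run_by_exemplar' requires a run index vector")
      }
      runs <- sort(unique(runs))
      out <- vector("list", n * length(runs))
      k <- 0L
      for (i in seq_len(n)) for (r in runs) {
        k <- k + 1L
        out[[k]] <- fold(c(a_ids[i], b_of_a[i]), r)
      }
      out
    })
  # structural invariants: fold disjointness and joint test coverage
  covered <- character(0)
  for (f in folds) {
    if (length(intersect(f$train$stimulus_id, f$test$stimulus_id))) {
      stopf("internal error: fold train/test stimulus overlap")
    }
    covered <- union(covered, f$test$stimulus_id)
  }
  if (!setequal(covered, all_ids)) {
    stopf("internal error: test sets do not cover every exemplar")
  }
  structure(list(folds = folds, scheme = scheme, pair = pair),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s: %d folds (%s vs %s)\n", x$scheme,
              length(x$folds), x$pair[1], x$pair[2]))
  invisible(x)
}

# --- classifiers ------------------------------------------------------------

#' Regularized linear discriminant classifier
#'
#' Binary LDA with the pooled within-class covariance shrunk toward a scaled
#' identity: `S* = (1 - shrinkage) S + shrinkage (tr(S)/p) I`. Equal priors;
#' decision-score ties break toward the lexicographically first class label.
#' With `shrinkage = 1` the rule reduces to a nearest-centroid classifier.
#'
#' @param train_X,train_y training matrix (rows = samples) and labels
#'   (exactly two classes).
#' @param test_X test matrix.
#' @param shrinkage shrinkage weight in `[0, 1]` (default 0.05).
#' @return character vector of predicted labels.
#' @export
fit_predict_lda <- function(train_X, train_y, test_X, shrinkage = 0.05) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  check_no_na(train_X, "train_X"); check_no_na(test_X, "test_X")
  if (shrinkage < 0 || shrinkage > 1) stopf("shrinkage must lie in [0, 1]")
  classes <- sort(unique(as.character(train_y)))
  if (length(classes) != 2) stopf("exactly two classes required in training data")
  y <- as.character(train_y)
  x1 <- train_X[y == classes[1], , drop = FALSE]
  x2 <- train_X[y == classes[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  p <- ncol(train_X)
  sw <- (crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))) /
    (nrow(train_X) - 2)
  tr_p <- sum(diag(sw)) / p
  # zero within-class scatter (noise-free identical trials): the shrinkage
  # target degenerates too, so shrink toward the plain identity instead,
  # which reduces the rule to nearest centroid
  if (tr_p == 0 && shrinkage > 0) tr_p <- 1
  s_reg <- (1 - shrinkage) * sw + shrinkage * tr_p * diag(p)
  w <- tryCatch(solve(s_reg, m2 - m1), error = function(e) {
    stopf(paste0("within-class covariance is singular; ",
                 "increase 'shrinkage' above 0"))
  })
  threshold <- sum(w * (m1 + m2)) / 2
  score <- drop(test_X %*% w) - threshold
  ifelse(score > 0, classes[2], classes[1])
}

#' Linear support vector classifier
#'
#' Soft-margin linear SVM (via e1071/libsvm), deterministic given the data.
#'
#' @param train_X,train_y training matrix and labels (two classes).
#' @param test_X test matrix.
#' @param cost soft-margin cost parameter (default 1).
#' @return character vector of predicted labels.
#' @export
fit_predict_svm <- function(train_X, train_y, test_X, cost = 1) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  check_no_na(train_X, "train_X"); check_no_na(test_X, "test_X")
  classes <- sort(unique(as.character(train_y)))
  if (length(classes) != 2) stopf("exactly two classes required in training data")
  fit <- e1071::svm(train_X, factor(train_y, levels = classes),
                    kernel = "linear", cost = cost, scale = FALSE)
  as.character(predict(fit, test_X))
}

classifier_fun <- function(classifier, shrinkage, cost) {
  switch(classifier,
    lda = function(xtr, ytr, xte) fit_predict_lda(xtr, ytr, xte, shrinkage),
    svm = function(xtr, ytr, xte) fit_predict_svm(xtr, ytr, xte, cost),
    stopf("unknown classifier '%s'", classifier))
}

# map a fold to row indices of a trial/sample table
fold_rows <- function(fold_half, stim_col, run_col) {
  sel <- stim_col %in% fold_half$stimulus_id
  r <- fold_half$run[1]
  if (!is.na(r)) {
    sel <- sel & if (r < 0) run_col != -r else run_col == r
  }
  which(sel)
}

# --- timecourse decoding ----------------------------------------------------

#' Time-resolved pairwise cross-decoding of sensor epochs
#'
#' Trains and tests a binary classifier at every timepoint under an
#' exemplar-generalizing fold plan: in each fold the classifier is trained on
#' all trials of the training exemplars and tested on all trials of the
#' held-out exemplars; fold accuracies (percent correct) are averaged.
#'
#' @param epochs a [sensor_epochs()] or a list of them (one per subject).
#' @param stimuli the [stimulus_set()].
#' @param pair category pair, e.g. `c("illusory_face", "matched_object")`.
#' @param scheme fold scheme (see [make_folds()]); default
#'   `"exhaustive_exemplar"`.
#' @param classifier `"lda"` (default) or `"svm"`.
#' @param shrinkage LDA shrinkage (default 0.05).
#' @param cost SVM cost (default 1).
#' @return a [decoding_result()] (subjects x timepoints, percent correct).
#' @export
decode_timecourse <- function(epochs, stimuli, pair,
                              scheme = "exhaustive_exemplar",
                              classifier = c("lda", "svm"),
                              shrinkage = 0.05, cost = 1) {
  classifier <- match.arg(classifier)
  if (inherits(epochs, "sensor_epochs")) epochs <- list(epochs)
  clf <- classifier_fun(classifier, shrinkage, cost)
  plan <- make_folds(stimuli, pair, scheme,
                     runs = if (scheme == "run_by_exemplar")
                       epochs[[1]]$trials$run else NULL)
  times <- epochs[[1]]$times_ms
  acc <- matrix(NA_real_, length(epochs), length(times))
  for (s in seq_along(epochs)) {
    ep <- epochs[[s]]
    keep <- ep$trials$category %in% pair
    trials <- ep$trials[keep, , drop = FALSE]
    dat <- ep$data[keep, , , drop = FALSE]
    truth <- trials$category
    tr_rows <- lapply(plan$folds, function(f)
      fold_rows(f$train, trials$stimulus_id, trials$run))
    te_rows <- lapply(plan$folds, function(f)
      fold_rows(f$test, trials$stimulus_id, trials$run))
    for (ti in seq_along(times)) {
      x <- dat[, , ti, drop = FALSE]
      dim(x) <- dim(dat)[1:2]
      fold_acc <- vapply(seq_along(plan$folds), function(f) {
        pred <- clf(x[tr_rows[[f]], , drop = FALSE], truth[tr_rows[[f]]],
                    x[te_rows[[f]], , drop = FALSE])
        mean(pred == truth[te_rows[[f]]])
      }, 0)
      acc[s, ti] <- 100 * mean(fold_acc)
    }
  }
  decoding_result(acc, pair, "time_ms", times, length(plan$folds),
                  scheme, classifier)
}

# --- ROI decoding -----------------------------------------------------------

#' Pairwise cross-decoding of fMRI ROI beta patterns
#'
#' Each (stimulus, run) beta pattern is one sample. The default scheme is the
#' combined leave-one-run-out and leave-one-exemplar-out procedure: the
#' held-out exemplar pair is tested on the held-out run only, while training
#' uses the remaining exemplars on the remaining runs.
#'
#' @param betas output of [generate_fmri_dataset()] (or the same structure:
#'   per subject, a named list of stimuli x runs x voxels arrays).
#' @param stimuli the [stimulus_set()].
#' @param pair category pair.
#' @param scheme fold scheme (default `"run_by_exemplar"`).
#' @param classifier `"svm"` (default) or `"lda"`.
#' @param shrinkage,cost classifier parameters.
#' @return a [decoding_result()] (subjects x ROIs, percent correct).
#' @export
decode_roi <- function(betas, stimuli, pair, scheme = "run_by_exemplar",
                       classifier = c("svm", "lda"), shrinkage = 0.05,
                       cost = 1) {
  classifier <- match.arg(classifier)
  clf <- classifier_fun(classifier, shrinkage, cost)
  rois <- names(betas[[1]])
  n_runs <- dim(betas[[1]][[1]])[2]
  plan <- make_folds(stimuli, pair, scheme,
                     runs = if (scheme == "run_by_exemplar") seq_len(n_runs)
                            else NULL)
  cat_of <- stats::setNames(stimuli$category, stimuli$id)
  acc <- matrix(NA_real_, length(betas), length(rois))
  for (s in seq_along(betas)) {
    for (ri in seq_along(rois)) {
      arr <- betas[[s]][[rois[ri]]]
      ids <- dimnames(arr)[[1]]
      keep <- cat_of[ids] %in% pair
      arr <- arr[keep, , , drop = FALSE]
      ids <- ids[keep]
      nr <- dim(arr)[2]
      # flatten to samples x voxels with (stimulus, run) bookkeeping
      x <- matrix(aperm(arr, c(1, 2, 3)), dim(arr)[1] * nr, dim(arr)[3])
      stim_col <- rep(ids, times = nr)
      run_col <- rep(seq_len(nr), each = length(ids))
      truth <- unname(cat_of[stim_col])
      fold_acc <- vapply(plan$folds, function(f) {
        tr <- fold_rows(f$train, stim_col, run_col)
        te <- fold_rows(f$test, stim_col, run_col)
        pred <- clf(x[tr, , drop = FALSE], truth[tr], x[te, , drop = FALSE])
        mean(pred == truth[te])
      }, 0)
      acc[s, ri] <- 100 * mean(fold_acc)
    }
  }
  decoding_result(acc, pair, "roi", rois, length(plan$folds), scheme,
                  classifier)
}

# --- searchlight ------------------------------------------------------------

#' Integer voxel offsets within a Euclidean radius
#' @param radius_voxels sphere radius in voxels (>= 1).
#' @return integer matrix with columns dx, dy, dz; includes the center.
#' @export
sphere_offsets <- function(radius_voxels) {
  if (radius_voxels < 1) stopf("radius must be >= 1 voxel")
  r <- floor(radius_voxels)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius_voxels^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Volumetric searchlight cross-decoding
#'
#' Decodes the category pair at every voxel in the mask, using as features
#' all voxels within `radius_voxels` (Euclidean, inclusive) of the center
#' that are also inside the mask. One sample per stimulus (run-averaged
#' betas); exemplar-only cross-validation (no run structure), matching the
#' faster whole-brain procedure.
#'
#' @param volume_betas 4-D array stimulus x x x y x z, with stimulus ids as
#'   the first dimnames.
#' @param mask 3-D logical array (same spatial dims); must be nonempty.
#' @param stimuli the [stimulus_set()].
#' @param pair category pair.
#' @param radius_voxels searchlight radius (default 3).
#' @param scheme fold scheme (default `"paired_exemplar"`).
#' @param classifier `"svm"` (default) or `"lda"`.
#' @param shrinkage,cost classifier parameters.
#' @return 3-D accuracy map (%) with `NA` outside the mask.
#' @export
searchlight_decode <- function(volume_betas, mask, stimuli, pair,
                               radius_voxels = 3,
                               scheme = "paired_exemplar",
                               classifier = c("svm", "lda"),
                               shrinkage = 0.05, cost = 1) {
  classifier <- match.arg(classifier)
  clf <- classifier_fun(classifier, shrinkage, cost)
  dims <- dim(volume_betas)
  if (length(dims) != 4) stopf("volume_betas must be stimulus x x x y x z")
  if (!any(mask)) stopf("mask is empty")
  ids <- dimnames(volume_betas)[[1]]
  cat_of <- stats::setNames(stimuli$category, stimuli$id)
  keep <- cat_of[ids] %in% pair
  ids <- ids[keep]
  truth <- unname(cat_of[ids])
  plan <- make_folds(stimuli, pair, scheme)
  offs <- sphere_offsets(radius_voxels)
  flat <- matrix(volume_betas, dims[1], prod(dims[2:4]))[keep, , drop = FALSE]
  vox_index <- function(x, y, z) x + (y - 1L) * dims[2] +
    (z - 1L) * dims[2] * dims[3]
  accmap <- array(NA_real_, dims[2:4])
  centers <- which(mask, arr.ind = TRUE)
  tr_rows <- lapply(plan$folds, function(f) which(ids %in% f$train$stimulus_id))
  te_rows <- lapply(plan$folds, function(f) which(ids %in% f$test$stimulus_id))
  for (ci in seq_len(nrow(centers))) {
    cx <- centers[ci, 1]; cy <- centers[ci, 2]; cz <- centers[ci, 3]
    nx <- cx + offs[, 1]; ny <- cy + offs[, 2]; nz <- cz + offs[, 3]
    ok <- nx >= 1 & nx <= dims[2] & ny >= 1 & ny <= dims[3] &
      nz >= 1 & nz <= dims[4]
    nx <- nx[ok]; ny <- ny[ok]; nz <- nz[ok]
    inmask <- mask[cbind(nx, ny, nz)]
    feats <- vox_index(nx[inmask], ny[inmask], nz[inmask])
    x <- flat[, feats, drop = FALSE]
    fold_acc <- vapply(seq_along(plan$folds), function(f) {
      pred <- clf(x[tr_rows[[f]], , drop = FALSE], truth[tr_rows[[f]]],
                  x[te_rows[[f]], , drop = FALSE])
      mean(pred == truth[te_rows[[f]]])
    }, 0)
    accmap[cx, cy, cz] <- 100 * mean(fold_acc)
  }
  accmap
}
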