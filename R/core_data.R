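# Typed containers: stimulus sets, sensor epochs, pattern matrices, RDMs,
# decoding results, and their readers/writers.

#' Construct a stimulus set
#'
#' A stimulus set describes the yoked three-category design: human faces,
#' illusory faces (face pareidolia), and matched non-face objects, where each
#' illusory face is paired ("yoked") with a visually similar object of the
#' same kind. Every illusory face must have exactly one matched-object yoke
#' and vice versa, and the three categories must have equal counts.
#'
#' @param items data.frame with columns `id`, `category` (one of
#'   `"human_face"`, `"illusory_face"`, `"matched_object"`), `yoke_id`
#'   (`NA` for human faces), `filename`, `tilt_deg` (-3 or +3).
#' @return a `stimulus_set` (a validated data.frame).
#' @export
stimulus_set <- function(items) {
  req <- c("id", "category", "yoke_id", "filename", "tilt_deg")
  miss <- setdiff(req, names(items))
  if (length(miss)) stopf("manifest is missing columns: %s",
                          paste(miss, collapse = ", "))
  items <- as.data.frame(items[, req], stringsAsFactors = FALSE)
  items$id <- as.character(items$id)
  items$yoke_id <- as.character(items$yoke_id)
  if (anyDuplicated(items$id)) {
    stopf("duplicate stimulus ids: %s",
          paste(unique(items$id[duplicated(items$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(items$category), CATEGORIES)
  if (length(bad)) stopf("unknown categories: %s", paste(bad, collapse = ", "))
  counts <- table(factor(items$category, levels = CATEGORIES))
  if (length(unique(as.integer(counts))) != 1L) {
    stopf("category counts are unequal: %s",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  ill <- items[items$category == "illusory_face", ]
  mat <- items[items$category == "matched_object", ]
  orphans <- character(0)
  for (k in seq_len(nrow(ill))) {
    y <- ill$yoke_id[k]
    if (is.na(y) || !y %in% mat$id) orphans <- c(orphans, ill$id[k])
  }
  for (k in seq_len(nrow(mat))) {
    y <- mat$yoke_id[k]
    if (is.na(y) || !y %in% ill$id) orphans <- c(orphans, mat$id[k])
  }
  if (length(orphans)) {
    stopf("broken yoke graph; orphaned items: %s",
          paste(orphans, collapse = ", "))
  }
  # yoking must be an involution (one-to-one)
  lut <- stats::setNames(c(ill$yoke_id, mat$yoke_id), c(ill$id, mat$id))
  back <- lut[lut[c(ill$id, mat$id)]]
  if (!identical(unname(back), c(ill$id, mat$id))) {
    stopf("yoke mapping is not one-to-one")
  }
  if (!all(items$tilt_deg %in% c(-3, 3))) {
    stopf("tilt_deg must be -3 or +3")
  }
  class(items) <- c("stimulus_set", "data.frame")
  items
}

#' Build the default synthetic stimulus set
#'
#' Creates a manifest of `3 * n_per_category` stimuli with ids `hum01...`,
#' `ill01...`, `mat01...`, yoking `illNN` to `matNN`, and alternating
#' +/-3 degree tilts (the tilt-judgment task used to keep observers alert).
#'
#' @param n_per_category exemplars per category (default 32, the full design).
#' @return a [stimulus_set()].
#' @export
make_stimulus_set <- function(n_per_category = 32) {
  stopifnot(n_per_category >= 1)
  n <- n_per_category
  ids <- c(sprintf("hum%02d", 1:n), sprintf("ill%02d", 1:n),
           sprintf("mat%02d", 1:n))
  items <- data.frame(
    id = ids,
    category = rep(CATEGORIES, each = n),
    yoke_id = c(rep(NA_character_, n), sprintf("mat%02d", 1:n),
                sprintf("ill%02d", 1:n)),
    filename = paste0(ids, ".png"),
    tilt_deg = rep_len(c(-3, 3), 3 * n),
    stringsAsFactors = FALSE
  )
  stimulus_set(items)
}

#' Load a stimulus manifest CSV
#'
#' Reads and validates a manifest (columns `id`, `category`, `yoke_id`,
#' `filename`, `tilt_deg`). If `image_dir` is given, checks that every image
#' file exists and warns when an image is not 400 x 400 pixels (the size the
#' stimuli are standardized to).
#'
#' @param path manifest CSV path.
#' @param image_dir optional directory holding the stimulus images (PNG).
#' @return a [stimulus_set()]; `attr(, "image_dir")` records the directory.
#' @export
load_stimulus_manifest <- function(path, image_dir = NULL) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  items <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  set <- stimulus_set(items)
  if (!is.null(image_dir)) {
    for (k in seq_len(nrow(set))) {
      f <- file.path(image_dir, set$filename[k])
      if (!file.exists(f)) stopf("image file missing for '%s': %s",
                                 set$id[k], f)
    }
    attr(set, "image_dir") <- image_dir
  }
  set
}

#' Write a stimulus manifest CSV
#' @param set a [stimulus_set()].
#' @param path output CSV path.
#' @export
write_stimulus_manifest <- function(set, path) {
  utils::write.csv(as.data.frame(unclass(set)), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Load one stimulus image from a manifest-backed set
#'
#' @param set a [stimulus_set()] loaded with an `image_dir`.
#' @param id stimulus id.
#' @return numeric array (grayscale matrix or H x W x channels in `[0, 1]`).
#' @export
load_stimulus_image <- function(set, id) {
  dir <- attr(set, "image_dir")
  if (is.null(dir)) stopf("stimulus set has no image_dir attached")
  row <- which(set$id == id)
  if (!length(row)) stopf("unknown stimulus id '%s'", id)
  f <- file.path(dir, set$filename[row])
  ext <- tolower(tools::file_ext(f))
  if (ext != "png") stopf("unsupported image format '.%s' (PNG expected)", ext)
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("reading images requires the 'png' package")
  }
  img <- png::readPNG(f)
  d <- dim(img)
  if (d[1] != 400 || d[2] != 400) {
    warnf("image '%s' is %dx%d, not the standard 400x400", id, d[1], d[2])
  }
  img
}

# ---------------------------------------------------------------------------
# Sensor epochs

#' Construct trial-resolved sensor epochs
#'
#' @param data numeric array, trials x channels x timepoints.
#' @param times_ms timepoint latencies (ms) relative to stimulus onset;
#'   strictly increasing with uniform step `1000 / sample_rate_hz`.
#' @param trials data.frame with one row per trial: `stimulus_id`,
#'   `category`, `run`, `repeat_idx`.
#' @param sample_rate_hz sampling rate in Hz.
#' @param feature_space `"channels"` (raw sensors) or `"components"` (PCA).
#' @return a `sensor_epochs` object.
#' @export
sensor_epochs <- function(data, times_ms, trials, sample_rate_hz,
                          feature_space = "channels") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("'data' must be a trials x channels x timepoints array")
  }
  check_no_na(data, "data")
  if (!is.data.frame(trials)) stopf("'trials' must be a data.frame")
  req <- c("stimulus_id", "category", "run", "repeat_idx")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stopf("'trials' is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(trials) != dim(data)[1]) {
    stopf("'trials' has %d rows but 'data' has %d trials",
          nrow(trials), dim(data)[1])
  }
  if (length(times_ms) != dim(data)[3]) {
    stopf("'times_ms' has length %d but 'data' has %d timepoints",
          length(times_ms), dim(data)[3])
  }
  check_no_na(times_ms, "times_ms")
  if (length(times_ms) > 1) {
    steps <- diff(times_ms)
    if (any(steps <= 0)) stopf("'times_ms' must be strictly increasing")
    expected <- 1000 / sample_rate_hz
    if (any(abs(steps - expected) > 1e-6 * max(1, expected))) {
      stopf("'times_ms' step is not uniform at 1000/sample_rate_hz = %g ms",
            expected)
    }
  }
  structure(list(data = data, times_ms = as.numeric(times_ms),
                 trials = trials, sample_rate_hz = sample_rate_hz,
                 feature_space = feature_space),
            class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sensor_epochs> %d trials x %d %s x %d timepoints (%g..%g ms @ %g Hz)\n",
    d[1], d[2], x$feature_space, d[3], min(x$times_ms), max(x$times_ms),
    x$sample_rate_hz))
  invisible(x)
}

#' Write / read sensor epochs
#'
#' Lossless round-trip of the epoch container (`data`, `times_ms`, `trials`,
#' sampling rate). Files are validated on read, so a container whose trial
#' table does not match the data dimensions is rejected with an error naming
#' the offending field.
#'
#' @param epochs a [sensor_epochs()].
#' @param path file path.
#' @return `read_epochs` returns a validated [sensor_epochs()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  saveRDS(unclass(epochs), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stopf("epoch file not found: %s", path)
  x <- readRDS(path)
  sensor_epochs(x$data, x$times_ms, x$trials, x$sample_rate_hz,
                feature_space = if (is.null(x$feature_space)) "channels"
                                else x$feature_space)
}

# ---------------------------------------------------------------------------
# Pattern matrices

#' Construct a pattern matrix (one feature vector per item)
#'
#' @param values numeric matrix, items x features (voxel betas, or
#'   trial-averaged component patterns at one timepoint).
#' @param item_labels unique item labels (stimulus ids).
#' @param feature_space `"voxels"`, `"components"`, or `"channels"`.
#' @param run optional run index the patterns come from.
#' @return a `pattern_matrix`.
#' @export
pattern_matrix <- function(values, item_labels,
                           feature_space = c("voxels", "components",
                                             "channels"), run = NULL) {
  feature_space <- match.arg(feature_space)
  values <- as.matrix(values)
  check_no_na(values, "values")
  if (length(item_labels) != nrow(values)) {
    stopf("'item_labels' length %d does not match %d rows",
          length(item_labels), nrow(values))
  }
  if (anyDuplicated(item_labels)) stopf("duplicate item labels")
  rownames(values) <- item_labels
  structure(list(values = values, item_labels = as.character(item_labels),
                 feature_space = feature_space, run = run),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("<pattern_matrix> %d items x %d %s\n", nrow(x$values),
              ncol(x$values), x$feature_space))
  invisible(x)
}

# ---------------------------------------------------------------------------
# RDMs

#' Construct a representational dissimilarity matrix
#'
#' @param matrix square symmetric dissimilarity matrix with zero diagonal.
#' @param labels item labels (unique, one per row/column).
#' @param metric metric tag: `"one_minus_spearman"`, `"one_minus_corr"`,
#'   `"abs_diff"`, or `"custom"`. Correlation metrics must lie in `[0, 2]`.
#' @return an `rdm` object.
#' @export
rdm <- function(matrix, labels, metric = "custom") {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stopf("RDM must be square")
  check_no_na(m, "matrix")
  if (length(labels) != nrow(m)) stopf("labels length must match RDM size")
  if (anyDuplicated(labels)) stopf("duplicate RDM labels")
  if (max(abs(m - t(m))) > 1e-10) stopf("RDM is not symmetric within 1e-10")
  if (max(abs(diag(m))) > 1e-10) stopf("RDM diagonal is not zero")
  if (metric %in% c("one_minus_spearman", "one_minus_corr") &&
      (min(m) < -1e-10 || max(m) > 2 + 1e-10)) {
    stopf("correlation-based RDM entries must lie in [0, 2]")
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  structure(list(matrix = m, labels = as.character(labels), metric = metric),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d (%s)\n", nrow(x$matrix), ncol(x$matrix),
              x$metric))
  invisible(x)
}

#' Subset an RDM to a set of labels
#' @param x an [rdm()].
#' @param labels labels to keep, in the order given.
#' @return an [rdm()].
#' @export
rdm_subset <- function(x, labels) {
  miss <- setdiff(labels, x$labels)
  if (length(miss)) stopf("labels not in RDM: %s", paste(miss, collapse = ", "))
  rdm(x$matrix[labels, labels, drop = FALSE], labels, metric = x$metric)
}

#' Write / read an RDM as CSV
#'
#' The CSV stores the full square matrix with a header row of labels and a
#' leading label column (inspectable in any spreadsheet). On read, symmetry
#' is enforced: off-diagonal pairs differing by more than 1e-8 are an error;
#' smaller discrepancies are averaged.
#'
#' @param x an [rdm()].
#' @param path CSV path.
#' @export
write_rdm <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  df <- data.frame(label = x$labels,
                   format(x$matrix, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("label", x$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  if (!file.exists(path)) stopf("RDM file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stopf("RDM file is not square")
  if (anyDuplicated(labels)) stopf("duplicate RDM labels in file")
  if (!identical(labels, colnames(m))) {
    stopf("row labels do not match column labels")
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) stopf("RDM file is asymmetric (max |a_ij - a_ji| = %g)",
                         asym)
  rdm((m + t(m)) / 2, labels, metric = "custom")
}

# ---------------------------------------------------------------------------
# Decoding results

#' Construct a decoding result
#'
#' Holds percent-correct accuracies for one binary category comparison,
#' per subject and per analysis unit (timepoint, ROI, or voxel).
#'
#' @param accuracy numeric matrix, subjects x units, in `[0, 100]`.
#' @param comparison character of length 2, the category pair.
#' @param unit `"time_ms"`, `"roi"`, or `"voxel"`.
#' @param unit_values vector identifying the columns (times in ms, ROI
#'   names, or voxel indices).
#' @param n_folds number of cross-validation folds (> 0).
#' @param scheme fold scheme tag.
#' @param classifier classifier tag.
#' @param chance chance level in percent (50 for binary decoding).
#' @return a `decoding_result`.
#' @export
decoding_result <- function(accuracy, comparison, unit, unit_values,
                            n_folds, scheme, classifier, chance = 50) {
  accuracy <- as.matrix(accuracy)
  check_no_na(accuracy, "accuracy")
  if (min(accuracy) < 0 || max(accuracy) > 100) {
    stopf("accuracies must lie in [0, 100]")
  }
  if (n_folds <= 0) stopf("fold count must be positive")
  if (ncol(accuracy) != length(unit_values)) {
    stopf("'unit_values' length does not match accuracy columns")
  }
  structure(list(accuracy = accuracy, comparison = comparison, unit = unit,
                 unit_values = unit_values, n_folds = n_folds,
                 scheme = scheme, classifier = classifier, chance = chance),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %s vs %s: %d subjects x %d %s (%s, %s, %d folds)\n",
    x$comparison[1], x$comparison[2], nrow(x$accuracy), ncol(x$accuracy),
    x$unit, x$scheme, x$classifier, x$n_folds))
  cat(sprintf("  grand mean %.2f%% (chance %g%%)\n", mean(x$accuracy),
              x$chance))
  invisible(x)
}

#' Tidy a decoding result into a long data.frame
#' @param x a [decoding_result()].
#' @param ... unused.
#' @return data.frame with columns `subject`, the unit column, `accuracy`,
#'   plus provenance columns `comparison`, `scheme`, `classifier`.
#' @export
as.data.frame.decoding_result <- function(x, ...) {
  df <- expand.grid(subject = seq_len(nrow(x$accuracy)),
                    unit = x$unit_values, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  names(df)[2] <- x$unit
  df$accuracy <- as.vector(x$accuracy)
  df$comparison <- paste(x$comparison, collapse = "_vs_")
  df$scheme <- x$scheme
  df$classifier <- x$classifier
  df
}
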