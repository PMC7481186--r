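# Image-computable model RDMs: graph-based visual saliency (Markov-chain
# equilibrium over feature dissimilarity graphs), GIST descriptors (pooled
# multi-scale multi-orientation filter energies), and the behavioral-rating
# RDM.

# --- small image utilities --------------------------------------------------

to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3 && d[3] >= 3) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  if (length(d) == 3 && d[3] == 1) return(img[, , 1])
  stopf("image must be a matrix or an H x W x channels array")
}

#' Bilinear image resize
#' @param img numeric matrix.
#' @param nr,nc output rows/columns.
#' @return resized matrix.
#' @export
bilinear_resize <- function(img, nr, nc) {
  sr <- nrow(img) / nr
  sc <- ncol(img) / nc
  yi <- pmin(pmax((seq_len(nr) - 0.5) * sr + 0.5, 1), nrow(img))
  xi <- pmin(pmax((seq_len(nc) - 0.5) * sc + 0.5, 1), ncol(img))
  y0 <- pmin(floor(yi), nrow(img) - 1L); y1 <- y0 + 1L
  x0 <- pmin(floor(xi), ncol(img) - 1L); x1 <- x0 + 1L
  wy <- yi - y0; wx <- xi - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  cc <- img[y1, x0, drop = FALSE]; dd <- img[y1, x1, drop = FALSE]
  (1 - wy) %o% (1 - wx) * a + (1 - wy) %o% wx * b +
    wy %o% (1 - wx) * cc + wy %o% wx * dd
}

# frequency grid in cycles/pixel for an n x n transform (unshifted fft order)
freq_axis <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))
  k / n
}

# one-sided log-Gabor transfer function; modulus of the filtered inverse
# transform is the analytic energy envelope
log_gabor_transfer <- function(n, f0, theta, sigma_ratio = 0.65,
                               sigma_theta = pi / 10) {
  fy <- matrix(freq_axis(n), n, n)        # rows
  fx <- matrix(freq_axis(n), n, n, byrow = TRUE)  # cols
  r <- sqrt(fx^2 + fy^2)
  ang <- atan2(fy, fx)
  radial <- matrix(0, n, n)
  nz <- r > 0
  radial[nz] <- exp(-(log(r[nz] / f0))^2 / (2 * log(sigma_ratio)^2))
  dth <- ((ang - theta + pi) %% (2 * pi)) - pi
  radial * exp(-dth^2 / (2 * sigma_theta^2))
}

gabor_energy <- function(img, f0, theta, sigma_ratio = 0.65,
                         sigma_theta = pi / 10) {
  n <- nrow(img)
  g <- log_gabor_transfer(n, f0, theta, sigma_ratio, sigma_theta)
  resp <- stats::fft(stats::fft(img) * g, inverse = TRUE) / length(img)
  Mod(resp)^2
}

# --- GBVS -------------------------------------------------------------------

#' GBVS Markov transition matrix for one feature map
#'
#' Fully connected chain over map locations; the weight of the edge from
#' node j to node i is `|log(m_i / m_j)| * exp(-d_ij^2 / (2 sigma^2))`
#' (feature dissimilarity times spatial proximity), and columns are
#' normalized to sum to one.
#'
#' @param feature_map positive numeric matrix.
#' @param sigma spatial decay in map pixels (default 0.15 x map width).
#' @param eps floor applied to non-positive map values.
#' @return column-stochastic matrix of size `length(feature_map)^2`.
#' @export
gbvs_transition <- function(feature_map, sigma = 0.15 * ncol(feature_map),
                            eps = 1e-6) {
  m <- pmax(as.vector(feature_map), eps)
  nr <- nrow(feature_map); ncl <- ncol(feature_map)
  ridx <- rep(seq_len(nr), times = ncl)
  cidx <- rep(seq_len(ncl), each = nr)
  d2 <- outer(ridx, ridx, `-`)^2 + outer(cidx, cidx, `-`)^2
  w <- abs(outer(log(m), log(m), `-`)) * exp(-d2 / (2 * sigma^2))
  diag(w) <- 0
  cs <- colSums(w)
  cs[cs == 0] <- 1
  sweep(w, 2, cs, `/`)
}

# stationary distribution of a column-stochastic matrix by power iteration
stationary_distribution <- function(m, tol = 1e-9, max_iter = 5000) {
  n <- nrow(m)
  v <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    v2 <- drop(m %*% v)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  warnf("power iteration did not reach tol %g in %d iterations", tol, max_iter)
  v
}

#' GBVS activation map for one feature map
#'
#' The activation is the stationary (equilibrium) distribution of the
#' Markov chain built by [gbvs_transition()]: mass concentrates at
#' locations that differ from their surroundings.
#'
#' @inheritParams gbvs_transition
#' @param tol power-iteration convergence tolerance.
#' @return matrix of the same shape as `feature_map`, summing to 1.
#' @export
gbvs_activation <- function(feature_map, sigma = 0.15 * ncol(feature_map),
                            tol = 1e-9, eps = 1e-6) {
  v <- stationary_distribution(gbvs_transition(feature_map, sigma, eps), tol)
  matrix(v, nrow(feature_map), ncol(feature_map))
}

# second, identically structured pass: edge weight into node i is
# proportional to the activation at i (times proximity); its equilibrium
# concentrates mass at the activation peaks
gbvs_normalize <- function(activation, sigma = 0.15 * ncol(activation),
                           tol = 1e-9, eps = 1e-12) {
  a <- pmax(as.vector(activation), eps)
  nr <- nrow(activation); ncl <- ncol(activation)
  ridx <- rep(seq_len(nr), times = ncl)
  cidx <- rep(seq_len(ncl), each = nr)
  d2 <- outer(ridx, ridx, `-`)^2 + outer(cidx, cidx, `-`)^2
  w <- a * exp(-d2 / (2 * sigma^2))   # rows = target node i
  diag(w) <- 0
  cs <- colSums(w)
  cs[cs == 0] <- 1
  m <- sweep(w, 2, cs, `/`)
  matrix(stationary_distribution(m, tol), nr, ncl)
}

#' Graph-based visual saliency map
#'
#' Computes feature channels (intensity; red-green and blue-yellow color
#' opponency for color images; four orientation energies) at two image
#' scales, runs each feature map through the GBVS Markov-chain activation
#' and normalization passes at a fixed internal map resolution, and sums
#' the normalized maps into a single saliency map that sums to one.
#'
#' @param image numeric matrix (grayscale) or H x W x 3 array, values in
#'   `[0, 1]`.
#' @param map_size internal map resolution (default 32).
#' @param sigma_frac spatial decay as a fraction of map width (default 0.15).
#' @param tol power-iteration tolerance (default 1e-9).
#' @param eps floor for non-positive feature values.
#' @return a `saliency_map`: nonnegative `map_size x map_size` matrix
#'   summing to 1, with the parameterization attached as attribute
#'   `params`.
#' @export
gbvs_saliency <- function(image, map_size = 32, sigma_frac = 0.15,
                          tol = 1e-9, eps = 1e-6) {
  has_color <- length(dim(image)) == 3 && dim(image)[3] >= 3
  gray <- to_gray(image)
  work <- bilinear_resize(gray, 4 * map_size, 4 * map_size)
  channels_at <- function(scale_div) {
    n <- 4 * map_size / scale_div
    g <- bilinear_resize(work, n, n)
    maps <- list(intensity = g)
    if (has_color) {
      r <- bilinear_resize(image[, , 1], n, n)
      gg <- bilinear_resize(image[, , 2], n, n)
      b <- bilinear_resize(image[, , 3], n, n)
      maps$rg <- abs(r - gg)
      maps$by <- abs(b - (r + gg) / 2)
    }
    for (oi in 0:3) {
      maps[[paste0("ori", oi * 45)]] <-
        gabor_energy(g, f0 = 0.15, theta = oi * pi / 4)
    }
    maps
  }
  sigma <- sigma_frac * map_size
  master <- matrix(0, map_size, map_size)
  for (scale_div in c(2, 4)) {
    for (m in channels_at(scale_div)) {
      fm <- bilinear_resize(m, map_size, map_size)
      act <- gbvs_activation(fm, sigma, tol, eps)
      master <- master + gbvs_normalize(act, sigma, tol)
    }
  }
  master <- master / sum(master)
  structure(master, class = c("saliency_map", "matrix"),
            params = list(map_size = map_size, sigma_frac = sigma_frac,
                          tol = tol, eps = eps, scales = c(2, 4),
                          orientations = c(0, 45, 90, 135)))
}

# --- GIST -------------------------------------------------------------------

#' GIST descriptor of an image
#'
#' Converts to grayscale, resizes to a square working size, applies a local
#' contrast normalization prefilter (removes luminance and local contrast
#' variation), filters with a bank of log-Gabor filters
#' (`n_scales x n_orientations`), and averages the filter energy within each
#' cell of a `grid x grid` spatial grid.
#'
#' @param image numeric matrix or H x W x channels array.
#' @param n_scales number of filter scales (default 4).
#' @param n_orientations number of orientations (default 8).
#' @param grid spatial grid cells per side (default 4).
#' @param size working image size in pixels (default 256; must be divisible
#'   by `grid`).
#' @return a `gist_descriptor`: numeric vector of length
#'   `n_orientations * n_scales * grid^2` with the parameterization as
#'   attribute `params`. A constant (degenerate) image yields an all-zero
#'   descriptor with a `warning` attribute rather than an error.
#' @export
gist_descriptor <- function(image, n_scales = 4, n_orientations = 8,
                            grid = 4, size = 256) {
  if (size %% grid != 0) stopf("size must be divisible by grid")
  g <- bilinear_resize(to_gray(image), size, size)
  pre <- gist_prefilter(g)
  warn_rec <- NULL
  if (max(abs(pre)) < 1e-12) {
    warn_rec <- "degenerate (constant) image; zero-energy descriptor"
  }
  fimg <- stats::fft(pre)
  cell <- size / grid
  out <- numeric(0)
  nms <- character(0)
  for (o in seq_len(n_orientations)) {
    theta <- (o - 1) * pi / n_orientations
    for (s in seq_len(n_scales)) {
      f0 <- 0.25 / 2^(s - 1)
      tf <- log_gabor_transfer(size, f0, theta,
                               sigma_theta = pi / n_orientations / 1.5)
      energy <- Mod(stats::fft(fimg * tf, inverse = TRUE) / length(pre))^2
      for (gy in seq_len(grid)) for (gx in seq_len(grid)) {
        rows <- ((gy - 1) * cell + 1):(gy * cell)
        cols <- ((gx - 1) * cell + 1):(gx * cell)
        out <- c(out, mean(energy[rows, cols]))
        nms <- c(nms, sprintf("o%d_s%d_r%d_c%d", o, s, gy, gx))
      }
    }
  }
  structure(stats::setNames(out, nms), class = "gist_descriptor",
            params = list(n_scales = n_scales,
                          n_orientations = n_orientations, grid = grid,
                          size = size),
            warning = warn_rec)
}

# local contrast normalization: remove a lowpass background, then divide by
# a lowpass estimate of the local contrast
gist_prefilter <- function(img, cutoff_cycles = 4) {
  n <- nrow(img)
  fy <- matrix(freq_axis(n), n, n)
  fx <- matrix(freq_axis(n), n, n, byrow = TRUE)
  h <- exp(-((fx^2 + fy^2) * n^2) / (2 * cutoff_cycles^2))
  lp <- function(x) Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n^2
  centered <- img - lp(img)
  local_sd <- sqrt(pmax(lp(centered^2), 0))
  centered / (0.2 + local_sd)
}

# --- behavioral and generic model RDMs -------------------------------------

#' Behavioral face-ness RDM
#'
#' Dissimilarity between two images is the absolute difference of their
#' mean ratings across raters.
#'
#' @param ratings matrix raters x images (colnames = stimulus ids); `NA`
#'   entries are allowed but every image needs at least one rating.
#' @return an [rdm()] with metric `"abs_diff"`.
#' @export
behavioral_rdm <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (is.null(colnames(ratings))) stopf("ratings must have image colnames")
  n_rated <- colSums(!is.na(ratings))
  if (any(n_rated == 0)) {
    stopf("image(s) with no ratings: %s",
          paste(colnames(ratings)[n_rated == 0], collapse = ", "))
  }
  means <- colMeans(ratings, na.rm = TRUE)
  d <- abs(outer(means, means, `-`))
  rdm(d, colnames(ratings), metric = "abs_diff")
}

#' Model RDM from saliency maps, GIST descriptors, or images
#'
#' Entry (i, j) is one minus the correlation between the flattened
#' maps/descriptors of items i and j.
#'
#' @param x named list: saliency maps, gist descriptors, plain numeric
#'   arrays, or (with `model != "precomputed"`) raw images.
#' @param model `"precomputed"` (default), `"saliency"` (run
#'   [gbvs_saliency()] on each image first), or `"gist"`.
#' @param method correlation variant: `"spearman"` (default, consistent
#'   with the neural RDMs) or `"pearson"`.
#' @param ... passed to [gbvs_saliency()] / [gist_descriptor()].
#' @return an [rdm()].
#' @export
model_rdm <- function(x, model = c("precomputed", "saliency", "gist"),
                      method = c("spearman", "pearson"), ...) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stopf("'x' must be a named list with unique names")
  }
  if (length(x) < 2) stopf("need >= 2 items")
  feats <- switch(model,
    precomputed = x,
    saliency = lapply(x, gbvs_saliency, ...),
    gist = lapply(x, gist_descriptor, ...))
  vecs <- vapply(feats, function(f) as.numeric(f), numeric(length(feats[[1]])))
  sds <- apply(vecs, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("constant descriptor (correlation undefined) for item(s): %s",
          paste(names(x)[sds == 0], collapse = ", "))
  }
  m <- 1 - stats::cor(vecs, method = method)
  diag(m) <- 0
  rdm(m, names(x),
      metric = if (method == "spearman") "one_minus_spearman"
               else "one_minus_corr")
}
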