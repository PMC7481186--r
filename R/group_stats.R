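# Group-level inference: t-tests against chance, multiple-comparison
# adjustment, and TFCE sign-permutation inference over 1-D timecourses.

#' One-sample t-test against chance
#'
#' @param values one value per subject (>= 2 subjects, nonzero variance).
#' @param chance the chance level (e.g. 50 for binary decoding accuracy,
#'   0 for a correlation).
#' @param tail `"one"` (default; alternative: mean > chance) or `"two"`.
#' @return list with `t`, `df`, `p`, `cohen_d`, and `ci_lower` (the lower
#'   bound of the one-sided 95% CI on the mean; upper bound is Inf).
#' @export
ttest_vs_chance <- function(values, chance, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (length(values) < 2) stopf("need >= 2 subjects")
  if (stats::sd(values) == 0) {
    # degenerate but well-defined null case: every subject exactly at chance
    if (all(values == chance)) {
      return(list(t = 0, df = length(values) - 1,
                  p = if (tail == "one") 0.5 else 1,
                  cohen_d = 0, ci_lower = -Inf))
    }
    stopf("zero variance across subjects")
  }
  alt <- if (tail == "one") "greater" else "two.sided"
  tt <- stats::t.test(values, mu = chance, alternative = alt)
  one_sided <- stats::t.test(values, mu = chance, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       cohen_d = mean(values - chance) / stats::sd(values),
       ci_lower = unname(one_sided$conf.int[1]))
}

#' Paired t-test with optional Bonferroni factor
#'
#' @param x,y paired values (e.g. per-item mean ratings of yoked illusory
#'   and matched images).
#' @param tail `"two"` (default) or `"one"` (alternative: mean(x - y) > 0).
#' @param bonferroni_k number of comparisons in the family; the returned p
#'   is `min(1, k * p)`.
#' @return list with `t`, `df`, `p` (corrected), `p_uncorrected`.
#' @export
paired_ttest <- function(x, y, tail = c("two", "one"), bonferroni_k = 1) {
  tail <- match.arg(tail)
  alt <- if (tail == "one") "greater" else "two.sided"
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = min(1, bonferroni_k * tt$p.value), p_uncorrected = tt$p.value)
}

#' Adjust p values for multiple comparisons
#'
#' Benjamini-Hochberg step-up FDR (with monotonicity enforcement) or
#' Bonferroni. Output order matches input order.
#'
#' @param pvals p values in `[0, 1]`.
#' @param method `"bh_fdr"` (default) or `"bonferroni"`.
#' @param alpha rejection level for the returned mask (default 0.05).
#' @return list with `adjusted` and logical `reject`.
#' @export
adjust_pvalues <- function(pvals, method = c("bh_fdr", "bonferroni"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1)) stopf("p values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = switch(method, bh_fdr = "BH",
                                                bonferroni = "bonferroni"))
  list(adjusted = adj, reject = adj <= alpha)
}

#' Threshold-free cluster enhancement of a 1-D statistic map
#'
#' `TFCE(t) = sum_h extent(h, t)^E * h^H * dh` over heights
#' `h = dh, 2 dh, ...`, where `extent(h, t)` is the length of the contiguous
#' supra-threshold run containing t at height h. Negative map values are
#' processed on the negated map and re-negated, so the output carries the
#' sign of the input.
#'
#' @param stat_map numeric vector (a statistic over time).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh height step (default 0.1; must be > 0).
#' @return numeric vector of TFCE scores, same length as `stat_map`.
#' @export
tfce_transform <- function(stat_map, E = 0.5, H = 2, dh = 0.1) {
  if (dh <= 0) stopf("dh must be > 0")
  check_no_na(stat_map, "stat_map")
  tfce_cpp(as.numeric(stat_map), E, H, dh)
}

#' TFCE sign-permutation inference across subjects
#'
#' Tests, at every timepoint, whether the group mean of the subject maps
#' (each already expressed relative to its null value, e.g. accuracy - 50)
#' exceeds zero. The observed group t-map is TFCE-enhanced; the null
#' distribution comes from random per-subject sign flips (exact enumeration
#' of all 2^n flips when n <= 12), and family-wise error over time is
#' controlled with the max-TFCE distribution.
#'
#' @param subject_maps matrix subjects x timepoints of (stat - null value).
#' @param n_perm permutations when sampling (default 1000; < 100 attaches a
#'   warning record, < 1 is an error).
#' @param alpha family-wise level (default 0.05).
#' @param tail `"one"` (default) or `"two"`.
#' @param seed integer seed for the sampled flips.
#' @param E,H,dh TFCE parameters.
#' @return list with `tfce` (observed TFCE map), `z` (z-equivalent of the
#'   corrected p values), `p_corrected`, logical `significant`, `t_map`,
#'   `exhaustive`, and optionally `warning`.
#' @export
tfce_signperm_inference <- function(subject_maps, n_perm = 1000,
                                    alpha = 0.05, tail = c("one", "two"),
                                    seed = 1, E = 0.5, H = 2, dh = 0.1) {
  tail <- match.arg(tail)
  subject_maps <- as.matrix(subject_maps)
  n <- nrow(subject_maps)
  if (n < 2) stopf("need >= 2 subjects")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  warn_rec <- if (n_perm < 100) {
    sprintf("n_perm = %d is low; corrected p values are coarse", n_perm)
  } else NULL

  ss <- colSums(subject_maps^2)
  n_t <- ncol(subject_maps)
  # t statistics are capped at +-1000: a degenerate zero-variance timepoint
  # (e.g. saturated decoding) is "infinitely" significant, but an unbounded
  # map would make the TFCE height integration arbitrarily long
  t_of_means <- function(means) {
    v <- (ss - n * means^2) / (n - 1)
    se <- sqrt(pmax(v, 0) / n)
    tt <- numeric(n_t)
    nz <- se > 1e-12
    tt[nz] <- means[nz] / se[nz]
    tt[!nz & abs(means) > 1e-12] <- sign(means[!nz & abs(means) > 1e-12]) * 1e3
    pmin(pmax(tt, -1e3), 1e3)
  }
  score <- function(tmap) {
    tf <- tfce_cpp(tmap, E, H, dh)
    if (tail == "two") abs(tf) else tf
  }
  obs_t <- t_of_means(colMeans(subject_maps))
  obs_tfce <- tfce_cpp(obs_t, E, H, dh)
  obs_score <- if (tail == "two") abs(obs_tfce) else obs_tfce

  exhaustive <- n <= 12
  if (exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    flips <- with_seed(seed, {
      matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    })
  }
  max_null <- apply(flips, 1, function(eps) {
    max(score(t_of_means(drop(eps %*% subject_maps) / n)))
  })
  if (exhaustive) {
    # the identity flip is one of the enumerated sign assignments
    p_corr <- vapply(obs_score, function(o) mean(max_null >= o - 1e-12), 0)
  } else {
    p_corr <- vapply(obs_score, function(o) {
      (1 + sum(max_null >= o - 1e-12)) / (1 + length(max_null))
    }, 0)
  }
  out <- list(tfce = obs_tfce, z = stats::qnorm(1 - pmin(pmax(p_corr, 1e-12),
                                                         1 - 1e-12)),
              p_corrected = p_corr, significant = p_corr <= alpha,
              t_map = obs_t, exhaustive = exhaustive)
  if (!is.null(warn_rec)) out$warning <- warn_rec
  out
}

#' Contiguous significant windows of a logical mask over time
#'
#' @param mask logical vector.
#' @param times_ms latencies corresponding to the mask entries.
#' @return data.frame with `onset_ms`, `offset_ms`, `n_timepoints` per run
#'   of consecutive TRUE values (zero rows if none).
#' @export
significant_windows <- function(mask, times_ms) {
  stopifnot(length(mask) == length(times_ms))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(onset_ms = times_ms[starts[keep]],
             offset_ms = times_ms[ends[keep]],
             n_timepoints = r$lengths[keep])
}
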