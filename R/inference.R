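#' Permutation test for a centroid-size difference
#'
#' Two-sided non-parametric test of a mean difference: the statistic is
#' the absolute difference of group means, and the null distribution is
#' built by re-drawing the group labels without replacement. The
#' p-value follows the (b + 1) / (cycles + 1) convention with ties
#' counted as exceedances, so it is never 0 and has granularity
#' 1 / (cycles + 1) — 1/1001 at the default 1000 cycles.
#' `method = "exact"` enumerates every split of the pooled sample (only
#' feasible for small groups) and returns the exact permutation
#' p-value, the fraction of splits with statistic >= observed.
#'
#' @param sizes_a,sizes_b numeric vectors (n >= 2 each) of centroid
#'   sizes.
#' @param cycles number of random relabelings (default 1000).
#' @param seed optional integer; fixes the relabeling stream.
#' @param method `"monte_carlo"` (default) or `"exact"`.
#' @return object of class `"permutation_result"`: list with
#'   `observed`, `null_stats`, `cycles`, `p_value`, `seed`,
#'   `statistic_kind`, `method`.
#' @export
permutation_test_size <- function(sizes_a, sizes_b, cycles = 1000L,
                                  seed = NULL,
                                  method = c("monte_carlo", "exact")) {
  method <- match.arg(method)
  if (length(sizes_a) < 2L || length(sizes_b) < 2L)
    stopf("both groups need n >= 2")
  if (method == "monte_carlo" && cycles < 1L) stopf("cycles must be >= 1")
  pool <- c(sizes_a, sizes_b)
  na <- length(sizes_a)
  stat <- function(idx_a) abs(mean(pool[idx_a]) - mean(pool[-idx_a]))
  observed <- stat(seq_len(na))
  if (method == "exact") {
    splits <- utils::combn(length(pool), na)
    if (ncol(splits) > 5e5)
      stopf("exact enumeration infeasible: %d splits", ncol(splits))
    null_stats <- apply(splits, 2, stat)
    p <- sum(null_stats >= observed - 1e-12) / length(null_stats)
    cycles <- length(null_stats)
  } else {
    null_stats <- with_seed_if(seed, vapply(
      seq_len(cycles),
      function(i) stat(sample.int(length(pool), na)),
      numeric(1)))
    p <- (sum(null_stats >= observed - 1e-12) + 1) / (cycles + 1)
  }
  structure(list(observed = observed, null_stats = null_stats,
                 cycles = cycles, p_value = p, seed = seed,
                 statistic_kind = "mean_size_difference", method = method),
            class = "permutation_result")
}

#' Permutation test for a shape difference
#'
#' Tests the separation of two groups in shape space. The statistic is
#' the Mahalanobis distance between the two group means, and it is
#' fully re-estimated — group means *and* pooled within-group
#' covariance — under every relabeling, in a retained principal-axis
#' subspace fixed from the observed scores (the retention depends only
#' on the pooled sample, not on the labels, so exchangeability is
#' preserved). Same p-value convention as [permutation_test_size()].
#'
#' @param x a `shape_variables` object or N x M score matrix.
#' @param labels length-N group labels.
#' @param group_a,group_b the two labels to compare.
#' @inheritParams permutation_test_size
#' @param cond_max condition ceiling for dimension retention.
#' @return a `"permutation_result"` (statistic_kind
#'   `"mahalanobis_shape"`).
#' @export
permutation_test_shape <- function(x, labels, group_a, group_b,
                                   cycles = 1000L, seed = NULL,
                                   cond_max = 1e8) {
  if (cycles < 1L) stopf("cycles must be >= 1")
  scores <- as_score_matrix(x)
  labels <- as.character(labels)
  sel <- labels %in% c(group_a, group_b)
  if (!any(labels == group_a) || !any(labels == group_b))
    stopf("groups '%s' and '%s' must both be present", group_a, group_b)
  sc <- scores[sel, , drop = FALSE]
  lab <- labels[sel]
  na <- sum(lab == group_a)
  if (na < 2L || sum(lab == group_b) < 2L) stopf("both groups need n >= 2")
  ret <- retain_scores(sc, lab, cond_max = cond_max)
  z <- ret$scores
  idx_a0 <- which(lab == group_a)
  dstat <- function(idx_a) {
    lab_perm <- rep(group_b, nrow(z)); lab_perm[idx_a] <- group_a
    pooled <- pooled_covariance(z, lab_perm)
    dm <- colMeans(z[idx_a, , drop = FALSE]) -
      colMeans(z[-idx_a, , drop = FALSE])
    sqrt(max(0, sum(forwardsolve(t(chol(pooled)), dm)^2)))
  }
  observed <- dstat(idx_a0)
  null_stats <- with_seed_if(seed, vapply(
    seq_len(cycles),
    function(i) dstat(sample.int(nrow(z), na)),
    numeric(1)))
  p <- (sum(null_stats >= observed - 1e-12) + 1) / (cycles + 1)
  structure(list(observed = observed, null_stats = null_stats,
                 cycles = cycles, p_value = p, seed = seed,
                 statistic_kind = "mahalanobis_shape",
                 method = "monte_carlo", retained = ret$retained),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed = %.4g, p = %.4g (%d cycles%s)\n",
              x$statistic_kind, x$observed, x$p_value, x$cycles,
              if (x$method == "exact") ", exact" else ""))
  invisible(x)
}

#' Repeatability (intraclass correlation) of repeated digitizations
#'
#' Model-II one-way ANOVA on repeated measures of the same specimens:
#' specimens are random effects, repeats are the within-specimen error.
#' With a specimens and n0 repeats each (balanced),
#' s2_among = max(0, (MS_among - MS_within) / n0) and
#' R = s2_among / (s2_among + s2_within) with s2_within = MS_within.
#' R near 1 means the digitizing error is negligible relative to
#' between-specimen variation; 1 - R is the measurement-error fraction.
#' Negative among-specimen variance estimates are truncated at 0, so
#' R is always in \[0, 1\].
#'
#' @param measurements numeric matrix, specimens x repeats (>= 2 of
#'   each; balanced design, no missing values).
#' @return object of class `"repeatability_result"`: list with `R`,
#'   `measurement_error` (1 - R), `ms_among`, `ms_within`,
#'   `n_specimens`, `n_repeats`.
#' @export
repeatability <- function(measurements) {
  m <- as.matrix(measurements)
  a <- nrow(m); n0 <- ncol(m)
  if (a < 2L) stopf("repeatability needs at least 2 specimens")
  if (n0 < 2L) stopf("repeatability needs at least 2 repeats per specimen")
  if (anyNA(m)) stopf("repeatability requires a balanced, complete design")
  means <- rowMeans(m)
  ms_among <- n0 * sum((means - mean(m))^2) / (a - 1)
  ms_within <- sum((m - means)^2) / (a * (n0 - 1))
  s2_among <- max(0, (ms_among - ms_within) / n0)
  r <- if (s2_among + ms_within > 0) s2_among / (s2_among + ms_within) else 0
  structure(list(R = r, measurement_error = 1 - r, ms_among = ms_among,
                 ms_within = ms_within, n_specimens = a, n_repeats = n0),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "<repeatability_result> R = %.4f (1 - R = %.4f); %d specimens x %d repeats\n",
    x$R, x$measurement_error, x$n_specimens, x$n_repeats))
  invisible(x)
}
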