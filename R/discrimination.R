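#' Pooled within-group covariance
#'
#' Group-wise sample covariances combined with weights
#' (n_g - 1) / (N - G): the usual pooled estimate underlying the
#' Mahalanobis distance and linear discriminant analysis.
#'
#' @param scores N x M numeric matrix of shape variables.
#' @param labels length-N group labels (coerced to character).
#' @return M x M symmetric positive semi-definite matrix.
#' @export
pooled_covariance <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  n <- nrow(scores); g <- length(groups)
  if (n - g < 1L) stopf("pooled covariance needs N - G >= 1")
  sizes <- table(labels)
  if (any(sizes < 2L))
    stopf("every group needs n >= 2 (offenders: %s)",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  s <- matrix(0, ncol(scores), ncol(scores))
  for (grp in groups) {
    xg <- scores[labels == grp, , drop = FALSE]
    s <- s + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  s / (n - g)
}

# Dimension-retention policy: rotate the scores to their principal axes
# and keep the leading m components such that (i) m <= N - G - extra_df
# and (ii) the pooled within-group covariance of the retained scores is
# numerically invertible (condition number < cond_max). With many shape
# variables and field-sized groups the full pooled covariance is
# ill-conditioned or singular; this makes the reduction explicit and
# reproducible. Mahalanobis distances are invariant to the rotation
# itself, so nothing is lost when all dimensions are kept.
retain_scores <- function(scores, labels, cond_max = 1e8, extra_df = 1L) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  g <- length(unique(labels))
  n <- nrow(scores)
  mmax <- min(ncol(scores), n - g - extra_df)
  if (mmax < 1L) stopf("too few specimens (%d) for %d groups", n, g)
  p <- stats::prcomp(scores, center = TRUE, scale. = FALSE)
  for (m in mmax:1) {
    proj <- p$x[, seq_len(m), drop = FALSE]
    ev <- eigen(pooled_covariance(proj, labels), symmetric = TRUE,
                only.values = TRUE)$values
    if (ev[m] > 0 && ev[1] / ev[m] < cond_max)
      return(list(scores = proj, retained = m,
                  rotation = p$rotation[, seq_len(m), drop = FALSE],
                  center = p$center))
  }
  stopf("pooled covariance singular at every candidate dimension; reduce variables")
}

as_score_matrix <- function(x) {
  if (inherits(x, "shape_variables")) x$scores else as.matrix(x)
}

# Squared Mahalanobis distances between all group means given a pooled
# covariance; returns G x G matrix.
group_mahal_sq <- function(scores, labels, pooled) {
  groups <- sort(unique(labels))
  means <- t(vapply(groups,
                    function(grp) colMeans(scores[labels == grp, , drop = FALSE]),
                    numeric(ncol(scores))))
  ch <- chol(pooled)
  z <- means %*% chol2inv(ch) %*% t(means)
  d2 <- outer(diag(z), diag(z), `+`) - 2 * z
  d2[d2 < 0] <- 0
  dimnames(d2) <- list(groups, groups)
  d2
}

#' Between-group Mahalanobis distance matrix
#'
#' D(g, h) = sqrt((m_g - m_h)' S^-1 (m_g - m_h)) with group mean scores
#' m and the pooled within-group covariance S, after the
#' dimension-retention policy (see Details). The classical plug-in
#' estimator (`correction = "none"`) is what morphometric software
#' conventionally tabulates, but it is biased upward in small samples:
#' E\[D^2\] = nu / (nu - p - 1) * (Delta^2 + p (1/n_g + 1/n_h)) with
#' nu = N - G pooled degrees of freedom and p retained dimensions.
#' `correction = "unbiased"` inverts that relation,
#' Delta^2_hat = (nu - p - 1)/nu * D^2 - p (1/n_g + 1/n_h), truncated at
#' zero — use it when the goal is to recover a population separation
#' rather than to reproduce conventional tables.
#'
#' @param x a `shape_variables` object or an N x M score matrix.
#' @param labels length-N group labels.
#' @param correction `"none"` (classical plug-in, default) or
#'   `"unbiased"`.
#' @param cond_max condition-number ceiling of the dimension-retention
#'   policy (default 1e8).
#' @return object of class `"distance_matrix"`: list with `labels`,
#'   `values` (symmetric, zero diagonal), `metric = "mahalanobis"`,
#'   `retained` (dimensions used).
#' @export
mahalanobis_matrix <- function(x, labels, correction = c("none", "unbiased"),
                               cond_max = 1e8) {
  correction <- match.arg(correction)
  scores <- as_score_matrix(x)
  labels <- as.character(labels)
  ret <- retain_scores(scores, labels, cond_max = cond_max)
  pooled <- pooled_covariance(ret$scores, labels)
  d2 <- group_mahal_sq(ret$scores, labels, pooled)
  if (correction == "unbiased") {
    groups <- rownames(d2)
    sizes <- table(labels)[groups]
    nu <- nrow(scores) - length(groups)
    p <- ret$retained
    if (nu - p - 1 <= 0)
      stopf("unbiased correction needs N - G > retained + 1")
    cpen <- outer(1 / as.numeric(sizes), 1 / as.numeric(sizes), `+`)
    d2 <- (nu - p - 1) / nu * d2 - p * cpen
    d2[d2 < 0] <- 0
    diag(d2) <- 0
  }
  distance_matrix(sqrt(d2), metric = "mahalanobis", retained = ret$retained)
}

#' Labeled symmetric distance matrix
#'
#' @param values symmetric non-negative matrix with dimnames, zero
#'   diagonal.
#' @param metric `"mahalanobis"` or `"procrustes"`.
#' @param retained retained dimensionality, when applicable.
#' @return object of class `"distance_matrix"`.
#' @export
distance_matrix <- function(values, metric = c("mahalanobis", "procrustes"),
                            retained = NA_integer_) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stopf("distance matrix needs labels as dimnames")
  if (max(abs(values - t(values))) > 1e-9) stopf("distance matrix must be symmetric")
  if (any(values < 0)) stopf("distances must be non-negative")
  structure(list(labels = rownames(values), values = values, metric = metric,
                 retained = retained),
            class = "distance_matrix")
}

#' @export
as.matrix.distance_matrix <- function(x, ...) x$values

#' @export
print.distance_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<distance_matrix> %s, %d groups%s\n", x$metric,
              length(x$labels),
              if (is.na(x$retained)) "" else
                sprintf(" (%d retained dimensions)", x$retained)))
  v <- round(x$values, digits)
  v[upper.tri(v)] <- NA
  print(v, na.print = "")
  invisible(x)
}

#' Canonical variate (factor-map) scores
#'
#' Discriminant axes maximizing between-group relative to pooled
#' within-group variance: eigenvectors of S^-1 B, solved via the
#' Cholesky-whitened symmetric eigenproblem. At most min(G - 1, M)
#' axes; with three groups this is the familiar two-axis factor map.
#' Axes are scaled so the pooled within-group variance along each is 1.
#'
#' @inheritParams mahalanobis_matrix
#' @return list with `scores` (N x n_axes), `axes` (loadings in retained
#'   space), `eigenvalues`, `power` (fraction of discriminating power
#'   per axis), `labels`, `retained`.
#' @export
canonical_scores <- function(x, labels, cond_max = 1e8) {
  scores <- as_score_matrix(x)
  labels <- as.character(labels)
  ret <- retain_scores(scores, labels, cond_max = cond_max)
  sc <- ret$scores
  groups <- sort(unique(labels))
  w <- pooled_covariance(sc, labels)
  grand <- colMeans(sc)
  b <- matrix(0, ncol(sc), ncol(sc))
  for (grp in groups) {
    dg <- colMeans(sc[labels == grp, , drop = FALSE]) - grand
    b <- b + sum(labels == grp) * tcrossprod(dg)
  }
  b <- b / (nrow(sc) - length(groups))
  l <- chol(w)
  sym <- forwardsolve(t(l), t(forwardsolve(t(l), b)))
  e <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  n_axes <- min(length(groups) - 1L, ncol(sc))
  vals <- pmax(e$values[seq_len(n_axes)], 0)
  axes <- backsolve(l, e$vectors[, seq_len(n_axes), drop = FALSE])
  cvs <- sweep(sc, 2, grand) %*% axes
  colnames(cvs) <- paste0("CV", seq_len(n_axes))
  list(scores = cvs, axes = axes, eigenvalues = vals,
       power = if (sum(vals) > 0) vals / sum(vals) else vals,
       labels = labels, retained = ret$retained)
}

#' Validated (leave-one-out) reclassification
#'
#' Each specimen is withheld in turn; group means and the pooled
#' within-group covariance are re-estimated from the remaining
#' specimens, and the withheld specimen is assigned to the group whose
#' mean is nearest in Mahalanobis distance. Ties (a measure-zero event)
#' break toward the earlier group in label sort order.
#' `method = "resubstitution"` skips the withholding and classifies
#' against statistics estimated from all specimens — optimistic, and
#' provided only for comparison.
#'
#' @inheritParams mahalanobis_matrix
#' @param method `"loo"` (default) or `"resubstitution"`.
#' @return object of class `"reclassification_report"`: list with
#'   `confusion` (true x assigned count matrix), `per_group` (data frame
#'   with `group`, `correct`, `total`, `percentage` and a formatted
#'   `"P% (correct/total)"` column), `method`, `retained`.
#' @export
loo_reclassify <- function(x, labels, method = c("loo", "resubstitution"),
                           cond_max = 1e8) {
  method <- match.arg(method)
  scores <- as_score_matrix(x)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  sizes <- table(labels)[groups]
  if (any(sizes < 3L))
    stopf("leave-one-out reclassification needs n >= 3 per group")
  # one extra df so every leave-one-out fold keeps an invertible pooled
  # covariance in the retained space
  ret <- retain_scores(scores, labels, cond_max = cond_max, extra_df = 2L)
  sc <- ret$scores
  n <- nrow(sc)
  assign_one <- function(xi, sc_fit, lab_fit) {
    pooled <- pooled_covariance(sc_fit, lab_fit)
    ch <- chol(pooled)
    d2 <- vapply(groups, function(grp) {
      dm <- xi - colMeans(sc_fit[lab_fit == grp, , drop = FALSE])
      sum(forwardsolve(t(ch), dm)^2)
    }, numeric(1))
    groups[which.min(d2)]  # which.min takes the first minimum: sort-order tie-break
  }
  assigned <- character(n)
  if (method == "loo") {
    for (i in seq_len(n))
      assigned[i] <- assign_one(sc[i, ], sc[-i, , drop = FALSE], labels[-i])
  } else {
    for (i in seq_len(n)) assigned[i] <- assign_one(sc[i, ], sc, labels)
  }
  confusion <- table(factor(labels, levels = groups),
                     factor(assigned, levels = groups))
  correct <- diag(confusion)
  per_group <- data.frame(
    group = groups, correct = as.integer(correct),
    total = as.integer(sizes),
    percentage = as.integer(round(100 * correct / as.numeric(sizes))),
    stringsAsFactors = FALSE
  )
  per_group$formatted <- sprintf("%d%% (%d/%d)", per_group$percentage,
                                 per_group$correct, per_group$total)
  structure(list(confusion = unclass(confusion), per_group = per_group,
                 method = method, retained = ret$retained),
            class = "reclassification_report")
}

#' @export
print.reclassification_report <- function(x, ...) {
  cat(sprintf("<reclassification_report> %s, %d retained dimensions\n",
              x$method, x$retained))
  print(x$per_group[, c("group", "formatted")], row.names = FALSE)
  invisible(x)
}
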