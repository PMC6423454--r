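#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of
#' the summed squared distances between each landmark and the centroid
#' of the configuration. Invariant to translation and rotation; scales
#' linearly under isotropic scaling.
#'
#' @param config a [landmark_config()] or a bare K x 2 coordinate matrix.
#' @return positive scalar, in the units of the input coordinates (mm
#'   when `SCALE=` was applied at read time).
#' @export
centroid_size <- function(config) {
  x <- if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
  if (nrow(x) < 2L) stopf("centroid size needs at least 2 landmarks")
  cs <- sqrt(sum(center_config(x)^2))
  if (cs < .Machine$double.eps)
    stopf("degenerate configuration: all landmarks coincident")
  cs
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of all configurations onto a common
#' consensus: each configuration is centred on its centroid, scaled to
#' unit centroid size, and rotated onto the current consensus by the
#' optimal *proper* rotation (determinant +1 — reflections are not
#' allowed, because wing chirality is biologically meaningful and all
#' specimens are digitized from the same wing side). The consensus is
#' the arithmetic mean of the aligned configurations, rescaled to unit
#' centroid size, and the loop repeats until its root-mean-square change
#' falls below `tol`. This is partial Procrustes superimposition: no
#' residual rescaling is applied after rotation.
#'
#' @param dataset a [landmark_dataset()] (N >= 2 specimens).
#' @param tol convergence tolerance on the RMS change of the consensus
#'   between iterations (default 1e-10).
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @return object of class `"aligned_shapes"`: list with `aligned`
#'   (K x 2 x N array), `consensus` (K x 2, unit centroid size),
#'   `centroid_sizes` (named N-vector, computed before scaling, in mm),
#'   `meta` (copied from the dataset), `iterations`, `converged`.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  arr <- dataset$coords
  n <- dim(arr)[3]
  if (n < 2L) stopf("generalized Procrustes analysis needs at least 2 specimens")
  cs <- apply(arr, 3, centroid_size)
  aligned <- array(NA_real_, dim = dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) aligned[, , i] <- center_config(arr[, , i]) / cs[i]
  consensus <- aligned[, , 1]
  consensus <- consensus / sqrt(sum(consensus^2))
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    # consensus is defined up to rotation; compare after aligning old to new
    delta <- sqrt(mean((new_cons -
      consensus %*% optimal_rotation(consensus, new_cons))^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(
    list(aligned = aligned, consensus = consensus,
         centroid_sizes = stats::setNames(cs, dimnames(arr)[[3]]),
         meta = dataset$meta, iterations = iter, converged = converged),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf(
    "<aligned_shapes> %d specimens x %d landmarks; %d iteration(s)%s\n",
    d[3], d[1], x$iterations,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Partial Procrustes distance between two shapes
#'
#' Root-sum-of-squares of coordinate differences after centring both
#' configurations, scaling each to unit centroid size, and rotating the
#' second onto the first by the optimal proper rotation. Symmetric, and
#' zero exactly when the shapes coincide up to a similarity transform
#' (translation, rotation, positive scaling — not reflection).
#'
#' @param a,b K x 2 coordinate matrices (or `landmark_config`s) with a
#'   common K.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  xa <- if (inherits(a, "landmark_config")) a$coords else as.matrix(a)
  xb <- if (inherits(b, "landmark_config")) b$coords else as.matrix(b)
  if (nrow(xa) != nrow(xb)) stopf("shapes have different landmark counts")
  xa <- center_config(xa) / centroid_size(xa)
  xb <- center_config(xb) / centroid_size(xb)
  xb <- xb %*% optimal_rotation(xb, xa)
  sqrt(sum((xa - xb)^2))
}

#' Centroid-size summary by sex and site
#'
#' One row per (sex, site) cell: sample size, mean centroid size, sample
#' (n-1) standard deviation, and range — the conventional layout of a
#' wing-size table. A single-specimen cell has no sample SD; it is
#' reported as 0 and flagged in the `degenerate` column with a warning,
#' rather than erroring (sparse field collections are common).
#'
#' @param aligned an [gpa()] result (centroid sizes are taken from it).
#' @return data frame with columns `sex`, `site`, `n`, `mean`, `sd`,
#'   `min`, `max`, `degenerate`.
#' @export
size_summary <- function(aligned) {
  meta <- aligned$meta
  cs <- aligned$centroid_sizes
  cells <- unique(meta[, c("sex", "site")])
  cells <- cells[order(cells$sex, cells$site), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- meta$sex == cells$sex[i] & meta$site == cells$site[i]
    v <- cs[sel]
    degen <- length(v) < 2L
    if (degen)
      warnf("size summary: cell (%s, %s) has a single specimen; SD reported as 0",
            cells$sex[i], cells$site[i])
    data.frame(sex = cells$sex[i], site = cells$site[i], n = length(v),
               mean = mean(v), sd = if (degen) 0 else stats::sd(v),
               min = min(v), max = max(v), degenerate = degen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
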