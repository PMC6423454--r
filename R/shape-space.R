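#' Thin-plate-spline bending-energy matrix
#'
#' The bending-energy matrix of the thin-plate spline interpolant
#' anchored on a reference configuration, using the kernel
#' U(r) = r^2 log(r^2). (The literature also writes 2 r^2 log r; the
#' global factor of 2 rescales the energy eigenvalues but leaves the
#' principal-warp eigenvectors — and hence all scores computed here,
#' which use no energy weighting — unchanged.) Computed on the
#' non-affine subspace as B = Q (Q' K Q)^-1 Q', where Q spans the null
#' space of the affine design [1 x y]; this is algebraically the
#' upper-left block of the inverse of the bordered TPS system, but is
#' numerically better behaved. B is symmetric, positive semi-definite,
#' and annihilates affine deformations: its null space is exactly the
#' span of (1, x, y), so it has K - 3 positive eigenvalues.
#'
#' @param reference K x 2 matrix (typically the consensus from [gpa()]);
#'   no two landmarks may coincide.
#' @return K x K bending-energy matrix.
#' @export
bending_energy_matrix <- function(reference) {
  x <- as.matrix(reference)
  k <- nrow(x)
  if (k < 4L) stopf("bending energy needs at least 4 landmarks")
  d2 <- as.matrix(stats::dist(x))^2
  if (any(d2[upper.tri(d2)] < 1e-24))
    stopf("coincident landmarks in reference: thin-plate kernel is singular")
  kern <- ifelse(d2 > 0, d2 * log(d2), 0)
  p <- cbind(1, x)
  q2 <- qr.Q(qr(p), complete = TRUE)[, 4:k, drop = FALSE]
  inner <- solve(crossprod(q2, kern %*% q2))
  b <- q2 %*% inner %*% t(q2)
  (b + t(b)) / 2
}

# Orthonormal basis of the principal (non-affine) warps of a reference:
# eigenvectors of its bending-energy matrix with positive eigenvalue,
# ordered from smallest bending energy (largest-scale deformation,
# warp 1) to largest. Returns list(vectors = K x (K-3), values).
principal_warps <- function(reference) {
  b <- bending_energy_matrix(reference)
  e <- eigen(b, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-9
  ord <- rev(which(keep))  # eigen() sorts decreasing; reverse -> increasing
  list(vectors = e$vectors[, ord, drop = FALSE], values = e$values[ord])
}

# 2K-dimensional orthonormal basis of the uniform (affine) shape
# subspace: the orthogonal complement of the non-affine warps within
# the tangent space (orthogonal to the two translations, the rotation
# and the scale direction of the reference). 2 columns.
uniform_basis <- function(reference, warp_vectors) {
  k <- nrow(reference)
  cc <- center_config(reference)
  cc <- cc / sqrt(sum(cc^2))
  tx <- flatten_config(cbind(rep(1, k), rep(0, k)))
  ty <- flatten_config(cbind(rep(0, k), rep(1, k)))
  sc <- flatten_config(cc)
  ro <- flatten_config(cbind(-cc[, 2], cc[, 1]))
  m <- k - 3L
  wx <- matrix(0, 2 * k, m); wy <- matrix(0, 2 * k, m)
  wx[seq(1, 2 * k, by = 2), ] <- warp_vectors
  wy[seq(2, 2 * k, by = 2), ] <- warp_vectors
  span <- cbind(tx, ty, sc, ro, wx, wy)     # rank 2K - 2
  qq <- qr(span)
  qr.Q(qq, complete = TRUE)[, (qq$rank + 1L):(2L * k), drop = FALSE]
}

# Full orthonormal shape-variable basis of a reference: one row per
# variable (warp j x/y pairs, then the uniform pair when requested),
# columns in (x1, y1, ..., xK, yK) flattening. Shared by the score
# computation and the synthetic generator, which specifies group shape
# offsets in exactly this basis.
tangent_basis <- function(reference, include_uniform = TRUE) {
  k <- nrow(reference)
  pw <- principal_warps(reference)
  m <- ncol(pw$vectors)
  basis <- matrix(0, nrow = 2 * m, ncol = 2 * k)
  labels <- character(2 * m)
  for (j in seq_len(m)) {
    vx <- matrix(0, k, 2); vx[, 1] <- pw$vectors[, j]
    vy <- matrix(0, k, 2); vy[, 2] <- pw$vectors[, j]
    basis[2 * j - 1, ] <- flatten_config(vx)
    basis[2 * j, ]     <- flatten_config(vy)
    labels[2 * j - 1]  <- sprintf("warp%d.x", j)
    labels[2 * j]      <- sprintf("warp%d.y", j)
  }
  if (include_uniform) {
    u <- uniform_basis(reference, pw$vectors)
    basis <- rbind(basis, t(u))
    labels <- c(labels, "uniform.1", "uniform.2")
  }
  list(basis = basis, labels = labels, eigenvalues = pw$values)
}

#' Partial-warp scores of Procrustes-aligned shapes
#'
#' Projects each specimen's Procrustes residual (aligned minus
#' consensus) onto the principal warps of the consensus, x and y
#' components separately, with no bending-energy weighting (weight
#' exponent alpha = 0) — so the scores are simply an orthonormal
#' re-expression of the Procrustes residuals, split by spatial scale.
#' With `include_uniform = TRUE` (the default, and what downstream
#' discrimination should use) the two-dimensional uniform (affine)
#' component is appended, completing the 2(K-3) + 2 = 2K - 4 shape
#' variables of the similarity tangent space.
#'
#' @param aligned an `aligned_shapes` object from [gpa()].
#' @param include_uniform append the uniform component? Default `TRUE`.
#' @return object of class `"shape_variables"`: list with `scores`
#'   (N x M matrix), `basis` (M x 2K orthonormal matrix, one row per
#'   shape variable in (x1, y1, ..., xK, yK) flattening), `basis_labels`,
#'   `eigenvalues` (bending energies of the K - 3 principal warps),
#'   `consensus`, `meta`, and — after [shape_pca()] — `pc_scores`,
#'   `pc_variance`, `pc_rotation`.
#' @export
partial_warp_scores <- function(aligned, include_uniform = TRUE) {
  n <- dim(aligned$aligned)[3]
  if (n < 2L) stopf("need at least 2 specimens for shape variables")
  k <- nrow(aligned$consensus)
  tb <- tangent_basis(aligned$consensus, include_uniform = include_uniform)
  basis <- tb$basis
  labels <- tb$labels
  resid <- vapply(seq_len(n), function(i)
    flatten_config(aligned$aligned[, , i] - aligned$consensus),
    numeric(2 * k))
  scores <- t(basis %*% resid)
  rownames(scores) <- dimnames(aligned$aligned)[[3]]
  colnames(scores) <- labels
  structure(
    list(scores = scores, basis = basis, basis_labels = labels,
         eigenvalues = tb$eigenvalues, consensus = aligned$consensus,
         meta = aligned$meta),
    class = "shape_variables"
  )
}

#' @export
print.shape_variables <- function(x, ...) {
  cat(sprintf("<shape_variables> %d specimens x %d shape variables%s\n",
              nrow(x$scores), ncol(x$scores),
              if (is.null(x$pc_scores)) "" else " (+PCA)"))
  invisible(x)
}

#' Principal components of the shape variables
#'
#' PCA of the partial-warp scores on the covariance matrix (the scores
#' share a common scale, so no correlation-matrix standardization).
#' An orthogonal rotation: total variance is conserved, and keeping all
#' components changes no Mahalanobis-based downstream result.
#'
#' @param vars a `shape_variables` object.
#' @return `vars` with `pc_scores` (N x min(N-1, M)), `pc_variance`
#'   (explained-variance fractions, non-increasing, summing to 1 over
#'   the retained components) and `pc_rotation` filled in.
#' @export
shape_pca <- function(vars) {
  sc <- vars$scores
  total_var <- sum(apply(sc, 2, stats::var))
  if (total_var < .Machine$double.eps)
    stopf("shape scores have zero variance; PCA is undefined")
  r <- min(nrow(sc) - 1L, ncol(sc))
  p <- stats::prcomp(sc, center = TRUE, scale. = FALSE, rank. = r)
  vars$pc_scores <- p$x
  vars$pc_rotation <- p$rotation
  vars$pc_variance <- p$sdev[seq_len(ncol(p$x))]^2 / sum(p$sdev^2)
  vars
}
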