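# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Center a K x 2 configuration on its centroid.
center_config <- function(x) {
  sweep(x, 2, colMeans(x))
}

# Optimal rotation (det +1, no reflection) carrying centred `x` onto
# centred `target`, both K x 2: the 2-D orthogonal Procrustes solution
# restricted to proper rotations.
optimal_rotation <- function(x, target) {
  m <- crossprod(x, target)
  sv <- svd(m)
  s <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  sv$u %*% s %*% t(sv$v)
}

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, restoring
# the caller's RNG state afterwards; otherwise use the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Flatten a K x 2 configuration to a length-2K vector (x1, y1, x2, y2, ...).
flatten_config <- function(x) as.numeric(t(x))

unflatten_config <- function(v) matrix(v, ncol = 2, byrow = TRUE)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
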