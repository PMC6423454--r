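test_that("bending-energy matrix is symmetric, PSD, and annihilates affine terms", {
  ref <- make_template_wing(14, seed = 2)
  b <- bending_energy_matrix(ref)
  expect_lt(max(abs(b - t(b))), 1e-9)
  ev <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-9)
  expect_equal(sum(ev > max(ev) * 1e-9), 11)  # K - 3 principal warps
  for (a in list(rep(1, 14), ref[, 1], ref[, 2]))
    expect_lt(max(abs(b %*% a)), 1e-8)
  expect_error(bending_energy_matrix(ref[c(1, 1, 2, 3), ]), "oincident")
})

test_that("unit-square bending energy matches the direct L-inversion oracle", {
  sq <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2)
  # independent construction: build the full bordered TPS system
  # L = [[K P],[P' 0]], invert it, and read off the upper-left block
  k <- nrow(sq)
  d2 <- as.matrix(dist(sq))^2
  kern <- ifelse(d2 > 0, d2 * log(d2), 0)
  p <- cbind(1, sq)
  l <- rbind(cbind(kern, p), cbind(t(p), matrix(0, 3, 3)))
  lk <- solve(l)[1:k, 1:k]
  lk <- (lk + t(lk)) / 2
  b <- bending_energy_matrix(sq)
  expect_equal(b, lk, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(eigen(b, symmetric = TRUE, only.values = TRUE)$values,
               eigen(lk, symmetric = TRUE, only.values = TRUE)$values,
               tolerance = 1e-9)
})

test_that("the shape-variable basis is orthonormal", {
  ref <- make_template_wing(14, seed = 4)
  tb <- wingmorph:::tangent_basis(ref, include_uniform = TRUE)
  expect_equal(dim(tb$basis), c(24, 28))  # 2(K-3) + 2 variables
  gram <- tb$basis %*% t(tb$basis)
  expect_lt(max(abs(gram - diag(24))), 1e-9)
})

test_that("a specimen identical to the consensus scores zero everywhere", {
  base <- make_template_wing()
  ds <- landmark_dataset(lapply(1:3, function(i)
    landmark_config(paste0("c", i), base, sex = "female", site = "a")))
  v <- partial_warp_scores(gpa(ds))
  expect_lt(max(abs(v$scores)), 1e-9)
})

test_that("a pure affine shear has zero non-uniform and non-zero uniform scores", {
  base <- make_template_wing()
  shear <- base %*% matrix(c(1, 0, 0.05, 1), 2, 2)  # x <- x + 0.05 y
  aligned <- structure(
    list(aligned = array(c(base, shear), dim = c(14, 2, 2),
                         dimnames = list(NULL, NULL, c("a", "b"))),
         consensus = base,
         centroid_sizes = c(a = 1, b = 1),
         meta = data.frame(specimen_id = c("a", "b"), sex = "female",
                           site = "s"),
         iterations = 0L, converged = TRUE),
    class = "aligned_shapes")
  v <- partial_warp_scores(aligned, include_uniform = TRUE)
  nonuniform <- v$scores[2, grepl("^warp", v$basis_labels)]
  uniform <- v$scores[2, grepl("^uniform", v$basis_labels)]
  expect_lt(max(abs(nonuniform)), 1e-9)
  expect_gt(sqrt(sum(uniform^2)), 1e-3)
})

test_that("scores obey Pythagoras and reconstruct the aligned shapes", {
  # after partial Procrustes superimposition a residual r retains a
  # second-order component |r|^2/2 along the scale direction, which the
  # 2K - 4 tangent basis does not carry: the identities hold to O(|r|^2)
  ds <- noisy_dataset(make_template_wing(), 15, noise_sd = 0.001, seed = 13)
  al <- gpa(ds)
  v <- partial_warp_scores(al, include_uniform = TRUE)
  for (i in 1:15) {
    resid <- al$aligned[, , i] - al$consensus
    r2 <- sum(resid^2)
    expect_lt(abs(sum(v$scores[i, ]^2) - r2), r2^2)
    recon <- al$consensus +
      matrix(drop(t(v$basis) %*% v$scores[i, ]), 14, 2, byrow = TRUE)
    expect_lt(max(abs(recon - al$aligned[, , i])), r2)
  }
  expect_lt(max(abs(colMeans(v$scores))), 1e-8)  # residuals from consensus
})

test_that("the basis is exactly complete on tangent-space deviations", {
  # deviations constructed orthogonal to translations, rotation and
  # scale must be carried without loss, to machine precision
  base <- make_template_wing(14, seed = 6)
  k <- 14
  withr::local_seed(15)
  sim <- cbind(c(rbind(rep(1, k), rep(0, k))),       # translate x
               c(rbind(rep(0, k), rep(1, k))),       # translate y
               c(t(base)),                           # scale
               c(t(cbind(-base[, 2], base[, 1]))))   # rotation
  q <- qr.Q(qr(sim))
  tang <- rnorm(2 * k) * 0.01
  tang <- tang - q %*% crossprod(q, tang)            # project out similarity
  dev <- matrix(tang, k, 2, byrow = TRUE)
  aligned <- structure(
    list(aligned = array(c(base + dev, base - dev), dim = c(k, 2, 2),
                         dimnames = list(NULL, NULL, c("a", "b"))),
         consensus = base, centroid_sizes = c(a = 1, b = 1),
         meta = data.frame(specimen_id = c("a", "b"), sex = "f", site = "s"),
         iterations = 0L, converged = TRUE),
    class = "aligned_shapes")
  v <- partial_warp_scores(aligned, include_uniform = TRUE)
  expect_equal(sum(v$scores[1, ]^2), sum(dev^2), tolerance = 1e-12)
  recon <- base + matrix(drop(t(v$basis) %*% v$scores[1, ]), k, 2,
                         byrow = TRUE)
  expect_lt(max(abs(recon - (base + dev))), 1e-12)
})

test_that("shape PCA conserves variance and matches the SVD oracle", {
  # axis-aligned toy: variances (4, 1) -> fractions (0.8, 0.2)
  withr::local_seed(5)
  z <- scale(matrix(rnorm(400), 200, 2), center = TRUE, scale = TRUE)
  z <- qr.Q(qr(z)) * sqrt(199)        # exactly uncorrelated, unit variance
  toy <- list(scores = cbind(2 * z[, 1], z[, 2]), meta = NULL)
  class(toy) <- "shape_variables"
  p <- shape_pca(toy)
  expect_equal(p$pc_variance, c(0.8, 0.2), tolerance = 1e-9)

  x <- matrix(rnorm(60), 10, 6)
  toy2 <- structure(list(scores = x), class = "shape_variables")
  p2 <- shape_pca(toy2)
  expect_equal(sum(p2$pc_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(p2$pc_variance) <= 1e-12))
  expect_equal(sum(apply(p2$pc_scores, 2, var)),
               sum(apply(x, 2, var)), tolerance = 1e-9)
  # SVD oracle: eigenvalues = singular values squared / (N - 1)
  sv <- svd(scale(x, center = TRUE, scale = FALSE))$d
  expect_equal(apply(p2$pc_scores, 2, var)[1:6], (sv^2 / 9)[1:6],
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(shape_pca(structure(list(scores = matrix(1, 5, 3)),
                                   class = "shape_variables")),
               "zero variance")
})
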