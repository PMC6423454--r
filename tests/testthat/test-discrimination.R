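test_that("pooled covariance weights group scatters by their df", {
  # hand fixture: three small 2-D groups
  g1 <- matrix(c(0, 1, 2, 0, 2, 1), 3, 2)
  g2 <- matrix(c(1, 3, 1, 5, 0, 2, 4, 2), 4, 2)
  g3 <- matrix(c(0, 4, 1, 1), 2, 2)
  scores <- rbind(g1, g2, g3)
  labels <- rep(c("a", "b", "c"), c(3, 4, 2))
  hand <- (2 * cov(g1) + 3 * cov(g2) + 1 * cov(g3)) / (9 - 3)
  expect_equal(pooled_covariance(scores, labels), hand, tolerance = 1e-12)

  # two groups with identical internal scatter pool to that scatter
  shift <- sweep(g2, 2, c(10, -4), `+`)
  expect_equal(pooled_covariance(rbind(g2, shift), rep(c("a", "b"), each = 4)),
               cov(g2), tolerance = 1e-12)

  expect_error(pooled_covariance(rbind(g1, g1[1, , drop = FALSE]),
                                 c("a", "a", "a", "b")),
               "n >= 2")
})

test_that("Mahalanobis distance matches hand arithmetic on a fixed fixture", {
  ga <- matrix(c(0, 1, 0, 1, 0, 0, 1, 1), 4, 2)
  gb <- matrix(c(3, 4, 3, 4, 1, 1, 2, 2), 4, 2)
  scores <- rbind(ga, gb)
  labels <- rep(c("a", "b"), each = 4)
  # step-by-step: means, pooled covariance, inverse, quadratic form
  dm <- colMeans(ga) - colMeans(gb)
  s <- (3 * cov(ga) + 3 * cov(gb)) / 6
  hand_d <- sqrt(drop(t(dm) %*% solve(s) %*% dm))
  got <- mahalanobis_matrix(scores, labels)
  expect_equal(as.matrix(got)["a", "b"], hand_d, tolerance = 1e-9)
  expect_equal(as.matrix(got)["a", "a"], 0)
  expect_lt(max(abs(got$values - t(got$values))), 1e-12)
})

test_that("with spherical pooled covariance D reduces to the Euclidean mean distance", {
  withr::local_seed(31)
  n <- 4000
  base <- matrix(rnorm(2 * n), n, 2)
  shift <- c(3, 4)
  scores <- rbind(base, sweep(base, 2, shift, `+`))  # identical scatter
  labels <- rep(c("a", "b"), each = n)
  # pooled covariance of two copies of `base` equals cov(base); whiten
  # by hand so it is exactly spherical
  w <- chol(solve(cov(base)))
  z <- scores %*% t(w)
  dmean <- sqrt(sum((colMeans(z[labels == "a", ]) -
                     colMeans(z[labels == "b", ]))^2))
  got <- as.matrix(mahalanobis_matrix(z, labels))["a", "b"]
  expect_equal(got, dmean, tolerance = 1e-9)
})

test_that("identical group means give zero distance", {
  withr::local_seed(8)
  x <- matrix(rnorm(60), 30, 2)
  x2 <- sweep(x, 2, colMeans(x))          # both groups centred identically
  got <- as.matrix(mahalanobis_matrix(rbind(x2, x2),
                                      rep(c("a", "b"), each = 30)))
  expect_equal(got["a", "b"], 0, tolerance = 1e-9)
})

test_that("D is invariant under invertible affine transforms of score space", {
  withr::local_seed(17)
  fx <- two_group_scores(20, 5, sep = 2, seed = 3)
  d0 <- as.matrix(mahalanobis_matrix(fx$scores, fx$labels))[1, 2]
  for (rep in 1:5) {
    a <- matrix(rnorm(25), 5, 5)
    while (abs(det(a)) < 0.1) a <- matrix(rnorm(25), 5, 5)
    shift <- rnorm(5)
    z <- sweep(fx$scores %*% a, 2, shift, `+`)
    expect_equal(as.matrix(mahalanobis_matrix(z, fx$labels))[1, 2], d0,
                 tolerance = 1e-6)
  }
})

test_that("the unbiased correction removes the plug-in inflation", {
  # null case: both groups from the same spherical population; the
  # plug-in D^2 concentrates around its penalty term, the corrected
  # estimate around 0
  withr::local_seed(23)
  reps <- 200
  d2_plug <- d2_unb <- numeric(reps)
  for (r in seq_len(reps)) {
    fx <- two_group_scores(16, 6, sep = 0, seed = 1000 + r)
    d2_plug[r] <- as.matrix(mahalanobis_matrix(fx$scores, fx$labels))[1, 2]^2
    d2_unb[r] <- as.matrix(mahalanobis_matrix(fx$scores, fx$labels,
                                              correction = "unbiased"))[1, 2]^2
  }
  nu <- 30; p <- 6; cpen <- 2 / 16
  expect_equal(mean(d2_plug), nu / (nu - p - 1) * p * cpen, tolerance = 0.15)
  # before the truncation at zero the corrected estimator is unbiased:
  # its mean over replicates is 0 within Monte-Carlo error
  expect_lt(abs(mean((nu - p - 1) / nu * d2_plug - p * cpen)), 0.12)
  expect_lt(mean(d2_unb), mean(d2_plug) / 2)
})

test_that("canonical axes match an independent generalized-eigen route", {
  withr::local_seed(41)
  g <- rep(c("a", "b", "c"), each = 15)
  means <- rbind(c(0, 0, 0), c(3, 1, 0), c(1, 4, 0.5))
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(45), 15, 3) %*% diag(c(1, 0.7, 1.3)), 2,
          means[i, ], `+`)))
  cv <- canonical_scores(x, g)
  expect_equal(ncol(cv$scores), 2)  # min(G - 1, M)
  # independent route: plain eigen of W^-1 B
  w <- pooled_covariance(x, g)
  grand <- colMeans(x)
  b <- matrix(0, 3, 3)
  for (grp in c("a", "b", "c")) {
    dg <- colMeans(x[g == grp, ]) - grand
    b <- b + 15 * tcrossprod(dg)
  }
  b <- b / (45 - 3)
  ev <- eigen(solve(w) %*% b)
  expect_equal(cv$eigenvalues, Re(ev$values[1:2]), tolerance = 1e-8)
  expect_equal(sum(cv$power), 1, tolerance = 1e-12)
  # canonical scores have unit pooled within-group variance per axis
  expect_equal(diag(pooled_covariance(cv$scores, g)), c(1, 1),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("two groups give one canonical axis aligned with the mean difference", {
  withr::local_seed(43)
  # spherical within-group scatter: axis must parallel the mean axis
  fx <- two_group_scores(200, 3, sep = 4, seed = 9)
  cv <- canonical_scores(fx$scores, fx$labels)
  expect_equal(ncol(cv$scores), 1)
  dmean <- colMeans(fx$scores[fx$labels == "g2", ]) -
    colMeans(fx$scores[fx$labels == "g1", ])
  cosang <- abs(sum(cv$axes[, 1] * dmean)) /
    sqrt(sum(cv$axes[, 1]^2) * sum(dmean^2))
  expect_gt(cosang, 0.98)
})

test_that("leave-one-out assignment matches exhaustive hand computation", {
  # 6-point fixture, 2 groups x 3, low enough dimension to do by hand
  pts <- matrix(c(0, 0, 1, 0, 0, 1,
                  4, 0, 5, 0, 4, 1), 6, 2, byrow = TRUE)
  labels <- rep(c("a", "b"), each = 3)
  hand_assign <- character(6)
  for (i in 1:6) {
    rest <- pts[-i, , drop = FALSE]
    lrest <- labels[-i]
    s <- pooled_covariance(rest, lrest)
    d2 <- vapply(c("a", "b"), function(g) {
      dm <- pts[i, ] - colMeans(rest[lrest == g, , drop = FALSE])
      drop(t(dm) %*% solve(s) %*% dm)
    }, numeric(1))
    hand_assign[i] <- names(which.min(d2))
  }
  rep_ <- loo_reclassify(pts, labels)
  hand_confusion <- unclass(table(factor(labels, c("a", "b")),
                                  factor(hand_assign, c("a", "b"))))
  expect_equal(rep_$confusion, hand_confusion, ignore_attr = TRUE)
  expect_equal(rowSums(rep_$confusion), c(3, 3), ignore_attr = TRUE)
})

test_that("well-separated clusters reclassify perfectly, identical ones at chance", {
  fx <- two_group_scores(15, 3, sep = 20, seed = 2)  # 20 within-SDs apart
  rep_ <- loo_reclassify(fx$scores, fx$labels)
  expect_equal(rep_$per_group$percentage, c(100, 100))
  expect_equal(rep_$per_group$formatted, c("100% (15/15)", "100% (15/15)"))

  fx0 <- two_group_scores(50, 4, sep = 0, seed = 6)
  rep0 <- loo_reclassify(fx0$scores, fx0$labels)
  acc <- sum(diag(rep0$confusion)) / 100
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 100))
  # reported percentages reproduce round(100 c / t) cell-wise
  expect_equal(rep0$per_group$percentage,
               as.integer(round(100 * rep0$per_group$correct /
                                  rep0$per_group$total)))
})

test_that("reclassification preconditions and resubstitution mode", {
  fx <- two_group_scores(2, 2, sep = 1, seed = 4)
  expect_error(loo_reclassify(fx$scores, fx$labels), "n >= 3")
  fx2 <- two_group_scores(10, 2, sep = 3, seed = 5)
  res <- loo_reclassify(fx2$scores, fx2$labels, method = "resubstitution")
  loo <- loo_reclassify(fx2$scores, fx2$labels)
  expect_gte(sum(diag(res$confusion)), sum(diag(loo$confusion)))
})
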