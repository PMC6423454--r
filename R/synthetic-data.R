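#' Stylized wing template configuration
#'
#' A deterministic (given `seed`) K-landmark template standing in for a
#' digitized mosquito wing: points spread along an elongated ellipse of
#' aspect ratio about 3:1 with a small seeded jitter (so the
#' configuration is generic — no coincident or collinear landmarks),
#' centred and scaled to unit centroid size. The anatomical identity of
#' individual landmarks is treated as opaque; only their ordering is
#' semantic.
#'
#' @param k number of landmarks (default 14, the usual wing design).
#' @param seed integer seed for the jitter.
#' @return K x 2 matrix, centroid at origin, centroid size 1.
#' @export
make_template_wing <- function(k = 14L, seed = 1L) {
  if (k < 4L) stopf("a wing template needs at least 4 landmarks")
  ang <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  base <- cbind(1.5 * cos(ang), 0.5 * sin(ang))
  jit <- with_seed_if(seed, matrix(stats::runif(2 * k, -0.04, 0.04), k, 2))
  x <- center_config(base + jit)
  x / sqrt(sum(x^2))
}

default_groups <- function() {
  data.frame(
    sex  = rep(c("female", "male"), each = 3),
    site = rep(c("coastal", "residential", "cultivated"), 2),
    n    = c(32L, 40L, 31L, 36L, 42L, 39L),
    size_mean = c(2.04, 2.06, 1.95, 1.57, 1.62, 1.54),
    size_sd   = c(0.11, 0.21, 0.16, 0.18, 0.15, 0.14),
    stringsAsFactors = FALSE
  )
}

default_separations <- function() {
  sites <- c("coastal", "residential", "cultivated")
  f <- matrix(c(0, 2.53, 3.80,
                2.53, 0, 3.13,
                3.80, 3.13, 0), 3, 3, dimnames = list(sites, sites))
  m <- matrix(c(0, 2.06, 2.63,
                2.06, 0, 1.79,
                2.63, 1.79, 0), 3, 3, dimnames = list(sites, sites))
  list(female = f, male = m, between_sex = 8)
}

#' Group mean offsets realizing target Mahalanobis separations
#'
#' Embeds G group means into the orthonormal shape-variable basis so
#' that, with isotropic per-variable noise of standard deviation
#' `sigma`, the *population* Mahalanobis distance between groups g and
#' h equals `separations[g, h]`. Since the basis is orthonormal and the
#' noise isotropic, the score covariance is sigma^2 I and the
#' population D is just the Euclidean mean distance divided by sigma —
#' so classical multidimensional scaling of sigma * separations gives
#' the required coordinates in closed form.
#'
#' @param separations G x G symmetric target distance matrix
#'   (dimnames = group names), in Mahalanobis units.
#' @param sigma isotropic score noise SD the dataset will be generated
#'   with.
#' @param n_vars dimension of the shape-variable space the offsets live
#'   in (2K - 4 for the full tangent space).
#' @param dims which coordinates of that space carry the embedding
#'   (default the first G - 1).
#' @return G x n_vars matrix of offset vectors (rows named by group),
#'   centred so the grand mean offset is zero.
#' @export
offsets_from_separations <- function(separations, sigma, n_vars,
                                     dims = NULL) {
  g <- nrow(separations)
  if (is.null(dims)) dims <- seq_len(g - 1L)
  if (length(dims) < g - 1L || max(dims) > n_vars)
    stopf("need %d embedding coordinates within 1..%d", g - 1L, n_vars)
  emb <- stats::cmdscale(separations * sigma, k = g - 1L)
  emb <- sweep(emb, 2, colMeans(emb))
  out <- matrix(0, g, n_vars, dimnames = list(rownames(separations), NULL))
  out[, dims[seq_len(ncol(emb))]] <- emb
  out
}

#' Synthetic study configuration
#'
#' Describes a multi-site, two-sex wing-landmark study to simulate.
#' The defaults reproduce the emulated survey design: 3 sites x 2
#' sexes with cell sizes (female 32/40/31, male 36/42/39; 220 total),
#' per-cell centroid-size distributions (means 1.54-2.06 mm, SDs
#' 0.11-0.21 mm), within-sex shape separations of 1.79-3.80
#' Mahalanobis units between sites, a between-sex shape separation of 8
#' units (wing sexual dimorphism is much stronger than site-level
#' divergence), and isotropic per-landmark digitizing/biological noise
#' of 0.008 shape units.
#'
#' @param template K x 2 base wing shape (default [make_template_wing()]).
#' @param groups data frame with columns `sex`, `site`, `n`,
#'   `size_mean`, `size_sd` (mm).
#' @param separations list with per-sex G x G site separation matrices
#'   (Mahalanobis units) and a `between_sex` scalar; `NULL` for no
#'   shape structure.
#' @param landmark_noise_sd isotropic per-landmark noise SD, in shape
#'   (unit-centroid-size) units.
#' @param seed RNG seed for [simulate_dataset()].
#' @return object of class `"synthetic_config"`; includes
#'   `shape_offsets`, a (sex:site)-named matrix of mean offsets in the
#'   template's shape-variable basis.
#' @export
synthetic_config <- function(template = make_template_wing(),
                             groups = default_groups(),
                             separations = default_separations(),
                             landmark_noise_sd = 0.008,
                             seed = 20161001L) {
  need <- c("sex", "site", "n", "size_mean", "size_sd")
  if (!all(need %in% names(groups)))
    stopf("groups needs columns: %s", paste(need, collapse = ", "))
  if (any(groups$n < 1L)) stopf("every group needs n >= 1")
  if (any(groups$size_mean <= 0)) stopf("size_mean must be positive")
  if (any(groups$size_sd < 0)) stopf("size_sd must be non-negative")
  if (landmark_noise_sd < 0) stopf("landmark_noise_sd must be non-negative")
  k <- nrow(template)
  n_vars <- 2L * k - 4L
  key <- paste(groups$sex, groups$site, sep = ":")
  offsets <- matrix(0, nrow(groups), n_vars, dimnames = list(key, NULL))
  if (!is.null(separations)) {
    sexes <- unique(groups$sex)
    for (s in sexes) {
      if (is.null(separations[[s]])) next
      rows <- which(groups$sex == s)
      sep <- separations[[s]][groups$site[rows], groups$site[rows]]
      offsets[rows, ] <- offsets_from_separations(
        sep, landmark_noise_sd, n_vars)
    }
    bs <- separations$between_sex
    if (!is.null(bs) && length(sexes) == 2L) {
      dim_sex <- length(unique(groups$site))  # first free coordinate
      offsets[groups$sex == sexes[1], dim_sex] <-
        offsets[groups$sex == sexes[1], dim_sex] + bs * landmark_noise_sd / 2
      offsets[groups$sex == sexes[2], dim_sex] <-
        offsets[groups$sex == sexes[2], dim_sex] - bs * landmark_noise_sd / 2
    }
  }
  structure(
    list(template = template, groups = groups, shape_offsets = offsets,
         landmark_noise_sd = landmark_noise_sd, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d groups, %d specimens, K = %d, noise sd = %g\n",
    nrow(x$groups), sum(x$groups$n), nrow(x$template), x$landmark_noise_sd))
  invisible(x)
}

#' Simulate a landmark dataset
#'
#' For each group, draws `n` specimens as
#' template + group shape offset (mapped from the shape-variable basis
#' back to landmark coordinates) + isotropic per-landmark Gaussian
#' noise, then centres the configuration and scales it so its true
#' centroid size is a draw from Normal(size_mean, size_sd) truncated at
#' zero (re-drawn on the negligible event of a non-positive draw), and
#' finally applies a random rotation and translation so that
#' superimposition downstream is non-trivial. Deterministic given the
#' seed in `cfg`.
#'
#' @param cfg a [synthetic_config()].
#' @return a [landmark_dataset()] with specimen ids `<sex>_<site>_<i>`.
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "synthetic_config"))
    stopf("simulate_dataset expects a synthetic_config")
  template <- cfg$template
  k <- nrow(template)
  tb <- tangent_basis(template, include_uniform = TRUE)
  with_seed_if(cfg$seed, {
    configs <- list()
    for (gi in seq_len(nrow(cfg$groups))) {
      grp <- cfg$groups[gi, ]
      off <- unflatten_config(
        drop(t(tb$basis) %*% cfg$shape_offsets[gi, ]))
      for (i in seq_len(grp$n)) {
        shape <- template + off +
          matrix(stats::rnorm(2 * k, 0, cfg$landmark_noise_sd), k, 2)
        cs_true <- -1
        while (cs_true <= 0)
          cs_true <- stats::rnorm(1, grp$size_mean, grp$size_sd)
        xy <- center_config(shape) / centroid_size(shape) * cs_true
        th <- stats::runif(1, 0, 2 * pi)
        rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        xy <- xy %*% rot
        xy <- sweep(xy, 2, stats::runif(2, -5, 5), `+`)
        configs[[length(configs) + 1L]] <- landmark_config(
          sprintf("%s_%s_%03d", grp$sex, grp$site, i), xy,
          sex = grp$sex, site = grp$site)
      }
    }
    landmark_dataset(configs)
  })
}

#' Simulate duplicate digitizations of a scalar measure
#'
#' Specimen-level true values are drawn from
#' Normal(`mean`, `among_sd`); each of `n_repeats` digitizations adds
#' independent Normal(0, `within_sd`) measurement noise. The true
#' intraclass correlation of the generating process is
#' among_sd^2 / (among_sd^2 + within_sd^2), attached as attribute
#' `"true_icc"` so recovery by [repeatability()] can be checked.
#'
#' @param n_specimens number of specimens (>= 2).
#' @param n_repeats digitizations per specimen (>= 2).
#' @param mean mean of the true measure (e.g. centroid size in mm).
#' @param among_sd between-specimen SD of the true measure.
#' @param within_sd SD of the per-digitization measurement noise.
#' @param seed optional RNG seed.
#' @return n_specimens x n_repeats numeric matrix with attributes
#'   `"true_values"` and `"true_icc"`.
#' @export
simulate_repeats <- function(n_specimens, n_repeats, mean = 2,
                             among_sd = 0.15, within_sd = 0.01,
                             seed = NULL) {
  if (n_specimens < 2L) stopf("need at least 2 specimens")
  if (n_repeats < 2L) stopf("need at least 2 repeats")
  with_seed_if(seed, {
    truth <- stats::rnorm(n_specimens, mean, among_sd)
    m <- truth + matrix(stats::rnorm(n_specimens * n_repeats, 0, within_sd),
                        n_specimens, n_repeats)
    structure(m, true_values = truth,
              true_icc = among_sd^2 / (among_sd^2 + within_sd^2))
  })
}
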