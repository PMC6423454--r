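# Shared fixture builders: everything is generated in code.

# A generic (non-degenerate) random K-landmark shape.
random_shape <- function(k = 14, seed = NULL, sd = 1) {
  draw <- function() matrix(stats::rnorm(2 * k, sd = sd), k, 2)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

rotate2 <- function(x, theta) {
  x %*% matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Dataset of n specimens: base shape + small noise, random similarity
# transforms, round-robin site labels.
noisy_dataset <- function(base, n, noise_sd = 0.01, sites = "a",
                          sex = "female", seed = 1) {
  withr::with_seed(seed, {
    configs <- lapply(seq_len(n), function(i) {
      x <- base + matrix(stats::rnorm(length(base), sd = noise_sd),
                         nrow(base), 2)
      x <- rotate2(x, stats::runif(1, 0, 2 * pi)) * stats::runif(1, 0.5, 2)
      x <- sweep(x, 2, stats::runif(2, -3, 3), `+`)
      landmark_config(sprintf("sp%03d", i), x, sex = sex,
                      site = sites[(i - 1) %% length(sites) + 1])
    })
    landmark_dataset(configs)
  })
}

# Two-group 1-D / low-D score fixture for discrimination tests.
two_group_scores <- function(n_per, p, sep = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per * p), n_per, p),
               matrix(stats::rnorm(n_per * p), n_per, p) +
                 matrix(rep(c(sep, rep(0, p - 1)), each = n_per), n_per, p))
    list(scores = x, labels = rep(c("g1", "g2"), each = n_per))
  })
}
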