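#' Subset a landmark dataset
#'
#' @param dataset a [landmark_dataset()].
#' @param idx logical or integer specimen index.
#' @return a `landmark_dataset` with the selected specimens.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(list(coords = dataset$coords[, , idx, drop = FALSE],
                 meta = dataset$meta[idx, , drop = FALSE]),
            class = "landmark_dataset")
}

pairwise_pval_matrix <- function(groups, fun) {
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  diag(m) <- 0
  for (i in seq_along(groups))
    for (j in seq_len(i - 1L)) m[i, j] <- m[j, i] <- fun(groups[i], groups[j])
  m
}

#' Run the full wing-morphometric analysis
#'
#' End-to-end orchestration of the classical landmark toolchain, per
#' sex: generalized Procrustes superimposition; centroid-size summary
#' and pairwise size permutation tests; partial-warp shape variables
#' with their principal components; between-site Mahalanobis distances
#' and pairwise shape permutation tests; leave-one-out validated
#' reclassification; canonical (factor-map) scores; per-site consensus
#' shapes. Across sexes, a neighbor-joining phenogram over the
#' sex x site group means. Sexes are never pooled for discrimination
#' or testing. The run is deterministic given `seed` (per-stage seeds
#' are derived from it).
#'
#' @param dataset a [landmark_dataset()] with >= 2 site groups per sex.
#' @param cycles permutation cycles for the size and shape tests
#'   (default 1000).
#' @param seed master RNG seed (default 20161001).
#' @param include_uniform include the uniform shape component (default
#'   `TRUE`).
#' @param cond_max condition ceiling of the dimension-retention policy.
#' @param tree_metric distance fed to the phenogram: `"procrustes"`
#'   (distances between group mean shapes) or `"mahalanobis"`.
#' @param correction Mahalanobis estimator for the distance tables, see
#'   [mahalanobis_matrix()].
#' @return object of class `"analysis_report"`: list with `size_table`,
#'   and per sex `size_pvals`, `shape_pvals`, `mahalanobis`,
#'   `reclassification`, `canonical`, `consensus` (per-site mean
#'   shapes); plus `tree` (`phylo`), `newick`, `tree_distances`, and
#'   `metadata` (seed, cycles, options, package version).
#' @export
run_full_analysis <- function(dataset, cycles = 1000L, seed = 20161001L,
                              include_uniform = TRUE, cond_max = 1e8,
                              tree_metric = c("procrustes", "mahalanobis"),
                              correction = c("none", "unbiased")) {
  tree_metric <- match.arg(tree_metric)
  correction <- match.arg(correction)
  meta <- dataset$meta
  sexes <- sort(unique(meta$sex))
  per_sex <- list()
  size_rows <- list()
  seed_i <- as.integer(seed)
  for (s in sexes) {
    sub <- subset_dataset(dataset, meta$sex == s)
    sites <- sort(unique(sub$meta$site))
    if (length(sites) < 2L)
      stopf("stage gpa [sex=%s]: need >= 2 site groups", s)
    aligned <- gpa(sub)
    size_rows[[s]] <- size_summary(aligned)
    vars <- shape_pca(partial_warp_scores(aligned,
                                          include_uniform = include_uniform))
    cs <- aligned$centroid_sizes
    site_of <- sub$meta$site
    size_p <- pairwise_pval_matrix(sites, function(a, b) {
      seed_i <<- seed_i + 1L
      permutation_test_size(cs[site_of == a], cs[site_of == b],
                            cycles = cycles, seed = seed_i)$p_value
    })
    shape_p <- pairwise_pval_matrix(sites, function(a, b) {
      seed_i <<- seed_i + 1L
      permutation_test_shape(vars, site_of, a, b, cycles = cycles,
                             seed = seed_i, cond_max = cond_max)$p_value
    })
    mahal <- mahalanobis_matrix(vars, site_of, correction = correction,
                                cond_max = cond_max)
    reclass <- loo_reclassify(vars, site_of, cond_max = cond_max)
    canon <- canonical_scores(vars, site_of, cond_max = cond_max)
    consensus <- lapply(stats::setNames(sites, sites), function(g) {
      m <- apply(aligned$aligned[, , site_of == g, drop = FALSE],
                 c(1, 2), mean)
      m / sqrt(sum(center_config(m)^2))
    })
    per_sex[[s]] <- list(aligned = aligned, vars = vars,
                         size_pvals = size_p, shape_pvals = shape_p,
                         mahalanobis = mahal, reclassification = reclass,
                         canonical = canon, consensus = consensus)
  }
  all_aligned <- gpa(dataset)
  all_vars <- partial_warp_scores(all_aligned,
                                  include_uniform = include_uniform)
  tree_d <- group_distance_matrix(all_aligned, all_vars,
                                  metric = tree_metric,
                                  cond_max = cond_max)
  tree <- neighbor_joining(tree_d)
  structure(
    list(size_table = do.call(rbind, c(size_rows, make.row.names = FALSE)),
         per_sex = per_sex, tree = tree, newick = to_newick(tree),
         tree_distances = tree_d,
         metadata = list(seed = as.integer(seed), cycles = as.integer(cycles),
                         include_uniform = include_uniform,
                         cond_max = cond_max, tree_metric = tree_metric,
                         correction = correction,
                         n_specimens = nrow(meta),
                         package_version =
                           as.character(utils::packageVersion("wingmorph")))),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n\nCentroid size by sex and site:\n")
  print(x$size_table, row.names = FALSE)
  for (s in names(x$per_sex)) {
    cat(sprintf("\n== %s ==\n", s))
    print(x$per_sex[[s]]$mahalanobis)
    cat("size p-values (lower triangle):\n")
    print(round(x$per_sex[[s]]$size_pvals, 3))
    cat("shape p-values (lower triangle):\n")
    print(round(x$per_sex[[s]]$shape_pvals, 3))
    print(x$per_sex[[s]]$reclassification)
  }
  cat("\nPhenogram (", x$tree_distances$metric, " distances):\n",
      x$newick, "\n", sep = "")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits machine-readable equivalents of the standard result tables:
#' CSVs for the size summary, p-value and distance matrices,
#' reclassification and canonical scores, per-group consensus shapes, a
#' Newick file for the phenogram, and a JSON summary with the run
#' metadata.
#'
#' @param report an [run_full_analysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$size_table, file.path(dir, "size_table.csv"),
                   row.names = FALSE)
  for (s in names(report$per_sex)) {
    ps <- report$per_sex[[s]]
    utils::write.csv(ps$size_pvals,
                     file.path(dir, sprintf("size_pvals_%s.csv", s)))
    utils::write.csv(ps$shape_pvals,
                     file.path(dir, sprintf("shape_pvals_%s.csv", s)))
    utils::write.csv(ps$mahalanobis$values,
                     file.path(dir, sprintf("mahalanobis_%s.csv", s)))
    utils::write.csv(ps$reclassification$per_group,
                     file.path(dir, sprintf("reclassification_%s.csv", s)),
                     row.names = FALSE)
    cv <- data.frame(specimen_id = rownames(ps$canonical$scores),
                     site = ps$canonical$labels, ps$canonical$scores)
    utils::write.csv(cv, file.path(dir, sprintf("canonical_%s.csv", s)),
                     row.names = FALSE)
    cons <- do.call(rbind, lapply(names(ps$consensus), function(g)
      data.frame(site = g, landmark = seq_len(nrow(ps$consensus[[g]])),
                 x = ps$consensus[[g]][, 1], y = ps$consensus[[g]][, 2])))
    utils::write.csv(cons, file.path(dir, sprintf("consensus_%s.csv", s)),
                     row.names = FALSE)
  }
  writeLines(report$newick, file.path(dir, "phenogram.nwk"))
  summary_json <- list(
    metadata = report$metadata,
    size_table = report$size_table,
    mahalanobis = lapply(report$per_sex, function(ps) ps$mahalanobis$values),
    size_pvals = lapply(report$per_sex, function(ps) ps$size_pvals),
    shape_pvals = lapply(report$per_sex, function(ps) ps$shape_pvals),
    reclassification = lapply(report$per_sex,
                              function(ps) ps$reclassification$per_group),
    newick = report$newick
  )
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(dir)
}
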