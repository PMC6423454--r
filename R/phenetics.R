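#' Neighbor-joining phenogram from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair (i, j) minimizing
#' Q(i, j) = (r - 2) d(i, j) - R_i - R_j is joined (ties break toward
#' the earliest pair in label order, so the result is deterministic),
#' with the standard branch-length formulas; the final three nodes are
#' connected by the closed-form star lengths. Consistent on additive
#' distances: the induced path-length matrix then reproduces the input
#' exactly. A negative branch length (possible on non-additive input)
#' is clamped to 0 with the deficit moved to the sibling edge so the
#' path length through the new node is preserved; the number of clamped
#' edges is recorded in the `"clamped"` attribute.
#'
#' @param d a [distance_matrix()], a symmetric labeled matrix, or a
#'   `dist` object, over >= 2 labels.
#' @return an unrooted `ape::phylo` tree (leaf set = the labels) with
#'   attribute `"clamped"`. Two labels give a degenerate single-edge
#'   tree, with a warning.
#' @export
neighbor_joining <- function(d) {
  dm <- if (inherits(d, "distance_matrix")) d$values else as.matrix(d)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("g", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n < 2L) stopf("neighbor joining needs at least 2 labels")
  placeholders <- paste0("t", seq_len(n))
  if (n == 2L) {
    warnf("only 2 labels: returning a degenerate single-edge tree")
    txt <- sprintf("(%s:%.12g,%s:%.12g);", placeholders[1], dm[1, 2] / 2,
                   placeholders[2], dm[1, 2] / 2)
    tree <- ape::read.tree(text = txt)
    tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
    attr(tree, "clamped") <- 0L
    return(tree)
  }
  sub <- placeholders           # growing newick fragment per active node
  act <- dm
  clamped <- 0L
  branch <- function(len, sibling_len) {
    # clamp negatives, preserving the path through the parent node
    if (len < 0) { clamped <<- clamped + 1L; c(0, sibling_len + len) }
    else c(len, sibling_len)
  }
  while (nrow(act) > 3L) {
    r <- nrow(act)
    rs <- rowSums(act)
    q <- (r - 2) * act - outer(rs, rs, `+`)
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1, ]   # first minimum: deterministic
    i <- min(ij); j <- max(ij)
    vi <- act[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- act[i, j] - vi
    b <- branch(vi, vj); vi <- b[1]; vj <- b[2]
    b <- branch(vj, vi); vj <- b[1]; vi <- b[2]
    new_d <- (act[i, ] + act[j, ] - act[i, j]) / 2
    merged <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], vi, sub[j], vj)
    keep <- setdiff(seq_len(r), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], new_d[keep]),
                 c(new_d[keep], 0))
    sub <- c(sub[keep], merged)
  }
  d12 <- act[1, 2]; d13 <- act[1, 3]; d23 <- act[2, 3]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  if (any(v < 0)) { clamped <- clamped + sum(v < 0); v[v < 0] <- 0 }
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 sub[1], v[1], sub[2], v[2], sub[3], v[3])
  tree <- ape::read.tree(text = txt)
  tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  attr(tree, "clamped") <- clamped
  tree
}

#' Serialize a tree to Newick text
#'
#' Standard Newick with branch lengths. Labels containing spaces or
#' Newick metacharacters are single-quoted (embedded quotes doubled),
#' per the format's quoting rules, so any label round-trips.
#'
#' @param tree an `ape::phylo` object.
#' @return a single Newick string, terminated by `;`.
#' @export
to_newick <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("to_newick expects an ape::phylo tree")
  quote_label <- function(s) {
    if (grepl("[][ ()':;,]", s))
      paste0("'", gsub("'", "''", s), "'")
    else s
  }
  edges <- tree$edge
  lens <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(edges)) else
    tree$edge.length
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  render <- function(node) {
    if (node <= n_tip) return(quote_label(tree$tip.label[node]))
    parts <- vapply(kids[[as.character(node)]], function(e) {
      child <- render(edges[e, 2])
      if (is.na(lens[e])) child else sprintf("%s:%.12g", child, lens[e])
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(unique(edges[, 1]), edges[, 2])
  paste0(render(root), ";")
}

#' Between-group shape distance matrix for tree building
#'
#' Builds the 6-leaf (sex x site) distance matrix that a shape
#' phenogram is computed from. `metric = "procrustes"` takes partial
#' Procrustes distances between group mean shapes (the mean of each
#' group's aligned configurations, rescaled to unit centroid size);
#' `metric = "mahalanobis"` takes Mahalanobis distances between group
#' mean scores under the covariance pooled over all groups.
#'
#' @param aligned an [gpa()] result over all specimens.
#' @param vars matching [partial_warp_scores()] result (needed for
#'   `"mahalanobis"`).
#' @param metric `"procrustes"` or `"mahalanobis"`.
#' @param group_key metadata columns defining the groups (default
#'   sex x site).
#' @param cond_max condition ceiling for dimension retention.
#' @return a [distance_matrix()].
#' @export
group_distance_matrix <- function(aligned, vars = NULL,
                                  metric = c("procrustes", "mahalanobis"),
                                  group_key = c("sex", "site"),
                                  cond_max = 1e8) {
  metric <- match.arg(metric)
  grp <- interaction(aligned$meta[group_key], sep = ":", drop = TRUE)
  labels <- sort(levels(grp))
  if (metric == "procrustes") {
    means <- lapply(labels, function(g) {
      m <- apply(aligned$aligned[, , grp == g, drop = FALSE], c(1, 2), mean)
      m / sqrt(sum(center_config(m)^2))
    })
    v <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (i in seq_along(labels))
      for (j in seq_len(i - 1L)) {
        v[i, j] <- v[j, i] <- procrustes_distance(means[[i]], means[[j]])
      }
    distance_matrix(v, metric = "procrustes")
  } else {
    if (is.null(vars)) stopf("metric 'mahalanobis' needs shape variables")
    mahalanobis_matrix(vars, as.character(grp), cond_max = cond_max)
  }
}
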