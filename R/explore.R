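#' Log2 / mean-centre transform used for unsupervised analyses
#'
#' The exploratory analyses (clustering, PCA) run on log2 mol% with
#' per-lipid mean centring, matching the log2 world of the panel score.
#'
#' @param matrix complete `"lipidome_matrix"` with positive values.
#' @param log2 take log2 first (default TRUE).
#' @param center per-column mean centring (default TRUE).
#' @return plain numeric matrix, samples x lipids.
#' @export
explore_transform <- function(matrix, log2 = TRUE, center = TRUE) {
  stopifnot(inherits(matrix, "lipidome_matrix"))
  if (anyNA(matrix)) stop("transform requires a complete matrix")
  m <- unclass(matrix)
  if (log2) {
    if (any(m <= 0)) stop("log2 transform requires positive values")
    m <- base::log2(m)
  }
  if (center) m <- scale(m, center = TRUE, scale = FALSE)
  m[, , drop = FALSE]
}

#' Hierarchical clustering of samples or lipids
#'
#' Agglomerative clustering with Euclidean distance and complete linkage.
#' The merge heights of complete linkage are ultrametric: cophenetic
#' distances dominate the original pairwise distances.
#'
#' @param matrix numeric matrix (e.g. from [explore_transform()]) or a
#'   complete `"lipidome_matrix"` (transformed internally with defaults).
#' @param axis cluster `"samples"` (rows) or `"lipids"` (columns).
#' @return a `"cluster_tree"`: list with the `hclust` object (`tree`), the
#'   distance matrix (`dist`), cophenetic distances (`cophenetic`) and the
#'   clustered axis.
#' @export
hierarchical_cluster <- function(matrix, axis = c("samples", "lipids")) {
  axis <- match.arg(axis)
  m <- if (inherits(matrix, "lipidome_matrix")) explore_transform(matrix) else matrix
  if (!is.matrix(m)) stop("'matrix' must be a matrix")
  if (axis == "lipids") m <- t(m)
  if (nrow(m) < 2L) stop("need at least 2 items to cluster")
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  structure(list(tree = hc, dist = d, cophenetic = stats::cophenetic(hc),
                 axis = axis),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d %s, complete linkage on Euclidean distance\n",
              length(x$tree$order), x$axis))
  invisible(x)
}

#' Cut a cluster tree and summarise within-clade correlation
#'
#' The tree is built on Euclidean distance, but cluster cohesion is also
#' usefully summarised as the mean pairwise Pearson correlation of the
#' member profiles; both views are reported per clade.
#'
#' @param ct a `"cluster_tree"`.
#' @param data the matrix the tree was built on (items in rows when
#'   `axis = "samples"`).
#' @param k number of clades.
#' @return data frame per clade: size, mean pairwise Pearson correlation,
#'   merge height (max within-clade cophenetic distance).
#' @export
clade_summary <- function(ct, data, k = 2L) {
  stopifnot(inherits(ct, "cluster_tree"))
  if (ct$axis == "lipids") data <- t(data)
  grp <- stats::cutree(ct$tree, k = k)
  coph <- as.matrix(ct$cophenetic)
  do.call(rbind, lapply(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    r <- if (length(idx) > 1L) {
      cc <- stats::cor(t(data[idx, , drop = FALSE]))
      mean(cc[upper.tri(cc)])
    } else NA_real_
    data.frame(clade = g, size = length(idx), mean_pearson = r,
               merge_height = if (length(idx) > 1L)
                 max(coph[idx, idx]) else 0)
  }))
}

#' Export a cluster tree as Newick
#'
#' Branch lengths encode merge heights, so cophenetic distances can be
#' recovered from the serialized tree.
#'
#' @param ct a `"cluster_tree"`.
#' @param path output file.
#' @export
write_tree_newick <- function(ct, path) {
  stopifnot(inherits(ct, "cluster_tree"))
  phy <- ape::as.phylo(ct$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Principal component analysis of lipid profiles
#'
#' Spectral decomposition of the covariance (or, with `scale = TRUE`,
#' correlation) structure of the samples x lipids matrix. Sign convention:
#' each component is flipped so that its largest-magnitude loading is
#' positive, making results reproducible across LAPACK builds.
#'
#' @param matrix numeric matrix or complete `"lipidome_matrix"` (the latter
#'   is log2-transformed first, matching [explore_transform()] without
#'   centring — centring is controlled here).
#' @param center,scale centring/unit-variance flags (defaults TRUE/FALSE).
#' @return a `"pca_result"`: list with `scores` (samples x components),
#'   `loadings` (lipids x components), `explained_variance` and
#'   `total_variance`.
#' @export
pca <- function(matrix, center = TRUE, scale = FALSE) {
  m <- if (inherits(matrix, "lipidome_matrix"))
    explore_transform(matrix, log2 = TRUE, center = FALSE) else matrix
  if (!is.matrix(m) || nrow(m) < 2L) stop("need a matrix with >= 2 samples")
  if (anyNA(m)) stop("PCA requires a complete matrix")
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance column(s) with scale = TRUE: ",
           paste(colnames(m)[sds == 0], collapse = ", "))
  }
  pr <- stats::prcomp(m, center = center, scale. = scale)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sweep(pr$x, 2, flip, "*")
  loadings <- sweep(pr$rotation, 2, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = pr$sdev^2,
                 total_variance = sum(pr$sdev^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  pct <- 100 * x$explained_variance / x$total_variance
  cat(sprintf("<pca_result> %d components; variance explained: %s\n",
              length(pct),
              paste(sprintf("%.1f%%", pct[seq_len(min(3, length(pct)))]),
                    collapse = ", ")))
  invisible(x)
}
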