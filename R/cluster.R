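#' @include AllClasses.R
NULL

#' Standardise each row to z-scores
#'
#' Centres each row to mean 0 and scales it to sample standard deviation 1
#' (n-1 denominator), the usual preprocessing before heatmap clustering.
#' Constant rows carry no clustering signal and map to all-zeros rather
#' than erroring.
#'
#' @param m numeric matrix with at least two columns.
#' @return matrix of the same shape.
#' @export
zscoreRows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L)
    prn_stop("prn_shape_error", "z-scoring needs at least 2 columns")
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  centred <- m - mu
  s[s == 0] <- Inf   # constant rows -> zeros
  centred / s
}

#' Pairwise distances between profiles
#'
#' Euclidean (L2) or Pearson (1 - correlation) distance between the rows or
#' columns of a complete matrix.
#'
#' @param m complete numeric matrix.
#' @param metric `"euclidean"` or `"pearson"`.
#' @param axis cluster `"rows"` (default) or `"cols"`.
#' @return symmetric distance matrix with zero diagonal, dimnames from the
#'   clustered axis.
#' @export
pairwiseDistance <- function(m, metric = c("euclidean", "pearson"),
                             axis = c("rows", "cols")) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (any(!is.finite(m)))
    prn_stop("prn_value_error", "distance input must be complete and finite")
  if (axis == "cols") m <- t(m)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(m, method = "euclidean"))
  } else {
    v <- apply(m, 1L, stats::sd)
    if (any(v == 0))
      prn_stop("prn_undefined_correlation_error",
               "zero-variance vector '%s' has undefined correlation",
               rownames(m)[v == 0][1L])
    d <- 1 - stats::cor(t(m))
    diag(d) <- 0
  }
  d
}

#' Agglomerative average-linkage (UPGMA) clustering
#'
#' At each step merges the pair of clusters with the minimal unweighted mean
#' inter-cluster distance; when several pairs tie exactly, the pair with the
#' lowest (row, column) index in the current cluster ordering is taken, so
#' the result is fully deterministic.
#'
#' @param d symmetric distance matrix (or `dist`) over n >= 2 items.
#' @return a [LinkageTree-class].
#' @export
averageLinkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    prn_stop("prn_matrix_error", "distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 2L)
    prn_stop("prn_matrix_error", "need at least 2 items to cluster")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  ids <- -seq_len(n)          # hclust convention: negative = leaf
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(ids)
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
    }
    merge[step, ] <- c(ids[bi], ids[bj])
    height[step] <- best
    # unweighted average linkage update over all remaining clusters
    newrow <- (sizes[bi] * d[bi, ] + sizes[bj] * d[bj, ]) /
      (sizes[bi] + sizes[bj])
    d[bi, ] <- newrow
    d[, bi] <- newrow
    d[bi, bi] <- 0
    keep <- setdiff(seq_len(k), bj)
    d <- d[keep, keep, drop = FALSE]
    sizes[bi] <- sizes[bi] + sizes[bj]
    sizes <- sizes[keep]
    ids[bi] <- step
    ids <- ids[keep]
  }
  new("LinkageTree", merge = merge, height = height, labels = labels)
}

.tree_leaves <- function(tree, node) {
  # leaves under a merge-matrix node; negative node = leaf index
  if (node < 0L) return(-node)
  row <- tree@merge[node, ]
  c(.tree_leaves(tree, row[1L]), .tree_leaves(tree, row[2L]))
}

#' Convert a LinkageTree to an hclust object
#'
#' @param tree a [LinkageTree-class].
#' @return an object of class `hclust` usable with [stats::cophenetic()],
#'   [stats::cutree()] and plotting.
#' @export
asHclust <- function(tree) {
  structure(list(merge = tree@merge, height = tree@height,
                 order = .tree_leaves(tree, nrow(tree@merge)),
                 labels = tree@labels, method = "average",
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' Serialise a LinkageTree to Newick
#'
#' @param tree a [LinkageTree-class].
#' @return single Newick string (ultrametric edge lengths from the merge
#'   heights).
#' @export
toNewick <- function(tree) {
  ape::write.tree(ape::as.phylo(asHclust(tree)))
}

#' Merge table of a LinkageTree
#'
#' @param tree a [LinkageTree-class].
#' @return data.frame with columns `member_a`, `member_b` (leaf labels or
#'   `#k` for the cluster formed at merge k) and `height`.
#' @export
mergeTable <- function(tree) {
  fmt <- function(v) vapply(v, function(e)
    if (e < 0) tree@labels[-e] else paste0("#", e), "")
  data.frame(member_a = fmt(tree@merge[, 1L]),
             member_b = fmt(tree@merge[, 2L]),
             height = tree@height, stringsAsFactors = FALSE)
}

#' First merge partner of a leaf
#'
#' Returns the labels of the leaves in the cluster that the query leaf first
#' joins — the basis for grouping assertions such as "the treated sample
#' groups with the reference, not with the disease line".
#'
#' @param tree a [LinkageTree-class].
#' @param leaf a leaf label present in the tree.
#' @return character vector of partner leaf labels.
#' @export
firstMergePartner <- function(tree, leaf) {
  idx <- match(leaf, tree@labels)
  if (is.na(idx))
    prn_stop("prn_lookup_error", "leaf '%s' is not in the tree", leaf)
  for (step in seq_len(nrow(tree@merge))) {
    row <- tree@merge[step, ]
    under <- lapply(row, function(node)
      if (node < 0L) -node else .tree_leaves(tree, node))
    hit <- vapply(under, function(lv) idx %in% lv, TRUE)
    if (any(hit)) {
      partner <- under[[which(!hit)[1L]]]
      return(tree@labels[partner])
    }
  }
  prn_stop("prn_lookup_error", "leaf '%s' never merges", leaf)  # unreachable
}
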