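#' Pearson correlation distance
#'
#' Pairwise distance d = 1 - r between the rows of a matrix, r the Pearson
#' correlation; d lies in \[0, 2\], is 0 on the diagonal, and is invariant
#' to positive affine transforms of any row. Zero-variance rows cannot be
#' correlated and are excluded with a warning.
#'
#' @param x Numeric matrix (rows = items to cluster, e.g. probes over
#'   condition means; transpose to cluster samples).
#' @return Symmetric distance matrix over the retained rows.
#' @export
pearson_distance <- function(x) {
  v <- apply(x, 1, stats::var)
  keep <- !is.na(v) & v > 0
  if (any(!keep)) {
    warning("excluding zero-variance row(s): ",
            paste(rownames(x)[!keep], collapse = ", "))
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("need at least two rows with variance > 0")
  d <- 1 - stats::cor(t(x))
  diag(d) <- 0
  d
}

#' Unweighted average-linkage (UPGMA) clustering
#'
#' Agglomerates items from a distance matrix; the distance between two
#' clusters is the unweighted average of all cross-pair distances
#' (Lance-Williams update with size weights). Ties in the merge distance
#' are broken deterministically by the smallest pair of leaf indices, so
#' repeated runs give identical trees. The result is an `hclust` object
#' (merge/height/order/labels), convertible to a dendrogram or, via
#' `linkage_newick()`, to Newick.
#'
#' @param d Symmetric numeric matrix with zero diagonal (as from
#'   `pearson_distance()`), or a `dist` object.
#' @return An object of class `hclust`.
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 2) stop("need at least two items")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active cluster bookkeeping: id < 0 = leaf -row, id > 0 = merge row
  active <- seq_len(n)            # indices into d / size / id
  id <- -seq_len(n)
  minleaf <- seq_len(n)           # smallest original leaf index, for ties
  size <- rep(1L, n)
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- dm[active[i], active[j]]
      if (dij < best_d - 1e-12) {
        best_d <- dij; best <- c(i, j)
      } else if (abs(dij - best_d) <= 1e-12) {
        cand <- sort(c(minleaf[active[i]], minleaf[active[j]]))
        cur <- sort(c(minleaf[active[best[1]]], minleaf[active[best[2]]]))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
          best_d <- dij; best <- c(i, j)
        }
      }
    }
    a <- active[best[1]]; b <- active[best[2]]
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- best_d
    # unweighted average update into slot a
    others <- setdiff(active, c(a, b))
    dm[a, others] <- dm[others, a] <-
      (size[a] * dm[a, others] + size[b] * dm[b, others]) / (size[a] + size[b])
    size[a] <- size[a] + size[b]
    minleaf[a] <- min(minleaf[a], minleaf[b])
    id[a] <- step
    active <- setdiff(active, b)
  }

  order <- tree_leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 call = match.call(), dist.method = "pearson"),
            class = "hclust")
}

# leaf order by left-to-right traversal of the merge tree
tree_leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' Serialize a linkage tree as Newick
#'
#' Converts the tree to a phylogeny (branch lengths derived from merge
#' height differences) and writes standard Newick.
#'
#' @param tree An `hclust` object.
#' @param path Optional file path; when NULL the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
linkage_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Co-expression neighbour query
#'
#' Probes whose condition profiles correlate with a reference profile at
#' or above a Pearson threshold, sorted by descending r. When the
#' reference is given as a probe id present in the matrix, that probe is
#' excluded from its own neighbour list.
#'
#' @param reference A probe id (character scalar) or a numeric profile on
#'   the same condition axis as `profiles`.
#' @param profiles Numeric matrix, probes x conditions (e.g. from
#'   `condition_means()`).
#' @param threshold Pearson r threshold; default 0.8.
#' @return data.frame with columns `probe_id`, `r`.
#' @export
coexpression_query <- function(reference, profiles, threshold = 0.8) {
  if (is.character(reference)) {
    if (!reference %in% rownames(profiles))
      stop("reference probe not in matrix: ", reference)
    ref_profile <- profiles[reference, ]
    profiles <- profiles[setdiff(rownames(profiles), reference), , drop = FALSE]
  } else {
    ref_profile <- reference
    if (length(ref_profile) != ncol(profiles))
      stop("reference profile length does not match the condition axis")
  }
  r <- as.vector(stats::cor(ref_profile, t(profiles)))
  keep <- !is.na(r) & r >= threshold
  out <- data.frame(probe_id = rownames(profiles)[keep], r = r[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$r, out$probe_id), , drop = FALSE]
}
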