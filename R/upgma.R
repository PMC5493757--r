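#' Group-average (UPGMA) agglomeration on a similarity matrix
#'
#' Agglomerates contigs by repeatedly merging the pair of clusters with the
#' highest mean cross-pair Pearson similarity (unweighted group average).
#' Internally this is run as average-linkage clustering on the distance
#' `d = 1 - r`, which is exactly equivalent; merge heights are reported on
#' the similarity scale (`1 - d`) and are non-increasing from the first
#' merge to the root.
#'
#' @param S a `vh_similarity` object or a symmetric similarity matrix with
#'   dimnames.
#' @return an object of class `vh_tree`: list with `hc` (the underlying
#'   `hclust`), `labels`, `sim_height` (similarity at each merge) and
#'   `members` (list of member label vectors per internal node).
#' @export
upgma_cluster <- function(S) {
  if (inherits(S, "vh_similarity")) S <- S$S
  S <- as.matrix(S)
  if (nrow(S) < 2) stopf("clustering needs at least 2 objects")
  if (is.null(rownames(S))) stopf("similarity matrix must have dimnames")
  if (any(is.na(S))) {
    idx <- which(is.na(S) & upper.tri(S), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(k)
      paste(rownames(S)[k[1]], colnames(S)[k[2]], sep = "~"))
    stopf("missing similarities for pair(s): %s",
          paste(pairs, collapse = ", "))
  }
  hc <- hclust(as.dist(1 - S), method = "average")
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    get_side <- function(v)
      if (v < 0) hc$labels[-v] else members[[v]]
    members[[k]] <- c(get_side(hc$merge[k, 1]), get_side(hc$merge[k, 2]))
  }
  structure(list(hc = hc, labels = hc$labels, sim_height = 1 - hc$height,
                 members = members),
            class = "vh_tree")
}

#' Export a dendrogram as Newick
#'
#' Branch depths encode `1 - r` so standard tree viewers display the
#' similarity structure.
#'
#' @param tree a `vh_tree` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "vh_tree"))
  ape::write.tree(ape::as.phylo(tree$hc), file = path)
  invisible(path)
}

#' @export
print.vh_tree <- function(x, ...) {
  cat(sprintf("vh_tree: UPGMA dendrogram over %d contigs\n",
              length(x$labels)))
  cat(sprintf("  merge similarities: %.3f (first) .. %.3f (root)\n",
              x$sim_height[1], x$sim_height[length(x$sim_height)]))
  invisible(x)
}
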