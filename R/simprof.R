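#' Ordered similarity profile of a group
#'
#' The SIMPROF test statistic is built on the group's similarity profile:
#' all `m(m-1)/2` pairwise Pearson correlations between member expression
#' profiles, sorted ascending. Members with zero-variance profiles are
#' excluded with a warning before profiling.
#'
#' @param x numeric matrix, group members in rows, samples in columns
#'   (m >= 2).
#' @return numeric vector of sorted pairwise correlations.
#' @export
similarity_profile <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("similarity profile needs at least 2 members")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("excluding %d zero-variance member(s) from the profile",
          sum(sds == 0))
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stopf("fewer than 2 non-constant members remain")
  }
  S <- cor(t(x))
  sort(S[upper.tri(S)])
}

#' SIMPROF test of multivariate structure within one group
#'
#' Tests whether a group of contigs shows more internal similarity structure
#' than expected if expression values were exchangeable across contigs
#' within each sample. The observed ordered similarity profile is compared
#' to the mean profile of `B1` within-sample permutations; the departure is
#' summarized as the pi statistic (summed absolute deviation), whose null
#' distribution comes from `B2` further permutations. The p-value uses the
#' add-one estimator `(1 + #\{pi_perm >= pi_obs\}) / (1 + B2)` and can never
#' be exactly zero.
#'
#' Groups of fewer than 3 members are returned untested (`tested = FALSE`,
#' not significant): a one-element similarity profile has no dispersion to
#' test.
#'
#' @param x numeric matrix, group members in rows, samples in columns.
#' @param B1 permutations for the mean profile (default 1000).
#' @param B2 permutations for the pi null (default 999).
#' @param seed RNG seed for the permutation stream.
#' @param alpha significance level (default 0.05); significance is declared
#'   at `p < alpha`.
#' @return an object of class `vh_simprof`: list with `size`, `tested`,
#'   `pi`, `p_value`, `significant`, `obs_profile`, `mean_profile`,
#'   `perm_pi`.
#' @export
simprof_single <- function(x, B1 = 1000L, B2 = 999L, seed = NULL,
                           alpha = 0.05) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < 3) {
    return(structure(list(size = m, tested = FALSE, pi = NA_real_,
                          p_value = NA_real_, significant = FALSE,
                          obs_profile = NULL, mean_profile = NULL,
                          perm_pi = NULL),
                     class = "vh_simprof"))
  }
  if (B1 < 99 || B2 < 99)
    stopf("at least 99 permutations are required (B1=%d, B2=%d)", B1, B2)
  set_seed_if(seed)
  k <- simprof_kernel(x, as.integer(B1), as.integer(B2))
  p <- (1 + sum(k$perm_pi >= k$pi_obs)) / (1 + B2)
  structure(list(size = m, tested = TRUE, pi = k$pi_obs, p_value = p,
                 significant = p < alpha, obs_profile = k$obs_profile,
                 mean_profile = k$mean_profile, perm_pi = k$perm_pi),
            class = "vh_simprof")
}

#' @export
print.vh_simprof <- function(x, ...) {
  if (!x$tested) {
    cat(sprintf("SIMPROF: group of %d, untested (size < 3)\n", x$size))
  } else {
    cat(sprintf("SIMPROF: group of %d, pi = %.4f, p = %.4g (%s)\n",
                x$size, x$pi, x$p_value,
                if (x$significant) "significant structure"
                else "homogeneous"))
  }
  invisible(x)
}

#' Recursive SIMPROF delimitation of statistically distinct clusters
#'
#' Walks the UPGMA dendrogram from the root: each node is SIMPROF-tested;
#' a significant node's children are tested in turn, while a non-significant
#' (or untestable, size < 3) node is emitted as one homogeneous cluster.
#' The maximal non-significant subtrees therefore partition all clustered
#' contigs into statistically distinct clusters.
#'
#' Each node's permutation seed is derived by stable hashing of its sorted
#' member ids together with `config$rng_seed`, so the clustering is
#' reproducible and independent of contig input order.
#'
#' @param tree a `vh_tree` from [upgma_cluster()].
#' @param rck a `vh_rck` object covering the tree's contigs.
#' @param config a `vh_config` supplying alpha, permutation counts, the log
#'   transform and the base seed.
#' @return an object of class `vh_clusters`: list with `assignments`
#'   (data.frame `contig_id`, `cluster`), `nodes` (per-node data.frame:
#'   `node`, `size`, `pi`, `p_value`, `tested`, `significant`) and `alpha`.
#' @export
simprof_recursive <- function(tree, rck, config = pipeline_config()) {
  stopifnot(inherits(tree, "vh_tree"), inherits(rck, "vh_rck"))
  x <- rck$rck
  if (config$log_transform) x <- log10(x + config$pseudocount)
  missing_ids <- setdiff(tree$labels, rownames(x))
  if (length(missing_ids) > 0)
    stopf("tree contig(s) absent from RCK matrix: %s",
          paste(missing_ids, collapse = ", "))

  merge <- tree$hc$merge
  nodes <- list()
  assign_env <- new.env(parent = emptyenv())
  assign_env$clusters <- list()

  node_label <- function(v) if (v < 0) paste0("leaf:", tree$labels[-v])
                            else paste0("node:", v)
  node_members <- function(v) if (v < 0) tree$labels[-v]
                              else tree$members[[v]]

  emit_cluster <- function(ids) {
    assign_env$clusters[[length(assign_env$clusters) + 1L]] <- ids
  }

  visit <- function(v) {
    ids <- node_members(v)
    if (length(ids) < 3) {
      nodes[[length(nodes) + 1L]] <<- data.frame(
        node = node_label(v), size = length(ids), pi = NA_real_,
        p_value = NA_real_, tested = FALSE, significant = FALSE,
        stringsAsFactors = FALSE)
      emit_cluster(ids)
      return(invisible(NULL))
    }
    res <- simprof_single(x[ids, , drop = FALSE],
                          B1 = config$n_perm_mean, B2 = config$n_perm_null,
                          seed = derive_seed(ids, config$rng_seed),
                          alpha = config$simprof_alpha)
    nodes[[length(nodes) + 1L]] <<- data.frame(
      node = node_label(v), size = res$size, pi = res$pi,
      p_value = res$p_value, tested = res$tested,
      significant = res$significant, stringsAsFactors = FALSE)
    if (res$significant && v > 0) {
      visit(merge[v, 1])
      visit(merge[v, 2])
    } else {
      emit_cluster(ids)
    }
    invisible(NULL)
  }

  root <- nrow(merge)
  if (root == 0) {
    # single-contig tree cannot arise from hclust; guard anyway
    emit_cluster(tree$labels)
  } else {
    visit(root)
  }

  clusters <- assign_env$clusters
  # stable cluster ids: order clusters by their lexicographically smallest
  # member so the labelling is independent of traversal order
  ord <- order(vapply(clusters, function(ids) min(ids), character(1)))
  clusters <- clusters[ord]
  assignments <- data.frame(
    contig_id = unlist(clusters),
    cluster = rep(sprintf("C%02d", seq_along(clusters)),
                  lengths(clusters)),
    stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  structure(list(assignments = assignments,
                 nodes = do.call(rbind, nodes),
                 alpha = config$simprof_alpha),
            class = "vh_clusters")
}

#' @export
print.vh_clusters <- function(x, ...) {
  cat(sprintf("vh_clusters: %d contigs in %d statistically distinct clusters (alpha = %g)\n",
              nrow(x$assignments), length(unique(x$assignments$cluster)),
              x$alpha))
  invisible(x)
}

#' Write SIMPROF node results and cluster assignments to TSV
#'
#' @param clusters a `vh_clusters` object.
#' @param nodes_path output path for the per-node results TSV.
#' @param clusters_path output path for the assignments TSV.
#' @return invisibly, a character vector of the written paths.
#' @export
write_simprof <- function(clusters, nodes_path, clusters_path) {
  stopifnot(inherits(clusters, "vh_clusters"))
  write.table(clusters$nodes, nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(clusters$assignments, clusters_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(nodes_path, clusters_path))
}
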