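#' Extract clusters containing both viral and eukaryotic markers
#'
#' Candidate virus-host associations live in statistically distinct clusters
#' that contain at least one viral marker contig (MCP, RdRP or REP) and at
#' least one eukaryotic marker contig (RPB1); clusters of a single domain
#' are discarded.
#'
#' @param clusters a `vh_clusters` object (or its `assignments` data.frame).
#' @param annotations contig annotation `data.frame`.
#' @return data.frame of assignments restricted to mixed clusters (possibly
#'   zero rows).
#' @export
extract_mixed_clusters <- function(clusters, annotations) {
  asg <- if (inherits(clusters, "vh_clusters")) clusters$assignments
         else clusters
  if (nrow(asg) == 0) return(asg)
  idx <- match(asg$contig_id, annotations$contig_id)
  if (anyNA(idx))
    stopf("cluster contig(s) absent from annotations: %s",
          paste(asg$contig_id[is.na(idx)], collapse = ", "))
  dom <- annotations$domain_class[idx]
  has_virus <- tapply(dom == "VIRUS", asg$cluster, any)
  has_euk <- tapply(dom == "EUKARYOTE", asg$cluster, any)
  mixed <- names(has_virus)[has_virus & has_euk]
  out <- asg[asg$cluster %in% mixed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the significance-filtered virus-host correlation network
#'
#' Nodes are the members of mixed (virus + eukaryote) SIMPROF clusters;
#' candidate edges are all within-cluster contig pairs, retained when the
#' two-sided t-test p-value of their Pearson correlation is at or below
#' `config$edge_alpha` (default `P <= 0.1`). Edges never cross cluster
#' boundaries. Significant negative correlations are retained but flagged
#' (`positive = FALSE`); set `config$positive_edges_only` to drop them,
#' reflecting the expectation that a virus replicating inside its host shows
#' a strong positive expression correlation.
#'
#' @param clusters a `vh_clusters` object.
#' @param sim a `vh_similarity` object (supplies r and the sample count).
#' @param annotations contig annotation `data.frame`.
#' @param config a `vh_config`.
#' @return an object of class `vh_network`: list with `nodes` (annotated
#'   node table), `edges` (source, target, r, p, cluster, positive) and
#'   `graph` (an `igraph` object). Empty when no mixed clusters exist (with
#'   a warning).
#' @export
build_network <- function(clusters, sim, annotations,
                          config = pipeline_config()) {
  stopifnot(inherits(sim, "vh_similarity"))
  mixed <- extract_mixed_clusters(clusters, annotations)
  empty_nodes <- data.frame(contig_id = character(), cluster = character(),
                            length_bp = integer(), marker = character(),
                            domain_class = character(),
                            taxon_label = character(),
                            stringsAsFactors = FALSE)
  empty_edges <- data.frame(source = character(), target = character(),
                            r = numeric(), p = numeric(),
                            cluster = character(), positive = logical(),
                            stringsAsFactors = FALSE)
  if (nrow(mixed) == 0) {
    warnf("no statistically distinct cluster contains both viral and eukaryotic contigs; returning an empty network")
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(structure(list(nodes = empty_nodes, edges = empty_edges,
                          graph = g), class = "vh_network"))
  }
  missing_sim <- setdiff(mixed$contig_id, rownames(sim$S))
  if (length(missing_sim) > 0)
    stopf("mixed-cluster contig(s) absent from similarity matrix: %s",
          paste(missing_sim, collapse = ", "))
  nodes <- merge(mixed, annotations, by = "contig_id", sort = FALSE)
  nodes <- nodes[order(nodes$cluster, nodes$contig_id), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- empty_edges
  for (cl in unique(mixed$cluster)) {
    ids <- sort(mixed$contig_id[mixed$cluster == cl])
    if (length(ids) < 2) next
    pr <- t(combn(ids, 2))
    r <- sim$S[cbind(pr[, 1], pr[, 2])]
    p <- correlation_p(r, sim$n_samples)
    keep <- p <= config$edge_alpha
    if (config$positive_edges_only) keep <- keep & r > 0
    if (!any(keep)) next
    edges <- rbind(edges, data.frame(
      source = pr[keep, 1], target = pr[keep, 2], r = r[keep], p = p[keep],
      cluster = cl, positive = r[keep] > 0, stringsAsFactors = FALSE))
  }
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "r", "p", "cluster", "positive")],
    directed = FALSE,
    vertices = nodes[, c("contig_id", "cluster", "length_bp", "marker",
                         "domain_class", "taxon_label")])
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "vh_network")
}

#' @export
print.vh_network <- function(x, ...) {
  cat(sprintf("vh_network: %d nodes, %d edges in %d mixed cluster(s)\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$cluster))))
  invisible(x)
}

#' Export a network as GraphML and/or TSV tables
#'
#' GraphML is importable by Cytoscape and other standard graph viewers; the
#' TSV export writes an edge list (source, target, r, p, cluster) and a node
#' table with annotations.
#'
#' @param network a `vh_network` object.
#' @param dir output directory (created if needed).
#' @param formats any of `"graphml"`, `"tsv"`.
#' @param prefix filename prefix (default `"network"`).
#' @return invisibly, a character vector of written paths.
#' @export
export_graph <- function(network, dir, formats = c("graphml", "tsv"),
                         prefix = "network") {
  stopifnot(inherits(network, "vh_network"))
  bad <- setdiff(formats, c("graphml", "tsv"))
  if (length(bad) > 0)
    stopf("unsupported export format(s): %s", paste(bad, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if ("graphml" %in% formats) {
    p <- file.path(dir, paste0(prefix, ".graphml"))
    igraph::write_graph(network$graph, p, format = "graphml")
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    pe <- file.path(dir, paste0(prefix, "_edges.tsv"))
    pn <- file.path(dir, paste0(prefix, "_nodes.tsv"))
    write.table(network$edges, pe, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(network$nodes, pn, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, pe, pn)
  }
  invisible(paths)
}
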