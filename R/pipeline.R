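#' Run the full virus-host linkage pipeline
#'
#' Orchestrates every stage in order — contig length filter, rarefaction and
#' RCK normalization, Pearson similarity, UPGMA clustering, recursive
#' SIMPROF delimitation, mixed-cluster network extraction, and viral
#' temporal-dynamics classification — writing each stage's output and a run
#' manifest under one directory. A stage failure halts the run with an error
#' naming the stage.
#'
#' @param counts path to the counts TSV, or a ready `vh_counts` object.
#' @param samples path to the samples TSV (ignored when `counts` is a
#'   `vh_counts`).
#' @param annotations path to the annotation TSV, or an annotation
#'   data.frame (ignored when `counts` is a `vh_counts`).
#' @param config a `vh_config` object or path to a YAML config.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with every stage result (`counts`, `rck`,
#'   `similarity`, `tree`, `clusters`, `network`, `dynamics`) and the
#'   `manifest` (also written as `manifest.json`).
#' @export
run_pipeline <- function(counts, samples = NULL, annotations = NULL,
                         config = pipeline_config(), outdir,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "vh_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    say("[%s] done in %.2fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  input_digests <- NULL
  if (inherits(counts, "vh_counts")) {
    cm <- counts
  } else {
    for (p in c(counts, samples,
                if (is.character(annotations)) annotations)) {
      if (!file.exists(p)) stopf("input file not found: %s", p)
    }
    input_digests <- as.list(tools::md5sum(
      c(counts, samples, if (is.character(annotations)) annotations)))
    cm <- stage("read", read_count_matrix(counts, samples, annotations))
  }

  cm_f <- stage("filter", filter_contigs(cm, config))
  say("[filter] %d of %d contigs retained (>= %d bp)",
      nrow(cm_f$counts), nrow(cm$counts), config$min_contig_length_bp)
  rck <- stage("normalize", rck_normalize(cm_f, config))
  sim <- stage("similarity", pearson_similarity(rck, config))
  tree <- stage("cluster", upgma_cluster(sim))
  clusters <- stage("simprof", simprof_recursive(tree, rck, config))
  say("[simprof] %d statistically distinct clusters",
      length(unique(clusters$assignments$cluster)))
  network <- stage("network",
                   build_network(clusters, sim, cm_f$contigs, config))
  say("[network] %d mixed clusters, %d edges retained",
      length(unique(network$nodes$cluster)), nrow(network$edges))
  dynamics <- stage("dynamics", dynamics_report(rck, cm_f$contigs, config))

  # stage outputs
  write_count_matrix(cm_f, file.path(outdir, "counts_filtered.tsv"))
  write_rck(rck, file.path(outdir, "rck.tsv"))
  write_similarity(sim, file.path(outdir, "similarity.tsv"))
  write_tree_newick(tree, file.path(outdir, "dendrogram.nwk"))
  write_simprof(clusters, file.path(outdir, "simprof_nodes.tsv"),
                file.path(outdir, "clusters.tsv"))
  export_graph(network, outdir)
  dyn <- dynamics
  dyn$fold_range <- format(dyn$fold_range, digits = 6)
  write.table(dyn, file.path(outdir, "dynamics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_config(config, file.path(outdir, "config.yaml"))

  manifest <- list(
    tool = "vhlink",
    version = as.character(utils::packageVersion("vhlink")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$rng_seed,
    config = unclass(config),
    input_digests = input_digests,
    n_contigs_input = nrow(cm$counts),
    n_contigs_filtered = nrow(cm_f$counts),
    n_samples = ncol(cm_f$counts),
    sample_set = cm_f$samples$sample_id,
    n_clusters = length(unique(clusters$assignments$cluster)),
    n_mixed_clusters = length(unique(network$nodes$cluster)),
    n_edges = nrow(network$edges),
    outputs = list(
      counts_filtered = "counts_filtered.tsv", rck = "rck.tsv",
      similarity = "similarity.tsv", dendrogram = "dendrogram.nwk",
      simprof_nodes = "simprof_nodes.tsv", clusters = "clusters.tsv",
      network_graphml = "network.graphml",
      network_edges = "network_edges.tsv",
      network_nodes = "network_nodes.tsv",
      dynamics = "dynamics.tsv", config = "config.yaml"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = cm_f, rck = rck, similarity = sim, tree = tree,
                 clusters = clusters, network = network,
                 dynamics = dynamics, manifest = manifest))
}
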