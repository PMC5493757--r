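mixed_fixture <- function() {
  ann <- data.frame(
    contig_id = c("v1", "v2", "e1", "e2", "v3"),
    length_bp = 1000L,
    marker = c("MCP", "RdRP", "RPB1", "RPB1", "REP"),
    domain_class = c("VIRUS", "VIRUS", "EUKARYOTE", "EUKARYOTE", "VIRUS"),
    taxon_label = c("Mimiviridae", "Picornavirales", "pelagophyte",
                    "diatom", "ssDNA virus"),
    stringsAsFactors = FALSE)
  asg <- data.frame(
    contig_id = c("v1", "e1", "e2", "v2", "v3"),
    cluster = c("C01", "C01", "C01", "C02", "C02"),
    stringsAsFactors = FALSE)
  list(ann = ann, asg = asg)
}

test_that("only clusters with both domains are retained", {
  fx <- mixed_fixture()
  out <- extract_mixed_clusters(fx$asg, fx$ann)
  # C02 is virus-only and must vanish
  expect_setequal(unique(out$cluster), "C01")
  expect_setequal(out$contig_id, c("v1", "e1", "e2"))

  # a lone MCP/RPB1 pair is the canonical retained cluster
  pair <- data.frame(contig_id = c("v1", "e1"), cluster = "P",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(extract_mixed_clusters(pair, fx$ann)), 2)

  empty <- fx$asg[0, ]
  expect_equal(nrow(extract_mixed_clusters(empty, fx$ann)), 0)
})

test_that("edges respect the significance threshold and cluster boundaries", {
  fx <- mixed_fixture()
  ids <- c("v1", "v2", "e1", "e2", "v3")
  S <- diag(5)
  dimnames(S) <- list(ids, ids)
  # within C01: v1~e1 strong, v1~e2 weak, e1~e2 moderate
  S["v1", "e1"] <- S["e1", "v1"] <- 0.99
  S["v1", "e2"] <- S["e2", "v1"] <- 0.10
  S["e1", "e2"] <- S["e2", "e1"] <- 0.80
  S["v2", "v3"] <- S["v3", "v2"] <- 0.999
  sim <- structure(list(S = S, ids = ids, n_samples = 8, dropped = character()),
                   class = "vh_similarity")
  clusters <- structure(list(assignments = fx$asg, nodes = NULL, alpha = 0.05),
                        class = "vh_clusters")
  net <- build_network(clusters, sim, fx$ann)

  key <- paste(pmin(net$edges$source, net$edges$target),
               pmax(net$edges$source, net$edges$target))
  expect_true("e1 v1" %in% key)
  expect_true("e1 e2" %in% key)                 # p(0.8, 8) < 0.1
  expect_false("e2 v1" %in% key)                # p(0.1, 8) >> 0.1
  expect_false("v2 v3" %in% key)                # virus-only cluster dropped
  expect_true(all(net$edges$p <= 0.1))
  # endpoints always share a cluster
  cl <- setNames(fx$asg$cluster, fx$asg$contig_id)
  expect_true(all(cl[net$edges$source] == cl[net$edges$target]))
  # every reported cluster keeps both domains
  dom <- setNames(fx$ann$domain_class, fx$ann$contig_id)
  for (cc in unique(net$nodes$cluster)) {
    d <- dom[net$nodes$contig_id[net$nodes$cluster == cc]]
    expect_setequal(unique(d), c("VIRUS", "EUKARYOTE"))
  }
})

test_that("perfect within-cluster correlation gives a complete subgraph", {
  fx <- mixed_fixture()
  asg <- fx$asg[fx$asg$cluster == "C01", ]
  ids <- asg$contig_id
  S <- matrix(1, 3, 3, dimnames = list(ids, ids))
  sim <- structure(list(S = S, ids = ids, n_samples = 8, dropped = character()),
                   class = "vh_similarity")
  net <- build_network(structure(list(assignments = asg), class = "vh_clusters"),
                       sim, fx$ann)
  expect_equal(nrow(net$edges), choose(3, 2))
})

test_that("negative correlations are flagged and optionally dropped", {
  fx <- mixed_fixture()
  asg <- fx$asg[fx$asg$cluster == "C01", ]
  ids <- asg$contig_id
  S <- matrix(0.99, 3, 3, dimnames = list(ids, ids))
  S["e1", "e2"] <- S["e2", "e1"] <- -0.99
  diag(S) <- 1
  sim <- structure(list(S = S, ids = ids, n_samples = 8, dropped = character()),
                   class = "vh_similarity")
  clusters <- structure(list(assignments = asg), class = "vh_clusters")
  net <- build_network(clusters, sim, fx$ann)
  neg <- net$edges[!net$edges$positive, ]
  expect_equal(nrow(neg), 1)
  net_pos <- build_network(clusters, sim, fx$ann,
                           pipeline_config(positive_edges_only = TRUE))
  expect_true(all(net_pos$edges$r > 0))
})

test_that("a run without mixed clusters warns and returns an empty network", {
  fx <- mixed_fixture()
  asg <- fx$asg[fx$asg$cluster == "C02", ]  # virus-only
  sim <- structure(list(S = diag(2), ids = asg$contig_id, n_samples = 8,
                        dropped = character()), class = "vh_similarity")
  expect_warning(
    net <- build_network(structure(list(assignments = asg),
                                   class = "vh_clusters"), sim, fx$ann),
    "empty network")
  expect_equal(nrow(net$edges), 0)
  expect_equal(igraph::vcount(net$graph), 0)
})

test_that("GraphML and TSV exports round-trip the graph", {
  fx <- mixed_fixture()
  asg <- fx$asg[fx$asg$cluster == "C01", ]
  ids <- asg$contig_id
  S <- matrix(0.95, 3, 3, dimnames = list(ids, ids)); diag(S) <- 1
  sim <- structure(list(S = S, ids = ids, n_samples = 8, dropped = character()),
                   class = "vh_similarity")
  net <- build_network(structure(list(assignments = asg),
                                 class = "vh_clusters"), sim, fx$ann)
  d <- withr::local_tempdir()
  paths <- export_graph(net, d)
  g2 <- igraph::read_graph(file.path(d, "network.graphml"),
                           format = "graphml")
  expect_setequal(igraph::V(g2)$name, ids)
  expect_equal(igraph::ecount(g2), nrow(net$edges))
  edges_tsv <- read.delim(file.path(d, "network_edges.tsv"))
  expect_equal(nrow(edges_tsv), nrow(net$edges))

  expect_error(export_graph(net, d, formats = "dot"), "unsupported")

  # empty network still writes valid files
  empty <- suppressWarnings(build_network(
    structure(list(assignments = asg[0, ]), class = "vh_clusters"),
    sim, fx$ann))
  paths2 <- export_graph(empty, file.path(d, "empty"))
  g3 <- igraph::read_graph(file.path(d, "empty", "network.graphml"),
                           format = "graphml")
  expect_equal(igraph::ecount(g3), 0)
})
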