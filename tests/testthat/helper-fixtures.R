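# Small in-code fixtures shared across test files.

tiny_annotations <- function() {
  data.frame(
    contig_id = c("v1", "v2", "e1", "e2"),
    length_bp = c(1000L, 2000L, 500L, 4000L),
    marker = c("MCP", "RdRP", "RPB1", "RPB1"),
    domain_class = c("VIRUS", "VIRUS", "EUKARYOTE", "EUKARYOTE"),
    taxon_label = c("Mimiviridae", "Dicistroviridae", "pelagophyte",
                    "diatom"),
    stringsAsFactors = FALSE)
}

tiny_samples <- function(n = 3, insitu = n, lib = 1000) {
  data.frame(
    sample_id = paste0("S", seq_len(n)),
    site = "TS",
    order_index = seq_len(n),
    treatment = c(rep("IN_SITU", insitu), rep("AMENDMENT", n - insitu)),
    library_size = rep(lib, length.out = n),
    stringsAsFactors = FALSE)
}

tiny_counts <- function(n_samples = 3, lib = 1000) {
  ann <- tiny_annotations()
  m <- matrix(c(10, 20, 30,
                5, 0, 15,
                40, 10, 25,
                8, 16, 24)[seq_len(4 * min(n_samples, 3))],
              nrow = 4, ncol = 3, byrow = TRUE,
              dimnames = list(ann$contig_id, paste0("S", 1:3)))
  m <- m[, seq_len(n_samples), drop = FALSE]
  count_matrix(m, ann, tiny_samples(n_samples, lib = lib))
}

# a vh_rck object built directly from a matrix (for dynamics/simprof tests)
make_rck <- function(m, samples = NULL, lengths_bp = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("c", seq_len(nrow(m)))
  samples <- samples %||% tiny_samples(ncol(m))
  if (is.null(colnames(m))) colnames(m) <- samples$sample_id
  contigs <- data.frame(
    contig_id = rownames(m),
    length_bp = lengths_bp %||% rep(1000L, nrow(m)),
    marker = "OTHER",
    domain_class = "VIRUS",
    taxon_label = "x",
    stringsAsFactors = FALSE)
  structure(list(rck = m, contigs = contigs, samples = samples,
                 depth = 1000, mode = "expected"),
            class = c("vh_rck"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rck built from in-situ series rows, optionally padded with flat
# amendment columns
dyn_rck <- function(..., n_amend = 0) {
  m <- do.call(rbind, list(...))
  n <- ncol(m)
  samples <- tiny_samples(n + n_amend, insitu = n)
  if (n_amend > 0) m <- cbind(m, matrix(1, nrow(m), n_amend))
  colnames(m) <- samples$sample_id
  make_rck(m, samples = samples)
}
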