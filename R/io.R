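# Marker scheme: MCP marks dsDNA giant viruses (NCLDVs), RdRP marks RNA
# viruses, REP (viral replicase) marks ssDNA viruses; RPB1 (RNA polymerase II
# large subunit) is the functional eukaryotic marker in poly-A selected data.
MARKER_LEVELS <- c("MCP", "RdRP", "REP", "RPB1", "OTHER")
DOMAIN_LEVELS <- c("VIRUS", "EUKARYOTE")
VIRAL_MARKERS <- c("MCP", "RdRP", "REP")

canonical_marker <- function(x) {
  idx <- match(toupper(x), toupper(MARKER_LEVELS))
  MARKER_LEVELS[idx]
}

validate_annotations <- function(ann) {
  req <- c("contig_id", "length_bp", "marker", "domain_class", "taxon_label")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0)
    stopf("annotation table is missing column(s): %s",
          paste(miss, collapse = ", "))
  ann <- ann[req]
  ann$contig_id <- as.character(ann$contig_id)
  dup <- ann$contig_id[duplicated(ann$contig_id)]
  if (length(dup) > 0)
    stopf("duplicate contig_id(s): %s", paste(unique(dup), collapse = ", "))
  len <- suppressWarnings(as.numeric(ann$length_bp))
  bad <- which(is.na(len) | len < 1 | len != round(len))
  if (length(bad) > 0)
    stopf("length_bp must be a positive integer; offending row(s): %s",
          paste(bad, collapse = ", "))
  ann$length_bp <- as.integer(len)
  mk <- canonical_marker(ann$marker)
  bad <- which(is.na(mk))
  if (length(bad) > 0)
    stopf("unknown marker (expected %s); offending row(s): %s",
          paste(MARKER_LEVELS, collapse = "/"), paste(bad, collapse = ", "))
  ann$marker <- mk
  dc <- toupper(as.character(ann$domain_class))
  bad <- which(!dc %in% DOMAIN_LEVELS)
  if (length(bad) > 0)
    stopf("unknown domain_class (expected VIRUS/EUKARYOTE); row(s): %s",
          paste(bad, collapse = ", "))
  ann$domain_class <- dc
  bad <- which(ann$marker %in% VIRAL_MARKERS & ann$domain_class != "VIRUS")
  if (length(bad) > 0)
    stopf("marker %s implies domain_class VIRUS; offending row(s): %s",
          paste(unique(ann$marker[bad]), collapse = "/"),
          paste(bad, collapse = ", "))
  bad <- which(ann$marker == "RPB1" & ann$domain_class != "EUKARYOTE")
  if (length(bad) > 0)
    stopf("marker RPB1 implies domain_class EUKARYOTE; offending row(s): %s",
          paste(bad, collapse = ", "))
  ann$taxon_label <- as.character(ann$taxon_label)
  ann
}

#' Read a contig annotation table
#'
#' Expects a UTF-8 tab-delimited file with header columns `contig_id`,
#' `length_bp`, `marker` (MCP/RdRP/REP/RPB1/OTHER), `domain_class`
#' (VIRUS/EUKARYOTE) and `taxon_label`. The marker scheme encodes which gene
#' identified each contig: MCP for giant (NCLDV) dsDNA viruses, RdRP for RNA
#' viruses, REP (replicase) for ssDNA viruses, and RPB1 for eukaryotes.
#' Rows violating the marker/domain consistency rules are rejected with the
#' offending row number.
#'
#' @param path path to the annotation TSV.
#' @return a validated `data.frame` of contig annotations.
#' @export
read_contig_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  ann <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
  validate_annotations(ann)
}

validate_samples <- function(si) {
  req <- c("sample_id", "site", "order_index", "treatment", "library_size")
  miss <- setdiff(req, names(si))
  if (length(miss) > 0)
    stopf("sample table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!"label" %in% names(si)) si$label <- si$sample_id
  si <- si[c(req, "label")]
  si$sample_id <- as.character(si$sample_id)
  dup <- si$sample_id[duplicated(si$sample_id)]
  if (length(dup) > 0)
    stopf("duplicate sample_id(s): %s", paste(unique(dup), collapse = ", "))
  tr <- toupper(as.character(si$treatment))
  bad <- which(!tr %in% c("IN_SITU", "AMENDMENT"))
  if (length(bad) > 0)
    stopf("treatment must be IN_SITU or AMENDMENT; offending row(s): %s",
          paste(bad, collapse = ", "))
  si$treatment <- tr
  oi <- suppressWarnings(as.numeric(si$order_index))
  if (any(is.na(oi) | oi < 0 | oi != round(oi)))
    stopf("order_index must be a non-negative integer")
  si$order_index <- as.integer(oi)
  ls <- suppressWarnings(as.numeric(si$library_size))
  if (any(is.na(ls) | ls < 1))
    stopf("library_size must be a positive integer")
  si$library_size <- ls
  si
}

#' Read a sample metadata table
#'
#' Tab-delimited with header columns `sample_id`, `site`, `order_index`
#' (temporal/ordinal position), `treatment` (`IN_SITU` or `AMENDMENT`),
#' `library_size` (total quality-trimmed fragments) and optionally `label`.
#'
#' @param path path to the samples TSV.
#' @return a validated `data.frame` of sample metadata.
#' @export
read_sample_info <- function(path) {
  if (!file.exists(path)) stopf("sample file not found: %s", path)
  si <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "", comment.char = "")
  validate_samples(si)
}

#' Construct a count matrix object
#'
#' Bundles the contigs-by-samples mapped-read-count matrix with its contig
#' annotations and sample metadata, after validating that dimensions agree,
#' counts are non-negative integers, and no sample's column total exceeds its
#' declared library size. Columns are ordered by `order_index`.
#'
#' @param counts integer matrix, contigs in rows (rownames = contig ids),
#'   samples in columns (colnames = sample ids).
#' @param contigs contig annotation `data.frame` (see
#'   [read_contig_annotations()]).
#' @param samples sample metadata `data.frame` (see [read_sample_info()]).
#' @return an object of class `vh_counts` with elements `counts`, `contigs`,
#'   `samples`.
#' @export
count_matrix <- function(counts, contigs, samples) {
  contigs <- validate_annotations(contigs)
  samples <- validate_samples(samples)
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stopf("counts must have contig ids as rownames")
  if (is.null(colnames(counts)))
    stopf("counts must have sample ids as colnames")
  if (nrow(counts) == 0) rownames(counts) <- character(0)
  missing_ann <- setdiff(rownames(counts), contigs$contig_id)
  if (length(missing_ann) > 0)
    stopf("contig(s) in counts absent from annotations: %s",
          paste(missing_ann, collapse = ", "))
  missing_si <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_si) > 0)
    stopf("sample(s) in counts absent from sample table: %s",
          paste(missing_si, collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be non-negative and finite")
  if (any(counts != round(counts)))
    stopf("counts must be integers")
  storage.mode(counts) <- "double"
  samples <- samples[samples$sample_id %in% colnames(counts), , drop = FALSE]
  samples <- samples[order(samples$order_index, samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  contigs <- contigs[match(rownames(counts), contigs$contig_id), ,
                     drop = FALSE]
  rownames(contigs) <- NULL
  counts <- counts[, samples$sample_id, drop = FALSE]
  over <- colSums(counts) > samples$library_size
  if (any(over))
    stopf("mapped counts exceed declared library_size for sample(s): %s",
          paste(samples$sample_id[over], collapse = ", "))
  structure(list(counts = counts, contigs = contigs, samples = samples),
            class = "vh_counts")
}

#' Read a count matrix with its sample metadata
#'
#' The counts TSV has contigs in rows (first column `contig_id`) and samples
#' in columns; every contig must appear in `annotations`. Columns are
#' reordered by the samples' `order_index`.
#'
#' @param path counts TSV path.
#' @param samples_path samples TSV path.
#' @param annotations contig annotation `data.frame`, or a path to an
#'   annotation TSV.
#' @return a `vh_counts` object.
#' @export
read_count_matrix <- function(path, samples_path, annotations) {
  if (!file.exists(path)) stopf("counts file not found: %s", path)
  if (is.character(annotations) && length(annotations) == 1)
    annotations <- read_contig_annotations(annotations)
  samples <- read_sample_info(samples_path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
  if (names(tab)[1] != "contig_id")
    stopf("counts TSV must have 'contig_id' as its first column")
  ids <- as.character(tab$contig_id)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (ncol(m) > 0 && !is.numeric(m)) stopf("counts must be numeric")
  rownames(m) <- ids
  count_matrix(m, annotations, samples)
}

#' Write a count matrix (and optionally metadata) back to TSV
#'
#' Output round-trips exactly through [read_count_matrix()].
#'
#' @param cm a `vh_counts` object.
#' @param counts_path output path for the counts TSV.
#' @param samples_path optional output path for the samples TSV.
#' @param annotations_path optional output path for the annotation TSV.
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path = NULL,
                               annotations_path = NULL) {
  stopifnot(inherits(cm, "vh_counts"))
  df <- data.frame(contig_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(annotations_path))
    write.table(cm$contigs, annotations_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(counts_path)
}

#' Drop short contigs before any statistics
#'
#' The statistical matrices only include contigs longer than 225 bp; the
#' default configuration keeps contigs with `length_bp >= 226`. Counts of
#' surviving contigs are untouched and row order is preserved.
#'
#' @param cm a `vh_counts` object.
#' @param config a `vh_config`; its `min_contig_length_bp` is the smallest
#'   retained length.
#' @param min_length_bp optional override of the configured threshold.
#' @return a filtered `vh_counts` object.
#' @export
filter_contigs <- function(cm, config = pipeline_config(),
                           min_length_bp = NULL) {
  stopifnot(inherits(cm, "vh_counts"))
  thr <- min_length_bp %||% config$min_contig_length_bp
  keep <- cm$contigs$length_bp >= thr
  if (!any(keep))
    stopf("no contigs remain after the %d bp length filter", thr)
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm$contigs <- cm$contigs[keep, , drop = FALSE]
  rownames(cm$contigs) <- NULL
  cm
}

#' @export
print.vh_counts <- function(x, ...) {
  cat(sprintf("vh_counts: %d contigs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  viruses: %d  eukaryotes: %d\n",
              sum(x$contigs$domain_class == "VIRUS"),
              sum(x$contigs$domain_class == "EUKARYOTE")))
  cat(sprintf("  in-situ samples: %d  amendment samples: %d\n",
              sum(x$samples$treatment == "IN_SITU"),
              sum(x$samples$treatment == "AMENDMENT")))
  invisible(x)
}

#' @export
dim.vh_counts <- function(x) dim(x$counts)
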