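#' Rarefy mapped read counts to a common library depth
#'
#' Normalizes for unequal sequencing effort by scaling every library to the
#' same number of fragments. Two modes are available:
#' \describe{
#'   \item{`expected`}{deterministic proportional scaling,
#'     `count * depth / library_size` (the expected value of subsampling).}
#'   \item{`subsample`}{a seeded multivariate-hypergeometric draw of `depth`
#'     fragments without replacement from each library; fragments that did
#'     not map to any contig form a remainder pool, so mapped totals scale
#'     correctly with the mapped fraction of each library.}
#' }
#'
#' @param cm a `vh_counts` object.
#' @param depth `"auto"` (the smallest library size) or a positive integer.
#' @param mode `"expected"` or `"subsample"`.
#' @param seed RNG seed, used only in `subsample` mode.
#' @return a numeric matrix of rarefied counts, same dimnames as
#'   `cm$counts`; integer-valued in `subsample` mode.
#' @export
rarefy <- function(cm, depth = "auto", mode = c("expected", "subsample"),
                   seed = NULL) {
  stopifnot(inherits(cm, "vh_counts"))
  mode <- match.arg(mode)
  if (nrow(cm$counts) == 0) stopf("count matrix has no contigs")
  lib <- cm$samples$library_size
  if (identical(depth, "auto")) depth <- min(lib)
  depth <- as.numeric(depth)
  if (!is.finite(depth) || depth < 1) stopf("depth must be a positive integer")
  if (mode == "expected") {
    out <- sweep(cm$counts, 2, depth / lib, `*`)
    return(out)
  }
  short <- which(lib < depth)
  if (length(short) > 0)
    stopf("depth %d exceeds library_size of sample(s): %s", depth,
          paste(cm$samples$sample_id[short], collapse = ", "))
  set_seed_if(seed)
  out <- cm$counts
  for (s in seq_len(ncol(out))) {
    cnt <- cm$counts[, s]
    # draw sequentially from the multivariate hypergeometric; the unmapped
    # remainder (library_size - sum(counts)) is the final implicit category
    remaining_draw <- depth
    remaining_pool <- lib[s]
    for (i in seq_along(cnt)) {
      x <- rhyper(1, m = cnt[i], n = remaining_pool - cnt[i],
                  k = remaining_draw)
      out[i, s] <- x
      remaining_draw <- remaining_draw - x
      remaining_pool <- remaining_pool - cnt[i]
    }
  }
  out
}

#' Length-normalize rarefied counts into RCK
#'
#' RCK ("rarefied counts per kilobase") divides each contig's rarefied count
#' by its length in kilobases, making expression comparable across contigs
#' of different lengths.
#'
#' @param rarefied numeric matrix from [rarefy()], rows aligned with
#'   `contigs`.
#' @param contigs contig annotation `data.frame` with `contig_id` and
#'   `length_bp`.
#' @return a numeric matrix of RCK values.
#' @export
compute_rck <- function(rarefied, contigs) {
  rarefied <- as.matrix(rarefied)
  if (nrow(rarefied) != nrow(contigs))
    stopf("rarefied matrix (%d rows) does not match contig list (%d)",
          nrow(rarefied), nrow(contigs))
  if (!is.null(rownames(rarefied)) &&
      !identical(rownames(rarefied), contigs$contig_id))
    stopf("rarefied matrix rownames do not match contig ids")
  rarefied / (contigs$length_bp / 1000)
}

#' Full RCK normalization of a count matrix
#'
#' Convenience wrapper: rarefies ([rarefy()]) and length-normalizes
#' ([compute_rck()]) in one step, keeping annotations and sample metadata
#' attached.
#'
#' @param cm a `vh_counts` object.
#' @param config a `vh_config` supplying depth, mode and seed defaults.
#' @param seed optional override of `config$rng_seed` for `subsample` mode.
#' @return an object of class `vh_rck` with elements `rck` (matrix),
#'   `contigs`, `samples`, `depth`, `mode`.
#' @export
rck_normalize <- function(cm, config = pipeline_config(), seed = NULL) {
  stopifnot(inherits(cm, "vh_counts"))
  depth <- config$rarefaction_depth
  if (identical(depth, "auto")) depth <- min(cm$samples$library_size)
  rar <- rarefy(cm, depth = depth, mode = config$rarefaction_mode,
                seed = seed %||% config$rng_seed)
  structure(list(rck = compute_rck(rar, cm$contigs),
                 contigs = cm$contigs, samples = cm$samples,
                 depth = depth, mode = config$rarefaction_mode),
            class = "vh_rck")
}

#' @export
print.vh_rck <- function(x, ...) {
  cat(sprintf("vh_rck: %d contigs x %d samples (depth %s, mode %s)\n",
              nrow(x$rck), ncol(x$rck), format(x$depth), x$mode))
  invisible(x)
}

#' Write an RCK matrix to TSV
#'
#' @param rck a `vh_rck` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rck <- function(rck, path) {
  stopifnot(inherits(rck, "vh_rck"))
  df <- data.frame(contig_id = rownames(rck$rck), rck$rck,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Proportional abundance of read groups per sample
#'
#' For each sample, the percentage of reads mapped to each group among the
#' scoped contigs (e.g., the share of each viral family among all non-NCLDV
#' viral reads). Samples with no scoped reads get an all-zero column and are
#' flagged in the `no_data` attribute.
#'
#' @param cm a `vh_counts` object.
#' @param grouping named character vector mapping contig ids to group
#'   labels.
#' @param scope character vector of contig ids to restrict to; defaults to
#'   all contigs named in `grouping`.
#' @return a groups-by-samples matrix of percentages (columns sum to 100
#'   where reads are present) with a logical `no_data` attribute per sample.
#' @export
proportional_abundance <- function(cm, grouping, scope = NULL) {
  stopifnot(inherits(cm, "vh_counts"))
  scope <- scope %||% names(grouping)
  if (length(scope) == 0) stopf("empty contig scope")
  missing_scope <- setdiff(scope, rownames(cm$counts))
  if (length(missing_scope) > 0)
    stopf("scoped contig(s) not in count matrix: %s",
          paste(missing_scope, collapse = ", "))
  ungrouped <- setdiff(scope, names(grouping))
  if (length(ungrouped) > 0)
    stopf("scoped contig(s) without a group: %s",
          paste(ungrouped, collapse = ", "))
  sub <- cm$counts[scope, , drop = FALSE]
  grp <- factor(grouping[scope])
  sums <- rowsum(sub, grp)
  totals <- colSums(sums)
  no_data <- totals == 0
  pct <- sweep(sums, 2, ifelse(no_data, 1, totals), `/`) * 100
  pct[, no_data] <- 0
  attr(pct, "no_data") <- no_data
  pct
}
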