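#' Pearson co-occurrence similarity between contig expression profiles
#'
#' Computes the full symmetric matrix of Pearson correlation coefficients
#' between the RCK profiles of all contigs across samples. Contigs whose
#' profile has zero variance (correlation undefined) are excluded from the
#' matrix with a warning and recorded in `dropped` — they are never silently
#' assigned r = 0.
#'
#' @param rck a `vh_rck` object.
#' @param config a `vh_config`; when `log_transform` is set, correlations
#'   are computed on `log10(RCK + pseudocount)`.
#' @return an object of class `vh_similarity`: list with `S` (correlation
#'   matrix), `ids`, `n_samples`, `dropped`.
#' @export
pearson_similarity <- function(rck, config = pipeline_config()) {
  stopifnot(inherits(rck, "vh_rck"))
  x <- rck$rck
  n <- ncol(x)
  if (n < 3)
    stopf("Pearson correlation needs at least 3 samples (got %d)", n)
  if (config$log_transform) x <- log10(x + config$pseudocount)
  sds <- apply(x, 1, stats::sd)
  dropped <- rownames(x)[sds == 0]
  if (length(dropped) > 0) {
    warnf("excluding %d zero-variance contig(s) from clustering: %s",
          length(dropped), paste(dropped, collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2)
    stopf("fewer than 2 contigs with non-constant profiles")
  S <- cor(t(x))
  diag(S) <- 1
  structure(list(S = S, ids = rownames(x), n_samples = n, dropped = dropped),
            class = "vh_similarity")
}

#' Two-sided p-value for a Pearson correlation
#'
#' Standard t-test on r: `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom; `r = +/-1` yields p = 0.
#'
#' @param r correlation coefficient(s) in `[-1, 1]` (vectorized).
#' @param n number of samples the correlation was computed over.
#' @return two-sided p-value(s).
#' @export
correlation_p <- function(r, n) {
  if (n < 3) stopf("correlation test needs n >= 3 (got %d)", n)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stopf("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0,
              2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                     lower.tail = FALSE))
  unname(p)
}

#' Write a similarity matrix to TSV
#'
#' @param sim a `vh_similarity` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "vh_similarity"))
  df <- data.frame(contig_id = rownames(sim$S), sim$S,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.vh_similarity <- function(x, ...) {
  cat(sprintf("vh_similarity: %d contigs over %d samples (%d dropped)\n",
              nrow(x$S), x$n_samples, length(x$dropped)))
  invisible(x)
}
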