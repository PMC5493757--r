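#' Pipeline configuration
#'
#' Collects every tunable parameter of the virus-host linkage pipeline in one
#' validated object. Defaults follow the published workflow: contigs longer
#' than 225 bp enter the statistics, the SIMPROF test runs at a 5%
#' significance level with 1,000 permutations (split 1,000 for the mean
#' profile and 999 for the null, the convention of the similarity-profile
#' method's reference implementation), and network edges are kept at
#' `P <= 0.1`.
#'
#' @param rarefaction_depth `"auto"` (smallest library size) or a positive
#'   integer number of fragments to rarefy every library to.
#' @param rarefaction_mode `"expected"` for deterministic proportional
#'   scaling, `"subsample"` for a seeded draw without replacement.
#' @param min_contig_length_bp minimum contig length (bp) retained by
#'   [filter_contigs()]; the default 226 keeps contigs strictly longer than
#'   225 bp.
#' @param simprof_alpha significance level of the SIMPROF test.
#' @param n_perm_mean number of permutations used to build the mean
#'   (expected) similarity profile (B1).
#' @param n_perm_null number of further permutations scored against the mean
#'   profile to form the null distribution of the pi statistic (B2).
#' @param edge_alpha p-value threshold (inclusive) for network edges.
#' @param log_transform if `TRUE`, correlate `log10(RCK + pseudocount)`
#'   instead of raw RCK.
#' @param pseudocount pseudocount added before the optional log transform.
#' @param steady_fold_max maximum max/min expression fold range for a
#'   steady-state call (default 10, "within an order of magnitude").
#' @param bust_fold_min minimum fold range for a boom-and-bust call
#'   (default 100, "two orders of magnitude").
#' @param detection_floor RCK value below which a contig counts as
#'   undetected, or `NULL` to use the smallest positive RCK in the matrix
#'   divided by 10.
#' @param positive_edges_only if `TRUE`, drop significant negative
#'   correlations from the network instead of flagging them.
#' @param rng_seed integer base seed for all stochastic steps.
#' @return an object of class `vh_config` (a validated named list).
#' @export
pipeline_config <- function(rarefaction_depth = "auto",
                            rarefaction_mode = c("expected", "subsample"),
                            min_contig_length_bp = 226L,
                            simprof_alpha = 0.05,
                            n_perm_mean = 1000L,
                            n_perm_null = 999L,
                            edge_alpha = 0.1,
                            log_transform = FALSE,
                            pseudocount = 1e-3,
                            steady_fold_max = 10,
                            bust_fold_min = 100,
                            detection_floor = NULL,
                            positive_edges_only = FALSE,
                            rng_seed = 1L) {
  rarefaction_mode <- match.arg(rarefaction_mode)
  if (!identical(rarefaction_depth, "auto")) {
    rarefaction_depth <- as.integer(rarefaction_depth)
    if (is.na(rarefaction_depth) || rarefaction_depth < 1)
      stopf("rarefaction_depth must be 'auto' or a positive integer")
  }
  if (!(simprof_alpha > 0 && simprof_alpha < 1))
    stopf("simprof_alpha must lie in (0, 1)")
  if (!(edge_alpha > 0 && edge_alpha < 1))
    stopf("edge_alpha must lie in (0, 1)")
  if (n_perm_mean < 99 || n_perm_null < 99)
    stopf("at least 99 permutations are required (got B1=%d, B2=%d)",
          n_perm_mean, n_perm_null)
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  if (steady_fold_max > bust_fold_min)
    stopf("steady_fold_max (%g) must not exceed bust_fold_min (%g)",
          steady_fold_max, bust_fold_min)
  if (!is.null(detection_floor) && detection_floor <= 0)
    stopf("detection_floor must be positive or NULL")
  cfg <- list(
    rarefaction_depth = rarefaction_depth,
    rarefaction_mode = rarefaction_mode,
    min_contig_length_bp = as.integer(min_contig_length_bp),
    simprof_alpha = simprof_alpha,
    n_perm_mean = as.integer(n_perm_mean),
    n_perm_null = as.integer(n_perm_null),
    edge_alpha = edge_alpha,
    log_transform = isTRUE(log_transform),
    pseudocount = pseudocount,
    steady_fold_max = steady_fold_max,
    bust_fold_min = bust_fold_min,
    detection_floor = detection_floor,
    positive_edges_only = isTRUE(positive_edges_only),
    rng_seed = as.integer(rng_seed)
  )
  structure(cfg, class = "vh_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path path to a YAML file whose keys mirror [pipeline_config()]
#'   arguments.
#' @return a `vh_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `vh_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vh_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.vh_config <- function(x, ...) {
  cat("Virus-host linkage pipeline configuration\n")
  for (k in names(x))
    cat(sprintf("  %-22s %s\n", k,
                if (is.null(x[[k]])) "auto" else format(x[[k]])))
  invisible(x)
}
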