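#' Parameters of the synthetic community generator
#'
#' Describes a synthetic poly-A metatranscriptome marker-gene survey shaped
#' like the field design the pipeline targets: a handful of in-situ time
#' points (default 5, emulating a ~4-week estuary time series) plus nutrient
#' amendment libraries, planted virus-host contig pairs whose latent
#' expression is coupled on the log scale, independent background contigs,
#' log-normal latent expression and negative-binomial (overdispersed) read
#' counts. Library sizes default to 1e5-1e6 fragments, a scaled-down stand-in
#' for the tens of millions of reads of a real survey.
#'
#' @param n_timepoints number of in-situ time points (>= 3).
#' @param n_amendment_samples number of nutrient-amendment libraries,
#'   generated as jittered replicates of the final time point.
#' @param n_planted_pairs number of planted virus-host pairs.
#' @param n_background_virus,n_background_euk independent background contigs
#'   per domain.
#' @param coupling correlation strength (0-1) tying a planted virus's latent
#'   log-expression to its host's.
#' @param regimes character vector (`"STEADY"`/`"BOOM_BUST"`) of length
#'   `n_planted_pairs`, or `NULL` to alternate.
#' @param library_size_range range of per-sample library sizes (fragments).
#' @param length_range_bp range of contig lengths (bp).
#' @param dispersion negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param mapped_fraction average fraction of each library mapping to the
#'   marker contigs.
#' @param steady_log_range range (log10 units) of the latent fold range of
#'   STEADY profiles; the default keeps steady folds at or below 10.
#' @param bust_log_range same for BOOM_BUST profiles; the default keeps bust
#'   folds at or above 100.
#' @param background_sd per-time-point log10 SD of background profiles.
#' @param amendment_jitter_sd log10 SD of amendment-library jitter.
#' @param seed RNG seed.
#' @return a validated list of class `vh_sim_params`.
#' @export
simulation_params <- function(n_timepoints = 5L,
                              n_amendment_samples = 3L,
                              n_planted_pairs = 4L,
                              n_background_virus = 10L,
                              n_background_euk = 10L,
                              coupling = 0.9,
                              regimes = NULL,
                              library_size_range = c(1e5, 1e6),
                              length_range_bp = c(300L, 8000L),
                              dispersion = 0.05,
                              mapped_fraction = 0.02,
                              steady_log_range = c(0.2, 0.9),
                              bust_log_range = c(2.2, 3.2),
                              background_sd = 0.5,
                              amendment_jitter_sd = 0.3,
                              seed = 1L) {
  p <- list(n_timepoints = as.integer(n_timepoints),
            n_amendment_samples = as.integer(n_amendment_samples),
            n_planted_pairs = as.integer(n_planted_pairs),
            n_background_virus = as.integer(n_background_virus),
            n_background_euk = as.integer(n_background_euk),
            coupling = coupling, regimes = regimes,
            library_size_range = library_size_range,
            length_range_bp = length_range_bp,
            dispersion = dispersion, mapped_fraction = mapped_fraction,
            steady_log_range = steady_log_range,
            bust_log_range = bust_log_range,
            background_sd = background_sd,
            amendment_jitter_sd = amendment_jitter_sd,
            seed = as.integer(seed))
  if (p$n_timepoints < 3)
    stopf("n_timepoints must be >= 3 for any downstream statistics")
  if (p$n_amendment_samples < 0 || p$n_planted_pairs < 0 ||
      p$n_background_virus < 0 || p$n_background_euk < 0)
    stopf("sample and contig counts must be non-negative")
  n_contigs <- 2 * p$n_planted_pairs + p$n_background_virus +
    p$n_background_euk
  if (n_contigs < 2)
    stopf("infeasible parameters: at least 2 contigs are required (got %d)",
          n_contigs)
  if (p$coupling < 0 || p$coupling > 1)
    stopf("coupling must lie in [0, 1]")
  if (!is.null(regimes)) {
    if (length(regimes) != p$n_planted_pairs ||
        !all(regimes %in% c("STEADY", "BOOM_BUST")))
      stopf("regimes must be length n_planted_pairs with values STEADY/BOOM_BUST")
  }
  if (p$dispersion < 0) stopf("dispersion must be non-negative")
  if (p$mapped_fraction <= 0 || p$mapped_fraction > 0.5)
    stopf("mapped_fraction must lie in (0, 0.5]")
  if (max(p$steady_log_range) > 1)
    stopf("steady_log_range must stay within one order of magnitude (<= 1)")
  if (min(p$bust_log_range) < 2)
    stopf("bust_log_range must span at least two orders of magnitude (>= 2)")
  if (diff(p$library_size_range) < 0 || p$library_size_range[1] < 1)
    stopf("invalid library_size_range")
  if (p$length_range_bp[1] < 1 || diff(p$length_range_bp) < 0)
    stopf("invalid length_range_bp")
  structure(p, class = "vh_sim_params")
}

# latent log10 profile with an exact target fold range (log10 units)
latent_profile <- function(n, base, log_range) {
  raw <- rnorm(n)
  span <- max(raw) - min(raw)
  if (span == 0) raw <- raw + c(0, rep(1, n - 1))  # degenerate draw
  span <- max(raw) - min(raw)
  base + (raw - min(raw)) / span * log_range - log_range / 2
}

# rescale a log10 profile affinely to an exact target range around a base
rescale_profile <- function(v, base, log_range) {
  span <- max(v) - min(v)
  if (span == 0) return(rep(base, length(v)))
  base + (v - mean(v)) * (log_range / span)
}

VIRUS_TAXA <- list(MCP = c("Mimiviridae", "Phycodnaviridae"),
                   RdRP = c("unclassified Picornavirales",
                            "Dicistroviridae"),
                   REP = c("ssDNA virus", "Nanoviridae"))
EUK_TAXA <- c("pelagophyte", "diatom", "dinoflagellate", "choanomonada",
              "stramenopile", "fungi", "prasinophyte", "jakobida")

# counts from expected values under the configured noise model
draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  cnt <- if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
         else rpois(n, lambda = mu)
  matrix(cnt, nrow = nrow(mu), ncol = ncol(mu), dimnames = dimnames(mu))
}

build_samples <- function(params, lib_sizes) {
  T <- params$n_timepoints
  A <- params$n_amendment_samples
  labels <- c(paste0("in situ t", seq_len(T)),
              rep(c("+N", "+P", "+N&P", "-N", "-P"), length.out = A))
  data.frame(
    sample_id = c(sprintf("S%d", seq_len(T)), sprintf("A%d", seq_len(A))[seq_len(A)]),
    site = "SYN",
    order_index = seq_len(T + A),
    treatment = c(rep("IN_SITU", T), rep("AMENDMENT", A)),
    library_size = lib_sizes,
    label = labels[seq_len(T + A)],
    stringsAsFactors = FALSE)
}

latent_to_counts <- function(latent_log10, len_bp, lib_sizes, params) {
  # expected count[i,s] = latent[i,s] * length_kb[i] * library_size[s] * scale,
  # with scale fixed so the average expected mapped fraction per library
  # equals mapped_fraction
  W <- 10^latent_log10 * (len_bp / 1000)
  scale <- params$mapped_fraction / mean(colSums(W))
  mu <- sweep(W * scale, 2, lib_sizes, `*`)
  counts <- draw_counts(mu, params$dispersion)
  over <- colSums(counts) > lib_sizes
  if (any(over))
    stopf("simulated mapped counts exceeded library size; lower mapped_fraction")
  counts
}

#' Simulate a synthetic virus-host marker-gene community
#'
#' Generates contig annotations, a counts-by-samples matrix and a ground
#' truth table. Planted pairs consist of a eukaryotic host contig whose
#' latent log10 expression follows its regime (steady or boom-and-bust) and
#' a viral contig whose latent profile is
#' `coupling * host + (1 - coupling) * noise` on the log scale, rescaled to
#' the regime's fold range so planted STEADY viruses stay within one order
#' of magnitude and planted BOOM_BUST viruses span at least two. Background
#' contigs are independent. Expected counts are
#' `10^latent * length_kb * library_size * scale` with negative-binomial
#' noise.
#'
#' @param params a `vh_sim_params` object.
#' @return a list of class `vh_sim` with elements `annotations`, `counts`
#'   (a `vh_counts`), and `truth` (list: `pairs` data.frame with virus/host
#'   ids and regimes, `latent_log10` matrix, `params`).
#' @export
simulate_community <- function(params = simulation_params()) {
  stopifnot(inherits(params, "vh_sim_params"))
  set.seed(params$seed)
  T <- params$n_timepoints
  A <- params$n_amendment_samples
  P <- params$n_planted_pairs
  BV <- params$n_background_virus
  BE <- params$n_background_euk

  regimes <- params$regimes %||%
    rep(c("STEADY", "BOOM_BUST"), length.out = max(P, 1))[seq_len(P)]

  v_ids <- sprintf("V_P%02d", seq_len(P))
  h_ids <- sprintf("H_P%02d", seq_len(P))
  bv_ids <- sprintf("V_B%02d", seq_len(BV))
  be_ids <- sprintf("E_B%02d", seq_len(BE))
  ids <- c(v_ids, h_ids, bv_ids, be_ids)
  n_contigs <- length(ids)

  log_rng_of <- function(regime)
    if (regime == "STEADY") runif(1, params$steady_log_range[1],
                                  params$steady_log_range[2])
    else runif(1, params$bust_log_range[1], params$bust_log_range[2])

  # amendment libraries are perturbed replicates of the final time point;
  # the virus-host coupling applies across the full latent profile (in-situ
  # and amendment columns alike), mirroring an infection that persists in
  # the incubation bottles
  with_amendment <- function(prof) {
    if (A == 0) return(prof)
    c(prof, prof[T] + rnorm(A, sd = params$amendment_jitter_sd))
  }
  latent <- matrix(0, n_contigs, T + A, dimnames = list(ids, NULL))
  for (k in seq_len(P)) {
    h_rng <- log_rng_of(regimes[k])
    h <- with_amendment(
      latent_profile(T, base = runif(1, -0.5, 0.5), log_range = h_rng))
    noise <- with_amendment(rnorm(T, sd = params$background_sd))
    v0 <- params$coupling * h + (1 - params$coupling) * noise
    # rescale the whole profile affinely so the in-situ fold range matches
    # the regime target; affine maps preserve the log-scale correlation
    v_rng <- log_rng_of(regimes[k])
    insitu_span <- max(v0[seq_len(T)]) - min(v0[seq_len(T)])
    v <- if (insitu_span == 0) rep(runif(1, -0.5, 0.5), T + A)
         else runif(1, -0.5, 0.5) + (v0 - mean(v0)) * (v_rng / insitu_span)
    latent[h_ids[k], ] <- h
    latent[v_ids[k], ] <- v
  }
  for (id in c(bv_ids, be_ids))
    latent[id, ] <- with_amendment(
      runif(1, -0.5, 0.5) + rnorm(T, sd = params$background_sd))

  lib_sizes <- round(runif(T + A, params$library_size_range[1],
                           params$library_size_range[2]))
  len_bp <- as.integer(round(runif(n_contigs, params$length_range_bp[1],
                                   params$length_range_bp[2])))
  samples <- build_samples(params, lib_sizes)
  colnames(latent) <- samples$sample_id

  v_markers <- sample(names(VIRUS_TAXA), P + BV, replace = TRUE)
  ann <- data.frame(
    contig_id = ids,
    length_bp = len_bp,
    marker = c(v_markers[seq_len(P)], rep("RPB1", P),
               v_markers[P + seq_len(BV)], rep("RPB1", BE)),
    domain_class = c(rep("VIRUS", P), rep("EUKARYOTE", P),
                     rep("VIRUS", BV), rep("EUKARYOTE", BE)),
    stringsAsFactors = FALSE)
  ann$taxon_label <- sample(EUK_TAXA, n_contigs, replace = TRUE)
  is_vir <- ann$domain_class == "VIRUS"
  ann$taxon_label[is_vir] <- vapply(ann$marker[is_vir], function(m)
    sample(VIRUS_TAXA[[m]], 1), character(1))

  counts <- latent_to_counts(latent, len_bp, lib_sizes, params)
  cm <- count_matrix(counts, ann, samples)
  truth <- list(pairs = data.frame(virus_id = v_ids, host_id = h_ids,
                                   regime = regimes,
                                   stringsAsFactors = FALSE),
                latent_log10 = latent, params = params)
  structure(list(annotations = cm$contigs, counts = cm, truth = truth),
            class = "vh_sim")
}

#' Simulate a null community with no multivariate structure
#'
#' Every cell's latent log10 expression is drawn i.i.d., so contigs carry no
#' co-occurrence structure at all; counts use the same length/library-size/
#' negative-binomial model as [simulate_community()]. Used to check the
#' SIMPROF test's type-I error calibration.
#'
#' @param n_contigs number of contigs (>= 3).
#' @param n_samples number of samples (>= 3); the first
#'   `max(3, n_samples - params$n_amendment_samples)` are labelled in-situ.
#' @param params a `vh_sim_params` (noise and size settings are reused).
#' @param seed optional override of `params$seed`.
#' @return a `vh_counts` object; its planted-pair truth is empty by
#'   construction.
#' @export
simulate_null <- function(n_contigs = 20L, n_samples = 8L,
                          params = simulation_params(), seed = NULL) {
  stopifnot(inherits(params, "vh_sim_params"))
  if (n_contigs < 3 || n_samples < 3)
    stopf("null simulation needs n_contigs >= 3 and n_samples >= 3")
  set.seed(seed %||% params$seed)
  ids <- sprintf("X%03d", seq_len(n_contigs))
  latent <- matrix(rnorm(n_contigs * n_samples, sd = params$background_sd),
                   n_contigs, n_samples, dimnames = list(ids, NULL))
  lib_sizes <- round(runif(n_samples, params$library_size_range[1],
                           params$library_size_range[2]))
  len_bp <- as.integer(round(runif(n_contigs, params$length_range_bp[1],
                                   params$length_range_bp[2])))
  n_insitu <- max(3L, n_samples - params$n_amendment_samples)
  samples <- data.frame(
    sample_id = sprintf("S%d", seq_len(n_samples)),
    site = "NULL",
    order_index = seq_len(n_samples),
    treatment = c(rep("IN_SITU", n_insitu),
                  rep("AMENDMENT", n_samples - n_insitu)),
    library_size = lib_sizes,
    stringsAsFactors = FALSE)
  colnames(latent) <- samples$sample_id
  dom <- rep(c("VIRUS", "EUKARYOTE"), length.out = n_contigs)
  ann <- data.frame(
    contig_id = ids, length_bp = len_bp,
    marker = ifelse(dom == "VIRUS", "MCP", "RPB1"),
    domain_class = dom,
    taxon_label = "synthetic null",
    stringsAsFactors = FALSE)
  counts <- latent_to_counts(latent, len_bp, lib_sizes, params)
  count_matrix(counts, ann, samples)
}

#' Write a simulated community to the pipeline's TSV formats
#'
#' Emits exactly the files [read_count_matrix()] and
#' [read_contig_annotations()] consume, plus the planted-pair truth table
#' and the generator parameters as YAML so a run can be reproduced.
#'
#' @param sim a `vh_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "vh_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth_pairs.tsv"),
             params = file.path(dir, "params.yaml"))
  write_count_matrix(sim$counts, paths["counts"], paths["samples"],
                     paths["annotations"])
  write.table(sim$truth$pairs, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  pr <- unclass(sim$truth$params)
  pr$regimes <- as.character(sim$truth$pairs$regime)
  yaml::write_yaml(pr, paths["params"])
  invisible(paths)
}

#' @export
print.vh_sim <- function(x, ...) {
  cat(sprintf("vh_sim: %d planted pairs, %d contigs x %d samples\n",
              nrow(x$truth$pairs), nrow(x$counts$counts),
              ncol(x$counts$counts)))
  invisible(x)
}
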