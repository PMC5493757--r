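#' Classify a viral contig's in-situ temporal dynamics
#'
#' Operationalizes the distinction between steady-state infection (marker
#' expression "within an order of magnitude" across time points) and
#' boom-and-bust dynamics (expression swinging by two or more orders of
#' magnitude, or a contig absent early and bursting later). Only `IN_SITU`
#' samples, ordered by `order_index`, enter the classification; nutrient
#' amendment libraries never change a call.
#'
#' Rules, with `fold_range = max / min` over positive RCK at detected
#' time points:
#' \itemize{
#'   \item fewer than 2 detected time points: `INSUFFICIENT_DATA`;
#'   \item detected at every time point and
#'     `fold_range <= steady_fold_max` (default 10): `STEADY`;
#'   \item `fold_range >= bust_fold_min` (default 100): `BOOM_BUST`;
#'   \item undetected at some time point with a burst at least
#'     `bust_fold_min` times the detection floor: `BOOM_BUST`
#'     (the absent-then-detected pattern);
#'   \item otherwise `INTERMEDIATE`.
#' }
#' The detection floor defaults to the smallest positive RCK anywhere in the
#' matrix divided by 10, so a hard zero followed by clear expression counts
#' as a boom.
#'
#' @param rck a `vh_rck` object.
#' @param contig_id contig to classify.
#' @param config a `vh_config` supplying the fold thresholds and optional
#'   `detection_floor`.
#' @return an object of class `vh_dynamics_call`: list with `contig_id`,
#'   `regime`, `fold_range`, `n_detected`, `detection_pattern` (logical per
#'   in-situ time point, in temporal order).
#' @export
classify_dynamics <- function(rck, contig_id, config = pipeline_config()) {
  stopifnot(inherits(rck, "vh_rck"))
  if (!contig_id %in% rownames(rck$rck))
    stopf("contig '%s' absent from RCK matrix", contig_id)
  insitu <- rck$samples[rck$samples$treatment == "IN_SITU", , drop = FALSE]
  if (nrow(insitu) < 3)
    stopf("dynamics classification needs at least 3 IN_SITU time points (got %d)",
          nrow(insitu))
  insitu <- insitu[order(insitu$order_index), , drop = FALSE]
  v <- rck$rck[contig_id, insitu$sample_id]
  floor <- config$detection_floor %||% {
    pos <- rck$rck[rck$rck > 0]
    if (length(pos) == 0) stopf("RCK matrix is all zero")
    min(pos) / 10
  }
  detected <- v > floor
  n_det <- sum(detected)
  fold <- if (n_det >= 1) max(v[detected]) / min(v[detected]) else NA_real_
  regime <- if (n_det < 2) {
    "INSUFFICIENT_DATA"
  } else if (all(detected) && fold <= config$steady_fold_max) {
    "STEADY"
  } else if (fold >= config$bust_fold_min) {
    "BOOM_BUST"
  } else if (!all(detected) && max(v) >= config$bust_fold_min * floor) {
    "BOOM_BUST"
  } else {
    "INTERMEDIATE"
  }
  structure(list(contig_id = contig_id, regime = regime,
                 fold_range = fold, n_detected = as.integer(n_det),
                 detection_pattern = unname(detected)),
            class = "vh_dynamics_call")
}

#' @export
print.vh_dynamics_call <- function(x, ...) {
  cat(sprintf("%s: %s (fold range %s, detected %d/%d time points)\n",
              x$contig_id, x$regime,
              if (is.na(x$fold_range)) "NA" else sprintf("%.3g", x$fold_range),
              x$n_detected, length(x$detection_pattern)))
  invisible(x)
}

#' Temporal dynamics report for all viral contigs
#'
#' Applies [classify_dynamics()] to every viral contig and tabulates the
#' calls.
#'
#' @param rck a `vh_rck` object.
#' @param annotations contig annotations; defaults to those attached to
#'   `rck`.
#' @param config a `vh_config`.
#' @return data.frame with one row per viral contig: `contig_id`, `marker`,
#'   `taxon_label`, `regime`, `fold_range`, `n_detected`,
#'   `detection_pattern` (dot-dash string, `+` detected / `-` not); the
#'   per-regime counts are attached as the `summary` attribute.
#' @export
dynamics_report <- function(rck, annotations = NULL,
                            config = pipeline_config()) {
  stopifnot(inherits(rck, "vh_rck"))
  ann <- annotations %||% rck$contigs
  viral <- ann[ann$domain_class == "VIRUS" &
               ann$contig_id %in% rownames(rck$rck), , drop = FALSE]
  rows <- lapply(viral$contig_id, function(id) {
    call <- classify_dynamics(rck, id, config)
    data.frame(contig_id = id,
               marker = viral$marker[viral$contig_id == id],
               taxon_label = viral$taxon_label[viral$contig_id == id],
               regime = call$regime, fold_range = call$fold_range,
               n_detected = call$n_detected,
               detection_pattern = paste(
                 ifelse(call$detection_pattern, "+", "-"), collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(contig_id = character(), marker = character(),
               taxon_label = character(), regime = character(),
               fold_range = numeric(), n_detected = integer(),
               detection_pattern = character(), stringsAsFactors = FALSE)
  attr(out, "summary") <- table(factor(
    out$regime, levels = c("STEADY", "BOOM_BUST", "INTERMEDIATE",
                           "INSUFFICIENT_DATA")))
  out
}
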