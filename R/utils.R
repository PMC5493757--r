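`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic seed derived from a set of identifiers
#'
#' Hashes a character vector of identifiers (order-independent) together with
#' a base seed into a 32-bit integer seed. Used to give every dendrogram node
#' its own reproducible permutation stream, so results do not depend on the
#' order in which nodes are visited or contigs were supplied.
#'
#' @param ids character vector of identifiers (sorted internally).
#' @param base_seed integer base seed.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(ids, base_seed) {
  s <- paste(sort(as.character(ids)), collapse = "\r")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

# set.seed only when a seed is supplied
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
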