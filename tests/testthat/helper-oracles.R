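# Independent oracles used to cross-check the implementation.

# Naive O(n^3) group-average agglomeration in similarity space: repeatedly
# merge the two clusters with the highest mean cross-pair similarity.
# Returns the merge heights (similarities) in merge order.
naive_upgma_heights <- function(S) {
  clusters <- as.list(seq_len(nrow(S)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_sim <- -Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        cross <- S[clusters[[a]], clusters[[b]], drop = FALSE]
        s <- mean(cross)
        if (s > best_sim) {
          best_sim <- s
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_sim)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# All 3 pairwise Pearson correlations of a 3 x 2 matrix, sorted.
profile_3x2 <- function(x) {
  r <- function(i, j) {
    a <- x[i, ] - mean(x[i, ])
    b <- x[j, ] - mean(x[j, ])
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  sort(c(r(1, 2), r(1, 3), r(2, 3)))
}

# Exact SIMPROF null for 3 contigs x 2 samples: enumerate all (3!)^2 = 36
# within-column permutation combinations; return the exact mean ordered
# profile and the 36 equally likely pi values.
exact_simprof_null_3x2 <- function(x) {
  stopifnot(nrow(x) == 3, ncol(x) == 2)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  profiles <- matrix(NA_real_, 36, 3)
  k <- 0
  for (p1 in perms) {
    for (p2 in perms) {
      k <- k + 1
      xp <- cbind(x[p1, 1], x[p2, 2])
      profiles[k, ] <- profile_3x2(xp)
    }
  }
  mean_profile <- colMeans(profiles)
  pi_values <- apply(profiles, 1, function(pr) sum(abs(pr - mean_profile)))
  list(mean_profile = mean_profile, pi_values = pi_values)
}

# Total-variation distance between two samples over a shared discrete
# support; each value of `draws` is assigned to the nearest atom.
tv_to_atoms <- function(draws, atoms) {
  u <- sort(unique(atoms))
  p_exact <- tabulate(match(atoms, u), nbins = length(u)) / length(atoms)
  nearest <- vapply(draws, function(d) which.min(abs(u - d)), integer(1))
  p_mc <- tabulate(nearest, nbins = length(u)) / length(draws)
  0.5 * sum(abs(p_exact - p_mc))
}
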