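test_that("simulation is deterministic under a fixed seed", {
  p <- simulation_params(seed = 123)
  s1 <- simulate_community(p)
  s2 <- simulate_community(p)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth$pairs, s2$truth$pairs)
  s3 <- simulate_community(simulation_params(seed = 124))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("planted latent profiles honour their regime fold ranges", {
  sim <- simulate_community(simulation_params(seed = 42, n_planted_pairs = 6))
  lat <- sim$truth$latent_log10
  insitu <- grep("^S", colnames(lat))
  for (k in seq_len(nrow(sim$truth$pairs))) {
    v <- lat[sim$truth$pairs$virus_id[k], insitu]
    fold <- 10^(max(v) - min(v))
    if (sim$truth$pairs$regime[k] == "STEADY") expect_lte(fold, 10)
    else expect_gte(fold, 100)
  }
})

test_that("tight coupling with little noise drives pair correlations to one", {
  sim <- simulate_community(simulation_params(
    seed = 7, coupling = 1, dispersion = 0,
    library_size_range = c(1e6, 2e6)))
  rck <- rck_normalize(sim$counts)
  for (k in seq_len(nrow(sim$truth$pairs))) {
    r <- cor(rck$rck[sim$truth$pairs$virus_id[k], ],
             rck$rck[sim$truth$pairs$host_id[k], ])
    expect_gt(r, 0.9)
  }
})

test_that("zero coupling leaves planted pairs looking like background", {
  rs <- replicate(30, {
    sim <- simulate_community(simulation_params(
      seed = sample.int(1e6, 1), coupling = 0, n_planted_pairs = 2,
      dispersion = 0.01))
    rck <- rck_normalize(sim$counts)
    x <- log10(rck$rck + 1e-3)
    mean(vapply(seq_len(2), function(k)
      cor(x[sim$truth$pairs$virus_id[k], ], x[sim$truth$pairs$host_id[k], ]),
      numeric(1)))
  })
  # mean pair correlation indistinguishable from zero at this replication
  expect_lt(abs(mean(rs)), 2.5 * sd(rs) / sqrt(length(rs)) + 0.15)
})

test_that("infeasible parameters are rejected", {
  expect_error(simulation_params(n_planted_pairs = 0, n_background_virus = 0,
                                 n_background_euk = 0), "at least 2 contigs")
  expect_error(simulation_params(coupling = 1.2), "coupling")
  expect_error(simulation_params(regimes = c("STEADY")), "regimes")
  expect_error(simulation_params(n_timepoints = 2), "n_timepoints")
  expect_error(simulation_params(dispersion = -1), "dispersion")
})

test_that("generated tables pass the package's own readers", {
  sim <- simulate_community(simulation_params(seed = 15))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  cm <- read_count_matrix(paths["counts"], paths["samples"],
                          paths["annotations"])
  expect_identical(cm$counts, sim$counts$counts)
  # truth round-trips losslessly
  truth2 <- read.delim(paths["truth"], stringsAsFactors = FALSE)
  expect_identical(truth2, sim$truth$pairs)
  params2 <- yaml::read_yaml(paths["params"])
  expect_equal(params2$seed, sim$truth$params$seed)
  expect_equal(params2$coupling, sim$truth$params$coupling)
})

test_that("null communities carry no planted structure", {
  p <- simulation_params(seed = 1)
  cm <- simulate_null(12, 6, p, seed = 5)
  expect_s3_class(cm, "vh_counts")
  expect_equal(dim(cm), c(12L, 6L))
  cm2 <- simulate_null(12, 6, p, seed = 6)
  expect_false(identical(cm$counts, cm2$counts))
  expect_error(simulate_null(2, 6, p), "n_contigs")

  # mean absolute off-diagonal correlation near the i.i.d. reference
  # (E|r| ~ sqrt(2/pi) / sqrt(n-1) for independent gaussian profiles)
  rs <- vapply(1:20, function(s) {
    cm <- simulate_null(10, 8, p, seed = 100 + s)
    rck <- rck_normalize(cm)
    S <- cor(t(log10(rck$rck + 1e-3)))
    mean(abs(S[upper.tri(S)]))
  }, numeric(1))
  ref <- sqrt(2 / pi) / sqrt(8 - 1)
  expect_lt(abs(mean(rs) - ref), 0.1)
})
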