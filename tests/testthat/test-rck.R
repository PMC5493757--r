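test_that("expected-mode rarefaction scales counts by depth over library size", {
  ann <- tiny_annotations()[1, , drop = FALSE]
  m <- matrix(10, 1, 3, dimnames = list("v1", paste0("S", 1:3)))
  cm <- count_matrix(m, ann, tiny_samples(3, lib = 1000))
  r <- rarefy(cm, depth = 500, mode = "expected")
  expect_equal(unname(r[1, ]), rep(5, 3))
  # depth equal to the library size is the identity
  expect_equal(rarefy(cm, depth = 1000, mode = "expected"), cm$counts)
})

test_that("expected-mode column totals equal depth times the mapped fraction", {
  cm <- tiny_counts()
  r <- rarefy(cm, depth = 400, mode = "expected")
  expect_equal(colSums(r),
               400 * colSums(cm$counts) / cm$samples$library_size)
})

test_that("RCK divides by contig length in kilobases", {
  contigs <- data.frame(contig_id = c("a", "b", "c"),
                        length_bp = c(2000L, 1000L, 500L))
  rar <- matrix(c(5, 0, 3), 3, 2,
                dimnames = list(contigs$contig_id, c("S1", "S2")))
  rck <- compute_rck(rar, contigs)
  expect_equal(rck["a", 1], 2.5)   # 5 reads on a 2 kb contig
  expect_equal(rck["b", 1], 0)
  expect_equal(rck["c", 1], 6)     # inverse proportionality to length
  # unit-length contig: RCK equals the rarefied count
  expect_equal(rck["b", 2], rar["b", 2])
  # linear in counts
  expect_equal(compute_rck(rar * 3, contigs), rck * 3)
})

test_that("subsampling matches the hypergeometric expectation", {
  ann <- tiny_annotations()[1, , drop = FALSE]
  m <- matrix(10, 1, 1, dimnames = list("v1", "S1"))
  cm <- count_matrix(m, ann, tiny_samples(1, lib = 1000))
  draws <- vapply(seq_len(1000), function(s)
    rarefy(cm, depth = 500, mode = "subsample", seed = s)[1, 1],
    numeric(1))
  expect_true(all(draws >= 0 & draws <= 10))
  # E[X] = depth * count / library = 5; SE of the mean ~ 0.05
  expect_lt(abs(mean(draws) - 5), 0.2)

  expect_error(rarefy(cm, depth = 2000, mode = "subsample", seed = 1),
               "S1")
})

test_that("subsampled counts never exceed the rarefaction depth per sample", {
  cm <- tiny_counts(lib = 200)
  r <- rarefy(cm, depth = 50, mode = "subsample", seed = 42)
  expect_true(all(colSums(r) <= 50))
  expect_true(all(r == round(r)))
  # same seed reproduces the draw
  expect_identical(r, rarefy(cm, depth = 50, mode = "subsample", seed = 42))
})

test_that("expected-mode RCK is invariant to jointly scaling counts and library size", {
  cm <- tiny_counts()
  rck1 <- rck_normalize(cm, pipeline_config(rarefaction_depth = 300))
  cm2 <- cm
  cm2$counts[, 2] <- cm2$counts[, 2] * 7
  cm2$samples$library_size[2] <- cm2$samples$library_size[2] * 7
  rck2 <- rck_normalize(cm2, pipeline_config(rarefaction_depth = 300))
  expect_equal(rck1$rck, rck2$rck)
})

test_that("auto depth is the smallest library size", {
  cm <- tiny_counts()
  cm$samples$library_size <- c(1000, 800, 1200)
  rck <- rck_normalize(cm)
  expect_equal(rck$depth, 800)
})

test_that("proportional abundance sums to 100 and flags empty samples", {
  ann <- tiny_annotations()
  m <- matrix(c(80, 0, 0,
                20, 0, 0,
                50, 0, 10,
                30, 0, 30), 4, 3, byrow = TRUE,
              dimnames = list(ann$contig_id, paste0("S", 1:3)))
  cm <- count_matrix(m, ann, tiny_samples(3, lib = 1000))
  grouping <- c(v1 = "A", v2 = "A", e1 = "B", e2 = "C")

  pct <- proportional_abundance(cm, grouping)
  expect_equal(unname(colSums(pct)[!attr(pct, "no_data")]),
               rep(100, 2))
  # hand-summed: S1 has A=100, B=50, C=30 reads of 180 total
  expect_equal(pct["A", "S1"], 100 / 180 * 100)
  expect_equal(pct["B", "S1"], 50 / 180 * 100)
  expect_true(attr(pct, "no_data")["S2"])
  expect_equal(unname(pct[, "S2"]), rep(0, 3))

  # restricting scope to the viral contigs: one group takes all reads
  pct_v <- proportional_abundance(cm, grouping, scope = c("v1", "v2"))
  expect_equal(unname(pct_v["A", "S1"]), 100)

  expect_error(proportional_abundance(cm, grouping, scope = character(0)),
               "empty")
  expect_error(proportional_abundance(cm, c(v1 = "A"), scope = c("v1", "e1")),
               "without a group")
})
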