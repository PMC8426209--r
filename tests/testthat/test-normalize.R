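test_that("geometric mean matches closed forms and rejects bad input", {
  expect_equal(geometric_mean(c(4, 9)), 6)
  expect_equal(geometric_mean(5), 5)
  expect_equal(geometric_mean(c(1, 10, 100)), 10)
  expect_error(geometric_mean(numeric(0)), "empty")
  expect_error(geometric_mean(c(2, 0)), "positive")
})

test_that("a sample scaled 2x (controls included) normalizes to identical columns", {
  genes <- c("g1", "g2", "g3", "hk1", "hk2", "neg1", "neg2", "neg3", "pos1", "pos2")
  cls <- c(rep("endogenous", 3), rep("housekeeping", 2),
           rep("negative_control", 3), rep("positive_control", 2))
  a <- c(40L, 80L, 160L, 100L, 200L, 2L, 4L, 6L, 500L, 1000L)
  counts <- cbind(A = a, B = 2L * a)
  rownames(counts) <- genes
  probes <- data.frame(gene_id = genes, probe_class = cls, stringsAsFactors = FALSE)
  norm <- normalize_counts(counts, probes)
  expect_equal(norm[, "A"], norm[, "B"])
  expect_equal(rownames(norm), c("g1", "g2", "g3"))
})

test_that("with all steps disabled the transform is log2(x + pseudocount)", {
  counts <- matrix(c(7L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  probes <- data.frame(gene_id = c("g1", "g2"),
                       probe_class = c("endogenous", "endogenous"),
                       stringsAsFactors = FALSE)
  p <- normalization_params(use_positive_controls = FALSE,
                            background_mode = "none",
                            housekeeping_mode = "none", pseudocount = 1)
  norm <- normalize_counts(counts, probes, p)
  expect_equal(norm["g1", "s1"], 3.0)
  expect_equal(norm["g2", "s1"], 0.0)
})

test_that("housekeeping geometric means are equalized across samples", {
  sim <- simulate_cohort(simulation_config(seed = 31, library_size_sd = 0.4))
  params <- normalization_params()
  cls <- sim$probes$probe_class
  # replay steps 1-3 to inspect the pre-log scaled matrix
  x <- sim$counts * 1.0
  pos <- x[cls == "positive_control", ] + ifelse(any(x[cls == "positive_control", ] == 0), 0.5, 0)
  gm <- apply(pos, 2, geometric_mean)
  x <- sweep(x, 2, geometric_mean(gm) / gm, `*`)
  neg <- x[cls == "negative_control", ]
  thr <- apply(neg, 2, function(v) mean(v) + 2 * sd(v))
  keep <- cls %in% c("endogenous", "housekeeping")
  x[keep, ] <- pmax(x[keep, ], matrix(thr, sum(keep), ncol(x), byrow = TRUE))
  hk <- x[cls == "housekeeping", ]
  f <- attr(normalize_counts(sim$counts, sim$probes, params), "hk_factors")
  gm_after <- apply(sweep(hk, 2, f, `*`), 2, geometric_mean)
  expect_lt(diff(range(gm_after)) / mean(gm_after), 1e-9)
})

test_that("normalization removes simulated library-size factors", {
  sim <- simulate_cohort(simulation_config(seed = 32, library_size_sd = 0.3))
  norm <- normalize_counts(sim$counts, sim$probes)
  rho <- stats::cor(sim$truth$samples$lib_factor, colMeans(norm),
                    method = "spearman")
  expect_lte(abs(rho), 0.1)
})

test_that("all-zero housekeeping in a sample is a named hard error", {
  sim <- simulate_cohort(small_config(seed = 33, group_sizes = c(A = 2L, B = 2L)))
  counts <- sim$counts
  counts[sim$probes$probe_class == "housekeeping", 2] <- 0L
  bad <- colnames(counts)[2]
  expect_error(normalize_counts(counts, sim$probes), bad)
})
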