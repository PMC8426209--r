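test_that("Kruskal-Wallis omnibus matches closed-form cases", {
  g <- rep(c("a", "b", "c"), each = 2)
  res <- kruskal_omnibus(rep(1, 6), g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  # fully separated groups: H from the rank formula without ties
  v <- c(1, 2, 3, 4, 5, 6)
  res2 <- kruskal_omnibus(v, g)
  H <- 12 / (6 * 7) * (2 * (1.5 - 3.5)^2 + 2 * (3.5 - 3.5)^2 + 2 * (5.5 - 3.5)^2)
  expect_equal(res2$statistic, H)
  expect_equal(res2$p.value, stats::pchisq(H, df = 2, lower.tail = FALSE))

  expect_error(kruskal_omnibus(1:5, c("a", "a", "b", "b", "c")), "< 2 samples")
})

test_that("pairwise Wilcoxon: exact enumeration case, symmetry, tie handling", {
  v <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  res <- pairwise_wilcoxon(v, g, list(c("a", "b")))
  expect_equal(res$p, 0.1)      # 2 of the C(6,3)=20 orderings, two-sided
  expect_true(res$exact)
  res_sw <- pairwise_wilcoxon(v, g, list(c("b", "a")))
  expect_equal(res_sw$p, res$p)

  tied <- c(1, 1, 1, 1, 1, 1)
  res_t <- pairwise_wilcoxon(tied, g, list(c("a", "b")))
  expect_false(res_t$exact)
  expect_equal(res_t$p, 1)

  big <- stats::rnorm(30)
  res_b <- pairwise_wilcoxon(big, rep(c("a", "b"), each = 15), list(c("a", "b")))
  expect_false(res_b$exact)     # combined n > 25 -> normal approximation
})

test_that("BH adjustment matches the step-up definition and its bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(13)
  for (i in 1:200) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p) && all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("signed fold change follows the +/- convention and is antisymmetric", {
  expect_equal(signed_fold_change(5, 5), 1.0)
  expect_equal(signed_fold_change(3, 5), -4.0)
  expect_equal(signed_fold_change(6.322, 5), 2.5, tolerance = 1e-3)
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50)
  keep <- a != b
  expect_equal(signed_fold_change(a, b)[keep], -signed_fold_change(b, a)[keep])
})

test_that("venn partition is a disjoint cover of the union", {
  vp <- venn_partition(c("g1", "g2"), "g2", character(0))
  expect_equal(vp$A_only, "g1")
  expect_equal(vp$A.B_only, "g2")
  expect_equal(sum(lengths(vp)), 2)

  same <- c("x", "y", "z")
  vp2 <- venn_partition(same, same, same)
  expect_equal(vp2$A.B.C, sort(same))
  expect_equal(sum(lengths(vp2)), 3)

  set.seed(31)
  for (i in 1:20) {
    pool <- paste0("g", 1:30)
    A <- sample(pool, sample(0:20, 1)); B <- sample(pool, sample(0:20, 1))
    C <- sample(pool, sample(0:20, 1))
    vp3 <- venn_partition(A, B, C)
    all_members <- unname(unlist(vp3))
    expect_equal(sort(all_members), sort(union(union(A, B), C)))
    expect_false(anyDuplicated(all_members) > 0)
  }
})

test_that("de_table flags a planted effect and estimates its fold change", {
  eff <- data.frame(gene_id = "GENE0001", group_a = "A", group_b = "D",
                    log2fc = -log2(2.5), stringsAsFactors = FALSE)
  cfg <- small_config(seed = 61, planted_effects = eff,
                      group_sizes = c(A = 13L, B = 6L, C = 6L, D = 26L))
  sim <- simulate_cohort(cfg)
  norm <- normalize_counts(sim$counts, sim$probes)
  de <- de_table(norm, sim$samples, pairs = list(c("A", "D")), fdr = 0.05,
                 gate_on_omnibus = FALSE)
  row <- de[de$feature == "GENE0001", ]
  expect_true(row$`sig_A.vs.D`)
  expect_lt(row$`fc_A.vs.D`, -1.5)
  expect_true("GENE0001" %in% significant_set(de, c("A", "D"), "down"))
  expect_false("GENE0001" %in% significant_set(de, c("A", "D"), "up"))
  expect_true(all(de$kw_p_adj >= de$kw_p))
})

test_that("omnibus gate suppresses pairwise flags for omnibus-null genes", {
  sim <- simulate_cohort(small_config(seed = 62))
  norm <- normalize_counts(sim$counts, sim$probes)
  base <- grep("^GENE", rownames(norm), value = TRUE)
  de <- de_table(norm[base, ], sim$samples, pairs = list(c("A", "B")))
  expect_true(all(!de$`sig_A.vs.B`[!de$kw_sig]))
})
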