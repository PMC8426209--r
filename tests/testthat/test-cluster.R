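test_that("row centering is exact and idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  cm <- center_rows(m)
  expect_equal(cm["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(cm["b", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_lt(max(abs(rowMeans(cm))), 1e-12)
  expect_equal(center_rows(cm), cm)
})

test_that("hcluster recovers separated blobs and honors k", {
  m <- cbind(matrix(0, 4, 5), matrix(10, 4, 5)) +
    matrix(rnorm(40, sd = 1e-3), 4)
  colnames(m) <- paste0("s", 1:10)
  rownames(m) <- paste0("f", 1:4)
  cl <- hcluster(m, axis = "columns", k = 2)
  expect_equal(unname(cl$cluster), rep(c("C1", "C2"), each = 5))
  expect_length(unique(hcluster(m, k = 1)$cluster), 1)
  expect_error(hcluster(m, k = 11), "k must lie")
})

test_that("hcluster is permutation-stable up to relabeling", {
  set.seed(4)
  m <- matrix(rnorm(8 * 20), 8, dimnames = list(paste0("f", 1:8), paste0("s", 1:20)))
  cl1 <- hcluster(m, k = 3)$cluster
  perm <- sample(colnames(m))
  cl2 <- hcluster(m[, perm], k = 3)$cluster[colnames(m)]
  # identical partitions: co-membership matrices agree
  same1 <- outer(cl1, cl1, "==")
  same2 <- outer(cl2, cl2, "==")
  expect_identical(same1, same2)
})

test_that("hot/cold labeling follows the total-TIL means, invariant to cluster ids", {
  assign <- list(cluster = c(s1 = "C1", s2 = "C1", s3 = "C2", s4 = "C2"))
  til <- c(s1 = 5, s2 = 5, s3 = 2, s4 = 2)
  lab <- label_hot_cold(assign, til)
  expect_equal(unname(lab), c("hot", "hot", "cold", "cold"))
  swapped <- list(cluster = c(s1 = "C2", s2 = "C2", s3 = "C1", s4 = "C1"))
  expect_equal(label_hot_cold(swapped, til), lab)
  # exact tie -> larger cluster cold, with warning
  assign3 <- list(cluster = c(s1 = "C1", s2 = "C2", s3 = "C2", s4 = "C2"))
  til3 <- c(s1 = 3, s2 = 3, s3 = 3, s4 = 3)
  expect_warning(lab3 <- label_hot_cold(assign3, til3), "tie")
  expect_equal(unname(lab3), c("hot", "cold", "cold", "cold"))
})

test_that("hot/cold recovery on planted cohorts reaches 95%", {
  acc <- vapply(1:5, function(i) {
    sim <- simulate_cohort(simulation_config(seed = 500 + i))
    norm <- normalize_counts(sim$counts, sim$probes)
    scores <- score_matrix(norm)
    cl <- hcluster(scores[setdiff(rownames(scores),
                                  c("total_TILs", "cytolytic_activity")), ], k = 2)
    lab <- label_hot_cold(cl, scores["total_TILs", ])
    mean(lab == sim$truth$samples$state)
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("association test matches enumeration and handles degeneracies", {
  expect_equal(association_test(matrix(c(1, 1, 1, 1), 2))$p.value, 1.0)
  # margins (2,2)/(2,2): three tables, observed diagonal one has p 1/3
  expect_equal(association_test(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3,
               tolerance = 1e-12)
  expect_warning(res <- association_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(res$p.value, 1.0)
  expect_error(association_test(matrix(1:3, 3, 1)), "2x2")
  set.seed(8)
  for (i in 1:50) {
    tab <- random_2x2()
    expect_equal(association_test(tab)$p.value, fisher_2x2_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("large r x c tables fall back to a seeded Monte-Carlo p", {
  tab <- matrix(c(40, 35, 52, 61, 38, 47, 55, 33, 60, 42, 39, 58), 3)
  res1 <- association_test(tab, exact_limit = 100)
  res2 <- association_test(tab, exact_limit = 100)
  expect_equal(res1$method, "monte-carlo")
  expect_identical(res1$p.value, res2$p.value)
  expect_true(res1$p.value > 0 && res1$p.value <= 1)
})

test_that("cross_table aligns on shared sample names", {
  a <- c(s1 = "hot", s2 = "cold", s3 = "cold")
  b <- c(s3 = "g1", s1 = "g2", s2 = "g1")
  tab <- cross_table(a, b)
  expect_equal(tab["cold", "g1"], 2)
  expect_equal(tab["hot", "g2"], 1)
})
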