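test_that("maximal enrichment gives the hypergeometric point mass", {
  universe <- paste0("g", 1:100)
  cat <- list(hit = universe[1:10], other = universe[11:30])
  res <- enrich(sig = universe[1:10], universe = universe, catalog = cat)
  expect_equal(res$p[res$category == "hit"], 1 / choose(100, 10),
               tolerance = 1e-12)
  expect_equal(res$direction[res$category == "hit"], "enriched")
})

test_that("an empty significant set yields p = 1 everywhere", {
  universe <- paste0("g", 1:30)
  cat <- list(a = universe[1:5], b = universe[6:20])
  res <- suppressWarnings(enrich(character(0), universe, cat))
  expect_true(all(res$p == 1))
})

test_that("enrichment validates the universe and skips non-overlapping sets", {
  universe <- paste0("g", 1:20)
  expect_error(enrich("zzz", universe, list(a = universe[1:3])), "zzz")
  expect_warning(res <- enrich(universe[1:2], universe,
                               list(a = universe[1:5], empty = c("x1", "x2"))),
                 "empty")
  expect_equal(res$category, "a")
})

test_that("enrich p equals the shared exact-test core on the same 2x2 table", {
  set.seed(71)
  universe <- paste0("g", 1:40)
  for (i in 1:25) {
    sig <- sample(universe, sample(1:20, 1))
    set <- sample(universe, sample(2:25, 1))
    res <- enrich(sig, universe, list(s = set))
    a <- length(intersect(sig, set)); b <- length(sig) - a
    c_ <- length(set) - a; d <- 40 - a - b - c_
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expect_equal(res$p, suppressWarnings(association_test(tab)$p.value),
                 tolerance = 1e-12)
    expect_equal(res$p, fisher_2x2_oracle_safe(tab), tolerance = 1e-10)
  }
})

test_that("BH across categories preserves the raw-p order", {
  set.seed(72)
  universe <- paste0("g", 1:60)
  cat <- lapply(1:8, function(i) sample(universe, 12))
  names(cat) <- paste0("c", 1:8)
  res <- enrich(sample(universe, 15), universe, cat)
  o <- order(res$p)
  expect_true(all(diff(res$p_adj[o]) >= -1e-15))
})

test_that("null significant sets give approximately uniform enrichment p", {
  set.seed(73)
  universe <- paste0("g", 1:200)
  cat <- list(s = universe[1:40])
  ps <- replicate(300, enrich(sample(universe, 50), universe, cat)$p)
  # discrete test, so compare against its own null by simulation-free bound:
  # uniformity up to discreteness -> KS distance moderate
  ks <- suppressWarnings(stats::ks.test(ps, "punif")$statistic)
  expect_lt(unname(ks), 0.2)
  expect_gt(mean(ps < 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps < 0.05), 0.1)
})

test_that("pathway coverage reproduces set arithmetic and rounded percents", {
  panel <- paste0("p", 1:150)
  pathway <- c(panel[1:150], paste0("x", 1:381))   # 150 of 531 covered
  cov <- pathway_coverage(pathway, panel,
                          de_sets = list(cmp1 = panel[1:30], cmp2 = panel[20:28]))
  expect_equal(cov$n_annotated, 531)
  expect_equal(cov$n_covered, 150)
  expect_equal(cov$coverage_percent, 28)
  expect_equal(cov$n_de_total, 30)

  full <- pathway_coverage(paste0("p", 1:10), panel)
  expect_equal(full$coverage_percent, 100)
  none <- pathway_coverage(paste0("y", 1:10), panel,
                           de_sets = list(a = panel[1:5]))
  expect_equal(none$n_covered, 0)
  expect_equal(none$per_comparison$n_de, 0L)
})
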