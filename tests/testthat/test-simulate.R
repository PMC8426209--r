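test_that("default cohort has the study bookkeeping and is seed-deterministic", {
  cfg <- simulation_config(seed = 7)
  sim <- simulate_cohort(cfg)
  expect_equal(ncol(sim$counts), 98)
  expect_equal(nrow(sim$counts), 770 + 20 + 8 + 6)
  expect_equal(unname(table(sim$samples$group)[names(cfg$group_sizes)]),
               unname(cfg$group_sizes), ignore_attr = TRUE)
  expect_equal(nrow(sim$truth$samples), 98)

  sim2 <- simulate_cohort(cfg)
  expect_identical(sim, sim2)

  # different seed, different draw
  sim3 <- simulate_cohort(simulation_config(seed = 8))
  expect_false(identical(sim$counts, sim3$counts))
})

test_that("written cohorts are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_config(seed = 42)
  write_cohort(simulate_cohort(cfg), d1, rcc = TRUE)
  write_cohort(simulate_cohort(cfg), d2, rcc = TRUE)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("a planted log2 effect is recovered in normalized group means", {
  eff <- data.frame(gene_id = "GENE0005", group_a = "A", group_b = "D",
                    log2fc = 1.0, stringsAsFactors = FALSE)
  cfg <- small_config(seed = 5, planted_effects = eff,
                      group_sizes = c(A = 20L, B = 6L, C = 8L, D = 20L))
  sim <- simulate_cohort(cfg)
  norm <- normalize_counts(sim$counts, sim$probes)
  grp <- align_groups(sim$samples, colnames(norm))
  diff <- mean(norm["GENE0005", grp == "A"]) - mean(norm["GENE0005", grp == "D"])
  expect_lt(abs(diff - 1.0), 0.35)
})

test_that("marker genes track their population's latent abundance; baselines do not", {
  sim <- simulate_cohort(simulation_config(seed = 21))
  norm <- normalize_counts(sim$counts, sim$probes)
  truth <- sim$truth
  marker_rows <- truth$genes[!is.na(truth$genes$population) &
                               truth$genes$probe_class == "endogenous", ]
  rho_m <- vapply(seq_len(nrow(marker_rows)), function(i)
    stats::cor(norm[marker_rows$gene_id[i], ],
               truth$latent[marker_rows$population[i], ], method = "spearman"),
    numeric(1))
  expect_gte(min(rho_m), 0.6)

  base <- grep("^GENE", rownames(norm), value = TRUE)[1:50]
  rho_b <- vapply(base, function(g)
    stats::cor(norm[g, ], truth$latent["T_cells", ], method = "spearman"),
    numeric(1))
  expect_lte(stats::median(abs(rho_b)), 0.2)
})

test_that("housekeeping expression is independent of hot/cold state", {
  nonsig <- 0L; reps <- 10
  for (i in seq_len(reps)) {
    sim <- simulate_cohort(simulation_config(seed = 300 + i))
    hk <- sim$counts[sim$probes$probe_class == "housekeeping", , drop = FALSE]
    gm <- apply(hk + 0.5, 2, geometric_mean) / sim$truth$samples$lib_factor
    p <- stats::wilcox.test(gm[sim$truth$samples$state == "hot"],
                            gm[sim$truth$samples$state == "cold"])$p.value
    nonsig <- nonsig + (p >= 0.05)
  }
  expect_gte(nonsig / reps, 0.9)
})

test_that("null cohorts equalize hot fractions and drop planted effects", {
  eff <- data.frame(gene_id = "GENE0001", group_a = "A", group_b = "B",
                    log2fc = 2, stringsAsFactors = FALSE)
  cfg <- small_config(seed = 9, planted_effects = eff)
  nul <- simulate_null(cfg)
  expect_null(nul$truth$effects)
  # with equal hot fractions, the group/state association should be null;
  # check the generative inputs directly
  cfg2 <- cfg; cfg2$planted_effects <- NULL
  cfg2$infiltration$hot_fraction[] <- mean(cfg$infiltration$hot_fraction)
  expect_identical(nul$counts, simulate_cohort(cfg2)$counts)
})

test_that("config validation rejects malformed designs", {
  expect_error(simulation_config(group_sizes = c(A = 1L, B = 5L)), ">= 2")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(
    infiltration = list(hot_mean = 2, cold_mean = 0, sd = 1, hot_fraction = 1.5)),
    "hot_fraction")
  expect_error(simulation_config(n_genes = 10), "marker genes")
  expect_error(simulate_cohort(small_config(planted_effects = data.frame(
    gene_id = "NOPE", group_a = "A", group_b = "B", log2fc = 1))),
    "not in panel")
})
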