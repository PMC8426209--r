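#' Simulation configuration
#'
#' Describes a synthetic targeted-panel cohort with known ground truth. The
#' defaults emulate the study design the package is built around: 98 lung
#' adenocarcinomas in four driver-defined groups (19 ERBB2-Ex20mut, 13
#' EGFR-Ex20mut, 40 EGFR-Ex18/19/21mut, 26 EGFR/ERBB2wt), a 770-gene
#' immune-focused endogenous panel, a latent two-state (hot/cold) immune
#' infiltration driving correlated marker-gene expression, and optional
#' planted group-contrast effects on non-marker genes.
#'
#' The infiltration model is a two-state mixture on the latent log2 scale:
#' each sample is hot with its group's `hot_fraction`, and each immune
#' population's latent abundance is Normal(state mean, `sd`). Defaults put
#' the hot and cold means 2 latent SD apart; per-group hot fractions default
#' to the observed hot/cold split of the study cohort (6/19, 3/13, 16/40,
#' 17/26).
#'
#' @param group_sizes named integer vector of samples per group.
#' @param n_genes number of endogenous genes (marker genes included).
#' @param n_housekeeping,n_neg_controls,n_pos_controls control probe counts.
#' @param marker_catalog named list of marker symbols per population; these
#'   symbols are used as gene ids of the marker genes.
#' @param infiltration list with `hot_mean`, `cold_mean`, `sd` (latent log2
#'   scale) and `hot_fraction` (single value or named per group).
#' @param planted_effects data.frame with columns `gene_id`, `group_a`,
#'   `group_b`, `log2fc`: samples of `group_a` get `log2fc` added to the
#'   gene's log2 mean, so the planted A-vs-B log2 difference equals `log2fc`.
#' @param dispersion negative-binomial dispersion (1/size); 0.1 is typical
#'   FFPE-panel overdispersion and gives ~0.5 log2 within-group SD at median
#'   panel counts.
#' @param library_size_sd SD (log2 scale) of the per-sample multiplicative
#'   library factor.
#' @param baseline_log2_range range of endogenous baseline log2 means.
#' @param seed master seed; all randomness flows from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(group_sizes = c("ERBB2-Ex20mut" = 19L,
                                              "EGFR-Ex20mut" = 13L,
                                              "EGFR-Ex18/19/21mut" = 40L,
                                              "EGFR/ERBB2wt" = 26L),
                              n_genes = 770L,
                              n_housekeeping = 20L,
                              n_neg_controls = 8L,
                              n_pos_controls = 6L,
                              marker_catalog = read_marker_catalog(),
                              infiltration = list(
                                hot_mean = 2, cold_mean = 0, sd = 1,
                                hot_fraction = c("ERBB2-Ex20mut" = 6 / 19,
                                                 "EGFR-Ex20mut" = 3 / 13,
                                                 "EGFR-Ex18/19/21mut" = 16 / 40,
                                                 "EGFR/ERBB2wt" = 17 / 26)),
                              planted_effects = NULL,
                              dispersion = 0.1,
                              library_size_sd = 0.2,
                              baseline_log2_range = c(5, 10),
                              seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be named", call. = FALSE)
  if (any(group_sizes < 2)) stop("each group needs >= 2 samples", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  hf <- infiltration$hot_fraction
  if (length(hf) == 1) hf <- stats::setNames(rep(hf, length(group_sizes)), names(group_sizes))
  if (!all(names(group_sizes) %in% names(hf)))
    stop("hot_fraction must cover every group", call. = FALSE)
  if (any(hf < 0 | hf > 1)) stop("hot_fraction must lie in [0,1]", call. = FALSE)
  infiltration$hot_fraction <- hf[names(group_sizes)]
  n_markers <- length(unique(unlist(marker_catalog)))
  if (n_genes < n_markers)
    stop("n_genes (", n_genes, ") smaller than the number of marker genes (",
         n_markers, ")", call. = FALSE)
  if (!is.null(planted_effects)) {
    need <- c("gene_id", "group_a", "group_b", "log2fc")
    if (!all(need %in% colnames(planted_effects)))
      stop("planted_effects needs columns ", paste(need, collapse = ", "), call. = FALSE)
    bad <- setdiff(c(planted_effects$group_a, planted_effects$group_b), names(group_sizes))
    if (length(bad) > 0) stop("planted effect on unknown group: ",
                              paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(group_sizes = group_sizes, n_genes = as.integer(n_genes),
                 n_housekeeping = as.integer(n_housekeeping),
                 n_neg_controls = as.integer(n_neg_controls),
                 n_pos_controls = as.integer(n_pos_controls),
                 marker_catalog = marker_catalog, infiltration = infiltration,
                 planted_effects = planted_effects, dispersion = dispersion,
                 library_size_sd = library_size_sd,
                 baseline_log2_range = baseline_log2_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a panel cohort with known ground truth
#'
#' Generative model, in draw order (all randomness under the master seed):
#' (1) endogenous/housekeeping baseline log2 means; (2) per-sample hot/cold
#' state by the group's hot fraction; (3) latent log2 abundance per immune
#' population, Normal(state mean, sd); (4) per-sample library factors,
#' 2^Normal(0, library_size_sd); (5) counts. A marker gene's log2 mean is
#' its baseline plus its population's latent abundance (slope fixed at 1, so
#' the score scale is the latent scale); non-marker endogenous genes use
#' baseline plus any planted contrast effect; housekeeping genes are
#' unaffected by state or effects; endogenous and housekeeping counts are
#' negative binomial with mean `2^log2mean * library factor`; negative
#' controls are low-mean Poisson; positive controls follow a fixed
#' geometric ladder times the library factor.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (probes x samples integer matrix), `probes`,
#'   `samples` (data.frame `sample_id`, `group`), and `truth` (list:
#'   `samples` with hot/cold state and library factor, `latent` populations
#'   x samples matrix, `genes` with baselines and marker population,
#'   `effects`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

#' Simulate a matched null cohort
#'
#' Identical generative model, but planted effects are removed and every
#' group shares the cohort-average hot fraction, so group labels carry no
#' signal (the latent infiltration structure itself is kept).
#'
#' @inheritParams simulate_cohort
#' @return as [simulate_cohort()].
#' @export
simulate_null <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  config$planted_effects <- NULL
  hf <- config$infiltration$hot_fraction
  w <- config$group_sizes / sum(config$group_sizes)
  config$infiltration$hot_fraction[] <- sum(hf * w)
  simulate_cohort(config)
}

simulate_cohort_impl <- function(config) {
  gs <- config$group_sizes
  n <- sum(gs)
  groups <- rep(names(gs), gs)
  sample_id <- sprintf("S%03d", seq_len(n))

  markers <- unique(unlist(config$marker_catalog))
  pop_of <- marker_population(config$marker_catalog)
  n_other <- config$n_genes - length(markers)
  gene_id <- c(markers, sprintf("GENE%04d", seq_len(n_other)))
  hk_id <- sprintf("HK%02d", seq_len(config$n_housekeeping))
  neg_id <- sprintf("NEG%02d", seq_len(config$n_neg_controls))
  pos_id <- sprintf("POS%02d", seq_len(config$n_pos_controls))
  probes <- data.frame(
    gene_id = c(gene_id, hk_id, neg_id, pos_id),
    probe_class = rep(c("endogenous", "housekeeping", "negative_control",
                        "positive_control"),
                      c(config$n_genes, config$n_housekeeping,
                        config$n_neg_controls, config$n_pos_controls)),
    stringsAsFactors = FALSE)

  eff <- config$planted_effects
  if (!is.null(eff)) {
    missing <- setdiff(eff$gene_id, gene_id)
    if (length(missing) > 0)
      stop_io("planted effect on gene(s) not in panel: ", paste(missing, collapse = ", "))
    if (any(eff$gene_id %in% markers))
      stop_io("planted effects must target non-marker genes")
  }

  # (1) baselines
  r <- config$baseline_log2_range
  base_endo <- stats::runif(config$n_genes, r[1], r[2])
  base_hk <- stats::runif(config$n_housekeeping, 7, 10)

  # (2) hot/cold states
  hf <- config$infiltration$hot_fraction[groups]
  state <- ifelse(stats::runif(n) < hf, "hot", "cold")

  # (3) latent abundances per population
  pops <- names(config$marker_catalog)
  mu_state <- ifelse(state == "hot", config$infiltration$hot_mean,
                     config$infiltration$cold_mean)
  latent <- matrix(stats::rnorm(length(pops) * n,
                                mean = rep(mu_state, each = length(pops)),
                                sd = config$infiltration$sd),
                   nrow = length(pops), dimnames = list(pops, sample_id))

  # (4) library factors
  libf <- 2^stats::rnorm(n, 0, config$library_size_sd)

  # per-gene x sample log2 means
  log2mu <- matrix(base_endo, nrow = config$n_genes, ncol = n,
                   dimnames = list(gene_id, sample_id))
  is_marker <- gene_id %in% markers
  log2mu[is_marker, ] <- log2mu[is_marker, , drop = FALSE] +
    latent[pop_of[gene_id[is_marker]], , drop = FALSE]
  if (!is.null(eff)) {
    for (k in seq_len(nrow(eff))) {
      in_a <- groups == eff$group_a[k]
      log2mu[eff$gene_id[k], in_a] <- log2mu[eff$gene_id[k], in_a] + eff$log2fc[k]
    }
  }

  # (5) counts
  size <- 1 / config$dispersion
  mu_endo <- sweep(2^log2mu, 2, libf, `*`)
  cnt_endo <- matrix(stats::rnbinom(length(mu_endo), mu = mu_endo, size = size),
                     nrow = nrow(mu_endo))
  mu_hk <- outer(2^base_hk, libf)
  cnt_hk <- matrix(stats::rnbinom(length(mu_hk), mu = mu_hk, size = size),
                   nrow = nrow(mu_hk))
  cnt_neg <- matrix(stats::rpois(config$n_neg_controls * n, lambda = 2),
                    nrow = config$n_neg_controls)
  ladder <- 2^seq(12, 2, length.out = config$n_pos_controls)
  mu_pos <- outer(ladder, libf)
  cnt_pos <- matrix(stats::rpois(length(mu_pos), lambda = mu_pos),
                    nrow = nrow(mu_pos))

  counts <- rbind(cnt_endo, cnt_hk, cnt_neg, cnt_pos)
  mode(counts) <- "integer"
  dimnames(counts) <- list(probes$gene_id, sample_id)

  truth <- list(
    samples = data.frame(sample_id = sample_id, group = groups, state = state,
                         lib_factor = libf, stringsAsFactors = FALSE),
    latent = latent,
    genes = data.frame(gene_id = probes$gene_id,
                       probe_class = probes$probe_class,
                       baseline_log2 = c(base_endo, base_hk,
                                         rep(NA_real_, config$n_neg_controls +
                                               config$n_pos_controls)),
                       population = c(ifelse(is_marker, pop_of[gene_id], NA_character_),
                                      rep(NA_character_, nrow(probes) - config$n_genes)),
                       stringsAsFactors = FALSE),
    effects = eff)

  list(counts = counts, probes = probes,
       samples = truth$samples[, c("sample_id", "group")], truth = truth)
}

marker_population <- function(catalog) {
  pop <- rep(names(catalog), lengths(catalog))
  sym <- unlist(catalog, use.names = FALSE)
  # a symbol listed for several populations keeps its first assignment
  keep <- !duplicated(sym)
  stats::setNames(pop[keep], sym[keep])
}

#' Write a simulated cohort to disk
#'
#' Emits `counts.tsv`, `probes.tsv`, `samples.tsv`, `truth_samples.tsv`,
#' `truth_latent.tsv`, `truth_genes.tsv` (and `truth_effects.tsv` when
#' effects were planted), optionally plus one RCC file per sample.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory.
#' @param rcc also write per-sample RCC files under `dir/rcc/`.
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(sim, dir, rcc = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_tsv(sim$probes, file.path(dir, "probes.tsv"))
  write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  write_tsv(sim$truth$samples, file.path(dir, "truth_samples.tsv"))
  write_tsv(sim$truth$latent, file.path(dir, "truth_latent.tsv"), id_col = "population")
  write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  if (!is.null(sim$truth$effects))
    write_tsv(sim$truth$effects, file.path(dir, "truth_effects.tsv"))
  if (rcc) write_rcc(sim$counts, sim$probes, file.path(dir, "rcc"))
  invisible(dir)
}
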