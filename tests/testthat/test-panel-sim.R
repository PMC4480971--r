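test_that("identical seeds reproduce the simulation bit for bit", {
  cfg <- simulation_config(n_genes = 50, n_driver_genes = 5,
                           n_cell_lines = 30, seed = 77)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$resp$ic50_log2, b$resp$ic50_log2)
  expect_identical(a$truth$true_weights, b$truth$true_weights)
  ca <- simulate_clinical_cohort(a$truth, cfg)
  cb <- simulate_clinical_cohort(b$truth, cfg)
  expect_identical(ca$expr, cb$expr)
  expect_identical(ca$pfs_months, cb$pfs_months)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_genes = 10, n_driver_genes = 11),
               "n_driver_genes")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(censor_rate = 1), "censor_rate")
  expect_error(simulation_config(n_driver_genes = 3, driver_ids = c(1, 2)),
               "driver_ids")
})

test_that("non-driver genes have true weight exactly zero", {
  sim <- small_sim()
  w <- sim$truth$true_weights
  expect_identical(unname(w[!names(w) %in% sim$truth$driver_gene_ids]),
                   rep(0, length(w) - length(sim$truth$driver_gene_ids)))
  expect_true(all(w[sim$truth$driver_gene_ids] != 0))
})

test_that("zero effect size leaves expression uncorrelated with IC50", {
  cfg <- simulation_config(n_genes = 200, n_driver_genes = 5,
                           n_cell_lines = 200, driver_effect_size = 0,
                           seed = 13)
  sim <- simulate_panel(cfg)
  r <- as.vector(cor(t(sim$expr), sim$resp$ic50_log2))
  expect_lt(mean(abs(r)), 2 / sqrt(200))
})

test_that("a single noiseless driver is perfectly correlated with IC50", {
  cfg <- simulation_config(n_genes = 50, n_driver_genes = 1,
                           n_cell_lines = 60, driver_effect_size = 0.5,
                           noise_sd = 1e-9, seed = 3)
  sim <- simulate_panel(cfg)
  r <- cor(sim$expr[sim$truth$driver_gene_ids, ], sim$resp$ic50_log2)
  expect_equal(abs(r), 1, tolerance = 1e-6)
})

test_that("bimodal panels have a valley that recovers the subpopulations", {
  cfg <- simulation_config(n_genes = 300, n_driver_genes = 4,
                           n_cell_lines = 200, driver_effect_size = 0.5,
                           noise_sd = 0.5, ic50_mode = "bimodal",
                           bimodal_gap = 5, seed = 11)
  sim <- simulate_panel(cfg)
  cut <- response_cutoff(sim$resp$ic50_log2, method = "valley")
  lab <- sim$resp$ic50_log2 < cut$value
  agree <- max(mean(lab == (sim$truth$group == 0)),
               mean(lab == (sim$truth$group == 1)))
  expect_gte(agree, 0.95)
})

test_that("log2 IC50 marginals track the configured center and SD", {
  stats <- t(sapply(1:50, function(s) {
    sim <- simulate_panel(simulation_config(
      n_genes = 60, n_driver_genes = 6, n_cell_lines = 80,
      ic50_center = 2, seed = s))
    c(m = mean(sim$resp$ic50_log2), s = sd(sim$resp$ic50_log2),
      e = sim$truth$expected_ic50_sd)
  }))
  se_mean <- sd(stats[, "m"]) / sqrt(50)
  expect_lt(abs(mean(stats[, "m"]) - 2), 3 * se_mean)
  ratio <- stats[, "s"] / stats[, "e"]
  se_ratio <- sd(ratio) / sqrt(50)
  expect_lt(abs(mean(ratio) - 1), 3 * se_ratio)
})

test_that("platform shift is an exact additive offset with a full probe map", {
  cfg0 <- simulation_config(n_genes = 40, n_driver_genes = 4,
                            n_cell_lines = 30, n_patients = 25,
                            platform_shift = 0, seed = 8)
  cfg5 <- simulation_config(n_genes = 40, n_driver_genes = 4,
                            n_cell_lines = 30, n_patients = 25,
                            platform_shift = 5, seed = 8)
  truth <- simulate_panel(cfg0)$truth
  c0 <- simulate_clinical_cohort(truth, cfg0)
  c5 <- simulate_clinical_cohort(truth, cfg5)
  expect_equal(unclass(c5$expr) - 5, unclass(c0$expr),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(nrow(c0$map), nrow(c0$expr))
  expect_identical(sub("^P2_", "", c0$map$source_id), c0$map$target_id)
})

test_that("no survival signal is generated when pfs_link is zero", {
  pvals <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 30, n_driver_genes = 3,
                             n_cell_lines = 30, n_patients = 120,
                             pfs_link = 0, censor_rate = 0.1, seed = s)
    sim <- simulate_panel(cfg)
    co <- simulate_clinical_cohort(sim$truth, cfg)
    cls <- ifelse(co$true_sensitive, "sensitive", "resistant")
    survival_stratify(cls, co$pfs_months, co$event)$logrank_p
  })
  # p-values roughly uniform: no excess of small values, wide spread
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals < 0.05), 0.25)
})

test_that("Cox recovers a designed hazard ratio of 0.5 between groups", {
  # bimodal truth puts the standardized sensitivity score ~1 unit either
  # side of zero, so pfs_link = log(2)/2 targets HR 0.5 (sensitive vs
  # resistant)
  cfg <- simulation_config(n_genes = 100, n_driver_genes = 4,
                           n_cell_lines = 50, driver_effect_size = 0.5,
                           noise_sd = 0.5, ic50_mode = "bimodal",
                           bimodal_gap = 6, n_patients = 500,
                           pfs_link = log(2) / 2, censor_rate = 0.15,
                           seed = 21)
  sim <- simulate_panel(cfg)
  co <- simulate_clinical_cohort(sim$truth, cfg)
  cls <- ifelse(co$true_sensitive, "sensitive", "resistant")
  s <- survival_stratify(cls, co$pfs_months, co$event)
  expect_gte(s$hazard_ratio, 0.40)
  expect_lte(s$hazard_ratio, 0.62)
})

test_that("simulated gene sets include the driver pathway", {
  sim <- small_sim()
  sets <- simulate_gene_sets(sim$truth, n_sets = 5, set_size = 20, seed = 2)
  expect_true(all(toupper(sim$truth$driver_gene_ids) %in%
                    sets$DRIVER_PATHWAY))
  expect_length(sets, 5)
})

test_that("a simulated study round-trips through the text formats", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_genes = 30, n_driver_genes = 3,
                           n_cell_lines = 20, n_patients = 15, seed = 4)
  sim <- simulate_panel(cfg)
  co <- simulate_clinical_cohort(sim$truth, cfg)
  sets <- simulate_gene_sets(sim$truth, n_sets = 3, set_size = 10, seed = 1)
  write_simulation(sim, co, dir, gene_sets = sets)
  expr2 <- read_expr_tsv(file.path(dir, "expression.tsv"))
  resp2 <- read_ic50_tsv(file.path(dir, "ic50.tsv"))
  expect_equal(unclass(expr2), unclass(sim$expr), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(resp2$ic50_log2, sim$resp$ic50_log2, tolerance = 1e-9)
  map2 <- read_probe_map_tsv(file.path(dir, "probe_map.tsv"))
  expect_identical(map2$source_id, co$map$source_id)
  sets2 <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_identical(sort(sets2$DRIVER_PATHWAY), sort(sets$DRIVER_PATHWAY))
})
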