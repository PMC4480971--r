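#' Configuration for the synthetic drug-response study
#'
#' The generator emulates the statistical structure of a cell-line
#' drug-sensitivity study: a log2 expression matrix whose driver genes
#' share a latent co-expression factor, log2 IC50 values that are a linear
#' combination of driver-gene expression plus noise (normal-like, or
#' bimodal with two subpopulations separated by `bimodal_gap` log2 units),
#' a clinical cohort on a distorted second platform, and progression-free
#' survival coupled to the true sensitivity score.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_driver_genes Number of driver genes (default 30).
#' @param n_cell_lines Panel size (default 200).
#' @param driver_effect_size Per-gene contribution of centered driver
#'   expression to log2 IC50 (default 0.5).
#' @param noise_sd SD of the additive log2 IC50 noise (default 1), > 0.
#' @param ic50_mode `"normal_like"` or `"bimodal"`.
#' @param bimodal_gap Distance between the two log2 IC50 mode centers
#'   (default 5; bimodal mode only).
#' @param n_patients Clinical cohort size (default 200).
#' @param platform_shift Additive log2 offset applied to the second
#'   platform (default 1).
#' @param pfs_link Log hazard ratio per unit of standardized true
#'   sensitivity score (default 1: higher IC50 score, earlier progression).
#' @param censor_rate Fraction of patients censored, in \[0, 1)
#'   (default 0.2).
#' @param seed Integer master seed; identical seeds give identical outputs.
#' @param driver_module_size Drivers are grouped into co-expression modules
#'   of this size, each sharing its own latent factor (default 5); genes
#'   within a module are mutually correlated the way co-regulated pathway
#'   members are, while different modules carry independent signal.
#' @param driver_ids Optional explicit gene indices to use as drivers
#'   (lets two drugs be simulated with disjoint driver sets).
#' @param map_fraction Fraction of second-platform features present in the
#'   generated best-match table (default 1).
#' @param ic50_center Center of the log2 IC50 distribution (default 0).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_driver_genes = 30,
                              n_cell_lines = 200, driver_effect_size = 0.5,
                              noise_sd = 1, ic50_mode = c("normal_like", "bimodal"),
                              bimodal_gap = 5, n_patients = 200,
                              platform_shift = 1, pfs_link = 1,
                              censor_rate = 0.2, seed = 1,
                              driver_module_size = 5,
                              driver_ids = NULL, map_fraction = 1,
                              ic50_center = 0) {
  ic50_mode <- match.arg(ic50_mode)
  if (n_driver_genes > n_genes)
    stop("n_driver_genes must not exceed n_genes")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (!is.null(driver_ids)) {
    driver_ids <- as.integer(driver_ids)
    if (length(driver_ids) != n_driver_genes ||
        any(driver_ids < 1L | driver_ids > n_genes))
      stop("driver_ids must be n_driver_genes valid gene indices")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_driver_genes = as.integer(n_driver_genes),
                 n_cell_lines = as.integer(n_cell_lines),
                 driver_effect_size = driver_effect_size,
                 noise_sd = noise_sd, ic50_mode = ic50_mode,
                 bimodal_gap = bimodal_gap,
                 n_patients = as.integer(n_patients),
                 platform_shift = platform_shift, pfs_link = pfs_link,
                 censor_rate = censor_rate, seed = as.integer(seed),
                 driver_module_size = max(1L, as.integer(driver_module_size)),
                 driver_ids = driver_ids, map_fraction = map_fraction,
                 ic50_center = ic50_center),
            class = "simulation_config")
}

# per-module latent sensitivity factors (modules x samples); for a bimodal
# panel every factor carries the same two-component mixture shift, chosen so
# the induced log2 IC50 modes sit bimodal_gap apart
draw_latent <- function(cfg, n, n_modules) {
  total <- cfg$driver_effect_size * cfg$n_driver_genes
  if (cfg$ic50_mode == "bimodal") {
    gap_z <- if (total > 0) cfg$bimodal_gap / total else cfg$bimodal_gap
    group <- stats::rbinom(n, 1L, 0.5)
    shift <- (group - 0.5) * gap_z
    z <- matrix(stats::rnorm(n_modules * n, 0, 0.1 * abs(gap_z)),
                n_modules, n, byrow = FALSE) +
      matrix(shift, n_modules, n, byrow = TRUE)
    list(z = z, group = group)
  } else {
    list(z = matrix(stats::rnorm(n_modules * n), n_modules, n),
         group = rep(NA_integer_, n))
  }
}

# driver residual SD on the expression scale
DRIVER_EXPR_NOISE <- 0.5

driver_modules <- function(cfg) {
  n_mod <- ceiling(cfg$n_driver_genes / cfg$driver_module_size)
  rep(seq_len(n_mod), each = cfg$driver_module_size)[seq_len(cfg$n_driver_genes)]
}

draw_expression <- function(cfg, truth, z, sample_ids) {
  n <- length(sample_ids)
  G <- cfg$n_genes
  e <- matrix(stats::rnorm(G * n, 0, 1), G, n) * truth$gene_sd
  e[truth$driver_idx, ] <- stats::rnorm(length(truth$driver_idx) * n, 0,
                                        DRIVER_EXPR_NOISE)
  m <- truth$baseline + e
  m[truth$driver_idx, ] <- m[truth$driver_idx, ] +
    truth$driver_signs * z[truth$module, , drop = FALSE]
  dimnames(m) <- list(truth$gene_ids, sample_ids)
  m
}

#' Simulate a training panel with known ground truth
#'
#' Generates gene expression (per-gene normal baseline; driver genes share
#' the latent sensitivity factor, so they are mutually correlated the way
#' pathway co-expression is), and log2 IC50 as the weighted sum of centered
#' driver expression plus `noise_sd` noise:
#' `log2(IC50) = center + sum_g w_g (x_g - mu_g) + noise`, with true weight
#' `w_g = +/- driver_effect_size` for drivers (half resistance-, half
#' sensitivity-directed) and exactly 0 otherwise.
#'
#' @param cfg A [simulation_config()].
#' @return List with `expr` (expression matrix), `resp`
#'   ([response_panel()]), and `truth`: `driver_gene_ids`, `true_weights`
#'   (full named vector), `true_score` per sample (the noiseless signal
#'   part), `group` (bimodal subpopulation, if any), `baseline`, and the
#'   analytic `expected_ic50_mean` / `expected_ic50_sd` implied by the
#'   configuration.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("CL%04d", seq_len(cfg$n_cell_lines))

  driver_idx <- if (is.null(cfg$driver_ids))
    sort(sample.int(cfg$n_genes, cfg$n_driver_genes)) else sort(cfg$driver_ids)
  signs <- rep(c(1, -1), length.out = cfg$n_driver_genes)
  baseline <- stats::rnorm(cfg$n_genes, 7, 1.5)
  # drivers are modeled as well-expressed genes: the intensity/variance
  # reduction is meant to discard unexpressed, invariant features, and true
  # drivers of drug response are assumed to sit in the expressed fraction
  baseline[driver_idx] <- stats::rnorm(cfg$n_driver_genes, 9, 0.8)
  gene_sd <- stats::runif(cfg$n_genes, 0.6, 1.4)

  module <- driver_modules(cfg)
  truth <- list(gene_ids = gene_ids, driver_idx = driver_idx,
                driver_signs = signs, baseline = baseline, gene_sd = gene_sd,
                module = module)
  lat <- draw_latent(cfg, cfg$n_cell_lines, max(module))
  expr <- draw_expression(cfg, truth, lat$z, sample_ids)

  w <- stats::setNames(numeric(cfg$n_genes), gene_ids)
  w[driver_idx] <- cfg$driver_effect_size * signs
  signal <- drop(crossprod(expr - baseline, w))
  ic50_log2 <- cfg$ic50_center + signal +
    stats::rnorm(cfg$n_cell_lines, 0, cfg$noise_sd)
  resp <- response_panel(sample_ids, 2^ic50_log2, ic50_mode = cfg$ic50_mode)

  D <- cfg$n_driver_genes; eff <- cfg$driver_effect_size
  mod_sizes <- tabulate(module)
  # bimodal: the mixture shift is common to all module factors, the
  # within-mode factor noise is independent per module
  var_latent <- if (cfg$ic50_mode == "bimodal") {
    gap_z <- if (eff * D > 0) cfg$bimodal_gap / (eff * D) else cfg$bimodal_gap
    D^2 * (gap_z / 2)^2 + sum(mod_sizes^2) * (0.1 * gap_z)^2
  } else sum(mod_sizes^2)
  exp_sd <- sqrt(eff^2 * (var_latent + D * DRIVER_EXPR_NOISE^2) +
                 cfg$noise_sd^2)

  list(expr = expr_matrix(expr, platform = "platform1"),
       resp = resp,
       truth = list(gene_ids = gene_ids,
                    driver_gene_ids = gene_ids[driver_idx],
                    true_weights = w,
                    true_score = stats::setNames(signal, sample_ids),
                    group = stats::setNames(lat$group, sample_ids),
                    baseline = stats::setNames(baseline, gene_ids),
                    gene_sd = gene_sd, module = module,
                    driver_idx = driver_idx, driver_signs = signs,
                    expected_ic50_mean = cfg$ic50_center,
                    expected_ic50_sd = exp_sd,
                    config = cfg))
}

#' Simulate a clinical cohort on a second platform
#'
#' Draws `n_patients` new samples from the panel's generative model, adds
#' `platform_shift` to every log2 value, renames all features to
#' second-platform identifiers (`P2_<id>`) and generates the best-match
#' probe map covering `map_fraction` of them. Progression times are
#' exponential with log hazard `pfs_link x` standardized true sensitivity
#' score (baseline median PFS 3 months); a `censor_rate` fraction of
#' patients is administratively censored at a uniform time before their
#' event.
#'
#' @param truth The `truth` element returned by [simulate_panel()].
#' @param cfg The same [simulation_config()].
#' @return List: `expr` (shifted, renamed matrix), `map` ([probe_map()]),
#'   `pfs_months`, `event`, `true_score`, `true_sensitive` (logical, score
#'   below the cohort median or, for bimodal panels, the low mode).
#' @export
simulate_clinical_cohort <- function(truth, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, 7L))
  ids <- sprintf("PT%04d", seq_len(cfg$n_patients))
  lat <- draw_latent(cfg, cfg$n_patients, max(truth$module))
  expr <- draw_expression(cfg, truth, lat$z, ids)
  w <- truth$true_weights
  score <- drop(crossprod(expr - truth$baseline, w))

  sd_s <- stats::sd(score)
  score_std <- if (sd_s > 0) (score - mean(score)) / sd_s else score * 0
  rate <- log(2) / 3 * exp(cfg$pfs_link * score_std)
  t_event <- stats::rexp(cfg$n_patients, rate)
  censored <- stats::runif(cfg$n_patients) < cfg$censor_rate
  pfs <- ifelse(censored, stats::runif(cfg$n_patients, 0, t_event), t_event)
  pfs <- pmax(pfs, 0.05)

  p2_ids <- paste0("P2_", rownames(expr))
  shifted <- expr + cfg$platform_shift
  rownames(shifted) <- p2_ids
  n_map <- max(1L, round(cfg$map_fraction * nrow(expr)))
  mapped <- sort(sample.int(nrow(expr), n_map))
  map <- probe_map(p2_ids[mapped], rownames(expr)[mapped])

  sensitive <- if (cfg$ic50_mode == "bimodal") lat$group == 0L
               else score < stats::median(score)
  list(expr = expr_matrix(shifted, platform = "platform2"),
       map = map,
       pfs_months = stats::setNames(pfs, ids),
       event = stats::setNames(as.integer(!censored), ids),
       true_score = stats::setNames(score, ids),
       true_sensitive = stats::setNames(sensitive, ids))
}

#' Simulate 10-dose dose-response curves with planted QC violations
#'
#' Clean curves are 4-parameter-free Hill curves over a 3-fold dilution
#' series with replicate CVs drawn in the clean range. A chosen number of
#' curves per QC rule get a planted violation — missing points, high-CV
#' points, a non-monotone inversion, or inhibition only at the highest dose
#' — recorded in the returned `truth` table.
#'
#' @param cfg A [simulation_config()] (only `n_cell_lines` and `seed` are
#'   used).
#' @param n_per_violation Curves planted per rule (default 2).
#' @return List: `curves` (long data frame `cell_line_id`, `dose`,
#'   `mean_response`, `cv`) and `truth` (`cell_line_id`, `planted`).
#' @export
simulate_dose_response <- function(cfg, n_per_violation = 2) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, 11L))
  n <- cfg$n_cell_lines
  doses <- 0.005 * 3^(0:9)
  ids <- sprintf("CL%04d", seq_len(n))
  ic50 <- stats::rlnorm(n, log(stats::median(doses)), 1)
  hill <- function(d, ic) 100 / (1 + (ic / d)^1.2)

  curves <- do.call(rbind, lapply(seq_len(n), function(i) {
    resp <- hill(doses, ic50[i]) + stats::rnorm(10, 0, 1.5)
    data.frame(cell_line_id = ids[i], dose = doses,
               mean_response = pmin(pmax(resp, 0), 100),
               cv = stats::runif(10, 4, 18), stringsAsFactors = FALSE)
  }))

  planted <- rep("none", n)
  rules <- c("missing_points", "high_cv", "non_monotone", "last_dose_only")
  victims <- sample.int(n, min(n, length(rules) * n_per_violation))
  for (k in seq_along(victims)) {
    i <- victims[k]
    rule <- rules[(k - 1L) %/% n_per_violation + 1L]
    planted[i] <- rule
    rows <- which(curves$cell_line_id == ids[i])
    if (rule == "missing_points") {
      curves$mean_response[sample(rows, 3L)] <- NA
    } else if (rule == "high_cv") {
      curves$cv[sample(rows, 4L)] <- stats::runif(4, 35, 60)
    } else if (rule == "non_monotone") {
      # strong inhibition at a low dose, weak at higher doses
      curves$mean_response[rows] <- c(5, 10, 80, 30, 30, 35, 40, 45, 60, 80)
    } else {
      curves$mean_response[rows] <- c(stats::runif(9, 0, 6), 70)
    }
  }
  list(curves = curves,
       truth = data.frame(cell_line_id = ids, planted = planted,
                          stringsAsFactors = FALSE))
}

#' Generate synthetic pathway gene sets for a simulated panel
#'
#' One gene set contains the true drivers (padded with random genes up to
#' `set_size`); the remaining sets are random draws from the gene universe.
#'
#' @param truth The `truth` element of [simulate_panel()].
#' @param n_sets Total number of sets (default 10).
#' @param set_size Genes per set (default 40).
#' @param seed Integer seed.
#' @return A named list of gene-id vectors (class `pathway_collection`);
#'   the driver set is named `"DRIVER_PATHWAY"`.
#' @export
simulate_gene_sets <- function(truth, n_sets = 10, set_size = 40, seed = 1) {
  set.seed(seed)
  genes <- toupper(names(truth$true_weights))
  drivers <- toupper(truth$driver_gene_ids)
  pad <- sample(setdiff(genes, drivers),
                max(0L, set_size - length(drivers)))
  sets <- c(list(DRIVER_PATHWAY = c(drivers, pad)),
            lapply(seq_len(n_sets - 1L), function(i)
              sample(genes, set_size)))
  names(sets)[-1L] <- sprintf("RANDOM_SET_%02d", seq_len(n_sets - 1L))
  structure(sets, class = "pathway_collection")
}

#' Write a simulated study to disk as plain-text files
#'
#' Emits the training expression TSV, IC50 TSV, clinical TSV, probe-map
#' TSV, a synthetic GMT, and a ground-truth JSON under `dir`.
#'
#' @param sim Output of [simulate_panel()].
#' @param cohort Output of [simulate_clinical_cohort()].
#' @param dir Output directory (created if needed).
#' @param gene_sets Optional `pathway_collection` to write.
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, cohort, dir, gene_sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expr_tsv(sim$expr, file.path(dir, "expression.tsv"))
  write_ic50_tsv(sim$resp, file.path(dir, "ic50.tsv"))
  write_expr_tsv(cohort$expr, file.path(dir, "cohort_expression.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$pfs_months),
               pfs_months = cohort$pfs_months, event = cohort$event,
               group = ifelse(cohort$true_sensitive, "sensitive", "resistant")),
    file.path(dir, "clinical.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$map, file.path(dir, "probe_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gene_sets))
    write_gmt(gene_sets, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(
    list(driver_gene_ids = sim$truth$driver_gene_ids,
         true_weights = as.list(sim$truth$true_weights[sim$truth$true_weights != 0]),
         seed = sim$truth$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
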