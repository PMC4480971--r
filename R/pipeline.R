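#' Parameters of the full training pipeline
#'
#' Collects every stage parameter with its standard default: the 40%
#' intensity cutoff, variance cutoff 1, raw permutation p cutoff 0.01, the
#' 150 x 1000 split ensemble with 5 top sets and the 90% overlap null
#' quantile, forward selection from the 5 highest-weighted genes, and the
#' pathway enrichment gate at p < 0.01. Smaller ensembles (e.g. 10 x 100)
#' are appropriate for simulated panels.
#'
#' @param keep_fraction Intensity filter fraction (default 0.40).
#' @param min_variance Variance cutoff (default 1).
#' @param p_cutoff Feature-selection raw p cutoff (default 0.01).
#' @param n_perm Permutations for feature selection (default 1000).
#' @param n_outer,n_inner Ensemble size (defaults 150, 1000).
#' @param top_sets Number of top outer sets (default 5).
#' @param overlap_q Overlap null quantile (default 0.90).
#' @param overlap_n_perm Random pairs for the overlap null (default 10000).
#' @param start,eps,window Forward-selection parameters (defaults 5,
#'   0.005, 10).
#' @param pathway_p_cutoff Enrichment p cutoff (default 0.01).
#' @param cutoff_method Score-cutoff method for the final model
#'   (default `"auto"`).
#' @param manual_cutoff Manual score cutoff, if `cutoff_method = "manual"`.
#' @param delta Non-inferiority slack in [score_balanced_sets()]
#'   (default 0.02).
#' @param n_components PLS components (default 2).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(keep_fraction = 0.40, min_variance = 1,
                            p_cutoff = 0.01, n_perm = 1000,
                            n_outer = 150, n_inner = 1000, top_sets = 5,
                            overlap_q = 0.90, overlap_n_perm = 10000,
                            start = 5, eps = 0.005, window = 10,
                            pathway_p_cutoff = 0.01,
                            cutoff_method = "auto", manual_cutoff = NULL,
                            delta = 0.02, n_components = 2, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Train a drug-sensitivity signature end to end
#'
#' Runs the complete model-building workflow on a training panel:
#' data reduction (intensity then variance filter, optional probeset
#' collapsing), middle-tertile removal for normal-like IC50 distributions,
#' experimental-label assignment, permutation feature selection, the
#' balanced/random split ensemble with PLSR models, top-set scoring and
#' representative selection, overlap filtering against the Jaccard
#' permutation null, SVD consensus weights, forward selection to the core
#' signature, optional pathway filtering, and the final full-panel refit
#' with score-cutoff calibration. Stage-by-stage feature and sample counts
#' (the reduction funnel) are recorded and reported via messages.
#'
#' @param expr Training expression matrix, features x samples (log2).
#' @param resp A [response_panel()] for (a superset of) the same samples.
#' @param cfg A [pipeline_config()].
#' @param probe_to_gene Optional named probe-to-gene vector for
#'   [collapse_probesets()].
#' @param pathways Optional `pathway_collection`; when given, the core
#'   signature is filtered to significantly enriched pathways.
#' @return A `drugresp_fit` list: `signature` (`functional_signature`),
#'   `core`, `consensus`, `representatives`, `feature_stats`, `ranked_sets`,
#'   `funnel`, `reduced_expr`, `resp` and the configuration.
#' @export
run_train <- function(expr, resp, cfg = pipeline_config(),
                      probe_to_gene = NULL, pathways = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"), inherits(resp, "response_panel"))
  funnel <- c(input_features = nrow(expr))

  m <- reduce_by_intensity(expr, cfg$keep_fraction)
  funnel["after_intensity"] <- nrow(m)
  m <- reduce_by_variance(m, cfg$min_variance)
  funnel["after_variance"] <- nrow(m)
  if (!is.null(probe_to_gene)) {
    m <- collapse_probesets(m, probe_to_gene)
    funnel["after_collapse"] <- nrow(m)
  }
  if (nrow(m) < cfg$start) stop("data reduction left too few features")

  resp <- subset_panel(resp, resp$sample_id %in% colnames(m))
  n_before <- nrow(resp)
  resp <- remove_middle_tertile(resp)
  if (nrow(resp) < n_before)
    message("middle tertile removed: ", n_before, " -> ", nrow(resp), " samples")
  m <- m[, resp$sample_id, drop = FALSE]

  lab_method <- if (ic50_mode(resp) == "bimodal") "valley" else "median"
  exp_cutoff <- response_cutoff(resp$ic50_log2, method = lab_method)
  resp <- assign_labels(resp, exp_cutoff)
  message("experimental cutoff (", exp_cutoff$method, "): ",
          signif(exp_cutoff$value, 4))

  stats_tab <- permutation_feature_test(m, resp, n_perm = cfg$n_perm,
                                        seed = derive_seed(cfg$seed, 1L))
  genes <- select_features(stats_tab, cfg$p_cutoff)
  funnel["selected_features"] <- length(genes)
  message(length(genes), " feature gene(s) selected at p_raw < ", cfg$p_cutoff)

  scfg <- split_config(n_outer = cfg$n_outer, n_inner = cfg$n_inner,
                       seed = derive_seed(cfg$seed, 2L))
  ens <- build_ensemble(m, resp, genes, scfg, n_components = cfg$n_components)
  ranked <- score_balanced_sets(ens, delta = cfg$delta)
  reps <- pick_representatives(ens, ranked, m, resp, k = cfg$top_sets)

  null_q <- overlap_null_quantile(nrow(resp),
                                  length(reps[[1L]]$random_train),
                                  n_perm = cfg$overlap_n_perm,
                                  q = cfg$overlap_q,
                                  seed = derive_seed(cfg$seed, 3L))
  reps <- filter_overlapping(reps, null_q)
  message(length(reps), " non-overlapping top model(s); overlap null q",
          100 * cfg$overlap_q, " = ", signif(null_q, 3))

  consensus <- consensus_weights(reps)
  representative <- select_representative_model(reps, consensus)
  core <- forward_select_core(representative, consensus, m, resp,
                              start = cfg$start, eps = cfg$eps,
                              window = cfg$window,
                              n_components = cfg$n_components)
  funnel["core_genes"] <- length(core$core_genes)
  message("core signature: ", length(core$core_genes), " gene(s)")

  enrichment <- NULL
  sig_genes <- core$core_genes
  if (!is.null(pathways)) {
    enrichment <- enrich_pathways(core$core_genes, rownames(m), pathways)
    sig_genes <- select_functional_genes(core$core_genes, enrichment,
                                         pathways, consensus,
                                         cfg$pathway_p_cutoff)
    # functional genes are uppercased symbols; map back to matrix rownames
    sig_genes <- rownames(m)[match(sig_genes, toupper(rownames(m)))]
    funnel["functional_genes"] <- length(sig_genes)
    message("functional signature: ", length(sig_genes), " gene(s)")
  }

  signature <- fit_final_model(
    sig_genes, m, resp,
    cutoff_method = cfg$cutoff_method, manual_value = cfg$manual_cutoff,
    pathways_used = if (is.null(enrichment)) NULL else
      enrichment[enrichment$p < cfg$pathway_p_cutoff, , drop = FALSE],
    n_components = cfg$n_components)

  structure(list(signature = signature, core = core, consensus = consensus,
                 representatives = reps, representative = representative,
                 feature_stats = stats_tab, selected_genes = genes,
                 ranked_sets = ranked, ensemble_metrics = ens$metrics,
                 enrichment = enrichment, funnel = funnel,
                 reduced_expr = m, resp = resp, config = cfg),
            class = "drugresp_fit")
}

#' Evaluate a trained signature on a clinical cohort
#'
#' Maps the cohort's features onto the training platform (when a probe map
#' is supplied), quantile-normalizes the cohort against the training
#' reference on the whole shared feature space, classifies the patients
#' with the signature's calibrated cutoff, and computes confusion metrics
#' against dichotomized PFS plus the survival stratification.
#'
#' @param sig A `functional_signature` (e.g. `fit$signature`).
#' @param cohort_expr Cohort expression matrix, features x patients.
#' @param reference Training expression matrix used as normalization
#'   reference (e.g. `fit$reduced_expr`).
#' @param pfs_months,event PFS in months and progression indicator.
#' @param pfs_cutoff Responder cutoff in months.
#' @param map Optional [probe_map()] from cohort to training features.
#' @param tag `"matched"` or `"cross"`.
#' @param normalize Quantile-normalize the cohort against the reference
#'   (default `TRUE`; set `FALSE` for data already on the training scale,
#'   e.g. the training panel itself).
#' @return A `stratification_result` (see [evaluate_cohort()]).
#' @export
run_evaluate <- function(sig, cohort_expr, reference, pfs_months, event,
                         pfs_cutoff, map = NULL, tag = "matched",
                         normalize = TRUE) {
  m <- if (is.null(map)) cohort_expr else map_probes(cohort_expr, map)
  shared <- intersect(rownames(m), rownames(reference))
  if (length(shared) == 0L) stop("no shared features with the reference")
  m <- m[shared, , drop = FALSE]
  if (normalize)
    m <- reference_quantile_normalize(m, reference[shared, , drop = FALSE])
  cohort <- clinical_cohort(m, pfs_months, event)
  evaluate_cohort(sig, cohort, pfs_cutoff, tag = tag)
}
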