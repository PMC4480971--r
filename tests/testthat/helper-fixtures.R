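# Shared fixtures, built in code at load time.

# small deterministic expression matrix; `values` listed feature by feature
toy_expr <- function(values, features = NULL, samples = NULL) {
  nr <- if (!is.null(features)) length(features) else length(values) / 2
  m <- matrix(values, nrow = nr, byrow = TRUE)
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  expr_matrix(m)
}

# a small labelled training panel with genuine signal, reused across tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 300, n_driver_genes = 10,
                               n_cell_lines = 120, seed = 42)
      cache <<- c(simulate_panel(cfg), list(cfg = cfg))
    }
    cache
  }
})

# a tiny fitted ensemble on the small panel, reused across ensemble tests
small_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      resp <- remove_middle_tertile(sim$resp)
      resp <- assign_labels(resp, response_cutoff(resp$ic50_log2, "median"))
      expr <- sim$expr[, resp$sample_id]
      st <- suppressMessages(
        permutation_feature_test(expr, resp, n_perm = 200, seed = 5))
      genes <- select_features(st, 0.01)
      scfg <- split_config(n_outer = 4, n_inner = 30, seed = 9)
      ens <- build_ensemble(expr, resp, genes, scfg)
      cache <<- list(sim = sim, resp = resp, expr = expr, genes = genes,
                     ens = ens)
    }
    cache
  }
})

# fabricate a minimal plsr_model with given 2-component loadings
fake_model <- function(loadings, genes = NULL) {
  L <- as.matrix(loadings)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(L)))
  rownames(L) <- genes
  structure(list(gene_ids = genes, n_components = ncol(L), loadings = L,
                 coefficients = stats::setNames(rep(0, nrow(L)), genes),
                 intercept = 0,
                 center = stats::setNames(rep(0, nrow(L)), genes),
                 scale = stats::setNames(rep(1, nrow(L)), genes)),
            class = "plsr_model")
}

fake_record <- function(train_ids, loadings = cbind(c(3, 0), c(4, 1)),
                        corr_bv = 0.5, auc_bv = 0.5, genes = NULL) {
  structure(list(model = fake_model(loadings, genes),
                 random_train = train_ids,
                 corr_bv = corr_bv, auc_bv = auc_bv),
            class = "split_model_record")
}
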