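#' Evaluate PLSR models over the full split ensemble
#'
#' Runs the balanced/random splitting scheme: for every outer balanced
#' split and every inner random split, a PLSR model is fitted on the
#' random-training samples (restricted to the selected feature genes) and
#' scored on both held-out parts — random validation and balance
#' validation — by Pearson correlation between predicted and experimental
#' log2 IC50 and by ROC AUC against the panel's sensitive/resistant labels.
#' Models are not stored: any split's model is reconstructible from the
#' configuration seed and its `(outer_index, inner_index)`.
#'
#' @param expr Expression matrix, genes x samples.
#' @param resp A labelled [response_panel()] (see [assign_labels()]).
#' @param genes Feature genes to model (from [select_features()]).
#' @param cfg A [split_config()].
#' @param n_components PLS components (default 2).
#' @return A `split_ensemble` list: `metrics` (one row per split with
#'   `corr_rv`, `auc_rv`, `corr_bv`, `auc_bv`), plus `cfg`, `genes`,
#'   `n_components`.
#' @export
build_ensemble <- function(expr, resp, genes, cfg, n_components = 2) {
  stopifnot(inherits(resp, "response_panel"), inherits(cfg, "split_config"))
  if (all(is.na(resp$label))) stop("assign class labels to the panel first")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) stop("genes absent from expression matrix")
  X <- t(expr[genes, resp$sample_id, drop = FALSE])
  y <- stats::setNames(resp$ic50_log2, resp$sample_id)
  lab <- stats::setNames(resp$label, resp$sample_id)

  rows <- vector("list", cfg$n_outer * cfg$n_inner)
  k <- 0L
  for (i in seq_len(cfg$n_outer)) {
    outer <- balanced_split(resp, cfg, derive_seed(cfg$seed, i, 0L))
    bv <- outer$balance_val
    for (j in seq_len(cfg$n_inner)) {
      inner <- inner_random_split(outer$train, cfg,
                                  derive_seed(cfg$seed, i, j))
      fit <- fit_plsr(X[inner$random_train, , drop = FALSE],
                      y[inner$random_train], n_components = n_components)
      k <- k + 1L
      rows[[k]] <- data.frame(
        outer_index = i, inner_index = j,
        corr_rv = held_out_corr(fit, X, y, inner$random_val),
        auc_rv = held_out_auc(fit, X, lab, inner$random_val),
        corr_bv = held_out_corr(fit, X, y, bv),
        auc_bv = held_out_auc(fit, X, lab, bv))
    }
  }
  structure(list(metrics = do.call(rbind, rows), cfg = cfg, genes = genes,
                 n_components = n_components),
            class = "split_ensemble")
}

held_out_corr <- function(fit, X, y, ids) {
  pred <- predict(fit, X[ids, , drop = FALSE])
  if (stats::sd(pred) == 0 || stats::sd(y[ids]) == 0) return(NA_real_)
  stats::cor(pred, y[ids])
}

held_out_auc <- function(fit, X, lab, ids) {
  l <- lab[ids]
  if (length(unique(l)) < 2L) return(NA_real_)
  roc_auc(predict(fit, X[ids, , drop = FALSE]), l)
}

#' Score and rank the outer balanced-split sets
#'
#' Each outer set is summarized over its inner splits by the selection
#' criteria: the correlation structure of random-validation performance
#' (`c2`, Spearman correlation between per-split correlation and AUC), the
#' requirement that balance validation have a narrower performance spread
#' than random validation (`c3`, IQR ratio, must be below 1), a
#' non-inferiority check of balance-validation medians against
#' random-validation medians on both metrics (`c4`, slack `delta`), and the
#' overall balance-validation performance level (`c5`, sum of
#' balance-validation median correlation and median AUC). Sets failing the
#' spread or non-inferiority check are excluded; survivors are ranked by
#' `c5`, ties by `c2`.
#'
#' @param ensemble A `split_ensemble`.
#' @param delta Non-inferiority slack on medians (default 0.02).
#' @return Data frame of surviving outer sets in rank order with
#'   per-criterion diagnostics.
#' @export
score_balanced_sets <- function(ensemble, delta = 0.02) {
  m <- ensemble$metrics
  per_outer <- lapply(split(m, m$outer_index), function(d) {
    ok <- stats::complete.cases(d[, c("corr_rv", "auc_rv", "corr_bv", "auc_bv")])
    d <- d[ok, , drop = FALSE]
    if (nrow(d) < 3L) return(NULL)
    c2 <- suppressWarnings(
      stats::cor(d$corr_rv, d$auc_rv, method = "spearman"))
    iqr_rv <- stats::IQR(d$corr_rv)
    c3 <- if (iqr_rv > 0) stats::IQR(d$corr_bv) / iqr_rv else Inf
    med <- vapply(d[, c("corr_rv", "auc_rv", "corr_bv", "auc_bv")],
                  stats::median, numeric(1))
    c4 <- med["corr_bv"] >= med["corr_rv"] - delta &&
      med["auc_bv"] >= med["auc_rv"] - delta
    data.frame(outer_index = d$outer_index[1L], n_inner_used = nrow(d),
               c2 = c2, c3 = c3, c4 = c4,
               c5 = med["corr_bv"] + med["auc_bv"],
               med_corr_bv = med["corr_bv"], med_auc_bv = med["auc_bv"],
               row.names = NULL)
  })
  tab <- do.call(rbind, per_outer)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no outer set produced usable inner-split metrics")
  surv <- tab[tab$c3 < 1 & tab$c4, , drop = FALSE]
  if (nrow(surv) < 2L)
    warning("fewer than 2 outer sets survive the selection criteria")
  if (nrow(surv) == 0L) return(surv)
  surv <- surv[order(-surv$c5, -surv$c2), , drop = FALSE]
  rownames(surv) <- NULL
  surv
}

#' Pick one representative model from each top outer set
#'
#' Within each of the `k` top-ranked outer sets, the inner split whose model
#' has the best balance-validation correlation is selected (ties broken by
#' higher balance-validation AUC, then lower inner index) and its model is
#' refitted from the reconstructed split.
#'
#' @param ensemble A `split_ensemble`.
#' @param ranked Output of [score_balanced_sets()].
#' @param expr,resp The expression matrix and labelled panel the ensemble
#'   was built from.
#' @param k Number of top sets (default 5).
#' @return List of `split_model_record`s: indices, fitted `model`,
#'   `random_train` ids and held-out metrics.
#' @export
pick_representatives <- function(ensemble, ranked, expr, resp, k = 5) {
  if (k > nrow(ranked)) {
    warning("only ", nrow(ranked), " surviving set(s); using all")
    k <- nrow(ranked)
  }
  m <- ensemble$metrics
  lapply(ranked$outer_index[seq_len(k)], function(i) {
    d <- m[m$outer_index == i & !is.na(m$corr_bv), , drop = FALSE]
    d <- d[order(-d$corr_bv, -d$auc_bv, d$inner_index), , drop = FALSE]
    best <- d[1L, ]
    refit_split_model(ensemble, expr, resp, i, best$inner_index, best)
  })
}

refit_split_model <- function(ensemble, expr, resp, outer_index, inner_index,
                              metrics_row) {
  outer <- balanced_split(resp, ensemble$cfg,
                          derive_seed(ensemble$cfg$seed, outer_index, 0L))
  inner <- inner_random_split(outer$train, ensemble$cfg,
                              derive_seed(ensemble$cfg$seed, outer_index, inner_index))
  X <- t(expr[ensemble$genes, , drop = FALSE])
  y <- stats::setNames(resp$ic50_log2, resp$sample_id)
  fit <- fit_plsr(X[inner$random_train, , drop = FALSE], y[inner$random_train],
                  n_components = ensemble$n_components)
  structure(list(outer_index = outer_index, inner_index = inner_index,
                 model = fit, random_train = inner$random_train,
                 random_val = inner$random_val, balance_val = outer$balance_val,
                 corr_bv = metrics_row$corr_bv, auc_bv = metrics_row$auc_bv,
                 corr_rv = metrics_row$corr_rv, auc_rv = metrics_row$auc_rv),
            class = "split_model_record")
}

#' Jaccard similarity of two sample-id sets
#'
#' @param a,b Non-empty character vectors (treated as sets).
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) stop("empty union")
  length(intersect(a, b)) / length(u)
}

#' Permutation null quantile for random-training overlap
#'
#' Empirical `q`-quantile of the Jaccard similarity between two
#' independently drawn uniform random subsets of `set_size` samples from a
#' panel of `panel_size`: the null against which observed overlap between
#' top models' random-training sets is judged significant.
#'
#' @param panel_size Number of samples in the panel.
#' @param set_size Size of each random-training set.
#' @param n_perm Number of random pairs (default 10000).
#' @param q Quantile (default 0.90).
#' @param seed Integer seed.
#' @return The null quantile, a number in \[0, 1\].
#' @export
overlap_null_quantile <- function(panel_size, set_size, n_perm = 10000,
                                  q = 0.90, seed = 1) {
  stopifnot(set_size <= panel_size, set_size >= 1)
  set.seed(seed)
  sims <- replicate(n_perm, {
    a <- sample.int(panel_size, set_size)
    b <- sample.int(panel_size, set_size)
    length(intersect(a, b)) / length(union(a, b))
  })
  as.numeric(stats::quantile(sims, q))
}

#' Drop top models that overlap significantly in training samples
#'
#' Greedy retention in rank order: a model is dropped when the Jaccard
#' similarity of its random-training set with any already-retained model
#' exceeds the permutation null quantile, so of an overlapping pair the
#' better-ranked model is kept.
#'
#' @param records List of `split_model_record`s in rank order.
#' @param null_q Overlap cutoff from [overlap_null_quantile()].
#' @return The retained sublist, in the original order.
#' @export
filter_overlapping <- function(records, null_q) {
  if (length(records) < 2L) return(records)
  kept <- list(records[[1L]])
  for (rec in records[-1L]) {
    over <- vapply(kept, function(kr)
      jaccard(rec$random_train, kr$random_train), numeric(1))
    if (all(over <= null_q)) kept <- c(kept, list(rec))
  }
  kept
}

#' SVD consensus of top-model gene weights
#'
#' Stacks the models' gene-weight vectors ([gene_weights()], zero-filled
#' over the union gene universe and each normalized to unit norm) into a
#' models x genes matrix and takes its first right singular vector as the
#' consensus weighting, sign-oriented so that its mean correlation with the
#' contributing models' weight vectors is non-negative.
#'
#' @param records List of `split_model_record`s (at least one).
#' @return A `consensus_weights` list: unit-norm `weights` named by gene,
#'   and `n_models`.
#' @export
consensus_weights <- function(records) {
  if (length(records) == 0L) stop("no models supplied")
  wlist <- lapply(records, function(r) gene_weights(r$model))
  genes <- sort(unique(unlist(lapply(wlist, names))))
  M <- do.call(rbind, lapply(wlist, function(w) {
    v <- stats::setNames(numeric(length(genes)), genes)
    v[names(w)] <- w
    v / sqrt(sum(v^2))
  }))
  if (!any(is.finite(M)) || all(M == 0)) stop("degenerate weight matrix")
  v1 <- svd(M)$v[, 1L]
  cors <- apply(M, 1L, function(row)
    if (stats::sd(row) == 0 || stats::sd(v1) == 0) 0 else stats::cor(row, v1))
  if (mean(cors) < 0) v1 <- -v1
  structure(list(weights = stats::setNames(v1, genes),
                 n_models = length(records)),
            class = "consensus_weights")
}

#' Select the model most similar to the consensus weighting
#'
#' @param records List of `split_model_record`s.
#' @param consensus A `consensus_weights`.
#' @return The record whose gene-weight vector (zero-filled over the
#'   consensus gene universe) has the highest Pearson correlation with the
#'   consensus; ties go to the higher balance-validation correlation.
#' @export
select_representative_model <- function(records, consensus) {
  genes <- names(consensus$weights)
  sims <- vapply(records, function(r) {
    w <- stats::setNames(numeric(length(genes)), genes)
    gw <- gene_weights(r$model)
    w[names(gw)] <- gw
    if (stats::sd(w) == 0) return(-Inf)
    stats::cor(w, consensus$weights)
  }, numeric(1))
  corr_bv <- vapply(records, function(r) r$corr_bv, numeric(1))
  records[[order(-sims, -corr_bv)[1L]]]
}

#' Forward selection of the core signature
#'
#' Genes are ordered by decreasing absolute consensus weight. Starting from
#' the `start` highest-weighted genes and adding one gene at a time, the
#' representative model is refitted on its random-training samples and
#' scored (correlation and AUC) on its balance-validation samples. The core
#' size is the earliest plateau: the smallest `k` such that neither metric
#' improves by more than `eps` anywhere in the next `window` additions. If
#' the curves keep rising to the end, the full gene set is returned with a
#' warning.
#'
#' @param representative A `split_model_record` (see
#'   [select_representative_model()]).
#' @param consensus A `consensus_weights`.
#' @param expr,resp Expression matrix and labelled panel.
#' @param start First evaluated signature size (default 5).
#' @param eps Improvement threshold per metric (default 0.005).
#' @param window Look-ahead width in genes (default 10).
#' @param n_components PLS components (default 2).
#' @return List: `core_genes`, `core_model`, `curve` (data frame `k`,
#'   `corr`, `auc`) and `plateau_k`.
#' @export
forward_select_core <- function(representative, consensus, expr, resp,
                                start = 5, eps = 0.005, window = 10,
                                n_components = 2) {
  ord <- order(-abs(consensus$weights), names(consensus$weights))
  genes <- names(consensus$weights)[ord]
  genes <- genes[genes %in% rownames(expr)]
  K <- length(genes)
  if (K < 2L) stop("fewer than 2 genes available for forward selection")
  if (K < start) {
    message("only ", K, " gene(s) available; starting forward selection there")
    start <- K
  }

  X <- t(expr[genes, , drop = FALSE])
  y <- stats::setNames(resp$ic50_log2, resp$sample_id)
  lab <- stats::setNames(resp$label, resp$sample_id)
  rt <- representative$random_train
  bv <- representative$balance_val

  ks <- seq.int(start, K)
  curve <- data.frame(k = ks, corr = NA_real_, auc = NA_real_)
  for (idx in seq_along(ks)) {
    k <- ks[idx]
    fit <- fit_plsr(X[rt, seq_len(k), drop = FALSE], y[rt],
                    n_components = n_components)
    curve$corr[idx] <- held_out_corr(fit, X[, seq_len(k), drop = FALSE], y, bv)
    curve$auc[idx] <- held_out_auc(fit, X[, seq_len(k), drop = FALSE], lab, bv)
  }

  plateau_k <- find_plateau(curve, eps = eps, window = window)
  if (is.na(plateau_k)) {
    warning("no performance plateau before exhausting genes; using all ", K)
    plateau_k <- K
  }
  core_genes <- genes[seq_len(plateau_k)]
  core_model <- fit_plsr(X[rt, core_genes, drop = FALSE], y[rt],
                         n_components = n_components)
  list(core_genes = core_genes, core_model = core_model,
       curve = curve, plateau_k = plateau_k)
}

# earliest plateau of the forward-selection performance curve: the smallest
# k (row of `curve`) such that neither metric improves by more than eps at
# any of the next `window` sizes; NA when the curves keep rising to the end
find_plateau <- function(curve, eps, window) {
  n <- nrow(curve)
  for (idx in seq_len(n)) {
    if (idx == n) break  # need at least one look-ahead point
    ahead <- seq.int(idx + 1L, min(idx + window, n))
    flat <- all(curve$corr[ahead] - curve$corr[idx] <= eps, na.rm = TRUE) &&
      all(curve$auc[ahead] - curve$auc[idx] <= eps, na.rm = TRUE)
    if (flat) return(curve$k[idx])
  }
  NA_integer_
}
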