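#' Fisher's variance-stabilizing transform of a correlation coefficient
#'
#' `f = 0.5 * ln((1 + r) / (1 - r))`, the inverse hyperbolic tangent. Under
#' the null the transformed sample correlation is approximately normal with
#' standard deviation `1 / sqrt(n - 3)`, which is what makes the normal fit
#' to permuted correlations in [permutation_feature_test()] well behaved.
#'
#' @param r Correlation value(s), strictly inside (-1, 1).
#' @return The transformed value(s); an odd function of `r`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z is defined for |r| < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` with input validation,
#' kept as a named step so the selection pipeline reads like its procedure:
#' step-up adjusted value `adj(i) = min over j >= i of p(j) * m / j`, capped
#' at 1, returned in input order.
#'
#' @param p Vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Permutation feature test on Fisher-transformed correlations
#'
#' For every gene, computes the Pearson correlation `r` between its
#' expression and log2(IC50), then builds a per-gene permutation null by
#' permuting the response vector `n_perm` times (one shared permutation
#' schedule across genes, which preserves gene-gene correlation under the
#' null). The permuted correlations are Fisher-transformed and fitted by
#' their sample mean and SD; the two-sided raw p-value of the observed,
#' transformed correlation comes from that normal fit, and
#' Benjamini-Hochberg adjusted values are computed over all tested genes.
#'
#' Genes with zero expression variance cannot be tested and are excluded
#' (count reported via message).
#'
#' @param expr Expression matrix, genes x samples.
#' @param resp A [response_panel()] covering the same samples.
#' @param n_perm Number of response permutations (default 1000).
#' @param seed Integer seed for the permutation schedule.
#' @return Data frame with one row per tested gene: `gene_id`, `r`, `f`,
#'   `null_mean`, `null_sd`, `p_raw`, `p_adj` and `direction`
#'   (`"sensitivity"` for r < 0, `"resistance"` for r > 0).
#' @export
permutation_feature_test <- function(expr, resp, n_perm = 1000, seed = 1) {
  stopifnot(inherits(resp, "response_panel"))
  if (ncol(expr) < 10L) stop("need at least 10 samples for the permutation test")
  y <- resp$ic50_log2[match(colnames(expr), resp$sample_id)]
  if (any(is.na(y))) stop("expression samples missing from the response panel")
  if (stats::sd(y) == 0) stop("response has zero variance")

  keep <- apply(expr, 1L, stats::sd) > 0
  if (any(!keep)) message(sum(!keep), " zero-variance gene(s) excluded")
  x <- t(expr[keep, , drop = FALSE])          # samples x genes
  n <- nrow(x)

  r_obs <- as.vector(stats::cor(x, y))
  f_obs <- fisher_z(clip_r(r_obs))

  set.seed(seed)
  perm <- replicate(n_perm, sample(y))         # samples x n_perm
  r_perm <- stats::cor(x, perm)                # genes x n_perm
  f_perm <- fisher_z(clip_r(r_perm))
  null_mean <- rowMeans(f_perm)
  null_sd <- apply(f_perm, 1L, stats::sd)

  p_raw <- 2 * stats::pnorm(-abs(f_obs - null_mean) / null_sd)
  data.frame(
    gene_id = rownames(expr)[keep],
    r = r_obs,
    f = f_obs,
    null_mean = null_mean,
    null_sd = null_sd,
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    direction = ifelse(r_obs < 0, "sensitivity", "resistance"),
    stringsAsFactors = FALSE
  )
}

# guard the Fisher transform against |r| numerically at 1
clip_r <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)

#' Select feature genes by raw permutation p-value
#'
#' @param stats Output of [permutation_feature_test()].
#' @param p_cutoff Raw p-value cutoff (default 0.01).
#' @return Character vector of selected gene ids, ordered by |r| descending.
#' @export
select_features <- function(stats, p_cutoff = 0.01) {
  sel <- stats[stats$p_raw < p_cutoff, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no features pass p_raw < ", p_cutoff,
         "; the panel may carry no expression-response signal")
  sel$gene_id[order(-abs(sel$r))]
}

#' Associate binary genetic events with drug response
#'
#' For each binary event row (mutation/amplification present = 1), computes
#' the Pearson correlation with log2(IC50) (positive = resistance-associated,
#' negative = sensitivity-associated), a permutation p-value over `n_perm`
#' shuffles of the IC50 vector, and a two-sided Fisher's exact test of the
#' 2x2 table of event status against the panel's sensitive/resistant labels.
#' Constant event rows are excluded (message).
#'
#' @param events Binary matrix, event genes x samples (0/1).
#' @param resp A labelled [response_panel()] (see [assign_labels()]).
#' @param n_perm Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @return Data frame: `gene_id`, `r`, `p_perm`, `fisher_exact_p`,
#'   `direction`.
#' @export
associate_genetic_events <- function(events, resp, n_perm = 1000, seed = 1) {
  stopifnot(inherits(resp, "response_panel"))
  if (all(is.na(resp$label))) stop("assign class labels to the panel first")
  y <- resp$ic50_log2[match(colnames(events), resp$sample_id)]
  lab <- resp$label[match(colnames(events), resp$sample_id)]
  if (any(is.na(y))) stop("event samples missing from the response panel")

  keep <- apply(events, 1L, function(e) stats::sd(e) > 0)
  if (any(!keep)) message(sum(!keep), " constant event row(s) excluded")
  ev <- events[keep, , drop = FALSE]

  set.seed(seed)
  perm <- replicate(n_perm, sample(y))
  res <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    r <- stats::cor(e, y)
    r_null <- as.vector(stats::cor(e, perm))
    p_perm <- (sum(abs(r_null) >= abs(r)) + 1) / (n_perm + 1)
    tab <- table(factor(e, levels = c(0, 1)),
                 factor(lab, levels = c("sensitive", "resistant")))
    fp <- stats::fisher.test(tab)$p.value
    data.frame(gene_id = rownames(ev)[i], r = r, p_perm = p_perm,
               fisher_exact_p = fp,
               direction = ifelse(r < 0, "sensitivity", "resistance"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
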