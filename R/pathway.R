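#' Read and write gene sets in GMT format
#'
#' Reading is delegated to `fgsea::gmtPathways()`; gene symbols are
#' uppercased and empty sets rejected. Writing emits one tab-separated line
#' per set: id, description, member genes.
#'
#' @param path GMT file path.
#' @return `read_gmt`: a named list of character vectors (class
#'   `pathway_collection`).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(toupper(g)))
  if (any(lengths(sets) == 0L)) stop("GMT file contains an empty gene set")
  structure(sets, class = "pathway_collection")
}

#' @rdname read_gmt
#' @param sets Named list of gene-symbol vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric enrichment of pathways in a core gene set
#'
#' For each pathway, the one-sided hypergeometric tail probability of
#' observing at least the seen overlap between the core genes and the
#' pathway, drawing `|core|` genes from the background universe (the genes
#' that entered feature selection). Pathways are intersected with the
#' background first; pathways with no background member are skipped with a
#' message. Raw p-values are gated downstream at `p < 0.01`; BH-adjusted
#' values are reported alongside.
#'
#' @param core_genes Character vector, the core signature genes.
#' @param background_genes Character vector, the discovery universe;
#'   must contain all core genes.
#' @param pathways A `pathway_collection` from [read_gmt()] or a named list.
#' @return Data frame: `pathway`, `size` (in background), `overlap`, `p`,
#'   `p_adj`, ordered by `p`.
#' @export
enrich_pathways <- function(core_genes, background_genes, pathways) {
  core_genes <- unique(toupper(core_genes))
  background_genes <- unique(toupper(background_genes))
  if (!all(core_genes %in% background_genes))
    stop("core genes must be a subset of the background universe")
  N <- length(background_genes)
  n_draw <- length(core_genes)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(toupper(pathways[[pw]]), background_genes)
    if (length(members) == 0L) {
      message("pathway '", pw, "' has no background member; skipped")
      return(NULL)
    }
    ov <- length(intersect(core_genes, members))
    p <- stats::phyper(ov - 1L, length(members), N - length(members),
                       n_draw, lower.tail = FALSE)
    data.frame(pathway = pw, size = length(members), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway overlaps the background universe")
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p, out$pathway), , drop = FALSE]
}

#' Restrict the core signature to significantly enriched pathways
#'
#' The functional signature is the union, over pathways with raw enrichment
#' p below `p_cutoff`, of the core genes sitting on those pathways —
#' stable-ordered by decreasing absolute consensus weight. When no pathway
#' reaches significance the full core set is returned with a warning
#' (fallback to the core model).
#'
#' @param core_genes Core signature genes.
#' @param enrichment Output of [enrich_pathways()].
#' @param pathways The same `pathway_collection`.
#' @param consensus Optional `consensus_weights` used for ordering.
#' @param p_cutoff Raw enrichment p cutoff (default 0.01).
#' @return Character vector of functional-signature genes.
#' @export
select_functional_genes <- function(core_genes, enrichment, pathways,
                                    consensus = NULL, p_cutoff = 0.01) {
  core_genes <- unique(toupper(core_genes))
  sig_pw <- enrichment$pathway[enrichment$p < p_cutoff]
  if (length(sig_pw) == 0L) {
    warning("no pathway significant at p < ", p_cutoff,
            "; falling back to the full core signature")
    return(core_genes)
  }
  sel <- unique(unlist(lapply(sig_pw, function(pw)
    intersect(core_genes, toupper(pathways[[pw]])))))
  if (!is.null(consensus)) {
    w <- abs(consensus$weights[match(sel, toupper(names(consensus$weights)))])
    w[is.na(w)] <- 0
    sel <- sel[order(-w, sel)]
  } else sel <- sort(sel)
  sel
}

#' Fit and calibrate the final signature model on the full panel
#'
#' Refits a 2-component PLSR on all retained panel cell lines restricted to
#' the signature genes, re-predicts the panel to obtain the score
#' distribution, and calibrates the sensitive/resistant score cutoff on it
#' ([response_cutoff()]; a manual override value may be supplied, e.g. a
#' score cutoff of 2). Per-gene direction labels are taken from the sign of
#' each gene's correlation with log2 IC50 (negative = sensitivity-specific,
#' positive = resistance-specific).
#'
#' @param signature_genes Genes of the functional (or core) signature.
#' @param expr Full-panel expression matrix, genes x samples.
#' @param resp The full [response_panel()].
#' @param cutoff_method Passed to [response_cutoff()] (default `"auto"`).
#' @param manual_value Manual cutoff value when `cutoff_method = "manual"`.
#' @param pathways_used Optional data frame of significant pathways to
#'   record.
#' @param n_components PLS components (default 2).
#' @return A `functional_signature`: `genes`, `directions`, `model`
#'   (`plsr_model`), `cutoff` (`score_cutoff`), `pathways`, `panel_scores`.
#' @export
fit_final_model <- function(signature_genes, expr, resp,
                            cutoff_method = "auto", manual_value = NULL,
                            pathways_used = NULL, n_components = 2) {
  if (length(signature_genes) == 0L) stop("empty signature")
  missing <- setdiff(signature_genes, rownames(expr))
  if (length(missing) > 0L)
    stop("signature genes absent from the panel: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  X <- t(expr[signature_genes, resp$sample_id, drop = FALSE])
  y <- resp$ic50_log2
  model <- fit_plsr(X, y, n_components = n_components)
  scores <- predict(model, X)
  cutoff <- response_cutoff(scores, method = cutoff_method,
                            manual_value = manual_value)
  dirs <- vapply(signature_genes, function(g)
    if (stats::cor(X[, g], y) < 0) "sensitivity" else "resistance",
    character(1))
  structure(list(genes = signature_genes,
                 directions = dirs,
                 model = model,
                 cutoff = cutoff,
                 pathways = pathways_used,
                 panel_scores = scores),
            class = "functional_signature")
}

#' Serialize or restore a signature model as JSON
#'
#' The JSON carries everything needed to score a new cohort: gene ids and
#' directions, per-component loadings, regression coefficients, intercept,
#' centering/scaling constants and the calibrated score cutoff, plus free
#' provenance fields.
#'
#' @param sig A `functional_signature`.
#' @param path Output / input file path.
#' @param provenance Optional named list (seed, configuration hash, ...).
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the restored `functional_signature`.
#' @export
write_model_json <- function(sig, path, provenance = NULL) {
  stopifnot(inherits(sig, "functional_signature"))
  m <- sig$model
  # arrays are stored unnamed, aligned with `genes`
  obj <- list(
    genes = sig$genes,
    directions = unname(sig$directions),
    n_components = m$n_components,
    loadings = unname(m$loadings),
    coefficients = unname(m$coefficients),
    intercept = m$intercept,
    center = unname(m$center),
    scale = unname(m$scale),
    cutoff = list(value = sig$cutoff$value, method = sig$cutoff$method),
    pathways = sig$pathways,
    provenance = provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- obj$genes
  L <- obj$loadings
  if (!is.matrix(L))
    L <- matrix(unlist(L), nrow = length(genes), byrow = TRUE)
  dimnames(L) <- list(genes, NULL)
  model <- structure(list(
    gene_ids = genes,
    n_components = obj$n_components,
    loadings = L,
    coefficients = stats::setNames(unlist(obj$coefficients), genes),
    intercept = obj$intercept,
    center = stats::setNames(unlist(obj$center), genes),
    scale = stats::setNames(unlist(obj$scale), genes)
  ), class = "plsr_model")
  structure(list(
    genes = genes,
    directions = stats::setNames(unlist(obj$directions), genes),
    model = model,
    cutoff = structure(list(value = obj$cutoff$value,
                            method = obj$cutoff$method),
                       class = "score_cutoff"),
    pathways = obj$pathways,
    panel_scores = NULL
  ), class = "functional_signature")
}
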