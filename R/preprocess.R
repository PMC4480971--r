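#' Quality control of dose-response curves
#'
#' Screens per-cell-line 10-dose inhibition curves before any cell line
#' enters model training. A curve is removed if it violates any of four
#' rules, and is flagged with the first rule it violates:
#'
#' 1. `missing_points`: three or more missing dose points;
#' 2. `high_cv`: four or more dose points with replicate CV above `cv_max`;
#' 3. `non_monotone`: inhibition at some lower dose exceeds inhibition at a
#'    higher dose by more than `inversion_tol` percentage points (unusual,
#'    non-sigmoid behaviour);
#' 4. `last_dose_only`: inhibition only at the highest tested dose (all
#'    lower-dose inhibitions below `floor_inhibition`).
#'
#' Curves with fewer than two usable points are flagged `too_few_points`
#' unconditionally.
#'
#' @param curves Long-format data frame with columns `cell_line_id`, `dose`,
#'   `mean_response` (percent inhibition; `NA` = missing point) and `cv`
#'   (replicate coefficient of variation, percent).
#' @param cv_max CV threshold in percent (default 30).
#' @param max_missing Missing-point count at which a curve is removed
#'   (default 3).
#' @param max_high_cv High-CV point count at which a curve is removed
#'   (default 4).
#' @param inversion_tol Tolerated inversion, percentage points of inhibition
#'   (default 20).
#' @param floor_inhibition Inhibition floor for the last-dose-only rule,
#'   percent (default 10).
#' @return A list with `retained` (cell-line ids passing QC) and `flags`
#'   (data frame `cell_line_id`, `flag`; `"pass"` for retained curves).
#' @export
qc_dose_response <- function(curves, cv_max = 30, max_missing = 3,
                             max_high_cv = 4, inversion_tol = 20,
                             floor_inhibition = 10) {
  stopifnot(all(c("cell_line_id", "dose", "mean_response", "cv") %in% colnames(curves)))
  ids <- unique(as.character(curves$cell_line_id))
  flag_one <- function(id) {
    cv <- curves[curves$cell_line_id == id, , drop = FALSE]
    cv <- cv[order(cv$dose), , drop = FALSE]
    if (any(diff(cv$dose) <= 0)) stop("doses must be strictly increasing: ", id)
    resp <- cv$mean_response
    ok <- !is.na(resp)
    if (sum(ok) < 2L) return("too_few_points")
    if (sum(!ok) >= max_missing) return("missing_points")
    if (sum(cv$cv[ok] > cv_max, na.rm = TRUE) >= max_high_cv) return("high_cv")
    # rule 3: a lower dose more inhibitory than a later dose beyond tolerance
    r <- resp[ok]
    if (length(r) >= 2L) {
      run_max <- cummax(r)
      if (any(run_max[-length(r)] - r[-1L] > inversion_tol)) return("non_monotone")
    }
    # rule 4: only the highest dose shows inhibition
    last_i <- max(which(ok))
    lower <- resp[ok & seq_along(resp) < last_i]
    if (length(lower) > 0L && all(lower < floor_inhibition) &&
        resp[last_i] >= floor_inhibition) return("last_dose_only")
    "pass"
  }
  flags <- vapply(ids, flag_one, character(1))
  list(
    retained = ids[flags == "pass"],
    flags = data.frame(cell_line_id = ids, flag = unname(flags),
                       stringsAsFactors = FALSE)
  )
}

#' Data reduction: intensity and variance filters
#'
#' `reduce_by_intensity` keeps the fraction of features with the highest
#' mean log2 intensity across samples (ties broken by lexical feature order);
#' `reduce_by_variance` keeps features whose sample variance (n-1
#' denominator) is at least `min_variance`. Applied in that order they
#' implement the standard two-step reduction of a whole-genome array down to
#' the expressed, variable subset.
#'
#' @param m Expression matrix (features x samples, log2).
#' @param keep_fraction Fraction of features to retain, in (0, 1].
#' @return The row-subset expression matrix, original row order preserved.
#' @export
reduce_by_intensity <- function(m, keep_fraction = 0.40) {
  if (nrow(m) == 0L) stop("empty expression matrix")
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must be in (0, 1]")
  n_keep <- max(1L, floor(keep_fraction * nrow(m)))
  means <- rowMeans(m)
  ord <- order(-means, rownames(m))  # ties -> lexically first
  keep <- sort(ord[seq_len(n_keep)])
  keep_attr(m[keep, , drop = FALSE], m)
}

#' @rdname reduce_by_intensity
#' @param min_variance Variance cutoff in squared log2 units (default 1).
#' @export
reduce_by_variance <- function(m, min_variance = 1.0) {
  if (ncol(m) < 2L) stop("variance filter needs at least two samples")
  v <- apply(m, 1L, stats::var)
  keep_attr(m[v >= min_variance, , drop = FALSE], m)
}

#' Collapse probesets to one representative row per gene
#'
#' For each gene the probeset with the highest mean intensity is kept as
#' representative; ties go to the higher-variance probeset, then to the
#' lexically smaller probeset identifier. Probes without a mapping are
#' dropped (count reported via message).
#'
#' @param m Expression matrix with probeset rownames.
#' @param probe_to_gene Named character vector, `names()` = probeset ids,
#'   values = gene symbols.
#' @return Expression matrix with one row per gene, rownames = gene symbols.
#' @export
collapse_probesets <- function(m, probe_to_gene) {
  genes <- probe_to_gene[rownames(m)]
  unmapped <- is.na(genes) | genes == ""
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped probeset(s) dropped")
    m <- m[!unmapped, , drop = FALSE]
    genes <- genes[!unmapped]
  }
  if (nrow(m) == 0L) stop("no mapped probesets left")
  means <- rowMeans(m)
  vars <- if (ncol(m) >= 2L) apply(m, 1L, stats::var) else rep(0, nrow(m))
  ord <- order(genes, -means, -vars, rownames(m))
  first <- ord[!duplicated(genes[ord])]
  out <- m[sort(first), , drop = FALSE]
  rownames(out) <- unname(genes[match(rownames(out), rownames(m))])
  out <- out[order(rownames(out)), , drop = FALSE]
  keep_attr(out, m)
}

#' Map test-platform features onto the training platform
#'
#' Renames features through a best-match probe map, drops unmapped features
#' (count reported via message) and resolves several sources mapping to the
#' same target by the [collapse_probesets()] rule (highest mean, then
#' highest variance, then lexical source id).
#'
#' @param m Expression matrix on the test platform.
#' @param map A [probe_map()].
#' @return Expression matrix with target-platform feature identifiers.
#' @export
map_probes <- function(m, map) {
  stopifnot(inherits(map, "probe_map"))
  tgt <- map$target_id[match(rownames(m), map$source_id)]
  dropped <- sum(is.na(tgt))
  if (dropped == nrow(m)) stop("no features of the matrix appear in the probe map")
  if (dropped > 0L) message(dropped, " unmapped feature(s) dropped")
  keep <- !is.na(tgt)
  mm <- m[keep, , drop = FALSE]
  names(tgt) <- rownames(m)
  out <- collapse_probesets(mm, tgt[keep])
  attr(out, "platform") <- "mapped"
  out
}

#' Quantile-normalize a test cohort against a training reference
#'
#' The reference distribution is the vector of per-rank means across the
#' reference samples (the standard quantile-normalization target). Each test
#' sample is then replaced rank by rank with that distribution: after
#' normalization, the sorted values of every test sample equal the reference
#' distribution exactly (tied test values receive the mean of the tied
#' ranks' reference values). When test and reference feature counts differ
#' (e.g. after best-match mapping losses), the reference distribution is
#' linearly interpolated at the test sample's quantile positions.
#'
#' Normalization is a within-sample monotone transform, so it preserves each
#' test sample's rank order; it is computed on the full shared feature space
#' before any signature subsetting.
#'
#' @param test Expression matrix to normalize.
#' @param reference Expression matrix defining the target distribution, on
#'   the same feature space as `test`.
#' @return `test` with every sample mapped onto the reference distribution.
#' @export
reference_quantile_normalize <- function(test, reference) {
  if (!all(rownames(test) %in% rownames(reference)))
    stop("test features missing from the reference matrix: ",
         paste(utils::head(setdiff(rownames(test), rownames(reference)), 5L),
               collapse = ", "))
  ref <- reference[rownames(test), , drop = FALSE]
  ref_dist <- sort(rowMeans(apply(ref, 2L, sort)))  # per-rank means
  n <- nrow(test)
  nr <- length(ref_dist)
  target <- if (nr == n) ref_dist else
    stats::approx(seq(0, 1, length.out = nr), ref_dist,
                  xout = seq(0, 1, length.out = n))$y
  out <- apply(test, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    # non-integer (tied) ranks take the mean of the straddling target values
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(test)
  attr(out, "platform") <- expr_platform(reference)
  out
}

keep_attr <- function(new, old) {
  attr(new, "platform") <- expr_platform(old)
  new
}
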