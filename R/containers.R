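#' Construct a validated log2 expression matrix
#'
#' Expression data throughout the package is a plain numeric matrix with
#' features (probesets or genes) in rows and samples in columns, log2 scale.
#' This helper validates the layout and attaches a platform label as an
#' attribute, so downstream cross-platform operations can assert that a
#' probe map is being applied to the platform it was built for.
#'
#' @param values Numeric matrix, features x samples, log2 intensities.
#' @param platform Character scalar naming the profiling platform.
#' @return The validated matrix with a `platform` attribute.
#' @export
expr_matrix <- function(values, platform = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression data must be a numeric matrix (features x samples)")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers in expression matrix")
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  attr(values, "platform") <- as.character(platform)[1L]
  values
}

#' @rdname expr_matrix
#' @param m An expression matrix.
#' @export
expr_platform <- function(m) {
  p <- attr(m, "platform")
  if (is.null(p)) "unspecified" else p
}

#' Construct a response panel of per-sample IC50 values
#'
#' Holds the drug-response side of a training panel: IC50 on the linear
#' scale as assayed, its log2 transform used as the regression response,
#' and (once a cutoff has been chosen) sensitive/resistant class labels.
#'
#' @param sample_id Character vector of cell-line identifiers.
#' @param ic50_linear Positive IC50 values on the linear concentration scale.
#' @param ic50_mode Declared shape of the IC50 distribution, `"normal_like"`
#'   or `"bimodal"`; drives cutoff selection and middle-tertile removal.
#' @return A `response_panel` data frame with columns `sample_id`,
#'   `ic50_linear`, `ic50_log2` and `label` (`NA` until labels are assigned).
#' @export
response_panel <- function(sample_id, ic50_linear,
                           ic50_mode = c("normal_like", "bimodal")) {
  ic50_mode <- match.arg(ic50_mode)
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicated sample identifiers")
  if (length(sample_id) != length(ic50_linear))
    stop("sample_id and ic50_linear lengths differ")
  if (!all(is.finite(ic50_linear)) || any(ic50_linear <= 0))
    stop("ic50_linear must be finite and positive")
  out <- data.frame(
    sample_id = sample_id,
    ic50_linear = as.numeric(ic50_linear),
    ic50_log2 = log2(as.numeric(ic50_linear)),
    label = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("response_panel", "data.frame")
  attr(out, "ic50_mode") <- ic50_mode
  out
}

#' Assign sensitive/resistant labels from a score cutoff
#'
#' Labels a panel by its experimental log2 IC50: strictly below the cutoff is
#' sensitive, at or above is resistant (the boundary goes to resistant for
#' determinism).
#'
#' @param panel A [response_panel()].
#' @param cutoff A `score_cutoff` from [response_cutoff()] or a numeric value
#'   in log2 IC50 units.
#' @return The panel with its `label` column filled in.
#' @export
assign_labels <- function(panel, cutoff) {
  stopifnot(inherits(panel, "response_panel"))
  value <- if (inherits(cutoff, "score_cutoff")) cutoff$value else as.numeric(cutoff)
  panel$label <- ifelse(panel$ic50_log2 < value, "sensitive", "resistant")
  attr(panel, "cutoff") <- value
  panel
}

ic50_mode <- function(panel) {
  m <- attr(panel, "ic50_mode")
  if (is.null(m)) "normal_like" else m
}

# keep response_panel class and attributes through row subsetting
subset_panel <- function(panel, idx) {
  out <- panel[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(panel)
  attr(out, "ic50_mode") <- attr(panel, "ic50_mode")
  attr(out, "cutoff") <- attr(panel, "cutoff")
  out
}

#' Read and write the package's tabular formats
#'
#' Plain TSV with a header row. Expression files have a `feature_id` first
#' column and one column per sample; IC50 files have `sample_id` and
#' `ic50_linear`; probe maps have `source_id` and `target_id` (each source
#' maps to at most one target).
#'
#' @param path File path.
#' @param platform Platform label to attach to the expression matrix.
#' @return `read_expr_tsv` an expression matrix; `read_ic50_tsv` a
#'   [response_panel()]; `read_probe_map_tsv` a two-column data frame.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_expr_tsv <- function(path, platform = "unspecified") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "feature_id")
    stop("expression TSV must start with a 'feature_id' column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$feature_id
  storage.mode(m) <- "double"
  expr_matrix(m, platform = platform)
}

#' @rdname table_io
#' @param m Expression matrix to write.
#' @export
write_expr_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param ic50_mode Declared IC50 distribution shape for the panel.
#' @export
read_ic50_tsv <- function(path, ic50_mode = "normal_like") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  response_panel(df$sample_id, df$ic50_linear, ic50_mode = ic50_mode)
}

#' @rdname table_io
#' @param panel Response panel to write.
#' @export
write_ic50_tsv <- function(panel, path) {
  utils::write.table(panel[, c("sample_id", "ic50_linear")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_probe_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_map(df$source_id, df$target_id)
}

#' Construct a probe best-match map
#'
#' @param source_id Feature identifiers on the test platform.
#' @param target_id Matching identifiers on the training platform.
#' @return A validated data frame with class `probe_map`.
#' @export
probe_map <- function(source_id, target_id) {
  if (length(source_id) != length(target_id)) stop("map columns differ in length")
  if (anyDuplicated(source_id))
    stop("each source feature may map to at most one target")
  out <- data.frame(source_id = as.character(source_id),
                    target_id = as.character(target_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_map", "data.frame")
  out
}

# deterministic seed derivation: a master seed fans out to per-stage /
# per-split seeds via a multiplicative-congruential step per index, so any
# single split is reconstructible from (master, outer_index, inner_index).
derive_seed <- function(master, ...) {
  m <- 2147483647
  idx <- c(...)
  s <- (as.double(master) %% m)
  for (i in idx) s <- (s * 48271 + as.double(i)) %% m
  as.integer(s)
}
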