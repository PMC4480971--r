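#' Fit a PLS1 regression of log2 IC50 on gene expression
#'
#' Partial least squares regression with a univariate response, fitted by
#' the NIPALS algorithm. Predictor columns are centered and (by default)
#' scaled to unit variance; the response is centered. Genes on the log2
#' scale have heterogeneous variances, so autoscaling keeps any single
#' high-variance gene from dominating the latent components. Zero-variance
#' columns are dropped with a message. The per-component loadings of the
#' first two components define the gene weights used throughout model
#' selection (see [gene_weights()]).
#'
#' @param X Numeric matrix, samples x genes, with gene colnames.
#' @param y Numeric response vector (log2 IC50), one value per row of `X`.
#' @param n_components Number of latent components (default 2).
#' @param scale Autoscale columns to unit variance (default `TRUE`).
#' @return A `plsr_model` with gene ids, per-component loadings, composite
#'   regression coefficients on the original expression scale, intercept,
#'   centering/scaling constants, fitted values and training sample ids.
#' @export
fit_plsr <- function(X, y, n_components = 2, scale = TRUE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite input")
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (is.null(colnames(X))) stop("X needs gene colnames")
  if (nrow(X) < n_components + 2L)
    stop("need at least n_components + 2 samples")

  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    message(sum(!keep), " zero-variance column(s) dropped")
    X <- X[, keep, drop = FALSE]
    ctr <- ctr[keep]; sds <- sds[keep]
  }
  if (ncol(X) == 0L) stop("no non-constant predictor columns")
  scl <- if (scale) sds else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  ybar <- mean(y)

  p <- ncol(Xs)
  A <- min(n_components, p, nrow(Xs) - 1L)
  W <- P <- matrix(0, p, A, dimnames = list(colnames(Xs), NULL))
  qv <- numeric(A)
  Xd <- Xs; yd <- y - ybar
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }     # response variance exhausted
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) { A <- a - 1L; break }
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; qv[a] <- q_a
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - t_a * q_a
  }
  if (A < 1L) stop("no usable PLS component (constant response?)")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  qv <- qv[seq_len(A)]

  b_scaled <- drop(W %*% solve(crossprod(P, W), qv))
  coef <- b_scaled / scl
  intercept <- ybar - sum(ctr * coef)
  fitted <- drop(X %*% coef) + intercept

  structure(list(
    gene_ids = colnames(X),
    n_components = A,
    loadings = P,
    x_weights = W,
    y_loadings = qv,
    coefficients = coef,
    intercept = intercept,
    center = ctr,
    scale = scl,
    scaled = scale,
    fitted = stats::setNames(fitted, rownames(X)),
    train_ids = rownames(X)
  ), class = "plsr_model")
}

#' Predict log2 IC50 from a fitted PLSR model
#'
#' @param object A `plsr_model`.
#' @param newdata Numeric matrix, samples x genes; must contain every model
#'   gene as a column (extra columns are ignored).
#' @param ... Unused.
#' @return Named numeric vector of predicted log2 IC50 scores.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  missing <- setdiff(object$gene_ids, colnames(newdata))
  if (length(missing) > 0L)
    stop("signature genes absent from the data: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  Xm <- newdata[, object$gene_ids, drop = FALSE]
  if (!all(is.finite(Xm))) stop("non-finite expression values")
  drop(Xm %*% object$coefficients) + object$intercept
}

#' Combined gene weights from the first two PLS components
#'
#' `w_g = sqrt(L1_g^2 + L2_g^2)`, the Euclidean norm of each gene's loadings
#' on components 1 and 2. Non-negative, invariant to a sign flip of either
#' component.
#'
#' @param model A `plsr_model` fitted with at least two components.
#' @return Named non-negative weight vector over the model's genes.
#' @export
gene_weights <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  if (model$n_components < 2L)
    stop("gene weights need at least 2 PLS components")
  w <- sqrt(model$loadings[, 1L]^2 + model$loadings[, 2L]^2)
  stats::setNames(as.vector(w), rownames(model$loadings))
}

#' ROC area under the curve for recovering response labels from scores
#'
#' AUC computed as the Mann-Whitney pair statistic with ties counted 0.5.
#' Orientation: lower predicted log2 IC50 means more sensitive, so a
#' perfectly ordered score vector (every sensitive below every resistant)
#' scores 1.
#'
#' @param scores Predicted log2 IC50 scores.
#' @param labels Character or factor vector with values `"sensitive"` /
#'   `"resistant"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  is_sen <- labels == "sensitive"
  is_res <- labels == "resistant"
  if (!all(is_sen | is_res)) stop("labels must be 'sensitive' or 'resistant'")
  n_s <- sum(is_sen); n_r <- sum(is_res)
  if (n_s == 0L || n_r == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_res]) - n_r * (n_r + 1) / 2) / (n_s * n_r)
}

#' Choose a sensitive/resistant cutoff on a score distribution
#'
#' For a normal-like distribution the sample median is used; for a clearly
#' bimodal distribution the cutoff is placed at the density valley between
#' the two dominant modes. `method = "auto"` applies a bimodality check: the
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth) must have
#' at least two modes and the minor side of the candidate valley must hold
#' at least `min_minor_mass` of the observations, otherwise the median is
#' used. `method = "manual"` records a user-supplied value (e.g. a score
#' cutoff of 2 when no clear separation point exists).
#'
#' @param values Numeric vector (experimental or predicted log2 IC50).
#' @param method One of `"auto"`, `"median"`, `"valley"`, `"manual"`.
#' @param manual_value Cutoff value when `method = "manual"`.
#' @param min_minor_mass Minimum fraction of observations on the minor side
#'   of the valley for the distribution to count as bimodal (default 0.10).
#' @return A `score_cutoff` list with elements `value` and `method`.
#' @export
response_cutoff <- function(values,
                            method = c("auto", "median", "valley", "manual"),
                            manual_value = NULL, min_minor_mass = 0.10) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(manual_value) || !is.finite(manual_value))
      stop("manual cutoff requires a finite manual_value")
    return(structure(list(value = as.numeric(manual_value), method = "manual"),
                     class = "score_cutoff"))
  }
  if (method == "median")
    return(structure(list(value = stats::median(values), method = "median"),
                     class = "score_cutoff"))
  if (length(values) < 10L)
    stop("need at least 10 values for a density-based cutoff")
  v <- find_density_valley(values)
  if (method == "valley") {
    if (is.null(v) || v$minor_mass < min_minor_mass)
      stop("density is effectively unimodal (no secondary mode carrying >= ",
           min_minor_mass, " of the data); use method = 'median' or 'manual'")
    return(structure(list(value = v$valley, method = "density_valley"),
                     class = "score_cutoff"))
  }
  # auto: valley if convincingly bimodal, else median
  if (!is.null(v) && v$minor_mass >= min_minor_mass)
    structure(list(value = v$valley, method = "density_valley"),
              class = "score_cutoff")
  else
    structure(list(value = stats::median(values), method = "median"),
              class = "score_cutoff")
}

# locate the valley between the two highest KDE modes; NULL if unimodal
find_density_valley <- function(values) {
  d <- stats::density(values, bw = "nrd0")
  y <- d$y; n <- length(y)
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2L) return(NULL)
  top2 <- is_max[order(-y[is_max])][1:2]
  lo <- min(top2); hi <- max(top2)
  valley_i <- lo + which.min(y[lo:hi]) - 1L
  valley <- d$x[valley_i]
  below <- mean(values < valley)
  list(valley = valley, minor_mass = min(below, 1 - below))
}
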