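#' Configuration of the balanced/random splitting scheme
#'
#' The ensemble explores `n_outer` balanced 70/30 outer splits (stratified by
#' IC50 tertile into training and balance-validation) and, inside each outer
#' training subset, `n_inner` unstratified 60/40 random splits into random
#' training and random validation. Overall the panel is divided 42% / 28% /
#' 30%. All randomness flows from `seed` through a counter scheme, so any
#' single split is reconstructible from `(seed, outer_index, inner_index)`.
#'
#' @param outer_train_fraction Outer training fraction (default 0.70).
#' @param inner_train_fraction Inner random-training fraction of the outer
#'   training subset (default 0.60).
#' @param n_outer Number of outer balanced splits (default 150).
#' @param n_inner Number of inner random splits per outer split
#'   (default 1000).
#' @param seed Master integer seed.
#' @return A `split_config` list.
#' @export
split_config <- function(outer_train_fraction = 0.70,
                         inner_train_fraction = 0.60,
                         n_outer = 150, n_inner = 1000, seed = 1) {
  stopifnot(outer_train_fraction > 0, outer_train_fraction < 1,
            inner_train_fraction > 0, inner_train_fraction < 1,
            n_outer >= 1, n_inner >= 1)
  structure(list(outer_train_fraction = outer_train_fraction,
                 inner_train_fraction = inner_train_fraction,
                 n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner),
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Remove the middle IC50 tertile from a normal-like panel
#'
#' For a drug whose IC50 distribution is normal-like, sensitive and
#' resistant lines are poorly separated in the middle of the distribution;
#' dropping the middle third sharpens the contrast before model training.
#' With `k = floor(n / 3)`, the `k` lowest and `k` highest log2 IC50 samples
#' are retained. Panels declared bimodal are returned unchanged (their two
#' modes already separate the classes).
#'
#' @param resp A [response_panel()].
#' @return The (possibly reduced) response panel.
#' @export
remove_middle_tertile <- function(resp) {
  stopifnot(inherits(resp, "response_panel"))
  if (ic50_mode(resp) == "bimodal") return(resp)
  n <- nrow(resp)
  if (n < 3L) stop("need at least 3 samples")
  k <- floor(n / 3)
  ord <- order(resp$ic50_log2, resp$sample_id)
  keep <- sort(c(ord[seq_len(k)], ord[seq.int(n - k + 1L, n)]))
  subset_panel(resp, keep)
}

#' Outer balanced split stratified by IC50 tertile
#'
#' Samples are ranked by log2 IC50 and cut into three equal-size groups
#' (remainders to the lower-IC50 groups); each group is split 70/30 at
#' random (counts rounded to nearest). The union over groups yields a
#' training subset and a balance-validation subset that each contain
#' members of every tertile, i.e. both sensitive and resistant lines.
#'
#' @param resp A [response_panel()].
#' @param cfg A [split_config()].
#' @param outer_seed Integer seed for this outer split.
#' @return List with `train` and `balance_val` character vectors of sample
#'   ids.
#' @export
balanced_split <- function(resp, cfg, outer_seed) {
  stopifnot(inherits(resp, "response_panel"))
  n <- nrow(resp)
  if (n < 9L) stop("need at least 9 samples for a stratified 3-group split")
  ord <- order(resp$ic50_log2, resp$sample_id)
  sizes <- rep(n %/% 3L, 3L)
  extra <- n %% 3L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 2L)) stop("a tertile has fewer than 2 samples")
  groups <- split(resp$sample_id[ord], rep(1:3, times = sizes))

  set.seed(outer_seed)
  train <- character(0); bval <- character(0)
  for (g in groups) {
    n_tr <- round(cfg$outer_train_fraction * length(g))
    n_tr <- min(max(n_tr, 1L), length(g) - 1L)  # both parts non-empty
    tr <- sample(g, n_tr)
    train <- c(train, tr)
    bval <- c(bval, setdiff(g, tr))
  }
  list(train = sort(train), balance_val = sort(bval))
}

#' Inner unstratified 60/40 random split
#'
#' @param train_ids Sample ids of an outer training subset.
#' @param cfg A [split_config()].
#' @param inner_seed Integer seed for this inner split.
#' @return List with `random_train` and `random_val` id vectors.
#' @export
inner_random_split <- function(train_ids, cfg, inner_seed) {
  n <- length(train_ids)
  n_rt <- round(cfg$inner_train_fraction * n)
  n_rt <- min(max(n_rt, 1L), n - 1L)
  set.seed(inner_seed)
  rt <- sample(train_ids, n_rt)
  list(random_train = sort(rt), random_val = sort(setdiff(train_ids, rt)))
}

#' Reconstruct one split assignment from its indices
#'
#' @param resp A [response_panel()].
#' @param cfg A [split_config()].
#' @param outer_index,inner_index 1-based split indices.
#' @return Data frame `sample_id`, `outer_index`, `inner_index`, `label`
#'   with label in `random_train` / `random_val` / `balance_val`.
#' @export
split_assignment <- function(resp, cfg, outer_index, inner_index) {
  outer <- balanced_split(resp, cfg, derive_seed(cfg$seed, outer_index, 0L))
  inner <- inner_random_split(outer$train, cfg,
                              derive_seed(cfg$seed, outer_index, inner_index))
  lab <- rep(NA_character_, nrow(resp))
  lab[resp$sample_id %in% inner$random_train] <- "random_train"
  lab[resp$sample_id %in% inner$random_val] <- "random_val"
  lab[resp$sample_id %in% outer$balance_val] <- "balance_val"
  data.frame(sample_id = resp$sample_id,
             outer_index = as.integer(outer_index),
             inner_index = as.integer(inner_index),
             label = lab, stringsAsFactors = FALSE)
}

#' Enumerate the full split ensemble
#'
#' Returns the `(outer_index, inner_index)` grid (n_outer x n_inner rows)
#' together with the derived seeds; any row can be materialized with
#' [split_assignment()].
#'
#' @param resp A [response_panel()] (validated for splittability).
#' @param cfg A [split_config()].
#' @return Data frame `outer_index`, `inner_index`, `outer_seed`,
#'   `inner_seed`.
#' @export
enumerate_splits <- function(resp, cfg) {
  stopifnot(inherits(cfg, "split_config"), nrow(resp) >= 9L)
  grid <- expand.grid(inner_index = seq_len(cfg$n_inner),
                      outer_index = seq_len(cfg$n_outer))[, 2:1]
  grid$outer_seed <- vapply(grid$outer_index,
                            function(i) derive_seed(cfg$seed, i, 0L), integer(1))
  grid$inner_seed <- mapply(function(i, j) derive_seed(cfg$seed, i, j),
                            grid$outer_index, grid$inner_index)
  rownames(grid) <- NULL
  grid
}
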