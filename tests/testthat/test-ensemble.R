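test_that("ensemble metrics cover every split with sane ranges", {
  fx <- small_ensemble()
  m <- fx$ens$metrics
  expect_identical(nrow(m), 4L * 30L)
  ok <- complete.cases(m)
  expect_gt(mean(ok), 0.9)
  expect_true(all(abs(m$corr_rv[ok]) <= 1 + 1e-12))
  expect_true(all(m$auc_bv[ok] >= 0 & m$auc_bv[ok] <= 1))
})

test_that("set scoring excludes wide or inferior balance validation", {
  base <- expand.grid(inner_index = 1:21, outer_index = 1:3)[, 2:1]
  set.seed(20)
  spread <- seq(-0.1, 0.1, length.out = 21)
  m <- data.frame(base,
                  corr_rv = 0.6 + rep(spread, 3),
                  auc_rv = 0.75 + rep(spread, 3) / 2)
  # outer 1: narrow, non-inferior balance validation (good)
  # outer 2: balance-validation spread wider than random validation
  # outer 3: balance-validation medians far below random validation
  m$corr_bv <- c(0.62 + spread / 4, 0.6 + spread * 3, 0.3 + spread / 4)
  m$auc_bv <- c(0.77 + spread / 8, 0.75 + spread * 3, 0.5 + spread / 8)
  ens <- structure(list(metrics = m), class = "split_ensemble")
  expect_warning(ranked <- score_balanced_sets(ens), "fewer than 2")
  expect_identical(ranked$outer_index, 1L)
  expect_lt(ranked$c3, 1)
  expect_true(ranked$c4)
})

test_that("representatives are the best balance-validation inner models", {
  fx <- small_ensemble()
  ranked <- suppressWarnings(score_balanced_sets(fx$ens))
  reps <- suppressWarnings(
    pick_representatives(fx$ens, ranked, fx$expr, fx$resp, k = 2))
  expect_lte(length(reps), 2L)
  for (rec in reps) {
    d <- fx$ens$metrics
    d <- d[d$outer_index == rec$outer_index & !is.na(d$corr_bv), ]
    expect_equal(rec$corr_bv, max(d$corr_bv))
    # the stored model is reconstructible from the split indices
    refit <- fit_plsr(
      t(fx$expr[fx$genes, rec$random_train]),
      setNames(fx$resp$ic50_log2,
               fx$resp$sample_id)[rec$random_train])
    expect_equal(refit$coefficients, rec$model$coefficients,
                 tolerance = 1e-12)
  }
})

test_that("representative tie-breaks prefer higher balance-validation AUC", {
  fx <- small_ensemble()
  ens <- fx$ens
  i <- ens$metrics$outer_index == 1L
  ens$metrics$corr_bv[i] <- 0.5           # tie every inner split
  ens$metrics$auc_bv[i] <- 0.5
  ens$metrics$auc_bv[i & ens$metrics$inner_index == 7L] <- 0.9
  ranked <- data.frame(outer_index = 1L)
  reps <- pick_representatives(ens, ranked, fx$expr, fx$resp, k = 1)
  expect_identical(reps[[1L]]$inner_index, 7L)
})

test_that("Jaccard similarity follows set arithmetic", {
  expect_identical(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_identical(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_error(jaccard(character(0), character(0)), "empty")
})

test_that("the overlap null quantile is coherent", {
  expect_equal(overlap_null_quantile(50, 50, n_perm = 50, seed = 1), 1)
  q1 <- overlap_null_quantile(300, 126, n_perm = 4000, q = 0.90, seed = 1)
  q2 <- overlap_null_quantile(300, 126, n_perm = 4000, q = 0.90, seed = 99)
  expect_lt(abs(q1 - q2), 0.03)
  q50 <- overlap_null_quantile(300, 126, n_perm = 2000, q = 0.50, seed = 7)
  q95 <- overlap_null_quantile(300, 126, n_perm = 2000, q = 0.95, seed = 7)
  expect_lte(q50, q95)
})

test_that("overlap filtering is greedy in rank order", {
  A <- fake_record(sprintf("s%d", 1:50))
  B <- fake_record(sprintf("s%d", 3:52))    # J(A,B) = 48/52 > cutoff
  C <- fake_record(sprintf("s%d", 60:109))  # disjoint from both
  kept <- filter_overlapping(list(A, B, C), null_q = 0.5)
  expect_identical(lapply(kept, `[[`, "random_train"),
                   list(A$random_train, C$random_train))
  expect_length(filter_overlapping(list(A, A), null_q = 0.99), 1L)
  far <- list(A, C)
  expect_identical(filter_overlapping(far, null_q = 0.5), far)
})

test_that("consensus weights summarize models by first singular vector", {
  w <- c(3, 1, 0.5, 0.2)
  recs <- lapply(1:3, function(i)
    fake_record("s1", loadings = cbind(w, 0)))
  cons <- consensus_weights(recs)
  expect_equal(sqrt(sum(cons$weights^2)), 1, tolerance = 1e-12)
  cosine <- sum(cons$weights * w / sqrt(sum(w^2)))
  expect_gt(cosine, 1 - 1e-10)
  single <- consensus_weights(recs[1])
  expect_equal(unname(single$weights), unname(w / sqrt(sum(w^2))),
               tolerance = 1e-12)
})

test_that("consensus is invariant to model order up to sign", {
  set.seed(21)
  recs <- lapply(1:4, function(i)
    fake_record("s1", loadings = cbind(runif(5), runif(5)),
                genes = sprintf("g%02d", 1:5)))
  c1 <- consensus_weights(recs)
  c2 <- consensus_weights(rev(recs))
  agree <- min(max(abs(c1$weights - c2$weights)),
               max(abs(c1$weights + c2$weights)))
  expect_lt(agree, 1e-10)
})

test_that("consensus handles models over different gene universes", {
  r1 <- fake_record("s1", loadings = cbind(c(3, 4), 0),
                    genes = c("g1", "g2"))
  r2 <- fake_record("s1", loadings = cbind(c(3, 4), 0),
                    genes = c("g2", "g3"))
  cons <- consensus_weights(list(r1, r2))
  expect_setequal(names(cons$weights), c("g1", "g2", "g3"))
  # the shared gene carries the largest consensus weight
  expect_identical(names(which.max(abs(cons$weights))), "g2")
})

test_that("the representative model is the one closest to consensus", {
  target <- c(5, 3, 1)
  close <- fake_record("s1", loadings = cbind(target, 0),
                       genes = c("g1", "g2", "g3"), corr_bv = 0.1)
  far <- fake_record("s1", loadings = cbind(c(1, 1, 5), 0),
                     genes = c("g1", "g2", "g3"), corr_bv = 0.9)
  cons <- consensus_weights(list(close, close, far))
  expect_identical(select_representative_model(list(far, close), cons)$corr_bv,
                   0.1)
})

test_that("plateau detection finds the earliest flat point", {
  k <- 5:60
  rising <- pmin(0.4 + 0.01 * (k - 5), 0.4 + 0.01 * 35)
  curve <- data.frame(k = k, corr = rising, auc = rising)
  # exactly flat after k = 40
  expect_identical(drugresp:::find_plateau(curve, eps = 0.005, window = 10),
                   40L)
  strictly_up <- data.frame(k = k, corr = 0.3 + 0.01 * k,
                            auc = 0.3 + 0.01 * k)
  expect_true(is.na(drugresp:::find_plateau(strictly_up, eps = 0.005,
                                            window = 10)))
  # a late bump beyond the window does not defer the plateau
  bump <- rising
  bump[k > 55] <- bump[k > 55] + 0.2
  curve2 <- data.frame(k = k, corr = bump, auc = bump)
  expect_identical(drugresp:::find_plateau(curve2, eps = 0.005, window = 10),
                   40L)
})

test_that("forward selection starts at five genes and returns a core fit", {
  fx <- small_ensemble()
  ranked <- suppressWarnings(score_balanced_sets(fx$ens))
  reps <- suppressWarnings(
    pick_representatives(fx$ens, ranked, fx$expr, fx$resp, k = 2))
  cons <- consensus_weights(reps)
  rep1 <- select_representative_model(reps, cons)
  core <- suppressWarnings(suppressMessages(
    forward_select_core(rep1, cons, fx$expr, fx$resp)))
  expect_identical(core$curve$k[1L], min(5L, length(cons$weights)))
  expect_identical(length(core$core_genes), as.integer(core$plateau_k))
  expect_setequal(core$core_model$gene_ids, core$core_genes)
  ord <- names(sort(-abs(cons$weights)))
  expect_true(all(core$core_genes %in% ord[seq_len(core$plateau_k)]))
})
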