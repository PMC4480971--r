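make_curve <- function(id, resp, cv = rep(10, 10)) {
  data.frame(cell_line_id = id, dose = 0.005 * 3^(0:9),
             mean_response = resp, cv = cv, stringsAsFactors = FALSE)
}
clean_sigmoid <- 100 / (1 + (0.5 / (0.005 * 3^(0:9)))^1.5)

test_that("dose-response QC applies the four removal rules in order", {
  curves <- rbind(
    make_curve("ok", clean_sigmoid),
    make_curve("miss3", replace(clean_sigmoid, c(2, 5, 8), NA)),
    make_curve("cv4", clean_sigmoid, cv = c(35, 35, 35, 35, rep(10, 6))),
    make_curve("invert", c(5, 10, 80, 30, 30, 35, 40, 45, 60, 80)),
    make_curve("lastonly", c(rep(2, 9), 70)),
    make_curve("sparse", c(50, rep(NA, 9)))
  )
  qc <- qc_dose_response(curves)
  flags <- setNames(qc$flags$flag, qc$flags$cell_line_id)
  expect_identical(unname(flags["ok"]), "pass")
  expect_identical(unname(flags["miss3"]), "missing_points")
  expect_identical(unname(flags["cv4"]), "high_cv")
  expect_identical(unname(flags["invert"]), "non_monotone")
  expect_identical(unname(flags["lastonly"]), "last_dose_only")
  expect_identical(unname(flags["sparse"]), "too_few_points")
  expect_identical(qc$retained, "ok")
})

test_that("two missing points or three high-CV points are tolerated", {
  curves <- rbind(
    make_curve("miss2", replace(clean_sigmoid, c(2, 5), NA)),
    make_curve("cv3", clean_sigmoid, cv = c(35, 35, 35, rep(10, 7))))
  qc <- qc_dose_response(curves)
  expect_setequal(qc$retained, c("miss2", "cv3"))
})

test_that("planted QC violations are recovered from simulated curves", {
  cfg <- simulation_config(n_genes = 10, n_driver_genes = 1,
                           n_cell_lines = 40, seed = 15)
  dr <- simulate_dose_response(cfg, n_per_violation = 2)
  qc <- qc_dose_response(dr$curves)
  merged <- merge(qc$flags, dr$truth, by = "cell_line_id")
  planted <- merged[merged$planted != "none", ]
  expect_identical(planted$flag, planted$planted)
  clean <- merged[merged$planted == "none", ]
  expect_gte(mean(clean$flag == "pass"), 0.9)
})

test_that("intensity filter keeps the top fraction by row mean", {
  m <- toy_expr(c(10, 10, 8, 8, 6, 6, 4, 4, 2, 2, 1, 1, 0, 0, 3, 3, 5, 5, 7, 7))
  out <- reduce_by_intensity(m, 0.4)
  expect_identical(nrow(out), 4L)
  expect_setequal(rownames(out),
                  rownames(m)[order(-rowMeans(m))][1:4])
  expect_identical(reduce_by_intensity(m, 1), m)
})

test_that("intensity ties break by lexical feature order", {
  m <- toy_expr(rep(5, 20))  # all rows identical
  out <- reduce_by_intensity(m, 0.4)
  expect_identical(rownames(out), sort(rownames(m))[1:4])
})

test_that("variance filter uses the unbiased sample variance", {
  m <- toy_expr(c(0, 2, 1, 1, 0.1, 1.6))  # variances 2, 0, 1.125
  out <- reduce_by_variance(m, 1)
  expect_setequal(rownames(out), c("f01", "f03"))
  expect_identical(reduce_by_variance(m, 0), m)
  expect_error(reduce_by_variance(m[, 1, drop = FALSE], 1), "two samples")
})

test_that("probeset collapsing keeps the highest-intensity probe per gene", {
  m <- toy_expr(c(8.1, 8.1, 6.2, 6.2, 3, 3), features = c("p1", "p2", "p3"))
  map <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB")
  out <- collapse_probesets(m, map)
  expect_identical(sort(rownames(out)), c("GENEA", "GENEB"))
  expect_equal(unname(out["GENEA", ]), unname(m["p1", ]))
})

test_that("collapsing ties on mean resolve by higher variance", {
  m <- toy_expr(c(4, 6, 5 - 2, 5 + 2, 1, 1),
                features = c("pA", "pB", "pC"))  # pA/pB mean 5, var 2 vs 8
  out <- collapse_probesets(m, c(pA = "G1", pB = "G1", pC = "G2"))
  expect_equal(unname(out["G1", ]), unname(m["pB", ]))
})

test_that("unmapped probes are dropped with a message", {
  m <- toy_expr(c(1, 1, 2, 2), features = c("p1", "p2"))
  expect_message(out <- collapse_probesets(m, c(p1 = "G1")), "1 unmapped")
  expect_identical(rownames(out), "G1")
})

test_that("probe mapping renames, drops and collapses duplicates", {
  m <- toy_expr(c(1, 2, 5, 6, 3, 4), features = c("a", "b", "c"))
  ident <- probe_map(rownames(m), rownames(m))
  expect_equal(unclass(map_probes(m, ident)), unclass(m),
               ignore_attr = TRUE)
  partial <- probe_map(c("a", "b"), c("x", "y"))
  expect_message(out <- map_probes(m, partial), "1 unmapped")
  expect_setequal(rownames(out), c("x", "y"))
  dup <- probe_map(c("a", "b", "c"), c("t", "t", "u"))
  out2 <- map_probes(m, dup)
  expect_equal(unname(out2["t", ]), unname(m["b", ]))  # higher-mean source
  expect_error(map_probes(m, probe_map("zz", "q")), "no features")
})

test_that("quantile normalization substitutes reference ranks exactly", {
  ref <- toy_expr(c(1, 1, 2, 2, 3, 3),
                  features = c("g1", "g2", "g3"), samples = c("r1", "r2"))
  test <- toy_expr(c(10, 30, 20), features = c("g1", "g2", "g3"),
                   samples = "t1")
  out <- reference_quantile_normalize(test, ref)
  expect_equal(unname(out[, "t1"]), c(1, 3, 2))
})

test_that("quantile normalization is shift-invariant and idempotent", {
  set.seed(1)
  ref <- toy_expr(rnorm(40, 7, 2), samples = sprintf("r%d", 1:2))
  ref_dist <- sort(rowMeans(apply(ref, 2, sort)))
  test <- matrix(ref_dist[sample(20)] + 5, ncol = 1,
                 dimnames = list(rownames(ref), "t1"))
  out <- reference_quantile_normalize(test, ref)
  expect_equal(sort(out[, 1]), ref_dist, ignore_attr = TRUE,
               tolerance = 1e-12)
  again <- reference_quantile_normalize(out, ref)
  expect_equal(unclass(again), unclass(out), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("quantile normalization preserves within-sample rank order", {
  set.seed(2)
  ref <- toy_expr(rnorm(60, 7, 2), features = sprintf("f%02d", 1:20),
                  samples = sprintf("r%d", 1:3))
  test <- toy_expr(rnorm(40, 9, 4), features = rownames(ref)[1:10],
                   samples = sprintf("t%d", 1:4))
  out <- reference_quantile_normalize(test, ref)  # interpolated reference
  for (j in 1:4)
    expect_identical(order(out[, j]), order(test[, j]))
})

test_that("reduction output is monotone in its thresholds", {
  sim <- small_sim()
  m <- sim$expr
  n1 <- nrow(reduce_by_variance(reduce_by_intensity(m, 0.5), 0.5))
  n2 <- nrow(reduce_by_variance(reduce_by_intensity(m, 0.5), 1.0))
  n3 <- nrow(reduce_by_variance(reduce_by_intensity(m, 0.3), 1.0))
  expect_gte(n1, n2)
  expect_gte(n2, n3)
})
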