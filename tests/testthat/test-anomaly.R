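make_table <- function(net, d = 5) curvature_map(net, d = d)

test_that("curvature differences use the zero convention for absent pairs", {
  a <- weighted_network(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  b <- weighted_network(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  dl <- curvature_delta(make_table(a), make_table(b))
  expect_equal(nrow(dl), 3L)
  # edge {1,3} exists only in a: delta equals its curvature in a
  r <- dl[dl$u == "n000" & dl$v == "n002", ]
  expect_equal(r$curv_disease, 0)
  expect_equal(r$delta, r$curv_control)
  expect_equal(dl$delta, dl$curv_control - dl$curv_disease)
  # identity and antisymmetry
  same <- curvature_delta(make_table(a), make_table(a))
  expect_true(all(same$delta == 0))
  rev <- curvature_delta(make_table(b), make_table(a))
  expect_equal(rev$delta, -dl$delta)
  # guard rails
  c_ <- weighted_network(rbind(c(0, 1), c(1, 0)))
  expect_error(curvature_delta(make_table(a), make_table(c_)), "node sets")
  expect_error(curvature_delta(make_table(a), make_table(b, d = 4)),
               "different d")
})

test_that("delta statistics use population moments", {
  st <- delta_stats(c(1, -1))
  expect_equal(st$mean, 0)
  expect_equal(st$sd, 1)
  expect_equal(delta_stats(rep(3, 5))$sd, 0)
  expect_error(delta_stats(numeric(0)), "empty")
  st <- delta_stats(rnorm(100), bins = 10)
  expect_equal(sum(st$counts), 100)
})

test_that("outlier selection respects cutoff, order and sign flips", {
  dl <- data.frame(u = c("a", "b", "c"), v = c("x", "y", "z"),
                   delta = c(16, -20, 3))
  out <- outlier_edges(dl, 15)
  expect_equal(out$u, c("b", "a"))
  expect_equal(nrow(outlier_edges(dl, Inf)), 0L)
  expect_error(outlier_edges(dl, -1), "positive")
  auto <- outlier_edges(dl, "auto")
  expect_equal(attr(auto, "cutoff"), 2 * delta_stats(dl$delta)$sd)
  flip <- dl; flip$delta <- -flip$delta
  expect_equal(paste(outlier_edges(flip, 15)$u),
               paste(outlier_edges(dl, 15)$u))
  # ties break lexicographically
  tie <- data.frame(u = c("b", "a"), v = c("q", "q"), delta = c(5, -5))
  expect_equal(outlier_edges(tie, 1)$u, c("a", "b"))
})

test_that("normalisation maps extremes to +/-1 and preserves order", {
  expect_equal(normalize_deltas(c(10, -10, 0)), c(1, -1, 0))
  expect_equal(normalize_deltas(rep(2, 4)), rep(0, 4))
  x <- rnorm(50)
  nx <- normalize_deltas(x)
  expect_equal(order(x), order(nx))
  expect_equal(max(nx), 1)
  expect_equal(min(nx), -1)
  expect_true(all(nx >= -1 & nx <= 1))
})

test_that("edge-weight differences treat absent edges as zero", {
  a <- weighted_network(rbind(c(0, .5, 0), c(.5, 0, 0), c(0, 0, 0)))
  b <- weighted_network(rbind(c(0, .3, .4), c(.3, 0, 0), c(.4, 0, 0)))
  expect_equal(weight_delta(a, b, c("n000", "n001")), 0.2)
  expect_equal(weight_delta(a, b, c("n000", "n002")), -0.4)
  expect_equal(weight_delta(a, b, c("n001", "n002")), 0)
  tab <- weight_delta(a, b)
  expect_equal(nrow(tab), 2L)   # union of the two edge sets
})

test_that("the anomaly fit recovers a planted perturbation end to end", {
  pair <- planted_pair(n = 25, p = 0.2, effect = 1.5, k = 3, seed = 101)
  fit <- curvature_anomaly(pair$control, pair$disease)
  expect_s3_class(fit, "curvature_anomaly")
  expect_setequal(unlist(fit$records[1, c("edge_u", "edge_v")]), pair$target)
  expect_equal(fit$records$delta,
               fit$records$curv_control - fit$records$curv_disease)
  expect_true(all(abs(fit$records$norm_delta) <= 1))
  # identical inputs: no signal anywhere
  null_fit <- curvature_anomaly(pair$control, pair$control)
  expect_true(all(null_fit$records$delta == 0))
  expect_equal(null_fit$n_outliers, 0L)
  # methods run
  expect_output(print(fit), "outliers")
  expect_s3_class(summary(fit), "data.frame")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  # records can be exported
  path <- tempfile()
  write_anomaly_table(fit$records, path)
  expect_equal(length(readLines(path)), nrow(fit$records) + 1L)
})

test_that("z-scores attach to the strongest outliers when requested", {
  pair <- planted_pair(n = 18, p = 0.25, effect = 1.5, k = 2, seed = 55)
  fit <- curvature_anomaly(pair$control, pair$disease, replicates = 5,
                           top_k = 2, seed = 9)
  expect_equal(sum(!is.na(fit$records$z)), 2L)
  expect_true(all(is.na(fit$records$z[-(1:2)])))
})
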