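test_that("network construction enforces shape, symmetry and labels", {
  expect_error(weighted_network(matrix(0, 2, 3)), "non-square")
  M <- matrix(c(0, 0.5, 0.4, 0), 2, 2)
  expect_error(weighted_network(M), "asymmetric")
  sym <- weighted_network(M, symmetrize = TRUE)
  expect_equal(sym$weights[1, 2], 0.45)
  expect_error(weighted_network(diag(3), labels = c("a", "b")),
               "label count mismatch")
  expect_error(weighted_network(matrix(0, 2, 2), labels = c("a", "a")),
               "unique")
  # unit diagonal of a raw correlation matrix is dropped
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(diag(weighted_network(C)$weights), c(n000 = 0, n001 = 0))
})

test_that("a small symmetric matrix ingests with its edges intact", {
  W <- rbind(c(0, .5, .3), c(.5, 0, .45), c(.3, .45, 0))
  net <- weighted_network(W)
  expect_s3_class(net, "weighted_network")
  expect_equal(length(net$labels), 3L)
  expect_equal(n_edges(net), 3L)
  expect_equal(edge_list(net)$weight, c(0.5, 0.3, 0.45))
})

test_that("matrix files round-trip bit-identically in both dialects", {
  net <- random_weighted_network(12, 0.4, seed = 7)
  mp <- tempfile(); lp <- tempfile()
  write_network(net, mp, lp)
  back <- read_network(mp, lp)
  expect_identical(back$weights, net$weights)
  expect_identical(back$labels, net$labels)
  # comma dialect is sniffed from the first line
  csv <- tempfile()
  writeLines(apply(net$weights, 1, paste, collapse = ","), csv)
  back2 <- read_network(csv)
  expect_equal(unname(back2$weights), unname(net$weights))
  expect_equal(back2$labels[1], "n000")   # default labels
  expect_error(read_network(mp, tempfile_with_lines(c("a", "b"))),
               "label count mismatch")
  expect_error(read_network(tempfile_with_lines(c("0 1 0", "1 0 1"))))
})

test_that("sparsify thresholds strictly below tau and is idempotent", {
  W <- rbind(c(0, .5, .3), c(.5, 0, .45), c(.3, .45, 0))
  net <- weighted_network(W)
  sp <- sparsify(net, 0.4)
  expect_equal(attr(sp, "surviving_edges"), 2L)
  expect_equal(sp$weights[1, 2], 0.5)
  expect_equal(sp$weights[2, 3], 0.45)
  expect_equal(sp$weights[1, 3], 0)
  expect_identical(sparsify(sp, 0.4)$weights, sp$weights)
  # negatives are preserved on ingest and removed by any positive threshold
  Wn <- rbind(c(0, -.2, .6), c(-.2, 0, .5), c(.6, .5, 0))
  netn <- weighted_network(Wn)
  expect_equal(netn$weights[1, 2], -0.2)
  expect_equal(sparsify(netn, 0.4)$weights[1, 2], 0)
  expect_warning(sparsify(netn, 0), "clamps")
  # tau = 0 keeps all positive edges
  expect_equal(suppressWarnings(n_edges(sparsify(netn, 0))), 2L)
})

test_that("mean_network averages element-wise and respects labels", {
  a <- weighted_network(rbind(c(0, .2), c(.2, 0)), labels = c("x", "y"))
  b <- weighted_network(rbind(c(0, .6), c(.6, 0)), labels = c("x", "y"))
  expect_equal(mean_network(list(a, b))$weights[1, 2], 0.4)
  expect_identical(mean_network(list(a))$weights, a$weights)
  expect_identical(mean_network(list(a, b))$weights,
                   mean_network(list(b, a))$weights)
  expect_error(mean_network(list()), "empty")
  c_ <- weighted_network(rbind(c(0, .6), c(.6, 0)), labels = c("x", "z"))
  expect_error(mean_network(list(a, c_)), "label mismatch")
})

test_that("anomaly tables are written with header and |delta| ordering", {
  rec <- data.frame(edge_u = c("a", "b"), edge_v = c("b", "c"),
                    curv_control = c(1, 2), curv_disease = c(0, 5),
                    delta = c(1, -3), norm_delta = c(1, -1),
                    weight_delta = c(0.1, -0.2), z = c(NA, 2.5))
  path <- tempfile()
  write_anomaly_table(rec, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_match(lines[1], "^edge_u\tedge_v\tcurv_control")
  expect_match(lines[2], "^b\tc")    # larger |delta| first
  write_anomaly_table(rec[0, ], path)
  expect_length(readLines(path), 1L)
  expect_error(write_anomaly_table(rec[1:3], path), "lack column")
})
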