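test_that("hand-evaluated curvatures are reproduced", {
  k3 <- fixture_network("K3")
  for (e in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_equal(forman_curvature(k3, e), 3.0)
  tab <- curvature_map(k3)
  expect_equal(tab$curvature, rep(3.0, 3))

  iso <- weighted_network(rbind(c(0, .5), c(.5, 0)))
  expect_equal(forman_curvature(iso, c(1, 2)), 1.0)

  # a node pair without an edge has curvature 0 by convention
  p3 <- weighted_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(forman_curvature(p3, c(1, 3)), 0)

  cc4 <- fixture_network("chorded_C4")
  expect_equal(forman_curvature(cc4, c("chorded_C4_0", "chorded_C4_1"), d = 4), 3.0)
  expect_equal(forman_curvature(cc4, c("chorded_C4_0", "chorded_C4_2"), d = 4), 4.0)
})

test_that("the full formula handles hanging and face-parallel edges", {
  expect_equal(forman_curvature_full(fixture_network("K3"), c(1, 2)), 3.0)
  star <- fixture_network("star13")
  expect_equal(forman_curvature_full(star, c(1, 2), mode = "all_cycles"), 0.0)
  k22 <- fixture_network("K22")
  el <- edge_list(k22)
  for (r in seq_len(nrow(el)))
    expect_equal(forman_curvature_full(k22, c(el$u[r], el$v[r]), d = 4,
                                       mode = "all_cycles"), 2.0)
})

test_that("curvature is symmetric in the edge orientation", {
  net <- random_weighted_network(12, 0.35, seed = 11)
  el <- edge_list(net)
  fs <- enumerate_faces(net, d = 5)
  for (r in seq_len(min(nrow(el), 15))) {
    expect_identical(forman_curvature(net, c(el$u[r], el$v[r]), faces = fs),
                     forman_curvature(net, c(el$v[r], el$u[r]), faces = fs))
  }
})

test_that("curvature_map handles empty graphs and matches per-edge calls", {
  empty <- weighted_network(matrix(0, 4, 4))
  expect_equal(nrow(curvature_map(empty)), 0L)
  net <- random_weighted_network(10, 0.4, seed = 12)
  tab <- curvature_map(net, d = 5)
  fs <- enumerate_faces(net, d = 5)
  for (r in seq_len(nrow(tab))) {
    expect_equal(tab$curvature[r],
                 forman_curvature(net, c(tab$u[r], tab$v[r]), faces = fs))
  }
  expect_error(curvature_map(net, d = 4, faces = fs), "different d")
})

test_that("weights scale linearly into node and face weights", {
  net <- random_weighted_network(9, 0.45, seed = 13)
  scaled <- weighted_network(net$weights * 0.5, labels = net$labels)
  expect_equal(node_weight(scaled), node_weight(net) * 0.5)
  w1 <- vapply(enumerate_faces(net, d = 5)$faces, `[[`, 0, "weight")
  w2 <- vapply(enumerate_faces(scaled, d = 5)$faces, `[[`, 0, "weight")
  expect_equal(w2, w1 * 0.5)
})

test_that("full/reduced agreement follows the hanging-edge condition", {
  ca <- curvature_agreement(fixture_network("K3"), c(1, 2))
  expect_false(ca$has_hanging)
  expect_equal(ca$full, 3.0)
  expect_equal(ca$reduced, 3.0)
  expect_true(ca$equal)

  ca <- curvature_agreement(fixture_network("star13"), c(1, 2))
  expect_true(ca$has_hanging)
  expect_equal(ca$full, 0.0)
  expect_equal(ca$reduced, 2.0)
  expect_false(ca$equal)

  ca <- curvature_agreement(fixture_network("K22"), c(1, 3), d = 4)
  expect_false(ca$has_hanging)
  expect_equal(ca$full, 2.0)
  expect_true(ca$equal)
})

test_that("agreement on hanging-free graphs ignores face weights", {
  # rescaling every face weight by a positive constant must not break the
  # equality of the two formulas
  net <- reweight(fixture_network("K222"), seed = 21)
  fs <- enumerate_faces(net, d = 4, mode = "all_cycles")
  fs_scaled <- fs
  fs_scaled$faces <- lapply(fs$faces, function(f) { f$weight <- f$weight * 7.3; f })
  el <- edge_list(net)
  for (r in seq_len(nrow(el))) {
    e <- c(el$u[r], el$v[r])
    full <- forman_curvature_full(net, e, d = 4, mode = "all_cycles",
                                  faces = fs_scaled)
    red <- forman_curvature(net, e, d = 4, mode = "all_cycles",
                            faces = fs_scaled)
    expect_equal(full, red, tolerance = 1e-12)
  }
})

test_that("optimized curvature agrees with the naive oracle on small graphs", {
  for (s in 1:10) {
    net <- random_weighted_network(8, 0.5, seed = 200 + s)
    if (!n_edges(net)) next
    expect_same_curvatures(curvature_map(net, d = 5),
                           oracle_curvature_map(net, d = 5))
  }
})
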