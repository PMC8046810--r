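test_that("node weights average incident edge weights", {
  star <- fixture_network("star13")
  expect_equal(node_weight(star, star$labels[1]), 1.0)
  W <- rbind(c(0, .4, .6), c(.4, 0, 0), c(.6, 0, 0))
  net <- weighted_network(W)
  expect_equal(node_weight(net, "n000"), 0.5)
  iso <- weighted_network(rbind(c(0, .5, 0), c(.5, 0, 0), c(0, 0, 0)))
  expect_equal(node_weight(iso, "n002"), 0)
  expect_error(node_weight(net, "zzz"), "unknown node")
  expect_equal(unname(node_weight(net)), c(0.5, 0.4, 0.6))
})

test_that("chordal faces realise the triangle-gluing construction", {
  k3 <- fixture_network("K3")
  fs <- enumerate_faces(k3, d = 5)
  expect_length(fs$faces, 1L)
  expect_equal(fs$faces[[1]]$weight, 1.0)

  cc4 <- fixture_network("chorded_C4")   # cycle 1-2-3-4 with chord 1-3
  fs <- enumerate_faces(cc4, d = 4)
  ords <- vapply(fs$faces, `[[`, 0L, "order")
  expect_equal(sort(ords), c(3L, 3L, 4L))
  f4 <- fs$faces[[which(ords == 4L)]]
  expect_equal(f4$weight, 2.0)            # sum of its two unit triangles
  expect_length(f4$tris, 2L)
  # the 4-face's boundary excludes the chord: edge {1,3} is incident to the
  # two triangles only
  expect_length(fs$edge_faces[["1:3"]], 2L)
  expect_length(fs$edge_faces[["1:2"]], 2L)  # triangle 123 + the 4-face

  k4 <- fixture_network("K4")
  ords <- vapply(enumerate_faces(k4, d = 4)$faces, `[[`, 0L, "order")
  expect_equal(as.integer(table(ords)), c(4L, 6L))  # 4 triangles, 3 cycles x 2 gluings
  ded <- enumerate_faces(k4, d = 4, dedupe_cycles = TRUE)
  expect_equal(sum(vapply(ded$faces, `[[`, 0L, "order") == 4L), 3L)
})

test_that("triangle-free and over-long cycles yield no chordal faces", {
  expect_length(enumerate_faces(fixture_network("K33"), d = 5)$faces, 0L)
  # 6-cycle: no faces of order <= 5 in either mode
  W <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; W[i, j] <- W[j, i] <- 1 }
  c6 <- weighted_network(W)
  expect_length(enumerate_faces(c6, d = 5)$faces, 0L)
  expect_length(enumerate_faces(c6, d = 5, mode = "all_cycles")$faces, 0L)
  expect_error(enumerate_faces(c6, d = 6), "d must be")
})

test_that("all_cycles mode lists every short cycle exactly once", {
  q3 <- fixture_network("Q3")
  fs <- enumerate_faces(q3, d = 4, mode = "all_cycles")
  expect_length(fs$faces, 6L)   # the six square faces of the cube
  expect_true(all(vapply(fs$faces, `[[`, 0L, "order") == 4L))
  expect_true(all(vapply(fs$faces, function(f) length(f$tris), 0L) == 0L))
  expect_true(all(vapply(fs$faces, `[[`, 0, "weight") == 1))
  # every chordal face boundary also appears in all_cycles mode
  for (s in 1:5) {
    net <- random_weighted_network(9, 0.45, seed = 40 + s)
    ch <- enumerate_faces(net, d = 5)
    ac <- enumerate_faces(net, d = 5, mode = "all_cycles")
    ckey <- unique(vapply(ch$faces, function(f) netcurv:::.cycle_key(f$boundary), ""))
    akey <- vapply(ac$faces, function(f) netcurv:::.cycle_key(f$boundary), "")
    expect_true(all(ckey %in% akey))
    expect_false(anyDuplicated(akey) > 0)
  }
})

test_that("cycle enumeration matches the brute-force subset oracle", {
  for (s in 1:8) {
    net <- random_weighted_network(8, 0.5, seed = 60 + s)
    A <- net$weights > 0
    mine <- netcurv:::.simple_cycles(A, 5L)
    ref <- oracle_cycles(A, 5L)
    key <- function(cycles) sort(vapply(cycles, function(c)
      netcurv:::.cycle_key(c), ""))
    expect_identical(key(mine), key(ref))
  }
})

test_that("faces through one edge agree with the filtered global set", {
  canon <- function(f) paste(netcurv:::.cycle_key(f$boundary),
                             paste(sort(vapply(f$tris, paste, "",
                                               collapse = ".")), collapse = "|"))
  for (s in 1:10) {
    net <- random_weighted_network(10, 0.4, seed = 70 + s)
    W <- net$weights; A <- W > 0
    fs <- enumerate_faces(net, d = 5)
    el <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(el))) {
      loc <- netcurv:::.faces_through_edge(A, W, el[r, 1], el[r, 2], 5)
      glo <- fs$faces[fs$edge_faces[[netcurv:::.ekey(el[r, 1], el[r, 2])]]]
      expect_identical(sort(vapply(loc, canon, "")),
                       sort(vapply(glo, canon, "")))
    }
  }
})

test_that("hanging edges are adjacent edges with no short common cycle", {
  star <- fixture_network("star13")
  for (d in 3:5) {
    h <- hanging_edges(star, c("star13_0", "star13_1"), d = d)
    expect_equal(nrow(h), 2L)   # the two other spokes
  }
  expect_equal(nrow(hanging_edges(fixture_network("K3"), c(1, 2), d = 3)), 0L)
  q3 <- fixture_network("Q3")
  el <- edge_list(q3)
  for (r in seq_len(nrow(el))) {
    expect_equal(nrow(hanging_edges(q3, c(el$u[r], el$v[r]), d = 4)), 0L)
    expect_equal(nrow(hanging_edges(q3, c(el$u[r], el$v[r]), d = 5)), 0L)
  }
  for (fx in c("K222", "K33")) {
    net <- fixture_network(fx)
    el <- edge_list(net)
    for (r in seq_len(nrow(el)))
      expect_equal(nrow(hanging_edges(net, c(el$u[r], el$v[r]), d = 4)), 0L)
  }
  expect_error(hanging_edges(star, c("star13_1", "star13_2")), "does not exist")
  # hanging edges never co-bound a face with the edge
  net <- random_weighted_network(10, 0.3, seed = 90)
  fs <- enumerate_faces(net, d = 5)
  el <- edge_list(net)
  for (r in seq_len(nrow(el))) {
    h <- hanging_edges(net, c(el$u[r], el$v[r]), d = 5)
    if (!nrow(h)) next
    pf <- parallel_edges(net, c(el$u[r], el$v[r]), fs, "within_face")
    co <- unique(paste(pf$u, pf$v))
    fids <- fs$edge_faces[[netcurv:::.ekey(match(el$u[r], net$labels),
                                           match(el$v[r], net$labels))]]
    bound <- unlist(lapply(fs$faces[fids], function(f) {
      be <- netcurv:::.boundary_edges(f$boundary)
      paste(net$labels[pmin(be[, 1], be[, 2])],
            net$labels[pmax(be[, 1], be[, 2])])
    }))
    expect_length(intersect(paste(h$u, h$v), bound), 0L)
  }
})

test_that("parallel edges follow the shared-endpoint XOR shared-face rule", {
  k3 <- fixture_network("K3")
  fs <- enumerate_faces(k3, d = 5)
  expect_equal(nrow(parallel_edges(k3, c(1, 2), fs, "within_face")), 0L)

  cc4 <- fixture_network("chorded_C4")
  fs4 <- enumerate_faces(cc4, d = 4)
  pf <- parallel_edges(cc4, c("chorded_C4_0", "chorded_C4_1"), fs4, "within_face")
  expect_equal(nrow(pf), 1L)       # only the opposite boundary edge {3,4}
  expect_equal(sort(c(pf$u, pf$v)), c("chorded_C4_2", "chorded_C4_3"))

  star <- fixture_network("star13")
  fss <- enumerate_faces(star, d = 5)
  pg <- parallel_edges(star, c("star13_0", "star13_1"), fss, "global")
  expect_equal(nrow(pg), 2L)       # spokes share the hub, no face
})

test_that("the ordered-sequence count matches direct enumeration", {
  # independent enumeration: count ordered j-tuples without replacement
  tuples <- function(pool, j) {
    if (j == 0) return(1)
    s <- 0
    for (x in pool) s <- s + tuples(setdiff(pool, x), j - 1)
    s
  }
  for (n in c(5, 7, 9, 12)) {
    for (d in 4:5) {
      direct <- sum(vapply(seq_len(d - 3),
                           function(j) tuples(seq_len(n - 3), j), 0))
      expect_equal(sequence_count(n, d), direct)
    }
  }
  expect_equal(sequence_count(10, 4), 7)
  expect_equal(sequence_count(5, 5), 4)
  expect_error(sequence_count(2, 5), "n >= 3")
  expect_error(sequence_count(10, 3), "d >= 4")
})
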