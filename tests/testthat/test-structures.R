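test_that("count_unknowns matches closed forms and exhaustive enumeration", {
  expect_identical(count_unknowns(7, 2, "unordered"), 21L)
  expect_identical(count_unknowns(2, 1, "unordered"), 1L)
  expect_identical(count_unknowns(2, 1, "ordered"), 1L)
  expect_identical(count_unknowns(34, 2, "unordered"), 561L)
  # ordered H for D = 2 equals (N-1) + (N-1)(N-2), checked by enumerating
  # all tuples with distinct indices excluding the focal node
  for (n in c(3, 5, 8, 12)) {
    others <- seq_len(n)[-1]
    enum <- length(others) + nrow(hordyn:::ordered_tuples(others, 2))
    expect_identical(count_unknowns(n, 2, "ordered"), as.integer(enum))
    expect_identical(count_unknowns(n, 2, "unordered"),
                     as.integer(length(others) + choose(n - 1, 2)))
  }
  expect_error(count_unknowns(4, 4), "max_order")
  expect_error(count_unknowns(1, 1), "n_nodes")
})

test_that("column layout is order-1 ascending then lexicographic order-2", {
  ci <- column_index(5, 2, node = 3)
  expect_equal(nrow(ci), count_unknowns(5, 2, "unordered"))
  expect_equal(ci$n1[ci$order == 1], c(1, 2, 4, 5))
  pairs <- ci[ci$order == 2, c("n1", "n2")]
  expect_true(all(pairs$n1 < pairs$n2))
  expect_equal(pairs$n1, c(1, 1, 1, 2, 2, 4))
  expect_equal(pairs$n2, c(2, 4, 5, 4, 5, 5))
})

test_that("structure invariants are enforced", {
  expect_error(hyper_structure(3, 1, data.frame(order = 1, node = 1, n1 = 1,
                                                weight = 1)),
               "repeated")
  expect_error(hyper_structure(4, 2, data.frame(order = 2, node = 1, n1 = 3,
                                                n2 = 2, weight = 1)),
               "increasing")
  expect_error(hyper_structure(3, 1, data.frame(order = 1, node = 1, n1 = 4,
                                                weight = 1)),
               "outside")
  expect_error(hyper_structure(3, 1, data.frame(order = 1, node = c(1, 1),
                                                n1 = c(2, 2), weight = c(1, 2))),
               "duplicate")
  # undirected construction rejects asymmetric weights
  asym <- data.frame(order = 1, node = c(1, 2), n1 = c(2, 1), weight = c(1, 0.5))
  expect_error(hyper_structure(3, 1, asym, directed = FALSE), "symmetry")
})

test_that("karate fixture has 78 links and a brute-force triangle count of 45", {
  edges <- karate_club_edges()
  expect_equal(nrow(edges), 78L)
  expect_equal(max(c(edges$from, edges$to)), 34L)
  tri <- triangle_census(edges, 34)
  expect_equal(nrow(tri), 45L)
  kc <- build_karate_complex(1, seed = 1)
  expect_equal(sum(kc$entries$order == 1) / 2, 78)
  expect_equal(sum(kc$entries$order == 2) / 3, 45)
  # at delta = 1 the promoted set equals the triangle census
  e2 <- kc$entries[kc$entries$order == 2, ]
  promoted <- unique(t(apply(cbind(e2$node, e2$n1, e2$n2), 1, sort)))
  expect_equal(nrow(promoted), 45L)
  expect_equal(promoted[order(promoted[, 1], promoted[, 2], promoted[, 3]), ],
               unname(tri[order(tri[, 1], tri[, 2], tri[, 3]), ]))
})

test_that("karate triangle census agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_edgelist(as.matrix(karate_club_edges()),
                                   directed = FALSE)
  expect_equal(igraph::count_triangles(g), igraph::count_triangles(
    igraph::make_graph("Zachary")))
  expect_equal(sum(igraph::count_triangles(g)) / 3, 45)
})

test_that("delta controls the promoted fraction with half-up rounding", {
  expect_equal(sum(build_karate_complex(0, seed = 1)$entries$order == 2), 0)
  expect_equal(sum(build_karate_complex(0.5, seed = 1)$entries$order == 2) / 3,
               23)  # round(22.5) half-up
  expect_equal(sum(build_karate_complex(0.2, seed = 1)$entries$order == 2) / 3,
               9)
  expect_error(build_karate_complex(1.2), "\\[0, 1\\]")
  # promoted triangles are triangles of the graph (simplicial closure)
  kc <- build_karate_complex(0.4, seed = 7)
  edges <- karate_club_edges()
  a <- matrix(FALSE, 34, 34)
  a[cbind(edges$from, edges$to)] <- TRUE
  a <- a | t(a)
  e2 <- kc$entries[kc$entries$order == 2, ]
  for (r in seq_len(nrow(e2))) {
    trio <- sort(c(e2$node[r], e2$n1[r], e2$n2[r]))
    expect_true(a[trio[1], trio[2]] && a[trio[1], trio[3]] && a[trio[2], trio[3]])
  }
})

test_that("LV fixture carries the published three-body couplings and sign pattern", {
  hs <- build_lv_hypergraph(seed = 5)
  e1 <- hs$entries[hs$entries$order == 1, ]
  e2 <- hs$entries[hs$entries$order == 2, ]
  expect_equal(nrow(e1), 8L)
  expect_equal(nrow(e2), 2L)
  expect_equal(sum(e1$weight > 0), 4L)
  expect_equal(sum(e1$weight < 0), 4L)
  expect_true(all(abs(e1$weight) <= 0.01))
  expect_equal(flatten(hs, 2)[["d2:3,7"]], 0.0062)
  expect_equal(flatten(hs, 4)[["d2:1,6"]], 0.0016)
  # seeded determinism
  expect_identical(build_lv_hypergraph(seed = 5)$entries, hs$entries)
  expect_false(isTRUE(all.equal(build_lv_hypergraph(seed = 6)$entries$weight,
                                hs$entries$weight)))
})

test_that("flatten and unflatten are mutual inverses", {
  # trivial empty case
  empty <- hyper_structure(3, 1)
  expect_equal(unname(flatten(empty, 1)), c(0, 0))
  # property over random structures
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:7, 1)
    hs <- random_structure(n, max_order = 2L, density = stats::runif(1, 0.2, 0.9))
    i <- sample(n, 1)
    v <- flatten(hs, i)
    ent <- unflatten(v, i, n, 2L, "unordered")
    back <- hyper_structure(n, 2L, ent)
    expect_equal(flatten(back, i), v)
    # entries of the round trip match the structure's entries for that node
    orig <- hs$entries[hs$entries$node == i & hs$entries$weight != 0, ]
    expect_equal(nrow(ent), nrow(orig))
  }
  expect_error(unflatten(c(1, 2), 1, 4, 2), "length")
})

test_that("hyperedge TSV and JSON round trips preserve the structure", {
  hs <- build_lv_hypergraph(seed = 3)
  tf <- tempfile(fileext = ".tsv")
  write_hyperedge_tsv(hs, tf)
  back <- read_hyperedge_tsv(tf)
  expect_equal(back$entries, hs$entries)
  expect_equal(back$n_nodes, hs$n_nodes)
  expect_identical(back$convention, hs$convention)

  js <- structure_to_json(hs)
  back2 <- structure_from_json(js)
  expect_equal(back2$entries, hs$entries)

  kc <- build_karate_complex(0.3, seed = 2)
  tf2 <- tempfile(fileext = ".tsv")
  write_hyperedge_tsv(kc, tf2)
  expect_equal(read_hyperedge_tsv(tf2)$entries, kc$entries)
  expect_false(read_hyperedge_tsv(tf2)$directed)
})
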