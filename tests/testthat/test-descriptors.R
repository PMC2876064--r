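test_that("the registry defines 52 stable descriptors (25 basic + 27 derived)", {
  reg <- descriptor_registry()
  expect_equal(nrow(reg), 52L)
  expect_equal(sum(!reg$derived), 25L)
  expect_equal(sum(reg$derived), 27L)
  expect_false(anyDuplicated(reg$id) > 0)
  expect_identical(reg$id, descriptor_registry()$id)
  expect_identical(names(compute_descriptors(k4_nip())), reg$id)
})

test_that("closed-form fixtures reproduce hand-derived descriptor values", {
  k4 <- k4_nip()   # K4 with unit weights
  v <- compute_descriptors(k4)
  expect_equal(v[["connectedness"]], 1)
  expect_equal(v[["diameter"]], 1)
  expect_equal(v[["radius"]], 1)
  expect_equal(v[["avg_clustering"]], 1)
  expect_equal(v[["weighted_avg_clustering"]], 1)
  expect_equal(v[["avg_vertex_betweenness"]], 0)
  expect_equal(v[["avg_closeness"]], 1)
  expect_equal(v[["n_maximal_cliques"]], 1)
  expect_equal(v[["max_clique_size"]], 4)
  expect_equal(v[["ni_degree"]], 0)
  expect_equal(v[["avg_degree"]], 3)
  expect_equal(v[["total_adjacency"]], 12)

  # path on 4 vertices: distances 1,2,3,1,2,1
  p4 <- fixture_graph(data.frame(a = c("a", "b", "c"), b = c("b", "c", "d"),
                                 w = 1))
  vp <- compute_descriptors(p4)
  expect_equal(vp[["diameter"]], 3)
  expect_equal(vp[["radius"]], 2)
  expect_equal(vp[["avg_distance"]], 10 / 6)
  expect_equal(vp[["total_distance"]], 10)
  expect_equal(vp[["n_maximal_cliques"]], 3)

  # star: center carries every leaf pair
  star <- fixture_graph(data.frame(a = "c0", b = c("l1", "l2", "l3"), w = 1))
  bs <- nip_betweenness(star, "vertex")
  expect_equal(bs[["c0"]], 1)
  expect_equal(unname(bs[c("l1", "l2", "l3")]), rep(0, 3))
  expect_equal(unname(nip_clustering(star)), rep(0, 4))

  # two disjoint edges: harmonic closeness (1 + 0 + 0)/3 everywhere
  de <- fixture_graph(data.frame(a = c("a", "c"), b = c("b", "d"), w = 1))
  expect_equal(unname(nip_closeness(de)), rep(1 / 3, 4))
  vd <- compute_descriptors(de)
  expect_equal(vd[["avg_distance"]], 1)      # only reachable pairs count
  expect_equal(vd[["diameter"]], 1)

  # single weighted edge: reciprocal-weight length
  e1 <- fixture_graph(data.frame(a = "a", b = "b", w = 4))
  expect_equal(nip_distances(e1, weighted = TRUE)["a", "b"], 0.25)

  # weighted triangle + pendant, Barrat by hand (ordered-pair form)
  g <- fixture_graph(data.frame(a = c("a", "a", "b", "a"),
                                b = c("b", "c", "c", "d"),
                                w = c(1, 2, 3, 4)))
  cw <- nip_clustering(g, weighted = TRUE)
  expect_equal(cw[["a"]], (1 + 2) / (7 * 2), tolerance = 1e-12)
  expect_equal(cw[["b"]], (1 + 3) / (4 * 1), tolerance = 1e-12)
  expect_equal(cw[["c"]], (2 + 3) / (5 * 1), tolerance = 1e-12)
  expect_equal(cw[["d"]], 0)
})

test_that("K4 betweenness is zero and empty graphs yield NaN descriptors", {
  expect_equal(unname(nip_betweenness(k4_nip(), "vertex")), rep(0, 4))
  g0 <- igraph::make_empty_graph(0, directed = FALSE)
  expect_warning(v <- compute_descriptors(g0), "empty")
  expect_true(all(is.nan(v)))
})

test_that("descriptors equal the naive oracle on random weighted graphs", {
  for (seed in 1:8) {
    g <- random_graph(n = sample(5:14, 1), p = 0.45, seed = seed)
    impl <- compute_descriptors(g)
    orac <- o_descriptors(g, cliques = o_cliques_brute(g))
    expect_equal(impl, orac[names(impl)], tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("betweenness matches exhaustive path enumeration on small graphs", {
  for (seed in c(2, 5, 9)) {
    g <- random_graph(n = sample(5:8, 1), p = 0.5, seed = seed)
    for (wt in c(FALSE, TRUE)) {
      expect_equal(nip_betweenness(g, "vertex", weighted = wt),
                   o_betweenness_enum(g, weighted = wt), tolerance = 1e-9,
                   info = paste("seed", seed, "weighted", wt))
    }
  }
})

test_that("maximal cliques match 2^n subset enumeration", {
  for (seed in 1:6) {
    g <- random_graph(n = sample(4:10, 1), p = 0.5, seed = 20 + seed)
    expect_equal(nip_maximal_cliques(g), o_cliques_brute(g))
  }
})

test_that("scaling weights leaves unweighted descriptors invariant", {
  g <- random_graph(10, 0.4, seed = 7)
  reg <- descriptor_registry()
  v1 <- compute_descriptors(g)
  g2 <- g
  igraph::E(g2)$weight <- igraph::E(g2)$weight * 3
  v2 <- compute_descriptors(g2)
  unweighted <- reg$id[!reg$weighted]
  expect_equal(v1[unweighted], v2[unweighted], tolerance = 1e-12)
  # weighted distances scale by 1/c
  expect_equal(v2[["weighted_avg_distance"]],
               v1[["weighted_avg_distance"]] / 3, tolerance = 1e-12)
})

test_that("descriptors are invariant under vertex relabeling", {
  g <- random_graph(9, 0.5, seed = 13)
  v1 <- compute_descriptors(g)
  g2 <- g
  # reverse the vertex names (an isomorphism)
  igraph::V(g2)$name <- rev(sprintf("Q%02d", seq_len(igraph::vcount(g2))))
  v2 <- compute_descriptors(g2)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("bounded descriptors stay in range and radius <= diameter <= 2 radius", {
  for (seed in 1:10) {
    g <- random_graph(sample(4:12, 1), 0.5, seed = 40 + seed)
    v <- compute_descriptors(g)
    expect_gte(v[["connectedness"]], 0); expect_lte(v[["connectedness"]], 1)
    cl <- c(nip_clustering(g), nip_clustering(g, weighted = TRUE))
    expect_true(all(cl >= 0 & cl <= 1))
    ni <- v[grep("^ni_", names(v))]
    ni <- ni[is.finite(ni)]
    expect_true(all(ni >= -1e-12 & ni <= 1 + 1e-12))
    if (igraph::is_connected(g) && igraph::vcount(g) > 1) {
      expect_lte(v[["radius"]], v[["diameter"]])
      expect_lte(v[["diameter"]], 2 * v[["radius"]])
    }
  }
})

test_that("descriptor tables round-trip through TSV", {
  nips <- list(t1 = k4_nip(), t2 = fixture_graph(
    data.frame(a = "a", b = "b", w = 2), isolated = "c"))
  desc <- suppressWarnings(descriptor_table(nips))
  expect_equal(desc$taxon_id, c("t1", "t2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptors(desc, path)
  back <- read_descriptors(path)
  expect_equal(back, desc, tolerance = 1e-15)
})
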