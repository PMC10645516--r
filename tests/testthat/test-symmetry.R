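# permutation action, the symmetry test, group detection, preservation

test_that("apply_permutation is the right action obeying the composition rule", {
  expect_identical(apply_permutation(c(1, 0, 0), 1:3), c(1, 0, 0))
  # sigma the 3-cycle with sigma(1) = 2: result_g = x_{sigma(g)}
  sigma <- c(2L, 3L, 1L)
  expect_identical(apply_permutation(c(1, 0, 0), sigma), c(0, 0, 1))
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    x <- sample(0:1, n, replace = TRUE)
    s <- sample.int(n); t <- sample.int(n)
    expect_identical(apply_permutation(apply_permutation(x, s), t),
                     apply_permutation(x, perm_compose(s, t)))
  }
  expect_error(apply_permutation(c(1, 0), 1:3), "lengths differ")
})

test_that("is_symmetry accepts true symmetries and rejects structure-breaking permutations", {
  p8 <- make_model("undirected_cycle_moran", n = 8)
  expect_true(is_symmetry(p8, 1:8))
  expect_true(is_symmetry(p8, rotation_perm(8, 2)))   # g -> g + 2 (mod 8)
  dc5 <- make_model("directed_cycle_moran", n = 5)
  refl5 <- c(1L, 5L, 4L, 3L, 2L)                      # g -> -g (mod 5)
  res <- is_symmetry(dc5, refl5)
  expect_false(isTRUE(res))
  expect_true(!is.null(attr(res, "violation")))
  star <- make_model("star_moran_db", n = 5)
  expect_false(isTRUE(is_symmetry(star, c(2L, 1L, 3L, 4L, 5L))))  # hub <-> leaf
  expect_error(is_symmetry(star, c(1L, 1L, 3L, 4L, 5L)), "not a permutation")
})

test_that("detected symmetry groups have the structure-group orders of the model families", {
  expect_equal(symmetry_group(make_model("well_mixed_moran", n = 4))$order, 24)     # n!
  expect_equal(symmetry_group(make_model("wright_fisher", n = 3))$order, 6)         # n!
  expect_equal(symmetry_group(make_model("island_moran", islands = 2, island_size = 2,
                                         migration = "1/10"))$order, 8)             # m!(k!)^m
  expect_equal(symmetry_group(make_model("class_moran", sizes = c(2, 3)))$order, 12) # prod n_j!
  expect_equal(symmetry_group(make_model("undirected_cycle_moran", n = 8))$order, 16) # 2n
  expect_equal(symmetry_group(make_model("directed_cycle_moran", n = 5))$order, 5)   # n
  expect_equal(symmetry_group(make_model("star_moran_db", n = 5))$order, 24)         # (n-1)!
})

test_that("every returned group satisfies the group axioms", {
  groups <- list(symmetry_group(make_model("star_moran_db", n = 4)),
                 symmetry_group(make_model("directed_cycle_moran", n = 5)),
                 symmetry_group(make_model("class_moran", sizes = c(2, 2))))
  for (g in groups) expect_true(validate_group(g))
})

test_that("generator closure yields subgroups and rejects non-symmetries", {
  p <- make_model("undirected_cycle_moran", n = 6)
  rot <- symmetry_group(p, generators = list(rotation_perm(6, 1)))
  expect_equal(rot$order, 6)  # rotations only
  both <- symmetry_group(p, generators = list(rotation_perm(6, 1),
                                              c(6L, 5L, 4L, 3L, 2L, 1L)))
  expect_equal(both$order, 12)
  expect_error(symmetry_group(p, generators = list(c(2L, 1L, 3L, 4L, 5L, 6L))),
               "not a symmetry")
})

test_that("site orbits recover population classes and transitivity", {
  wm <- site_orbits(symmetry_group(make_model("well_mixed_moran", n = 4)))
  expect_length(wm$orbits, 1)
  expect_true(wm$transitive)
  star <- site_orbits(symmetry_group(make_model("star_moran_db", n = 5)))
  expect_equal(star$orbits, list(1L, 2:5))
  expect_false(star$transitive)
  cls <- site_orbits(symmetry_group(make_model("class_moran", sizes = c(2, 3))))
  expect_equal(cls$orbits, list(1:2, 3:5))   # the configured class partition
  trivial <- selsym:::new_symmetry_group(3, matrix(1:3, 1))
  expect_equal(site_orbits(trivial)$orbits, list(1L, 2L, 3L))
})

test_that("symmetries preserve one-step and m-step transition probabilities exactly", {
  models <- list(make_model("well_mixed_moran", n = 4),
                 make_model("undirected_cycle_moran", n = 5),
                 make_model("star_moran_db", n = 5),
                 make_model("class_moran", sizes = c(2, 2)),
                 make_model("well_mixed_moran", n = 3, r = "3/2", u = "1/10"))
  for (p in models) {
    g <- symmetry_group(p)
    P <- build_chain(p)
    expect_true(verify_transition_preservation(P, g)$ok, info = p$model)
    expect_true(verify_transition_preservation(P, g, steps = 2)$ok, info = p$model)
  }
  # the trivial group passes vacuously; a wrong "group" is caught
  P <- build_chain(make_model("star_moran_db", n = 4))
  expect_true(verify_transition_preservation(
    P, selsym:::new_symmetry_group(4, matrix(1:4, 1)))$ok)
  bad <- selsym:::new_symmetry_group(4, rbind(1:4, c(2L, 1L, 3L, 4L)))
  out <- verify_transition_preservation(P, bad)
  expect_false(out$ok)
  expect_gt(nrow(out$violations), 0)
})

test_that("detected groups of neutral graph models equal the graph automorphism group", {
  # independent oracle: automorphism count of the underlying (di)graph
  cyc <- igraph::graph_from_adjacency_matrix(cycle_adjacency(6, directed = FALSE) > 0,
                                             mode = "undirected")
  expect_equal(symmetry_group(make_model("undirected_cycle_moran", n = 6))$order,
               as.numeric(igraph::count_automorphisms(cyc)$group_size))
  star <- igraph::graph_from_adjacency_matrix(star_adjacency(5) > 0,
                                              mode = "undirected")
  expect_equal(symmetry_group(make_model("star_moran_db", n = 5))$order,
               as.numeric(igraph::count_automorphisms(star)$group_size))
})

test_that("groups serialize to JSON and back", {
  g <- symmetry_group(make_model("directed_cycle_moran", n = 4))
  f <- tempfile(fileext = ".json")
  write_group_json(g, f)
  g2 <- read_group_json(f)
  expect_identical(group_keyset(g), group_keyset(g2))
})

test_that("cycle notation round-trips", {
  sigma <- c(3L, 4L, 5L, 1L, 2L, 6L)
  expect_identical(parse_cycle_notation(cycle_notation(sigma), 6), sigma)
  expect_equal(cycle_notation(c(2L, 3L, 1L)), "(1 2 3)")
})
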