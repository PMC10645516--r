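# state orbits, the lumped chain, Burnside counting, bounds

test_that("state orbits partition the state space with constant allele counts", {
  # full symmetric group: one orbit per number of 1 alleles
  ol <- state_orbits(make_structure_group("symmetric", 4))
  expect_length(ol$orbits, 5)
  expect_equal(vapply(ol$orbits, `[[`, numeric(1), "allele_count"), 0:4)
  expect_equal(vapply(ol$orbits, `[[`, integer(1), "size"), choose(4, 0:4))
  # trivial group: all states non-equivalent
  triv <- selsym:::new_symmetry_group(3, matrix(1:3, 1))
  expect_length(state_orbits(triv)$orbits, 8)
  # cyclic group of order 5 on 5 sites: 8 binary necklaces
  expect_length(state_orbits(make_structure_group("cyclic", 5))$orbits, 8)
  # members share the allele count and cover all states exactly once
  ol2 <- state_orbits(make_structure_group("dihedral", 5))
  all_members <- unlist(lapply(ol2$orbits, `[[`, "members"))
  expect_setequal(all_members, 1:32)
  for (o in ol2$orbits) {
    counts <- vapply(o$members, function(i) sum(index_to_state(i, 5)), numeric(1))
    expect_true(all(counts == o$allele_count))
  }
})

test_that("the reduced chain reproduces the classical Moran chain on allele counts", {
  p <- make_model("well_mixed_moran", n = 3)
  g <- symmetry_group(p)
  ol <- state_orbits(g)
  rc <- build_reduced_chain(build_chain(p), ol)
  expect_equal(rc$R, 4)   # indexed by 0..3 mutants
  expect_equal(rc$labels, c("000", "100", "110", "111"))
  # from one mutant: up 2/9, down 2/9, stay 5/9 -- exactly
  expect_identical(c(rc$num[2, 3], rc$den[2, 3]), c(2, 9))
  expect_identical(c(rc$num[2, 1], rc$den[2, 1]), c(2, 9))
  expect_identical(c(rc$num[2, 2], rc$den[2, 2]), c(5, 9))
  expect_equal(unname(rowSums(as.matrix(rc))), rep(1, 4), tolerance = 1e-15)
})

test_that("lumping over a non-symmetry partition is rejected with a diagnostic", {
  P <- build_chain(make_model("star_moran_db", n = 4))
  wrong <- state_orbits(make_structure_group("symmetric", 4))
  expect_error(build_reduced_chain(P, wrong), "lumpability violation")
})

test_that("reduced-chain dynamics agree with the full chain", {
  # stationary: orbit-summed full-chain pi equals the reduced-chain pi
  p <- make_model("well_mixed_moran", n = 3, u = "1/10")
  g <- symmetry_group(p)
  ol <- state_orbits(g)
  P <- build_chain(p)
  rc <- build_reduced_chain(P, ol)
  pi_full <- stationary_distribution(P)$pi
  pi_red <- stationary_distribution(as.matrix(rc))$pi
  lumped <- vapply(ol$orbits, function(o) sum(pi_full[o$members]), numeric(1))
  expect_equal(pi_red, lumped, tolerance = 1e-9)
  # absorption: reduced-chain fixation matches representative states' rho
  ps <- make_model("star_moran_db", n = 5)
  gs <- symmetry_group(ps)
  ols <- state_orbits(gs)
  rcs <- build_reduced_chain(build_chain(ps), ols)
  rho_full <- fixation_probabilities(ps)$rho
  rho_red <- reduced_chain_fixation(rcs)
  reps <- vapply(ols$orbits, `[[`, integer(1), "representative")
  expect_equal(rho_red, rho_full[reps], tolerance = 1e-10)
})

test_that("cycle decompositions of cycle-graph rotations follow the gcd rule", {
  expect_equal(cycle_count(rotation_perm(6, 1))$count, 1)
  cd2 <- cycle_count(rotation_perm(6, 2))
  expect_equal(cd2$count, 2)
  expect_setequal(lapply(cd2$cycles, sort), list(c(1L, 3L, 5L), c(2L, 4L, 6L)))
  expect_equal(cycle_count(rotation_perm(6, 3))$count, 3)
  expect_equal(cycle_count(1:7)$count, 7)   # identity: every site is a fixed point
})

test_that("Burnside counts equal brute-force orbit enumeration for 2 and 3 alleles", {
  groups <- list(sym4 = make_structure_group("symmetric", 4),
                 star5 = make_structure_group("star", 5),
                 class23 = make_structure_group("class_partition", 5, sizes = c(2, 3)),
                 cyc6 = make_structure_group("cyclic", 6),
                 dih6 = make_structure_group("dihedral", 6),
                 block22 = make_structure_group("block_partition", 4,
                                                block_count = 2, block_size = 2))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    for (m in 2:3) {
      expect_equal(count_reduced_states(g, m),
                   length(state_orbits(g, num_alleles = m,
                                       max_states = 3^8)$orbits),
                   info = paste(nm, m))
    }
  }
  # non-group input fails the divisibility consistency check
  notgroup <- selsym:::new_symmetry_group(3, rbind(1:3, c(2L, 1L, 3L), c(3L, 2L, 1L)))
  expect_error(count_reduced_states(notgroup), "not a group")
})

test_that("the closed-form counts of the standard families hold", {
  # well-mixed: n + 1
  for (n in 2:7) {
    expect_equal(count_reduced_states(make_structure_group("symmetric", n)), n + 1)
  }
  # classes: prod (n_j + 1)
  for (sz in list(c(2, 3), c(1, 4), c(2, 2, 2), c(3, 3, 4))) {
    expect_equal(count_reduced_states(
      make_structure_group("class_partition", sum(sz), sizes = sz)),
      prod(sz + 1))
  }
  # star on n sites: 2n (hub state x mutant count among the leaves)
  for (n in 3:8) {
    expect_equal(count_reduced_states(make_structure_group("star", n)), 2 * n)
  }
  # directed cycle: necklace formula; equals the cyclic-group Burnside count
  expect_equal(count_directed_cycle(5), 8)
  expect_equal(count_directed_cycle(6), 14)
  expect_equal(count_directed_cycle(1), 2)
  expect_equal(count_directed_cycle(1, num_alleles = 3), 3)
  for (n in 2:10) {
    expect_equal(count_directed_cycle(n),
                 count_reduced_states(make_structure_group("cyclic", n)))
  }
  # prime cycle lengths: 2 + (2^n - 2)/n
  for (n in c(2, 3, 5, 7, 11)) {
    expect_equal(count_directed_cycle(n), 2 + (2^n - 2) / n)
  }
  # reflections merge orbits: dihedral count strictly below rotations-only
  expect_lt(count_reduced_states(make_structure_group("dihedral", 6)),
            count_directed_cycle(6))
  expect_equal(count_reduced_states(make_structure_group("dihedral", 6)), 13)
})

test_that("orbit-count bounds hold exactly and collapse in the degenerate cases", {
  # S = n!: both bounds equal n + 1 ; S = 1: both equal 2^n
  for (n in 2:8) {
    b <- state_count_bounds(n, factorial(n))
    expect_equal(c(b$lower, b$upper), c(n + 1, n + 1))
    b1 <- state_count_bounds(n, 1)
    expect_equal(c(b1$lower, b1$upper), c(2^n, 2^n))
  }
  # prime directed cycle: bounds coincide at 2 + (2^n - 2)/n
  b5 <- state_count_bounds(5, 5)
  expect_equal(c(b5$lower, b5$upper), c(8, 8))
  # star on 5 sites: S = 4! gives 6 <= R <= 2 + n(n-1) = 22, R = 10 inside
  b24 <- state_count_bounds(5, 24)
  expect_identical(c(b24$lower_num, b24$lower_den), c(6, 1))
  expect_identical(c(b24$upper_num, b24$upper_den), c(22, 1))
  expect_true(bounds_hold(b24, 10))
  # bounds hold for every computed (n, S, R) triple across the families
  cases <- list(list(g = make_structure_group("symmetric", 5)),
                list(g = make_structure_group("star", 6)),
                list(g = make_structure_group("cyclic", 7)),
                list(g = make_structure_group("dihedral", 7)),
                list(g = make_structure_group("class_partition", 6, sizes = c(2, 4))),
                list(g = make_structure_group("block_partition", 6,
                                              block_count = 3, block_size = 2)))
  for (cs in cases) {
    g <- cs$g
    R <- count_reduced_states(g)
    expect_true(bounds_hold(state_count_bounds(g$n, g$order), R),
                info = paste(g$n, g$order, R))
  }
})

test_that("orbit tables and reduced chains export", {
  g <- symmetry_group(make_model("well_mixed_moran", n = 3))
  ol <- state_orbits(g)
  rc <- build_reduced_chain(build_chain(make_model("well_mixed_moran", n = 3)), ol)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  write_reduced_csv(rc, f1)
  expect_equal(nrow(utils::read.csv(f1, row.names = 1)), 4)
  write_orbits_json(ol, f2, members = TRUE)
  parsed <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(nrow(parsed), 4)
})
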