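# chain construction, absorption, stationarity

test_that("next_state implements inheritance with mutation flips", {
  x <- c(1, 0, 1, 1)
  expect_equal(next_state(x, 1:4), x)                          # identity map
  set.seed(11)
  for (rep in 1:20) {                                          # x' = x o alpha
    a <- sample.int(4, 4, replace = TRUE)
    expect_equal(next_state(x, a), x[a])
  }
  # a cycle state where site 8 takes a mutated copy of site 7
  y <- c(1, 0, 1, 0, 1, 0, 0, 1)
  a <- 1:8; a[8] <- 7L
  out <- next_state(y, a, mutated = 8L)
  expect_equal(out[1:7], y[1:7])
  expect_equal(out[8], 1 - y[7])
  expect_error(next_state(x, c(1:3, 9L)), "out of range")
})

test_that("the selection chain is row-stochastic with absorbing constant states when mutation-free", {
  for (p in list(make_model("well_mixed_moran", n = 4),
                 make_model("star_moran_db", n = 4),
                 make_model("directed_cycle_moran", n = 4))) {
    P <- build_chain(p)
    S <- 2^p$n
    # exact row sums
    for (i in seq_len(S)) {
      s <- selsym:::rat_sum(P$num[i, ], P$den[i, ])
      expect_identical(c(s$num, s$den), c(1, 1))
    }
    expect_equal(P$num[1, 1] / P$den[1, 1], 1)
    expect_equal(P$num[S, S] / P$den[S, S], 1)
    expect_true(all(as.matrix(P) >= 0))
  }
})

test_that("neutral well-mixed n=3 transitions from one mutant are 2/9 up and 2/9 down", {
  P <- build_chain(make_model("well_mixed_moran", n = 3))
  i <- state_index(c(1, 0, 0))
  up <- selsym:::rat_sum(P$num[i, c(state_index(c(1, 1, 0)), state_index(c(1, 0, 1)))],
                         P$den[i, c(state_index(c(1, 1, 0)), state_index(c(1, 0, 1)))])
  expect_identical(c(up$num, up$den), c(2, 9))
  down <- chain_entry(P, i, state_index(c(0, 0, 0)))
  expect_identical(down, c(2, 9))
})

test_that("two-step transition matrix satisfies Chapman-Kolmogorov", {
  P <- as.matrix(build_chain(make_model("undirected_cycle_moran", n = 4, u = "1/8")))
  P2 <- P %*% P
  expect_equal(unname(rowSums(P2)), rep(1, nrow(P)), tolerance = 1e-12)
  # two applications of one step agree with the squared matrix on a start mass
  v <- numeric(nrow(P)); v[3] <- 1
  expect_equal(as.vector((v %*% P) %*% P), as.vector(v %*% P2), tolerance = 1e-12)
})

test_that("fixation probabilities: boundaries, neutrality, and the classic Moran formula", {
  fx <- fixation_probabilities(make_model("well_mixed_moran", n = 3))
  expect_equal(fx$rho[1], 0)
  expect_equal(fx$rho[8], 1)
  for (g in 1:3) {
    expect_equal(fx$rho[state_index(single_mutant(3, g))], 1 / 3, tolerance = 1e-12)
  }
  # with selection: birth-death chain on mutant counts gives
  # rho_1 = (1 - 1/r) / (1 - 1/r^n)
  r <- 2
  fx2 <- fixation_probabilities(make_model("well_mixed_moran", n = 4, r = r))
  expect_equal(fx2$rho[state_index(single_mutant(4, 1))],
               (1 - 1 / r) / (1 - 1 / r^4), tolerance = 1e-10)
  # mutation present -> not defined
  expect_error(fixation_probabilities(make_model("well_mixed_moran", n = 3, u = "1/10")),
               "mutation-free")
  # fixation axiom failure is diagnosed
  expect_error(fixation_probabilities(disconnected_demes_process()),
               "fixation axiom")
})

test_that("stationary distribution exists uniquely with mutation and is invariant under symmetries", {
  p <- make_model("well_mixed_moran", n = 3, u = "1/10")
  P <- build_chain(p)
  pi <- stationary_distribution(P)
  expect_equal(sum(pi$pi), 1, tolerance = 1e-12)
  expect_equal(as.vector(pi$pi %*% as.matrix(P)), pi$pi, tolerance = 1e-9)
  g <- make_structure_group("symmetric", 3)
  for (k in seq_len(g$order)) {
    sp <- selsym:::state_permutation(g$elements[k, ], 3)
    expect_equal(pi$pi[sp], pi$pi, tolerance = 1e-9)
  }
  # mutation-free chain: two absorbing states, no unique pi
  expect_error(stationary_distribution(build_chain(make_model("well_mixed_moran", n = 3))),
               "not unique")
  expect_error(stationary_distribution(diag(4)), "not unique")
})

test_that("transition matrices export to CSV and sparse triples", {
  P <- build_chain(make_model("well_mixed_moran", n = 2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile()
  write_chain_csv(P, f1)
  back <- utils::read.csv(f1, row.names = 1)
  expect_equal(unname(as.matrix(back)), unname(as.matrix(P)), tolerance = 1e-12)
  write_chain_sparse(P, f2)
  tri <- utils::read.table(f2, header = TRUE)
  expect_equal(sum(tri$prob), 4)  # four unit row sums
})
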