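# fixation-axiom decision, witnesses, certificates, and the closure oracle

test_that("always_possible_maps returns the state-independent parentage maps", {
  wm <- make_model("well_mixed_moran", n = 3)
  D <- always_possible_maps(wm)
  # every (parent, dying) replacement map, with the n self-replacements
  # collapsing onto the identity: n(n-1) + 1 maps
  expect_length(D, 3 * 2 + 1)
  expect_true(any(vapply(D, function(m) all(m == 1:3), logical(1))))
  dc <- make_model("directed_cycle_moran", n = 3)
  Ddc <- always_possible_maps(dc)
  expect_length(Ddc, 3)   # one map per dying site, no identity
  expect_false(any(vapply(Ddc, function(m) all(m == 1:3), logical(1))))
})

test_that("the axiom holds with a re-verifiable witness on standard models", {
  models <- list(make_model("well_mixed_moran", n = 4),
                 make_model("directed_cycle_moran", n = 5),
                 make_model("star_moran_db", n = 5),
                 make_model("island_moran", islands = 2, island_size = 2,
                            migration = "1/10"),
                 make_model("wright_fisher", n = 3))
  for (p in models) {
    D <- always_possible_maps(p)
    keys <- vapply(D, paste, character(1), collapse = ",")
    res <- check_fixation_axiom(p)
    expect_true(res$holds, info = p$model)
    w <- res$witness
    # every witness map is available in every state
    for (m in w$map_sequence) {
      expect_true(paste(m, collapse = ",") %in% keys, info = p$model)
    }
    # the composition m1 o m2 o ... o mk is constant at the target site
    v <- seq_len(p$n)
    for (i in rev(seq_along(w$map_sequence))) v <- w$map_sequence[[i]][v]
    expect_true(all(v == w$target_site), info = p$model)
  }
})

test_that("axiom failures come with an unmergeable-pair certificate", {
  res1 <- check_fixation_axiom(identity_only_process(3))
  expect_false(res1$holds)
  expect_null(res1$witness)
  expect_length(res1$certificate, 2)
  # the certificate pair really cannot merge: identity is the only map
  expect_true(res1$certificate[1] != res1$certificate[2])

  res2 <- check_fixation_axiom(disconnected_demes_process())
  expect_false(res2$holds)
  cert <- res2$certificate
  # the certified pair straddles the two demes
  expect_true(xor(cert[1] <= 2, cert[2] <= 2))
  # and no composite of always-possible maps merges it
  cl <- composite_map_closure(always_possible_maps(disconnected_demes_process()), 4)
  expect_true(all(cl[, cert[1]] != cl[, cert[2]]))
})

test_that("the decision agrees with the semigroup-closure oracle", {
  procs <- list(make_model("well_mixed_moran", n = 3),
                make_model("directed_cycle_moran", n = 4),
                make_model("star_moran_db", n = 4),
                identity_only_process(3),
                disconnected_demes_process(),
                random_process(4, seed = 101),
                random_process(5, seed = 202, n_events = 2),
                random_process(3, seed = 303, mutation = TRUE))
  for (p in procs) {
    decided <- check_fixation_axiom(p)$holds
    cl <- composite_map_closure(always_possible_maps(p), p$n)
    has_constant <- any(apply(cl, 1, function(v) length(unique(v)) == 1))
    expect_identical(decided, has_constant,
                     info = paste(p$model, p$params$seed %||% ""))
  }
})

test_that("single-site populations satisfy the axiom trivially", {
  res <- check_fixation_axiom(identity_only_process(1))
  expect_true(res$holds)
  expect_equal(res$witness$target_site, 1L)
})

test_that("witnesses serialize to JSON", {
  w <- check_fixation_axiom(make_model("well_mixed_moran", n = 3))$witness
  f <- tempfile(fileext = ".json")
  write_witness_json(w, f)
  back <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(back$target_site, w$target_site)
  expect_equal(length(back$map_sequence), length(w$map_sequence))
  for (i in seq_along(back$map_sequence)) {
    expect_equal(unlist(back$map_sequence[[i]]), w$map_sequence[[i]])
  }
})
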