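# fixtures built in code: degenerate and negative-control processes

# process whose only parentage map is the identity in every state
identity_only_process <- function(n) {
  sup <- lapply(seq_len(2^n), function(i) {
    list(alpha = matrix(seq_len(n), 1), U = matrix(FALSE, 1, n),
         pnum = 1, pden = 1)
  })
  selection_process(n, sup, model = "identity_only")
}

# two well-mixed demes of two sites each, with no migration between them:
# ancestries can never cross demes, so the fixation axiom fails
disconnected_demes_process <- function() {
  n <- 4L
  sup <- lapply(seq_len(2^n), function(i) {
    rows <- list()
    for (d in seq_len(n)) {
      deme <- if (d <= 2) 1:2 else 3:4
      for (p in deme) {
        a <- seq_len(n); a[d] <- p
        rows[[length(rows) + 1L]] <- a
      }
    }
    E <- length(rows)
    list(alpha = do.call(rbind, rows), U = matrix(FALSE, E, n),
         pnum = rep(1, E), pden = rep(E, E))
  })
  selection_process(n, sup, model = "disconnected_demes")
}

# canonical sortable representation of a group's element set
group_keyset <- function(g) {
  sort(apply(g$elements, 1, paste, collapse = ","))
}

single_mutant <- function(n, g) {
  x <- rep(0L, n); x[g] <- 1L
  x
}

# exact transition probability as num/den pair
chain_entry <- function(P, i, j) c(P$num[i, j], P$den[i, j])

rotation_perm <- function(n, j) ((seq_len(n) - 1 + j) %% n) + 1L
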