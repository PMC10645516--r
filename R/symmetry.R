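#' Symmetries of a selection process
#'
#' A symmetry is a permutation sigma of the sites such that for every state x
#' and every replacement event (alpha, U),
#' `p_x(alpha, U) = p_{x sigma}(sigma^-1 o alpha o sigma, sigma^-1(U))`,
#' where `(x sigma)_g = x_{sigma(g)}`. The symmetries of a process form a
#' group under composition; it acts on sites on the left (`g -> sigma(g)`)
#' and on states on the right (`x -> x sigma`).
#'
#' @name symmetry
NULL

## cached per-state support keys for fast matching
support_keys <- function(process) {
  lapply(process$support, function(ev) {
    list(keys = event_keys(ev$alpha, ev$U), pnum = ev$pnum, pden = ev$pden)
  })
}

#' Test whether a permutation is a symmetry of a process
#'
#' Checks the defining probability equality over the full enumerated support:
#' every event (alpha, U) of every state x must correspond, with equal
#' probability, to the event (sigma^-1 o alpha o sigma, sigma^-1(U)) of the
#' permuted state x sigma, with supports matching exactly in both directions.
#'
#' @param process a `selection_process`.
#' @param sigma permutation image vector of length `process$n`.
#' @param cache optional precomputed `support_keys(process)` (internal reuse).
#' @return TRUE or FALSE; on FALSE the attribute `"violation"` holds one
#'   violating (state, event) witness.
#' @export
is_symmetry <- function(process, sigma, cache = NULL) {
  stopifnot(inherits(process, "selection_process"))
  n <- process$n
  if (length(sigma) != n) stop("permutation length differs from site count")
  sigma <- check_perm(sigma)
  sinv <- perm_inverse(sigma)
  keys <- cache %||% support_keys(process)
  sp <- state_permutation(sigma, n)
  for (i in seq_len(2^n)) {
    ev <- process$support[[i]]
    j <- sp[i]
    tgt <- keys[[j]]
    if (nrow(ev$alpha) != length(tgt$keys)) {
      return(structure(FALSE, violation = list(state = i, reason = "support size")))
    }
    # sigma^-1 o alpha o sigma and sigma^-1(U), applied to every event at once
    ta <- matrix(sinv[ev$alpha[, sigma, drop = FALSE]], nrow = nrow(ev$alpha))
    tu <- ev$U[, sigma, drop = FALSE]
    tk <- event_keys(ta, tu)
    m <- match(tk, tgt$keys)
    if (anyNA(m)) {
      e <- which(is.na(m))[1]
      return(structure(FALSE, violation = list(
        state = i, alpha = ev$alpha[e, ], U = which(ev$U[e, ]),
        reason = "transformed event absent in permuted state")))
    }
    ok <- prob_equal(process$exact, ev$pnum, ev$pden, tgt$pnum[m], tgt$pden[m])
    if (!all(ok)) {
      e <- which(!ok)[1]
      return(structure(FALSE, violation = list(
        state = i, alpha = ev$alpha[e, ], U = which(ev$U[e, ]),
        reason = "probability mismatch")))
    }
  }
  TRUE
}

## ---- the symmetry_group class -----------------------------------------------

new_symmetry_group <- function(n, elements) {
  keys <- apply(elements, 1, paste, collapse = ",")
  elements <- elements[order(keys), , drop = FALSE]
  elements <- elements[!duplicated(apply(elements, 1, paste, collapse = ",")), ,
                       drop = FALSE]
  storage.mode(elements) <- "integer"
  structure(list(n = n, elements = elements, order = nrow(elements)),
            class = "symmetry_group")
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat("symmetry group on", x$n, "sites, order", x$order, "\n")
  show <- min(x$order, 8L)
  for (i in seq_len(show)) cat(" ", cycle_notation(x$elements[i, ]), "\n")
  if (x$order > show) cat("  ...\n")
  invisible(x)
}

#' Check the group axioms on a set of permutations
#'
#' Verifies that the element set contains the identity and is closed under
#' composition and inversion.
#'
#' @param group a `symmetry_group`.
#' @return TRUE, or FALSE with attribute `"reason"`.
#' @export
validate_group <- function(group) {
  el <- group$elements
  keys <- apply(el, 1, paste, collapse = ",")
  idkey <- paste(seq_len(group$n), collapse = ",")
  if (!idkey %in% keys) return(structure(FALSE, reason = "missing identity"))
  for (i in seq_len(nrow(el))) {
    if (!paste(perm_inverse(el[i, ]), collapse = ",") %in% keys) {
      return(structure(FALSE, reason = "not closed under inversion"))
    }
    for (j in seq_len(nrow(el))) {
      if (!paste(perm_compose(el[i, ], el[j, ]), collapse = ",") %in% keys) {
        return(structure(FALSE, reason = "not closed under composition"))
      }
    }
  }
  TRUE
}

## closure of a generating set under composition
perm_closure <- function(n, gens) {
  seen <- new.env(parent = emptyenv())
  store <- list()
  add <- function(p) {
    k <- paste(p, collapse = ",")
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      store[[length(store) + 1L]] <<- p
      TRUE
    } else FALSE
  }
  add(perm_identity(n))
  for (g in gens) { add(g); add(perm_inverse(g)) }
  frontier <- store
  while (length(frontier)) {
    fresh <- list()
    for (a in frontier) for (b in store) {
      p <- perm_compose(a, b)
      if (add(p)) fresh[[length(fresh) + 1L]] <- p
      q <- perm_compose(b, a)
      if (add(q)) fresh[[length(fresh) + 1L]] <- q
    }
    frontier <- fresh
    if (length(store) > 1e6) stop("group closure exceeds 10^6 elements")
  }
  do.call(rbind, store)
}

## marginal replacement weights in a constant state: key matrix with entry
## [g, h] the reduced probability that alpha(g) = h (marginalized over U).
## Constant states are invariant under every permutation, so a symmetry must
## satisfy M[sigma(g), sigma(h)] = M[g, h]: a cheap exact prefilter.
marginal_key_matrix <- function(process, state_idx) {
  n <- process$n
  ev <- process$support[[state_idx]]
  M <- matrix("0/1", n, n)
  for (g in seq_len(n)) {
    for (h in seq_len(n)) {
      sel <- ev$alpha[, g] == h
      if (any(sel)) {
        s <- if (process$exact) rat_sum(ev$pnum[sel], ev$pden[sel])
             else list(num = sum(ev$pnum[sel] / ev$pden[sel]), den = 1)
        M[g, h] <- if (process$exact) rat_format(s$num, s$den)
                   else sprintf("%.12g", s$num)
      }
    }
  }
  M
}

#' Compute the symmetry group of a selection process
#'
#' Without generators, searches all `n!` permutations (capped at `n <= 8`),
#' pruning with an exact necessary condition on the marginal replacement
#' probabilities of the two constant states before running the full support
#' check. With generators, each is verified by [is_symmetry()] and the closure
#' under composition is returned (a subgroup of the full symmetry group).
#'
#' @param process a `selection_process`.
#' @param generators optional list of permutation image vectors.
#' @return a `symmetry_group`.
#' @examples
#' proc <- make_model("directed_cycle_moran", n = 5)
#' symmetry_group(proc)$order  # the 5 rotations
#' @export
symmetry_group <- function(process, generators = NULL) {
  stopifnot(inherits(process, "selection_process"))
  n <- process$n
  cache <- support_keys(process)
  if (!is.null(generators)) {
    for (k in seq_along(generators)) {
      if (!isTRUE(is_symmetry(process, generators[[k]], cache))) {
        stop("generator ", k, " (", cycle_notation(check_perm(generators[[k]])),
             ") is not a symmetry of the process")
      }
    }
    return(new_symmetry_group(n, perm_closure(n, generators)))
  }
  if (n > 8) {
    stop("brute-force symmetry search is capped at n <= 8 ",
         "(finding symmetries embeds graph automorphism); supply generators")
  }
  perms <- all_permutations(n)
  M0 <- marginal_key_matrix(process, 1L)
  M1 <- marginal_key_matrix(process, 2L^n)
  pass <- vapply(seq_len(nrow(perms)), function(k) {
    s <- perms[k, ]
    all(M0[s, s] == M0) && all(M1[s, s] == M1)
  }, logical(1))
  found <- list()
  for (k in which(pass)) {
    if (isTRUE(is_symmetry(process, perms[k, ], cache))) {
      found[[length(found) + 1L]] <- perms[k, ]
    }
  }
  new_symmetry_group(n, do.call(rbind, found))
}

#' Site orbits (equivalent sites) of a symmetry group
#'
#' Sites g and h are equivalent when some group element maps g to h. The
#' orbits of this action partition the sites and formalize the notion of
#' "class"; a transitive action (a single orbit) means the population is
#' homogeneous from the gene's-eye view.
#'
#' @param group a `symmetry_group`.
#' @return list with `orbits` (list of increasing site vectors, ordered by
#'   least member) and `transitive` (logical).
#' @export
site_orbits <- function(group) {
  n <- group$n
  rep_of <- vapply(seq_len(n), function(g) min(group$elements[, g]), integer(1))
  # group closure makes min-image a canonical orbit label
  orbits <- split(seq_len(n), rep_of)
  orbits <- orbits[order(as.integer(names(orbits)))]
  names(orbits) <- NULL
  list(orbits = orbits, transitive = length(orbits) == 1L)
}

#' Verify that a group preserves transition probabilities
#'
#' For every group element sigma and every pair of states (x, y), checks
#' `P[x -> y] == P[x sigma -> y sigma]` (exactly for exact chains). With
#' `steps > 1` the check is applied to the numeric `steps`-step matrix within
#' tolerance.
#'
#' @param P a `transition_matrix`.
#' @param group a `symmetry_group` on the same sites.
#' @param steps number of chain steps (default 1).
#' @param tol tolerance for float/multi-step comparisons.
#' @param max_violations stop collecting after this many (default 10).
#' @return list with `ok`, `violations` (data frame with columns `sigma`
#'   in cycle notation, `from`, `to`), and `steps`.
#' @export
verify_transition_preservation <- function(P, group, steps = 1, tol = 1e-9,
                                           max_violations = 10) {
  stopifnot(inherits(P, "transition_matrix"), inherits(group, "symmetry_group"))
  if (P$n != group$n) stop("matrix and group site counts differ")
  n <- P$n
  viol <- list()
  exact1 <- P$exact && steps == 1
  if (exact1) {
    Nm <- P$num; Dm <- P$den
  } else {
    Pm <- P$num / P$den
    M <- Pm
    for (s in seq_len(steps - 1)) M <- M %*% Pm
  }
  for (k in seq_len(group$order)) {
    sp <- state_permutation(group$elements[k, ], n)
    bad <- if (exact1) {
      which(Nm[sp, sp] != Nm | Dm[sp, sp] != Dm, arr.ind = TRUE)
    } else {
      which(abs(M[sp, sp] - M) > tol, arr.ind = TRUE)
    }
    if (nrow(bad)) {
      for (b in seq_len(min(nrow(bad), max_violations - length(viol)))) {
        viol[[length(viol) + 1L]] <- data.frame(
          sigma = cycle_notation(group$elements[k, ]),
          from = bad[b, 1], to = bad[b, 2])
      }
      if (length(viol) >= max_violations) break
    }
  }
  list(ok = length(viol) == 0,
       violations = if (length(viol)) do.call(rbind, viol)
                    else data.frame(sigma = character(0), from = integer(0),
                                    to = integer(0)),
       steps = steps)
}

## ---- serialization ----------------------------------------------------------

#' Export/import a symmetry group as JSON
#'
#' The JSON carries the site count, the order, image vectors and cycle
#' notation for every element.
#'
#' @param group a `symmetry_group`.
#' @param path file path.
#' @export
write_group_json <- function(group, path) {
  obj <- list(n = group$n, order = group$order,
              elements = unname(lapply(seq_len(group$order),
                                       function(i) group$elements[i, ])),
              cycles = vapply(seq_len(group$order),
                              function(i) cycle_notation(group$elements[i, ]),
                              character(1)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_group_json
#' @export
read_group_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  el <- if (is.matrix(obj$elements)) obj$elements else do.call(rbind, obj$elements)
  new_symmetry_group(as.integer(obj$n), el)
}
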