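#' selsym: symmetry analysis for finite models of natural selection
#'
#' A selection process is a pair (G, p): a finite set G of n genetic sites,
#' each housing one of two alleles (0 or 1), together with, for every binary
#' population state x, a probability distribution p_x over pairs (alpha, U) of
#' a parentage map alpha : G -> G (site g inherits from site alpha(g)) and a
#' mutation set U of sites whose inherited allele is flipped. One step of the
#' induced Markov chain on states samples (alpha, U) from p_x and sets
#' x'_g = x_{alpha(g)} for g outside U and x'_g = 1 - x_{alpha(g)} for g in U.
#'
#' The package builds this chain exactly, finds the permutations of sites that
#' preserve p (the symmetry group of the process), lumps the chain onto orbits
#' of the group action, and counts or bounds the orbits by Burnside/Polya
#' enumeration.
#'
#' Sites are indexed 1..n throughout, matching the labelling used in figures
#' of cycle and star populations. States are indexed by
#' `state_index(x) = 1 + sum(x_g 2^(g-1))` (site 1 least significant).
#'
#' @keywords internal
"_PACKAGE"

## ---- state indexing ---------------------------------------------------------

#' State/index conversions
#'
#' Binary population states map to 1-based indices via
#' `index = 1 + sum(x_g * 2^(g-1))`: the all-0 state is index 1, the all-1
#' state is index `2^n`. This fixed bijection is used for transition-matrix
#' rows/columns and orbit representatives.
#'
#' @param x binary state vector.
#' @param i state index in `1..2^n`.
#' @param n number of sites.
#' @export
state_index <- function(x) {
  as.integer(1 + sum(x * 2^(seq_along(x) - 1)))
}

#' @rdname state_index
#' @export
index_to_state <- function(i, n) {
  as.integer(intToBits(i - 1L))[seq_len(n)]
}

#' @rdname state_index
#' @export
state_bitstring <- function(x) paste(x, collapse = "")

# matrix of all m-ary states (rows = states in index order, cols = sites)
all_states <- function(n, num_alleles = 2L) {
  m <- num_alleles
  S <- m^n
  D <- matrix(0L, S, n)
  idx <- 0:(S - 1)
  for (g in seq_len(n)) {
    D[, g] <- as.integer(idx %% m)
    idx <- idx %/% m
  }
  D
}

## ---- events and support -----------------------------------------------------

# Canonical keys for (alpha, U) events; used for aggregation and for the
# exact support matching inside is_symmetry().
event_keys <- function(alpha, U) {
  akey <- apply(alpha, 1, paste, collapse = ",")
  ukey <- apply(U, 1, function(r) paste(which(r), collapse = ","))
  paste(akey, ukey, sep = "|")
}

# Aggregate duplicate (alpha, U) pairs, summing probabilities. Microscopic
# sampling narratives that induce the same event must be merged before any
# probability comparison.
aggregate_events <- function(alpha, U, pnum, pden, exact) {
  keys <- event_keys(alpha, U)
  if (anyDuplicated(keys)) {
    first <- !duplicated(keys)
    grp <- match(keys, keys[first])  # ids 1..k in first-occurrence order
    k <- sum(first)
    if (exact) {
      on <- numeric(k); od <- rep(1, k)
      for (e in seq_along(keys)) {
        j <- grp[e]
        r <- rat_add(on[j], od[j], pnum[e], pden[e])
        on[j] <- r$num; od[j] <- r$den
      }
      pnum <- on; pden <- od
    } else {
      pnum <- as.vector(rowsum(pnum / pden, grp))  # sorted ids == id order
      pden <- rep(1, k)
    }
    alpha <- alpha[first, , drop = FALSE]
    U <- U[first, , drop = FALSE]
  }
  list(alpha = alpha, U = U, pnum = pnum, pden = pden)
}

# probability equality respecting the arithmetic mode
prob_equal <- function(exact, n1, d1, n2, d2, tol = 1e-9) {
  if (exact) rat_eq(n1, d1, n2, d2)
  else abs(n1 / d1 - n2 / d2) <= tol * max(1, abs(n1 / d1), abs(n2 / d2))
}

## ---- the selection_process class -------------------------------------------

#' Construct a selection process from an explicit support table
#'
#' Low-level constructor: `support` holds, for each of the `2^n` states (in
#' [state_index()] order), the finite distribution over replacement events.
#' Each state's entry is a list with components `alpha` (integer event-by-site
#' matrix of parentage maps), `U` (logical event-by-site matrix of mutation
#' sets), and `pnum`/`pden` (probability numerators/denominators; in float
#' mode `pden` is all 1 and `pnum` holds doubles).
#'
#' Most users should call [make_model()] instead.
#'
#' @param n number of sites.
#' @param support list of length `2^n` as described above.
#' @param exact logical: exact rational arithmetic?
#' @param model,params optional descriptive metadata.
#' @param site_labels optional display labels (default `"1".."n"`).
#' @param validate check event shapes and probability sums (default TRUE).
#' @return object of class `selection_process`.
#' @export
selection_process <- function(n, support, exact = TRUE, model = "explicit",
                              params = list(), site_labels = NULL,
                              validate = TRUE) {
  n <- as.integer(n)
  stopifnot(n >= 1, length(support) == 2^n)
  support <- lapply(support, function(ev) {
    ev$alpha <- matrix(as.integer(ev$alpha), nrow = nrow(ev$alpha))
    ev$U <- matrix(as.logical(ev$U), nrow = nrow(ev$U))
    aggregate_events(ev$alpha, ev$U, ev$pnum, ev$pden, exact)
  })
  proc <- structure(
    list(n = n, model = model, params = params, exact = exact,
         site_labels = site_labels %||% as.character(seq_len(n)),
         support = support),
    class = "selection_process")
  if (validate) {
    diag <- validate_process(proc, check_axiom = FALSE)
    if (!diag$ok) {
      stop("invalid selection process: ",
           paste(diag$problems, collapse = "; "), call. = FALSE)
    }
  }
  proc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.selection_process <- function(x, ...) {
  cat("selection process (", x$model, "): n =", x$n, "sites,",
      2^x$n, "states,", if (x$exact) "exact" else "float", "arithmetic\n")
  nev <- vapply(x$support, function(e) nrow(e$alpha), integer(1))
  cat("support events per state:", min(nev), "-", max(nev), "\n")
  invisible(x)
}

#' Enumerate the replacement-event support of a state
#'
#' Returns the distinct (parentage map, mutation set) pairs with positive
#' probability in state `x`, with probabilities summing to 1. Events arising
#' from different microscopic choices (e.g. parent = dying site in a Moran
#' step, for each choice of dying site) are aggregated.
#'
#' @param process a `selection_process`.
#' @param x binary state vector of length `process$n`.
#' @return list of events; each event is a list with `alpha` (parentage image
#'   vector), `mutated` (integer vector of mutated sites), `prob` (double) and,
#'   in exact mode, `prob_num`/`prob_den`.
#' @export
enumerate_support <- function(process, x) {
  stopifnot(inherits(process, "selection_process"))
  if (length(x) != process$n) stop("state length differs from site count")
  if (!all(x %in% c(0, 1))) stop("state entries must be 0 or 1")
  ev <- process$support[[state_index(x)]]
  lapply(seq_len(nrow(ev$alpha)), function(e) {
    list(alpha = ev$alpha[e, ],
         mutated = which(ev$U[e, ]),
         prob = ev$pnum[e] / ev$pden[e],
         prob_num = ev$pnum[e], prob_den = ev$pden[e])
  })
}

#' Diagnostic validation of a selection process
#'
#' Checks, for every state, that event probabilities are positive and sum to 1
#' (exactly in exact mode, within `tol` otherwise), that parentage maps and
#' mutation sets index valid sites, that no duplicate (alpha, U) events
#' remain, and (optionally) whether the fixation axiom holds. Nothing is
#' raised; all findings are reported.
#'
#' @param process a `selection_process`.
#' @param check_axiom also run [check_fixation_axiom()]?
#' @param tol float-mode tolerance on probability sums.
#' @return list with `ok` (no structural problems), `problems` (character),
#'   `prob_sum_dev` (per-state deviation of the probability sum from 1) and,
#'   when requested, `fixation_axiom` (logical) and `witness`.
#' @export
validate_process <- function(process, check_axiom = TRUE, tol = 1e-9) {
  n <- process$n
  problems <- character(0)
  dev <- numeric(2^n)
  for (i in seq_len(2^n)) {
    ev <- process$support[[i]]
    if (nrow(ev$alpha) == 0) {
      problems <- c(problems, sprintf("state %d: empty support", i))
      dev[i] <- 1
      next
    }
    if (ncol(ev$alpha) != n || ncol(ev$U) != n) {
      problems <- c(problems, sprintf("state %d: event width != n", i))
    }
    if (any(ev$alpha < 1 | ev$alpha > n)) {
      problems <- c(problems, sprintf("state %d: parentage map out of range", i))
    }
    if (any(ev$pnum <= 0) || any(ev$pden <= 0)) {
      problems <- c(problems, sprintf("state %d: non-positive event probability", i))
    }
    if (anyDuplicated(event_keys(ev$alpha, ev$U))) {
      problems <- c(problems, sprintf("state %d: duplicate (alpha,U) events", i))
    }
    if (process$exact) {
      s <- rat_sum(ev$pnum, ev$pden)
      dev[i] <- s$num / s$den - 1
      if (!(s$num == s$den)) {
        problems <- c(problems,
                      sprintf("state %d: probabilities sum to %s, not 1",
                              i, rat_format(s$num, s$den)))
      }
    } else {
      dev[i] <- sum(ev$pnum / ev$pden) - 1
      if (abs(dev[i]) > tol) {
        problems <- c(problems,
                      sprintf("state %d: probabilities sum to %.12g, not 1",
                              i, 1 + dev[i]))
      }
    }
  }
  out <- list(ok = length(problems) == 0, problems = problems,
              prob_sum_dev = dev)
  if (check_axiom) {
    ax <- check_fixation_axiom(process)
    out$fixation_axiom <- ax$holds
    out$witness <- ax$witness
    out$axiom_certificate <- ax$certificate
  }
  out
}
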