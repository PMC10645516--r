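#' Orbits of the group action on population states
#'
#' Two states are equivalent when some group element permutes one into the
#' other; the equivalence classes are the orbits of the right action
#' `x -> x sigma`. Equivalent states carry the same number of each allele.
#' States over `num_alleles > 2` alleles are supported for counting purposes.
#'
#' @param group a `symmetry_group`.
#' @param n number of sites (defaults to `group$n`).
#' @param num_alleles number of allele types (default 2).
#' @param max_states guard on `num_alleles^n` (default 2^12).
#' @return object of class `state_orbit_list`: list with `orbits` (each orbit
#'   a list with `representative` state index, `rep_state`, `members`, `size`,
#'   `allele_count`), `orbit_of` (state index -> orbit id), `n`, `num_alleles`.
#'   Orbits are ordered by representative index (the minimal member).
#' @export
state_orbits <- function(group, n = group$n, num_alleles = 2,
                         max_states = 2^12) {
  stopifnot(inherits(group, "symmetry_group"), n == group$n)
  m <- as.integer(num_alleles)
  if (m < 2) stop("num_alleles must be >= 2")
  S <- m^n
  if (S > max_states) stop("state space ", S, " exceeds max_states = ", max_states)
  D <- all_states(n, m)
  powm <- m^(seq_len(n) - 1)
  canon <- seq_len(S)
  for (k in seq_len(group$order)) {
    sigma <- group$elements[k, ]
    mapped <- as.integer(1 + D[, sigma, drop = FALSE] %*% powm)
    canon <- pmin(canon, mapped)
  }
  # group closure => the minimum image over all elements is orbit-constant
  members <- split(seq_len(S), canon)
  reps <- as.integer(names(members))
  ord <- order(reps)
  orbits <- lapply(ord, function(i) {
    r <- reps[i]
    st <- D[r, ]
    list(representative = r,
         rep_state = st,
         members = as.integer(members[[i]]),
         size = length(members[[i]]),
         allele_count = if (m == 2) sum(st) else tabulate(st + 1L, nbins = m))
  })
  orbit_of <- integer(S)
  for (i in seq_along(orbits)) orbit_of[orbits[[i]]$members] <- i
  structure(list(orbits = orbits, orbit_of = orbit_of, n = n, num_alleles = m),
            class = "state_orbit_list")
}

#' @export
print.state_orbit_list <- function(x, ...) {
  cat(length(x$orbits), "state orbits over", x$num_alleles^x$n, "states\n")
  invisible(x)
}

orbit_labels <- function(ol) {
  vapply(ol$orbits, function(o) paste(o$rep_state, collapse = ""), character(1))
}

#' Lump the selection chain onto state orbits
#'
#' The reduced chain on orbits has transition probability
#' `P[ [x] -> [y] ] = sum over z in [y] of P[x -> z]`, which is independent of
#' the representative x precisely because the orbits come from true symmetries.
#' That well-definedness (strong lumpability) is verified for every member of
#' every orbit before the reduced chain is returned; a violation means the
#' partition was not built from symmetries of this chain and raises an error
#' naming the orbit, two differing members, and the target orbit.
#'
#' @param P a `transition_matrix`.
#' @param orbits a `state_orbit_list` over the same binary state space.
#' @return object of class `reduced_chain`: list with `orbits`, `num`/`den`
#'   entry matrices (rows/columns in orbit order), `R`, `exact`, `labels`
#'   (representative bitstrings).
#' @export
build_reduced_chain <- function(P, orbits) {
  stopifnot(inherits(P, "transition_matrix"),
            inherits(orbits, "state_orbit_list"))
  if (orbits$num_alleles != 2 || orbits$n != P$n) {
    stop("orbits must partition the binary state space of the chain")
  }
  R <- length(orbits$orbits)
  S <- 2^P$n
  # per-state rational row sums onto each target orbit
  sum_n <- matrix(0, S, R); sum_d <- matrix(1, S, R)
  for (i in seq_len(S)) {
    for (b in seq_len(R)) {
      mem <- orbits$orbits[[b]]$members
      if (P$exact) {
        s <- rat_sum(P$num[i, mem], P$den[i, mem])
        sum_n[i, b] <- s$num; sum_d[i, b] <- s$den
      } else {
        sum_n[i, b] <- sum(P$num[i, mem] / P$den[i, mem])
      }
    }
  }
  # lumpability: the sums must be constant across each source orbit
  for (a in seq_len(R)) {
    mem <- orbits$orbits[[a]]$members
    ra <- mem[1]
    for (x2 in mem[-1]) {
      for (b in seq_len(R)) {
        same <- prob_equal(P$exact, sum_n[ra, b], sum_d[ra, b],
                           sum_n[x2, b], sum_d[x2, b])
        if (!same) {
          stop("lumpability violation: orbit ", a, " members ", ra, " and ",
               x2, " have different total probability into orbit ", b,
               " (", rat_format(sum_n[ra, b], sum_d[ra, b]), " vs ",
               rat_format(sum_n[x2, b], sum_d[x2, b]), "); the orbit ",
               "partition was not built from true symmetries of this chain")
        }
      }
    }
  }
  reps <- vapply(orbits$orbits, function(o) o$representative, integer(1))
  structure(list(orbits = orbits, num = sum_n[reps, , drop = FALSE],
                 den = sum_d[reps, , drop = FALSE], R = R, exact = P$exact,
                 labels = orbit_labels(orbits)),
            class = "reduced_chain")
}

#' @export
print.reduced_chain <- function(x, ...) {
  cat("reduced chain on", x$R, "state orbits (",
      if (x$exact) "exact" else "float", ")\n")
  invisible(x)
}

#' @export
as.matrix.reduced_chain <- function(x, ...) {
  m <- x$num / x$den
  dimnames(m) <- list(x$labels, x$labels)
  m
}

#' Fixation probabilities on a reduced chain
#'
#' For a mutation-free model the all-0 and all-1 states are singleton orbits
#' and absorbing in the reduced chain too; this solves the reduced absorption
#' system for the probability of ending in the all-1 orbit.
#'
#' @param rc a `reduced_chain` whose first and last orbits (by representative)
#'   are the two constant states.
#' @return numeric vector over orbits.
#' @export
reduced_chain_fixation <- function(rc) {
  Pm <- rc$num / rc$den
  R <- rc$R
  sizes <- vapply(rc$orbits$orbits, function(o) o$size, integer(1))
  if (sizes[1] != 1 || sizes[R] != 1 || Pm[1, 1] != 1 || Pm[R, R] != 1) {
    stop("reduced chain does not have absorbing constant-state orbits; ",
         "is the process mutation-free?")
  }
  trans <- setdiff(seq_len(R), c(1L, R))
  rho <- numeric(R); rho[R] <- 1
  if (length(trans)) {
    rho[trans] <- solve(diag(length(trans)) - Pm[trans, trans, drop = FALSE],
                        Pm[trans, R])
  }
  rho
}

## ---- Burnside / Polya counting and bounds ------------------------------------

#' Count reduced states by Burnside's lemma
#'
#' The number of orbits of the group action on `num_alleles^n` states equals
#' the group average of `num_alleles^c(sigma)`, where `c(sigma)` is the number
#' of cycles of sigma. Computed exactly; a non-integer average indicates the
#' input set is not a group and raises an error.
#'
#' @param group a `symmetry_group`.
#' @param num_alleles number of allele types (default 2).
#' @return the exact orbit count as a double-stored integer.
#' @examples
#' g <- make_structure_group("symmetric", n = 4)
#' count_reduced_states(g)  # n + 1 = 5
#' @export
count_reduced_states <- function(group, num_alleles = 2) {
  stopifnot(inherits(group, "symmetry_group"))
  m <- num_alleles
  total <- 0
  for (k in seq_len(group$order)) {
    total <- total + m^cycle_count(group$elements[k, ])$count
    rat_check(total)
  }
  if (total %% group$order != 0) {
    stop("Burnside sum ", total, " is not divisible by the order ",
         group$order, ": the element set is not a group")
  }
  total / group$order
}

#' Reduced-state count for a rotation-symmetric (directed cycle) population
#'
#' The rotations of a directed n-cycle form the cyclic group of order n, and
#' rotating by j vertices decomposes the sites into gcd(n, j) cycles, so the
#' orbit count is `(1/n) * sum_j m^gcd(n, j)` -- the classical necklace count.
#' For prime n and two alleles this equals `2 + (2^n - 2)/n`.
#'
#' @param n cycle length (>= 1).
#' @param num_alleles number of allele types (default 2).
#' @return exact orbit count.
#' @export
count_directed_cycle <- function(n, num_alleles = 2) {
  stopifnot(n >= 1)
  m <- num_alleles
  total <- sum(m^vapply(seq_len(n), function(j) rat_gcd(n, j), numeric(1)))
  rat_check(total)
  if (total %% n != 0) stop("internal error: necklace sum not divisible by n")
  total / n
}

#' Bounds on the number of reduced states
#'
#' From the site count n and group order S alone, the orbit count R of the
#' binary-state action satisfies
#' `max(n + 1, 2 + (2^n - 2)/S) <= R <= 2 + (1/S) * sum_{k=1}^{n-1}
#'  choose(n, k) * gcd(S, k! (n-k)!)`.
#' Both bounds are returned as exact rationals, without rounding; use
#' [bounds_hold()] for exact comparison against an integer count.
#'
#' @param n number of sites (>= 1; capped so factorials stay exactly
#'   representable).
#' @param S group order (>= 1).
#' @return object of class `state_count_bounds` with exact `lower_num`,
#'   `lower_den`, `upper_num`, `upper_den` and numeric `lower`, `upper`.
#' @export
state_count_bounds <- function(n, S) {
  stopifnot(n >= 1, S >= 1, n == round(n), S == round(S))
  if (n > 17) stop("bounds require exact factorials; n <= 17")
  # lower bound: max(n + 1, 2 + (2^n - 2)/S)
  l1 <- list(num = n + 1, den = 1)
  l2 <- rat_add(2, 1, 2^n - 2, S)
  lower <- if (l1$num * l2$den >= l2$num * l1$den) l1 else l2
  # upper bound
  acc <- list(num = 0, den = 1)
  for (k in seq_len(max(n - 1, 0))) {
    g <- rat_gcd(S, factorial(k) * factorial(n - k))
    term <- rat_check(choose(n, k) * g)
    acc <- rat_add(acc$num, acc$den, term, S)
  }
  upper <- rat_add(2, 1, acc$num, acc$den)
  structure(list(lower_num = lower$num, lower_den = lower$den,
                 upper_num = upper$num, upper_den = upper$den,
                 lower = lower$num / lower$den, upper = upper$num / upper$den,
                 n = n, S = S),
            class = "state_count_bounds")
}

#' @export
print.state_count_bounds <- function(x, ...) {
  cat("reduced-state bounds for n =", x$n, ", S =", x$S, ": ",
      rat_format(x$lower_num, x$lower_den), "<= R <=",
      rat_format(x$upper_num, x$upper_den), "\n")
  invisible(x)
}

#' @rdname state_count_bounds
#' @param bounds a `state_count_bounds`.
#' @param R integer orbit count to test.
#' @export
bounds_hold <- function(bounds, R) {
  bounds$lower_num <= R * bounds$lower_den &&
    R * bounds$upper_den <= bounds$upper_num
}

## ---- export -----------------------------------------------------------------

#' Export a reduced chain and its orbit table
#'
#' The CSV carries the reduced transition matrix with orbit-representative
#' bitstrings as headers; the orbit JSON lists representative, size and allele
#' count per orbit (and optionally the members).
#'
#' @param rc a `reduced_chain`.
#' @param ol a `state_orbit_list`.
#' @param path output file.
#' @param members include full member lists in the JSON?
#' @export
write_reduced_csv <- function(rc, path) {
  utils::write.csv(as.matrix(rc), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_reduced_csv
#' @export
write_orbits_json <- function(ol, path, members = FALSE) {
  obj <- lapply(ol$orbits, function(o) {
    out <- list(representative = paste(o$rep_state, collapse = ""),
                size = o$size, allele_count = o$allele_count)
    if (members) out$members <- o$members
    out
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
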