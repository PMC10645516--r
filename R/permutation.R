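#' Permutations of genetic sites
#'
#' A permutation of the site set is represented as an integer vector `image`
#' of length n with `image[g]` giving the image of site `g` (1-based). The
#' composition convention is `perm_compose(s, t)(g) = s(t(g))`, which together
#' with the right action [apply_permutation()] gives the composition rule
#' `(x s) t = x (s o t)` on states.
#'
#' @param sigma,s,t integer vectors: permutation images.
#' @name permutations
NULL

check_perm <- function(sigma) {
  n <- length(sigma)
  if (!all(sort(as.integer(sigma)) == seq_len(n))) {
    stop("not a permutation: image is not a rearrangement of 1..n", call. = FALSE)
  }
  as.integer(sigma)
}

#' @rdname permutations
#' @param n number of sites.
#' @export
perm_identity <- function(n) seq_len(n)

#' @rdname permutations
#' @export
perm_compose <- function(s, t) s[t]

#' @rdname permutations
#' @export
perm_inverse <- function(sigma) order(sigma)

#' Apply a permutation to a population state
#'
#' Implements the right group action of site permutations on binary states:
#' the result holds allele `x[sigma[g]]` at site `g`. Satisfies
#' `apply_permutation(apply_permutation(x, s), t) ==
#'  apply_permutation(x, perm_compose(s, t))`.
#'
#' @param x binary state vector (0/1), one entry per site.
#' @param sigma permutation image vector of the same length.
#' @return the permuted state.
#' @export
apply_permutation <- function(x, sigma) {
  if (length(x) != length(sigma)) stop("state and permutation lengths differ")
  x[sigma]
}

#' Cycle decomposition of a permutation
#'
#' Partitions the sites into the cycles of `sigma`: sites g and h lie in one
#' cycle exactly when some power of `sigma` maps h to g. The number of cycles
#' drives Burnside orbit counting (see [count_reduced_states()]).
#'
#' @param sigma permutation image vector.
#' @return object of class `cycle_decomposition`: list with `cycles` (list of
#'   integer vectors partitioning the sites) and `count`.
#' @examples
#' rot2 <- c(3L, 4L, 5L, 6L, 1L, 2L)  # rotate a 6-cycle by two vertices
#' cycle_count(rot2)$count            # 2 cycles: (1 3 5)(2 4 6)
#' @export
cycle_count <- function(sigma) {
  sigma <- check_perm(sigma)
  n <- length(sigma)
  seen <- logical(n)
  cycles <- list()
  for (g in seq_len(n)) {
    if (seen[g]) next
    cyc <- integer(0)
    h <- g
    repeat {
      cyc <- c(cyc, h)
      seen[h] <- TRUE
      h <- sigma[h]
      if (h == g) break
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  structure(list(cycles = cycles, count = length(cycles)),
            class = "cycle_decomposition")
}

#' @export
print.cycle_decomposition <- function(x, ...) {
  cat("cycle decomposition:", cycle_notation_from_cycles(x$cycles),
      "(", x$count, "cycles )\n")
  invisible(x)
}

cycle_notation_from_cycles <- function(cycles) {
  paste0(vapply(cycles, function(c) paste0("(", paste(c, collapse = " "), ")"),
                character(1)), collapse = "")
}

#' Disjoint-cycle notation for a permutation
#'
#' @param sigma permutation image vector.
#' @return a string such as `"(1 3 5)(2 4 6)"`; fixed points are shown as
#'   singleton cycles.
#' @export
cycle_notation <- function(sigma) {
  cycle_notation_from_cycles(cycle_count(sigma)$cycles)
}

#' Parse disjoint-cycle notation into a permutation
#'
#' @param s string such as `"(1 3 5)(2 4 6)"`; sites not mentioned are fixed.
#' @param n number of sites.
#' @return permutation image vector of length `n`.
#' @export
parse_cycle_notation <- function(s, n) {
  sigma <- seq_len(n)
  body <- regmatches(s, gregexpr("\\(([^()]*)\\)", s))[[1]]
  for (cyc in body) {
    elems <- as.integer(strsplit(trimws(gsub("[()]", "", cyc)), "[ ,]+")[[1]])
    if (any(is.na(elems)) || any(elems < 1) || any(elems > n)) {
      stop("bad cycle ", cyc, " for n = ", n)
    }
    k <- length(elems)
    if (k > 1) for (i in seq_len(k)) sigma[elems[i]] <- elems[i %% k + 1L]
  }
  check_perm(sigma)
}

#' All permutations of n sites
#'
#' @param n number of sites (capped at 9: the result has n! rows).
#' @return integer matrix with one permutation image per row.
#' @export
all_permutations <- function(n) {
  if (n > 9) stop("refusing to enumerate ", n, "! permutations")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- nrow(sub)
    out[row:(row + block - 1L), pos] <- n
    out[row:(row + block - 1L), -pos] <- sub
    row <- row + block
  }
  out
}
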