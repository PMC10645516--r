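#' One replacement-mutation step applied to a state
#'
#' Each non-mutated site g inherits the allele of its parent site `alpha[g]`;
#' each site in `mutated` inherits the opposite allele of its parent.
#'
#' @param x binary state vector.
#' @param alpha parentage map: integer image vector (need not be bijective).
#' @param mutated integer vector of mutated sites (may be empty).
#' @return the subsequent state.
#' @examples
#' # site 8 replaced by a mutated copy of site 7, all other sites survive
#' x <- c(1, 0, 1, 0, 1, 0, 1, 0)
#' a <- 1:8; a[8] <- 7L
#' next_state(x, a, mutated = 8L)
#' @export
next_state <- function(x, alpha, mutated = integer(0)) {
  n <- length(x)
  if (length(alpha) != n) stop("parentage map length differs from state length")
  if (any(alpha < 1 | alpha > n)) stop("parentage map index out of range")
  if (length(mutated) && any(mutated < 1 | mutated > n)) {
    stop("mutation set index out of range")
  }
  xp <- x[alpha]
  xp[mutated] <- 1 - xp[mutated]
  xp
}

## ---- transition matrices ----------------------------------------------------

new_transition_matrix <- function(n, num, den, exact) {
  structure(list(n = n, num = num, den = den, exact = exact),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition matrix on", 2^x$n, "states (",
      if (x$exact) "exact" else "float", ")\n")
  invisible(x)
}

#' @export
as.matrix.transition_matrix <- function(x, ...) {
  m <- x$num / x$den
  labs <- vapply(seq_len(2^x$n), function(i)
    state_bitstring(index_to_state(i, x$n)), character(1))
  dimnames(m) <- list(labs, labs)
  m
}

#' Build the selection Markov chain of a process
#'
#' Constructs the exact row-stochastic transition matrix on all `2^n` binary
#' states: the entry from x to y sums the probabilities of every support event
#' (alpha, U) of x with `next_state(x, alpha, U) == y`. In a mutation-free
#' process the single-allele states (indices 1 and `2^n`) are absorbing.
#'
#' @param process a `selection_process`.
#' @param max_n guard on state-space size (default 12, i.e. 4096 states).
#' @return object of class `transition_matrix` with exact `num`/`den` entry
#'   matrices; use `as.matrix()` for the numeric matrix with bitstring labels.
#' @export
build_chain <- function(process, max_n = 12) {
  stopifnot(inherits(process, "selection_process"))
  n <- process$n
  if (n > max_n) stop("state space 2^", n, " exceeds max_n = ", max_n)
  S <- 2^n
  pow2 <- 2^(seq_len(n) - 1)
  num <- matrix(0, S, S)
  den <- matrix(1, S, S)
  states <- all_states(n)
  for (i in seq_len(S)) {
    x <- states[i, ]
    ev <- process$support[[i]]
    E <- nrow(ev$alpha)
    X <- matrix(x[ev$alpha], E, n)
    X <- (X + ev$U) %% 2
    targets <- as.integer(1 + X %*% pow2)
    for (e in seq_len(E)) {
      j <- targets[e]
      if (process$exact) {
        r <- rat_add(num[i, j], den[i, j], ev$pnum[e], ev$pden[e])
        num[i, j] <- r$num; den[i, j] <- r$den
      } else {
        num[i, j] <- num[i, j] + ev$pnum[e] / ev$pden[e]
      }
    }
  }
  new_transition_matrix(n, num, den, process$exact)
}

## state-index permutation induced by a site permutation: entry i gives the
## index of (x_i) sigma, where (x sigma)_g = x_{sigma(g)}
state_permutation <- function(sigma, n) {
  pow2 <- 2^(seq_len(n) - 1)
  states <- all_states(n)
  as.integer(1 + states[, sigma, drop = FALSE] %*% pow2)
}

## ---- absorption and stationarity --------------------------------------------

#' Fixation probabilities of allele 1
#'
#' For a mutation-free process satisfying the fixation axiom, the all-0 and
#' all-1 states are the only absorbing states and all others are transient.
#' This solves the absorption linear system for the probability `rho[x]` of
#' eventual absorption in the all-1 state from each initial state x.
#'
#' @param process a mutation-free `selection_process`.
#' @param check_axiom verify the fixation axiom first (default TRUE).
#' @return object of class `fixation_vector`: list with `rho` (length `2^n`,
#'   indexed by [state_index()]) and `n`.
#' @export
fixation_probabilities <- function(process, check_axiom = TRUE) {
  stopifnot(inherits(process, "selection_process"))
  if (any(vapply(process$support, function(ev) any(ev$U), logical(1)))) {
    stop("fixation probabilities are defined for mutation-free processes only")
  }
  if (check_axiom) {
    ax <- check_fixation_axiom(process)
    if (!ax$holds) {
      stop("fixation axiom fails (certificate: sites ",
           paste(ax$certificate, collapse = ", "),
           " can never share an ancestor); the absorption system is singular")
    }
  }
  P <- as.matrix(build_chain(process))
  S <- 2^process$n
  trans <- setdiff(seq_len(S), c(1L, S))
  rho <- numeric(S)
  rho[S] <- 1
  if (length(trans)) {
    Q <- P[trans, trans, drop = FALSE]
    b <- P[trans, S]
    sol <- tryCatch(solve(diag(length(trans)) - Q, b),
                    error = function(e) {
                      stop("absorption system is singular; the process has ",
                           "additional recurrent states", call. = FALSE)
                    })
    rho[trans] <- sol
  }
  structure(list(rho = rho, n = process$n), class = "fixation_vector")
}

#' @export
print.fixation_vector <- function(x, ...) {
  cat("fixation probabilities over", 2^x$n, "states\n")
  singles <- vapply(seq_len(x$n), function(g) {
    s <- rep(0L, x$n); s[g] <- 1L
    x$rho[state_index(s)]
  }, numeric(1))
  cat("single-mutant rho by site:", paste(signif(singles, 6), collapse = " "), "\n")
  invisible(x)
}

#' Stationary distribution of a selection chain
#'
#' Requires a unique stationary distribution (recurring mutation with complete
#' gene flow); uniqueness is verified by checking that the null space of
#' `t(P) - I` is one-dimensional. Mutation-free chains have two absorbing
#' states and are rejected with an explicit error.
#'
#' @param P a `transition_matrix` (from [build_chain()]) or a plain
#'   row-stochastic numeric matrix.
#' @param tol numerical tolerance for the rank and verification checks.
#' @return object of class `stationary_distribution`: list with `pi` and `n`.
#' @export
stationary_distribution <- function(P, tol = 1e-9) {
  Pm <- if (inherits(P, "transition_matrix")) as.matrix(P) else as.matrix(P)
  S <- nrow(Pm)
  A <- t(Pm) - diag(S)
  sv <- svd(A)
  nullity <- sum(sv$d < tol * max(sv$d, 1))
  if (nullity != 1) {
    stop("stationary distribution is not unique (null space of t(P) - I has ",
         "dimension ", nullity, "); the chain likely lacks recurring mutation")
  }
  pi <- sv$v[, S]
  pi <- pi / sum(pi)
  if (any(pi < -1e-8)) stop("stationary solve produced negative mass")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  if (max(abs(as.vector(pi %*% Pm) - pi)) > 1e-7) {
    stop("stationary verification failed: pi P != pi")
  }
  n <- if (inherits(P, "transition_matrix")) P$n else round(log2(S))
  structure(list(pi = as.vector(pi), n = n), class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("stationary distribution over", length(x$pi), "states\n")
  invisible(x)
}

## ---- export -----------------------------------------------------------------

#' Export a transition matrix
#'
#' `write_chain_csv` writes the dense matrix with state bitstrings (site 1
#' leftmost) as row and column headers; `write_chain_sparse` writes nonzero
#' entries as `from,to,prob` index triples.
#'
#' @param P a `transition_matrix`.
#' @param path output file.
#' @export
write_chain_csv <- function(P, path) {
  utils::write.csv(as.matrix(P), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
write_chain_sparse <- function(P, path) {
  m <- P$num / P$den
  nz <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(from = nz[, 1], to = nz[, 2], prob = m[nz])
  df <- df[order(df$from, df$to), ]
  utils::write.table(df, path, sep = " ", row.names = FALSE, quote = FALSE)
  invisible(path)
}
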