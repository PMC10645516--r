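#' Symmetrize a process over a permutation group
#'
#' Group-averages the support: the new probability of event (alpha, U) in
#' state x is the mean over group elements sigma of the probability of
#' (sigma^-1 o alpha o sigma, sigma^-1(U)) in state x sigma. For a bona fide
#' group, every element of `group` is a symmetry of the result, and a process
#' already symmetric under the group is returned unchanged. Used to build
#' test fixtures with a prescribed symmetry group.
#'
#' @param process a `selection_process`.
#' @param group a `symmetry_group` on the same sites.
#' @return a `selection_process`.
#' @export
symmetrize_process <- function(process, group) {
  stopifnot(inherits(process, "selection_process"),
            inherits(group, "symmetry_group"))
  n <- process$n
  if (group$n != n) stop("group and process site counts differ")
  S <- group$order
  support <- vector("list", 2^n)
  for (i in seq_len(2^n)) {
    alpha_l <- list(); U_l <- list(); pn <- c(); pd <- c()
    for (k in seq_len(S)) {
      sigma <- group$elements[k, ]
      sinv <- perm_inverse(sigma)
      j <- state_permutation(sigma, n)[i]
      ev <- process$support[[j]]
      # event (beta, V) of x sigma contributes to (sigma o beta o sigma^-1,
      # sigma(V)) of x, with weight 1/S
      a <- matrix(sigma[ev$alpha[, sinv, drop = FALSE]], nrow = nrow(ev$alpha))
      u <- ev$U[, sinv, drop = FALSE]
      alpha_l[[k]] <- a; U_l[[k]] <- u
      if (process$exact) {
        w <- vapply(seq_along(ev$pnum), function(e)
          unlist(rat_mul(ev$pnum[e], ev$pden[e], 1, S)), numeric(2))
        pn <- c(pn, w[1, ]); pd <- c(pd, w[2, ])
      } else {
        pn <- c(pn, ev$pnum / ev$pden / S); pd <- c(pd, rep(1, nrow(a)))
      }
    }
    support[[i]] <- list(alpha = do.call(rbind, alpha_l),
                         U = do.call(rbind, U_l), pnum = pn, pden = pd)
  }
  selection_process(n, support, exact = process$exact,
                    model = paste0(process$model, "+symmetrized"),
                    params = process$params)
}

#' Generate a reproducible random selection process
#'
#' Draws, for every state, `n_events` random parentage maps with random
#' small-integer weights, and mixes in a uniform well-mixed replacement
#' component with total weight `mix_weight`. The well-mixed component places
#' every single-replacement map in every state's support, so the fixation
#' axiom is guaranteed by construction. Probabilities are exact rationals and
#' the same seed always reproduces the same process. A generic draw has only
#' the trivial symmetry; combine with [symmetrize_process()] to impose a
#' group.
#'
#' @param n number of sites.
#' @param seed integer seed.
#' @param n_events random maps per state.
#' @param mix_weight weight of the well-mixed component (rational in (0, 1]).
#' @param mutation if TRUE each random event also flips one random site.
#' @return a `selection_process`.
#' @export
random_process <- function(n, seed, n_events = 3, mix_weight = "1/10",
                           mutation = FALSE) {
  check_n(n)
  mw <- parse_rational(mix_weight)
  if (mw$num <= 0 || mw$num > mw$den) stop("mix_weight must lie in (0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # well-mixed component: all n^2 (parent, dying) single-replacement maps
  base_alpha <- matrix(rep(seq_len(n), each = n * n), n * n, n)
  row <- 1L
  for (d in seq_len(n)) for (p in seq_len(n)) {
    base_alpha[row, d] <- p
    row <- row + 1L
  }
  base_pn <- rep(mw$num, n * n)
  base_pd <- rep(mw$den * n * n, n * n)
  rest <- list(num = mw$den - mw$num, den = mw$den)  # 1 - mix_weight
  support <- vector("list", 2^n)
  for (i in seq_len(2^n)) {
    alpha <- matrix(sample.int(n, n_events * n, replace = TRUE), n_events, n)
    U <- matrix(FALSE, n_events, n)
    if (mutation) U[cbind(seq_len(n_events), sample.int(n, n_events, TRUE))] <- TRUE
    w <- sample.int(9, n_events, replace = TRUE)
    W <- sum(w)
    if (rest$num > 0) {
      pn <- numeric(n_events); pd <- numeric(n_events)
      for (e in seq_len(n_events)) {
        r <- rat_mul(rest$num, rest$den, w[e], W)
        pn[e] <- r$num; pd[e] <- r$den
      }
      support[[i]] <- list(alpha = rbind(base_alpha, alpha),
                           U = rbind(matrix(FALSE, n * n, n), U),
                           pnum = c(base_pn, pn), pden = c(base_pd, pd))
    } else {
      support[[i]] <- list(alpha = base_alpha, U = matrix(FALSE, n * n, n),
                           pnum = base_pn, pden = base_pd)
    }
  }
  selection_process(n, support, exact = TRUE, model = "random",
                    params = list(seed = seed, n_events = n_events,
                                  mix_weight = mw))
}
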