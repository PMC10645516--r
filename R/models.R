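#' Construct a built-in selection process
#'
#' Builds the full per-state replacement/mutation support for one of the
#' standard model families. Fitness is genic: allele 1 has fitness `r`, allele
#' 0 fitness 1. Mutation is i.i.d. per site with probability `u`, applied
#' after replacement, so `p_x(alpha, U) = p_x(alpha) * u^|U| * (1-u)^(n-|U|)`.
#' All constructors use exact rational arithmetic when `r` and `u` (and graph
#' weights) are exactly representable rationals, which they are for the usual
#' inputs.
#'
#' Update rules (the death step draws the dying site uniformly over all n
#' sites; these conventions are fixed so detected symmetry groups are
#' reproducible):
#' \describe{
#'   \item{`well_mixed_moran`}{parent drawn from all n sites proportional to
#'     fitness (self-replacement allowed), dying site uniform;
#'     `alpha` = identity except `alpha(dead) = parent`.}
#'   \item{`wright_fisher`}{every site independently draws its parent from all
#'     n sites proportional to fitness; support has `n^n` parentage maps per
#'     state (limited to `n <= max_n`, default 6).}
#'   \item{`graph_moran_db`}{death-birth on a weighted (di)graph `graph` with
#'     `graph[i, j]` the weight with which site i can parent site j: dying
#'     site uniform, parent among in-neighbours proportional to
#'     weight x fitness.}
#'   \item{`graph_moran_bd`}{birth-death: parent from all sites proportional
#'     to fitness, offspring placed on an out-neighbour proportional to edge
#'     weight.}
#'   \item{`directed_cycle_moran`}{death-birth on the directed n-cycle
#'     (site g's only in-neighbour is g-1 mod n).}
#'   \item{`undirected_cycle_moran`}{death-birth on the undirected n-cycle.}
#'   \item{`star_moran_db`}{death-birth on the star with hub at site 1.}
#'   \item{`class_moran`}{classes of sizes `sizes` occupying consecutive
#'     sites; dying site uniform, parent from all sites proportional to
#'     `class_weights[class(parent), class(dead)] * fitness`. The default
#'     weight matrix has pairwise-distinct positive entries, so only
#'     within-class permutations are symmetries.}
#'   \item{`island_moran`}{`islands` islands of `island_size` sites; dying
#'     site uniform; its replacement's parent comes from the same island with
#'     probability `1 - migration` (uniform by fitness within the island) and
#'     from the other islands with probability `migration` (uniform by fitness
#'     over all outside sites). Requires `0 < migration < 1`.}
#'   \item{`explicit_table`}{a user-supplied support table; see
#'     [read_model_spec()] for the file format.}
#' }
#'
#' @param model built-in model name (see Details) or a list with a `model`
#'   entry plus parameters, as returned by parsing a config file.
#' @param n number of sites.
#' @param r fitness of allele 1 (> 0); may be numeric or a string `"3/2"`.
#' @param u per-site mutation probability in `[0, 1]`; numeric or string.
#' @param graph square weight matrix for the graph models (non-negative,
#'   zero diagonal recommended).
#' @param directed for `graph_moran_*`: is `graph` to be taken as directed?
#'   (informational; the matrix itself already encodes direction).
#' @param sizes class sizes for `class_moran`.
#' @param class_weights optional class-to-class parent weight matrix
#'   (`[j, k]` = weight of a parent in class j when the dying site is in
#'   class k).
#' @param islands,island_size,migration island-model parameters.
#' @param table explicit support table (list of per-state entries).
#' @param max_n guard on `n` for `wright_fisher` support enumeration.
#' @return a validated [selection_process()].
#' @examples
#' proc <- make_model("well_mixed_moran", n = 3)
#' enumerate_support(proc, c(1, 0, 0))
#' @export
make_model <- function(model, n = NULL, r = 1, u = 0, graph = NULL,
                       directed = FALSE, sizes = NULL, class_weights = NULL,
                       islands = NULL, island_size = NULL, migration = NULL,
                       table = NULL, max_n = 6) {
  if (is.list(model)) {
    spec <- model
    return(make_model(spec$model,
                      n = spec$n, r = spec$r %||% 1, u = spec$u %||% 0,
                      graph = spec$graph, directed = spec$directed %||% FALSE,
                      sizes = spec$sizes %||% spec$classes,
                      class_weights = spec$class_weights,
                      islands = spec$islands, island_size = spec$island_size,
                      migration = spec$migration, table = spec$table,
                      max_n = spec$max_n %||% 6))
  }
  rr <- parse_rational(r)
  uu <- parse_rational(u)
  if (rr$num <= 0) stop("fitness r must be positive")
  if (uu$num < 0 || uu$num > uu$den) stop("mutation probability u must lie in [0, 1]")

  known <- c("well_mixed_moran", "wright_fisher", "graph_moran_db",
             "graph_moran_bd", "directed_cycle_moran", "undirected_cycle_moran",
             "star_moran_db", "class_moran", "island_moran", "explicit_table")
  if (!model %in% known) {
    stop("unknown model '", model, "'; available: ", paste(known, collapse = ", "))
  }

  proc <- switch(model,
    well_mixed_moran = {
      check_n(n)
      build_moran_support(n, rr, uu, model,
                          parent_weights = function(x, d, w) w)
    },
    wright_fisher = {
      check_n(n)
      if (n > max_n) stop("wright_fisher support has n^n maps per state; ",
                          "n = ", n, " exceeds max_n = ", max_n)
      build_wf_support(n, rr, uu)
    },
    graph_moran_db = build_graph_db(graph, rr, uu, "graph_moran_db"),
    graph_moran_bd = build_graph_bd(graph, rr, uu),
    directed_cycle_moran = {
      check_n(n, min = 3)
      build_graph_db(cycle_adjacency(n, directed = TRUE), rr, uu,
                     "directed_cycle_moran")
    },
    undirected_cycle_moran = {
      check_n(n, min = 3)
      build_graph_db(cycle_adjacency(n, directed = FALSE), rr, uu,
                     "undirected_cycle_moran")
    },
    star_moran_db = {
      check_n(n, min = 3)
      build_graph_db(star_adjacency(n), rr, uu, "star_moran_db")
    },
    class_moran = build_class_moran(sizes, class_weights, rr, uu),
    island_moran = build_island_moran(islands, island_size, migration, rr, uu),
    explicit_table = make_explicit_process(table)
  )
  proc
}

check_n <- function(n, min = 1) {
  if (is.null(n) || length(n) != 1 || is.na(n) || n < min || n != round(n)) {
    stop("site count n must be an integer >= ", min)
  }
}

## fitness weights as integers: allele 1 -> r_num, allele 0 -> r_den
fitness_weights <- function(x, rr) ifelse(x == 1, rr$num, rr$den)

## expand a list of pure-replacement events with i.i.d. per-site mutation
expand_mutation <- function(alpha, pnum, pden, n, uu) {
  E <- nrow(alpha)
  noU <- matrix(FALSE, E, n)
  if (uu$num == 0) return(list(alpha = alpha, U = noU, pnum = pnum, pden = pden))
  if (n > 6) stop("mutation support enumeration (2^n mutation sets per map) ",
                  "is limited to n <= 6")
  subsets <- all_states(n) == 1L          # 2^n x n logical
  k <- rowSums(subsets)
  un <- uu$num; ud <- uu$den
  fnum <- un^k * (ud - un)^(n - k)        # u^|U| (1-u)^(n-|U|) numerators
  keep <- which(fnum > 0)
  out_alpha <- alpha[rep(seq_len(E), each = length(keep)), , drop = FALSE]
  out_U <- subsets[rep(keep, times = E), , drop = FALSE]
  out_n <- numeric(E * length(keep)); out_d <- numeric(E * length(keep))
  idx <- 1L
  for (e in seq_len(E)) {
    for (s in keep) {
      rp <- rat_mul(pnum[e], pden[e], fnum[s], ud^n)
      out_n[idx] <- rp$num; out_d[idx] <- rp$den
      idx <- idx + 1L
    }
  }
  list(alpha = out_alpha, U = out_U, pnum = out_n, pden = out_d)
}

## generic Moran-type builder: dying site uniform over n, parent from all
## sites with state-dependent integer weights
build_moran_support <- function(n, rr, uu, model_name, parent_weights) {
  states <- all_states(n)
  support <- vector("list", 2^n)
  id <- seq_len(n)
  for (i in seq_len(2^n)) {
    x <- states[i, ]
    w <- fitness_weights(x, rr)
    alpha <- matrix(rep(id, each = n * n), n * n, n)
    pnum <- numeric(n * n); pden <- numeric(n * n)
    row <- 1L
    for (d in seq_len(n)) {
      wts <- parent_weights(x, d, w)
      W <- sum(wts)
      for (p in seq_len(n)) {
        alpha[row, d] <- p
        pnum[row] <- wts[p]; pden[row] <- W * n
        row <- row + 1L
      }
    }
    keep <- pnum > 0
    ev <- expand_mutation(alpha[keep, , drop = FALSE], pnum[keep], pden[keep],
                          n, uu)
    support[[i]] <- ev
  }
  selection_process(n, support, exact = TRUE, model = model_name,
                    params = list(r = rr, u = uu))
}

build_wf_support <- function(n, rr, uu) {
  states <- all_states(n)
  maps <- all_states(n, num_alleles = n) + 1L   # n^n parentage maps
  support <- vector("list", 2^n)
  for (i in seq_len(2^n)) {
    x <- states[i, ]
    w <- fitness_weights(x, rr)
    W <- sum(w)
    # p(alpha) = prod_g w[alpha(g)] / W^n, exact integers
    pnum <- apply(maps, 1, function(a) prod(w[a]))
    rat_check(pnum); rat_check(W^n)
    ev <- expand_mutation(maps, pnum, rep(W^n, nrow(maps)), n, uu)
    support[[i]] <- ev
  }
  selection_process(n, support, exact = TRUE, model = "wright_fisher",
                    params = list(r = rr, u = uu))
}

## convert a numeric weight matrix to integers (scale by lcm of denominators)
integer_weights <- function(W) {
  if (is.null(W)) stop("graph model requires a weight matrix 'graph'")
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("graph weight matrix must be square")
  if (any(W < 0)) stop("graph weights must be non-negative")
  dens <- apply(W, c(1, 2), function(v) {
    r <- as_rational(v, max_den = 1e6)
    if (is.null(r)) stop("graph weight ", v, " not representable as a rational")
    r$den
  })
  L <- Reduce(function(a, b) a / rat_gcd(a, b) * b, as.vector(dens), accumulate = FALSE)
  round(W * L)
}

build_graph_db <- function(graph, rr, uu, model_name) {
  W <- integer_weights(graph)
  n <- nrow(W)
  if (any(colSums(W) == 0)) {
    stop("graph has an isolated vertex (no in-neighbour): death-birth ",
         "updating has no possible parent for it")
  }
  states <- all_states(n)
  support <- vector("list", 2^n)
  for (i in seq_len(2^n)) {
    x <- states[i, ]
    f <- fitness_weights(x, rr)
    alpha <- NULL; pnum <- NULL; pden <- NULL
    rows <- list(); pn <- c(); pd <- c()
    for (d in seq_len(n)) {
      wts <- W[, d] * f
      Wd <- sum(wts)
      for (p in which(wts > 0)) {
        a <- seq_len(n); a[d] <- p
        rows[[length(rows) + 1L]] <- a
        pn <- c(pn, wts[p]); pd <- c(pd, Wd * n)
      }
    }
    support[[i]] <- expand_mutation(do.call(rbind, rows), pn, pd, n, uu)
  }
  selection_process(n, support, exact = TRUE, model = model_name,
                    params = list(r = rr, u = uu, graph = W))
}

build_graph_bd <- function(graph, rr, uu) {
  W <- integer_weights(graph)
  n <- nrow(W)
  if (any(rowSums(W) == 0)) {
    stop("graph has a vertex with no out-neighbour: birth-death updating ",
         "cannot place its offspring")
  }
  states <- all_states(n)
  support <- vector("list", 2^n)
  for (i in seq_len(2^n)) {
    x <- states[i, ]
    f <- fitness_weights(x, rr)
    F <- sum(f)
    rows <- list(); pn <- c(); pd <- c()
    for (p in seq_len(n)) {
      Rp <- sum(W[p, ])
      for (d in which(W[p, ] > 0)) {
        a <- seq_len(n); a[d] <- p
        rows[[length(rows) + 1L]] <- a
        pn <- c(pn, f[p] * W[p, d]); pd <- c(pd, F * Rp)
      }
    }
    support[[i]] <- expand_mutation(do.call(rbind, rows), pn, pd, n, uu)
  }
  selection_process(n, support, exact = TRUE, model = "graph_moran_bd",
                    params = list(r = rr, u = uu, graph = W))
}

#' Adjacency matrices for cycle and star populations
#'
#' `cycle_adjacency(n, directed = TRUE)` has an edge from each site g to
#' g+1 (mod n); the undirected version adds the reverse edges. `star_adjacency`
#' joins the hub (site 1) to each of the n-1 leaves in both directions.
#'
#' @param n number of sites.
#' @param directed directed cycle?
#' @export
cycle_adjacency <- function(n, directed = TRUE) {
  W <- matrix(0, n, n)
  for (g in seq_len(n)) W[g, g %% n + 1L] <- 1
  if (!directed) W <- W + t(W)
  W
}

#' @rdname cycle_adjacency
#' @export
star_adjacency <- function(n) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- 1
  W[2:n, 1] <- 1
  W
}

build_class_moran <- function(sizes, class_weights, rr, uu) {
  if (is.null(sizes) || any(sizes < 1) || any(sizes != round(sizes))) {
    stop("class_moran requires positive integer class sizes")
  }
  K <- length(sizes)
  n <- sum(sizes)
  cls <- rep(seq_len(K), times = sizes)
  if (is.null(class_weights)) {
    # pairwise-distinct positive entries: breaks any cross-class symmetry
    class_weights <- outer(seq_len(K), seq_len(K),
                           function(j, k) (j - 1) * K + k)
  }
  CW <- integer_weights(class_weights)
  if (nrow(CW) != K) stop("class_weights must be ", K, " x ", K)
  if (any(colSums(CW) == 0)) stop("some class can never be parented")
  build_moran_support(n, rr, uu, "class_moran",
                      parent_weights = function(x, d, w) CW[cls, cls[d]] * w)
}

build_island_moran <- function(islands, island_size, migration, rr, uu) {
  if (is.null(islands) || is.null(island_size) ||
      islands < 2 || island_size < 1) {
    stop("island_moran requires islands >= 2 and island_size >= 1")
  }
  mm <- parse_rational(migration %||% stop("island_moran requires a migration rate"))
  if (mm$num <= 0 || mm$num >= mm$den) {
    stop("migration rate must lie strictly in (0, 1) so that the fixation ",
         "axiom holds and islands remain distinguishable from one population")
  }
  m <- islands; k <- island_size; n <- m * k
  isl <- rep(seq_len(m), each = k)
  # parent weight: same island (1-mig)/F_in, other islands mig/F_out, as
  # integers after clearing the migration denominator. F_in/F_out depend on
  # the state, so weights are assembled per (state, dying site).
  build_moran_support(n, rr, uu, "island_moran",
    parent_weights = function(x, d, w) {
      same <- isl == isl[d]
      Fin <- sum(w[same]); Fout <- sum(w[!same])
      wt <- numeric(n)
      wt[same] <- (mm$den - mm$num) * w[same] * Fout
      wt[!same] <- mm$num * w[!same] * Fin
      rat_check(wt)
      wt
    })
}
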