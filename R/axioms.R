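#' Parentage maps available in every state
#'
#' Returns the set D of parentage maps whose marginal probability (summed over
#' mutation sets) is positive in every population state. These are the maps
#' from which a fixation witness may be assembled.
#'
#' @param process a `selection_process`.
#' @return list of parentage image vectors.
#' @export
always_possible_maps <- function(process) {
  stopifnot(inherits(process, "selection_process"))
  keysets <- lapply(process$support, function(ev) {
    unique(apply(ev$alpha, 1, paste, collapse = ","))
  })
  common <- Reduce(intersect, keysets)
  lapply(common, function(k) as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
}

#' Decide the fixation axiom
#'
#' The axiom requires one site g and a finite sequence of parentage maps, each
#' available with positive probability in every state, whose composition sends
#' every site to g -- i.e. some site can, with positive probability, spread its
#' descendants to the whole population. Deciding this is the synchronizing-word
#' problem for the map set D of [always_possible_maps()]: a constant composite
#' exists if and only if every pair of sites can be merged by some composite
#' (checked by breadth-first search on site pairs). A positive answer returns
#' a witness assembled by greedily collapsing the image of the running
#' composite; the witness is re-verified by explicit composition before
#' return. A negative answer returns a certificate pair that no composite over
#' D can merge.
#'
#' @param process a `selection_process`.
#' @return list with `holds` (logical), `witness` (list with `target_site` and
#'   `map_sequence`, maps in temporal order so that
#'   `m1 o m2 o ... o mk` is constant) or NULL, and `certificate` (an
#'   unmergeable site pair) or NULL.
#' @export
check_fixation_axiom <- function(process) {
  stopifnot(inherits(process, "selection_process"))
  n <- process$n
  D <- always_possible_maps(process)
  if (!length(D)) {
    return(list(holds = FALSE, witness = NULL, certificate = integer(0),
                reason = "no parentage map is available in every state"))
  }
  if (n == 1) {
    return(list(holds = TRUE,
                witness = list(target_site = 1L, map_sequence = list(D[[1]])),
                certificate = NULL))
  }
  # pair BFS (backwards): dist[p] = fewest maps merging pair p; via[p] = the
  # first map to apply on that shortest route, nxt[p] = the successor pair
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  P <- nrow(pairs)
  pair_id <- matrix(0L, n, n)
  for (p in seq_len(P)) {
    pair_id[pairs[p, 1], pairs[p, 2]] <- p
    pair_id[pairs[p, 2], pairs[p, 1]] <- p
  }
  # image of each pair under each map: 0 = merged
  img <- matrix(0L, P, length(D))
  for (d in seq_along(D)) {
    a <- D[[d]][pairs[, 1]]
    b <- D[[d]][pairs[, 2]]
    img[, d] <- ifelse(a == b, 0L, pair_id[cbind(pmin(a, b), pmax(a, b))])
  }
  dist <- rep(NA_integer_, P)
  via <- rep(NA_integer_, P)
  nxt <- rep(NA_integer_, P)
  for (p in seq_len(P)) {
    d <- which(img[p, ] == 0L)
    if (length(d)) { dist[p] <- 1L; via[p] <- d[1]; nxt[p] <- 0L }
  }
  repeat {
    changed <- FALSE
    for (p in which(is.na(dist))) {
      best_d <- NA_integer_; best <- Inf
      for (d in seq_along(D)) {
        q <- img[p, d]
        if (q != 0L && !is.na(dist[q]) && dist[q] < best) {
          best <- dist[q]; best_d <- d
        }
      }
      if (!is.na(best_d)) {
        dist[p] <- best + 1L; via[p] <- best_d; nxt[p] <- img[p, best_d]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(dist)) {
    bad <- which(is.na(dist))[1]
    return(list(holds = FALSE, witness = NULL,
                certificate = c(pairs[bad, 1], pairs[bad, 2])))
  }
  # greedy witness assembly: repeatedly merge two members of the image of the
  # running composite by prepending (in composition order) the merge word
  phi <- seq_len(n)        # running composite, built as W_k o ... o W_1
  seq_maps <- list()       # final composition read left-to-right
  guard <- 0L
  while (length(unique(phi)) > 1) {
    guard <- guard + 1L
    if (guard > n * n) stop("internal error: witness assembly did not converge")
    im <- sort(unique(phi))
    a <- im[1]; b <- im[2]
    # shortest word merging (a, b): maps applied first-to-last m1, m2, ...
    word <- list()
    p <- pair_id[a, b]
    repeat {
      word[[length(word) + 1L]] <- D[[via[p]]]
      if (nxt[p] == 0L) break
      p <- nxt[p]
    }
    # W = m_L o ... o m_1 ; as an image vector w[g] = m_L(...m_1(g))
    w <- seq_len(n)
    for (mp in word) w <- mp[w]
    phi <- w[phi]
    # composition W o phi reads (m_L, ..., m_1) then the previous sequence
    seq_maps <- c(rev(word), seq_maps)
  }
  target <- unique(phi)
  # re-verify by explicit composition: v[h] = m1(m2(...mk(h)))
  v <- seq_len(n)
  for (i in seq(length(seq_maps), 1)) v <- seq_maps[[i]][v]
  if (!all(v == target)) stop("internal error: witness failed re-verification")
  list(holds = TRUE,
       witness = list(target_site = as.integer(target),
                      map_sequence = seq_maps),
       certificate = NULL)
}

#' Closure of a map set under composition
#'
#' Enumerates all distinct composite maps generated by a set of parentage maps
#' (used as an independent oracle for the fixation-axiom decision: the axiom
#' holds if and only if the closure contains a constant map).
#'
#' @param maps list of image vectors.
#' @param n number of sites.
#' @param max_size abort if the semigroup exceeds this many maps.
#' @return integer matrix with one composite map per row.
#' @export
composite_map_closure <- function(maps, n, max_size = 1e5) {
  seen <- new.env(parent = emptyenv())
  store <- list()
  add <- function(v) {
    k <- paste(v, collapse = ",")
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      store[[length(store) + 1L]] <<- v
      TRUE
    } else FALSE
  }
  for (m in maps) add(as.integer(m))
  frontier <- store
  while (length(frontier)) {
    fresh <- list()
    for (a in frontier) for (b in store) {
      if (add(a[b])) fresh[[length(fresh) + 1L]] <- a[b]
      if (add(b[a])) fresh[[length(fresh) + 1L]] <- b[a]
      if (length(store) > max_size) stop("composite closure exceeds max_size")
    }
    frontier <- fresh
  }
  do.call(rbind, store)
}

#' Serialize a fixation witness as JSON
#'
#' @param witness the `witness` component of [check_fixation_axiom()].
#' @param path file path.
#' @export
write_witness_json <- function(witness, path) {
  jsonlite::write_json(list(target_site = witness$target_site,
                            map_sequence = witness$map_sequence),
                       path, auto_unbox = TRUE)
  invisible(path)
}
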