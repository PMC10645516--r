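#' Read a model specification file
#'
#' Parses a JSON or YAML config (dispatched on file extension) describing
#' either a built-in model or an explicit support table, and returns the
#' validated process. Recognized keys: `model`, `n`, `r`, `u`, `graph` (inline
#' adjacency matrix or path to a graph file), `directed`, `sizes`/`classes`,
#' `class_weights`, `islands`, `island_size`, `migration`, `table`. A spec
#' with `kind: structure` instead returns the [make_structure_group()] result.
#'
#' Explicit tables list every state as a bitstring (site 1 leftmost) with its
#' events; probabilities written as rational strings (`"3/16"`) are preserved
#' exactly and survive a write/read round trip losslessly:
#' \preformatted{
#' {"model": "explicit_table", "n": 2,
#'  "table": [
#'    {"state": "00", "events": [{"alpha": [1, 1], "U": [], "p": "1/2"},
#'                               {"alpha": [2, 2], "U": [], "p": "1/2"}]},
#'    ...]}
#' }
#'
#' @param path config file (`.json`, `.yaml`, `.yml`).
#' @return a `selection_process` or, for `kind: structure`, a `symmetry_group`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  spec <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                               simplifyMatrix = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unrecognized config extension '", ext, "' (use .json or .yaml)"))
  if (identical(spec$kind, "structure")) {
    return(make_structure_group(spec$structure, n = spec$n, sizes = spec$sizes,
                                block_count = spec$block_count,
                                block_size = spec$block_size))
  }
  if (is.null(spec$model)) stop("config has no 'model' key")
  if (is.character(spec$graph) && length(spec$graph) == 1) {
    spec$graph <- read_graph(spec$graph, directed = spec$directed %||% FALSE)
  }
  if (!is.null(spec$graph) && !is.matrix(spec$graph)) {
    spec$graph <- do.call(rbind, spec$graph)
  }
  make_model(spec)
}

#' Read a population graph
#'
#' `.csv` files are read as square adjacency matrices; anything else as an
#' edge list with one `i j weight` triple per line (weight optional, default
#' 1). Undirected edge lists are symmetrized.
#'
#' @param path graph file.
#' @param n number of sites (inferred from the data when omitted).
#' @param directed treat edges as directed?
#' @return numeric weight matrix.
#' @export
read_graph <- function(path, n = NULL, directed = FALSE) {
  if (tolower(tools::file_ext(path)) == "csv") {
    W <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(W) <- NULL
    if (nrow(W) != ncol(W)) stop("adjacency CSV is not square")
    return(W)
  }
  el <- utils::read.table(path, header = FALSE,
                          col.names = c("i", "j", "w")[1:min(3, max(utils::count.fields(path)))],
                          fill = TRUE)
  if (is.null(el$w)) el$w <- 1
  el$w[is.na(el$w)] <- 1
  n <- n %||% max(el$i, el$j)
  W <- matrix(0, n, n)
  for (row in seq_len(nrow(el))) {
    W[el$i[row], el$j[row]] <- el$w[row]
    if (!directed) W[el$j[row], el$i[row]] <- el$w[row]
  }
  W
}

## explicit-table constructor (entry point used by make_model)
make_explicit_process <- function(table) {
  if (is.null(table) || !length(table)) stop("explicit_table requires a 'table'")
  states <- vapply(table, function(s) s$state, character(1))
  n <- nchar(states[1])
  if (length(table) != 2^n || anyDuplicated(states)) {
    stop("explicit table must list every one of the 2^n states exactly once")
  }
  # exact unless some probability is a bare non-integer double
  exact <- all(vapply(table, function(s) {
    all(vapply(s$events, function(e) {
      is.character(e$p) || (is.numeric(e$p) && !is.null(as_rational(e$p, 1e6)))
    }, logical(1)))
  }, logical(1)))
  support <- vector("list", 2^n)
  for (s in table) {
    x <- as.integer(strsplit(s$state, "")[[1]])  # site 1 leftmost
    if (!all(x %in% 0:1)) stop("bad state bitstring: ", s$state)
    E <- length(s$events)
    alpha <- matrix(0L, E, n); U <- matrix(FALSE, E, n)
    pnum <- numeric(E); pden <- numeric(E)
    for (e in seq_len(E)) {
      ev <- s$events[[e]]
      alpha[e, ] <- as.integer(unlist(ev$alpha))
      us <- as.integer(unlist(ev$U))
      if (length(us)) U[e, us] <- TRUE
      if (exact) {
        r <- parse_rational(ev$p)
        pnum[e] <- r$num; pden[e] <- r$den
      } else {
        pnum[e] <- if (is.character(ev$p)) {
          r <- parse_rational(ev$p); r$num / r$den
        } else ev$p
        pden[e] <- 1
      }
    }
    support[[state_index(x)]] <- list(alpha = alpha, U = U, pnum = pnum, pden = pden)
  }
  selection_process(n, support, exact = exact, model = "explicit_table")
}

#' Write a process as an explicit-table spec
#'
#' Serializes the full support of any process in the explicit-table format
#' read by [read_model_spec()]. Exact probabilities are written as rational
#' strings, so write-then-read reproduces the process exactly.
#'
#' @param process a `selection_process`.
#' @param path output file (`.json` or `.yaml`).
#' @export
write_model_spec <- function(process, path) {
  n <- process$n
  table <- lapply(seq_len(2^n), function(i) {
    x <- index_to_state(i, n)
    ev <- process$support[[i]]
    list(state = state_bitstring(x),
         events = lapply(seq_len(nrow(ev$alpha)), function(e) {
           list(alpha = ev$alpha[e, ],
                U = which(ev$U[e, ]),
                p = if (process$exact) rat_format(ev$pnum[e], ev$pden[e])
                    else ev$pnum[e] / ev$pden[e])
         }))
  })
  spec <- list(model = "explicit_table", n = n, table = table)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}
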