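#' Full symmetry analysis of a selection process
#'
#' Runs the whole pipeline on one process: symmetry group (brute force or from
#' supplied generators), site orbits and transitivity, state orbits and the
#' reduced chain with its lumpability check, the Burnside orbit count against
#' the order-based bounds, the fixation axiom with its witness, and (when
#' applicable) fixation probabilities or the stationary distribution.
#'
#' @param process a `selection_process`.
#' @param generators optional list of permutations passed to
#'   [symmetry_group()].
#' @param fixation solve for fixation probabilities when the process is
#'   mutation-free (default TRUE).
#' @param stationary solve for the stationary distribution when mutation is
#'   present (default TRUE).
#' @return object of class `analysis_report` (a list; see fields in the
#'   examples and print method).
#' @export
analyze_process <- function(process, generators = NULL, fixation = TRUE,
                            stationary = TRUE) {
  stopifnot(inherits(process, "selection_process"))
  group <- symmetry_group(process, generators)
  so <- site_orbits(group)
  P <- build_chain(process)
  preserve <- verify_transition_preservation(P, group)
  ol <- state_orbits(group)
  rc <- build_reduced_chain(P, ol)   # errors on lumpability violation
  R <- count_reduced_states(group)
  bounds <- state_count_bounds(process$n, group$order)
  ax <- check_fixation_axiom(process)
  mutation_free <- !any(vapply(process$support, function(ev) any(ev$U), logical(1)))
  rep <- list(
    model = process$model, n = process$n, exact = process$exact,
    group_order = group$order,
    group = group,
    group_cycles = vapply(seq_len(group$order),
                          function(i) cycle_notation(group$elements[i, ]),
                          character(1)),
    site_orbits = so$orbits, transitive = so$transitive,
    transition_preserved = preserve$ok,
    reduced_states = R,
    orbit_count_by_enumeration = length(ol$orbits),
    bounds = bounds,
    bounds_hold = bounds_hold(bounds, R),
    lumpable = TRUE,
    fixation_axiom = ax$holds,
    witness = ax$witness,
    reduced_chain = rc
  )
  if (fixation && mutation_free && ax$holds) {
    rep$fixation <- fixation_probabilities(process, check_axiom = FALSE)
  }
  if (stationary && !mutation_free) {
    rep$stationary <- tryCatch(stationary_distribution(P),
                               error = function(e) NULL)
  }
  structure(rep, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== selection process analysis ==\n")
  cat("model:", x$model, " n =", x$n, " arithmetic:",
      if (x$exact) "exact" else "float", "\n")
  cat("symmetry group order:", x$group_order, "\n")
  gens <- utils::head(x$group_cycles[x$group_cycles != cycle_notation(seq_len(x$n))], 4)
  if (length(gens)) cat("sample elements:", paste(gens, collapse = "  "), "\n")
  cat("site orbits:",
      paste(vapply(x$site_orbits, function(o) paste0("{", paste(o, collapse = " "), "}"),
                   character(1)), collapse = " "),
      if (x$transitive) "(transitive)" else "(not transitive)", "\n")
  cat("reduced states R =", x$reduced_states, "of", 2^x$n,
      "; bounds", rat_format(x$bounds$lower_num, x$bounds$lower_den), "<= R <=",
      rat_format(x$bounds$upper_num, x$bounds$upper_den),
      if (x$bounds_hold) "(hold)" else "(VIOLATED)", "\n")
  cat("transition preservation:", if (x$transition_preserved) "verified" else "FAILED",
      "; lumpability: verified\n")
  cat("fixation axiom:", if (x$fixation_axiom) "holds" else "FAILS")
  if (x$fixation_axiom) {
    cat(" (witness: ", length(x$witness$map_sequence),
        " maps onto site ", x$witness$target_site, ")", sep = "")
  }
  cat("\n")
  if (!is.null(x$fixation)) {
    singles <- vapply(seq_len(x$n), function(g) {
      s <- rep(0L, x$n); s[g] <- 1L
      x$fixation$rho[state_index(s)]
    }, numeric(1))
    cat("single-mutant fixation probabilities:",
        paste(signif(singles, 6), collapse = " "), "\n")
  }
  if (!is.null(x$stationary)) {
    cat("stationary distribution computed over", length(x$stationary$pi), "states\n")
  }
  invisible(x)
}

#' Export an analysis report as JSON
#'
#' @param report an `analysis_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    model = report$model, n = report$n,
    group_order = report$group_order,
    group_elements = report$group_cycles,
    site_orbits = report$site_orbits,
    transitive = report$transitive,
    reduced_states = report$reduced_states,
    bounds = list(lower = rat_format(report$bounds$lower_num, report$bounds$lower_den),
                  upper = rat_format(report$bounds$upper_num, report$bounds$upper_den)),
    bounds_hold = report$bounds_hold,
    transition_preserved = report$transition_preserved,
    fixation_axiom = report$fixation_axiom)
  if (!is.null(report$witness)) {
    obj$witness <- list(target_site = report$witness$target_site,
                        map_sequence = report$witness$map_sequence)
  }
  if (!is.null(report$fixation)) obj$fixation <- report$fixation$rho
  if (!is.null(report$stationary)) obj$stationary <- report$stationary$pi
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
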