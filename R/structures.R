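#' Symmetry groups of named population structures
#'
#' Builds, directly from a structure description and independently of any
#' concrete process, the permutation group a population structure induces:
#' \describe{
#'   \item{`symmetric`}{all `n!` permutations (well-mixed haploids).}
#'   \item{`class_partition`}{permutations fixing each class setwise; classes
#'     of sizes `sizes` occupy consecutive sites; order `prod(sizes!)`.}
#'   \item{`block_partition`}{permutations preserving a partition into
#'     `block_count` interchangeable blocks of `block_size` consecutive sites
#'     (islands of haploids, or diploid individuals with `block_size = 2`);
#'     order `block_count! * (block_size!)^block_count`.}
#'   \item{`dihedral`}{rotations and reflections of the n-cycle, order `2n`.}
#'   \item{`cyclic`}{rotations of the n-cycle, order `n`.}
#'   \item{`star`}{permutations fixing the hub (site 1), order `(n-1)!`.}
#' }
#'
#' Groups are materialized as explicit element sets (needed for element-wise
#' cycle counts in Burnside counting), capped at `max_order` elements.
#'
#' @param kind one of the structure names above.
#' @param n number of sites (required for all kinds; for partitions it must
#'   match the sizes).
#' @param sizes class sizes (`class_partition`).
#' @param block_count,block_size block structure (`block_partition`).
#' @param max_order refuse to materialize groups larger than this.
#' @return a `symmetry_group`.
#' @examples
#' make_structure_group("dihedral", n = 8)$order       # 16
#' make_structure_group("class_partition", n = 5, sizes = c(2, 3))$order  # 12
#' @export
make_structure_group <- function(kind, n, sizes = NULL, block_count = NULL,
                                 block_size = NULL, max_order = 1e6) {
  kind <- match.arg(kind, c("symmetric", "class_partition", "block_partition",
                            "dihedral", "cyclic", "star"))
  check_n(n)
  order_guard <- function(o) {
    if (o > max_order) stop("group order ", o, " exceeds max_order = ", max_order)
  }
  elements <- switch(kind,
    symmetric = {
      order_guard(factorial(n))
      all_permutations(n)
    },
    class_partition = {
      if (is.null(sizes) || sum(sizes) != n || any(sizes < 1)) {
        stop("class_partition requires positive sizes summing to n")
      }
      order_guard(prod(factorial(sizes)))
      blocks <- split(seq_len(n), rep(seq_along(sizes), times = sizes))
      product_of_block_perms(n, blocks)
    },
    block_partition = {
      if (is.null(block_count) || is.null(block_size) ||
          block_count * block_size != n) {
        stop("block_partition requires block_count * block_size == n")
      }
      order_guard(factorial(block_count) * factorial(block_size)^block_count)
      block_wreath(n, block_count, block_size)
    },
    dihedral = {
      if (n < 3) stop("dihedral structure requires n >= 3")
      rot <- lapply(0:(n - 1), function(j) ((seq_len(n) - 1 + j) %% n) + 1L)
      refl <- lapply(rot, function(r) r[((n - 1 - (seq_len(n) - 1)) %% n) + 1L])
      do.call(rbind, c(rot, refl))
    },
    cyclic = {
      do.call(rbind, lapply(0:(n - 1), function(j) ((seq_len(n) - 1 + j) %% n) + 1L))
    },
    star = {
      if (n < 2) stop("star structure requires n >= 2")
      order_guard(factorial(n - 1))
      leafperms <- all_permutations(n - 1) + 1L
      cbind(rep(1L, nrow(leafperms)), leafperms)
    })
  new_symmetry_group(n, elements)
}

## all permutations fixing each block setwise (cartesian product of
## within-block permutations)
product_of_block_perms <- function(n, blocks) {
  per_block <- lapply(blocks, function(b) {
    p <- all_permutations(length(b))
    matrix(b[p], nrow(p), length(b))
  })
  counts <- vapply(per_block, nrow, integer(1))
  total <- prod(counts)
  out <- matrix(0L, total, n)
  idx <- rep(1L, length(blocks))
  for (row in seq_len(total)) {
    for (j in seq_along(blocks)) {
      out[row, blocks[[j]]] <- per_block[[j]][idx[j], ]
    }
    # odometer increment
    for (j in seq_along(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= counts[j]) break
      idx[j] <- 1L
    }
  }
  out
}

## permutations preserving a partition into equal consecutive blocks,
## allowing block interchange: site (b-1)k + i -> (pi_B(b)-1)k + pi_b(i)
block_wreath <- function(n, m, k) {
  blocks <- split(seq_len(n), rep(seq_len(m), each = k))
  inner <- product_of_block_perms(n, blocks)
  bperms <- all_permutations(m)
  out <- matrix(0L, nrow(inner) * nrow(bperms), n)
  row <- 1L
  for (bp in seq_len(nrow(bperms))) {
    # block relabelling as a site permutation
    moveto <- integer(n)
    for (b in seq_len(m)) {
      moveto[blocks[[b]]] <- blocks[[bperms[bp, b]]]
    }
    for (ip in seq_len(nrow(inner))) {
      out[row, ] <- moveto[inner[ip, ]]
      row <- row + 1L
    }
  }
  out
}
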