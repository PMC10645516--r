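---
title: "Symmetry analysis of finite selection processes: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry analysis of finite selection processes: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selsym)
```

## The model

`selsym` works with finite, two-allele models of natural selection seen from
the gene's-eye view. A population is a fixed set of **sites**
$G = \{1, \dots, n\}$, each housing one allele, $0$ or $1$. A population
state is a vector $x \in \{0,1\}^G$. One time step samples, from a
state-dependent distribution $p_x$, a pair consisting of

* a **parentage map** $\alpha : G \to G$, where $\alpha(g)$ is the site from
  which $g$'s next allele is copied ($\alpha(g) = g$ means survival), and
* a **mutation set** $U \subseteq G$, the sites whose inherited allele is
  flipped.

The next state is
$$x'_g = \begin{cases} x_{\alpha(g)} & g \notin U \\ 1 - x_{\alpha(g)} & g \in U. \end{cases}$$

This scheme subsumes the standard population-genetic update rules: Moran
birth-death and death-birth updating on weighted graphs, Wright-Fisher
resampling, class-structured and island-structured populations. All of these
are available through `make_model()`; arbitrary processes can be given as
explicit per-state event tables (`read_model_spec()`).

A valid process must also satisfy the **fixation axiom**: some site must be
able, through a finite sequence of parentage maps each available with
positive probability in every state, to become the ancestor of the whole
population. Section "The fixation axiom" below describes how the package
decides this.

### Conventions

* Sites are numbered $1, \dots, n$ (R's native indexing).
* States are indexed $1, \dots, 2^n$ with site 1 as the least significant
  bit: `state_index(x)` $= 1 + \sum_g x_g 2^{g-1}$. Bitstring labels print
  site 1 leftmost, so state `"100"` has a mutant at site 1 only.
* Permutations are image vectors: `sigma[g]` is $\sigma(g)$. The group acts
  on sites on the left and on states on the right, $(x\sigma)_g =
  x_{\sigma(g)}$, so `apply_permutation(x, sigma)` is `x[sigma]`.
* In composite parentage maps $\alpha_1 \circ \alpha_2 \circ \cdots \circ
  \alpha_m$, the maps are written in the temporal order in which the steps
  occur, and the *ancestry* composition reads left-to-right: the ancestor of
  site $h$ after $m$ steps is $\alpha_1(\alpha_2(\cdots \alpha_m(h)))$.
  Witnesses returned by `check_fixation_axiom()` follow this convention.

## Exact arithmetic

Built-in models carry their event probabilities as exact rationals
(numerator/denominator pairs of integer-valued doubles, always below
$2^{53}$, with overflow checks). Transition matrices, lumpability checks,
symmetry tests, and Burnside counts are all evaluated by exact rational
comparison, so none of those results depend on a floating-point tolerance.

The two linear solves — fixation probabilities and the stationary
distribution — use double-precision dense linear algebra (`solve()`, `svd()`)
on the exact matrix entries; results are verified to satisfy their defining
equations to $10^{-9}$. For the state-space sizes the package handles
($n \le 12$, i.e. at most $4096$ states), this is accurate to near machine
precision.

## Symmetries

A permutation $\sigma$ of sites is a **symmetry** of the process when, for
every state $x$ and event $(\alpha, U)$,
$$p_x(\alpha, U) = p_{x\sigma}\left(\sigma^{-1} \circ \alpha \circ \sigma,\; \sigma^{-1}(U)\right).$$

`is_symmetry()` tests this definition literally, by exact comparison of the
transformed support of $x\sigma$ against the support of $x$ in every state.
Two consequences are verified independently in the test suite and available
as runtime checks:

* symmetries preserve transition probabilities,
  $P_{x \to y} = P_{x\sigma \to y\sigma}$
  (`verify_transition_preservation()`, exact for one step), and
* the set of all symmetries is a group (`validate_group()`).

`symmetry_group()` finds the full group by brute force over all $n!$
permutations (feasible for $n \le 8$ thanks to an exact necessary-condition
prefilter on per-site replacement probabilities), or by closing a
user-supplied generator list. For the named families the detected groups
match the structure groups built directly by `make_structure_group()`:

| model | group | order |
|---|---|---|
| well-mixed (Moran or Wright-Fisher) | $S_n$ | $n!$ |
| classes of sizes $n_1, \dots, n_m$ | $\prod_j S_{n_j}$ | $\prod_j n_j!$ |
| $m$ islands of size $k$ (also diploids, $k=2$) | $S_m \wr S_k$ | $m!\,(k!)^m$ |
| undirected cycle | dihedral | $2n$ |
| directed cycle | cyclic | $n$ |
| star (hub + leaves) | $S_{n-1}$ on the leaves | $(n-1)!$ |

## Reduction

Symmetric states are dynamically interchangeable, so the chain can be
**lumped** onto orbits of the group action on states. `state_orbits()`
enumerates the orbits; `build_reduced_chain()` forms the quotient chain
$$P_{[x] \to [y]} = \sum_{z \in [y]} P_{x \to z},$$
and *always* verifies strong lumpability exactly — that the row sum onto
each target orbit is constant across the source orbit — raising an error
with the offending orbit otherwise. Passing a partition that does not come
from a symmetry group therefore fails loudly rather than silently producing
a non-Markov "chain".

The number of reduced states follows from Burnside's lemma: with $m$
alleles and a symmetry group of order $S$,
$$R = \frac{1}{S} \sum_{\sigma} m^{c(\sigma)},$$
where $c(\sigma)$ is the number of cycles of $\sigma$
(`count_reduced_states()`, `cycle_count()`). For rotations of an $n$-cycle,
$c = \gcd(n, j)$, which yields the classical binary-necklace count for the
directed cycle (`count_directed_cycle()`). The group order alone bounds $R$:

$$\max\!\left(n + 1,\; 2 + \frac{2^n - 2}{S}\right) \;\le\; R \;\le\; 2 + \frac{1}{S} \sum_{k=1}^{n-1} \binom{n}{k} \gcd\!\big(S,\, k!\,(n-k)!\big),$$

computed exactly by `state_count_bounds()`. Both bounds collapse to $n + 1$
when $S = n!$ and to $2^n$ when $S = 1$.

```{r reduce}
p <- make_model("star_moran_db", n = 5)
g <- symmetry_group(p)
g$order                                     # (n-1)! = 24
count_reduced_states(g)                     # 2n = 10 reduced states, not 32
state_count_bounds(5, g$order)
```

## The fixation axiom

Deciding the fixation axiom is a synchronizing-word problem: let $D$ be the
set of parentage maps available with positive probability in *every* state
(`always_possible_maps()`). The axiom holds if and only if some finite
composition of maps in $D$ is constant. `check_fixation_axiom()` decides
this by the standard pair-merging criterion — a constant composite exists
exactly when every pair of sites can be merged by some composite — using
breadth-first search on site pairs. A positive answer returns a **witness**
(a concrete map sequence whose composition is constant), re-verified by
explicit composition before return; a negative answer returns a
**certificate**, a pair of sites no composite can merge. An exhaustive
semigroup-closure oracle (`composite_map_closure()`) is kept alongside for
independent verification in the tests.

```{r axiom}
ax <- check_fixation_axiom(make_model("directed_cycle_moran", n = 5))
ax$holds
length(ax$witness$map_sequence)   # maps composing to a constant map
```

## Consequences for evolutionary quantities

Because symmetries preserve transition probabilities, all derived
quantities are orbit-constant: single-mutant fixation probabilities agree
across sites in one site orbit, and the stationary distribution of a
mutation-carrying process satisfies $\pi(x) = \pi(x\sigma)$.

```{r consequences}
p <- make_model("star_moran_db", n = 4)
rho <- fixation_probabilities(p)$rho
rho[sapply(1:4, function(g) state_index(replace(rep(0, 4), g, 1)))]
```

The hub value differs from the (equal) leaf values, mirroring the site
orbits $\{1\}, \{2, 3, 4\}$.

## Worked example: a cycle population

```{r worked}
p <- make_model("undirected_cycle_moran", n = 6)
analyze_process(p)
```

## Scope and limitations

* Full chains are built for $n \le 12$; brute-force group detection for
  $n \le 8$ (use generators beyond that); Wright-Fisher supports enumerate
  all $n^n$ parentage maps and are capped at $n \le 6$.
* Linear solves are double precision (see "Exact arithmetic" above);
  everything combinatorial is exact.
* For the well-mixed diploid family (blocks of size 2), the reduced-state
  count reported is the Burnside/brute-force value, which for $N$
  individuals equals $(N+1)(N+2)/2$ — the number of unordered multisets of
  the three genotypes $00$, $01$, $11$ (e.g. 6 orbits for two diploid
  individuals).
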