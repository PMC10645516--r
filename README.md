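# selsym

Symmetry analysis and state-space reduction for finite models of natural
selection.

## The problem

A finite population is a set of genetic **sites** $G = \{1,\dots,n\}$, each
housing one allele (0 or 1). One step of evolution samples, from a
state-dependent distribution $p_x$, a **parentage map** $\alpha$ (site $g$
copies its next allele from site $\alpha(g)$) and a **mutation set** $U$
(sites whose inherited allele flips):

$$x'_g = \begin{cases} x_{\alpha(g)} & g \notin U \\ 1 - x_{\alpha(g)} & g \in U. \end{cases}$$

This induces a Markov chain on the $2^n$ population states that subsumes the
Moran and Wright–Fisher models, evolution on weighted graphs, and
class/island structure. The chain is exponentially large, but population
structure is usually symmetric: a permutation $\sigma$ of sites is a
**symmetry** when

$$p_x(\alpha, U) = p_{x\sigma}\big(\sigma^{-1}\!\circ\alpha\circ\sigma,\ \sigma^{-1}(U)\big) \quad \text{for all } x, \alpha, U.$$

Symmetries preserve transition probabilities, so the chain can be lumped
exactly onto orbits of the symmetry group — often collapsing $2^n$ states to
a handful. `selsym` provides the whole pipeline with exact rational
arithmetic:

- **Processes**: built-in constructors (`make_model()`) for well-mixed
  Moran/Wright–Fisher, graph Moran (birth–death and death–birth; cycles,
  stars, arbitrary weighted graphs), class- and island-structured
  populations, plus explicit event tables and JSON/YAML configs
  (`read_model_spec()`).
- **Chains**: exact transition matrices (`build_chain()`), fixation
  probabilities, stationary distributions.
- **Symmetries**: the definition test (`is_symmetry()`), full-group
  detection or generator closure (`symmetry_group()`), site orbits,
  exact transition-preservation verification, named structure groups
  (`make_structure_group()`).
- **Reduction**: state orbits, the lumped chain with a mandatory exact
  lumpability check (`build_reduced_chain()`), Burnside orbit counts
  (`count_reduced_states()`, `count_directed_cycle()`), and exact
  group-order bounds on the reduced state count (`state_count_bounds()`).
- **Fixation axiom**: decision via the synchronizing-word criterion with a
  re-verifiable witness or an unmergeable-pair certificate
  (`check_fixation_axiom()`).
- **Fixtures**: group-averaging (`symmetrize_process()`) and reproducible
  random processes (`random_process()`).

## Worked example

A Moran process on the undirected 6-cycle:

```r
library(selsym)
p <- make_model("undirected_cycle_moran", n = 6)
analyze_process(p)
```

```
== selection process analysis ==
model: undirected_cycle_moran  n = 6  arithmetic: exact 
symmetry group order: 12 
sample elements: (1)(2 6)(3 5)(4)  (1 2)(3 6)(4 5)  (1 2 3 4 5 6)  (1 3)(2)(4 6)(5) 
site orbits: {1 2 3 4 5 6} (transitive) 
reduced states R = 13 of 64 ; bounds 43/6 <= R <= 64 (hold) 
transition preservation: verified ; lumpability: verified
fixation axiom: holds (witness: 5 maps onto site 6)
single-mutant fixation probabilities: 0.166667 0.166667 0.166667 0.166667 0.166667 0.166667 
```

The detected group is the dihedral group of the hexagon (order $2n = 12$);
the 64-state chain lumps to 13 binary-necklace states; and by symmetry every
single mutant fixes with probability $1/n$.

Counting and bounding without building anything:

```r
count_reduced_states(make_structure_group("star", 5))   # 10  (= 2n)
count_directed_cycle(7)                                  # 20  (= 2 + (2^7-2)/7)
state_count_bounds(5, 24)
```

```
reduced-state bounds for n = 5 , S = 24 :  6 <= R <= 22 
```

Deciding the fixation axiom with a verifiable witness:

```r
ax <- check_fixation_axiom(make_model("directed_cycle_moran", n = 4))
ax$witness
```

```
$target_site
[1] 3

$map_sequence
$map_sequence[[1]]
[1] 1 2 3 3
...
```

Composing the witness maps (temporal order, ancestry read left to right)
gives the constant map onto site 3 — every site's allele descends from
site 3.

See the vignette (`vignettes/selsym-methods.Rmd`) for the model
conventions, the exact-arithmetic design, and the mathematics behind the
reduction and the bounds.

## Command line

A thin CLI wraps the exported functions:

```sh
Rscript inst/cli/selsym.R report --spec model.yaml
Rscript inst/cli/selsym.R count --spec model.yaml
Rscript inst/cli/selsym.R check-axiom --spec model.yaml --out witness.json
```
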