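---
title: "Module contribution scoring on targets–(pathways)–targets networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module contribution scoring on targets–(pathways)–targets networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tptnet)
```

## The model

`tptnet` analyses interventions that hit many protein targets at once. Its
input is a bipartite annotation of targets to pathways plus a table linking
pathways to diseases; everything else is derived.

**Network.** The one-mode projection of the annotation is the
targets–(pathways)–targets (TPT) network: targets are nodes, and an edge
joins two targets annotated to at least one common pathway. Edges remember
the shared pathway set; the edge weight is its size. The projection is a
deterministic function of the annotation (idempotent, order-independent),
and targets that share no pathway with anyone remain as isolated nodes so
that the later normalisations stay exact.

**Modules.** The network is partitioned by Louvain modularity optimisation.
The underlying hypothesis is functional: targets that cluster together
through shared pathways are likelier to act together, so modules — not
individual targets — are the unit of therapeutic attribution.

**Contribution scores.** Let $u(p)$ be the number of modules with at least
one member annotated to pathway $p$, and $v(d)$ the number of pathways
linked to disease $d$. Each pathway splits its unit of support equally over
its incident modules ($1/u$ each), and each disease splits its unit equally
over its supporting pathways ($1/v$ each). The contribution score of module
$m$ toward disease $d$ is

$$\mathrm{CS}(m, d) \;=\; \sum_{p \,\in\, X(m,d)} \frac{1}{u(p)}\,\frac{1}{v(d)},$$

where $X(m,d)$ is the set of pathways relevant to both. Because every
covered pathway's module shares sum to one, $\sum_m \mathrm{CS}(m,d) = 1$
for every disease whose supporting pathways all appear in the network —
the conservation property the test suite checks to $10^{-12}$ on the
worked example and on batches of random instances.

Module–pathway incidence is defined through *membership* ("at least one
member target annotated to $p$"), not through intra-module edges. The two
definitions differ exactly when a pathway's members sit in different
modules with no internal edge; membership is the definition under which a
two-module pathway credits both modules, which is what the scoring
algorithm requires.

**Validation.** The module × disease association is tested with Pearson's
chi-square. A contingency table needs counts, so the default (and only
built-in) builder uses the integer pathway-link counts $|X(m,d)|$ rather
than the real-valued CS matrix; the builder argument keeps this choice
explicit and replaceable. Yates continuity correction is off by default
and only ever applies to 2×2 tables; uncorrected Pearson is the common
default for larger tables. A parallel validation counts, per module and
ATC level-1 drug class, the distinct network targets bound by approved
drugs of that class; a target with drugs in several classes counts once in
each class, since the class tallies are reported independently.

**Target importance.** Inside the selected module each target's degree,
betweenness, closeness and eigenvector centralities are normalised by the
module-wide maximum and averaged:

$$\mathrm{TI}_i = \frac{1}{4}\left(\frac{DC_i}{\max DC} +
\frac{BC_i}{\max BC} + \frac{CC_i}{\max CC} +
\frac{EC_i}{\max EC}\right).$$

$\mathrm{TI} \in [0,1]$, with 1 attained exactly by a target maximal in
all four. The top `top_fraction` of the ranking (ceiling semantics, so 10%
of 199 targets selects 20) is recommended for follow-up, with predicted
compounds attached when a compound–target table is supplied.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `resolution` | 1.0 | Louvain resolution; 1.0 is plain modularity. |
| `random_seed` | 1 | Drives the Louvain node-visit order (and simulation). |
| `fdr_threshold` | 0.01 | Benjamini–Hochberg cutoff of the optional over-representation filter. |
| `top_fraction` | 0.1 | Fraction of ranked targets selected, by ceiling. |
| `edge_weighting` | `shared_pathway_count` | Louvain edge weights; `unweighted` ignores multiplicity. |
| `centrality_scope` | `module_subgraph` | Graph on which centralities are computed. |

Two of these encode genuinely open design choices:

* **Edge weighting.** Whether module detection should count shared-pathway
  multiplicity is not determined by the model; weighted detection is the
  default because the multiplicity is real signal (two targets sharing
  five pathways are more strongly tied than two sharing one), and an
  unweighted mode is provided for sensitivity analysis.
* **Centrality scope.** TI normalises by the maximum *within the module*,
  which is well defined whether the raw centralities come from the
  module-induced subgraph or the full network. The default is the module
  subgraph — the ranking is meant to order targets by their role inside
  the therapeutic module — but `full_network` is available, and the two
  modes genuinely differ for targets that bridge modules.

## The over-representation stage

The enrichment filter is a standard one-sided hypergeometric
over-representation test (upper tail: probability of an overlap at least
as large as observed), Benjamini–Hochberg corrected across tested
pathways. The background universe defaults to the targets of the supplied
universe annotation, because a genome-scale background is an input, not
something the package can conjure; `universe_size` can widen it. The stage
is optional — a pre-filtered annotation can be supplied directly, and the
pipeline only runs enrichment when a universe annotation is given. Tests
verify the p-values against exhaustive enumeration of all possible query
draws on small universes.

## Numerical and degenerate-case choices

* **Eigenvector centrality** is computed by power iteration on $A + I$
  (the diagonal shift preserves eigenvectors and prevents the sign
  oscillation a bipartite spectrum would cause), from a uniform start
  vector, to a max-norm tolerance of $10^{-8}$ within 1000 iterations,
  scaled to maximum 1. The fixed start keeps repeated runs bit-identical —
  a requirement for byte-identical pipeline outputs that randomly started
  Krylov solvers do not meet — and the result is cross-checked against an
  independent eigensolver in the tests. Non-convergence raises an error
  reporting the residual.
* **Closeness** is the inverse *mean* shortest-path distance to the other
  members of the node's connected component, 0 for isolated nodes. This
  keeps the quantity comparable across components of a disconnected
  module subgraph.
* **Zero-maximum centralities** (e.g. betweenness in a clique) contribute
  0 to TI for every node while the averaging denominator stays 4, so TI
  remains defined on degenerate modules; a clique's members all get
  TI = 3/4.
* **Ties** are broken lexicographically everywhere (enrichment rows by
  pathway id at equal p, ranking rows by target id at equal TI, module
  selection by smallest module id at equal mean CS), so all outputs are
  reproducible orderings.
* **Module ids** are canonicalised to consecutive integers by decreasing
  size, ties by the lexicographically smallest member, making partitions
  comparable across runs and seeds.
* **Uncovered inputs** degrade softly with warnings: pathways annotating
  only targets absent from the network get $u = 0$ and are excluded from
  scoring; diseases whose pathways are all uncovered are dropped; empty
  tables yield empty results rather than crashes, except where the result
  would be meaningless (empty query, single-target module, degenerate
  contingency table), which raise typed errors.

## The synthetic generator

`generate_planted()` emulates the structure the method assumes: groups of
targets tied together by group-private pathways (the first private pathway
of each module annotates all of its targets, guaranteeing internal
connectivity and full coverage; the rest annotate random subsets of at
least two), a controllable rate of cross-module pathways (two random
targets from each of two random modules), and diseases linked to the
private pathways of a designated owner module with probability
`propensity`. The bundled 24-target worked example (`fig7_fixture()`) is
the deterministic special case with three groups of 9/8/7 targets and five
pathways whose module incidences are (1, 1, 2, 2, 3).

What the generator does *not* emulate: annotation noise (false
target–pathway links), heavy-tailed pathway sizes, overlapping or nested
pathway memberships, and the strong degree heterogeneity of real
interactomes. Passing tests therefore demonstrate the correctness of the
algorithmic machinery and its statistical behaviour under clean planted
structure, not robustness to annotation error in real databases.

Test and acceptance problem sizes are deliberately modest — instances of
2–5 modules with 6–20 targets each, batches of 50–100 seeds — which is
where the planted structure is informative and brute-force oracles
(exhaustive hypergeometric enumeration, triple-loop score recomputation,
single-move local-optimality checks of the planted partition) remain
exact.

## Limitations

* The CS of a module is driven entirely by pathway–disease co-annotation;
  it inherits whatever biases the annotation sources carry and cannot see
  direction of effect (activation vs inhibition).
* Louvain is a heuristic: on ambiguous networks different seeds can give
  different partitions. The seed is part of the configuration and the run
  manifest precisely so that this is visible; the planted-recovery tests
  quantify behaviour only under clear modular structure.
* Chi-square validity requires adequate expected counts; with few pathways
  per module–disease cell the test is reported but should be read with the
  usual small-count caution.
* Identifiers are opaque case-sensitive strings; no cross-namespace
  mapping (gene symbol vs UniProt) is attempted.
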