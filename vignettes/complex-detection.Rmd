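---
title: "GO-informed multi-objective detection of protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GO-informed multi-objective detection of protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`complexGO` detects protein complexes in a protein–protein interaction
(PPI) network by evolving network partitions under two conflicting
objectives that are computed from Gene Ontology (GO) semantics rather
than from topology. This vignette is the package's account of the method:
the model and its assumptions, the parameters that matter, the numerical
conventions, the design choices we made where the design was genuinely
open, and what the bundled synthetic benchmarks do and do not demonstrate.

## 1. The semantic model

### Term-level similarity

The GO is a set of directed acyclic graphs whose edges carry typed
relations. For a term $A$ we extract its ancestor subgraph
$DAG_A = (A, T_A, E_A)$: the term, all ancestors reachable through
`is_a`, `part_of` or `regulates` edges, and the relations induced among
them (`ancestor_dag()`). Each member $t$ receives a *semantic
contribution*: $S_A(A) = 1$, every ontology root scores 0, and any other
ancestor scores the maximum product of edge weights along a path from the
focus,

$$S_A(t) = \max\{\, W_e \cdot S_A(t') : t' \in \mathrm{children}(t)
\text{ within } DAG_A \,\},$$

with attenuation weights $W_e$ of 0.8 (`is_a`), 0.6 (`part_of`) and 0.7
(`regulates`). Zeroing the root encodes the view that sharing only the
ontology root carries no information. Two clause-precedence corners are
fixed deliberately:

* when the focus itself is a root, the focus clause wins ($S = 1$), which
  is what makes the self-similarity identity $SS(A,A) = 1$ hold;
* with multiple roots in $T_A$, each one scores 0.

The *semantic value* is $SV(A) = \sum_{t \in T_A} S_A(t) \ge 1$, and two
terms compare as

$$SS(A,B) = \frac{\sum_{t \in T_A \cap T_B} \big(S_A(t) + S_B(t)\big)}
{SV(A) + SV(B)},$$

which is symmetric, lies in $[0,1]$, equals 1 at identity and 0 when the
ancestor sets are disjoint (terms from different GO aspects, for
instance). Only ancestors enter the model; shared *descendants* are not
considered. Since ancestor-DAG extraction dominates the cost, all
DAGs, contributions and pair values are memoized per ontology and weight
vector (`ss_source()`); the cache must be rebuilt if the weights change.

### Protein-level similarity

A protein's annotation set is the union of its terms over the three GO
aspects; annotations with a `NOT` qualifier are skipped at load and terms
missing from the ontology are dropped with a warning. Two proteins
compare by the best-match average,

$$FS_{BMA}(P_1,P_2) = \frac{\sum_{A \in \mathcal{T}_{P_1}} \max_B SS(A,B)
+ \sum_{B \in \mathcal{T}_{P_2}} \max_A SS(A,B)}
{|\mathcal{T}_{P_1}| + |\mathcal{T}_{P_2}|},$$

precomputed once for all pairs into the symmetric matrix
$\mathbf{FS}_{BMA}$ (`build_fs_matrix()`). Proteins without usable
annotations get all-zero rows and columns *including the diagonal*: zero
is the conservative no-evidence value, and making the convention total
keeps every downstream formula finite. By default the three aspects are
pooled; no slim reduction or information-content weighting is performed.

## 2. The objectives

For a partition $\mathcal{C} = \{C_1,\dots,C_K\}$ let
$\mathrm{IS}_{\mathrm{Intra}}(v)$ be the summed similarity of protein $v$
to the other members of its complex and $\mathrm{IS}_{\mathrm{Inter}}(v)$
its summed similarity to everything outside. Both objectives are
minimized.

**Compactness.**
$$\mathrm{ICS}_{\mathrm{Intra}}(\mathcal{C}) = \sum_{k=1}^{K}
\left( \frac{|C_k|^2 - (V_k + R_k)}{|C_k|} + D_k \right)$$
where $V_k = \sum_{v \in C_k} \mathrm{IS}_{\mathrm{Intra}}(v)$ is the
complex's semantic volume, $R_k$ adds
$\mathrm{IS}_{\mathrm{Intra}}/(\mathrm{IS}_{\mathrm{Intra}} +
\mathrm{IS}_{\mathrm{Inter}})$ for every member whose intra similarity
strictly dominates, and $D_k$ is the cohesiveness penalty: the sum of
semantic distances $1 - FS_{BMA}$ over unordered member pairs, divided by
$|C_k|$. A fully similar pair collapses its bracket to exactly 0; an
all-singleton partition with zero similarity scores $n$.

**Separation.**
$$\mathrm{ICS}_{\mathrm{Inter}}(\mathcal{C}) = K \cdot \sum_{i=1}^{K}
\left( \frac{\sum_{v \in C_i}
\mathrm{IS}_{\mathrm{Inter}}(v)/\mathrm{IS}_{\mathrm{Intra}}(v)}{|C_i|}
+ \mathrm{weak}_i \right)$$
where $\mathrm{weak}_i$ counts members whose inter-complex similarity
strictly exceeds their intra-complex similarity. The outer factor $K$ is
kept literally as stated, so fragmentation is penalized super-linearly.

Three reconstruction choices deserve flagging, each isolated behind one
function for easy substitution:

* the semantic volume $V_k$ is defined as the summed intra similarity of
  the members — the semantic analogue of the volume term in topological
  community-score models;
* the semantic distance is $1 - FS_{BMA}$, the natural dual of the
  similarity matrix already in scope, with distance 0 to self;
* zero-division conventions: a ratio with numerator and denominator both
  0 is 0, and $\mathrm{IS}_{\mathrm{Intra}} = 0 <
  \mathrm{IS}_{\mathrm{Inter}}$ yields
  $\mathrm{IS}_{\mathrm{Inter}}/\varepsilon$ with $\varepsilon = 10^{-6}$
  — a large but finite penalty (configurable via the `eps` arguments).

Both objectives are checked in the test suite against a naive
per-definition implementation on *every* set partition of up to seven
proteins.

## 3. Representation and operators

**Chromosomes.** Locus-based adjacency: gene $i$ holds the index of a
network neighbour of protein $P_i$; the complexes are the connected
components of the locus–allele graph (`decode()`). Feasibility — every
allele a true neighbour — is closed under all operators, so no repair
step exists. Isolated proteins carry a self-sentinel allele and always
decode to singletons.

**Crossover.** Canonical uniform crossover: with probability $p_c$ the
child takes, per gene, parent 1's allele when the per-gene uniform draw
is at most 0.5 and parent 2's otherwise; with probability $1 - p_c$ it
copies parent 1.

**FS-PTO mutation.** The chromosome is decoded once, then proteins are
scanned in ascending index order. For each protein we compare
$F_{\mathrm{Intra}}$ (summed similarity to its current complex) with
$F_{\mathrm{Inter}}$ for every other complex, under the *current working
membership* — moves take effect immediately, so the operator has
sequential semantics and a single pass per application. A weak protein
(best $F_{\mathrm{Inter}} > F_{\mathrm{Intra}}$) moves to the arg-max
complex when its personal uniform draw is at most $p_m$; the gate is
per-protein, not per-chromosome. The genotype realization re-points the
protein's allele to its highest-similarity network neighbour *inside the
target complex*; if the target contains no neighbour of the protein the
move is skipped, preserving feasibility. Ties (equal $F_{\mathrm{Inter}}$,
equal neighbour similarity) break toward the smallest index. A
consequence of the sequential semantics worth knowing: once a protein has
moved, proteins that pointed at it may legitimately follow in the same
pass.

**Driver.** MOEA/D with $\mu$ scalar subproblems, uniformly spread
two-objective weight vectors, Tchebycheff scalarization with a maintained
ideal point, mating restricted to each subproblem's $T$-neighbourhood,
neighbourhood replacement on improvement, and an unbounded external
archive of nondominated solutions. These internals are the canonical
decomposition defaults; the framework itself does not prescribe them.
Exactly $\mu \times \mathrm{generations}$ offspring evaluations are
performed. One clustering is reported per run by a knee-point proxy:
min–max normalize both objectives over the archive and take the smallest
sum, ties broken lexicographically (`select_solution()`). This selection
step is deliberately simple plumbing — the archive itself is the
method's result.

## 4. Parameters

| Parameter | Default | Meaning |
|---|---|---|
| $\mu$ | 100 | population size = number of subproblems |
| generations | 100 | $\mu \times$ generations $= 10{,}000$ evaluations |
| $p_c$ | 0.8 | uniform crossover probability |
| $p_m$ | 0.2 | FS-PTO per-protein move probability |
| $T$ | 20 | neighbourhood size (capped at $\mu$) |
| runs | 30 | independent runs averaged by the pipeline |
| $W_e$ | 0.8 / 0.6 / 0.7 | `is_a` / `part_of` / `regulates` weights |
| $\varepsilon$ | $10^{-6}$ | zero-intra ratio guard |
| $\delta$ | 0.2 | Jaccard matching threshold |

All dimensionless. Evaluation averages recall, precision and F-score
arithmetically across runs; the F-score is averaged per run, **not**
recomputed from averaged recall and precision (the two differ on
asymmetric inputs, which is why a reported mean F is generally not the
harmonic mean of the reported means).

## 5. Evaluation and the noise protocol

Matching is many-to-many: a reference complex is recovered if *some*
predicted complex reaches Jaccard $\delta$, and a predicted complex is
correct if it matches *some* reference complex; no bijective assignment
is imposed. Reference complexes are first restricted to the proteins of
the analyzed network (complexes emptied by restriction are dropped with a
message), since a method cannot be penalized for proteins it never saw.
Raising $\delta$ can only lower recall and precision; the suite tests
this monotonicity.

`perturb()` alters exactly $\mathrm{round}(p \cdot m)$ edges. Degree
targeting anchors each single alteration at the currently
highest-(lowest-)degree protein, ties broken by identifier order, with
the partner drawn uniformly among non-neighbours (for additions) or the
removed edge drawn uniformly among incident edges (for deletions).
Degrees are re-evaluated after every alteration — dynamic rather than
frozen ranking; the frozen variant is a defensible alternative, but
dynamic targeting lets pendant-protein counts drift the way degree-ranked
noise does in practice. Deletions may isolate proteins; they stay in the
vertex set so $n$ is constant across noise levels. Replicate $r$ of a
treatment reseeds with `seed + r - 1`, and identical specifications give
byte-identical edge lists.

## 6. The synthetic benchmark generator

`generate_planted()` produces a self-contained bundle: a
planted-partition graph (per-complex random spanning tree for guaranteed
intra connectivity, then Bernoulli intra edges at `p_in` and inter edges
at `p_out`), a balanced tree ontology with one top-level branch per
complex, per-protein annotations drawn from the home branch with
probability `coherence` (otherwise from a random other branch), and the
planted complexes as the truth catalog. Defaults: 4 complexes of 8
proteins, `p_in = 0.6`, `p_out = 0.02`, `coherence = 0.9`, ontology depth
3 and branching 3, 3 annotation draws per protein, no unannotated
proteins. Depth and branching are the smallest values that give each
branch enough leaves (9) for within-complex annotation diversity while
keeping sibling-leaf similarity well above zero; 3 draws per protein
mirrors the handful of specific annotations a typical curated protein
carries. A `multiparent` toggle adds random `part_of` cross-edges for
DAG (rather than tree) coverage, and an `unannotated_fraction` exercises
the zero-similarity convention.

What the generator emulates: block-structured interaction density,
catalog-style disjoint reference complexes, and annotations whose
intra-complex functional similarity statistically exceeds inter-complex
similarity (the test suite verifies the gap across seeds, and it is
exactly the assumption FS-PTO and the objectives exploit). What it does
**not** emulate: scale-free degree distributions, overlapping complexes,
aspect-heterogeneous or evidence-weighted annotations, and
information-content effects from annotation corpora. Passing on planted
fixtures therefore demonstrates correctness of the machinery and
recoverability under the stated assumption — not performance on curated
yeast data.

## 7. Problem sizes and reproducibility

The shipped tests and the acceptance script run at desk scale, a choice
made so the whole suite re-runs in well under an hour on one CPU: the
recovery check uses the default 32-protein fixture with $\mu = 40$ and 40
generations over ten seeds (the suite requires $F \ge 0.9$ at
$\delta = 0.2$ in at least nine of ten), oracle equivalence is exhaustive
over all 1,044 partitions of 4-, 6- and 7-element sets, and robustness
smoke tests use two-complex fixtures. Every stochastic component takes an
explicit integer seed: runs reseed as `seed + run - 1`, perturbation
replicates as `seed + replicate - 1`, so any table the pipeline emits is
reproducible byte-for-byte from its master seed.

## 8. Known limitations

* Partitions only: the representation decodes to disjoint complexes;
  overlapping complexes are out of scope.
* The semantic model uses ancestors only; methods that also credit shared
  descendants or annotation-corpus information content will rank some
  term pairs differently.
* FS-PTO's sequential pass is order-dependent by construction (ascending
  index); a different scan order can yield a different, equally valid
  local improvement.
* With many unannotated proteins the objectives lose signal (all-zero
  similarity rows), and detection quality degrades toward topology-blind
  behaviour; the package does not fall back to a topological objective.
* `run_robustness()` reuses the clean-network similarity matrix, which is
  correct (annotations are unaffected by topological noise) but means
  noise studies probe the search, not the semantics.
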