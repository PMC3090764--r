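---
title: "Exact minimum-recombinant phasing of two-site pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact minimum-recombinant phasing of two-site pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedphase2)
```

## The problem and its assumptions

A diploid member carries two haplotypes; genotyping reports only the
unordered allele pair per site. Given a pedigree in which **every member
is genotyped at exactly two biallelic SNP sites**, `pedphase2` finds a
haplotype configuration for all members that minimizes the total number
of recombination events (two-site MRHC), a problem that is NP-hard even
in this restricted form because pedigrees may be looped. The package
assumes:

* complete genotypes (no missing data) and no genotyping errors;
* two sites per member — multi-site pedigrees raise a parity-consistency
  problem between overlapping site pairs and are out of scope;
* biallelic markers (alleles 0/1; PED input codes them 1/2);
* arbitrary pedigree structure: loops, many spouses, spouses that are
  descendants, several families per parent are all supported. A child
  has either two recorded parents or none.

With two sites, at most one crossover per transmission is detectable: a
transmitted haplotype either equals a parental haplotype (cost 0) or is
the between-site recombinant of the parent's pair (cost 1).

## From pedigree to signed graph

Members are labelled from their genotypes: *green* (both sites
homozygous, equal values), *red* (both homozygous, different values),
*grey* (both heterozygous — phase unknown, green resolution {00, 11} or
red resolution {01, 10}), or *unlabeled* (exactly one heterozygous
site — the haplotype pair is unique and recombinations in the member's
own transmissions are undetectable).

The signed pedigree graph has one vertex per labelled member; a
**positive edge** joins each labelled parent–child pair (equal labels
unless the transmission recombines) and a **negative edge** joins the
two labelled parents of an unlabeled child (different labels unless a
transmission to that child recombines). For a full red/green colouring,
the *frustrated* edges — positive across the cut, negative within a
side — count the recombination events, and the minimum over colourings
(the line index) is the MRHC optimum. Parallel edges are kept: two
unlabeled children of the same couple are two independent potential
events.

Two forced-colour situations are resolved at construction time, both
consequences of transmissions that admit no alternative:

* **Doubly-homozygous parents.** A parent homozygous at both sites has
  two identical haplotypes, transmits one fixed haplotype, and no
  recombination in it is detectable; a grey child joined to it by a
  positive edge necessarily carries that haplotype and takes the
  parent's colour. The forcing does **not** cascade: a grey vertex
  coloured this way still has two distinct haplotypes, so its own
  children remain free. (Treating every coloured vertex as a forcing
  source is tempting but wrong — it can triple-count events that a
  single recombination in the middle generation explains; the
  brute-force oracle rejects that variant on six-member examples.)
* **Complementary unlabeled parent pairs.** If both parents of a grey
  child are unlabeled at *different* sites, the parent heterozygous only
  at site 1 can transmit only (x, a) and the other only (b, y), so the
  child's complementary pair must be {(b̄, a), (b, ā)} — green exactly
  when a ≠ b. These parents have no vertices, so no edge can carry the
  constraint; the child is coloured directly.

A third constraint involves no grey child at all: a trio with an
**unlabeled child** (heterozygous at site s), a **grey parent** p, and an
unlabeled co-parent q heterozygous at the *other* site. q's transmitted
allele at site s is fixed, so the haplotype p must pass to the child is
fully determined, and p avoids a recombination exactly when its phase
matches that haplotype's colour (green iff the child's and q's
homozygous-site values differ). These unary preferences are encoded as
positive edges from p to one of two shared resolved anchor vertices
(`.fgreen`/`.fred`). Both completions were found by exhaustive
comparison against the phasing oracle and are required for the graph
optimum to equal the MRHC optimum; without them the line index can
undercount. Each constraint consumes an unlabeled child, so the graph
still has at most n vertices and O(n) edges.

## Data reduction

`reduce_to_fixpoint()` shrinks (G, k) to (G′, k′) with a deterministic
worklist, recording every action in a replayable trace:

* forced-conflict check: resolved–resolved frustrated edges alone
  exceeding the budget give an immediate No;
* edge cleanups between two resolved vertices (frustrated edges charge
  1, satisfied edges are free);
* degree-0 and degree-1 grey deletions (colour chosen at replay:
  arbitrary = green by convention, or same/opposite of the neighbour);
* the degree-2 grey cases: deletion at the cost its configuration
  forces, merging into a positive-edge neighbour (the merged vertex
  inherits that neighbour's eventual colour), recolouring in place when
  a negative edge to a resolved vertex can simply be satisfied, and the
  replacement of a negative–negative path by a positive edge. When both
  degree-2 edges are parallel to a single neighbour the same logic
  specializes: equal signs are satisfiable for free, mixed signs
  frustrate exactly one edge;
* majority forcing: a grey vertex whose conflicts-if-red among resolved
  neighbours exceed half its total degree must be green (flipping it can
  only help, whatever the grey neighbours do), and symmetrically;
* budget forcing (decision mode only): a colour whose forced conflicts
  would exceed the remaining budget is excluded; if both colours are
  excluded the instance is a No. This rule is k-dependent and therefore
  disabled in pure optimization runs.

The reduced graph contains no grey vertex of degree below three. The
trace replays in reverse: merged vertices inherit their target's colour
and deleted vertices follow their recorded directive, so a colouring of
G′ extends to all of G with frustration exactly `spent + l(G′)` — the
test suite checks this identity against brute-force enumeration on
hundreds of random signed graphs.

What survives reduction are small balanced cores in which every grey
vertex keeps degree ≥ 3 — for instance two grey parents with three
unlabeled children (parallel negative edges) — plus resolved vertices
attached to them. Budget forcing at small k clears most of these, which
is why decision-mode reduction is so much stronger than pure
optimization-mode reduction on easy instances.

## Bipartization by edge removal and iterative compression

Three line-index-preserving transformations make the residue a standard
problem:

1. every positive edge (u, v) becomes two consecutive negative edges
   through a fresh grey vertex y adjacent only to u and v (if u and v
   agree, y goes opposite to both for free; if they disagree, one of the
   two new edges pays the cost the positive edge already paid);
2. all red vertices merge into one supernode and all green into
   another; both are relabelled grey and pinned to opposite sides by
   k + 1 parallel negative guard edges — a solution within budget k
   cannot afford to frustrate them all. A pure optimization run uses
   |E| + 1 guards, since no optimum exceeds |E|;
3. negating the weights reinterprets the all-negative graph as an
   unsigned multigraph in which a colouring's frustrated edges are its
   monochromatic edges, i.e. the minimum edge deletions that make the
   graph bipartite equal the line index.

`edge_bipartization()` solves the instance to optimality by iterative
compression: edges enter one at a time in sorted endpoint order; while
the current optimal set X stays valid nothing happens; otherwise
X′ = X ∪ {e} is compressed. Each X′ edge is replaced by three
consecutive edges (cycle parities are preserved and any smaller solution
is disjoint from the new X′, the middle edges); all valid side
assignments of the subdivision endpoints are enumerated with the first
edge's orientation fixed by colour symmetry (2^k′ partitions); for each,
a minimum edge cut between the two sides of G \ X′ is computed by BFS
augmenting-path max-flow on unit capacities, aborting once the flow
exceeds the budget. The best cut of size ≤ k′ replaces X. The overall
running time is O(2^k · n²) on these sparse graphs.

The recovered two-colouring maps back through every layer — subdivision
vertices and guards are dropped, supernode sides orient the red/green
interpretation, the reduction trace recolours deleted vertices — and the
frustrated edges of the *original* graph localize the events: a
frustrated positive edge charges the parent of its parent–child pair; a
frustrated negative edge charges, by convention, the father of the trio
that induced it. `count_recombinations()` recounts events directly from
the haplotypes (per trio, minimized over the two parental-origin
assignments) and always agrees with the frustration count.

## Decision and optimization

`mrhc_decide(ped, k)` runs the decision pipeline at budget k.
`mrhc_minimize(ped)` increments k starting from the forced-conflict
lower bound until the answer is Yes — in the fixed-parameter regime k is
small, so the incremental loop beats binary search in practice and
reuses the strongest (budget-dependent) reduction at every step. Ties
among optimal configurations are broken deterministically (sorted edge
processing, fixed merge targets, green-by-convention for unconstrained
vertices, paternal-first haplotype ordering), so identical inputs give
byte-identical outputs.

## The simulator

`simulate_pedigree()` emulates large, highly complex looped pedigrees:
growth is family by family; one parent is drawn uniformly from the
existing members (members accumulate many spouses), and with probability
`loop_rate` = 0.15 the partner is an existing member of the opposite
sex — possibly a blood relative or a descendant, which is what creates
cycles — otherwise a new external founder joins. Children per family are
1 + Poisson(1.33). Founder haplotypes are uniform over {00, 01, 10, 11},
which makes each site heterozygous with probability 1/2 and so labels
about half the members — the regime in which every reduction rule is
exercised. These defaults were calibrated once against the published
scale of such graphs (roughly n/2 vertices, 0.35n positive and 0.09n
negative edges at n = 1000) and not revisited. Recombination is either a
per-transmission rate or an exact planted count; planted events are
recorded as truth but are only an upper bound on the detectable optimum,
since a crossover in a parent with a shared allele can transmit a
haplotype the parent could also have passed intact.

What the simulator does **not** model: realistic demography, sex-biased
recombination rates, linkage-map distances, genotyping error, or missing
data. Passing tests on simulated pedigrees therefore demonstrate
correctness of the combinatorial method under its stated assumptions,
not robustness to real-data artefacts.

## The reduction-efficiency experiment

`scripts/acceptance.R` regenerates the kernelization experiment: 20
pedigrees with member counts spread evenly over 1000–10000, two sites,
recombination-free gene dropping, signed-graph construction, reduction
to fixpoint, and the mean percentages of vertices and edges eliminated.
The reduction runs in decision mode with budget k = 0: the data are
generated without recombination, so 0 is the known optimum and the k = 0
decision run — the first step of the incremental solve, with *all*
forcing rules active, including the budget-dependent one — is the
natural setting in which the full rule set applies. The same experiment
with budget-dependent forcing disabled leaves noticeably more residue,
because balanced degree-≥3 grey cores are irreducible without a budget
argument.

## Numerical and engineering choices

* Colour, sign, and budget arithmetic is exact integer arithmetic; there
  are no tolerances anywhere in the method.
* The working graph for reduction lives in an environment (vectors plus
  incidence lists), so each rule application costs O(degree); the
  10000-member experiment reduces in seconds.
* Max-flow uses unit-capacity BFS augmenting paths with an early abort
  at limit + 1 augmentations; cuts come from residual reachability.
* Brute-force oracles guard their input sizes (≤ 24 grey vertices,
  ≤ 24 vertices, ≤ 12 members) and fail loudly rather than truncate.
* All randomness flows through explicit integer seeds; a simulation is
  fully determined by its `sim_params()`.

## Known limitations

* Exactly two sites; files with more sites are rejected at parse time.
* No missing data or genotyping error handling — inconsistent trios
  abort with a diagnostic rather than being repaired.
* The reported configuration is one optimum among possibly many; the
  event *count* is canonical, the event *placement* follows the stated
  conventions (father-side attribution for negative edges).
* Runtime is exponential in k (the minimum number of recombinations),
  as expected for a fixed-parameter method; pedigrees requiring many
  recombination events are outside the intended regime.
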