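---
title: "Gene-order phylogenies and ancestral genome reconstruction with orderphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-order phylogenies and ancestral genome reconstruction with orderphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orderphy)
```

## The problem

Multi-chromosome eukaryotic genomes — the motivating case is the
Saccharomycetaceae yeasts — differ not only in sequence but in gene
*order*: inversions, translocations, chromosome fusions and fissions
rearrange genes, while deletions, insertions, duplications and
whole-genome duplication (WGD) change gene content.  `orderphy` treats
these genome-level events as the phylogenetic signal.  Each genome is a
set of linear chromosomes, each chromosome an ordered list of signed
gene-family identifiers (the sign is the strand).  Every gene has two
extremities, a head (5') and a tail (3'); two consecutive genes define a
*gene adjacency*, an unordered pair of extremities.  The gene order
`{1, -2, 3, 4}` carries the adjacencies `{1t,2t}, {2h,3h}, {3t,4h}`.

Gene content and gene adjacencies become binary presence/absence
characters over the taxa (`encode()`).  Duplicated genes remain binary
in the matrix — presence is 1 for any copy number — with copy numbers
of two or more kept in a side table.  Telomeric adjacencies are not
characters by default (they are tracked separately for assembly); the
`include_telomeres` flag exposes the alternative.

## The two-state evolutionary model

Characters evolve on the tree under an asymmetric two-state
continuous-time chain with loss rate $\lambda$ (present $\to$ absent)
and gain rate $\mu$ (absent $\to$ present):

$$P(1 \to 0; t) = \frac{\lambda}{\lambda+\mu}\left(1 - e^{-(\lambda+\mu)t}\right),
\qquad
P(0 \to 1; t) = \frac{\mu}{\lambda+\mu}\left(1 - e^{-(\lambda+\mu)t}\right).$$

The rate asymmetry comes from double-cut-and-join (DCJ) accounting of
rearrangement events: an event removes two of the roughly $n + C$
adjacencies a genome with $n$ genes and $C$ chromosomes carries, but
creates two out of $\binom{2n+2}{2}$ possible extremity pairings.  With
$E$ expected events, the per-adjacency loss probability is $2E/(n+C)$
and the gain probability for a *specific* new adjacency is
$2E/\binom{2n+2}{2}$ (`adjacency_loss_prob()`, `adjacency_gain_prob()`).
Only the $\lambda/\mu$ ratio is identifiable once branch lengths are
free, so `model_params_from_genomes()` fixes $\lambda = 1$ (branch
lengths are then expected losses per present character) and sets
$\mu = (n+C)/\binom{2n+2}{2}$; the $E$ factor cancels from the ratio.
No among-character rate variation is modelled; per-class (adjacency vs
content) rates are exposed as an extension point but share the default.

`dcj_distance()` provides event counts between observed genomes through
the classical adjacency-graph formula $d = N - (c + i/2)$ with $N$
shared genes, $c$ cycles and $i$ odd paths.  Duplicates are first
reduced to one exemplar copy (first occurrence), the simplest
reproducible rule; the distance is computed on shared content, with
content differences reported separately by `event_breakdown()`.

## Tree inference

`infer_tree()` maximizes the pruning likelihood of the binary matrix:
a neighbour-joining start on Jaccard distances between presence rows,
then rounds of per-branch univariate optimization
(`optimize_branch_lengths()`, coordinate ascent with `stats::optimize`)
and nearest-neighbour-interchange hill climbing with
first-improvement acceptance in a fixed edge order, stopping when no
move gains more than $10^{-6}$ log units.  The chain is reversible, so
the likelihood is rooting-invariant and the search works on unrooted
binary trees.  `bootstrap_support()` resamples matrix columns with
replacement, re-infers each replicate, and reports bipartition
percentages, classified as strong (> 90), medium (60–90) or weak
(< 60).  A `write_phylip()` export lets users run an external ML
program instead and feed the result back as a guide tree.

Branch lengths of a user guide tree are re-optimized before
reconstruction, and the optimizer is unit-agnostic: guide trees may
carry lengths in arbitrary units (raw event counts, substitutions) or
none at all, and the saturated region of the transition function is a
flat surface where coordinate ascent cannot move.  One sweep is
therefore climbed both from the supplied lengths and from a neutral
0.5 per branch, and the better basin is pursued to convergence.  Each
sweep visits the edges in preorder with exact, incrementally updated
pruning messages, so a sweep costs one up-and-down pass over the tree.

## Ancestral reconstruction

For each internal node $a$ of the unrooted guide tree, the tree is
re-rooted at $a$ and the posterior of every character is computed by
Bayes' rule from the pruning partial likelihoods $p_a(s)$,

$$P(G_a = 1 \mid O_a) = \frac{f \, p_a(1)}{f \, p_a(1) + (1-f)\, p_a(0)},$$

where the product over subtrees runs over all three subtrees incident
to $a$, so every genome in the data set informs every ancestor
(`reconstruct_all()`; internally the re-rootings share one
message-passing sweep, which is algebraically identical).  A tree with
$n$ leaves yields $n-2$ ancestors.

Two priors $f$ are available.  The default is the empirical leaf
frequency of the character.  The pipeline, however, uses the
*stationary* prior $\mu/(\lambda+\mu)$: under heavy rearrangement the
likelihood ratio of "present at the root and repeatedly lost" against
"gained once on one internal branch" grows so large (gains are
$\sim 2n$ times rarer than losses) that with a leaf-frequency prior
essentially every character ever observed is promoted into every
ancestor.  The stationary prior encodes how unlikely a specific
adjacency is to exist at all and keeps the posterior calibrated — on
simulated data it removes thousands of false positives per ancestor at
a negligible cost in recall.  `select_content()` keeps families with
posterior strictly above the threshold (default 0.5; ties excluded).

A post-WGD ancestor is produced from its pre-WGD ancestor by the
explicit `double_genome()` operation (every chromosome copied); WGD is
never inferred implicitly.

## Chromosome assembly

Selected genes and adjacency posteriors become a travelling-salesman
instance (`build_tsp()`): each gene is a contracted node with a head
and a tail port, one cap node stands for chromosome ends, and joining
two extremities costs $-\log(\varepsilon + P)$ with $\varepsilon =
10^{-9}$ flooring unobserved pairs, so the minimum-cost Hamiltonian
cycle maximizes the product of adjacency posteriors.  `solve_tour()`
builds the tour by greedy edge matching — candidate adjacencies
accepted in decreasing posterior under port and subtour constraints,
leftover path ends joined greedily — then improves it with
candidate-guided 2-opt reversals and single-gene or-opt relocations
(plus plain exhaustive 2-opt/or-opt sweeps on small tours), optionally
chained through double-bridge perturbation restarts.  The cap travels
inside the cycle during improvement, so the solver, not a
post-processing step, decides which join the chromosome end absorbs.  Greedy
edge matching was chosen over nearest-neighbour construction because
the cost structure is an almost-flat floor plus a sparse set of cheap
candidate edges; matching commits to the cheap edges globally instead
of painting itself into corners path-front-first.  For instances of up
to a dozen genes an exact Held–Karp dynamic program over gene subsets
and entry ports is available (`method = "exact"`) and anchors the
correctness tests.

`split_into_chromosomes()` opens the cycle at the cap (placed where it
saves the most cost) and introduces further chromosome ends at
extremity positions ranked by a strict telomere priority: telomeric in
the parent and both children genomes; in both children; in any two of
the three; in the parent only; in one child — breaking ties toward
low-posterior adjacencies — until the chromosome count reaches the
median of the parent's and children's counts (overridable).  If
candidates run out, remaining cuts fall back to the lowest-posterior
adjacencies, with a message.  In the pipeline, ancestors are assembled
postorder so the two children handed to these rules are
already-assembled ancestors or observed leaves; the parent side, not
yet assembled, is represented by its nearest observed leaf through the
parent edge.  Output chromosomes are canonically oriented (first
family ID smaller than last) and sorted, making runs reproducible
byte-for-byte.

## The simulator and what passing tests mean

`evolve()` places a start genome (families $1..n$ split evenly over
the configured chromosomes) at an internal root of a random binary
topology and walks each edge, drawing events from the configured mix
until the accumulated number of *gene-adjacency changes* reaches a
per-edge budget drawn uniformly from the configured interval.  A
change is one element of the symmetric difference between the
telomere-inclusive adjacency sets before and after an event — e.g. a
mid-chromosome inversion removes two adjacencies and creates two, four
changes.  Defaults are the study conditions: 20 genomes, 5,000 genes,
8 chromosomes, budget $U[2750, 8250]$ per edge.  The event mix
(inversion 0.70, translocation 0.10, fusion 0.02, fission 0.02,
deletion 0.08, insertion 0.04, duplication 0.04) and the geometric
mean segment length of 5 genes are the package's own choices — fixed
once, documented here, and config-overridable — since no fitted yeast
event rates are published; inversion dominance and few-gene segment
scale are the consensus picture for close yeast relatives.  Every
event is logged with its parameters, so `replay_events()` reproduces
any node genome exactly, and realized per-edge changes become the true
branch lengths.

These conditions are deliberately harsh.  At the default budget the
per-edge churn is roughly half an adjacency-change per adjacency, so
adjacencies conserved across all twenty leaves are essentially absent,
and a sizeable fraction of true ancestral adjacencies leaves a trace
in at most one leaf — no method can recover those.  Passing the
simulation tests therefore demonstrates near-ceiling recovery of gene
*content* and recovery of adjacencies up to that information limit,
not a claim that adjacency reconstruction is near-perfect under
arbitrary rates.  Real data differ from the simulator in further ways
the tests cannot speak to: homology families come from an external
database and carry assignment errors, contigs fragment chromosomes
(inflating telomeres), and event rates vary across lineages.

## Evaluation metrics

`accuracy()` scores a reconstruction against a truth as the Jaccard
agreement $|G \cap G'| / |G \cup G'|$, separately for content (family
sets) and adjacencies (telomeres excluded), with false positives
($G \setminus G'$) and false negatives ($G' \setminus G$).
`non_split_adjacencies()` returns the adjacencies present in every
genome of a set.  `synteny_blocks()` finds maximal runs of two or more
single-copy genes with identical order and orientation (reversed,
sign-flipped runs count once, as reversed); no gaps are allowed, and
duplicated families are excluded as anchors.  `dotplot_coords()`
produces per-family cumulative coordinates for colinearity dot plots.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run the simulation
protocol at 1,000 genes with the per-edge budget scaled by the same
factor (to $U[550, 1650]$), which preserves the per-adjacency change
intensity of the full-size protocol — the quantity that governs
reconstruction difficulty — while keeping a complete multi-replicate
run in minutes on one CPU; the simulator's own defaults remain the
full-size conditions.  Other numerical choices: pruning messages are
rescaled per character with accumulated log factors (no underflow on
deep caterpillars); branch lengths are optimized on $[0, 50]$ with
`stats::optimize` tolerance $10^{-6}$; degenerate posteriors (prior 0
or 1 against a contradicting zero likelihood) return the prior; NNI
tie-breaks are first-improvement in a fixed deterministic edge order;
assembly, simulation and bootstrap draw all randomness from the
user-supplied seed.

## Known limitations

Ancestral reconstruction is marginal per character, not joint over
nodes; duplication-aware rearrangement distances (and genome halving
for post-WGD ancestors) are out of scope — duplicates are handled by
exemplar reduction and the explicit doubling operation; the ML search
is a local NNI hill climb and can in principle stop at a local
optimum, mitigated by the NJ start; and the TSP heuristic guarantees
no optimality bound, though it matches the exact optimum on nearly all
small random instances in the test suite.
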