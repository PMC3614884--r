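---
title: "Discovering between-pathway modules with bpmcut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering between-pathway modules with bpmcut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpmcut)
```

## The model

Quantitative genetic-interaction screens assign every measured gene pair
an epistasis score: negative when the double knockout is sicker than the
single knockouts predict, positive when it is healthier. Two pathways
that can substitute for each other leave a characteristic footprint —
aggravating (negative) interactions *between* the pathways' genes,
because losing one member of each wing removes both routes at once, and
alleviating or cohesive (positive) interactions *within* each wing. A
**between-pathway module (BPM)** is a pair of gene sets with exactly
that structure.

`bpmcut` treats the screen as a signed weighted graph and looks for
bipartitions that concentrate negative weight across the cut and
positive weight inside the sides, i.e. that minimize

$$\Phi(S) \;=\; \sum_{(u,v)\ \text{cross}} w(u,v)\;-\;\sum_{(u,v)\ \text{within}} w(u,v).$$

Globally minimizing $\Phi$ is intractable, and a single global cut would
in any case say little about the many local module pairs a genome
harbors. The algorithm therefore samples **local** optima: a partition
is a *LocalMaxCut* when no gene $v$ would lower $\Phi$ by switching
sides, i.e. its imbalance
$h(v) = \sum_{u \sim v,\ \text{same side}} w(u,v) - \sum_{u \sim v,\ \text{other side}} w(u,v)$
is non-negative (within tolerance). Flipping $v$ changes $\Phi$ by
exactly $2h(v)$, which is both the move rule and the termination
argument of the search.

From $M$ independent seeded random starts, each driven to a LocalMaxCut,
every gene $g$ defines a candidate BPM by *co-occurrence*: genes on
$g$'s side in at least a fraction $C$ of the $M$ partitions form module
1 (with $g$), genes on the opposite side at least $C$ of the time form
module 2. Genes with no stable allegiance to $g$ — the majority — join
neither. Candidates are then pruned by module size and by pairwise
Jaccard overlap of their flattened gene sets.

## Parameters

| parameter | default | meaning and guidance |
|---|---|---|
| `M` | 250 | random restarts. More restarts sharpen the co-occurrence fractions (binomial noise $\approx \sqrt{C(1-C)/M}$) and reduce run-to-run wobble; the output of two runs converges as `M` grows. Much smaller values make the fractions too noisy to threshold at `C`. |
| `C` | 0.9 | co-occurrence threshold, in (0.5, 1]. `C` ≤ 0.5 would let a gene enter both modules and is rejected. Lowering `C` (e.g. to 0.8) admits genes with weaker allegiance and typically yields more, larger BPMs. |
| `J` | 0.66 | maximum flattened Jaccard index between any two reported BPMs. |
| `min_size`, `max_size` | 3, 25 | inclusive bounds on each module. Size-1 or 2 modules are rarely interpretable; very large ones usually reflect a global cut rather than a module. |
| `eps` | 1e-9 | stability tolerance. The stability condition is stated with a strict inequality; with real-valued weights, exact ties and floating-point drift would make that ill-defined, so a gene moves only when $h(v) < -\varepsilon$. Every move then lowers $\Phi$ by at least $2\varepsilon$, guaranteeing termination. |
| weight transform | identity | SGA-type scores are used unchanged; for E-MAP-type scores the sign-retaining square $w \mapsto \mathrm{sign}(w)\,w^2$ stretches strong interactions relative to weak ones and speeds convergence. |
| enrichment `p_cutoff` | 0.05 | reported terms must have corrected $p$ at or below it. |
| simulations | auto | $\min(10000, \max(1000, \#\text{modules}))$; resampling estimates below ~1000 draws are too variable to trust. |

## Numerical and algorithmic choices

Where the procedure is under-specified, this package fixes it as
follows; other defensible choices could shift which local optimum an
individual start reaches, so they are part of the package's contract:

* **Move schedule.** Repeated full sweeps over the genes in a seeded
  random order (a fresh permutation per sweep), applying each flip
  immediately (asynchronous updates); a sweep without flips terminates.
  The sweep-order generator is a self-contained xorshift64\* stream, so
  results are identical across platforms and standard-library versions.
* **Seeds.** Restart $i$ (0-based) uses seed `base_seed + i` for both
  its random start and its sweep orders. This makes the ensemble a pure
  function of (`base_seed`, `M`), independent of how many worker
  processes compute it, and keeps all derived seeds in 32-bit range
  (checked).
* **Safety valve.** `max_sweeps` defaults to $10n$; exceeding it raises
  an error carrying the partial partition rather than returning a
  silently unstable result. With finite weights and $\varepsilon > 0$
  it is unreachable in practice.
* **Duplicate measurements.** A pair reported in both orientations is
  merged by averaging, with a warning — high-throughput matrices
  commonly contain both triangles. Self-pairs are dropped (the graph has
  no self-loops); blank or non-finite scores are dropped, not imputed.
* **Overlap pruning keep-rule.** Greedy over a canonical order —
  descending flattened size, ties by the byte-wise smallest generating
  gene — keeping a BPM iff its Jaccard with everything already kept is
  below `J`. Largest-first retains the most informative representative
  of an overlapping family and is deterministic. Two BPMs with identical
  gene sets from different generators are duplicates here.
* **Degenerate inputs.** A gene whose candidate has an empty opposite
  module contributes nothing (not an error); genes absent from the
  interaction table never enter the graph, so there are no zero-degree
  vertices.

## The enrichment stand-in

Enrichment services that correct by stochastic simulation are emulated
offline: each module is tested by the one-sided hypergeometric tail
$P(X \ge k)$ with population `|genespace|`, term size $K$ and draw size
$|module|$, and corrected against a null built by drawing
`n_simulations` random genespace subsets of the module's size and
recording each draw's *minimum* raw $p$ over all terms. The corrected
value $(1 + \#\{\text{draws with min-}p \le p_{\text{raw}}\}) /
(1 + n_{\text{sim}})$ is the add-one rank of the observation in that
null, which accounts for testing every term at once. Annotations are
taken as given — no GO-graph propagation. A remote enrichment client
would need exactly the inputs this package assembles — gene list per
module, genespace, p-value cutoff, simulation count — and would return
(term, p) pairs; only that request contract is specified here, and no
network code ships, so offline corrected p-values are *not* expected to
match any live service's numerically.

The genespace defaults to the genes of the interaction data itself:
screens measure a biased, pre-selected slice of the genome, and testing
against the whole genome would overstate significance of anything
characteristic of the slice.

## The synthetic benchmark — what it shows and what it does not

`generate_planted_table()` plants one or more pathway pairs (all
within-set edges at `within_weight` + noise, all between-set edges at
`between_weight` + noise) among background genes whose mutual pairs
carry pure $N(0, \sigma^2)$ noise edges with probability
`edge_density`. Defaults — one 5+5 pair at weights $\pm 1$, 40
background genes, noise sd 0.1, density 0.25 — emulate a small screen
with a single strong compensatory structure; density 0.25 reflects the
sparsity of a thresholded interaction matrix. `recovery_score()` grades
predictions side-awarely (module labels carry no meaning), as the mean
per-module Jaccard under the better of the two alignments.

Two honest limitations. First, background genes share no measured pair
with planted genes, so the planted signal is the only systematic
structure; in a real screen unrelated genes *do* share noisy
measurements with pathway genes, and any gene whose noise edges give it
a consistent net preference for one side will join a module at every
stable cut — real BPMs therefore carry hangers-on that this benchmark
by construction cannot produce. Second, the generator makes no attempt
to model E-MAP measurement error, batch structure, or the missing-value
patterns of real screens. Passing the recovery tests demonstrates that
the search, extraction and pruning machinery is correct, not that
module boundaries in real data will be clean.

Problem sizes throughout the test suite are chosen to keep the whole
suite fast while leaving the properties sharp: exhaustive stable-set
oracles run on graphs of at most 10 genes ($2^{n-1}$ enumerations),
ensembles in property checks use $M$ between 6 and 100, and the planted
recovery study uses 100 independent tables of 50 genes.

## Known limitations

* The search returns *local* optima by design; there is no guarantee of
  the globally optimal cut, and no annealing or restart strategy beyond
  the $M$ independent random starts.
* Results depend on the unspecified-by-the-model schedule choices above
  only through which local optimum each start reaches; ensembles are
  large enough that the extracted co-occurrence structure is robust, but
  single partitions should not be interpreted on their own.
* No significance score is attached to a BPM beyond GO enrichment;
  overlapping BPMs are pruned, never merged.
* Essential genes (absent from knockout screens) are invisible; the
  exclusion list can only remove further genes, not add missing ones.
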