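---
title: "Testing species-tree branches for polytomies with quartet frequencies"
author: "polyquart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing species-tree branches for polytomies with quartet frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The multi-species coalescent (MSC) describes how gene genealogies form
inside a species tree: within a species-tree branch carrying *k* gene
lineages, pairs coalesce at rate `choose(k, 2)` per coalescent unit (CU;
generations divided by the haploid population size). Its best-known
consequence concerns quartets. For an unrooted four-taxon species tree
`ab|cd` with internal branch length *x* CU, a gene tree matches the
species tree topology with probability `p1 = 1 - (2/3) exp(-x)` and each
alternative (`ac|bd`, `ad|bc`) with probability `(1/3) exp(-x)`. Three
facts drive everything in this package:

* `x = 0` makes all three topologies equally likely — a hard polytomy is
  indistinguishable from a bifurcation joined by a zero-length branch;
* `p1 >= 1/3` always, with equality only at `x = 0`;
* over `n` independent loci the topology counts `(n1, n2, n3)` are
  multinomial, so they concentrate: the chance of a frequency deviating
  from its mean by `eps` is at most `2*exp(-2*eps^2*n)`
  (`hoeffding_bound()`).

## The test

For each internal branch B of the species tree we pose the null
hypothesis that B has length zero. Operationally — and this is the
formulation that remains valid even when the MSC assumptions are doubtful
— the null states that the gene-tree quartets around B support the three
NNI-equivalent resolutions of B in equal numbers. With tallied frequencies
`(n1, n2, n3)`, `n = n1 + n2 + n3`, the goodness-of-fit statistic

```
chi2 = (n1 - n/3)^2/(n/3) + (n2 - n/3)^2/(n/3) + (n3 - n/3)^2/(n/3)
```

is asymptotically chi-squared with 2 degrees of freedom under the null;
`polytomy_pvalue()` is its upper tail, `exp(-chi2/2)` in closed form.

Three assumptions matter. (A1) *Locality*: all positive-length branches of
the given species tree are correct, so the internal branch of any quartet
around B, restricted to the species tree, has B's length. (A2) Gene trees
are an error-free random sample from the MSC. (A3) The chi-squared
approximation for three equiprobable outcomes is adequate only for
`n >= 10`; below that, results are flagged `applicable = FALSE` rather
than trusted (and `collapse_nonrejected()` treats them as non-rejections).
We deliberately keep df = 2 — counting each *gene* as one observation —
rather than treating the m quartets around a branch as independent
(df = 2m): quartets sharing lineages are strongly dependent, and the
liberal variant would inflate false positives.

### Aggregating quartets around a branch

A quartet around B takes one leaf from each of the four subtrees adjacent
to B (the two child subtrees; the sister subtree; the rest). Any single
such quartet gives a valid test (`method = "single"`), as does the
per-topology median across quartets of per-quartet gene counts
(`method = "median"`). The default (`method = "mean"`) lets each gene tree
*j* contribute the fraction `f[i,j] = n[i,j] / sum_i n[i,j]` of its
present, resolved quartets around B with topology *i*, and sums fractions
over genes. For complete binary gene trees this equals the mean over
quartets of per-quartet counts; with missing or unresolved quartets the
normalisation implicitly imputes them proportionally to the resolved ones.
A gene with *no* present resolved quartet around B is discarded for B, so
the effective number of genes is branch-specific (`effective_n` in all
outputs); A3 refers to this effective count.

The mean method is not merely convenient: averaging across many
(dependent) quartets shrinks the per-gene variance of the contribution
below that of a single Bernoulli quartet, making the test slightly
conservative under the null and more powerful under the alternative — a
behaviour visible in the calibration experiments below.

### Counting without enumerating

Enumerating all `|A||B||C||D|` quartets per gene is O(N^4). The package
instead counts displayed quartets by inclusion–exclusion over each gene
tree: an edge *e* "separates" a quartet when both of one pair lie on one
side and both of the other pair on the other side; the separating edges of
a displayed quartet form a path whose interior vertices see one pair
together in one adjacent component and the other pair together in another.
Summing edge separations and subtracting interior-vertex coincidences
therefore scores each displayed quartet exactly once, for any tree shape
(multifurcations included) and any pattern of missing taxa. All terms are
products of per-subtree membership counts obtained in one postorder pass,
so the per-gene cost is linear in tree size per branch. An explicit O(N^4)
enumerator (four-point condition on unit-length path distances) is kept in
the test suite as an independent oracle; the two agree to 1e-9 on trees
with missing taxa and polytomies.

## Parameters that matter

* `alpha` (default 0.05): the significance level used for the `rejected`
  column and for collapsing. Units: probability.
* `method` (default `"mean"`): quartet aggregation, see above.
* `correction` (default `"none"`): optional Bonferroni or
  Benjamini–Hochberg adjustment across applicable branches. Off by
  default: large-scale scans that do not target pre-specified hypotheses
  were the motivating use, and the unadjusted per-branch p-values remain
  the primary output.
* `threshold` in `contract_low_support()` (same scale as the gene trees'
  support values; "at or below" semantics): collapsing poorly supported
  gene-tree branches turns unreliable resolutions into polytomies, which
  the tallies then treat as uninformative rather than as signal. This can
  either help (noise removal) or hurt (effective n shrinks); there is no
  universally good threshold. Support scale (percent vs fraction) is
  auto-detected from the data; edges without support are never contracted.

## The simulator and what it does (not) emulate

`simulate_gene_trees()` draws genealogies exactly under the MSC, directly
in CU, for one haploid sample per species; multifurcating species-tree
nodes and zero-length branches both behave as simultaneous divergences.
Because the test consumes only topologies, and the topology distribution
is fully determined by CU lengths, no generation-level bookkeeping is
performed; `generations_to_cu()` converts at the boundary (e.g. the
12-taxon fixtures: 1.6 M generations over a population of 2e5 equals
8 CU).

The simulator emulates *true* gene trees: free recombination across loci,
no recombination within a locus, no estimation error, no duplication,
loss, or transfer. Consequently, passing calibration tests say nothing
about robustness to gene-tree estimation error, the dominant nuisance in
practice. `perturb_gene_trees()` offers a clearly labelled surrogate —
random NNI rearrangements at a configurable per-edge rate — which mimics
random mis-resolution but not the biased, signal-dependent structure of
real inference error.

`yule_species_tree()` generates species trees by the pure-birth process
conditioned on the taxon count, rescales them to an exact height in
generations, and converts to CU. One consequence of the exact-height
rescaling is that the nominal speciation rate cancels from the final
branch-length distribution (it only sets the pre-scaling time unit); the
parameter is retained for interface completeness, and variation in ILS
levels is obtained through the height (2.5, 10, or 50 CU in the built-in
experiment settings).

The 12-taxon fixtures (`s12_fixture()`) pin down only the features that
define the experiments: total height 8 CU; variant A with two 3-child
polytomies, a 0.2 CU branch (`P0`) and a 1 CU branch (`P3`); variant B
with one 5-child polytomy and a 2 CU branch (`P7`). The remaining branch
lengths are package constants chosen to keep all non-focal branches at
least 1 CU, so focal-branch behaviour is insensitive to them under true
gene trees.

## Numerical choices

* p-values use `pchisq(..., lower.tail = FALSE)`; the closed form
  `exp(-chi2/2)` is asserted in the tests to 1e-10.
* `min_genes_to_reject()` uses the closed-form ceiling
  `qchisq(1 - alpha, 2) / (2 (1 - exp(-x))^2)` with a one-step guard
  against boundary rounding; an upward-scanning oracle is kept in the
  tests. The required gene count grows as `1/x^2`: halving the branch
  length quadruples the requirement, asymptotically — the exact ratio is
  `((1 - e^-x) / (1 - e^(-x/2)))^2`, e.g. 3.90 at x = 0.05, 3.98 at
  x = 0.01, approaching 4 as x → 0.
* Fractions are accumulated in double precision; tallies are written with
  six significant digits. All-zero tallies (no informative gene) yield NA
  statistics rather than errors, so whole-tree runs never abort.
* Ties in `quartet_topology()` (all three pairings equidistant) mean the
  induced quartet is a star and are classified `unresolved`.
* The species tree is unrooted internally: a branch incident to the root
  of a rooted input merges with its counterpart, and every internal edge
  then has four non-empty sides. If an endpoint of an edge is itself a
  polytomy, its extra components are pooled into the corresponding far
  set, keeping the four sets disjoint while every sampled quartet still
  straddles the focal edge.
* In the gene-flow deviation model the middle term's exponent constant
  (the fixed network branch contribution) defaults to 4 and is exposed as
  `network_const`, since the printed source formula is typographically
  ambiguous; the implemented reading reduces exactly to the MSC at
  `lambda = 0` and reproduces the qualitative anomaly (an `x` where
  `p1 = 1/3`) for intermediate `lambda`.

## Problem sizes used in the checks

The built-in experiments are sized for a desktop run. Type-I calibration:
the variant-A fixture, 50 replicates × 1000 true gene trees, testing the
branch that arbitrarily resolves a 3-child polytomy — the rejection
fraction at `alpha = 0.05` stays within binomial noise of the nominal
level (the mean aggregation makes it mildly conservative). Power: 50-taxon
Yule trees at heights 2.5/10/50 CU, 1000 true gene trees per replicate,
all internal branches tested and pooled by true length; branches of
0.1–0.2 CU are rejected essentially always, branches of 0.05–0.15 CU
roughly nine times out of ten. The same quantities are recomputed from
scratch, at slightly larger replicate counts, by `scripts/acceptance.R`.

## Known limitations

* The test is only as meaningful as its assumptions: systematic deviations
  from the MSC (gene flow, homology errors, biased gene-tree error) shift
  quartet frequencies in ways the null does not model. `skewed_probs()`
  and `gene_flow_probs()` quantify two such regimes — notably, gene flow
  can make combined frequencies exactly uniform on a *binary* network,
  which no frequency-based test can tell apart from a polytomy.
* Failing to reject is never evidence *for* a polytomy; it may only
  reflect insufficient effective n for the branch length at hand
  (`min_genes_to_reject()` gives the ballpark requirement).
* One haploid sample per species; multi-individual sampling is not
  modelled.
* The median aggregation enumerates all quartets and is limited to small
  trees; it exists to validate the mean approximation, not for production
  use.
* Newick is the only supported format; nexus input should be converted
  upstream.
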