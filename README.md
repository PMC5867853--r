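# polyquart

Quartet-frequency polytomy tests for phylogenetic species trees.

## The problem

Species trees are almost always drawn as bifurcating, but some
relationships may be genuinely unresolved — either because several
lineages diverged (nearly) simultaneously (a *hard* polytomy) or because
the data at hand cannot distinguish a short branch from a zero-length one
(a *soft* polytomy). Whether a branch of a species tree should be replaced
by a polytomy cannot be decided from a single alignment: gene trees
legitimately disagree with the species tree through incomplete lineage
sorting (ILS), and any test must account for that discordance.

`polyquart` is for phylogenomicists with a species tree and a collection of
gene trees (e.g. the inputs and outputs of a summary method such as
ASTRAL) who want, per internal branch, a p-value for the null hypothesis
*"this branch has length zero"* — equivalently, for a frequentist answer
to *"is my dataset sufficient to resolve this relationship?"*.

## The test

Under the multi-species coalescent (MSC), for a quartet species tree
`ab|cd` whose internal branch has length *x* coalescent units (CU;
generations divided by haploid population size), a gene tree shows the
three unrooted quartet topologies with probabilities

    p1 = 1 - (2/3) e^(-x),   p2 = p3 = (1/3) e^(-x).

At *x* = 0 all three equal 1/3. For each internal branch B of an N-taxon
species tree, quartets "around B" take one leaf from each of the four
subtrees adjacent to B; counting gene-tree topologies over these quartets
gives frequencies (n1, n2, n3) with n = n1 + n2 + n3. Under the polytomy
null hypothesis,

    chi2 = sum_i (n_i - n/3)^2 / (n/3)

is asymptotically chi-squared with 2 degrees of freedom (p-value
`exp(-chi2/2)` in closed form). Each gene tree contributes its *fraction*
of resolved, present quartets of each topology, so a gene counts as one
observation regardless of how many quartets surround the branch — the
conservative treatment of quartet dependence. Gene trees with no present,
resolved quartet around a branch are discarded there, so the *effective*
number of genes varies across branches; the chi-squared approximation is
only trusted when it is at least 10.

The package also provides the closed-form power analysis (smallest number
of genes that can reject a branch of given length), skewed and
MSC-with-gene-flow deviation models, a coalescent gene-tree simulator
operating directly in CU, and Yule species-tree generation.

## Worked example

Simulate 500 gene trees under a 12-taxon species tree of height 8 CU that
contains two hard polytomies, then test an arbitrary binary resolution of
it:

```r
library(polyquart)
sp       <- s12_fixture("A")                       # two 3-child polytomies
resolved <- resolve_arbitrarily(sp, seed = 3)      # new branches: length 0
genes    <- simulate_gene_trees(sp, 500, seed = 5)
polytomy_test(resolved, genes)
```

```
Polytomy test: 9 internal branches, 500 gene trees (method: mean)
effective n across branches: min 500 / median 500 / max 500
rejected at alpha = 0.05: 7 of 9 applicable branches
 branch_id                clade length    n1     n2     n3 effective_n     chi2    p_value applicable
         1               t10,t9    0.0 185.0 161.20 153.80         500   3.1940  2.025e-01       TRUE
         2              t11,t12    1.5 431.0  32.00  37.00         500 628.9000 2.697e-137       TRUE
         3       t10,t11,t12,t9    2.0 447.8  25.58  26.67         500 711.1000 3.910e-155       TRUE
         4                t7,t8    3.0 479.5   9.50  11.00         500 880.8000 5.484e-192       TRUE
         5                t1,t2    1.0 390.8  53.69  55.56         500 451.9000  7.320e-99       TRUE
         6                t3,t4    1.8 443.4  34.56  22.06         500 689.6000 1.821e-150       TRUE
         7          t1,t2,t3,t4    0.0 162.7 168.40 168.80         500   0.1385  9.331e-01       TRUE
         8       t1,t2,t3,t4,t5    0.2 230.9 141.80 127.40         500  37.7200  6.431e-09       TRUE
         9 t10,t11,t12,t7,t8,t9    2.0 451.2  24.50  24.35         500  728.4000 6.838e-159       TRUE
```

The two zero-length branches (rows 1 and 7) are the arbitrary resolutions
of the true polytomies: their quartet frequencies are near-equal and the
null is retained. Every true positive-length branch, including the short
0.2 CU branch (row 8), is rejected. The tree with non-rejected branches
collapsed back into polytomies is `collapse_nonrejected(tst)`; p-values go
into the newick output via `write_annotated_tree(tst, "out.nwk")`.

How many genes does a branch length require?

```r
min_genes_to_reject(c(0.1, 0.05, 0.02), alpha = 0.05)
#> [1]  331 1260 7641
```

## Command line

A thin wrapper over the same functions is installed as `exec/polyquart`:

```sh
polyquart test --species sp.nwk --genes genes.nwk --out run1 --alpha 0.05
polyquart test --species sp.nwk --genes genes.nwk --contract 10 --out run2
polyquart power --branch-length 0.1
polyquart simulate --fixture A --genes 1000 --seed 7 --out genes.nwk
```

`test` writes a per-branch TSV (`run1.tsv`) and a p-value-annotated newick
(`run1.nwk`); `--contract 10` first collapses gene-tree branches with
support at or below 10, which can raise power when gene trees are noisy.

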