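---
title: "Decision-tree SNP barcoding: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree SNP barcoding: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtsb)
```

## The problem

A conventional DNA barcode (for animals, typically the ~650 bp mitochondrial
COI fragment) carries far more sequence than is needed to tell apart the
members of one fixed panel of species: within a coherent taxon most columns
of the alignment are invariant and therefore uninformative. `dtsb` compresses
a panel of aligned barcode sequences — one representative per species — into
per-species *SNP barcodes*: short ordered sets of (alignment position,
nucleotide) pairs such that each set matches exactly one species in the
panel. The compression is performed by a greedy binary decision tree whose
internal nodes test single alignment columns.

The barcodes are diagnostic *within the panel only*. They say nothing about
species outside it, and re-running the pipeline on an extended panel can
change every barcode; this is inherent to the method, not an implementation
limit.

## Coordinate frame: the trimmed common region

Aligned sequences of unequal raw length protrude at the 5'/3' ends, visible
as terminal gaps in the shorter records. `trim_common_region()` removes every
column not covered by all sequences at the two ends, leaving a blunt-ended
block that is renumbered 1..M and used as the reference frame for all
positions reported downstream. Two deliberate choices:

* **Only terminal gaps trigger trimming.** A gap is "terminal" for a row if
  it lies before the row's first base or after its last. Internal alignment
  gaps are kept, but any column containing a gap — or an ambiguity code
  (`N`, `R`, `Y`, ...) — in any sequence is excluded from split candidacy,
  because the per-site counts are defined over the four canonical bases
  only. The source data for this kind of analysis (one curated reference
  sequence per species) rarely contains internal gaps; when it does, the
  exclusion is conservative: it can cost informative sites but can never
  produce a barcode that depends on an unobserved base.
* **Positions are 1-based** on the trimmed block, matching how diagnostic
  sites are reported in the barcoding literature.

## The position score

At a node holding $n$ sequences, each candidate column $p$ with base counts
$f_A, f_C, f_G, f_T$ is scored

$$\mathrm{score}_p \;=\; \frac{\mathrm{mid} - \mathrm{diff}_p}{\mathrm{mid}} + \mathrm{weight}_p,
\qquad \mathrm{mid} = \frac{n}{2},
\qquad \mathrm{diff}_p = \min_{i \in \{A,C,G,T\}} \lvert \mathrm{mid} - f_i \rvert ,$$

with a diversity bonus keyed to the number of base types present at the
column: 0 (one type), 1 (two), 0.66 (three), 0.33 (four). The first term
rewards *balance* — how close the best single-nucleotide cut comes to
splitting the node in half, which is what keeps the tree shallow and the
barcodes short; the bonus prefers clean biallelic sites over three- and
four-allele ones, whose best cut isolates a smaller fraction of the node.
The score lies in $[0, 2]$ and a perfectly balanced biallelic site attains
the maximum 2. The weights are the tabulated decimal constants 0.66 and
0.33, not $2/3$ and $1/3$: they are part of the score's definition, and
keeping them as exact decimals makes score ties exactly detectable.

Two details are worth stating because the defining formulas leave them open:

* **diff uses the absolute value.** The worked example that fixes the
  score's arithmetic evaluates $\lvert 4 - 7 \rvert = 3$, so the minimand
  must be $\lvert \mathrm{mid} - f_i \rvert$, not $\mathrm{mid} - f_i$.
* **Exact comparison.** Internally a score is ranked by the integer key
  $100\,(n - 2\,\mathrm{diff}) + w_{100}\,n$ (with $w_{100} \in \{0, 100,
  66, 33\}$), which equals the score scaled by $100 n$. All candidate
  ranking and tie detection is integer arithmetic, so the tie-break rules
  below behave identically on every platform.

## Tree construction

`build_tree()` grows the tree greedily from the full panel:

1. candidate columns at a node are those excluded nowhere in the full panel
   and variable within the node's subset;
2. the node splits on the maximal-score candidate; ties go to the smallest
   position index;
3. the **pivot** nucleotide is the one whose count is closest to mid (the
   argmin of diff), ties broken alphabetically $A < C < G < T$; species
   carrying the pivot form the left branch, all others the right branch —
   at a tri- or tetra-allelic site the non-pivot alleles are pooled, which
   keeps the tree strictly binary;
4. recursion stops at singleton subsets.

For a variable column every present base has count strictly between 0 and
$n$, so the pivot always splits off a proper, non-empty subset and the
recursion terminates with exactly $N$ leaves and $N-1$ decision nodes. No
pruning, depth cap or minimum node size is applied: with one sequence per
species there is no within-species variance to overfit, and the tree must
reach singleton purity for the barcodes to be diagnostic. Two species with
identical sequences over the candidate columns are reported as
indistinguishable by name — that is a property of the input panel, and no
barcode set can resolve it.

Positions may be selected repeatedly in different subtrees (the worked
8-species example in `figure3_fixture()` selects position 8 twice), which is
one reason the realised barcodes are often shorter than the worst case.

## Barcode extraction and bounds

A species' barcode is its root-to-leaf path, recorded in decision-level
order with the species' *own* nucleotide at each decision site (the branch
taken is recoverable by comparison with the pivot). The position-sorted,
duplicate-collapsed form is the printable tag (`"p3:C;p8:T"`), and
`match_barcode()` assigns a query to the unique species whose tag it
matches, falling back to `"unknown"`.

For $N$ species the per-species barcode length lies in
$[\lceil N/4 \rceil,\; N-1]$: at best every site is perfectly informative
four ways; at worst the tree degenerates to a caterpillar. With $M$
variable sites the number of candidate site multisets of worst-case size is
$\binom{N-1+M-1}{N-1}$ — `snp_combination_count()` evaluates it in exact
big-integer arithmetic (for 17 species and 185 SNPs it is
$\binom{200}{16} \approx 1.7\times 10^{22}$, far beyond double precision),
using a small built-in base-$10^4$ multiply/divide routine since the
package deliberately has no heavy numeric dependencies.

## Alternative split criteria

`build_tree(..., criterion = "gain")` and `"gini"` replace the score with
the two textbook impurity criteria, generalised to the panel's multi-class
setting (each species is its own class, so a node of $m$ species has
entropy $\log_2 m$): candidate (position, pivot) cuts are ranked by entropy
drop, or by size-weighted child Gini impurity. The binary-target forms
`info_bits()`, `expected_entropy()`, `information_gain()` and
`gini_index()` are exported exactly as defined for direct use and testing.
These criteria are comparison plug-ins; the balance score is the default
and the documented behaviour, and criteria are never mixed within one
tree. All structural guarantees (singleton leaves, self-consistent
classification) hold for every criterion.

## The synthetic panel generator

`random_panel()` emulates the study design — a panel of congeneric species
sequenced at one locus — with a star-shaped divergence model: a uniform
random root sequence, and each species derived by independent per-site
substitution with probability 0.1, the order of typical congeneric COI
divergence. Panels are rejection-sampled (bound: 1000 draws) until all
species are pairwise distinct, since discriminability is a precondition of
the method; optional per-site count constraints pin selected columns to an
exact allele spectrum, which is how the validation suite reconstructs
printed worked-example columns. The generator is a pure function of its
arguments (the caller's RNG stream is saved and restored).

What the model deliberately omits: phylogenetic structure among the species
(every pair is equidistant), transition/transversion bias, rate
heterogeneity across sites, indels and ambiguity codes. Passing tests on
these panels therefore demonstrate the *algorithmic* guarantees —
uniqueness, diagnostic equivalence of tree and barcodes, length bounds,
greedy optimality at every node — not the empirical barcode lengths one
would obtain on real, phylogenetically structured data, where shared
derived alleles make balanced splits rarer.

`figure3_fixture()` reconstructs the published 8×8 worked example from its
printed constraints (the original matrix exists only as a figure): column 1
counts (0,7,0,1), column 6 counts (0,4,0,4), root split at position 6 with
score 2, tree positions {1,2,5,6,7,8} with position 8 chosen twice at the
stated places. Every one of those properties is asserted in the test suite.

## Validation scale

The property suite exercises 200 seeded random panels with $N \in [2, 20]$
species and $M \in [\max(4, 2N), 200]$ sites (the lower bound on $M$ scales
with $N$ so that pairwise-distinct panels are generically attainable under
the 0.1 substitution rate), plus a 17-species × 185-site panel mirroring
the shape of the original Columbidae analysis. On every panel the suite
checks barcode uniqueness, agreement of `match_barcode()` with
`classify()`, the $N-1$ length bound, and node-by-node agreement of the
greedy split with an independent brute-force scan.

## Known limitations

* Panel-relative validity: barcodes must be regenerated whenever the panel
  changes, and cannot flag out-of-panel species (queries from unknown
  species will be assigned to some leaf by `classify()`; `match_barcode()`
  is stricter and can return `"unknown"`).
* One sequence per species: within-species polymorphism is not modelled; a
  diagnostic site that is polymorphic within a species will misclassify
  some individuals.
* Greedy, not optimal: the tree minimises nothing globally; shorter barcode
  sets may exist for a given panel.
* Columns with gaps or ambiguity codes anywhere in the panel are discarded
  as candidates, which can lose informative sites in poorly curated panels.
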