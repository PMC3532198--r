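---
title: "Methods: digital differential display, GO similarity and bootstrap-supported biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital differential display, GO similarity and bootstrap-supported biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dddclust)
```

This vignette is the package's account of its methods: the statistical
model behind each stage, the tunable parameters and their defaults, the
numerical conventions, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## Digital differential display

EST libraries are treated as multinomial draws: library $\ell$ sequences
$N_\ell$ reads from a gene-proportion vector. Pooling the libraries of a
condition sums counts and totals, and a gene's *transcript frequency* in a
pool is $f = x / N$ with $x$ the pooled count and $N$ the pooled total.
Two pools A and B are compared per gene by:

* the **signed fold change**: magnitude $\max(f_t, f_o)/\min(f_t, f_o)$
  where $f_t$ is the frequency in the designated *test pool* and $f_o$ in
  the other pool; positive when the test pool is higher. A gene observed
  in only one pool has no finite ratio and is flagged *exclusive*
  (`+`/`-`, encoded $\pm\infty$). Equality reports $+1$.
* a **two-sided Fisher exact test** on the $2\times2$ table
  $\{(x_A, N_A - x_A), (x_B, N_B - x_B)\}$, using the point-probability
  rule: the p-value is the total hypergeometric probability of all tables
  with the observed margins whose probability does not exceed the observed
  table's, with a relative tolerance of $1 + 10^{-7}$ guarding floating
  ties. Probabilities are evaluated in log space and the enumeration runs
  over the gene margin $x_A + x_B$, so the cost is independent of the
  (large) pool totals.

`run_ddd()` retains genes with finite $|{\rm fold}| \ge$ `min_fold`
(default 2 — the operative filter of the published analysis) and always
retains exclusives; Benjamini–Hochberg q-values are computed over *all*
tested genes before filtering. No q-value cutoff is applied by default
(`alpha = NULL`): the source analysis states a fold rule but no
significance threshold alongside it, so significance filtering is opt-in.

Two conventions matter for reproducing published tables. First, the sign
is always relative to the test pool, declared in the `pool_manifest()`;
published tables that flip column order between contrasts are reproduced
by declaring the appropriate test pool rather than by reordering columns.
Second, folds are computed from unrounded frequencies and only *reported*
at 2 decimals (frequencies at 4), rounding half away from zero
(`round_half_up()`); tables whose folds were computed from unrounded
counts can therefore differ from a recomputation off their own rounded
frequencies by one unit in the last printed digit.

## Subtractive candidate filtering

Candidate narrowing is ordinary set arithmetic made auditable: every step
(`intersect_contrasts()`, `exclude_genes()`, `map_identifiers()`) logs
(step, n\_before, n\_removed, n\_after) in the `candidate_set`'s
provenance log, so published counts (say, 76 shared candidates minus 18
pan-disease genes = 58) are verifiable line by line. The step order is
fixed — intersect, then exclude, then map — matching the narrative order
of the analysis this package reimplements; exclusion and mapping commute
only when the mapping is injective on the exclusion list, so the order is
part of the method, not a convenience. Identifier mapping drops
unmappable sources (with a warning) and collapses canonical duplicates
keeping the first occurrence, which is how conversion shrinks candidate
counts in practice.

## Wang semantic similarity

The between-term measure is Wang's graph-based similarity. For an anchor
term $a$, every ancestor $t$ (via `is_a` or `part_of`) receives an
S-value: $S_a(a) = 1$ and
$S_a(t) = \max_{t' \in {\rm children}(t)} w(t' \to t)\, S_a(t')$,
i.e. the best decaying path from the anchor, with the standard
contribution factors $w_{is\_a} = 0.8$, $w_{part\_of} = 0.6$
(configurable; the source analysis names only the measure, and these are
its canonical constants). With $SV(a) = \sum_t S_a(t)$,

$$\mathrm{Sim}(a,b) = \frac{\sum_{t \in T_a \cap T_b} S_a(t) + S_b(t)}
                           {SV(a) + SV(b)} \in [0, 1].$$

Gene-pair similarity is the **best-match average** over the genes' direct
annotation sets (sizes $m$ and $n$): each term contributes its maximum
similarity to the other gene's set and the two-way sum is divided by
$m + n$. Identical sets score exactly 1. Direct annotations anchor the
computation — ancestors enter only through S-value propagation — matching
the Wang construction; annotations are never pre-propagated.

Two points were genuinely open and are package decisions:

* **Cross-namespace combination.** How per-namespace scores merge into one
  number is not specified by the source analysis. The package takes the
  unweighted mean over the namespaces in which *both* genes are annotated,
  records the namespaces used on the returned value, and returns missing
  when there is none.
* **Missing-annotation policy.** Candidates with no usable annotation are
  dropped from the similarity matrix (with a warning and a record in the
  `"dropped"` attribute) rather than zero-filled — zero-filling would
  manufacture spurious "dissimilar" profiles, and dropping mirrors how
  unconvertible/unannotated genes fall out of real analyses.

## Hierarchical clustering with multiscale bootstrap support

Candidates are clustered on their similarity profiles against the
reference panel. The default distance is $1 - r$ (Pearson correlation,
missing entries excluded pairwise; pairs must share at least 3 columns,
and a constant profile is an error naming the gene). Linkage is UPGMA by
default (complete and single are available). The agglomeration is written
in the package rather than delegated, for one reason: when several pairs
tie at the minimal distance, the pair whose merged leaf set is
lexicographically smallest is chosen, so replicate trees are a
deterministic function of their distance matrix and cluster membership
can be matched across replicates without ambiguity. Away from ties the
trees agree with `stats::hclust` (asserted in the tests).

Cluster uncertainty follows the multiscale bootstrap. At each relative
scale $\rho \in \{0.5, 0.6, \ldots, 1.4\}$ (ten scales), the reference
*columns* are resampled with replacement to size
$n_\rho = \max(3, \mathrm{round}(p\rho))$ and the resampled matrix is
reclustered through the identical code path. A cluster of the observed
tree scores a hit in a replicate containing a node with the same leaf
set; the hit rate is its bootstrap probability $BP_\rho$. The probit
transform $\psi_\rho = \Phi^{-1}(1 - BP_\rho)$ is fitted by weighted
least squares as $\psi_\rho = v\sqrt{\rho} + c/\sqrt{\rho}$ with binomial
delta-method weights $B\,\phi(\psi)^2 / (BP(1-BP))$, giving

$$AU = 1 - \Phi(v - c), \qquad BP_{\rm fit} = 1 - \Phi(v + c).$$

Defaults are $B = 1000$ replicates per scale and the ten scales above,
the customary settings of this procedure. `pick_clusters()` traverses the
tree top-down and reports a node, pruning its subtree, when its AU
reaches `alpha` (default 0.95); leaves are never reported alone.

Numerical conventions, chosen after measuring the alternatives:

* A $BP$ of exactly 0 or 1 has an infinite probit and carries no
  information about the curve's *shape*, so such scales are excluded from
  the fit. Keeping them, clamped into $[1/(2B), 1 - 1/(2B)]$, was tried
  first and rejected: the clamped flat segment drags the fit toward a
  constant curve and systematically deflates AU for precisely the most
  strongly supported clusters.
* A curve with fewer than two informative scales cannot be extrapolated
  and resolves to its degenerate limit — $1 - 1/(2B)$ (all high) or
  $1/(2B)$ (all low) — i.e. extreme support up to the Monte-Carlo
  resolution of $B$ replicates. Informative scales collapsing onto a
  single distinct $\rho$ leave the node unfittable (`AU = NA`).
* The root contains every gene in every replicate by construction; its
  $BP \equiv 1$ curve is structural, not evidential, so the root is
  reported with `AU = NA` and is never selected by `pick_clusters()` from
  a bootstrap fit. (`pick_clusters()` honours whatever supports it is
  given, so a hand-constructed support table can still select the root.)
* In bootstrap replicates a resampled profile can be constant (e.g. a
  degenerate column draw); its undefined correlations are treated as 0
  (distance 1) rather than aborting the replicate, keeping the replicate
  count fixed. The *observed* clustering still treats a constant profile
  as an error.

## The synthetic-data generator

The generator exists so that every stage is testable offline; its
defaults are the package's desk-scale study conditions.

* **Libraries** (`simulate_libraries()`): baseline gene proportions are
  drawn from a symmetric Dirichlet with concentration 0.5 — producing the
  strong abundance skew characteristic of transcript counts, including
  effectively silent genes. Each library's depth is uniform on
  20,000–50,000 ESTs and its counts are one multinomial draw (fixed
  sequencing depth, unlike independent Poisson counts). Planted
  differential genes have their proportion multiplied (up) or divided
  (down) by the planted fold in query-condition libraries, then
  renormalised. The default configuration is 300 genes and 6 reference +
  6 query + 20 other-tissue libraries — far below a real compendium's
  scale (hundreds of libraries, tens of thousands of genes) but
  structurally identical to the two-contrast pooled design.
* **Ontology** (`simulate_ontology()`): per namespace, a root with a
  fixed set of top-level branch heads; each later term joins a uniformly
  chosen branch and attaches to 1–2 of its existing terms (second parent
  with probability 0.2), each edge `is_a` with probability 0.8, else
  `part_of`. Growing within branches was a deliberate revision: with
  fully uniform attachment one branch absorbs most terms and disjoint
  multi-branch structure — which the planted groups require — almost
  never arises. Within-branch double parents still create the diamond
  motifs that exercise max-over-paths S-value propagation.
* **Annotations** (`simulate_annotations()`): each planted group is
  assigned a disjoint branch; members draw Poisson-many distinct terms
  from their branch (a draw larger than the branch is an error rather
  than a silent truncation), with a per-term leakage probability of
  substituting a uniform term; background genes draw uniformly. A gene
  whose Poisson draw is zero is present with an empty set — which, as in
  real data, later drops it from the similarity matrix.

One seed drives everything: the three generators use `seed`, `seed + 1`,
`seed + 2` so their draws are independent but jointly reproducible.

What the generator does **not** emulate: 3'-end coverage bias, library
normalisation or subtraction artefacts, sequencing error, tissue-specific
baseline differences among the "other" libraries, and the annotation
incompleteness structure of real GO. Passing tests therefore demonstrate
that the machinery is correct under its stated model, not that the
biological conclusions of any particular real-data analysis are
reproduced — real-data results additionally depend on database releases
that are not part of this package.

## The packaged demonstration dataset

`demo_group_config()` / `demo_group_data()` define the planted-two-group
dataset used by the recovery tests: one namespace of 60 terms, two groups
of 28 genes on disjoint branches, 6 expected terms per gene, zero
leakage; 8 genes per group are clustered as candidates against the
remaining 40 as reference columns. The 40-column reference panel is a
measured design choice: scoring the 16 candidates against only themselves
leaves so few columns that low-scale resamples occasionally consist of
columns from a single group, which leaves the group nodes' BP curves flat
just below 1 — a regime where the AU extrapolation is genuinely
uninformative. With 40 reference columns that event is negligible and
recovery is robust. This mirrors the real design, where candidates are
scored against a separate tissue-specific reference list.

## Problem sizes used by the test suite

The suite runs the bootstrap at full $B = 1000$ on the 16-candidate demo
dataset, checks oracle agreement of the Fisher test on 500 random small
tables and of the S-value engine on random DAGs of up to 30 terms, and
estimates type-I error on 2000 simulated null genes; the variance
monotonicity of AU is checked at $B = 200$ versus $800$ on an 8-gene
fixture with five scales. These sizes are the package's chosen desk-scale
study conditions; all are generated in code at test time.

## Known limitations

* AU p-values are frequentist approximations; at desk scale (tens of
  genes, 10 scales, $B = 1000$) their Monte-Carlo error is visible in the
  third decimal, and clusters whose BP curves are degenerate at every
  scale are reported at the resolution limit rather than extrapolated.
* The Fisher enumeration is exact but conservative, as is inherent to
  conditioning on both margins of sparse count tables.
* The OBO reader covers the subset needed here (`is_a`,
  `relationship: part_of`, `is_obsolete`); it is not a general OBO 1.4
  parser, and `intersection_of`/cross-products are out of scope.
* GAF files cannot represent a gene with no annotations, so write/read
  round-trips are exact on annotated genes only.
* Identifier namespaces are opaque strings throughout; no Entrez/UniGene
  semantics are assumed.
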