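---
title: "Ancestral gene-content flux: model, corrections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral gene-content flux: model, corrections, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoflux)
```

## The problem

Given a rooted species tree for a set of genomes (typically a mix of
isolates, single-cell genomes and metagenome-assembled genomes of varying
completeness) and one gene tree per protein family, we want per-branch
counts of gene **duplications**, **losses**, **intra-set lateral transfers
(intra-LGT)** and **originations**, the reconstructed proteome content of
every ancestor, and downstream summaries: where gains came from, which
originating families were later duplicated or lost in which descendant
lineages, and whether particular clades changed faster than the rest of the
tree.

## The reconciliation model

`reconcile_undated()` implements minimum-cost **undated DTL parsimony**. For
gene node $u$ and species branch $x$ the dynamic program evaluates, in this
order: the two speciation assignments of $u$'s children to $x$'s child
branches, a duplication on $x$ ($\delta$), and a transfer ($\tau$) sending
one child to the cheapest branch *incomparable* to $x$ (neither its ancestor
nor descendant). Passing a lineage through a species node charges a loss
($\lambda$) on the skipped child branch. The family's origination is the
branch the gene-tree root maps to, chosen freely by cost: a family observed
only inside one subtree originates inside that subtree and is *not* charged
phantom losses outside it. Unrooted gene trees are reconciled under every
rooting and the cheapest is kept.

Assumptions worth stating plainly:

* The model is a *parsimony substitute* for probabilistic reconciliation
  with rate estimation and gene-tree amalgamation. The event taxonomy and
  branch mapping are the same, but counts are minimum-cost point estimates,
  not posterior expectations, and gene-tree error propagates directly into
  event calls.
* Transfers are constrained only by branch incomparability (the standard
  undated surrogate); no global time consistency across families is
  enforced.
* All transfers landing inside the tree are intra-LGT by definition;
  transfers *from outside* the sampled set are indistinguishable from de
  novo formation at this stage and surface as originations (their source is
  assessed separately, see `classify_origination()`).

**Costs.** Defaults $\delta = 2$, $\tau = 3$, $\lambda = 1$ (unitless,
per event). Losses are cheapest because repeated independent losses of the
same ancestral family are the commonest event in prokaryote evolution;
transfers are dearest because a transfer is the strongest claim — it
asserts a donor–recipient relationship. Ties between equal-cost histories
are broken towards fewer transfers, then fewer duplications, then the
lexicographically smallest species-branch label; results are therefore
deterministic, and the preference order mirrors the cost rationale.

**Completeness.** An absence at a leaf with completeness $c \in (0, 1]$ is
charged $\lambda\,c$ rather than $\lambda$. Rationale: under independent
gene observation, a family truly present in a genome of completeness $c$ is
unobserved with probability $1 - c$; linearly discounting the terminal loss
cost is the simplest parsimony analogue of probabilistic completeness
handling. It is an approximation we state rather than inherit: nothing in
the published record specifies the original computation. The discount only
ever lowers costs (tested as a monotonicity property).

## Per-branch aggregation and ancestral content

`aggregate_events()` sums per-family tallies; `classify_gains()` partitions
gains exactly: every duplication is a gain on its branch, every
transfer-receipt is an intra-LGT gain on the receiving branch, and each
family contributes exactly one origination. The identity
$\text{gains} = \Sigma d + \Sigma t + n_\text{families}$ is asserted in the
tests. `ancestral_content()` counts the gene lineages surviving at each
species node under the chosen reconciliation; `detect_expansions()` flags
copy-number changes strictly exceeding a fold threshold (default 10), and
families appearing from zero copies are reported as *novel* rather than
"expanded", since a fold change from zero is undefined.

## Fate of originating families

For the families originating on a branch, `fate_of_families()` scores each
descendant genome: raw lost fraction $\hat p_L$ (zero observed copies) and
raw duplicated fraction $\hat p_D$ (two or more copies). Both are biased by
incompleteness, in opposite directions, so the corrected values are

$$p_L = \mathrm{clip}\!\left(\frac{\hat p_L - (1 - c)}{c},\, 0,\, 1\right),
\qquad
p_D = \mathrm{clip}\!\left(\frac{\hat p_D}{c},\, 0,\, 1\right),$$

i.e. the expected false-loss rate $1 - c$ is subtracted and the remainder
rescaled, and observed duplication counts are inflated by $1/c$ (a
duplicated family is scored from observing $\ge 2$ of its copies; at
moderate copy numbers the dominant error is missing the second copy, which
the $1/c$ rescaling compensates to first order — it is exact for two-copy
families only if at most one copy is ever missed, so $p_D$ is a first-order
correction, not an estimator with guarantees). Unbiasedness of $p_L$ under
the generative model (true loss fraction 0.3, completeness 0.7, 200
genomes) is verified to within 5 percentage points in the acceptance suite.
Genomes can be pooled into genus-style groups: pooled presence is the
maximum over members and pooled completeness is
$1 - \prod_i (1 - c_i)$, the probability that at least one member observes
a present gene.

## Clade rate comparisons

The published record reports clade-level significance without naming a
test, so `compare_clade_rates()` makes the null explicit: the statistic is
the difference in mean per-branch event count between a clade's branches
and the rest, and the null redraws the clade label set uniformly among
branches (`n_perm` default 9,999). The add-one correction
$p = (1 + \#\{|s_\text{perm}| \ge |s_\text{obs}|\})/(1 + n_\text{perm})$
never reports zero. Branches are treated as exchangeable units; this
ignores branch length and phylogenetic autocorrelation, which is why the
result is a descriptive contrast, not a rate-model test. Its p-values are
not expected to reproduce any published values. Whether "proteome changes"
should sum all four classes or only gains is genuinely ambiguous; both are
exposed via `event_class`.

## Families, markers, medoids

`cluster_families()` replaces pan-genome machinery by Markov clustering
(expansion 2, inflation 1.5) of a bitscore-weighted, identity-thresholded
similarity graph — identity floors 35% for families and 50% for core
markers map the original stringencies onto a fully testable algorithm. The
known behavioural gap: MCL has no exact equivalent of "do not split
paralogs", so paralog granularity is approximate. Filters follow the stated
order — members shorter than 30 aa are removed *before* families smaller
than 4 are dropped — because the order changes results. Core markers must
be single-copy wherever present and present in at least 85% of
*near-complete* genomes; "near complete" is undefined in the source and
fixed here at completeness ≥ 90% (the conventional high-quality MAG
boundary), configurable. Whether the 85% rule should count genomes before
or after the contamination filter is unstated; the API takes the caller's
`kept_genomes`, making the choice explicit.

The family medoid minimises summed BLOSUM62 distances
$d(i,j) = 1 - S(i,j)/\max(S(i,i), S(j,j))$ over pair-gap-free columns; the
normalisation is bounded, zero for identical sequences, and fixed here
because only "BLOSUM62 distances" is specified. Ties go to the
lexicographically smallest id.

## Taxonomy

AAI between two genomes is the mean percent identity over reciprocal best
hits (best by bitscore, ties by e-value then subject id), symmetrized by
averaging directions. Genus and species are single-linkage clusters at AAI
strictly above 70% and 95%; class, order and family are single-linkage
clusters of Pearson distances between patristic-distance profiles
(self-entries excluded) cut strictly below 0.34, 0.13 and 0.015. Single
linkage at nested thresholds guarantees rank nesting within each system,
but *not* between the AAI and the phylo-distance systems; conflicts are
reported, not resolved. One numerical edge: a flat distance profile (e.g. a
two-genome cherry equidistant from everything else) has undefined Pearson
correlation; identical flat profiles are assigned distance 0, non-identical
ones distance 1.

## Annotation filters and origination sources

`filter_hits()` keeps hits with e-value ≤ 1e−5, identity ≥ 35%, alignment
length ≥ 80 and bitscore ≥ 100 — boundary values are *kept* because the
source phrases the filter as strict removal conditions, while its
figure-caption paraphrase inverts the strictness; the removal phrasing
wins and everything is configurable. Proteome novelty is the share of a
genome's proteins with no qualifying hit; any-qualifying-hit is the
default and a best-hit-only mode is a flag, since the original choice is
underdetermined. Origination sources: a family whose medoid has no
qualifying non-self-phylum hit in the external database is putative de
novo; otherwise the donor domain comes from the best remaining hit.

## The simulator: what a green test does and does not establish

`simulate_gene_content()` evolves each family from a single origination
(branch drawn proportional to branch length — a Poisson process on the
tree) through competing exponential duplication/transfer/loss processes per
gene copy; transfers re-insert at a uniform incomparable branch, matching
the reconciliation model. Exact per-branch tallies and node-by-family copy
numbers are recorded as ground truth. Two deliberate conventions:

* Families are conditioned on survival (extinct histories are redrawn, with
  a cap): observed families in real data are necessarily non-extinct, and
  this makes "total inferred originations = number of families" an exact
  invariant.
* `origination_rate` is retained in `evol_params` for interface
  completeness but each family originates exactly once; family count is
  controlled by `n_families`.

Sequences evolve under the uniform 20-state replacement model, chosen
because its closed-form identity decay
$\mathbb{E}[\text{identity}] = 0.05 + 0.95\,e^{-(20/19)\,\mu d}$ provides
an analytic oracle for the sequence layer; per-site substitution counts are
Poisson and the final state uses the exact jump-chain distribution
$P(\text{same} \mid k) = \tfrac1{20} + \tfrac{19}{20}(-\tfrac1{19})^k$.
Incompleteness is simulated as independent Bernoulli gene retention, the
same observation model the corrections assume. `simulate_hits()` derives
outfmt-6-style tables from full-length identities with monotone
bitscore/e-value transforms.

The simulator deliberately does **not** emulate: among-site or among-family
rate heterogeneity, empirical amino-acid exchangeabilities, indels and
alignment error, gene-tree estimation error, local alignment statistics of
real search tools, contamination, or linked (non-independent) gene loss on
contigs. Green tests therefore establish internal consistency of inference
with the stated generative model and exact arithmetic of the corrections —
not robustness to the full messiness of real MAG data. Defaults for the
stated validation worlds are fixed by the acceptance criteria (16 taxa, 300
families, duplication 0.3, transfer 0.1, loss 0.5 per gene per unit branch
length, completeness 1; fate world: 200 genomes, loss fraction 0.3,
completeness 0.7) and are not tuned.

## Numerical choices

* Cost comparisons use an absolute tolerance of 1e−9; all DP argmins scan
  candidates in lexicographic branch-label order with strict improvement,
  so equal-cost choices resolve to the smallest label.
* MCL: self-loops at each node's maximum incident weight, column
  normalisation, pruning below 1e−10, convergence at max-change < 1e−8,
  attractor systems merged by union–find.
* The permutation p-value is add-one corrected; permutation draws depend
  only on the seed argument.
* Single-member families reconcile trivially (origination on the tip
  branch, zero cost) without building a degenerate one-leaf tree.

## Known limitations

Parsimony counts are lower bounds under the cost regime, not event-rate
estimates; hot branches with many events compress. The completeness
discount is linear and terminal-only: ancestral losses are never
discounted. The permutation test treats branches as exchangeable. AAI on
few shared families is noisy, and the simulator's hit tables are global
(full-length) alignments, so local-homology artefacts are out of scope.
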