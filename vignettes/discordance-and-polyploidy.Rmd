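---
title: "Methods: quantifying gene-tree discordance and testing polyploidy hypotheses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gene-tree discordance and testing polyploidy hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsq)
```

# The problem

Phylogenomic datasets routinely show widespread conflict between individual
gene trees and the species tree. Two biological processes dominate the
explanations: incomplete lineage sorting (ILS) — ancestral polymorphism that
fails to sort along species boundaries, expected whenever internal branches
are short relative to ancestral population sizes — and reticulation
(hybridization, allopolyploidy). Separately, whole-genome duplications
(WGDs) leave signatures in collinear (syntenic) gene copies and in the
distribution of synonymous divergence (Ks) between paralogs, and the
question of whether two lineages *share* a WGD or duplicated
*independently* is itself a tree-topology question.

`ilsq` implements the corresponding inference machinery as a reusable,
fully testable pipeline: multispecies-coalescent (MSC) simulation,
per-branch theta estimation, quartet concordance analysis with regression
and chi-square agreement tests, split-support classification, collinear
gene-tree WGD tests, Ks mixture fitting, and LTR insertion-time dating. A
synthetic-data module generates every input with known ground truth, so the
whole pipeline is exercised end to end without any genome-scale download.

# The coalescent model and its conventions

## Simulation

Gene trees are simulated within a rooted binary species tree whose internal
branch lengths are in coalescent units. Within a species-tree branch of
duration $t$ carrying $k$ gene lineages, coalescences occur after
exponential waiting times at rate $\binom{k}{2}$, the coalescing pair
chosen uniformly; lineages surviving to the top of a branch enter the
parent branch, and the root branch is unbounded (all remaining lineages
eventually coalesce). One allele is sampled per species by default, which
makes terminal branch durations topologically inert; outputs still set them
to 1 to mirror the convention of coalescent-unit species trees. Species
trees need not be ultrametric: each lineage accumulates its own pending
branch length, so gene-tree branch lengths are path-consistent for any
input.

## Theta

Theta here is defined as the ratio of a branch's length in mutation units
(substitutions/site, e.g. from a maximum-likelihood analysis) to its length
in coalescent units (e.g. from a quartet-based species-tree method):
$\theta = \ell_{\mathrm{mut}} / \ell_{\mathrm{coal}}$. Larger theta means a
larger ancestral population and more ILS. Note this deviates from the
classical population-genetic convention $\tau = 2t/\theta$; there is no
factor of 2 anywhere in this package, and `coalescent_scale()` is its exact
inverse (`coalescent length = mutation length / theta`). We adopt the
no-factor form because it is the operational definition used in the
empirical workflow this package reimplements; mixing conventions, not the
choice itself, is what produces wrong answers.

Branches are matched between the two unit systems by bipartition, not node
order, so differently rooted inputs work; the two root-adjacent edges of a
rooted tree induce the same bipartition and their lengths are summed, which
is the correct unrooted treatment. Terminal branches are excluded — a
quartet-based method carries no information about them.

## Quartet concordance and branch lengths from support

For an internal branch, four taxon groups are defined (the two child
clades, and the two subtrees on the far side of the edge); every quartet
drawing one taxon per group traverses that branch, and under the MSC the
species-tree resolution has probability

$$q_1 = 1 - \tfrac{2}{3} e^{-t},$$

with each minor resolution at $\tfrac{1}{3}e^{-t}$ — exactly, for any
surrounding tree shape, because conditional on the two focal lineages
failing to coalesce in the branch, exchangeability makes the eventual
resolution uniform over the three topologies. `coalescent_length_from_support()`
inverts this: $\hat t = -\log(\tfrac{3}{2}(1 - q_1))$, clipped to 0 below
$q_1 = 1/3$ and capped at 10 coalescent units (at $q_1 \to 1$ the estimator
diverges; 10 units implies discordance below $10^{-4}$, beyond any signal
estimable from 20,000 gene trees).

Numerical choices in the tabulation:

* **Resolved-only denominators.** Unresolved and missing quartets are
  tallied but excluded from frequency denominators; coalescent expectations
  are statements about resolved quartets.
* **Pooling.** Branch supports pool raw counts with equal weight per
  (gene tree, quartet) pair; a `per_tree` weighting (each tree's quartets
  averaged first) is exposed because published tools differ and neither
  choice is derivably "the" right one.
* **Minor-topology identity.** For the chi-square comparison around a
  focal branch, the two minor topologies are identified structurally (group
  1 pairing with group 3, versus group 1 with group 4), so the same column
  means the same topology in both datasets; `q2 >= q3` ordering is applied
  only for reporting.

## The ILS assessment

`run_ils_assessment()` chains the pieces the way the empirical workflow
does: simulate 20,000 gene trees from the coalescent-unit species tree
(with-ILS expectation); rescale the mutation-unit tree by a nominal
$\theta = 0.001$ and simulate again (no-ILS baseline — internal branches
become tens to hundreds of coalescent units, so essentially every gene tree
matches the species topology); tabulate quartet frequencies for the
empirical collection and both simulations; regress simulated on empirical
frequencies with `lm()`; and per focal branch, chi-square the two
minor-topology counts of the empirical set against the with-ILS simulation.
A with-ILS $R^2$ close to 1 alongside a visibly lower no-ILS $R^2$ says the
discordance pattern is the one ILS predicts; a non-significant chi-square at
a branch says ILS alone explains the local minor-topology balance, while a
significant one leaves room for hybridization or other processes. Raw
p-values are reported (as in the workflow being reimplemented) with
Benjamini–Hochberg companions, since the branch-wise tests are a family.

One statistical caveat is inherent to the pooled-count design: when a focal
branch's groups contain several taxa, the pooled quartets reuse the same
gene trees and are therefore positively correlated, so the chi-square's
multinomial assumption is optimistic and branch-level p-values run somewhat
anti-conservative. For a branch whose four groups are single taxa (one
quartet, independent tallies) the test is exactly calibrated — the test
suite verifies 5% type-I error under the null in that design — so
borderline rejections at multi-taxon branches deserve skepticism while
clear ones remain interpretable.

## Split support classification

`classify_split_support()` scores a split against each gene tree restricted
to the taxa present: an edge with support at or above the threshold
(default 75%) is *strongly supported*, below it *weakly supported*; an
absent split that becomes compatible once all low-support edges are
contracted is *weakly rejected*, otherwise *strongly rejected*. Supports in
$(0,1]$ (posterior-style) are rescaled to the percent scale at parse time
so one threshold applies uniformly. Trees on which the restriction leaves
fewer than two taxa on either side are uninformative and excluded from the
proportions.

# Polyploidy tests

## Shared versus independent WGD

For two species A and B each carrying duplicate collinear copies, the
unrooted quartet on the four copies decides: `((A1,A2),(B1,B2))` — each
species' copies sister — means the duplications postdate the A–B split
(*independent*); either cross-species pairing places one duplication in the
common ancestor (*shared*). Both cross pairings count as shared — only one
is conventionally written out, but the second is the same history with
copy labels swapped, and copy labels carry no homology information. For
triplicated genomes (3+3 copies), *independent* requires each species'
copies to form a clade on the induced six-tip subtree (the strictest
consistent reading of the marked-branch notation for triplications);
resolved violations are *shared*, under-resolved subtrees are *other*.
Copies of further species in a tree are ignored, and the verdict is
invariant to rooting and to swapping A and B. Under a uniform-random
topology null exactly one of the three quartet resolutions is independent,
so the expected independent proportion is 1/3 — a property the tests
verify by simulation.

## Ks mixtures

WGDs appear as peaks in the distribution of per-block median Ks.
`fit_ks_mixture()` fits a $k$-component Gaussian mixture by
expectation–maximization on raw (not log) Ks values truncated to
$(0, \mathrm{max\_ks}]$ (default 5 — synonymous saturation makes larger
values uninformative). Initialization is deterministic (means at evenly
spaced sample quantiles, common initial standard deviation, equal weights),
convergence is a relative log-likelihood change below $10^{-6}$ within 500
iterations, standard deviations are floored at $10^{-4}$ to prevent
component collapse, and components are returned sorted by mean — so the fit
is a pure function of its inputs, no seed needed. The log-likelihood trace
is returned and tested to be non-decreasing (the EM guarantee); BIC is
reported for order selection. The published mixture tool's exact
parameterization (truncation, block weighting) is not documented; these
choices are ours and are stated rather than inferred.

## LTR insertion times

The two long terminal repeats of a retrotransposon are identical on
insertion, so their divergence $K$ dates it: $T = K/(2r)$. The default rate
$r = 3.8\times10^{-9}$ per site per year is twice the synonymous coding
rate $1.9\times10^{-9}$, reflecting the faster evolution of repeats; both
constants are exposed (`clock_rates()`) and overridable.

# The synthetic world

The generators state a world once and the tests live in it:

* `gen_species_tree()` draws a random coalescent topology, internal
  coalescent-unit lengths uniform on a stated range, terminal branches 1,
  and a mutation-unit twin with internal lengths $\theta \cdot \ell$ — so
  theta recovery has an exact construction inverse. Defaults (7 taxa,
  lengths on $[0.2, 1.2]$, $\theta = 0.1$) emulate a rapid radiation:
  internal branches short enough for 10–40% discordance, theta within the
  0.027–0.224 decade reported for deep angiosperm branches.
* Acceptance-grade checks use 20,000 simulated gene trees, the scale of the
  workflow being reimplemented; theta recovery spans true values
  {0.03, 0.1, 0.22} and branch lengths on $[0.5, 2]$ where the
  quartet-support inversion is well conditioned.
* `gen_wgd_copy_trees()` emits the two WGD backbones with a tunable
  per-tree probability of one random nearest-neighbor interchange. NNI was
  chosen over SPR because on a four-tip backbone its outcome set is
  exhaustively enumerable (the two alternative resolutions, uniformly), so
  noisy expectations are computable by brute force rather than estimated.
* `gen_ks_mixture_sample()` draws i.i.d. mixture samples with negatives
  rejected; the two-component default (0.6·N(0.5, 0.15) + 0.4·N(1.07, 0.2))
  places one peak at the Ks value typical of a single ancient WGD.

What a green test does *not* establish: the generators draw gene trees from
the exact model the estimators assume. Real data add gene-tree estimation
error, missing taxa, alignment and orthology artifacts, rate variation, and
reticulation; none are modeled here (gene-loss/fractionation after WGD and
sequence-level simulation are explicit non-goals). Green means the
machinery is correct, not that the biological conclusions of any particular
dataset are.

# Reproducibility and numerical details

* Every stochastic entry point takes a seed. Batch simulation derives a
  per-replicate seed deterministically from (seed, replicate index), so
  replicate $i$ is independent of `n_trees` — the property RNG stream
  jumping provides, implemented without a jumpable generator.
  `run_ils_assessment()` derives its baseline-simulation seed from the main
  seed, so a report is byte-reproducible from one integer.
* Split and quartet operations run on 31-bit taxon bitmasks, capping
  reference sets at 30 taxa — ample for syntenic/quartet workflows of this
  kind (the motivating analyses used 14 genomes); larger sets error
  immediately rather than degrade.
* The no-ILS baseline theta defaults to 0.001. (Described in its source as
  "two hundred times less" than the smallest observed theta 0.027 — the
  ratio is actually 27 — the stated value, not the stated ratio, is used.)
* Chi-square tests are Pearson, df 1, no continuity correction; an all-zero
  column with non-zero rows contributes 0 by the 0/0 convention; an
  all-zero row is an error, not a statistic.
* Branch lengths absent from an input newick stay absent (`NA`), never 0;
  operations that need them say so.

# Limitations

Beyond the synthetic-world caveats above: no multi-allele coalescent
beyond the config hook, no migration or bounded root, no hybridization
network search, no species-tree estimation, and no Ks computation from
alignments — all deliberate scope boundaries. The quartet machinery treats
every gene tree as unrooted and every input tree's support labels as
exchangeable with bootstrap percentages after rescaling; mixed support
semantics within one file cannot be detected.
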