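# ilsq

Coalescent simulation, quartet concordance and polyploidy tests for
phylogenomic discordance.

`ilsq` is for phylogenomicists who see conflict among their gene trees and
want to know how much of it incomplete lineage sorting (ILS) can explain —
and, separately, whether the whole-genome duplications (WGDs) visible in
their genomes are shared with other lineages or arose independently. It
packages the full inference chain as tested, reusable functions plus a
command-line interface, with a synthetic-data module that generates every
input with known ground truth.

## What it computes

**ILS machinery.** Gene trees are simulated under the multispecies
coalescent (MSC) within a species tree measured in coalescent units. For an
internal branch of length *t*, the species-tree quartet resolution appears
with probability

    q1 = 1 - (2/3) exp(-t),

each minor resolution with (1/3) exp(-t). The package tabulates quartet
frequencies over all four-taxon subsets, computes per-branch supports
(q1, q2, q3), inverts the formula to estimate branch lengths in coalescent
units, and estimates per-branch

    theta = (mutation-unit length) / (coalescent-unit length),

a proxy for ancestral population size and hence ILS intensity (no factor of
2; see the methods vignette). `run_ils_assessment()` compares an empirical
gene-tree set against a with-ILS simulation and a no-ILS baseline
(theta = 0.001) by `lm()` regression of quartet frequencies and by
chi-square tests on the two minor topologies around each focal branch.
`classify_split_support()` scores splits as strongly/weakly
supported/rejected with a 75% contraction rule.

**Polyploidy machinery.** Copy-labeled collinear gene trees are classified
by the unrooted quartet on the copies — `((A1,A2),(B1,B2))` supports
independent WGDs in A and B, cross pairings a shared one (3+3 copies
handle triplications). Ks distributions are summarized by per-block medians
and fitted with a deterministic Gaussian-mixture EM; LTR retrotransposon
insertions are dated by `T = K / (2r)` with r = 3.8e-9 per site per year by
default.

## Worked example

```r
library(ilsq)

# A stated synthetic world: 7 taxa, internal branches 0.2-1.2 coalescent
# units, true theta 0.1 on every branch.
world <- gen_species_tree(n_taxa = 7, cu_range = c(0.2, 1.2),
                          mu_theta = 0.1, seed = 1)

# An "empirical" collection: 20,000 MSC gene trees from that tree.
empirical <- simulate_gene_trees(world$coalescent, n_trees = 20000,
                                 seed = 101, keep_trees = FALSE)

report <- run_ils_assessment(empirical, world$mutation, world$coalescent,
                             sim_config(n_trees = 20000, seed = 202))
report
#> ILS assessment (20000 simulated trees, seed 202)
#>   R^2 with-ILS sim vs empirical: 0.9999
#>   R^2 no-ILS (theta = 0.001) vs empirical: 0.9075
#>   theta range on shared branches:  0.100 - 0.100
#>   chi-square on minor topologies (4 focal branches):
#>                split      chi_sq df     p_value   p_adj_bh
#>          s01,s03,s04 2.997318210  1 0.083402466 0.16680493
#>      s01,s03,s04,s05 1.928709273  1 0.164899726 0.21986630
#>  s01,s02,s03,s04,s05 8.638278610  1 0.003291723 0.01316689
#>  s01,s02,s05,s06,s07 0.002075551  1 0.963662376 0.96366238
```

Read: the empirical discordance pattern is essentially identical to the
with-ILS expectation (R² = 0.9999) and visibly less like the no-ILS
baseline (R² = 0.9075); theta is recovered at its true value 0.1 on every
internal branch. The chi-square column illustrates the caveat documented in
the vignette — with multi-taxon groups the pooled test runs
anti-conservative, so one of four null branches dips below 0.05 here.

```r
ks <- gen_ks_mixture_sample(data.frame(weight = c(0.6, 0.4),
                                       mean = c(0.5, 1.07),
                                       sd = c(0.15, 0.2)),
                            n = 2000, seed = 1)
fit_ks_mixture(ks$values, k = 2)
#> Gaussian mixture fit to 2000 Ks values (k = 2 )
#>   component 1: weight 0.618, mean 0.507, sd 0.159
#>   component 2: weight 0.382, mean 1.071, sd 0.199
#>   logLik -385.07, BIC 808.15, converged in 46 iterations
#>   Ks peak (heaviest component): 0.507

copies <- gen_wgd_copy_trees("independent_wgd", n = 200, noise = 0.2,
                             seed = 1)
independent_wgd_proportion(copies$trees, "A", "B")$proportion
#> [1] 0.845

ltr_insertion_time(0.0076) / 1e6   # Myr
#> [1] 1
```

Both mixture components land within 0.01 of their true means; with 20% NNI
noise on independent-WGD backbones, 84.5% of trees still support the
independent event (expectation 1 - noise = 0.8).

## Command line

```sh
CLI=$(Rscript -e 'cat(ilsq::ilsq_cli())')
Rscript $CLI simulate --species-tree sp.nwk --n 20000 --seed 1 --out gts.nwk
Rscript $CLI ils-report --empirical gts.nwk --mu-tree mu.nwk \
        --cu-tree cu.nwk --n 20000 --seed 1 --out report/
Rscript $CLI wgd-classify --trees copies.nwk --species-a A --species-b B \
        --out wgd.json
Rscript $CLI ks-fit --ks ks.tsv --k 2 --out fit.json
Rscript $CLI synth --scenario msc --n 1000 --seed 1 --out synth/
```

Every subcommand with a `--seed` is byte-deterministic across runs.

## Documentation

The methods vignette (`vignettes/discordance-and-polyploidy.Rmd`) documents
the model and its assumptions, every tunable with units and defaults, the
synthetic world and what a green test does and does not establish, numerical
choices, and known limitations (30-taxon bitmask cap, pooled chi-square
anti-conservatism, no reticulation or gene-tree error modeling).
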