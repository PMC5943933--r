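---
title: "Inferring fitness relationships among cancer drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring fitness relationships among cancer drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitnessnet)
```

## Model

Somatic driver alterations are under selection, and the selective advantage
of one driver often depends on the state of pathways surrounding *other*
drivers. `fitnessnet` operationalizes this as follows.

**Inputs.** A gene expression matrix over tumor and normal samples; an
undirected background gene interaction network; a list of driver genes; a
binary mutation profile (which samples carry a non-synonymous alteration of
each driver); optionally a directed signaling network for validation.

**Expression preprocessing.** Rows with duplicated gene symbols are
averaged, then every row is z-scored across samples using the unbiased
(n − 1) standard deviation. Zero-variance rows are set to zero and flagged
rather than dropped, so the network universe is stable.

**Module activity and score.** For a gene set *M*, the activity of a sample
is the mean z-scored expression of the members. The module score is the
absolute Welch *t*-statistic of tumor vs. normal activity. Welch's form was
chosen over the pooled-variance *t* because the two conditions have no
reason to share a variance, and over rank statistics because activity is
already an average of z-scores and approximately continuous.

**Stochastic greedy search.** Starting from a driver seed, at each step we
enumerate *all* network neighbors of the current module whose addition
improves the score by more than an `improvement_threshold` (default 0.05,
interpreted as *relative* gain `(S' − S)/S`; when the current score is
exactly zero the absolute gain is used so growth can start). One eligible
neighbor is chosen uniformly at random; growth stops when no neighbor is
eligible or the module reaches `max_module_size` (default 30). Repeating
the walk (`n_iter`, default 5000) samples the landscape of
expression-coherent neighborhoods instead of committing to a single local
optimum. Duplicate modules are collapsed with a multiplicity `count`, and
every downstream fraction uses the multiset.

**Differential expression.** Per-gene significance uses a label-permutation
test on the absolute Welch *t*-statistic with an add-one estimator,
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, tie-tolerant at 1e−9 so that
floating-point noise in recomputed statistics cannot flip a tie.
Benjamini–Hochberg adjustment controls FDR at `alpha` (default 0.05). BH is
appropriate because gene-level tests are positively dependent at worst and
FDR, not FWER, is the quantity of interest for a screening step.

**Module filtering.** A candidate module of size *m* containing *k*
differentially expressed genes out of *K* in a universe of *N* network
genes is kept if its one-sided hypergeometric enrichment
`P(X ≥ k)` survives BH at 0.05. The universe is the intersection of
expression and network genes, because only those genes were reachable by
the search.

**Fitness network.** The weight of the directed edge *d → u* is the
fraction of *d*'s retained modules (with multiplicity) that contain driver
*u*. The denominator is the number of *retained* modules, not the number of
sampling iterations: an edge weight should measure conditional dependence
among meaningful modules, not the seed's raw yield.

**Fitness core.** The indegree ratio of node *u* is
`indegree / (indegree + outdegree)` over unweighted edges; the core is
`{u : IDR(u) > δ}` with a strict inequality and δ = 0.7 by default. A
strict threshold keeps balanced hubs (IDR exactly δ) out of the core.

## Validation statistics

**Mutation coverage.** With Γ(g) the set of samples altered in *g*,
coverage of a gene set is `|∪ Γ(g)|`. *Relative* coverage is
`|Γ(core) ∩ Γ(non-core)| / |Γ(non-core)|`; *absolute* coverage is
`|Γ(core)| / |Γ(core) ∪ Γ(non-core)|`. Both print as
`(denominator, numerator, ratio)` with four decimals.

**Co-occurrence / exclusivity.** For drivers *u*, *v* the 2×2 table
`[[|U∩V|, |U\V|], [|V\U|, |rest|]]` over the sample universe is tested with
one-sided Fisher tests: the upper tail calls co-occurrence, the lower tail
calls mutual exclusivity; the two calls are mutually exclusive by
construction. A `two_sided` variant is available behind a flag for
conservative reporting.

**Edge classes.** With a fixed core, edges fall in four classes
(non-core→non-core, core→core, non-core→core, core→non-core); class
enrichment at each weight cutoff is tested against the universe of all
ordered node pairs.

**Signaling continuity.** A fitness edge *d → u* is *continuous* if *u* is
reachable from *d* in the directed signaling network
(`igraph::distances(mode = "out")`), *unmapped* if either endpoint is
absent. Enrichment compares continuous fractions of fitness edges against
all mapped ordered pairs.

**Consensus.** The consensus of several fitness networks keeps edges
present in *all* of them, with the mean weight. Weight filtering is closed
(`weight ≥ cutoff`), and the default cutoff sweep uses step 0.005 (201
cutoffs on [0, 1]).

## Synthetic data: scope and limitations

All shipped experiments run on synthetic instances; the generator defaults
*are* the study conditions and are never tuned per run.

```{r spec}
unlist(synthetic_spec()[c("n_genes", "n_tumor", "n_normal", "n_mut_samples",
                          "n_drivers", "module_size", "effect_size",
                          "mutation_rate", "seed")])
```

An instance consists of a preferential-attachment background network
(`igraph::sample_pa`, m = 2) of 150 genes, 25 + 25 samples of unit
Gaussian noise with one planted module of size 5 shifted by 2 standard
deviations in tumors, 15 drivers, Bernoulli(0.15) mutations over 60
samples with one planted co-occurring pair and one planted exclusive pair
(strength 1 = deterministic), and one planted signaling path. The second
module member is promoted to driver, creating a known ground-truth fitness
edge. These sizes were chosen so a full pipeline run completes in seconds
on one CPU while leaving the planted signal comfortably detectable but not
trivial (effect 2 sd on 25 + 25 samples gives per-gene power well below 1,
so the *module*-level pooling is genuinely exercised).

What the synthetic scope does **not** cover: copy-number–driven expression
effects, tumor purity and subclonality, correlated (pathway-structured)
noise, and scale (real cohorts have ~20,000 genes; the search cost is
linear in iterations and roughly linear in module size × mean degree, so
scaling is a matter of time, not algorithm). Conclusions about real cohorts
require real data through the same entry points (`read_expression()`,
`read_network()`, `read_mutations()`, `read_drivers()`).

## Worked run

```{r run}
inst <- generate_worked_example()
degs <- detect_degs(inst$expression, n_perm = 500, seed = 5)
fit <- suppressMessages(
  fit_fitness_network(inst$expression, inst$network, inst$drivers,
                      cfg = sampling_config(n_iter = 200, seed = 6),
                      degs = degs))
tidy(fit)
glance(fit)
indegree_ratio(fit$network)
```

The planted dependency (`r inst$truth$planted_pairs[[1]]$source` →
`r inst$truth$planted_pairs[[1]]$target`) is recovered at full weight.

## Numerical choices

* Permutation p-values use the add-one estimator, so 0 is never reported
  and the minimum is `1/(1 + n_perm)`; a warning fires when that floor
  cannot reach `alpha`.
* All tail tests (`phyper`, `fisher.test`) come from base R; the test suite
  re-derives them with explicit `choose()` sums on small instances.
* Edge weights are written with full precision (17 significant digits) so
  written networks round-trip exactly.
* Every stochastic entry point takes an explicit seed; module sampling uses
  one seed per driver (offset by driver index) so per-driver results do not
  depend on driver order.
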