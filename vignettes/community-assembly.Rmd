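---
title: "Null models and gene-set constraints for gill symbiont communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models and gene-set constraints for gill symbiont communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gillsym)
```

## The system and the questions

Shipworms (wood-boring bivalves of the family Teredinidae) carry
intracellular bacterial endosymbionts in a gill organ, and each host
individual harbors a small community — typically one to five species —
drawn from a modest pool of candidate symbionts. Two questions drive the
analyses in this package:

1. **Is community composition random?** Given each host's observed
   symbiont richness, would random assembly from the candidate pool
   explain the observed combinations, the never-observed pairs, and the
   ubiquity of nitrogen-fixing members?
2. **What must a community minimally encode?** Since every observed
   community supported a living host, the intersection of the gene
   complements of observed communities bounds the core gene set (nitrogen
   fixation genes, lignocellulose-active CAZymes) required for host
   survival.

## The richness-preserving null model

All null-model machinery conditions on the observed per-host richness
$k_i$: each host is re-assigned a uniformly random $k_i$-subset of the
$S$-species pool, independently across hosts. Richness is preserved
because it is confounded with host condition and sampling depth; only
species *identity* is randomized.

Three exact consequences of this null are used directly:

* **Pair inclusion.** A fixed pair of species is included in a random
  $k$-subset with probability
  $\binom{S-2}{k-2}/\binom{S}{k} = \frac{k(k-1)}{S(S-1)}$, zero for
  $k < 2$ (`pair_inclusion_prob()`). For the pool of 7 this is
  $\binom{5}{k-2}/\binom{7}{k}$.
* **Exact absence test.** For a pair never observed together, the
  probability of zero co-occurrences across all hosts is the
  Poisson-binomial zero-success probability
  $\prod_i (1 - p_i)$ with $p_i$ the per-host inclusion probability
  (`pair_absence_test()`). BH and Holm corrections are applied across
  the tested pairs.
* **Guarantee probability.** With $m$ designated species (the nitrogen
  fixers), a host of richness $k$ misses all of them with probability
  $\binom{S-m}{k}/\binom{S}{k}$, so the chance that *every* host holds
  at least one is $\prod_i \left(1 - \binom{S-m}{k_i}/\binom{S}{k_i}\right)$
  (`guarantee_prob()`). It is 1 for an empty cohort, 0 whenever some
  host has richness 0, and monotone in both $m$ and each $k_i$.

For whole-combination frequencies the null is sampled instead
(`mc_randomize()`): the count of hosts whose community exactly equals a
fixed $k$-combination is Binomial$(n_k, 1/\binom{S}{k})$ under the null
(`exact_combination_null()` is the closed-form oracle, used in the test
suite to calibrate the sampler), but the joint behaviour across the
whole family of combinations is most conveniently summarized by
simulation.

### Monte Carlo choices

* **Replicates.** 10 000 by default; the standard error of a null mean
  is then below $0.01\sqrt{n}$ counts.
* **Two-sided p-value.** $p = \min\!\big(1,\; 2\min(N_{\ge} + 1,
  N_{\le} + 1)/(R+1)\big)$, where $N_{\ge}$ ($N_{\le}$) counts
  replicates with a frequency at least (at most) the observed one. The
  add-one correction keeps a combination more extreme than every
  replicate at $2/(R+1)$ rather than 0; it can be disabled via
  `null_config(pseudocount = FALSE)`.
* **Family for multiplicity.** All combinations whose size occurs among
  the specimens (`universe = "sizes_present"`), the choice that tests
  every combination the randomization can actually produce without
  inflating the family with impossible sizes. `all_nonempty` and
  `observed_only` are available; the family used is recorded in the
  output.
* **Envelope.** The reported null envelope uses order statistics at
  indices $\lfloor R(1-\gamma)/2 \rfloor$ (at least 1) and
  $\lceil R(1+\gamma)/2 \rceil$ with $\gamma = 0.95$: no interpolation,
  so the bounds are achievable integer counts.
* **Determinism.** A single RNG stream seeded from
  `null_config(seed = )`; identical seeds give identical output, which
  the pipeline relies on for byte-identical reruns.
* **Degenerate inputs.** Aposymbiotic (empty) specimens contribute
  nothing to any combination and are excluded from the randomization
  but reported; a specimen with $k = S$ is legal and simply always
  receives the full pool.

## Detection threshold and richness

Presence is abundance strictly greater than a percent threshold
(`derive_presence()`), default 0 (any mapped reads count as detection).
No single threshold is canonical — it trades sensitivity against
index-hopping and mapping noise — so the threshold is recorded in the
presence matrix and in every downstream output, and changing it changes
richness and therefore every null-model quantity. Richness summaries use
the sample (n−1) standard deviation.

The taxon pool defaults to the columns of the abundance table (the union
of taxa ever detected, $S = 7$ in the system this package models) and
can be widened explicitly; the null models need $S$ even for taxa absent
from a particular subset of specimens.

## Gene-content constraints

**Nitrogen fixation.** The prediction rule is purely structural: a
genome is called a fixer if and only if it encodes all six essential
core classes *nifH, D, K, E, N, B*. Regulatory (*nifA, L*) and accessory
(*nifM, S, T, U, V, W, Q, Z, J*) classes never enter the call — *nifJ*
in particular occurs in genomes of non-fixers, so its absence does not
revoke a prediction and its sole presence does not create one. The rule
is monotone: adding classes never turns a fixer into a non-fixer.

**Sufficient communities.** Every observed community supported a living
host, hence must supply all symbiont-dependent functions. Only the
*minimal* observed communities bind the intersection: an observed
community with an observed strict subset is dropped
(`sufficient_communities()` returns the minimal antichain). On the
co-occurrence patterns this package models — where two species each
occur alone and one pair has no observed sub-community — the antichain
rule reproduces the manually curated choice of two singletons plus one
pair, and it generalizes to any dataset.

**Core sets.** A community's gene complement is the union over members;
the core is the intersection of these unions across sufficient
communities (`core_gene_set()`), which is antitone in the set of
communities. The lignocellulose-active subset is selected by substrate
tags (`lignocellulose_filter()`), with a controlled vocabulary covering
the structural polymers of wood (cellulose, xylan, mannan, β-glucan,
xyloglucan, arabinan, galactan, lignin) and their degradation
oligosaccharides, plus an editable alias table for the substrate-string
variants emitted by annotation pipelines. Subfamilies with no substrate
annotation are treated as non-matching and counted, never silently
dropped.

**Diversity versus richness.** Lignocellulose-active CAZyme diversity is
the number of unique lignocellulose-active subfamilies per gill
metagenome — the union over community members (default), because the
community is the functional unit that digests wood for the host. A
per-MAG mode is retained for genome-level comparisons. Groups defined by
richness are compared with a Kruskal–Wallis test; when the omnibus test
is significant at α = 0.05, Dunn's post hoc test with Holm correction
follows, summarized by a compact letter display (greedy insertion in
mean-rank order; groups sharing a letter are not significantly
different). Running the post hoc without a significant omnibus is a
precondition violation unless forced.

## Species delimitation

Genome bins are clustered into species on an undirected graph with an
edge wherever symmetrized gANI > 95 and alignment fraction > 0.60 (both
strict), taking connected components — single-linkage semantics. With
the strongly bimodal identity structure typical of these symbionts
(within-species gANI ≫ 98, between-species pairs too distant for the
ANI tool to report at all), the linkage choice is inert, but it is
stated because other datasets may place values near the cutoffs. ANI is
asymmetric; reciprocal records are combined by arithmetic mean
(configurable to min/max), and a single available direction is used
as-is. Missing pairs are treated as below threshold, mirroring tools
that omit distant comparisons. Representatives are chosen by the
conventional dereplication score completeness − 5 × contamination, with
ties broken by lower strain heterogeneity, then genome id.

## The synthetic-data generator

`simulate_dataset()` emulates the study design this package models: 36
specimens in two host groups (14 + 22) drawing communities from a pool
of 7 species, 3 of them nitrogen fixers. Choices, and what they do and
do not emulate:

* **Richness distributions** are per-group categorical distributions
  over k = 1..5; the defaults put means at 2.2 (max 3) and 2.7 (max 5),
  matching the published cohort summaries.
* **Enrichment** multiplies the sampling weight of exact combinations
  (the tested unit is the exact community, matching how patterns are
  counted); with no enrichment the generator *is* the null model, which
  is what makes the family-wise error checks meaningful.
* **`require_fixer`** uses rejection sampling so the richness marginal
  is untouched; the acceptance rate is recorded in the truth sidecar.
* **Abundances** are symmetric Dirichlet (concentration 1 by default)
  over community members; **depth** is log-normal with mean 1e6 reads
  and sdlog 0.3 — a deliberately simple noise model. Real metagenomes
  add compositional biases, mapping ambiguity between close relatives,
  and index hopping; passing tests on synthetic data therefore
  validates the *statistical machinery*, not robustness to those
  artifacts.
* **Catalogs** plant a known core (58 subfamilies, 23
  lignocellulose-tagged) plus disjoint private subfamilies per taxon,
  and nif complements that mirror the published gene-class table
  (fixers with all 17 classes, one fixer lacking *nifJ*, one non-fixer
  with *nifJ* alone), so core-recovery and fixer-prediction tests have
  exact expected answers.
* **ANI simulation** draws within-cluster gANI from U(97, 100) and AF
  from U(0.85, 1), omitting between-cluster records by default.

Test problem sizes were chosen so the full suite exercises 10 000-replicate
randomizations on 36-specimen cohorts, 50-run error-control and power
batches, and enumeration oracles up to a few thousand assignments.

## Reconstructed cohort profile

The per-specimen richness values of the published cohort are not
redistributed with this package, so `reconstructed_richness_profile()`
provides a synthetic stand-in constrained to match every printed
summary: group sizes, rounded means and sample standard deviations,
maxima, and the counts of sole-symbiont specimens. Those constraints pin
the composition almost completely. The nitrogen-fixer guarantee
probability computed on this profile is 3.0 × 10⁻⁵ — the same order as
the published bound (< 3 × 10⁻⁵), but the quantity is sensitive at the
percent level to the exact unobserved composition, which is why the test
suite asserts its order of magnitude rather than the printed inequality.
The profile supports cohort-level quantities that depend only on the
richness distribution; it cannot reproduce pattern-level results (e.g.
the number of distinct co-occurrence patterns), which require the true
specimen-by-taxon table.

## Known limitations

* Detection is threshold-based on relative abundance; there is no
  modelling of false-positive mappings between closely related genomes.
* The null model gives every species equal selection probability;
  prevalence- or abundance-weighted nulls (fixed-fixed swaps, C-score)
  are out of scope by design — the equal-probability null is the
  hypothesis being tested.
* The Monte Carlo power to detect an enriched combination is limited by
  the two-sided add-one p-value and Holm correction; with 22 specimens
  and a tenfold weight on one triplet, detection probability is near
  0.6, not 1 (measured in the acceptance suite).
* Dunn's z is two-sided; one-sided alternatives are not implemented.
* The dbCAN-overview reader handles the common tabular dialect (tool
  columns plus a support count); exotic variants may need pre-mapping.
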