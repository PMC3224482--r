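---
title: "Reverse causal reasoning on signed causal networks: models and methods"
author: "stressrcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse causal reasoning on signed causal networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressrcr)
```

## The problem

A transcriptomic comparison between two conditions — say cigarette-smoke
exposed versus sham-exposed mouse lung — yields a list of genes whose mRNA
levels changed significantly, each with a direction. The list itself says
little about *mechanism*. Reverse causal reasoning (RCR) turns the question
around: given a knowledge graph of signed causal assertions
("the transcriptional activity of Nfe2l2 increases the mRNA of Nqo1"),
which upstream entities, if their activity had increased or decreased, would
best explain the observed pattern of changes? Each candidate entity plus a
direction is a *hypothesis*, and hypotheses are scored probabilistically
rather than asserted.

This package implements the full stack: the network data model, the
state-change caller that produces the directional gene lists, the scoring
engine, downstream coverage/pattern analytics, and a synthetic benchmark
generator with planted ground truth.

## The network model

Nodes are *functionalized* biological entities written in a compact grammar
`tag(entity)`: `r(Nqo1)` is an mRNA abundance, `p(Keap1)` a protein
abundance, `taof(Nfe2l2)` a transcriptional activity, and so on across a
closed ten-category vocabulary (`term_functions()`). Edges are directed and
signed (+1 increases, −1 decreases), annotated with species, tissue context
and PMID evidence. Non-causal edges merely connect functional forms of one
entity (an mRNA to its protein) and are excluded from all inference. Edge
identity is the tuple (source, target, sign, causal); re-asserting an edge
merges its evidence. Edges with identical endpoints and opposite signs are
deliberately both retained — context-dependent regulation is real biology —
and such pairs later surface as sign-ambiguous signature entries.

The canonical serialization is a tab-separated edge list
(`parse_network_tsv()` / `export_graph()`), with SIF and GraphML export for
visualization tools. Two serialization details are package conventions: the
`blocks` column accepts `source:`/`target:`-qualified building-block labels
(a bare label applies to both endpoints), and isolated nodes are written as
rows with relation word `node`, so that parsing an exported file reproduces
an equal model exactly.

Entity names are opaque symbols: no ortholog mapping is attempted between
species naming conventions, because no mapping rule is defensible without
external annotation.

## Calling state changes

`state_changes()` implements the standard two-group microarray filter chain:

1. **Quantile normalization** (`quantile_normalize()`, via
   `limma::normalizeQuantiles` with tie averaging): each sample is forced
   onto the common distribution of sorted-row means. Normalization always
   precedes testing.
2. **Per-probe test** (`differential_test()`): on the log2 scale, the log2
   fold change is the difference of group means and the raw p-value comes
   from a pooled-variance two-sample t statistic. A moderated
   (variance-shrunk) statistic would differ for very small replicate
   numbers, but the downstream logic consumes only the filter chain, so the
   plain pooled test keeps the pipeline transparent and exactly testable
   against the textbook formula. Linear-scale input containing zeros is
   offset by +1 before the log transform.
3. **Benjamini–Hochberg adjustment** (`bh_adjust()`).
4. **Thresholds** (`call_state_changes()`): a probe passes iff adjusted
   p < 0.05 *and* linear |fold change| > 1.3 (both strict), and, when the
   abundance filter is enabled, mean intensity > 250. The abundance filter
   is off by default — it is appropriate for platforms where low-intensity
   probes are noise-dominated, and 250 is the documented conventional floor.
5. **Gene collapse**: a gene changed if at least one of its probes passed.
   A gene whose probes pass in *both* directions has no defensible
   direction: it is dropped from the change list (logged in the
   `conflicting` attribute) but kept in the measured population, which
   avoids fabricating a direction. The population of measured genes is
   independent of the thresholds by construction.

## Scoring hypotheses

For every network node, its *downstream signature* is the set of measured
mRNAs it causally controls, each with the sign it takes when the node's
activity increases (`build_signatures()`). A node needs at least
`min_downstream_measured = 4` measured targets to be scored at all — with
fewer, no meaningful prediction is possible. A node's own mRNA is excluded
from its signature: a hypothesis must not explain itself.

Each eligible node is scored in both directions against the state changes:

- **Richness** (`score_richness()`) is the hypergeometric upper tail
  P(X ≥ k) of drawing k state changes when the node's n targets are drawn
  from a population of N measured genes containing K state changes. It asks:
  is this node *connected* to the changes more than chance predicts?
- **Concordance** (`score_concordance()`) is the binomial upper tail
  P(X ≥ c) of observing c direction-consistent overlaps among c + contra
  directional trials under a fair coin. It asks: do the *signs* agree with
  the hypothesized direction? Sign-ambiguous overlaps count toward k (they
  are evidence of connectivity) but are excluded from the concordance
  trials (they carry no directional information).

A hypothesis is significant when richness p < 0.1, concordance p < 0.1, and
c ≥ `min_correct = 4` consistent changes — the conventional operating point
for this class of analysis. These are screening cutoffs on raw p-values;
significance is statistical, not biological, and no multiple-testing
correction is applied across hypotheses by default (a BH option exists).
Both directions are always reported; `best_direction()` gives the
one-row-per-term view, ties broken toward increase for determinism.

Two genuinely open design points are resolved as configuration:

- **The hypergeometric universe.** The default population N is *all measured
  genes* after probe mapping; the alternative
  (`population_mode = "all-network-downstream-measured"`) restricts N to
  measured genes downstream of at least one network node. Neither choice is
  canonical; the default is the larger, more conservative universe.
- **Direction reporting.** Scoring both directions is the superset of any
  single-direction convention, so nothing is lost.

## Coverage, overlap and prediction patterns

`coverage()` reports the fraction of state changes "explained": a change in
gene g is explained if some significant hypothesis has a causal edge to
r(g) whose implied direction (edge sign × hypothesis direction) matches the
observed direction. Direction consistency is required by default because a
direction-blind rule inflates coverage arbitrarily; the permissive variant
is available via `require_sign_match = FALSE`. `coverage_by_nodes()`
restricts the explaining set, e.g. to a single master regulator.
`overlap_statistics()` intersects state-change sets by gene and by
gene+direction, reporting fractions against both sets, since the
denominators differ for sets of unequal size.

`assign_clusters()` classifies a term's significance calls across the
classic three-comparison perturbation design (c1 exposed-vs-sham in the
reference genotype, c2 exposed-vs-sham in the perturbed genotype, c3
perturbed-vs-reference under exposure) into lettered patterns A–E, applied
in order with first match winning. Two edge conventions are fixed here
because no rule is otherwise forced: cluster A requires *no* call in c2
(patterns with c2 = c1 fall through to B), and cluster E requires c3 = 0 (a
significant c3 with c1 = 0 is unclustered).

## The synthetic benchmark generator

`synthetic_spec()` / `simulate_rcr_experiment()` generate a bipartite
regulator → transcript network, a planted state-change realization, and an
expression matrix realizing it. The generator emulates exactly the
statistical structure RCR assumes — signed one-hop signatures plus noisy
direction agreement — and nothing more: no multi-hop cascades (the scoring
is one-hop, so depth adds no testable behaviour), no probe effects,
saturation, batch structure or tissue heterogeneity. Passing benchmarks
therefore demonstrates the *inference machinery*, not robustness to real
microarray artefacts.

Defaults are the package's reference conditions: 50 regulators, 2000 genes,
Poisson out-degree with mean 8 (floored at 1), 5 active regulators,
direction-agreement probability q = 1, background change rate b = 0, 5
samples per group, log2 effect 2, log2 noise 0.1. Noise in direction
agreement is split by `flip_prob` (default 0.5): a non-concordant target
flips direction with half the mass and stays unchanged with the other half,
making concordance power tunable independently of richness power.

Two identifiability choices are built in, and both follow from the exact
recovery guarantee the generator is designed to support:

- **Disjoint target sets.** By default each regulator's targets are sampled
  without global replacement. With q = 1 and b = 0 this makes recovery
  *exactly* provable: every active regulator with at least 4 targets is
  significant in its planted direction (richness tail is astronomically
  small, concordance is 0.5^n ≤ 0.0625 < 0.1), and every inactive regulator
  has overlap k = 0, hence richness 1, hence can never be significant.
  Shared targets (set `allow_shared_targets = TRUE`) reintroduce the
  real-world possibility that two regulators imply conflicting directions
  for one gene, which breaks the exactness of the guarantee.
- **Eligible active sets.** When the active set is not given explicitly, it
  is drawn deterministically from regulators with out-degree ≥ 4,
  alternating directions. An active regulator with fewer measured targets
  than the eligibility minimum is unrecoverable by construction, so
  planting one would only test the sampler, not the method.

All randomness flows from the single spec seed through fixed per-stage
sub-seeds, so network, state changes and expression are independently
reproducible.

### What the benchmarks show

At the reference conditions the test suite verifies (sizes chosen to keep
each property decisive at interactive scale):

- the scoring functions agree with exhaustive placement enumeration for all
  populations N ≤ 12 and with explicit binomial tail sums for up to 30
  trials, to 1e-12;
- with q = 1, b = 0, planted-regulator precision, recall and direction
  accuracy are 1 at 20 consecutive seeds;
- the expression pipeline recovers ≥ 95% of planted state changes with
  correct direction (effect 2, noise 0.1, 5v5) at pinned seeds, and the
  state-change count is monotone in every threshold over 100 random
  matrices.

In the noisy regime (q = 0.8, b = 0.02) mean precision stays ≈ 1, while
mean recall settles near its analytic value of ≈ 0.72: averaging the
trinomial distribution of (consistent, contradicting, absent) target
outcomes over the degree distribution, configurations such as c = 5 with
one contradiction (concordance 7/64 = 0.109) narrowly miss the 0.1 cutoff.
This is a property of the operating point, not of the implementation, and
the corresponding benchmark records it as such.

### Known limitations

- Quantile normalization maps each column's extreme order statistics to the
  mean of extremes, so planted effects on genes at the very edge of the
  intensity range are compressed; at small gene counts this occasionally
  costs a planted state change the fold-change cutoff.
- The pooled-variance test is anti-conservative for tiny replicate numbers
  relative to moderated alternatives; with the default 5v5 benchmark this
  is immaterial, but users with n = 2–3 per group should interpret raw
  p-values cautiously.
- `synthetic_stress_network()` is a deterministic stand-in whose *summary
  statistics* (node-category counts, edge totals, species split, evidence
  counts, tissue composition) match a published reference-scale stress
  network; its wiring is arbitrary, and it exists to exercise parsing,
  export and counting at realistic scale — not to support biological
  conclusions.

## A worked example

```{r example}
f <- system.file("extdata", "mini_stress_network.tsv", package = "stressrcr")
net <- parse_network_tsv(f, name = "mini-stress")
net

pop <- c("Nqo1", "Hmox1", "Gclc", "Gclm", "Prdx1", "Txnrd1", "Cyp1a1",
         "Cyp1b1", "Ahrr", "Hspa5", "Ddit3", "Xbp1", "Herpud1", "Vegfa",
         "Slc2a1", "Ldha", "Epo", paste0("Z", 1:80))
scs <- state_change_set("CS 1d vs sham", pop, data.frame(
  gene = c("Nqo1", "Hmox1", "Gclc", "Gclm", "Prdx1", "Hspa5", "Ddit3"),
  direction = "increased"))

fit <- rcr(net, scs)
fit
coverage(scs, fit, net)
```

The oxidative-stress master regulator is called increased and its
repressor decreased — the loss-of-repressor reading of the same evidence —
while the ER-stress factor, with only two of its four targets changed,
stays below significance.
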