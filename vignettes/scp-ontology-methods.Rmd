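---
title: "Methods: populating, relating and dynamically enriching an SCP ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: populating, relating and dynamically enriching an SCP ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scptools)
```

## The model

An SCP ontology is a rooted 5-level tree. The level-0 root stands for
whole-cell function; level-1 nodes are broad chapters of cell biology
(cytoskeleton dynamics, metabolism, ...); levels 2–4 refine them down to
individual pathways and small networks. Every node has exactly one parent
one level up, so siblings ("children set") partition their parent's scope.
Two assumptions drive everything in this package:

1. **Literature evidence is competitive.** An abstract set retrieved for
   one SCP also mentions genes that really belong to neighbouring SCPs
   (cargo proteins in endocytosis abstracts, glycosylated substrates in
   glycosylation abstracts). A raw mention count is therefore not
   evidence of membership; what is informative is how *selectively* a
   gene's mentions concentrate in one SCP compared to the competing SCPs
   of the same level and of the same children set.
2. **Function is contextual.** Whole-cell outcomes engage SCPs from
   different branches of the taxonomy. The competition itself can be
   mined for these cross-branch relationships: if removing SCP A from the
   ontology makes SCP B absorb A's members, A and B draw on the same
   literature and are functionally coupled.

## The population pipeline

`populate()` runs, deterministically:

1. **Abstract minimum.** Pairs below the per-level minimum abstract count
   are removed. Defaults 4/3/2/1 for levels 1–4: higher levels have much
   larger abstract sets, so a fixed count means progressively weaker
   relative evidence and a stricter minimum compensates.
2. **Validation adjustments.** Pairs labeled M (a non-gene term
   misread as a gene) are removed; pairs labeled S (gene belongs to a
   sibling) keep 34% of their count (`sibling_penalty_factor = 0.34`,
   i.e. a 66% reduction) and stay fractional.
3. **Same-level enrichment (levels 2 and 3).** Counts are normalized per
   SCP so each SCP's total equals the level target (3000 for levels 1–2,
   1000 for levels 3–4) — without this, SCPs with huge abstract sets
   would dominate every comparison. Each pair is then scored with the
   one-sided Fisher upper tail against all SCPs of the level, and per
   gene the associations below the largest gap in sorted −log10(p) are
   removed.
4. **Children-set enrichment (all levels).** The same normalization, test
   and cutoff, but against siblings only. This is what separates a gene
   correctly among closely related SCPs, which all score well against the
   whole level. Levels 1 and 4 skip step 3 and are instead gated by
   inheritance (level-1 genes must appear in a level-2 child or level-3
   grandchild; level-4 genes in their level-3 parent): level 1 has too
   few competitors for a same-level comparison to mean much, and level 4
   covers biology too sparsely.
5. **Finalization.** F-labeled pairs are dropped, T-labeled pairs that
   the cutoffs would have removed are reinstated (`origin =
   "reinstated"`), level-3 and level-2 genes are propagated to their
   ancestors (`origin = "propagated"`), and genes are ranked within each
   SCP.

### Numerical choices

* **Contingency tables on the normalized scale.** After normalization the
  SCP's article total *is* the normalization target, so the table is
  `a = round(norm count)`, `a + b = target`, `c = round(sum of the gene's
  normalized counts over the other background SCPs)`, `c + d = (n_bg − 1)
  × target`. Margins stay consistent because every normalized SCP sums to
  the target.
* **Rounding.** Fisher's test needs integers; normalized counts are
  rounded immediately before each test and kept fractional everywhere
  else, so repeated adjustment and renormalization do not accumulate
  rounding error.
* **Underflow.** p-values are clamped to the smallest positive double;
  −log10(p) values entering the gap cutoff are therefore always finite.
* **Largest-gap ties.** Equal maximal gaps resolve toward the top of the
  list (fewest, most selective associations kept — selectivity is the
  point of the cutoff). When *all* values are equal there is no
  informative gap and everything is kept; this also guarantees that two
  siblings with identical count vectors are treated symmetrically and
  that a tie group is never split.
* **Single-SCP genes.** A gene observed in only one background SCP has no
  gap to compute and is kept.
* **Ranking key.** Within an SCP genes are ordered by ascending
  children-set p-value, ties by descending adjusted count, then
  alphabetically. The children-set p-value is the one score every
  populated level shares (same-level p-values do not exist for levels 1
  and 4). Propagated rows carry no p-value and sort last.

## Leave-one-out relationship inference

`infer_scp_edges()` removes one level-3 SCP at a time, re-populates the
level (`repopulate_without()`), and scores each remaining SCP by how
strongly it absorbs the removed SCP's members (`score_competition()`): a
member gene that newly enters an SCP of prior size N at rank r contributes
max(0, (N + 1) − r); a member already present contributes its rank
improvement, worsened ranks contribute nothing. The per-SCP sum divided by
N is the edge weight.

Decisions made here:

* The scoring counts **positional improvements** (numeric rank value
  decreasing); that is the only reading under which "a gene's rank
  increased" and "sum of rank decreases" describe the same event.
* In leave-one-out runs only M-labeled removals apply; F-labeled pairs
  are kept. Re-populating without the full false-positive removal keeps
  the competition honest — the inference should see the raw competitive
  landscape, not the manually cleaned one. The S penalty and the T
  shield, which adjust evidence rather than remove pairs, still apply.
* "Members" of the removed SCP are its T-labeled pairs when validation
  labels exist; for unlabeled corpora (all synthetic runs) the baseline
  populated gene set stands in.
* A remaining SCP that was empty at baseline is skipped: normalizing by
  its prior size (zero) is undefined.
* Edges are directed (removed → remaining) for scoring; unit building
  and network extraction treat them as undirected with the max of the two
  directions.
* `top_fraction()` keeps `ceiling(q × N)` edges including all edges tied
  at the cutoff score (no order dependence), after dropping edges whose
  endpoints both carry an excluded class tag. "Signaling" membership is a
  node tag inherited from the level-1 ancestor unless a node carries its
  own tags — signaling–signaling relationships mostly reflect shared
  genes, not functional coupling.

## Standard and dynamic enrichment

The enrichment universe defaults to the union of all genes annotated at
the tested level: it is self-contained, reproducible, and does not depend
on an external genome annotation. No multiple-testing correction is
applied by default (targets are ranked by raw p-value, matching how the
results are consumed); Benjamini–Hochberg is available via `adjust =
"BH"`. Units of size 3 accept *any* connected induced subgraph — a path
A–B–C and a triangle both qualify; requiring a path would make the unit
set depend on which of two equally strong edges was inferred first. Every
member SCP of a unit must contain at least one perturbed gene.
`extract_context_network()` breaks ties between equally large components
toward the component containing the best-ranked result, so its output is
deterministic. The published 26%-variant of the edge threshold is just
`q = 0.26`, not a special case.

## The synthetic-data generator

The generator emulates the competitive structure of SCP-specific
literature:

* Every gene has one **primary level-3 SCP**; level-1/2 SCPs own the
  union of their descendants' genes; level-4 SCPs deterministically split
  their parent's members (round-robin), emulating finer sub-processes.
* The number of abstracts mentioning gene g in SCP s is
  `Binomial(abstracts_per_scp, p)` with p = `p_member` (default 0.10) for
  members, the edge rate (default `p_related` = 0.03) for planted leakage
  pairs, and `p_background` (0.002) otherwise. A binomial rather than a
  Poisson keeps counts bounded by the abstract-set size, as per-document
  binarized counting requires.
* Mention rates are scaled per gene by a lognormal **fame multiplier**
  (`gene_rate_sd = 0.8`, mean 1). Real literature counts are heavily
  skewed across genes — well-studied genes are mentioned more often in
  every abstract set. The multiplier cancels in the within-gene
  competitive enrichment (all of a gene's counts scale together) but
  produces the realistic interleaving of within-SCP ranks on which the
  leave-one-out scoring depends: with perfectly homogeneous genes, a
  member entering a foreign SCP always lands at the bottom of the ranking
  and every rank delta clamps to zero.
* Expression profiles mix a per-SCP latent tissue profile with
  independent noise so two genes sharing an SCP correlate at `rho`
  (default 0.5 over 30 tissues), shifted to a non-negative RPKM-like
  scale (offset 8, truncation at 0 — a measure-zero event at this
  offset, so Pearson correlations are unaffected).
* Labels generated from the truth can be flipped at a configurable rate
  and overlaid with planted S/M confusions.

Everything is a pure function of (spec, seed); the caller's RNG state is
restored.

**What the fixtures do not emulate:** real synonym ambiguity and
tokenization noise in abstracts (dictionary quality is exercised only on
small constructed texts), correlated abstract sets between related SCPs
beyond pairwise planted leakage, heterogeneous abstract-set sizes, and
the iterative human validation loop (labels arrive in one batch).
Passing tests therefore demonstrate that the machinery recovers planted
structure under a faithful generative model, not that any particular
biological corpus would be curated correctly.

## Study conditions used by tests and the acceptance script

The recovery study uses 4 level-1 / 16 level-2 / 64 level-3 SCPs, 800
genes, 200 abstracts per SCP, mention rates 0.10/0.03/0.002, and six
disjoint planted leakage pairs at the related-mention rate — large enough
that each level-3 SCP holds ~12 genes and the leave-one-out scan covers
64 re-populations, small enough to run in seconds. Co-expression checks
use 110 genes × 30 tissues (≥ 50 shared and ≥ 5000 background pairs) for
power at `rho = 0.5`, and 200 independent null corpora of 48 genes for
the size of the KS test; the null rejection rate is allowed a generous
band around the nominal 5% because pairs sharing a gene are not
independent observations.

## Known limitations

* The pipeline's precision depends on the taxonomy being roughly
  balanced; a children set with a single populated SCP cannot be
  redistributed (its genes keep p = 1 and survive by default).
* Rank-based leave-one-out scores are coarse for very small SCPs
  (N ≤ 2): a single entering gene can produce a large normalized score.
* `sequential_child_removal()` enumerates 2^k subsets; above
  `max_enumerate` children it samples subsets per removal size, so
  trajectories for very large families are estimates.
* The dictionary matcher is exact token-sequence matching with greedy
  longest-match; it does not do stemming, fuzzy matching, or
  disambiguation beyond the non-gene-class suppression rule, and
  ambiguous synonyms credit every mapped gene.
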