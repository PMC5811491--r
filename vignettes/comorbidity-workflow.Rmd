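---
title: "Comparing the genetic architecture of two comorbid disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the genetic architecture of two comorbid disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The question and the model

Epidemiology can tell us that two disorders co-occur; it cannot tell us why.
`comorbnet` implements one systems-biology answer: compare the two
disorders' curated susceptibility genes at three levels — the genes
themselves, the biological pathways they over-represent, and their shared
neighborhood in the protein–protein interaction (PPI) network — and use the
network to nominate genes plausibly involved in both disorders. The package
was built around the nicotine-addiction/schizophrenia comorbidity, where the
two curated gene sets (276 and 331 genes, each merged from core, prioritized
and association-study evidence lists) share 52 genes, but every stage is
generic over any pair of symbol lists.

### Over-representation statistics

For a disease set with $n$ genes inside a background universe of $N$ genes,
and a term annotating $K$ universe genes of which $k$ are in the disease
set, the enrichment p-value is the hypergeometric upper tail

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

computed with `stats::phyper` (stable for universes far beyond $10^5$
genes). Multiplicity is handled by Benjamini–Hochberg step-up over all terms
tested in one run — one collection, one disease set; families are never
pooled across diseases or across collections, matching how per-run
correction works in the common ORA tools. A term enters testing only when
its overlap reaches `min_overlap` (default 2, configurable); singleton
overlaps are almost never biologically interpretable and inflate the BH
family. The EASE variant (`method = "ease"`), which recomputes the tail with
the overlap reduced by one, is offered for comparability with DAVID output;
the default is the standard tail.

Two gates are conventional and kept as per-collection `alpha` defaults:
$P_{BH} < 0.01$ for pathway collections and FDR $< 0.05$ for GO biological
process. Both are single parameters per run, not hard-coded.

### Background universe

The original analyses ran through hosted tools whose background population
is not documented. We default to *annotation closure*: $N$ is the number of
genes appearing in at least one term of the collection. This is the most
common convention, is fully reproducible from the GMT file alone, and avoids
silently counting unannotatable genes. An explicit user universe can be
supplied to `annotation_collection()`/`read_gmt()`. Input genes outside the
universe reduce $n$ and are reported, never silently tested — untestable
symbols should not deflate anyone's p-values.

### Subnetworks and guilt-by-association

The PPI edge list is cleaned (self-interactions removed, unordered
duplicates collapsed, isolated nodes dropped, with counts reported), then
each disease's genes are mapped as *seeds*. A disease subnetwork holds the
mapped seeds, their *first neighbors*, and — in the default
`"seed_incident"` mode — exactly the edges touching a seed. The source
description of this step names only seeds and first neighbors, and its
reported edge counts are of the same order as its node counts, which is
consistent with seed-incident edges and not with full induced subgraphs;
because the text does not settle the point, `"induced"` mode (which adds
neighbor–neighbor edges without changing the neighbor set) is available as a
config flag for sensitivity analysis.

The shared subnetwork is the node and edge intersection of the two disease
subnetworks, with each node given a role (seed of A only, seed of B only,
common seed, neighbor) from its membership in the *full* input gene lists.
Candidate prediction then applies the guilt-by-association rule: a node that
(i) is not in either input gene list and (ii) interacts directly with at
least `min_degree` (default 5) of the common disease genes present in the
network is reported as a new candidate for both disorders. The degree is
counted against the common genes, not against all shared nodes — that is the
operative sentence of the procedure being modeled — but the target set is an
argument, so other choices are one call away. Seeds missing from the
interactome are tolerated and reported; in the motivating study exactly one
of the 52 shared genes was absent, leaving 51 degree targets.

Ordering of every output table is deterministic (p ascending then term name;
degree descending then symbol; edges lexicographic), and p-values are
serialized in scientific notation with six significant digits, so reruns are
byte-identical.

## What the synthetic generators emulate

The generators exist so every stage can be tested against known ground truth
without downloading 2017-era database snapshots, which are the only way to
reproduce the original numeric tables.

* `generate_annotations()` draws terms of uniform random size (default
  10–50 genes, the typical mid-size pathway range) from the universe.
* `generate_disease_sets()` plants enrichment: each disease set carries
  `ceiling(hit_fraction * |term|)` members of each of its planted terms
  (default `hit_fraction = 0.8`, i.e. strong but not total coverage), the
  two sets share *exactly* `shared_count` genes (drawn preferentially from
  terms planted in both diseases, so shared pathways have ground truth), and
  background fill is sampled outside all planted terms and kept disjoint
  between the sets. The disjointness makes the planted counts exact rather
  than approximate; it also means background genes never blur the planted
  signal, so recovery tests certify the statistics, not luck.
* `generate_ppi()` uses an independent-pair (Erdős–Rényi) background — the
  degree-threshold rule being tested is insensitive to degree-distribution
  shape, and the model admits closed-form edge-count checks (realized
  background counts sit within binomial error of $\binom{n}{2}p$). Planted
  candidates are wired to exactly their requested number of shared genes;
  background edges between candidates and shared genes are suppressed so
  recorded wiring equals realized degree, and (by default) every designated
  shared gene receives at least one interaction so the degree targets all
  exist as nodes. A scale-free/degree-sequence background is noted as future
  work.
* One master seed drives deterministic child seeds per artifact, so a
  fixture bundle is byte-identical across reruns and each artifact can be
  regenerated independently.

The `"paper"` preset of `write_fixture_bundle()` reproduces the study's
operating conditions at desk scale: 2,000-gene universe, 100 terms, disease
sets of 276/331 sharing 52, one shared gene held out of the network, 11
plantable hubs at degrees 5–9 plus 4 sub-threshold decoys.

**What passing these benchmarks does not show:** real interactomes are
scale-free with heavy ascertainment bias, real annotation terms overlap
heavily and hierarchically, and real disease lists carry curation error.
Synthetic recovery certifies the *procedure* — the statistics, the
bookkeeping, the thresholds — not the biological validity of any particular
candidate. The published per-pathway p-values and interactome counts depend
on the specific KEGG/PINA releases used at the time and are treated as
descriptive, not as reproduction targets; the published significant-pathway
*name lists* are shipped verbatim and their shared/specific split (12/8/11)
is reproduced exactly.

## Numerical and degenerate-input choices

* Tail computation at $k = 0$ returns exactly 1; `k > min(n, K)` and
  inconsistent margins are errors, not silent zeros.
* `bh_adjust()` rejects p-values outside $(0, 1]$ rather than clamping.
* Empty intersection of two subnetworks is a valid, flagged result; zero
  mapped seeds is an error (there is nothing to anchor a subnetwork on).
* Symbol normalization is uppercase + trim only. Alias and cross-species
  mapping are deliberately out of scope: they are irreproducible without
  pinning an HGNC release, and silent remapping is the classic source of
  phantom overlaps between gene lists. Duplicates within a source are
  collapsed and counted.
* Term-order permutations of a collection, and input order of merged
  sources, cannot change any result; ties in output tables are broken by
  name.

## Problem sizes used in the test suite

The bundled checks run the enrichment-recovery benchmark at 50 replicates
(universe 2,000, 100 terms, 5 planted terms per disease) and the candidate
benchmark at 20 random networks (2,000 nodes, background edge probability
$5 \times 10^{-4}$, 51 degree targets); the exhaustive hypergeometric
enumeration sweeps every configuration up to $N = 12$ and the BH oracle runs
1,000 random vectors. These sizes keep a full suite run under a minute on a
laptop while leaving the planted effects far from the decision boundaries:
the weakest planted term (8 hits in a 10-gene term) sits around
$p \approx 10^{-5}$, three orders of magnitude below its BH gate, and the
expected background degree from a candidate to the shared genes is
$\approx 0.03$, so threshold crossings by chance are essentially impossible.

## Known limitations

* No GO-graph topology awareness (parent/child double counting is the
  user's concern, as in any flat ORA).
* No kappa-style term grouping of redundant significant pathways.
* Candidate scoring is degree-only by design; centrality or diffusion
  scores are out of scope.
* The pipeline assumes symbol-keyed inputs; identifier mapping belongs
  upstream.
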