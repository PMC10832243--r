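---
title: "Network pharmacology of a multi-herb formula: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology of a multi-herb formula: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-herb prescriptions act through many compounds hitting many
targets at once, so single-pathway pharmacology describes them poorly.
Network pharmacology replaces the one-drug-one-target frame with an
inference chain over sets and graphs:

1. **Oral-activity screening.** Candidate compounds are filtered by
   eight ADME properties — Lipinski's rule of five (molecular weight,
   ALogP, hydrogen-bond donors and acceptors) extended with oral
   bioavailability (OB), drug-likeness (DL), Caco-2 permeability and
   rotatable bond count (RBN).
2. **Target integration.** Predicted compound–target links from several
   sources (pharmacophore matching, ligand-based prediction,
   chemical–protein association databases) are thresholded on each
   source's native confidence score and unioned.
3. **Disease intersection.** Disease gene lists from several databases
   are unioned; the intersection with the compound-target union gives
   the putative disease targets of the formula.
4. **PPI hub selection.** The protein–protein interaction subnetwork
   induced on the intersection is scored with three node centralities
   (degree, betweenness, closeness); nodes above the cohort median on
   all three simultaneously are the hub genes.
5. **Compound ranking.** In the typed disease–herb–compound–target
   network, compounds are ranked by their degree and those strictly
   above the median degree are the main active compounds.
6. **Over-representation.** Hub genes are tested against GO/KEGG-style
   annotation terms with the one-sided hypergeometric test and
   Benjamini–Hochberg correction.

The package implements each stage as a tested function over plain
tab-separated inputs, a config-driven pipeline (`run_pipeline()`,
`run_subset_reanalysis()`) over the whole chain, and a synthetic-data
generator that plants known ground truth behind every stage.  The
curated SH003/NSCLC reference tables (see `?sh003_data`) provide a real
worked example: the three-herb formula SH003 (*Astragalus
membranaceus*, *Angelica gigas*, *Trichosanthes kirilowii*) in the
non-small cell lung cancer context.

## The ADME screen

`adme_criteria()` encodes the eight cutoffs with explicit comparison
operators:

| property | operator | cutoff | unit |
|----------|----------|--------|------|
| MW       | `<`      | 500    | Da   |
| ALogP    | `<`      | 5      | —    |
| Hdon     | `<`      | 5      | count |
| Hacc     | `<`      | 10     | count |
| OB       | `>=`     | 30     | %    |
| DL       | `>=`     | 0.18   | —    |
| Caco-2   | `>`      | −0.4   | log scale |
| RBN      | `<=`     | 10     | count |

Operator strictness is deliberate and observable at the boundaries: the
curated reference table contains two compounds (liquiritigenin,
marmesin) with DL exactly 0.18 that are accepted, fixing `>=` for DL,
while the Lipinski conditions are conventionally strict.  A compound
with a missing property cannot be declared orally active
(`missing_policy = "fail"` by default); `"pass"` and `"error"` are
available for sensitivity analyses.  Each screen returns the full
compound × criterion verdict matrix, so the selection is auditable row
by row.

## Score dialects and thresholds

Interaction scores come in two dialects — STRING-style integers in
0–1000 and probabilities in \[0, 1\].  The dialect is declared in the
configuration and validated against the data, never guessed: silent
scale confusion (filtering 0–1000 scores at 0.7) is the dominant
practical failure in this kind of analysis.  All score filters are
*strictly greater than* the threshold (0.7 on the unit scale, 700 on
the STRING scale), matching the conventional "high confidence > 0.7"
reading.

Unmapped gene symbols are uppercased and retained rather than dropped,
with a report listing them; dropping would silently shrink every
downstream set size.  Aliases mapping to several canonical symbols
resolve to the lexicographically first and are flagged — the input data
do not determine a better rule, and a deterministic flagged choice
beats a silent arbitrary one.

## Centralities and the hub rule

Degree supports two conventions.  `"simple"` is the textbook neighbor
count and satisfies the handshake lemma; `"doubled"` is twice that, the
value reported by network viewers that import each undirected
interaction as two directed arcs.  Published hub tables produced with
such viewers contain only even degrees; the doubled convention (the
default for centrality tables) reproduces them, while `"simple"` is
used for graph-theoretic invariants.

Betweenness is normalized by `(n − 1)(n − 2)/2` with `n` the full
network size; graphs with fewer than three nodes score zero.  Closeness
is computed within each connected component — `(k − 1)/Σd` for a node
in a component of size `k` — which keeps values in \[0, 1\] on
disconnected graphs; isolates score 0.  The induced network keeps every
member of the query gene set as a node (isolates are counted and
reported), and the medians are taken over all induced nodes.  Both
centralities agree with exhaustive brute-force oracles (Floyd–Warshall
distances plus layer-by-layer path counting) to 1e−9 on hundreds of
random graphs in the test suite.

Hub selection takes the per-measure medians of the full pre-selection
table (even counts average the two central order statistics) and keeps
nodes exceeding all three.  Strictness defaults to `>`: in the curated
79-gene reference table every minimum strictly exceeds its printed
cutoff (degree 22 > 20, betweenness 0.00157 > 0.00156, closeness
0.39599 > 0.38889), and with 239 nodes the degree median 20 is attained
by nodes that were not selected.  Both policies give the same 79 genes
on that table, so the choice is recorded as a flag rather than
hard-coded.

## Compound ranking

Compound degree defaults to counting compound–target edges only
(`degree_scope = "target_edges_only"`): the curated degree table is
consistent with reading a compound's degree as its connectivity to the
core targets.  The alternative `"all_edges"` scope (herb edges count
too) is one flag away and exported in the audit output.  The selection
cutoff is the median of the compound degrees with strict `>`; the
curated 20-compound table has median exactly 10 and three compounds
sitting at it, which are flagged (`at_median`) but not selected —
consistent with the published choice of eight main compounds.

## The over-representation test

`hypergeom_pvalue(k, n, K, N)` is the upper tail `P(X ≥ k)` of the
hypergeometric distribution, evaluated through the log-space tail of
`phyper` for stability.  BH adjustment is applied within each namespace
(BP/MF/CC/KEGG), and the significance filter is strict on the
*adjusted* p-value, default `alpha = 0.001`.  The background defaults
to all genes in the annotation database; there is no universally
correct background, so it is explicit and overridable rather than
implicit.  The test is one-sided over-representation only; term-fusion
heuristics (kappa grouping) and GO-graph propagation are intentionally
out of scope — annotations are taken as given in the GMT.  Published
per-term p-values from 2021-era GO/KEGG releases are not reproducible
from a different annotation snapshot, which is why the test suite
validates the statistic (exact enumeration for N ≤ 12, null
calibration) rather than specific printed p-values.

Two calibration results (recomputed by `analysis/04` and the acceptance
script, not quoted from anywhere): under uniform null queries the
fraction of term tests with p < 0.05 stays inside the 99% binomial band
around 0.05 computed at the replicate count — replicates, not term
tests, are the independent units, since all terms in a replicate share
one query — and the calibration scenario uses terms of 100–400 genes
against a 2,000-gene background so the discrete tail is near-continuous
(small terms make the test conservative, which would show up as a rate
deficit, not an inflation).  A term planted at 20:1 sampling odds is
ranked first in 100 of 100 seeded replicates.

## What the synthetic generators emulate

`synthetic_scenario()` fixes every knob; each generator is a pure
function of the scenario (seeded internally, global RNG stream
restored), so the same scenario is byte-identical across runs.  The
defaults are the reference study's conditions at desk scale:

* **Compounds** — 965 candidates, of which exactly 20 pass the screen
  by construction.  Passer properties bracket the ranges observed in
  the curated table (MW 240–320 Da, ALogP 1–3, OB 30–70%, DL
  0.18–0.35); each failer violates exactly one randomly chosen
  criterion, so every verdict branch is exercised.
* **Targets and disease genes** — a 290-gene target union and a
  2,000-gene disease set planted with an exact 239-gene overlap inside
  a 3,000-gene universe (the real disease union is an order of
  magnitude larger; the overlap, which drives everything downstream,
  is kept at the study's value).  Links carry above-threshold scores;
  30% sub-threshold decoys exercise the score filter.  Disease genes
  are split over three overlapping pseudo-source lists so the union
  step is non-trivial.
* **PPI** — a 200-node core–periphery graph: 10 planted hubs wired to
  every node with probability 0.5 against a 0.02 background, nodes
  anchored on the planted overlap genes.  A core–periphery model was
  chosen over preferential attachment because the ground-truth hub set
  is unambiguous, making recovery decidable.
* **Annotation** — 50 terms of 20–60 genes; planted terms over-sample
  the query at 20:1 odds.

What the generators do *not* emulate: real STRING score distributions,
GO's term hierarchy and annotation propagation, correlated ADME
properties, or compound-level target multiplicity biases.  Passing the
recovery tests therefore shows the machinery is correct and calibrated
on data of this shape — it does not certify performance on any real
database export.

### Hub recovery is judged at the top of the ranking

The median rule always admits roughly the upper half of the cohort on
each measure; with three positively correlated centralities the
selected set is typically 25–50% of the network (the curated reference
selects 79 of 239).  A planted set of 10 hubs in a 200-node graph can
therefore never make the *whole* selection match the planted set —
that is a property of the median rule, not an implementation defect.
`hub_recovery_jaccard()` accordingly scores recovery where it is
decidable: the Jaccard index between the planted hubs and the first
`k = |planted|` entries of the (degree-sorted) hub ranking.  On the
default scenario this is 1.0.

## Numerical and degeneracy choices

* Medians of even-length vectors are the mean of the two central order
  statistics (R's `median`).
* Output orderings are fully deterministic: hub tables sort by degree,
  then betweenness, then symbol; enrichment by adjusted p, then term
  id; ties never depend on input order.
* Duplicate PPI edges collapse to the maximum score; self-loops are
  dropped and counted.
* Empty inputs fail loudly where the operation is meaningless (empty
  gene set for induction, empty core target set, empty compound
  subset) and return typed empty results where it is not (empty
  compound table, query disjoint from all terms).
* The pipeline is deterministic end to end for fixed inputs; the
  `seed` in the configuration exists for the generators.

## Problem sizes

The test suite and the analysis scripts run at deliberately desk-sized
scales — 200 oracle graphs of up to 30 nodes, 1,000 calibration
replicates against 40 terms, 100 planted-term seeds, the default
3,000-gene universe — sizes at which exhaustive oracles are exact and
the full suite completes in well under a minute of compute per stage.

## Known limitations

* Identifier normalization is exactly as good as the supplied alias
  table; there is no live lookup and no fuzzy matching.
* The centralities are unweighted; confidence scores gate edge
  inclusion but do not weight paths.
* The enrichment background choice materially changes p-values and is
  left to the analyst once the default (all annotated genes) is
  inappropriate.
* The curated reference tables cover the 20 screened compounds and the
  published hub tables; the full upstream candidate set and the raw
  database exports are not redistributable, so full-scale re-derivation
  from raw exports requires the user's own downloads.
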