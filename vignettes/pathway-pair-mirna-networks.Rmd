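---
title: "Pathway-pair networks and their miRNA regulators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-pair networks and their miRNA regulators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirPathNet)
```

# The analysis in one paragraph

Basal (triple-negative-like) breast tumors differ from normal breast
tissue not only in single genes but in the joint state of functional
pathways. `mirPathNet` identifies *pairs* of pathways whose combined
per-sample state discriminates basal from normal samples, and then asks
which microRNAs regulate many genes inside those coupled pathways. The
procedure has six steps: (1) differential expression between the two
classes, (2) Fisher exact pathway enrichment of the differentially
expressed genes (DEGs), (3) a per-sample discriminating score for every
pair of enriched pathways, (4–5) Monte Carlo cross-validated
classification with AUC-based selection of the top pathway pairs, and
(6) attachment of miRNAs to the selected pair network via mutual
information (MI) and Fisher's exact test, summarised per miRNA as
*degree centrality* (DC) — the number of regulated genes counted once
per pathway slot per pair.

# Step 1 — differential expression

Expression values are continuous, nonnegative, normalized (the scale
of the values is arbitrary; all statistics are computed on
`log2(v + 1)`). Features with low variance are removed first
(`lowVarianceFilter()`); when no explicit threshold is given, the
bottom 5% of features by log-scale variance are dropped — a
conservative reading of "exclude genes with small variance" that never
removes real signal at the package's default scales.

The test is Welch's t on `log2(v + 1)` (`degTest()`), with a Wilcoxon
rank-sum option. A count-model test (edgeR-style) is deliberately not
used: the pipeline consumes already-normalized continuous values for
which a location test on the log scale is the defined, self-contained
choice, and the decision rule is unchanged (`|logFC| > 1` and p
< 0.01). Two conventions had to be fixed because they are commonly
left implicit:

* **logFC** is basal minus normal on `log2(v + 1)`, pseudo-count 1.
* The 0.01 threshold is applied to the **Benjamini–Hochberg adjusted**
  p-value by default (`useAdjusted = TRUE`); applying it to the raw p
  is exposed as an option, since the two readings ("p value < 0.01"
  vs. "p values were adjusted") are both defensible.

# Step 2 — pathway enrichment

Each pathway is tested for over-representation of DEGs with a
one-sided Fisher exact test (upper hypergeometric tail; enrichment is
directional, so a two-sided test would be wrong here). P-values are BH
adjusted across pathways and a pathway is *enriched* when the adjusted
p is below 0.01. The gene universe defaults to the tested genes that
appear in at least one pathway; "all tested genes" is selectable. Both
are standard; the pathway-restricted universe is the stricter default
because genes outside every pathway can never contribute to an
overlap. Pathways with fewer than `minSetSize = 3` genes in the
universe are excluded with a message.

# Steps 3–5 — pathway-pair classifier

For a gene set, the per-sample *activity* is the mean of per-gene
z-scores of `log2(v + 1)` (z-scored across all samples; zero-variance
genes are dropped, and a set left without variable genes scores 0).
The *discriminating score* of a pathway pair is, by default, the
difference of the two activities; a product metric is selectable. The
original score this stands in for is not public, so the metric is
isolated behind one interface (`pairScore()`) and documented as a
stand-in: any per-sample scalar per pair can replace it without
touching the rest of the pipeline.

All unordered pairs of enriched pathways are evaluated under Monte
Carlo cross-validation (`runMccv()`): per repeat, the majority class
is downsampled to the minority count (class balancing without
replacement), the balanced pool is split 60/40 stratified by class, a
Random Forest (100 trees) is fitted per pair on that pair's score
alone, and train/test AUCs are recorded. Defaults are 50 repeats and
top-10 selection. Design choices that matter:

* **Training AUC uses out-of-bag votes.** Resubstitution predictions
  of a Random Forest on a single feature are near-perfect for every
  pair, which would make the per-bootstrap ranking meaningless; OOB
  votes are the standard honest estimate.
* **Per-bootstrap ranking uses the training AUC** ("best performance
  in the training dataset"), switchable to test AUC.
* **Direction-free AUC.** The sign of a pair score is an artefact of
  lexicographic pathway ordering. The `auc_rank` classifier route
  therefore ranks by `max(u, 1 − u)` on the training split and carries
  the learned orientation to the test split; the Random Forest route
  learns the orientation itself and reports the AUC of its predicted
  class probability.
* **Ties break lexicographically** on pair identifiers everywhere, so
  rankings are deterministic and invariant to input order.

The final ranking orders pairs by how often they reached a
per-bootstrap top-10 (`selection_count`), then by mean test AUC, and
marks the global top-10 as the network.

# Step 6 — miRNA integration

Candidate (miRNA, gene) links are restricted to a user-supplied target
map — the package is agnostic about which prediction database produced
it. For each candidate whose gene lies in the selected pair network,
MI between the miRNA's and the gene's expression is estimated on the
samples shared by the two layers; by default **tumor samples only**,
because the network describes the tumor state (an all-samples option
exists). The estimator is the plug-in MI in bits over 3
equal-frequency bins, with a permutation p-value from 999 relabelings
(all defaults exposed). Links with permutation p < 0.05 are retained;
each miRNA is then tested for over-representation of its supported
targets among the network genes (one-sided Fisher, admission at
p < 0.05), and admitted miRNAs are attached to the pairs through their
supported genes.

**Degree centrality counts genes per pathway slot per pair**, not
unique genes: a gene regulated under both pathways of a pair, or
recurring across pairs, contributes once per slot. This is the only
convention consistent with the published worked example packaged with
`mirPathNet` (`loadTable1Fixture()`): miR-365 regulates 15 + 6 genes
in one coupled pair and 6 + 15 in another (DC 42), miR-135b 6 + 6 in a
single pair (DC 12). The "42 over 96" / "12 over 35" denominators —
total genes in the coupled pathways — depend on the full pathway
definitions of a commercial database and are only computable when such
definitions are supplied.

Numerical details of the MI estimator: equal-frequency binning uses
first-occurrence ranks, so tied values may be split across bins
(deterministic, and immaterial for continuous expression); a constant
vector yields MI 0 and p 1 by definition; permutation p-values are
`(1 + hits) / (nPerm + 1)` with ties counted as hits, which is mildly
conservative. Each candidate link's permutation stream is seeded from
the master seed plus the link's position in lexicographic order, so
results do not depend on candidate ordering.

# The synthetic cohort generator

`generateCohort()` draws the two expression layers from a log-normal
model: per-feature baselines uniform on `[3, 10]` (log2 scale), i.i.d.
Gaussian noise with standard deviation `dispersion` (default 0.25)
around them, and values `2^x`. This emulates normalized RNA-seq
expression as it reaches this pipeline — continuous, nonnegative,
roughly log-normal — and deliberately not read counts: no sequencing
depth, library size, batch structure, or mean–variance coupling is
modelled, so passing tests say nothing about normalization pipelines
upstream.

Planted structure, all recorded in the returned ground truth:

* **DE pathways.** `nDePathways` of the `nPathways` disjoint gene sets
  carry a tumor-class shift of `deLog2fc` log2 units (default 2).
  Planted pathways alternate the sign of their shift (up, down, up,
  …). Real tumors dysregulate pathways in both directions, and the
  contrast matters here: a difference-of-activities score between two
  pathways shifted identically cancels by construction (per-gene
  z-scores saturate near ±1 per class whatever the shift magnitude),
  so a generator planting only one direction could never produce
  discriminative pairs under the default metric.
* **Regulator miRNAs.** `nRegulatorMirnas` miRNAs (default 2) receive
  a fixed +1.5 log2 tumor shift (so their predicted direction is
  defined) and each is wired to `targetsPerRegulator` genes drawn
  disjointly from the planted pathways' genes. In tumor samples each
  target is rebuilt as `sign · sqrt(strength) ·` (standardized
  regulator) `+ sqrt(1 − strength) ·` noise, scaled by `dispersion`,
  so the squared tumor-class regulator–target correlation is
  approximately `regulationStrength` (default 0.8) with sign
  `regulationSign` (default −1, canonical repression).
* **Decoy targets.** Every non-regulator miRNA receives the same
  number of targets drawn uniformly from all genes, giving the Step-6
  Fisher test a real null population.

Pathways are disjoint so that ground truth is unambiguous; real
pathway collections overlap heavily, and the enrichment and DC
conventions handle that (genes count per slot), but parameter-recovery
tests would be ill-defined on overlapping truth. All randomness flows
from one master seed; stage sub-generators use fixed offsets, so
identical configurations are byte-identical on disk.

Default sizes — 40/40/40 samples, 300 genes, 50 miRNAs, 12 pathways of
10–20 genes — are desk-scale choices: large enough that the planted
effects dominate sampling noise (a log2 shift of 2 at dispersion 0.25
and n = 40 per class is unambiguous), small enough that the whole
pipeline runs in seconds. The test suite exercises the pipeline at
these sizes; the enrichment-background check uses 24 pathways over 500
genes (a majority-non-DE universe is required for enrichment to be
detectable at all), and null calibrations average over 20 generator
seeds.

# Degenerate inputs and edge policies

* Identical classes: logFC 0, p 1, nothing called.
* Zero-variance features: dropped by the activity calculation; a
  constant matrix yields zero activity, MI 0.
* Fewer than two enriched pathways: the pipeline aborts at Step 3 with
  the stage name; completed stages keep their outputs under a
  `.partial` suffix.
* No miRNA passing the Fisher gate: the network keeps its pairs and an
  empty miRNA table, with a message.
* `topK` larger than the number of pairs: capped, all pairs selected.

# Known limitations

* The pair score is a declared stand-in; conclusions about *which*
  pairs win can change under a different metric, though the selection
  machinery would not.
* The Welch/Wilcoxon tests ignore count overdispersion; on raw counts
  a dispersion-moderated model would be preferable.
* MI on 3 equal-frequency bins with ~40 samples has limited power for
  weak regulation; the permutation test controls the false-positive
  rate (verified against its nominal level in the tests) but strength
  well below the default 0.8 will be missed.
* The generator's ground truth is planted marginally per gene;
  correlated co-expression structure within pathways, which could
  inflate pathway-activity variance in real data, is not emulated.
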