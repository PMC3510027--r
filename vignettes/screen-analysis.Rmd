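---
title: "Suppressor screen analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressor screen analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screensift)
library(data.table)
```

screensift implements the analysis chain of an arrayed siRNA suppressor
screen read out by kinetic caspase 3/7 fluorescence: per-well activity
estimation, two-stage plate normalization, mean + SEM hit calling,
Parent-Child-Union Gene Ontology enrichment with a two-proportion
quality-control filter, and hit-network construction over a user-supplied
interactome. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology is genuinely
open.

## Per-well activity

Each well is read repeatedly on a fluorescence plate reader (e.g. every
44 minutes for a lysate end-point assay, or near-continuously at 51-second
intervals). The readout is the rate of substrate cleavage, so each read
series is reduced to its ordinary least-squares slope in RFU·min⁻¹ and
divided by the well's total protein mass (mg, from a BCA assay):

$$\mathrm{activity} = \frac{\hat\beta_{\mathrm{OLS}}(\mathrm{RFU} \sim t)}{\mathrm{protein\ (mg)}}
\quad [\mathrm{RFU\,min^{-1}\,mg^{-1}}]$$

Unweighted OLS is the standard estimator for linear kinetic windows; it is
exact on noiseless linear data for any read schedule, and invariant to the
fluorescence baseline. Negative slopes are reported as-is — clipping them
would bias the control ratios downstream. The number of reads entering the
slope is whatever the kinetic file contains (at least two distinct times);
it is a property of the instrument schedule, not of this package.

## Two-stage normalization

Arrayed libraries are organized by gene family, so plate-mean scaling would
confound biology with plate layout. Instead:

1. **Position normalization.** Each well value is divided by the mean of
   that grid position across all plates screened the same day (a batch of
   28–30 plates in the emulated design). This removes multiplicative
   position effects (edge evaporation, dispenser gradients). Control wells
   sit at fixed positions, so their position averages are taken over like
   wells; all wells, controls included, enter their own position's average.
2. **Negative-control scaling.** Each well is then expressed as a fraction
   of the arithmetic mean of the plate's negative-control wells (mutant
   construct + non-targeting siRNA; three wells per plate by default). The
   negative-control mean maps to 1 by construction.

The order (position first, control second) follows the screen design the
package emulates; the control reference is therefore computed on
position-normalized values. A consequence worth knowing: the per-position
day average includes test wells, so if many strong suppressors share a
grid position the remaining siRNAs at that position are inflated upward.
With realistic hit rates (a few percent) the effect is small; the
synthetic-data tests document it at dense spiking.

## Hit calling

Per siRNA pool, the replicate normalized values (3 or 4) are aggregated to
a mean and a standard error of the mean (sample SD, $n-1$ denominator,
divided by $\sqrt n$). The screen-wide dispersion $\sigma$ is the SD of all
per-pool means (sample denominator by default; at thousands of pools the
population/sample distinction is negligible, and a switch exposes it). A
pool is a **suppressor hit** when

$$\bar x + \mathrm{SEM} < 1 - \sigma$$

strictly. In the published screen this cutoff is $1 - 0.317 = 0.683$, and
all 130 published suppressor rows satisfy it — the last-ranked row passes
by 0.001, which is why the inequality's strictness matters. Hits are ranked
ascending by mean (strongest suppression first). The symmetric enhancer
flag ($\bar x - \mathrm{SEM} > 1 + \sigma$) is a convenience only; the
analysis chain is built around suppressors. Libraries carry duplicate pools
for some genes; records are kept per pool, and `gene_rollup()` reports per
gene the pool with the smallest mean + SEM.

Replicates lost to failed wells are dropped pairwise; a pool needs at least
two surviving replicates to be callable.

On the published two-SD remark: applying mean + SEM < $1-2\sigma$ to the
published table yields a different count than applying mean < $1-2\sigma$,
and the exact criterion used for that aside is not recoverable; the package
takes no position and reproduces only the one-SD hit rule.

## Parent-Child-Union enrichment

Annotations obey the true-path rule: a gene annotated to a term is
implicitly annotated to all its ancestors, so annotation sets are closed
upward before any counting. Term-for-term hypergeometric testing then
inherits signal down the DAG; the Parent-Child-Union test conditions it
away. For term $t$ with parents $\mathrm{pa}(t)$, let $\mathrm{pu}$ be the
population genes annotated to the union of the parents. Given that
$k_{\mathrm{pu}}$ study genes fall in $\mathrm{pu}$, the p-value is the
hypergeometric upper tail of the number also annotated to $t$, drawing
$k_{\mathrm{pu}}$ from $|\mathrm{pu}|$ genes of which $m_t$ carry $t$. For
a root the parent union is the whole population and the test reduces to
the classic one.

Filtering follows the screen's reporting rules:

* **BH correction** across exactly the tested terms (those with at least
  one propagated study gene), threshold `alpha = 0.05` on adjusted values.
* **Level filter**: the level of a term is its shortest is_a distance from
  its namespace root (root = 0). "Below level 2" is read as *level > 2*,
  i.e. levels 0–2 are excluded as uninformative near-root categories;
  `min_level` exposes this. Levels are computed per namespace; namespaces
  are tested jointly.
* **QC proportions filter**: the population is deliberately genome-scale
  (the screened library lacks power as a background), so a category can be
  enriched against the genome yet typical of the library. The filter
  compares the category's proportion in the hit set ($\hat p_1 = x_1/n_1$)
  with its proportion in the screened library ($\hat p_2 = x_2/n_2$) by
  the pooled two-proportion z-test,
  $z = (\hat p_1-\hat p_2)/\sqrt{\hat p(1-\hat p)(1/n_1+1/n_2)}$ with
  $\hat p$ the combined proportion, two-tailed against the normal.
  Categories with $p > 0.05$ (raw, as reported in this methodology) are
  dropped; under-represented categories ($\hat p_1 < \hat p_2$) are kept
  by the two-tailed rule but flagged `depleted` so users can exclude them.
  When the pooled proportion is 0 or 1 the statistic is undefined and
  p = 1 is returned with a flag.
* Categories inapplicable to the organism are a manual curation concern;
  `exclude_terms` accepts an exclusion list but nothing is automated.

Ancestors of a genuinely enriched term often retain signal after
conditioning (their own parents also carry the propagated genes); seeing a
planted term's ancestors among the survivors is expected behavior, not an
error.

## Hit networks

Over a user-supplied interactome (SIF/TSV; `direct` = physical contact,
`indirect` = functional relation), two constructions:

* **Direct-connection network**: induced subgraph on the hit genes with
  isolated hits removed — a hit joins only by touching another hit with no
  intervening node. A focus gene (e.g. the disease gene the screen is
  built around) can be added afterwards with all its edges to members.
* **Shortest-path network**: for every seed pair whose shortest interactome
  path has at most `max_intervening` (default 1) non-seed interior nodes,
  one canonical shortest path is kept; connectors are flagged. Canonical =
  fewest non-seed interiors, ties broken by the lexicographically smallest
  interior node sequence. The tie-break is deliberately independent of
  `max_intervening`, which makes the result deterministic (byte-identical
  under input row reordering) and monotone: raising the cap never removes
  members. Whether a proprietary pathway tool connects pairs greedily or
  optimizes connector reuse globally is unknowable; the per-pair canonical
  union is an explicit, reproducible surrogate, and published connection
  counts from such tools are not reproduction targets.

## The synthetic-data generator

No raw screen is redistributable at package scale, so every stage is
validated on generated data with known truth.

**Screens** (`generate_screen()`). 96-well plates, 12 fixed-position
control wells (3 each of negative, positive, and the two wild-type
toxicity roles), 84 test wells; triplicate plates of each source plate
screened the same day; up to 30 plates per day. Raw activity is
`base × effect × position factor × plate scale` with log-normal position
factors (sdlog 0.10) and plate scales (sdlog 0.15), Gaussian replicate
noise on the effect scale (SD 0.05), and linear kinetic reads (8 reads
every 44 min, additive read noise 1 RFU) — multiplicative structure that
the two normalization stages are designed to remove, with parameters as
configuration rather than claims about any particular instrument. Spiked
suppressors default to effect 0.4. Control effects (positive 0.3, wild-type
roles 0.15/0.10) are plausibility choices; only the negative control enters
normalization. What is *not* modeled: outlier wells, spatial gradients that
change within a day, heavy-tailed noise, siRNA off-target structure — so a
passing calibration here shows the arithmetic chain is faithful to its
model, not that the model exhausts real screens.

**Ontologies** (`generate_ontology()`). A layered random DAG under one
root (parents always one layer up, so construction layer equals shortest
root distance), with per-term direct annotation rates that grow toward the
root (factor 2.5 per layer, capped at 0.3) — in real ontologies shallow
categories cover much of the genome, and without that property
parent-union conditioning is saturated and no term is detectable by
construction. Planted enriched terms are childless terms at layer ≥ 3,
over-annotated by `fold` (default 10×) in the study genes only: childless
so propagation cannot dilute the planted fold, layer ≥ 3 so they clear the
level filter. Defaults (130 study genes, 1,000-gene universe, library 40%
of the universe) mirror the shape of a 130-hit screen against a genome
background with a several-thousand-gene library, scaled down.

**Interactomes** (`generate_interactome()`). Background edges touch only
background nodes; planted structure uses dedicated nodes: a seed clique
(exactly the direct-connection network), seed pairs bridged by dedicated
single connectors (exactly the 1-intervening connectors), and decoy seeds
attached only to background nodes (never members). Decoy attachment nodes
are disjoint so no background node can become an unplanned connector.

All generators are pure functions of their parameters and seed.

## Calibration oracle

`predict_operating_point()` predicts the null hit rate and spike-in recall
by simulating the noise model and both normalization stages directly on
arrays — no files, no slope fitting, no shared code with the pipeline. It
reproduces the denominator noise the pipeline re-injects (shared
per-position day means, three-well control means), which is what makes the
null hit rate a few percent rather than the naive tail probability. Tests
require the file-level pipeline to land within three binomial standard
deviations of this prediction on a 2,000-pool screen. Hit calls are mildly
positively correlated through the shared cutoff and batch denominators, so
the binomial yardstick is slightly generous about seed-to-seed spread;
it is the conventional scale for a calibration of this kind.

## Numerical choices and degenerate inputs

* Slope fitting refuses a degenerate (constant) time axis; activity
  refuses non-positive protein mass.
* Position normalization refuses a zero per-position mean and mixed plate
  geometries; control normalization refuses a non-positive control mean.
* `screen_sd` of identical means is 0, which `call_hits` rejects (σ must
  lie in (0,1)); an exactly-null screen is therefore called with an
  explicit `sigma` override.
* PCU returns p = 1 with a flag when no study gene reaches the parent
  union; BH validates its inputs and preserves input order; the QC test
  returns p = 1 with a flag at pooled proportions 0 or 1.
* Test problem sizes: 2,000-pool screens with a 20,000-pool oracle run,
  200 enumeration cases for the PCU oracle (≤ 12 terms, ≤ 15 genes),
  1,000 vectors for the BH oracle, 20 null-ontology runs, 100 random
  graphs for the network oracles — sizes chosen to make the statistical
  checks sharp while the whole suite stays fast on one CPU.

## Worked example

```{r example}
dir <- tempfile("demo")
scr <- generate_screen(dir, n_sirna = 500, n_spiked = 25, seed = 7)
act <- compute_plate_activities(scr$paths$kinetics, scr$paths$protein,
                                scr$paths$layout)
man <- fread(scr$paths$manifest, colClasses = list(character = "plate_id"))
summary <- call_hits(summarize_screen(normalize_screen(act, man)))
summary
mean(scr$truth$spiked %in% summary$hits$sirna_id)  # spike-in recall
```

## Known limitations

* The OBO/GAF/SIF readers cover the dialects the generator emits and the
  common fields of real files (is_a, alt_id, obsoletes; NOT qualifiers);
  they are not full-spec parsers of every optional tag.
* Relations beyond is_a (part_of and other relationship tags) are ignored
  for levels, propagation, and conditioning.
* Enrichment is tested jointly across namespaces; if per-namespace BH
  families are wanted, run `enrich()` per namespace.
* The QC filter uses the normal approximation; with very small hit sets
  (tens of genes) and rare categories its p-values are approximate, which
  matches how such filters are used in practice.
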