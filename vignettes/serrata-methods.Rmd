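---
title: "serrata: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{serrata: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

serrata implements a gene-discovery workflow for familial serrated polyposis
syndrome (SPS): prioritize rare germline variants that co-segregate in
affected families, corroborate candidate tumor-suppressor genes with paired
somatic data under the Knudson two-hit model, and characterise the somatic
mutational landscape of the lesions. This vignette explains each model, the
parameters that matter, what the synthetic cohort does and does not emulate,
and the design choices made where the design was genuinely open.

## Germline prioritization

Variants arrive annotated (gene, impact class, population allele
frequencies, six pathogenicity-predictor verdicts) as VCF INFO tags; the
package never queries external databases. Prioritization is three rounds of
declining mechanism and increasing judgment:

1. **Hard filters.** Retain a variant iff its population allele frequency is
   *strictly* below `maf_threshold` (default 0.001, i.e. MAF < 0.1%), its
   impact is missense or truncating (nonsense, frameshift, essential
   splice), and — for missense — at least `min_deleterious_votes` (default
   3, `>=`) of the six predictors call it deleterious. Truncating variants
   pass on impact alone because predictors typically return no verdict for
   them; an unavailable verdict never counts as deleterious. The variant's
   MAF is the *maximum* over all frequency databases present — the
   conservative resolution of an open question (the source study used
   several databases jointly without stating a reconciliation rule).
2. **Co-segregation and exclusion.** Keep variants carried by every
   affected, sequenced member of the family (dominant reading: het or
   hom-alt both count as carriage; a hom-alt carrier does not violate a
   dominant model). A recessive route (all hom-alt, or an unphased
   gene-level compound-het surrogate) is available but rarely fires in
   practice, matching the study population. Missing genotypes fail the
   shared rule by default (conservative; configurable). A variant is then
   removed *everywhere* if it mis-segregates in any other family of the
   cohort, or appears on an external exclusion list. Gene-level exclusion
   lists (known non-cancer disease gene, vague function) are applied here.
3. **Function prioritization.** Keep only genes in at least one prioritized
   set — cancer development, senescence, epigenetic regulation — attaching
   the set name as the selection criterion. The original curation was
   manual and irreproducible; serrata deliberately encodes it as
   user-supplied gene lists and makes no attempt to infer function.

## Two-hit integration

A somatic sample first passes paired QC: the fraction of the germline
callable footprint shared with the somatic callable footprint must reach
0.70. Then, per candidate gene:

* **Second-hit SNV/indel:** any somatic missense/truncating variant in the
  gene with depth >= 10 and alternative allele frequency (AAF) >= 0.20,
  excluding the germline site itself.
* **Loss of heterozygosity:** at each germline-heterozygous site in the
  gene, the somatic alt count is tested against `Binomial(depth, 0.5)` with
  a two-sided exact binomial test. A site calls LOH only when `p < alpha`
  (default 0.01), `|AAF - 0.5| >= delta` (default 0.15), *and* the variant
  allele is the retained one — wild-type retention contradicts a two-hit
  mechanism and never calls. A gene calls LOH when the candidate site
  calls, or when at least half of the testable sites are imbalanced in one
  consistent direction and the candidate site leans the same way.

The LOH machinery of the tool the study used is not described in the paper;
serrata substitutes a transparent exact-binomial allelic-imbalance test with
an effect-size floor and a direction requirement — the same inferential
target, fully specifiable and testable. `alpha` and `delta` are our
calibration (the paper is silent); `min_depth = 10` is anchored to the
study's coverage rule. No multiple-testing correction is applied by default
because the candidate set is small after prioritization;
Benjamini-Hochberg is a flag away for wider scans. At the defaults and
depth ~100, the per-site false-positive rate is ~0.002 and power against a
retained-allele fraction of 0.8 exceeds 0.99 (both verified by simulation
in the test suite).

Samples without a paired germline exome are cleaned against a pooled-normal
panel (variants present in >= 1 panel sample are removed) and contribute to
mutational profiling but not to two-hit evidence.

## Somatic mutational profiling

* **Burden.** TMB = mutations per megabase of callable footprint (from the
  sample's BED; the paper never states its denominator, so it is explicit
  and overridable here). SNV and indel burdens are reported separately and
  combined; classes use strict thresholds — hypermutated > 10/Mb,
  ultra-hypermutated > 100/Mb, so a sample at exactly 10 is
  non-hypermutated. Classification uses the combined burden (an open
  question in the source; both components are always reported).
* **Context classification.** SNVs map to the 96 pyrimidine-centred
  trinucleotide categories; purine-reference mutations are
  reverse-complemented with their flanks, making the labelling strand
  involutive. Indels map to an 83-category scheme (type, size, homopolymer
  run length, tandem-repeat count, microhomology) whose exact bin grammar
  ships with the package documentation (`?id_categories`) because the
  source defines none. Events with `N` in context or complex substitutions
  are counted as unclassifiable — excluded from category vectors but
  included in burden, which is a count metric.
* **Signature refitting.** Per-sample category counts are fitted against a
  signature catalog by non-negative least squares, then pruned greedily:
  the smallest-weight signature is removed (and the rest refitted) while
  its weight is below 0.05 or its removal costs less than 0.01 in
  reconstruction cosine. Refitting — not de-novo extraction — is the
  honest tool at a dozen samples, and matches a per-sample
  contribution-of-known-signatures readout. Aetiology flags (clock-like,
  MMR deficiency, artifact) are raised when the summed weight of a group
  passes 0.05, guarding against over-reading trace refit weights.
* **Drivers.** Somatic variants in BRAF, KRAS, POLE, POLD1 and the MMR
  genes are always reported, with no AAF cut; they are tiered instead
  (high at AAF >= 0.20). Hotspots (BRAF V600E, KRAS A146T) are matched by
  exact string equality on the short protein change — no codon
  recomputation.

## The synthetic cohort: what a green test establishes

Raw data for the source cohort are not publicly available, so serrata ships
a first-class simulator whose defaults *are* the stated world: 16 families
(13 of 2 affected, one each of 3, 4, 6 — 39 patients), a causal variant per
family satisfying every filter, shared background calibrated to an expected
24.5 round-1 survivors per family, somatic samples for all but one family
with one sample built to fail the 70% QC rule and one unpaired sample
cleaned against a 110-sample panel, per-sample burdens anchored to the
reported values (27.6 and 89 mut/Mb hypermutated, 100.6 indels/Mb
ultra-hypermutated), clock-like-dominant signature mixtures with
MMR-deficiency admixture in hypermutated samples, one planted somatic
second-hit SNV family and one planted LOH family (retained-allele fraction
0.8, a purity proxy; the paper states none), and driver hotspots at the
reported carrier counts and AAF tiers.

Values the study does not state were fixed once at field-realistic levels:
germline depth ~80x and somatic ~100x (the study reports mean coverage
> 95x), somatic AAF noise beta-binomial around 0.45 with mild
overdispersion (concentration 50), background impact mix 40/30/30
missense/synonymous/other.

Deliberate departures from real data, and their consequences:

* **Identifiability by construction.** Background somatic mutations avoid
  candidate- and driver-gene intervals. Real hypermutated tumors plant
  incidental same-gene passengers that are indistinguishable from true
  second hits at the variant level; the simulator removes this ambiguity so
  that recovery tests can demand precision = recall = 1.0. A green
  two-hit test therefore establishes that the *rules* are implemented
  correctly, not that passenger confusion cannot occur in practice (the
  pipeline carries the sample's hypermutation class as a caveat column for
  exactly this reason).
* **Synthetic signature profiles.** The COSMIC catalog is an external
  database and cannot ship. The bundled profiles mimic their namesakes
  qualitatively (SBS1: C>T at NpCpG; SBS5: broad T>C; SBS15/21:
  MMR-deficiency-like; ID1/ID2: 1 bp T events at long homopolymers) with
  peak masses chosen so the non-negative least-squares problem is well
  conditioned. Green refit tests establish estimator correctness against
  these profiles, not COSMIC-numerical fidelity.
* **Refit-recovery experiment without pruning.** The cosine-drop pruning
  rule at its 0.01 default mathematically suppresses any contribution below
  roughly 0.13 (removing a weight-w signature from an otherwise-explained
  mixture costs about `1 - cos(atan(w/(1-w)))` in cosine when profile norms
  are comparable). The recovery experiment therefore fits over the known
  4-signature support with pruning disabled and mixtures whose
  contributions are all >= 0.10; it measures estimator accuracy. Pruning
  behaviour itself is tested separately on exact mixtures at the defaults.
  Trace contributions (< ~0.1) are a documented limitation of refitting at
  n = 1000.
* **Genes are intervals, not transcripts.** Only gene membership matters to
  any rule in scope, so the gene map is 20 kb tiles on a 5 Mb synthetic
  chromosome. Effect re-annotation, splicing, phasing and CNV segments are
  out of scope.
* **Second hits are planted in prioritized genes**, so the pipeline anchors
  its two-hit scan on the round-3 candidate set. The study's genome-wide
  LOH screen followed by curation is subsumed: `integrate_two_hits()`
  accepts any candidate table if a wider scan is wanted.

## Numerical choices and degenerate inputs

Strictness at boundaries follows the stated rules everywhere: MAF strictly
below threshold, predictor votes `>=`, burden classes strictly above 10 and
100, AAF tiers `>=` 0.20, QC `>=` 0.70. Catalog profiles must sum to 1
within 1e-6 and are renormalised exactly. A zero catalog vector yields a
defined empty refit. Empty germline callable regions, zero footprints and
rank-deficient catalogs raise errors or warnings rather than propagating
nonsense. Ties in the candidate table are broken by (family, gene) radix
order so all outputs are byte-stable; every stage derives its randomness
from the single run seed.

## Known limitations

Phasing-free compound-het detection cannot distinguish cis from trans;
epigenetic second hits (promoter methylation) are reported nowhere because
the assays are out of scope; the simulator draws family members
independently rather than through meiosis (co-segregation is imposed, not
inherited); and signature refitting against a small synthetic catalog says
nothing about extraction of novel signatures.
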