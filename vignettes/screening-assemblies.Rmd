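---
title: "Screening genome assemblies for contaminant and HGT candidate CDS"
author: "xenoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genome assemblies for contaminant and HGT candidate CDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoscan)
```

## The model

A genome assembly is a set of scaffolds; its annotation a set of
predicted coding sequences (CDS). Some CDS may not belong to the target
organism at all. Two biological situations produce taxonomically alien
CDS and require opposite handling:

* **contamination** — DNA of a co-sequenced organism was assembled into
  its own scaffolds; these should be removed;
* **horizontal gene transfer (HGT)** — a gene of foreign ancestry was
  genuinely integrated into the host genome; these are biology, not
  noise.

Similarity against a reference database cannot separate the two, because
both look foreign. `xenoscan` follows the principle that the difference
is *synteny*: an HGT is physically linked (same scaffold) to confidently
resident genes, a contaminant is not — it co-occurs with other foreign
genes on scaffolds of its own.

The screen therefore runs in two stages. Stage 1 assigns every CDS a
taxonomic category by a majority vote over its best protein-similarity
hits. Stage 2 maps foreign candidates and confident-resident CDS onto the
scaffolds and adjudicates each foreign candidate by the company it keeps.
Every CDS ends in exactly one of: `confident_arthropod` (resident),
`other_metazoa`, `foreign` (with a source group), `orphan`, `unassigned`;
and every foreign candidate in exactly one of `hgt_candidate`,
`contaminant_candidate`, `uncertain`.

### Assumptions

* The reference set spans all domains of life and its species are mapped
  to seven groups: five foreign source groups (eubacteria, archaea,
  fungi, viridiplantae, protists), the resident clade, and the remaining
  members of the enclosing clade. Metazoan contaminants are deliberately
  out of reach: a CDS voted `other_metazoa` is reported but never called
  a contaminant.
* Hits are taken as given (12-column tabular search output); the screen
  does not run the search itself.
* A scaffold is the unit of physical linkage. If scaffolding is in
  doubt, classification can be repeated on contigs; more candidates then
  end up `uncertain`.

## Parameters

All constants live in one object, `pipeline_thresholds()`:

| parameter | default | unit | role |
|---|---|---|---|
| `min_hit_identity_pct` | 40 | % | hit retention (strict `>`) |
| `min_hit_aln_len_aa` | 75 | aa | hit retention (strict `>`) |
| `max_hit_evalue` | 1e-10 | — | hit retention (strict `<`) |
| `min_hits`, `min_distinct_species` | 2, 2 | count | orphan rule, on retained hits |
| `top_n_hits` | 10 | count | voting set |
| `majority_fraction` | 0.70 | fraction | group majority |
| `confident_metazoa_fraction` | 1.00 | fraction | resident call requires all-metazoan top hits |
| `min_map_len_bp` | 100 | bp | mapping filter (inclusive `>=`) |
| `min_map_identity_pct` | 95 | % | mapping filter (inclusive `>=`) |
| `min_scaffold_len_bp` | 200 | bp | input filter |
| `min_cds_len_bp` | 150 | bp | input filter (after longest-transcript selection) |
| `family_identity_fraction` | 0.60 | fraction | single-linkage family cutoff |
| `logit_adjustment` | 0.025 | fraction | squeeze for the logit of proportions |

The hit filters are strict inequalities because they bound what is
*excluded*; the mapping and input filters are inclusive because a
"minimum of 100 bp" is an attainable bound. Identity exactly 40.0 % is
thus excluded while a mapping of exactly 100 bp is kept; both conventions
are tested at their boundaries.

Majorities count *hits*, not species — ten hits to one bacterial species
and its close relative are strong evidence even though only two species
are involved; the two-species floor is enforced separately on the
retained set. Ties at the top-10 E-value boundary are broken by bitscore
(descending) then subject id, making the voting set reproducible.

## Decision details worth knowing

* **Rule order.** Foreign majorities are tested before the resident
  rule. At the default 70 % threshold the rules are mutually exclusive
  (two groups cannot both hold ≥ 70 % of one voting set), so the order
  only matters for permissive non-default thresholds.
* **Chimeric alignments.** A CDS whose 5′ and 3′ ends map to two
  scaffolds links them. The resident tag propagates across the connected
  components of these links, so a fragmented resident region still
  rescues its HGT candidates. A chimeric foreign CDS is an HGT candidate
  if *either* scaffold is resident-tagged; its own second part never
  counts as the corroborating "other foreign CDS" of the contaminant
  rule — a CDS cannot corroborate itself.
* **Mixed foreign company.** A scaffold holding, say, one eubacterial
  and two fungal candidates still makes them all contaminant candidates:
  mutual corroboration does not require one source group. The
  consistency test (below) then surfaces such scaffolds as anomalies
  rather than silently discarding them.
* **Denominators.** Percentages are reported against three denominators
  (all CDS; CDS with a taxonomic assignment, i.e. neither orphan nor
  unassigned; foreign candidates). The "of assigned" denominator is the
  headline one — orphans carry no evidence either way.

## Validations

**Tetranucleotide PCA.** Contaminant and resident CDS usually differ in
nucleotide composition. `kmer_profiles()` computes stranded sliding-
window 4-mer frequencies (windows containing non-ACGT symbols are
skipped; a profile with fewer than 50 windows is flagged);
`pca_separation()` centers the profiles (no variance scaling — the
frequencies share one scale, and rare-word inflation is unwanted),
decomposes by SVD, canonicalizes component signs (largest-magnitude
loading positive) and scores the contaminant/resident split as the mean
silhouette width in the space of the first three components. The score
makes a visual check numeric: ~0 for indistinguishable clouds, above 0.5
for clearly separated ones.

**Consistency of contaminant scaffolds.** A contaminant scaffold
(≥ 2 contaminant CDS, no resident CDS) should derive from one organism,
hence one source group. `consistency_check()` reports every contaminant
scaffold with its group multiset; mixed scaffolds are likely assembly
chimeras between two contaminants.

**Families.** `cluster_families()` groups candidates by single-linkage
at ≥ 60 % pairwise identity (connected components of the identity
graph), with deterministic family ids (smallest member id). Pairwise
identities come from an input table; alignment itself is out of scope.

**Fragmentation.** `fragment_assembly()` splits every scaffold into *k*
pieces, partitioning its mapped CDS into contiguous chunks, and
`n50_uncertain_regression()` fits logit(uncertain fraction) on
log₁₀(N50) by OLS. Base-10 logs are used for readability of the N50
axis; the choice only rescales the slope. The logit squeeze clamps
proportions into `[0.025, 0.975]` — interior values are untouched, and
the 0.025 default is a common remedy-of-zeroes convention.

## The synthetic-assembly generator

`generate_fixture()` builds all pipeline inputs with planted ground
truth: host scaffolds carrying resident genes, contaminant scaffolds
whose genes derive from a compositionally divergent model, HGT genes
(foreign-composition genes on host scaffolds), chimeric host genes split
across scaffold pairs, and optionally one mixed-origin contaminant
scaffold (one eubacterial plus two fungal CDS). Gene sequences come from
order-1 Markov chains — host mildly AT-rich, the divergent source
GC-rich, mixed linearly by `composition_divergence`; intergenic filler is
drawn i.i.d. from the corresponding base composition, which is
sufficient because only CDS enter the compositional validation. Hits are
synthesized to reflect each CDS's true origin (host genes get 8
arthropod + 2 other-metazoan top hits; foreign genes 10 hits within
their group) and corrupted at rate `hit_noise`; mappings are the true
placements.

Default sizes — 30 host scaffolds of 50 kb with 8 genes each, 6
contaminant scaffolds of 4 genes, 5 HGT genes, 3 chimeric host genes,
divergence 0.5, noise 0 — give an assembly of ~270 CDS in which every
category is populated and a full run takes seconds; that is the regime
used throughout the tests and the acceptance script. Two published
contamination regimes are reachable by configuration: many small
contaminant scaffolds with few CDS each (aphid-like) versus few long
scaffolds packing many CDS (bumblebee-like).

What the generator does *not* emulate: real protein evolution (hits are
synthesized, not searched — a documented hook lets real search output
replace them), assembly from reads, repeat content, and gappy scaffolds.
Passing the planted-truth tests therefore demonstrates the decision
logic is correct, not that the thresholds are optimal for any particular
real dataset.

## Numerical choices and degenerate inputs

* N50: smallest length L with cumulative length of scaffolds ≥ L at
  least half the assembly; singleton and uniform lists are handled
  exactly.
* Empty hit tables are legal: every CDS becomes an orphan and a report
  is still produced.
* A mapping whose CDS is unknown to stage 1 is ignored with a warning;
  a subject species missing from the taxonomy is an error (never a
  silent default).
* Best placements are chosen by identity, then alignment length, then
  scaffold id — an explicit, documented tie-break, since upstream
  mappers do not define one.
* PAF target coordinates (0-based half-open) are shifted to the internal
  1-based inclusive convention on read; GFF3 passes through unchanged;
  PAF identity is residue matches / alignment block length.
* All randomness is confined to the generator and controlled by its
  single integer seed; the screen itself is deterministic, and repeated
  runs produce byte-identical outputs.

## Limitations

* Detection power degrades with assembly fragmentation: scaffolds
  carrying one CDS cannot be adjudicated, so contamination prevalence is
  underestimated in low-N50 assemblies — quantified by the negative
  slope of the uncertain-fraction regression.
* Metazoan contaminants are invisible by design.
* The screen annotates; it does not edit assemblies. The only removal
  aid offered is whole-scaffold exclusion of contaminant scaffolds.
* Phylogenetic confirmation of HGT (alignment, tree inference,
  inspection) is downstream of this package; the family clustering
  output is its entry point.
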