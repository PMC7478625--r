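---
title: "Methods: annotation confidence, co-occurrence pangenomics, pathway calling and marker phylogenomics"
author: "corepan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corepan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

corepan implements the analysis core of a genus-scale comparative
study of gut anaerobes: reconciling multiple annotation evidence
streams into confidence-tiered function calls, counting orthologue
co-occurrence to delimit core and pan-genomes, evaluating pathway
requirement trees for completeness and vitamin
synthesis-versus-salvage strategies, and reconstructing phylogenomic
trees from concatenated single-copy markers. This vignette records
the models, the tunable parameters, the numerical choices, and what
the synthetic-data tests do and do not establish.

## Evidence model and trusted-cutoff filtering

Each gene may carry hits from four sources: equivalog profile HMMs
(TIGRFAM-style models whose above-cutoff hits imply a specific
conserved function), KEGG Orthology assignments, protein-family
(FIGfam-style) assignments, and domain-level HMMs (Pfam-style).
HMM-tier hits are compared against the model's *trusted cutoff* — the
curator-set bit score above which hits are considered guaranteed true
— and retained iff `bit_score >= trusted_cutoff`. The comparison is
inclusive, matching hmmsearch's own `--cut_tc` behaviour; ties at the
cutoff are kept. By default the *full-sequence* bit score is compared
(hmmsearch tblout column 6); when several domains hit one protein the
best-single-domain score (column 9) can be selected instead with
`readHitTable(..., score = "domain")`. Full-sequence is the default
because the cutoff published with a model refers to the sequence
score; the choice is exposed because either convention appears in
practice. HMMER's tabular output does not carry cutoffs, so the
reader takes a named `cutoffs` vector (accession → bits).

Gene positions are 0-based ranks along a contig, not nucleotide
coordinates: every neighbourhood argument in the package is about
gene order (operons), never base pairs.

## The operational confidence scale

`assignConfidence()` fuses one gene's surviving hits. The reported
function is that of the highest-priority source — equivalog > KO >
family > domain — and the tier is:

| evidence for the chosen function            | tier     |
|---------------------------------------------|----------|
| equivalog hit above cutoff                  | HIGH     |
| KO and family agree                         | HIGH     |
| KO alone                                    | MODERATE |
| family alone, with genome context           | MODERATE |
| family alone, without context               | LOW      |
| domain hit only ("hole filler")             | LOW      |
| nothing                                     | NONE     |

Two points were genuinely open and were decided as follows. First,
the placement of *family-only without context*: the scale's governing
principle is that conserved genome context is what upgrades a
family-only call, so without context such a call sits at LOW rather
than MODERATE; with context it is MODERATE. This keeps the mapping
total (every evidence pattern has a tier, and NONE occurs exactly
when no evidence survives) and makes context do real work. Second,
conflicting functions across sources: the highest-priority source
wins, but all hits stay listed in the `sources` audit column, so a
KO/family disagreement is visible downstream.

Context itself (`genomeContextSupport()`) is true when at least one
*other* gene within ±`window` ranks on the same contig is assigned —
at any tier above NONE — to a function sharing a pathway with the
candidate call. The window defaults to 5 gene ranks and is
strand-agnostic: typical bacterial operons span a handful of genes,
and the motivating observations (e.g. arabinose-utilisation genes
recognisable only by family evidence but sitting inside their pathway
neighbourhood) concern immediately adjacent genes. Whether context
must hold in every strain or any strain of a species is ambiguous in
the source material; corepan evaluates context per genome and leaves
cross-strain aggregation to the caller.

`annotateGenome()` runs two passes: pass 1 assigns tiers with context
off; pass 2 recomputes the context-dependent (family-only) calls
using only pass-1 tiers of the neighbours. Context support therefore
cannot be circular (two family-only genes cannot bootstrap each other
to MODERATE), and a third pass would change nothing. The scale is
replaceable: `scaleFn` accepts any function of (supporting sources,
present sources, context), so a study-specific scale table can be
substituted without touching package code.

## Core/pan-genome co-occurrence

An `OrthologueTable` is a (group, genome, gene) membership list;
presence means ≥ 1 member gene, so paralogues count once. The core of
a genome set is the groups present in every listed genome — adding a
genome can only shrink it. For species-level statistics a taxon
"contains" a group under `all_strains` (every strain has it; the
default, and the convention used for species-vs-species comparisons)
or `any_strain`. The pairwise matrix diagonal is always the taxon's
own core under `all_strains`, matching the usual reading of such
figures (the diagonal is the within-species core size); off-diagonal
entries count groups present in both taxa under the chosen rule.
Venn-exclusive counts enumerate all 2^k − 1 subsets exactly and are
limited to 7 taxa; the counts sum to the number of groups present in
at least one taxon under the rule.

Orthologue tables from a dedicated predictor (PorthoMCL-style TSV)
are the first-class input. The built-in `clusterOrthologues()` exists
so the pipeline runs end to end with no external tool: it forms
reciprocal best hits per genome pair from normalised global-alignment
identity (matches / longer sequence length, BLOSUM62, gap open 10 /
extend 0.5), keeps pairs at or above `identityThreshold` (default
0.7), and takes single-linkage components. An exact shared-k-mer
prescreen (k = 8) limits alignment to plausible pairs without
changing results for sequences that could pass the threshold. It is a
deliberate stand-in, not an MCL reimplementation — the analysis value
is in the downstream counting — and all ties break lexicographically
by gene id so output is order-independent.

## Pathway completeness and strategy calls

A pathway definition is an AND/OR tree over function ids with a
minimum qualifying tier (default MODERATE — family-plus-context
evidence is accepted as pathway presence, which mirrors how
moderate-confidence calls were treated in the motivating study; the
per-pathway threshold is a column in the definitions file, so it can
be tightened to HIGH per pathway). A leaf is satisfied when any gene
carries that function at or above the threshold. Completeness counts
*top-level AND children* — "missing gene" units — with an OR subtree
counting as a single unit; `(a & b & (c|d))` with only `a` present is
1/3 complete, missing `b` and `(c|d)`. Leaf-weighted completeness was
considered and rejected as a default because it over-penalises
pathways with long alternative branches; the unit semantics are in
`evaluateRequirement()` and a different weighting is a small local
change. Status is complete (1.0), absent (0.0) or partial (between).
Completeness is monotone: raising a tier, adding an assignment or
lowering `min_tier` can never lower it.

Strategy classification takes one synthesis and one salvage/transport
definition for the same micronutrient and maps the two satisfied
flags onto synthesizer / salvager / both / neither. The shipped
definitions file (`inst/extdata/pathways/roseburia_pathways.tsv`)
encodes the study pathways — central carbon routes, the
butyrogenesis operon (`thl, bhbD, cro, bcd, etfA, etfB` plus the
butyryl-CoA:acetate-CoA transferase), serine biosynthesis with its
`serB`/`thrH`/`glyA` alternatives, the dispersed histidine operon
genes, and the eight B-vitamin synthesis/salvage pairs (thiamine with
the `thiC` vs `cytX`+`thiD` routes and the ThiT ECF transporter,
riboflavin/RibU, pantothenate/PanT, pyridoxine `pdxST` vs
`pdxKYH`/`pdxU2`, biotin/BioY, folate/FolT, niacin without a known
transporter, and the anaerobic cobalamin pathway — modelled without a
cobalt-reductase step — with BtuCDF). It is data: editing the TSV
changes the profile without code changes.

## Marker phylogenomics

The default marker panel is the 18 single-copy
ribosomal/translation-associated TIGRFAM equivalogs (RpoB, InfC,
NusA, RplA/B/D/M/N/P/S/T, RpsB/C/E/J/S, SmpB, Tsf), shipped as a
config table. `extractSingleCopy()` keeps a (marker, genome) cell
only when exactly one above-cutoff hit exists; a marker with a
missing or duplicated hit in any genome is either dropped genus-wide
(`drop_marker`, logged) or raises an error (`fail`). Both policies
exist because the right behaviour for duplicated markers is a study
decision, not a package one; `drop_marker` is the default as the
conservative choice for concatenation.

Distances: the amino-acid distance is the Poisson correction
d = −ln(1 − p), with p the mismatch fraction under *pairwise*
deletion of gaps/ambiguities (complete deletion discards too much of
a patchy concatenation; pairwise deletion is the default in common
distance software). Pairs with p ≥ 1 are flagged saturated and the
pair is reported as NA rather than an arbitrary large number; a pair
with zero comparable sites is an error naming the pair. The
nucleotide distance is the Tamura–Nei (1993) closed form from the two
transition proportions, the transversion proportion and the empirical
base frequencies of the pair; non-positive logarithm arguments flag
saturation the same way. In the symmetric limit (equal frequencies,
all twelve substitution directions equally frequent, i.e.
P1 = P2 = Q/4) the TN93 value reduces to the Jukes–Cantor distance,
which the test suite checks to 1e-9 alongside a dual-implementation
comparison at 1e-12.

Tree search: the package builds neighbor-joining trees on
model-corrected distances rather than a maximum-likelihood search.
NJ is consistent on additive inputs (verified on random additive
matrices), fully deterministic here — Q-criterion ties break on the
lexicographically smallest clade-label pair — and fast enough to
bootstrap densely. This is a documented method substitution: ML
search is out of scope, and on the saturated-free distances the
markers produce the NJ topology is the quantity of interest. Negative
limb lengths are clamped to zero with the total deficit recorded on
the tree (`clampedDeficit` attribute). Bootstrap supports resample
single alignment columns with replacement (not partition-aware;
partition-aware resampling would be a straightforward variant but the
conventional column bootstrap is the default), rebuild the NJ tree
per replicate, and report for each internal edge of the point tree
the percentage of replicates containing the same bipartition. All
bootstrap randomness flows from the `seed` argument through a private
RNG stream, so runs are reproducible and never disturb the caller's
RNG state.

## The synthetic-data generator

`simulationConfig()` defaults describe the emulated study conditions:
5 species × 2 strains (a ten-genome genus with a handful of species),
an 18-marker single-copy panel, and noise-free evidence
(`fn = fp = 0`). Family counts (core 100, 25 accessory per species,
10 private per strain), protein length (~80 aa) and marker length
(120 columns) are the package's own simulation-tractable choices:
large enough that clustering, annotation and tree building are
non-trivial, small enough that the full test suite runs in well under
a minute per cohort. Sequences are generated by mutating per-family
ancestors at a fixed within-family divergence (2 %) rather than by
forward evolution along a tree — sufficient for clustering and
distance tests and fully seeded. Vitamin pathway families follow a
sampled per-genome strategy (synthesizer / salvager / both / neither
at 0.4/0.3/0.2/0.1 — a deliberately mixed population so every verdict
class is exercised); non-synthesizers receive a uniform 0..k−1 subset
of the k synthesis genes so partial and absent statuses both occur.
Pathway genes are placed as contiguous operon blocks, which is what
makes genome-context rescue testable. Evidence simulation drops each
gene × source hit independently with probability `fn`; true HMM
scores sit an exponential margin (mean 15 bits) above their trusted
cutoff so zero-noise recovery is exact, while spurious hits (rate
`fp`) carry a wrong accession and a score centred *on* the cutoff so
roughly half are removed by filtering. Marker alignments evolve
site-independently, without indels, under Poisson amino-acid,
Jukes–Cantor or TN93 nucleotide models (the nucleotide models sample
exact transition-probability matrices; the amino-acid model draws a
Poisson number of substitutions per site, each to a uniformly chosen
different residue — at realistic depths the resulting
Poisson-corrected estimate carries a small negative bias from
convergent substitutions, which stays within sampling error at the
simulated lengths).

What passing the synthetic tests shows: the counting, scale,
evaluator and tree machinery are exact on inputs whose truth is
known, and degrade in the expected direction as evidence drops out
(completeness falls monotonically with `fn`; a complete pathway can
become partial but an absent one can never become complete). What it
does not show: robustness to real-data phenomena the generator
deliberately omits — indels and misalignment, paralogue expansions
beyond duplicates, horizontal transfer, chimeric assemblies,
annotation biases that correlate across sources, and reference
databases that simply lack a clade's genes (the situation that
motivates the context rescue in the first place).

## Problem sizes and budgets

The acceptance script runs the full study-scale cohort (10 genomes,
~1500 genes, 18 markers × 120 columns, 100 bootstrap replicates) in
about ten seconds; the test suite (including 200 brute-force
co-occurrence comparisons and 100 additive NJ recoveries) completes
in well under a minute. These sizes are the package's chosen test
conditions, stated here so they can be scaled deliberately rather
than rediscovered.

## Known limitations

* The RBH clusterer is a stand-in; genuinely hard orthology (domain
  shuffling, deep paralogy) needs a dedicated predictor, whose tables
  the package reads directly.
* The published external reproduction (the genus core count of the
  motivating study) requires downloading the study's deposited
  orthologue tables; the test that recomputes it fails until those
  tables are placed under `inst/extdata/external/`.
* NJ replaces ML tree search by design; for publication-grade trees
  on real alignments, export the concatenation and run an ML tool,
  then read the result back with `readNewickTree()`.
* Completeness semantics treat an OR branch as one unit; pathways
  whose alternatives differ greatly in length may warrant a custom
  weighting.
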