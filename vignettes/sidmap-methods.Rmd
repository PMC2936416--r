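---
title: "Methods: mapping antibody epitopes from Y2H fragment screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping antibody epitopes from Y2H fragment screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidmap)
```

## The experimental setting

A single-chain antibody (scFv) fused to a DNA-binding domain is mated
against a saturated library of random-primed cDNA fragments fused to an
activation domain. Every retained diploid marks a prey fragment that bound
the antibody. Because the library is random-primed and screened to
saturation (coverage around ten times its primary complexity), the
*multiplicity and layout* of retained fragments is informative: many
independent overlapping fragments of one gene indicate a specific
interaction, and the region shared by all of them — the selected
interacting domain (SID) — brackets the epitope.

Two regimes are expected and both occur in practice. A *linear* epitope
lets short fragments bind, so the SID narrows toward the epitope as clones
accumulate. A *conformational* sensor binds only the folded (for small
GTPases, GTP-loaded) protein, so only fragments spanning the whole folding
core are retained and the SID is the core itself — a full-core SID is
positive evidence for a non-linear epitope.

## Coordinates and frame

All nucleotide and residue coordinates are 1-based inclusive; an interval
`[1462, 1540]` has `1540 - 1462 + 1 = 79` residues. BED export is the one
place converted to 0-based half-open. The stop codon is excluded from
protein lengths, and fragments reaching into UTRs or across the stop codon
are clamped to the CDS before translation, with partial codons at either
end dropped (`floor`): only fully encoded residues can present epitope.

A fragment is in frame (IF) iff it is in sense orientation and its first
base inside the CDS sits on a codon boundary; frame is defined relative to
the source ORF because a fragment starting mid-codon produces a different
peptide downstream of the activation-domain fusion regardless of the
linker, which is assumed frame-neutral. Antisense fragments are always
OOF. OOF and antisense clones are *retained in all totals and percentages*
(screen tables list them) but contribute no fragment interval, so they
never shape a SID. Whether an OOF clone could ever legitimately support a
SID is unresolved; excluding them is the conservative choice and a
`pbs_min` filter allows the stricter high-confidence-only variant.

## SIDs and clusters

Fragments of one gene are clustered as connected components under
shared-residue overlap (abutting intervals do not cluster). The SID of a
cluster is the intersection `[max(starts), min(stops)]` with
`complete = TRUE`. Chained clusters with an empty global intersection
never occur in the screens this models, but the operation must be total:
the fall-back is the leftmost deepest coverage plateau, flagged
`complete = FALSE` rather than silently splitting the cluster. Screen
percentages are rounded half-up to integers (2 of 3 clones reports as
67%).

## The confidence score

The score ranks prey genes by how surprising their fragment support is
under a null of indiscriminate competition for the bait: clones fall on
genes length-weighted (`w_g = L_g / sum(L)`), fragment placements are
uniform. For a cluster with `n_d` independent fragments (distinct 5′
starts — in a random-primed library, identical starts are most plausibly
amplification duplicates of one priming event):

- `p_count = P(X >= n_d)`, `X ~ Binomial(N, w_g)`, an exact tail sum;
- `p_overlap` = probability that the `n_d` representative fragments
  (longest per start) would share at least one residue by chance;
- `evalue = G * p_count * p_overlap` (Bonferroni over the `G` genes),
  thresholded A/B/C at 1e-10 / 1e-5 / 1e-2.

Singletons are category D outright: one fragment carries no
reproducibility evidence, whatever its e-value. Category E (connectivity
index — fraction of registry screens retaining the gene — at or above
`tau = 0.25`) and category F (registered artifacts) take precedence, in
that order below F. The thresholds are package defaults, exposed in
`pipeline_config()`; published screens of this design print categories but
no thresholds, and reproducing any particular historical score
implementation is a non-goal. A visible consequence of the surrogate:
full-core (conformational) clusters collapse to one or two distinct starts,
so their count term is weak even when the percentage evidence is
overwhelming — the score is at its best for linear epitopes with many
independent starts.

`p_overlap` is enumerated exhaustively when the start-combination space is
at most 1e6 and otherwise estimated by Monte Carlo (default 10,000 draws,
seeded). The Monte-Carlo estimate is Laplace-smoothed,
`(hits + 1) / (draws + 2)`, so it is strictly positive and the e-value
never degenerates to an exact zero; its resolution floor (~1e-4) only
matters multiplied into `p_count`, which carries the discriminating power.

## Tiling deconvolution

Gap-repair tiling tests sub-fragments of the smallest positive clone. The
narrowed region is the intersection of all positive tiles minus the union
of all negative tiles, keeping the longest remaining run (leftmost on
ties); inconsistent inputs (empty positive intersection, or negatives
covering it entirely) are errors, not empty results. Subtracting negative
residues reads each negative call as falsifying the residues it covers.
That is the information a *clean* negative carries, but a tile straddling
an epitope boundary would be called negative while covering true epitope
residues. The simulation used in the tests therefore models calls the way
the assay produces interpretable ones: the tiled region itself (the
smallest prey clone, a known positive) anchors the calls, tiles containing
the planted epitope are positive, tiles disjoint from it negative, and
boundary-straddling tiles are excluded as uninterpretable under a hard
two-outcome call. Under that model the recovered region provably contains
the epitope and avoids all negatives, which is what the tests assert.

## Homologue comparison

SID peptides are compared by global alignment (match +1, mismatch −1, gap
−2, linear; configurable — published figures of this kind name no scheme,
and at >90% identity the choice is immaterial). For more than two
sequences a center-star progressive alignment is built from the pairwise
alignments; pairwise identities are computed per pair from their own
global alignment (matches over aligned columns, dual-gap columns
excluded). The common SID block is the longest run of alignment columns
where every sequence has a residue — the cross-homologue narrowing step —
with identities recomputed inside the block.

## The synthetic generator

`sim_config()` defaults encode the screen conditions the analysis assumes:
insert lengths lognormal with untruncated mean 750 nt (between the 700 nt
and 800 nt means of fly and human placenta random-primed libraries),
σ = 0.5 and bounds [150, 3000] nt (the shape parameters are the package's
own choice; only the means are published); genes competing length-weighted;
uniform fragment starts; 50 genes of 150–500 aa (desk-scale: large enough
that the target weight is realistically small, small enough that a
hundred seeded screens run in seconds); a 21-aa planted epitope; screens
of a few dozen retained clones; background rate 5%.

Selection is a hard containment rule — a specific clone must be IF on the
target and span the epitope (linear) or the whole core (conformational) —
plus uniform background. This is the minimal mechanism producing the two
observed regimes; it deliberately omits affinity gradations,
mating-efficiency and colony-count noise, sequencing errors, and any
secondary true target. Background clones are drawn from the *non-target*
genes: a nonspecific binder on the target gene is experimentally
indistinguishable from a specific one, and including such clones would
make "the SID always contains the planted epitope" false for rare overlap
configurations without adding any testable signal. Consequently the
background count check uses weights renormalized over non-target genes.
Passing tests on these simulations show the pipeline's logic is correct
under its own null; they do not show robustness to real-data pathologies
(chimeric clones, mis-annotated CDS offsets, paralogue cross-mapping).

## Numerical and degenerate-input choices

- Ties everywhere break deterministically: lowest ORF id, then lowest
  start; reruns with one seed are byte-identical.
- `assign_prey` seeds with non-overlapping 15-mers and extends either
  exactly (`exact_match`) or ungapped with an X-drop of 10
  (`seeded_match`); placements below `min_match_nt` (>= 30) report
  unmapped. Any common substring of at least 29 nt contains a full seed,
  so no reportable placement is missed.
- Empty screens are valid inputs and produce empty, zero-total reports.
- Clones entirely within a UTR, or leaving no complete codon after
  clamping, are reported OOF by the mapper rather than failing the screen;
  the strict per-record operations (`classify_frame`,
  `to_residue_interval`) raise classed errors instead.

## Problem sizes in the test suite

Oracle comparisons run on 1,000 random clusters (protein lengths up to
500) and enumerated overlap instances up to L = 50, n = 3; simulation
recovery uses 100 seeded linear screens (32 clones, background 5%) and 50
conformational screens; tiling recovery 60 seeded designs of 17 tiles.
The bundled `synthetic_screen_suite()` reproduces the *published screen
compositions* (3/8/191/60/352 clones; SID spans 13–174, 2–178; 35/33/70-aa
myosin SIDs with a 29-aa, >93%-identical common block; a 7-clone giantin
cluster with a 250-aa SID) from synthetic sequences — it is a structural
stand-in built from the published summary numbers, not a copy of any
per-clone screen data.
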