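---
title: "Signature-based classification of siroheme sulfite reductase-like proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based classification of siroheme sulfite reductase-like proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siroclass)
```

## The biological problem

Dissimilatory sulfite reductase (Dsr) reduces sulfite to sulfide at a
siroheme center coupled to a [Fe4-S4] cluster. Methanogenic archaea carry a
family of open reading frames with Dsr-type structural signatures but
unknown function — Dsr-like proteins (Dsr-LP) — as well as the chimeric
F420H2-dependent sulfite reductase (Fsr), whose N-terminal half (Fsr-N) is
an F420H2-dehydrogenase homolog and whose C-terminal half (Fsr-C) is a Dsr
homolog. `siroclass` implements a rule-based annotation of these proteins
from their primary sequence, built on four signature families:

1. the **coupled siroheme-[Fe4-S4] site** — four conserved cysteines;
2. the **peripheral [Fe4-S4] cluster** (written `*`) — four further
   conserved cysteines of the Dsr-type electron-shuttling cluster;
3. an **additional ferredoxin-type [Fe4-S4] cluster** (written `**`) —
   absent from DsrA/B, located between the peripheral block and the
   C-terminus;
4. four **sulfite-binding Arg/Lys residues** (SB1–SB4, counted from the
   N-terminus).

A protein with the siroheme site alone is a **group I** Dsr-LP; adding the
peripheral cluster gives **group II** (a predicted evolutionary
intermediate — the rule engine deliberately reports it even though no
natural representative is known); adding the additional cluster as well
gives **group III**. Subgroups `a`/`b`/`c` lack SB1/SB2/SB3 respectively and
`d` carries all four; SB4 is invariably conserved in natural sulfite
reductases, so a missing SB4 yields no subgroup and an explicit
`MISSING_SB4` flag rather than a fifth subgroup. A protein combining an
FrhB-like core and a Dsr-like region in N→C order is classified as the
fused chimera **Fsr**; the reverse order is flagged
(`FUSION_ORDER_VIOLATION`) and left unclassified, since no such
architecture has been described.

Freestanding Fsr-N relatives are classified by domain architecture around
the FrhB core (the minimal F420-interacting unit): a bare core is
**FrhB-like**; a core with ≥2 ferredoxin-type motifs N-terminal and none
C-terminal is the **FpoF family** (Fsr-N, FpoF/FqoF, FGltS(I)-α, aFsr-β);
the mirror image is **FdhB-like** (FdhB, FGltS(II)-α). Genomic-context tags
(`glutamate_synthase_adjacent`, `aSir_adjacent`) refine FpoF-family and
FdhB-like calls into `FGltS(I)-alpha`, `aFsr-beta` and `FGltS(II)-alpha`
sublabels; without a context table the package does not attempt to
distinguish these clades.

## The anchor profile

Signature positions are defined by a packaged, versioned *anchor profile*
(`inst/extdata/anchor_profile.yaml`): a DsrB-like reference sequence with
twelve anchor sites (4 siroheme Cys, 4 peripheral Cys, 4 SB Arg/Lys), an
FrhB-core reference, the additional-motif coordinates, and the
ferredoxin-motif spacing. Both references are synthetic composites, tagged
`[synthetic]` in their FASTA headers: scaffolds whose anchor coordinates
are authoritative for this artifact rather than curated natural sequences.
This makes every classifier decision exactly testable; applying the
pipeline to real data is a matter of swapping in a profile built on a
natural DsrB/FrhB reference, with no code change. Two deliberate choices:

* The FrhB-core reference contains **no cysteine**, so ferredoxin-motif
  counts on a query can only come from genuine N-/C-terminal extensions.
* Some natural DsrB sequences couple the siroheme through a non-conserved
  cysteine outside the four canonical anchors; that position is *not* an
  anchor here and never counts toward siroheme-site presence.

## Detection

**Anchor mapping.** The DsrB-like reference is globally aligned to the
query (three-state affine-gap dynamic programming); each anchor site
reports the query residue aligned to its reference position. A site is
*occupied* iff that residue is in the site's allowed set (Cys for cluster
sites, Arg/Lys for SB sites); a site aligned to a gap is unoccupied —
absence of evidence at the anchor. The siroheme and peripheral sites are
called present when at least `siroheme_min_anchors` /
`peripheral_min_anchors` of their four cysteines are occupied. The default
is the strict 4-of-4, because the siroheme motif is the defining feature of
the family and ought to be intact; both thresholds are configurable down to
3 for degraded sequences.

**Ferredoxin motifs.** Cys-spacing pattern `C-x(2)-C-x(2)-C-x(3)-C`
(canonical bacterial-ferredoxin spacing; the gap ranges are configurable in
the profile), matched left-greedily and non-overlapping. The additional
(`**`) cluster is called when at least one motif lies strictly after the
mapped peripheral anchor block; if no reference position after the
peripheral block maps onto the query there is no evidence window and the
feature is absent.

**FrhB core.** The core reference is globally aligned to the query and the
score is normalized by the reference's self-alignment score; the core is
present when the normalized score reaches `core_score_threshold` (default
0.5). The threshold sits far above the empirical null — same-composition
shuffles score near or below 0 — while tolerating the end-gap cost the
global aligner charges for the flanking domains of a chimera.

One caveat worth stating: anchor occupancy is positional, so mapping the
Dsr reference onto a *non-homologous* query (an FrhB-family protein, a
random sequence) produces occasional chance hits — e.g. a lysine that
happens to align to an SB anchor. These fields are positional noise in that
regime, and the classifier never consults them without the siroheme gate,
so labels are unaffected; the test suite likewise compares them against
planted truth only where a Dsr-like region was planted.

## Alignment machinery

The aligner is a deliberately simple, fully specified stand-in for a
production MSA tool, not a replica of one:

* **Pairwise**: Needleman-Wunsch/Gotoh with affine gaps (a run of length
  *L* costs `gap_open + (L-1)·gap_extend`; defaults −11/−1 with BLOSUM62).
  Ties are broken substitution > gap-in-query > gap-in-reference, fixing a
  unique, deterministic traceback. Scores are verified against an
  independent recursion (itself validated by exhaustive path enumeration on
  tiny strings).
* **Multiple**: center-star merging of pairwise alignments around the
  record with maximal summed pairwise score ("once a gap, always a gap",
  insertions left-justified). Simpler and deterministic; adequate for the
  closely related families this package targets, and documented as
  non-equivalent to progressive aligners.
* **Trimming**: a column is kept iff its gap fraction ≤ `max_gap_fraction`
  (default 0.5) — a coarse, explicitly configurable proxy for
  conserved-block selection, idempotent by construction. The kept-column
  list maps trimmed to original coordinates.

## The tree stage

The phylogeny stage exists to test clade-structure claims (e.g. that group
I Dsr-LPs form a clade distinct from group III/Fsr-C-like sequences) at
desk scale, not to reproduce maximum-likelihood or Bayesian analyses:

* distances: mismatch fraction *p* under pairwise deletion, optionally
  Poisson-corrected `−ln(1−p)`; pairs at `p ≥ 0.95` are capped at the
  corresponding distance and flagged as saturated (the logarithm is
  unstable near 1);
* neighbor joining with a deterministic tie-break (lexicographically
  smallest pair of cluster labels, a cluster labeled by its smallest taxon
  id); negative branch lengths are clamped to zero and counted. NJ is exact
  on additive matrices, which the tests exploit as an oracle;
* bootstrap: columns resampled with replacement; the support of each
  internal edge of the *full-data* tree is the fraction of replicate trees
  containing the same bipartition (mirroring how support is usually drawn
  on a single tree, rather than building a consensus). Replicates with an
  undefined distance (a pair with no comparable columns) are dropped,
  counted and warned about;
* monophyly of a taxon set on an unrooted tree = the set forms one side of
  some edge bipartition; an outgroup-aware rooted variant is available.

## The synthetic generator

The generator is the package's stand-in for genome-mined sequence sets: it
emulates a reference-like protein family in which any subset of the
signatures has been planted or ablated, with tunable noise. Ablation is by
substitution (Cys→Ala at cluster sites, Arg/Lys→Ala at SB sites) rather
than deletion — mirroring how the natural subgroups differ, and keeping
coordinates fixed across labels. Architectures are built by concatenation:
the chimera template is two ferredoxin motifs + FrhB core + linker + an
intact group-IIId region (a chimera of roughly 540 residues against the
natural Fsr's 620, with the same N→C domain order). Noise is an independent
per-site substitution process — uniform over the 19 alternative residues, at
rate `mu` outside anchors and `anchor_mu` at anchors — plus Poisson-many
indels of length 1–3 placed uniformly; by default indels avoid anchor ±2
neighborhoods so planted truth stays well-defined (an adversarial mode
lifts this). Anchor coordinates are re-indexed across indels and returned
as part of the ground truth.

What the generator does *not* emulate: tree-structured evolution (sequences
within a family are i.i.d. around the template), realistic substitution
processes, domain-length variation, or compositional bias. Passing tests
therefore demonstrate that the detectors and classifier invert the
generator's feature model under noise — they do not certify performance on
real genomic data, where anchor conservation and inter-domain distances are
messier. The profile-swap design is the intended path to real data.

## Validation choices and problem sizes

The package validates itself at sizes chosen to keep the full suite fast
while leaving no rule untested: the classifier is enumerated over its full
2×2×2×16 feature space; zero-noise round trips cover all 16 concrete labels
× 10 replicates; the aligner is checked against an independent optimum on
200 random short pairs; NJ against 50 random additive matrices (n ≤ 8); and
the monophyly property on 20 seeded two-family datasets (groups Ia vs IIId,
8 sequences each, `mu = 0.03`/site, 100 bootstrap replicates, requiring
support ≥ 0.9 for both family clades). `scripts/acceptance.R` recomputes
all of these from scratch under a caller-supplied seed.

## Degenerate inputs and numerical notes

Empty FASTA, duplicate ids and non-amino-acid characters are hard errors
naming the offender. Alignment of an empty sequence is an error; an
all-gapped anchor mapping is legal and yields an unclassifiable feature
vector. Trimming may legitimately return zero columns, in which case the
tree stage is skipped by the pipeline. Q-matrix ties in NJ are resolved at
a relative tolerance of 1e-12 before the lexicographic tie-break; branch
lengths are written with `%.17g` so round-tripping through Newick preserves
path distances to well below the 1e-9 oracle tolerance. All pipeline
randomness derives from the single config seed (the bootstrap uses
`seed + 1`), and helpers that seed locally save and restore the caller's
RNG state, so identical inputs give byte-identical outputs.

## Known limitations

* Group labels rest on positional anchors; remote homologs whose anchors
  drift outside the aligner's reach will be under-called (no profile-HMM
  machinery by design).
* Center-star MSA quality degrades for deeply diverged inputs; the tree
  stage inherits that.
* The NJ/bootstrap stage is a stand-in: it tests clade structure on
  synthetic or user data, and makes no claim of equivalence to ML or
  Bayesian inference.
* Named Fsr-N clades (FpoF vs FqoF vs aFsr-β) are only distinguished when a
  context table is supplied; organism strings are reported verbatim, with
  no normalization.
* A protein with both N- and C-terminal ferredoxin extensions around the
  core matches no described architecture and is flagged rather than
  guessed at.
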