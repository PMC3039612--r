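---
title: "Mining and annotating plant Hsf families: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and annotating plant Hsf families: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsfminer)
```

## The biological model

Heat shock transcription factors (Hsfs) are the terminal activators of the
heat shock response. Plant Hsfs share a modular architecture: a conserved
DNA-binding domain (DBD) of roughly 100 residues near the N-terminus, a
flexible linker, an oligomerization domain (the HR-A/B region) built from
hydrophobic heptad repeats that drive coiled-coil trimerization, a basic
nuclear localization signal (NLS) just C-terminal of the HR-A/B region, and,
in class A proteins, a C-terminal activation domain carrying AHA motifs
(aromatic-hydrophobic-acidic activator modules) often flanked by a leucine-
rich nuclear export signal (NES).

Classification rests on the HR-A/B geometry: class A proteins carry a
21-residue insertion between the HR-A and HR-B heptad blocks, class C a
7-residue insertion, and class B none (a single continuous heptad pattern).
The linker length supports the same split (class-typical ranges 9--39,
50--78 and 14--49 residues for A, B, C), but only as corroborating evidence:
in the published maize family two class-C linkers (50 and 53 residues) fall
outside the stated class-C range, so `assign_class()` treats the linker as
an advisory consistency flag and lets the insertion rule decide. The
insertion tolerance is plus or minus 2 residues so that a single misplaced
heptad phase cannot flip a class.

`hsfminer` implements the complete mining workflow: profile detection of the
DBD, heptad-scan delimitation of the HR-A/B region, classification, motif
annotation, duplicate-pair calling, a neighbor-joining phylogeny of the
conserved N-terminal module with bootstrap support and reference-based
subclass assignment, and physicochemical and qPCR expression summaries.

## Domain detection

The original survey chained BLASTP, Pfam and SMART. To keep the pipeline
self-contained, `hsfminer` replaces those services with two internal
scanners whose behaviour is fully testable:

* **DBD profile scan.** A position-specific scoring matrix over the
  20-residue alphabet. The default profile (`hsf_dbd_profile()`) models each
  column of a 91-residue DBD template - the published 52-residue DBD core
  consensus extended by fixed flanks - emitting its consensus residue with
  probability 0.5 and background residues otherwise; scores are log2
  odds against the Swiss-Prot average composition. The acceptance threshold
  defaults to 0.6 times the profile's self-score. An external P-value
  threshold (the survey used BLASTP at 0.001) does not transfer to a
  different scoring system; a relative self-score floor does, and 0.6
  separates template copies carrying 8% per-site noise (expected score about
  0.85 of self) from shuffled sequences (measured false-positive rate below
  5%, and 0 in most runs) with a wide margin. The ambiguity code X scores 0
  everywhere; B/Z/U are rejected on input.

* **Heptad scan** (`find_hrab()`). A coiled-coil heptad is a 7-residue unit
  `abcdefg` with hydrophobic residues (L/I/V/M/F) at `a` and `d`. The
  scanner marks every position whose `a` and `d` slots are both
  hydrophobic and chains such heptads at step 7 (same register). Chains of
  at least 2 heptads are candidate blocks; the best-scoring ordered pair of
  blocks separated by at most 30 residues becomes HR-A and HR-B, the gap
  between them is the insertion, and a lone block is a continuous (class-B
  style) region. Requiring *both* `a` and `d` is deliberate: with an
  either/or rule a planted NES (for example `LENLALNI`, L at offsets 1 and
  4) seeds a spurious two-heptad chain downstream of a genuine continuous
  block, and the pair selector then reports a fake insertion. The 30-residue
  pair cap reflects that the largest biological insertion in this family is
  21 residues; more distant hydrophobic blocks are separate features, not an
  insertion.

Candidate filtering (`identify_candidates()`) mirrors the published order:
keep proteins with a DBD hit, collapse isoforms mapping to the same
chromosome location (longest protein wins; ties go to the lexicographically
smallest id so reruns are identical), then require an HR-A/B region.
Per-stage drop counts are logged.

## Motif scanners

The three motif scanners are rule-based stand-ins for PredictNLS, NetNES and
manual AHA curation. Their rules were calibrated once against the 25 NLS,
13 NES and 16 AHA strings printed for the maize family (bundled as
`hsf_table2()`), under two constraints: every printed string must be
detected when embedded in neutral context, and length-matched background
windows must fire in fewer than 5% of draws. "Background" here is the
composition the scanners actually scan in this pipeline - polar spacers and
disorder-like flank residues (S/T/N/Q/G/A/P/D/E/H/K/R) - not globular-core
sequence; that is a deliberate idealization and the main caveat when
applying the scanners to arbitrary proteins.

* **NLS**: maximal clusters of K/R (consecutive basics at most 3 apart).
  Monopartite hits need at least 3 basics within at most 7 residues, basic
  first and last residues, and a basic fraction of at least 0.6. Bipartite
  hits are two clusters (at least 2 and 3 basics) separated by a 5--12
  residue spacer, rendered in the compact notation `KRK7KKRRR`. Hits are
  ranked by proximity to the HR-B end and the nearest is flagged primary,
  reflecting the experimental finding that only the cluster adjacent to the
  HR-A/B region acts as the functional NLS. The published motif set forces
  the 3-basic minimum (printed NLSs such as `RKK` and `KRMR` have only 3);
  the density requirement is what keeps the background rate low against
  K/R-containing disordered flanks.

* **NES**: windows of 5--12 residues, hydrophobic (L/I/V/F/M) first and
  last residue, at least 2 hydrophobics, hydrophobic density at least
  0.375; overlapping windows merge to the best-scoring. The published NES
  entries are heterogeneous (one has only 2 hydrophobics in 5 residues), so
  the rule is intentionally permissive and relies on the terminal-residue
  anchors plus the hydrophobic-free background for specificity.

* **AHA**: windows of 8--12 residues scored by their fraction of aromatic
  (W/Y/F), hydrophobic (L/I/V/M) and acidic (D/E) residues, requiring at
  least one of each class and a fraction of at least 0.5 - the minimum over
  the printed family motifs (`EQIWGVDASA` and `LKMFESGVLN` sit exactly at
  0.5, and `AQPWAEMDE`'s only hydrophobic is M, which is why M is in the
  set). At most two non-overlapping hits are reported, matching the AHA1/
  AHA2 layout of real activation domains. Class B and C members never
  receive AHA hits in reports - these classes lack activator function - so
  scanner hits there are suppressed and flagged rather than shown.

Annotation regions follow the family architecture: NLS and NES are scanned
from the HR-B end to the C-terminus, AHA from the primary NLS onward. The
one published NES located inside an HR-A/B region is treated as an
annotated exception, not something the scanner should target.

## Duplicate-pair calling

`global_align()` is a Needleman-Wunsch alignment with affine gaps (open 10,
extend 0.5, BLOSUM62), implemented in C++ with fixed traceback tie-breaking
(diagonal, then gap in the first sequence) so results are reproducible; its
optimality is tested against exhaustive enumeration of all alignments on
small inputs. A pair is a duplication when the aligned (both-residue)
columns cover more than 80% of the longer protein and the similarity of the
aligned region exceeds 70% - both strict, so a coverage of exactly 0.800
fails. Similarity counts positive-scoring substitutions by default
(`mode = "positives"`); the source criteria say "similarity" without
defining it, and positives are the standard reading, with identity
selectable. The coverage denominator is the longer protein's residue count
(the analysis is protein-level). Pairs on the same chromosome are tandem
duplications, pairs across chromosomes segmental.

## Phylogeny

Trees are built from the conserved N-terminal module (DBD start through
HR-B end, `extract_nterminal()`), the region informative across the family.
The pipeline is: progressive multiple alignment, pairwise-deletion
p-distances, Poisson correction `d = -ln(1 - p)`, Saitou-Nei neighbor
joining, column-bootstrap support.

The progressive aligner replaces ClustalX: a UPGMA guide tree on 3-mer
Jaccard distances drives profile-profile Needleman-Wunsch merges. Every
tie (guide-tree joins, merge orientation, DP traceback) is broken
canonically in the sequence ids, so permuting the input permutes only row
order. A pre-computed external alignment can be passed directly to the
distance and tree functions to decouple alignment quality from tree logic.

Neighbor joining breaks Q-criterion ties by the lexicographically smallest
label pair and clamps negative branch-length estimates to zero (flagged via
an attribute), the convention familiar from mainstream tree software. On
additive matrices the implementation reproduces the generating tree exactly
(tested on random trees of up to 12 taxa against an independent simulator).
Bootstrap support resamples alignment columns with replacement - 1000
replicates by default, per the family-survey convention - rebuilds each
replicate tree and maps the percentage of replicates containing each
original bipartition onto the original tree (not a consensus tree), which
matches how such trees are presented. A replicate whose resampled columns
leave some pair with no shared sites is skipped, which only deflates
support. Saturated pairs (p-distance 1 after resampling) are capped just
below 1 before correction. Rooting places the root at the midpoint of the
outgroup's pendant edge (the yeast Hsf1 ortholog is the conventional
outgroup for this family). Subclass assignment gives each query the label
of the smallest clade with bootstrap support strictly above 50 that
contains the query and at least one labeled reference; clades mixing
reference labels leave the query unassigned and flagged, so annotation
conflicts are reported rather than arbitrated.

## Physicochemistry, EST matching and expression

Molecular weight sums average residue masses plus one water (average, not
monoisotopic, matching protein-survey scale). Net charge is a
Henderson-Hasselbalch sum over termini and D/E/C/Y/H/K/R side chains; the
pKa set is selectable (EMBOSS default, Sillero and DTASelect alternatives)
because published pI tables rarely state their source tool - agreement
within about 0.2 pH units is the realistic expectation across sets. The pI
is found by bisection on the bracket (net charge is strictly decreasing in
pH); convergence is on bracket width rather than charge magnitude because
titration curves can be nearly flat around the pI, where a charge-based
stop fires early and cheaply loses precision.

EST matching applies the digital-expression criteria - identity above 95%,
aligned length above 200 bp, E-value below 1e-10 - to the optimal local
alignment (Smith-Waterman, exact rather than seed-and-extend, affordable at
desk scale). The E-value is Karlin-Altschul `K m n exp(-lambda S)` with
lambda solved numerically from the match/mismatch scoring system and K an
approximate constant; the criteria operate far from the E-value boundary,
so the approximation is immaterial in practice.

Relative expression uses plain delta-delta-Ct: per condition,
`dCt = mean Ct(gene) - mean Ct(reference)`; `ddCt` is treated minus
calibrator (the unstressed condition); fold change is `2^(-ddCt)`,
normalized to the Actin-style internal control. No amplification is encoded
as an `NA` Ct; genes silent in both conditions are `not_expressed`.
Response categories use the strict published thresholds: above 2-fold up,
below 0.5-fold down, boundaries inclusive to "unchanged". Amplification-
efficiency correction is out of scope, as in the source protocol.

## The synthetic family generator

`simulate_family()` makes every downstream stage testable without
downloads. Its defaults are the published family's study conditions: 25
members split 15/7/3 across classes A/B/C, insertions 21/0/7, class-typical
linker ranges, and 9 planted duplicate pairs of which the first is tandem
and the rest segmental - the published 8-to-1 split. Each member is
assembled as flank, DBD (the bundled template with 8% per-site
substitution noise), linker, HR-A (3 heptads with L/I/V/M at `a`/`d`),
insertion, HR-B (2 heptads), then spacer, NLS, optional NES, and for class
A one or two AHA motifs, then a final flank.

Composition is engineered so that every feature is the only signal of its
kind: heptad non-core positions, insertions and motif spacers use a
7-letter polar alphabet; terminal flanks and the linker use a 12-letter
disorder-like alphabet that adds D/E/H/K/R but still excludes the
hydrophobic and aromatic residues the NES/AHA scanners key on. Flank
lengths are drawn from 20--150 residues, giving member lengths of roughly
250--500 aa - the spread of the real family (257--528 aa). Both choices
matter for the duplication stage: with uniform short flanks and a single
polar alphabet, unrelated members are so alignable that they pass the
80%/70% criteria; under the realistic spread, exactly the planted pairs
pass.

Duplicates are made by `mutate_duplicate()`: i.i.d. substitutions at the
configured divergence (default 5%), with substitutions at heptad `a`/`d`
positions resampled within the hydrophobic set - purifying selection on the
coiled-coil register, without which a third of duplicates lose a heptad and
their class. Short indels (Poisson count, 1--3 residues) are confined to
the terminal flanks so all internal ground-truth coordinates shift by a
single computable offset. Expected identity remains one minus the
divergence, and the operation deliberately does not compose (two rounds at
d are not one round at 2d). Every record draws its RNG stream from
(seed, id), so enlarging a family never perturbs existing members.

What the generator does *not* emulate: real DBD sequence diversity (one
template with i.i.d. noise, no indel structure inside domains), genuinely
disordered flanks (i.i.d. letters, no low-complexity runs), motif
degeneracy beyond the template sets, and genome-scale decoy proteomes.
Passing the recovery tests therefore shows the pipeline's logic is correct
under the family's declared architecture, not that the scanners would
retain their specificity on a full proteome.

The Ct simulator mirrors the published heat-shock assay: 25 target genes -
12 configured above 2-fold up, 5 below 0.5-fold down, 5 unchanged, 3 with
no amplification - plus the reference gene, 3 replicates, baseline 24
cycles and 0.25-cycle measurement noise. At zero noise the recovered folds
are exact by construction; at the default noise a gene whose true fold sits
near a strict category boundary can cross it, which is faithful to the
assay being modeled.

## Problem sizes and numerical conventions

The bundled checks run at desk scale by design: the default 25-member
family end to end with 1000 bootstrap replicates, a 60-member family for
recovery rates, brute-force alignment oracles on 3-letter sequences up to
length 6 (exhaustive up to length 2 plus seeded samples - the full cross
product of all ~1100 sequences is out of proportion to what it would
prove), 100 random additive trees for the neighbor-joining oracle, and
dense-grid oracles for the isoelectric point. All coordinates are 1-based
inclusive, the notation of the published domain tables; half-open
conversions are private. All randomness flows from explicit seeds, and
every report writer is byte-deterministic.
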