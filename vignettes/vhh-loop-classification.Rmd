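---
title: "Classifying VHH CDR3 loop conformations and designing structure-guided synthetic libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying VHH CDR3 loop conformations and designing structure-guided synthetic libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhhkit)
```

## The problem

A camelid VHH binds antigen without a light chain, and the conformation of
its CDR3 loop relative to framework region 2 (FR2) shapes the paratope.
Three gross conformations occur: an extended loop standing away from FR2
(*Upright*), in which FR2 residues are solvent-exposed and often join the
paratope; a loop folded back over FR2 (*Roll*), stabilized by hydrophobic
FR2 hallmark residues, in which the whole CDR3 recognizes the antigen; and
an intermediate (*Half-Roll*). Human VH domains, whose FR2 faces the light
chain, are almost exclusively Half-Roll: Upright and Roll are VHH-specific
conformations, which is why a synthetic VHH library intended to reproduce
camelid binding behaviour should be designed around them.

vhhkit implements (i) the two-index geometric classification of CDR3
conformations, (ii) the curation machinery for building a structure dataset
on which such statistics are computed, (iii) contact-based paratope mapping,
(iv) a four-sub-library synthetic VHH library designer with exact diversity
accounting, and (v) the post-screening triage arithmetic used when such a
library is panned against a target.

## The classification indices

For a Kabat-numbered domain, let *n* denote the CDR3 endpoint H102. Two
indices are computed from the Cα trace:

* **d** (Å): the distance between Cα(H46) and Cα of residue (*n* − 5),
  walking back five positions through the numbered chain (insertion-coded
  residues count as ordinary positions). H46 sits in the middle of FR2, and
  (*n* − 5) sits in the loop body, so d measures whether the loop folds over
  the framework.
* **θ_base** (degrees): the pseudo-dihedral over the Cα atoms of residues
  (*n* + 1), (*n*), (*n* − 1), (*n* − 2) — the torsion of the loop's
  C-terminal anchor. It is the standard right-handed torsion about the
  central axis, computed by the cross-product/atan2 formulation and mapped
  from (−180°, 180°] to [0°, 360°) by adding 360° to negatives. The wrapped
  convention is used because the Upright population spans the 180° branch
  point (140° to 360°), where a signed convention would split it in two.

The class is a fixed partition of the (θ, d) plane: **Upright** iff
θ ≥ 140° and d ≥ 15 Å; **Roll** iff θ < 140° and d < 10 Å; **Half-Roll**
otherwise. Boundary handling follows the convention that the Upright corner
is closed (≥) and the Roll corner open (strict <); mixed combinations,
including the d ∈ [10 Å, 15 Å) band, are Half-Roll. The thresholds are
arguments of `classify_loop()`, so a user can move them, but the defaults
are the published operating point and the partition property (exactly one
class per point) holds for any threshold choice. Loops shorter than five
residues leave the indices undefined; they are reported as *Indeterminate*,
with an optional user-supplied manual label mirroring visual classification
of such structures.

A known internal tension in the published description of the Roll region
(one statement of the distance rule uses "less than 10 Å", another "10 Å or
more") is resolved in favour of d < 10 Å, which is the physically consistent
reading — a loop covering FR2 brings (*n* − 5) close to H46 — and is what
`classify_loop()` implements.

## Kabat numbering

The numberer anchors on four nearly invariant motifs: the first framework
cysteine (H22), the FR2 tryptophan (H36), the second framework cysteine
(H92), and the FR4 W-G-x-G motif (H103), with fixed inter-anchor framework
lengths (FR1 25, FR2 14, FR3 29, FR4 11 positions). CDR length variation is
absorbed per the Kabat convention: insertions lettered at 35 (CDR1), 52
(CDR2) and 100 (CDR3); short loops truncate, with CDR3 keeping its final
H101/H102 positions (a 5-residue CDR3 is numbered 95, 96, 97, 101, 102).
The CDR1 region of the shipped scheme is the Kabat/Chothia union H26–H35
(a pure-Kabat H31–H35 variant is available); CDR2 is H50–H65 and CDR3
H95–H102, so the insertion-free baselines are 16 and 8 residues, and the
Roll-preferred 17-residue CDR2 carries a 52A insertion.

This heuristic is deliberately simple and auditable rather than a full
profile-HMM aligner: it fixes framework lengths, so domains with framework
indels (notably the common 82a/b/c FR3 insertions of full-length antibody
numbering) are out of its scope. When bit-exact parity with an external
numberer is needed, `apply_external_numbering()` ingests a position-mapping
table verbatim (0-based `seq_index`, `kabat_number`, `insertion_code`
columns; `read_anarci_csv()` parses the wide CSV format of ANARCI-style
tools), validates monotonicity, and produces the same `DomainNumbering`
object.

## Dataset curation and statistics

`filter_records()` applies the dataset-construction rules — heavy-chain-only
(or paired, for a human VH reference set), X-ray method, resolution strictly
better than 2.8 Å, optional species match, and hapten exclusion — and logs
every rejection by rule; records missing required metadata are rejected with
reason `missing-metadata`, never silently kept. "Hapten-antigen complex" is
operationalized as a declared convention: no polymer antigen chain and all
non-water ligands below 1000 Da (overridable per record), since the original
criterion is not stated operationally. `dedup_exact()` removes 100%-identity
duplicates (the only clustering level used), keeping the best-resolution
representative and breaking ties by entry id. Dataset sizes (e.g. 330 VHH /
926 human VH) are snapshots of a live database and therefore not fixed
constants of this package; the pipeline logs the counts for whatever
snapshot it is given. `class_length_summary()` produces the CDR3-length
histogram per class, the CDR2-length-by-class contingency with row
percentages (the statistic behind "Roll-type domains have mostly 17-residue
CDR2s, Upright mostly 16"), and the cysteine fraction stratified at CDR3
length 16 — long CDR3s tend to carry an extra Cys forming a stabilizing
disulfide, which is why the library design caps CDR3 at 15.

## Paratope mapping

`contact_residues()` declares an antibody residue a contact iff its minimum
heavy-atom distance to any antigen chain is within the cutoff. The default
cutoff is 4.5 Å — a conventional heavy-atom contact distance; the published
analysis never quantifies "close to the antigen", so exact reproduction of
that figure is not possible and the cutoff is exposed as an argument.
Hydrogens are ignored (rarely present in X-ray models at the resolutions
admitted by curation). `region_usage()` aggregates contacts into the seven
regions; fractions sum to one. Upright-style complexes show non-zero FR2
usage; Roll-style complexes concentrate in CDR3.

## Library design and sampling

The designer builds four sub-libraries: *Upright 6*, *Upright 12*,
*Roll 12*, *Roll 15* (the number is the randomized CDR3 length). Invariants
enforced at validation: every Upright CDR2 has 16 residues and every Roll
CDR2 17; the CDR3 alphabet is the 17-letter set excluding Cys (unwanted
disulfides), Met and Pro (oxidation- and structure-liability); CDR3 length
is at most 15. Default repertoire sizes are 150 CDR1 sequences and 71/69
CDR2 sequences (Upright/Roll); default CDR3 lengths 6/12/12/15. These
defaults are the study conditions of the design, not tuning knobs.

Because the actual humanized framework sequences of a proprietary library
are not public, the shipped scaffolds are synthetic DP-47/IGHV3-23\*01
-flavoured placeholders trimmed to the fixed framework lengths, with the
two FR2 variants differing at the hallmark tetrad H37/H44/H45/H47
(camelid-like F/E/R/F for Upright, whose FR2 is solvent-exposed and
paratope-forming; VH-like V/G/L/W for Roll, where the loop buries FR2).
Any real scaffold can be supplied through the YAML/R config of
`build_design()`.

Likewise, the curated CDR1/CDR2 repertoires of a real library are not
public; `make_repertoires()` generates distinct random stand-ins of the
correct sizes and lengths. The default design draws them from a 20-letter
alphabet minus Cys and Trp: curated camelid loop repertoires essentially
never carry a free cysteine, and excluding tryptophan keeps the four-anchor
numbering heuristic unambiguous on every sampled sequence (the first Trp
after CDR1 must be the FR2 anchor). `make_repertoires()` itself defaults to
the full 20-letter alphabet for generic use.

CDR3 randomization models equimolar trimer-phosphoramidite synthesis as iid
uniform draws over the 17 letters, with no coupling between positions — the
idealization of "equally mixed" trimers. `composition_qc()` quantifies how
close a sampled (or sequenced) CDR3 population is to that design: per
position, the total-variation distance from uniform (½ Σ|f − 1/17|) and a
chi-square statistic on 16 degrees of freedom. At 100,000 sequences the
expected per-position TVD is well under 0.02, the bound asserted in the
tests.

Diversity is the theoretical sequence space |CDR1| · |CDR2| · 17^L per
sub-library, computed in exact integer arithmetic (a small base-10⁴
big-integer routine; the Roll 15 space, ≈ 3 × 10²², exceeds the exact range
of doubles). Physical molecule counts of a synthesized library are a
different quantity and out of scope. Reverse translation uses one codon per
amino acid (trimer semantics) from a validated table (no stop codons, each
codon translating to its key); cassette assembly concatenates
5′UTR–VHH–His-tag–3′UTR with 0-based half-open coordinates; the restriction
audit reports exact matches of BsmBI (CGTCTC) and BtgZI (GCGATG) recognition
sites on both strands, since stray internal sites would break Golden-Gate
style assembly.

## Screening triage

`call_binders()` applies the BLI response threshold strictly (> 0.1);
`unique_clones()` counts unique full protein sequences (uniqueness by
identical CDR sets would be an alternative reading; full-sequence identity
is the implemented convention). `attribute_sublibrary()` labels a clone by
the unique sub-library whose frameworks match exactly, whose CDR1/CDR2 are
repertoire members and whose CDR3 length matches — zero or multiple matches
give "other", the bucket for clones mutated during screening.
`select_window()` selects development candidates with K_D < 1 nM and
T_m > 60 °C, both strict; 60 °C is the default because it matches the
plotted selection window, while a stricter 65 °C variant is also in
circulation — the threshold is an argument.

## The synthetic-data generators, and what passing tests mean

`make_loop_trace()` builds a chain whose five geometry-defining Cα atoms are
placed analytically: the torsion quad is constructed in a local frame from
the target angle, and H46 is placed at exactly the target distance from the
(*n* − 5) residue; remaining residues lie on a smooth generic trace. No
optimization loop is involved, so `loop_geometry()` recovers the targets to
1e-6 over a full (θ, d) grid — this validates the measurement machinery, not
the biology. Fixtures are plausible (≈ 3.8 Å Cα spacing) but not
force-field-validated, and the classification thresholds themselves are
taken as given: tests demonstrate that the indices and the partition are
computed correctly, not that real VHH structures fall where the published
scatter plot puts them. Verifying the latter requires real structures
(e.g. the classification of downloaded exemplar entries), which the offline
test suite deliberately does not depend on.

`make_clone_table()` plants ground truth: known sub-library proportions,
duplicate and mutant rates (mutants get one FR2 substitution, guaranteeing
"other" attribution), binder fractions with responses drawn clear of the
0.1 threshold, log-uniform K_D over 10⁻¹² to 10⁻⁷ M and normal T_m
(mean 65 °C, sd 8 °C) with T_agg slightly below T_m — realistic marginals
for a VHH screening campaign, but with no correlation structure between
affinity and stability.

## Numerical choices and problem sizes

Degenerate torsions (coincident or collinear points) raise typed errors
rather than returning NaN. Altloc resolution keeps the highest-occupancy
conformer, ties broken by label order. PDB fixed-column output limits
coordinate round trips to 1e-3 Å, which propagates to ≈ 0.05° in recovered
angles; in-memory fixtures are used where 1e-6 recovery is asserted. The
test suite exercises the torsion oracle on 10⁵ random quadruples, the class
partition on an exhaustive 0.5° × 0.1 Å grid, the fixture round trip on a
36 × 20 target grid, composition QC on a 100,000-sequence sample, and the
curation statistics on a seeded n = 1000 class-conditional simulation —
sizes chosen so the full suite completes in about a minute while the
binomial bounds being asserted are sharp.

## Known limitations

* The Kabat heuristic assumes the four anchor motifs and fixed framework
  lengths; unusual domains need an external numbering table.
* Hapten exclusion is a molecular-weight heuristic, declared rather than
  derived.
* The paratope cutoff is a convention; published contact figures without a
  stated cutoff cannot be reproduced exactly.
* Scaffolds and repertoires shipped by default are synthetic placeholders;
  conclusions about a specific real library require its real inputs.
* No canonical-class prediction from sequence, no loop modelling, no
  molecular-dynamics validation of sampled designs — the package stops at
  geometry measured from coordinates that already exist.
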