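---
title: "Analysing tandem C2H2 zinc-finger arrays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing tandem C2H2 zinc-finger arrays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfarray)
```

## The problem

Many transcription factors read DNA through long tandem arrays of C2H2
zinc fingers: ~25-residue domains in which two cysteines on a β-hairpin
and two histidines on an α-helix hold a zinc ion, and the helix lies in
the major groove. The immune-regulatory protein ZFAT (human UniProt
Q9P243) is an extreme example — eighteen fingers plus an AT-hook — and is
the kind of system this package was written around. Solution-NMR studies
of such arrays pose four recurring analysis tasks, which map onto the
package's modules:

1. **Where are the fingers, and of which kind?** Detect the
   C-x(2,4)-C-x(10,14)-H-x(3,5)-H motif in the sequence, classify the
   Cys spacer (C-X2-C Krüppel-like loop versus the rarer C-X4-C extended
   loop) and the His spacer, which fixes the helix class: H-X3-H is the
   canonical recognition helix, H-X4-H inserts one residue and makes the
   final helical turn *bulge out*.
2. **What does the bulged-out turn look like in the ensemble?** The
   wider turn is closed by a π-type backbone hydrogen bond donated by the
   second His to the residue five before it (which in an H-X4-H finger is
   exactly the first His). Whether the turn is genuinely π-helical is
   decided by the backbone dihedrals of the second His and of the residue
   just before it, summarised over the NMR ensemble as mean ± SD and
   compared against the ideal α (φ = −65.0°, ψ = −40.0°) and ideal π
   (φ = −57.1°, ψ = −69.7°) references.
3. **How rigidly are neighbouring fingers coupled?** Superpose every
   conformer on one finger and measure the residual spread of a
   neighbour as a per-model RMSD; short atypical linkers (KKIK, GAAP)
   can restrain neighbours that the canonical TGEKP linker leaves free
   in the absence of DNA.
4. **What DNA might the array prefer?** Apply a recognition code — an
   empirical map from the residues at helix positions −1, +2, +3, +6
   (and +10 in bulged-out fingers) to preferred bases — per finger, and
   assemble per-unit composite sites antiparallel (each more C-terminal
   finger binds the next triplet toward the 5′ end).

Because the deposited coordinate sets behind such studies are external
database entries, every stage here is also exercised by a synthetic-data
module that builds sequences and multi-model structures with known
ground truth.

## Conventions and key parameters

**Residue numbering.** Author numbering from the coordinate file is used
throughout; nothing is renumbered. Deposited constructs often carry
expression tags (a GSSGSSG N-terminal tag is common), so sequence-derived
finger positions are mapped onto structures by an explicit
`numbering_offset`; `detect_numbering_offset()` can find it by aligning
the four coordinating positions to CYS/CYS/HIS/HIS residue names, and is
deliberately overridable.

**Scanner windows.** The spacer windows (Cys spacer 2–4, core 10–14, His
spacer 3–5 residues) cover all finger variants seen in ZFAT-like arrays
while excluding chance Cys/His pairs, and are exposed as arguments of
`scan_fingers()`. Matching is greedy left-to-right and non-overlapping,
with shortest-spacer preference on ties — deterministic, and correct on
tandem arrays where fingers follow each other closely. Fingers with a
five-residue His spacer are classified `other` rather than forced into
either helix class. The reported finger span is `cys1 − 2` through the
second His; motif boundaries, not construct boundaries.

**Helix key positions.** The first coordinating His sits at helix
position +7, so the key positions are located from it: −1 → his1−8,
+2 → his1−5, +3 → his1−4, +6 → his1−1, +10 → his1+3. +10 is only
reported for bulged-out fingers, where the wider turn brings it onto the
DNA face.

**Linker typing.** `canonical_TGEKP` requires a five-residue match of
T-G-[E/Q]-[K/R]-[P/S]; linkers longer than 8 residues are `long_spacer`
(and break tandem units, threshold exposed); everything else is
`atypical`. The 8-residue threshold reflects the observation that
functional recognition units are joined by linkers of roughly
TGEKP-length, while inter-unit spacers are several-fold longer.

**Dihedral statistics.** Per-model angles are wrapped to (−180°, 180°];
the ensemble mean is the circular mean, and the SD is the sample
(n−1) standard deviation of the shortest angular deviations from that
mean. For helical angles far from ±180° this is numerically identical to
the arithmetic convention customarily printed for NMR ensembles; at the
wrap point it remains well defined, and the synthetic tests exercise that
case explicitly. Whether deposited ensembles report SDs over all 20
conformers or a subset is generally unstated; we assume all models.

**Hydrogen-bond criterion.** N···O < 3.5 Å, plus (when an amide
hydrogen is present) H···O < 2.6 Å and N–H···O > 120°. The literature on
bulged-out helices asserts the π bond's existence without printing
criteria, so the common geometric rule is used; over an ensemble the
bond is summarised as the fraction of models in which it forms, with a
default 0.5 fraction for the boolean flag — a bond that a summary calls
"formed" should be present in most conformers, not one.

**Zinc-site windows.** Ligand–Zn distances in [1.8, 2.6] Å and
ligand–Zn–ligand angles in [90°, 130°] flag a site as tetrahedral; both
windows bracket restrained NMR coordination geometry and are arguments,
not constants. Without a zinc atom the ligand centroid serves as a
pseudo-zinc and the report is flagged `inferred`.

**Superposition.** Proper-rotation Kabsch via SVD with the determinant
correction; reflections are never returned, and near-collinear point
sets warn about conditioning. The test suite checks the minimised RMSD
against a brute-force quaternion-grid-plus-polish oracle to 1e−9 and
against an independent implementation.

**Flexibility reference.** Published interfinger RMSDs rarely state
whether the spread is measured against a mean structure, a single model,
or all model pairs. The default here is the two-pass mean fit — superpose
on model 1, average, re-superpose once onto the mean, measure against
the final mean — which is the standard convention for NMR ensemble
precision. `reference = "model1"` and `"pairwise"` are provided for
validation against numbers computed under other conventions; pairwise
means run systematically higher (each pair accumulates two deviations
from the mean). Cα is the default atom set, appropriate for interdomain
displacements of tens of Å; a backbone set is available. Identical fit
and measure ranges are allowed (the self-spread of the fitted core);
partially overlapping ranges are rejected rather than silently truncated,
because neighbouring domain ranges in deposition records often share a
boundary residue and the caller should decide which side owns it.

## The recognition-code table

The residue→base calls are data, not code: a three-column delimited
table (`position`, `amino_acid`, `bases`) shipped at
`inst/extdata/recognition_code.tsv` and replaceable by the user. The
packaged default holds the classical canonical-code entries (Arg/Lys → G,
Asn/Gln → A, Glu/Asp → C, His → G at +3, small side chains → T). Two
assembly conventions needed fixing where the field is loose:

* **+2 cross-strand contact.** The +2 residue touches the complementary
  strand just 3′ of the finger's triplet. The table stores the contacted
  base; the prediction reports its complement appended 3′ on the
  finger's reading strand, so every subsite is a single-strand 5′→3′
  string.
* **+10 in bulged-out fingers.** Treated as an additive extended contact
  prepending a 5′ base — but only when no +2 entry already supplied the
  fourth base, keeping subsites at 3–4 nucleotides. Unknown residues
  yield N rather than an error, since ZFAT-like fingers carry many
  non-canonical key residues; several preferred bases collapse to IUPAC
  ambiguity codes.

Composite sites concatenate member subsites in reverse finger order
(antiparallel binding). The N-half/C-half AT-versus-GC summary counts
only bases whose IUPAC code resolves to one class (A/T/W vs G/C/S).

## The synthetic-data module

The generators are first-class, tested code, and define the conditions
under which the analyses are validated:

* `build_peptide()` places backbone atoms by internal-coordinate
  chaining (NeRF) from fixed ideal bond geometry (N–CA 1.458 Å,
  CA–C 1.525 Å, C–N 1.329 Å, trans ω by default), so any φ/ψ table can
  be realised and must be recovered by `backbone_dihedrals()` within
  0.1° — the two implementations share no code path for the torsion.
* `make_finger_ensemble()` adds isotropic per-coordinate Gaussian noise;
  its expected RMSD to the ensemble mean has the closed form
  σ√(3(M−1)/M).
* `make_hinged_ensemble()` builds two helical domains joined by a
  glycine linker and rotates domain B per model by an angle drawn from
  N(0, σ) about one seeded random axis through the hinge CA. Domain A
  stays fixed, so the flexibility statistic sees exactly the injected
  spread, with closed-form expectation
  R·E[√(1 − 2ρcosθ + ρ²)], ρ = e^(−σ²/2), where R is the rms
  perpendicular distance of the measured atoms from the axis. One
  deliberate simplification: the rotation is applied to the downstream
  half of the linker as well, and the one peptide bond at the hinge may
  distort. Exact chain closure under interpolated dihedrals is an
  inverse-kinematics problem out of proportion to a geometric test-bed;
  the domains themselves stay internally rigid, which is what the
  statistic measures. Models clashing into domain A (any CA–CA contact
  under 2 Å) are redrawn, up to 100 times.
* `make_motif_sequence()` plants C2H2 motifs of chosen spacer classes
  over a background alphabet that excludes Cys and His, so ground truth
  is unambiguous and spurious matches are impossible by construction.

What passing these tests does and does not show: the synthetic ensembles
have exact geometry, a single rigid hinge, no side chains beyond the
coordinating atoms, and backgrounds that cannot fake motifs. Real
depositions have restrained-but-imperfect geometry, several coupled
degrees of freedom between domains, and sequences in which Cys/His pairs
can occur by chance near true fingers. The synthetic suite therefore
validates the *machinery* (conventions, statistics, determinism,
parameter recovery); validation against real depositions is a separate
step, driven by `reproduce_reference_analysis()` on locally downloaded
copies of the relevant UniProt/PDB entries (see the test suite's
acceptance file for the expected values and tolerances).

Problem sizes used by the checks — 200 planted-motif sequences for
scanner recall, 100-model hinged ensembles at σ ∈ {5°, 15°, 30°},
200-model ensembles for angular-SD recovery — were chosen so that
sampling error sits well inside the 15 % recovery bands while the whole
suite stays desk-scale.

## Numerical and degenerate-input choices

* Alternate locations resolve to the highest occupancy, first-seen on
  ties (NMR files rarely have any; the rule just needs to be
  deterministic).
* `select_atoms()` enforces cross-model completeness at selection time,
  naming the first missing (model, residue, atom) — load time stays
  permissive so that heterogeneous files can still be inspected.
* Terminal residues raise boundary errors for the undefined dihedral
  rather than returning NA, so ensemble statistics can never silently
  average over a shorter model.
* Ties in flexibility rankings keep input order (stable sort).
* The two ensemble flavours commonly deposited per domain (torsion-angle
  calculation versus force-field-refined) can differ slightly in helix
  dihedrals; when validating against published per-residue statistics
  the refined ensemble is the default choice, checking the twin when the
  refined entry disagrees.

## Known limitations

* No profile/HMM scoring: degenerate fingers lacking a coordinating
  residue are invisible to the scanner by design.
* Helix extent is taken from the motif convention, not from geometry; no
  DSSP-style assignment is attempted.
* The recognition code is the classical canonical one; it predicts
  preferences, not affinities, and no genome scanning or PWM machinery
  is included.
* The flexibility statistic is a geometric proxy; it is not a
  relaxation-order-parameter analysis and carries no model of linker
  dynamics.
* mmCIF, assemblies, restraint files and chemical-shift data are out of
  scope for the reader.
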