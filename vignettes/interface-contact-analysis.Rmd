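---
title: "Typed interface contact maps and binding-site transfer"
author: "InterfaceContacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed interface contact maps and binding-site transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InterfaceContacts)
```

## Background

NF-Y is a heterotrimeric transcription factor whose NF-YB and NF-YC
subunits dimerize through histone-fold domains before NF-YA joins the
complex on CCAAT-box DNA.  The 59-residue Arabidopsis orphan protein
QQS binds NF-YC, and truncation pull-downs place its binding activity
in two regions, aa 1–12 and aa 41–59.  Both regions resemble the
NF-YB N-terminal stretch adjacent to the histone-binding domain
(NF-YB-51-57 and NF-YB-62-70), which in crystal structures of the
NF-Y complex is buried against a hydrophobic NF-YC interface.  The
package's pipeline formalizes the structural argument: type the
contacts that the NF-YB segments make in the crystal structures,
compare them across two crystal forms, align the QQS motif peptides
onto the segments, and transfer the contacts positionally to propose
QQS binding sites on NF-YC.

This vignette documents the model, the parameters and the design
decisions, and what the synthetic-data validation does and does not
demonstrate.

## The contact model

All rules are distance rules on heavy atoms; crystal structures of
this resolution class carry no hydrogens, so the reader discards any
H/D atoms and all criteria are heavy-atom (or group-centroid)
criteria with no angular terms.  A residue pair across an interface
may carry several interaction types at once (a salt bridge is
recorded as ionic *and* hydrogen bond); each type stores its minimal
qualifying distance, so a single-line-per-pair view can always be
recovered by collapsing.

| type        | measured between                                     | cutoff |
|-------------|------------------------------------------------------|--------|
| hydrophobic | side-chain carbons (plus Met SD)                     | 5.0 Å  |
| ionic       | charged-group heavy atoms of an acidic/basic pair    | 6.0 Å  |
| hbond       | donor (N/O/S with H in the parent residue, plus backbone N) to acceptor (lone-pair O/N/S, plus backbone O) | 3.5 Å; 4.0 Å with sulphur |
| cation-π    | cation center to aromatic ring centroid              | 6.0 Å  |
| DNA flag    | any residue heavy atom to any DNA heavy atom         | 5.0 Å  |

Atom-group choices the cutoffs do not themselves dictate:

* **Histidine** is classed positive and participates as both a cation
  center (ring centroid) and an aromatic ring, because no protonation
  model is imposed; since every contact record carries its type, users
  can filter His-mediated contacts out if they prefer a stricter
  reading.
* **Arginine's** cation center is the guanidinium centroid over
  NE/CZ/NH1/NH2; **lysine's** is NZ.
* **Ring centroids**: Phe/Tyr six-membered ring, His imidazole, and
  the full nine-atom indole for Trp.
* **Asn/Gln** side-chain N donates only and side-chain O accepts
  only; Ser/Thr/Tyr hydroxyls do both; backbone N donates and
  backbone O accepts for every residue.
* **Hydrophobic contacts are side-chain only** (backbone carbons
  excluded); the backbone participates in hydrogen bonds only.  Gly
  therefore has no hydrophobic atoms and is classed aliphatic.
* **Sulphur cutoff**: the 4.0 Å threshold applies when *either*
  partner atom is sulphur (Cys SG donor/acceptor, Met SD acceptor).
  `sulfurEitherPartner = FALSE` restricts it to sulphur donors only,
  for users who want the donor-keyed reading.

Residue classes (`classifyResidue`) are the six-way interface
colouring: aliphatic G/A/V/L/I/M, negative D/E, positive K/R/H, polar
S/T/N/Q/C, aromatic F/W/Y, and proline alone.

## Structure input

`readPDB()` reads the fixed-column PDB subset that the analysis
needs: ATOM/HETATM with author numbering, insertion codes kept as
suffix tokens (spans compare on the integer part), waters dropped,
only the highest-occupancy altloc retained (first seen on ties), only
the first MODEL of multi-model files, and MSE renamed to MET.
Unknown HETATM residues are typed `other` and excluded from contact
typing; residues named like nucleotides are typed `nucleic` and serve
as DNA for proximity flags.  Elements are taken from columns 77–78
when present, otherwise inferred from the atom name.

Because the crystal-structure depositions do not label which chain is
which subunit, chain roles (NF-YA/NF-YB/NF-YC/DNA) are supplied in
the run configuration, never guessed.

## Comparative maps

Two structures are compared through a user-supplied one-to-one
residue mapping (a TSV of corresponding chain/number pairs); a helper
builds one from an ungapped alignment of two chains when the
numbering differs systematically.  A contact is *shared* only when
the mapped residue pair carries the *same* interaction type in both
maps — a pair that is hydrophobic in one form and ionic in the other
is structure-specific in both directions.  The membership labels
`both`/`a_only`/`b_only` mirror the solid/broken/dashed line
convention of comparative interface diagrams, and the partition
identities |shared| + |only-A| = |map A| (and likewise for B) hold by
construction and are asserted in the tests.

## Motifs

Patterns use a compact dialect: a fixed letter, `[X/Y]` alternatives,
and `-` as a *single-position* wildcard.  Reading `-` as one wildcard
position is what makes `REQEIYV` match `R[E/D]Q[D/E]-[Y/F/W][L/V]`
exactly, so that reading is canonical here.  A wildcard matches any
letter including the ambiguity code X; an alternative set never
matches X (conservative treatment of ambiguous residues).

`deriveConsensus` works per column of an ungapped block: one distinct
residue gives a fixed letter, up to `maxAlternatives` (default 3)
distinct residues give a set ordered by column frequency then
alphabetically (deterministic rendering), more give a wildcard.  By
construction every input row matches the derived pattern.
`scanDatabase` reports all overlapping hits in record order and drops
any record matching an exclusion pattern anywhere — the
histone-like-sequence filter is realized as user-supplied exclusion
patterns, since no operational definition of "histone-like" is fixed
by the source analysis.

The ungapped `alignSegment` scores 2 per identity and 1 per
same-class column (class-aware mode), ties breaking to the smallest
offset.  Note one arithmetic consequence of the class table: in
`REQEIYV` vs `RDQDAWL` the Ile/Ala column scores 1 (both aliphatic),
giving a window score of 9.

A second discrepancy worth recording: the C-terminal QQS motif
`VARLKMRVI` is nine residues (spanning aa 41–49), and a strict
positional reading of `[V/I]-R[L/I]M[K/R]-[I/V/L]` (eight positions)
does not literally match it; the alignment register behind that
printed consensus is not recoverable.  The package therefore derives
consensus patterns from the alignment blocks it is given and does not
assert the printed second pattern against its source peptide.

## Fragment registry

The registry ships as an editable TSV pair (constructs + parent
lengths): the QQS truncations QQS-1-12, QQS-13-47, QQS-11-59,
QQS-41-59, QQS-48-59 on the 59-residue parent, and the 145-residue
HsNF-YC N-terminal construct.  The MBP pull-down result is the
canonical outcome; the GST-bait anomaly for QQS-1-12 (no pull-down,
attributed to masking by the GST moiety) is kept as a note, not
reconciled.  The HsNF-YC full-chain length is deliberately left NA
rather than imported from an external database.

*Minimal binding regions* are derived in two steps: discard binding
spans wholly contained in a non-binding span, then discard binding
spans that strictly contain another retained binding span (a coarse
construct such as QQS-11-59 adds no localization beyond the finer
QQS-41-59 it contains), and merge what remains into maximal runs.
The one-step union rule alone would return aa 1–59 for the QQS
series; the second step is what recovers the experimentally mapped
regions aa 1–12 and aa 41–59.

## Binding-site transfer

`transferSites` is positional, not energetic: each contact of a donor
segment residue whose partner chain passes the filter is copied to
the aligned peptide position, type and membership verbatim.  A
message flags positions where the peptide residue's polarity class
differs from the donor's, since the chemical plausibility of such a
transferred contact is weaker.  The partner filter defaults in the
pipeline to the NF-YC chain, matching the observation — checkable
from the maps themselves — that the second donor segment makes no
NF-YA contacts.  `linkerReport` then summarizes the two-site
topology; for motifs at aa 5–11 and aa 41–49 on the 59-residue
peptide the inter-motif linker is aa 12–40, 29 residues.

```{r}
hits <- scanSequence(parsePattern("R[E/D]Q[D/E]-[Y/F/W][L/V]"), "REQEIYV")
hits
```

## Synthetic data: what it emulates and what it does not

`makeToyStructure` emulates the *inputs* of the analysis — multi-chain
heavy-atom PDB files with author numbering and an optional DNA
duplex stub — with exact ground truth.  Each planted pair is built
from idealized side-chain templates, centred on the head group that
defines the requested type, and separated by a numerically solved
translation so the type-defining group distance equals the target
within 0.01 Å.  A deterministic orientation search plus a
post-placement audit guarantees that *only* the requested interaction
channel qualifies and every other channel is outside its cutoff by
the requested margin; geometrically impossible requests (e.g. a
hydrophobic plant between glycines, or a near-miss inside the margin)
error out rather than silently degrade.  Decoy pairs are placed clear
of every cutoff, and each pair lives in its own 40 Å grid cell so
pairs cannot interact across cells.

What this does **not** emulate: realistic packing density, backbone
connectivity between neighbouring residues, crystallographic
disorder, waters, or rotamer statistics.  Passing the recovery and
oracle-equivalence suites therefore demonstrates that the detector
implements the distance rules exactly, not that the rules themselves
are optimal for crowded real interfaces — on real structures,
residues participate in many simultaneous marginal contacts that the
isolated-cell fixtures deliberately avoid.

`makeMotifDb` plants pattern realizations in uniform-random
background sequences and re-draws any background window that
accidentally matches a planted or exclusion pattern, so scan truth
tables are exact; carriers of different planted patterns are
disjoint.  `makeAlignmentBlock` samples rows so every member of every
alternative set is witnessed.  All generators are pure functions of
(spec, seed); identical seeds give byte-identical files.

`makePairedComplex` combines these into the two-crystal-forms
fixture: donor segments at B 51–57 and B 62–70 contacting a partner
chain, with planted contacts partly shared and partly specific to one
form, paired with the 7- and 9-residue QQS motif peptides.

## Numerical choices

* Placement solves separations by bracketed root finding on a 0.5 Å
  grid refined by `uniroot` to 10⁻⁹; the outermost root is taken so
  pairs are pulled apart, not interpenetrating.
* Contact distances are exact minima over the group atom pairs;
  pipeline TSVs print 3 decimals, which makes repeated runs
  byte-identical.
* Cutoff comparisons are inclusive (≤); enlarging any cutoff can only
  add contacts of that type (asserted over 1,000 random
  enlargements).
* Alignment and consensus tie-breaks are deterministic: smallest
  offset, frequency-then-alphabet ordering.
* Degenerate inputs: an empty selection is a valid `ResidueSet`; an
  empty map summarizes to zero counts with no character label; a
  pattern longer than its sequence scans to an empty hit table.

## Validation problem sizes

The shipped validation suite checks the contact engine against an
independent brute-force oracle on 100 randomized jittered structures
(each well under 500 atoms), planted-contact recovery on 10 fixtures
of 4 planted + 6 decoy pairs at ±0.5 Å margins, monotonicity on 1,000
random cutoff enlargements, motif scanning against a naive oracle on
1,000 random pattern/sequence pairs, and end-to-end pipeline
determinism and truth transfer on the paired complex.  These sizes
give the properties enough room to fail while keeping the whole suite
inside a couple of minutes on one core.

## Known limitations

* No angular criterion for hydrogen bonds and no solvent model;
  distance-only rules are intentionally faithful to the published
  cutoffs, so the maps are permissive relative to stereochemically
  strict H-bond definitions.
* His is simultaneously cationic and aromatic; users wanting a
  protonation-aware treatment must filter by type.
* Binding-site transfer does not re-evaluate chemistry for the
  peptide residue and makes no energetic claim; it is a positional
  hypothesis generator.
* mmCIF, NMR ensembles and symmetry expansion are out of scope for
  the PDB reader.
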