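# InterfaceContacts

Residue-level analysis of protein–protein interfaces by typed distance
cutoffs, degenerate consensus-motif scanning, and alignment-based
binding-site transfer.

## The scientific problem

QQS (*Qua-Quine Starch*) is a 59-residue *Arabidopsis thaliana* orphan
protein that physically interacts with the NF-YC subunit of the
heterotrimeric CCAAT-binding transcription factor NF-Y.  Pull-down
experiments with QQS truncations locate two binding regions — the
N-terminal aa 1–12 and the C-terminal aa 41–59 — and sequence
alignment of those regions against NF-YB reveals two degenerate
motifs, `R[E/D]Q[D/E]-[Y/F/W][L/V]` (QQS-5-11, `REQEIYV`) and
`[V/I]-R[L/I]M[K/R]-[I/V/L]` (QQS-41-49, `VARLKMRVI`), that resemble
the NF-YB N-terminal region (NF-YB-51-57 and NF-YB-62-70) adjacent to
the histone-binding domain.  The structural hypothesis — that QQS
occupies the two NF-YC interfaces normally bound by the NF-YB
N-terminus — rests on residue-level contact maps of NF-Y crystal
structures.

This package implements that analysis chain as reusable, tested
components:

* **Contact typing.** For residues *a*, *b* on opposite sides of an
  interface, a typed contact is recorded when the minimal heavy-atom
  (or group-centroid) distance satisfies
  d(hydrophobic) ≤ 5 Å over side-chain carbons,
  d(ionic) ≤ 6 Å over charged-group atoms of an acidic/basic pair,
  d(H-bond) ≤ 3.5 Å donor→acceptor (4.0 Å when sulphur is involved),
  d(cation-π) ≤ 6 Å between a cation center and an aromatic ring
  centroid.  Protein residues within 5 Å of DNA heavy atoms are
  flagged.
* **Comparative maps** across two structures through a one-to-one
  residue mapping, labelling each contact `both` / `a_only` /
  `b_only` (the solid / broken / dashed legend of comparative
  interface diagrams).
* **Degenerate motifs**: PROSITE-like patterns (`[E/D]` alternatives,
  `-` single-position wildcard), consensus derivation from ungapped
  alignment blocks, and database scanning with exclusion filters.
* **Fragment registry** of peptide constructs with pull-down outcomes
  and span arithmetic.
* **Binding-site transfer** of a donor segment's contacts onto an
  aligned candidate peptide, with the two-site linker report.
* **Synthetic data** generators that plant typed contacts and motifs
  with exact ground truth, so every stage is testable without
  downloading structures or databases.

## Worked example

```r
library(InterfaceContacts)

toy <- makeToyStructure(list(
  plantedContact("ARG", "B", 51, "ASP", "C", 10, type = "ionic",       distance = 5.0),
  plantedContact("LEU", "B", 54, "LEU", "C", 13, type = "hydrophobic", distance = 4.5),
  plantedContact("LYS", "B", 56, "PHE", "C", 15, type = "cation_pi",   distance = 5.0),
  plantedContact("SER", "C", 40, type = "dna_contact", distance = 4.0)),
  decoys = 2, dna = TRUE, seed = 42)

s <- readPDB(toy$text, id = "demo")
m <- buildContactMap(selectResidues(s, "B", c(51, 57)),
                     selectResidues(s, "C"),
                     dna = selectResidues(s, "D"))
m
#> ContactMap on "demo": 3 x 6 residues, 3 typed contact(s)
#>   (cation_pi: 1, hydrophobic: 1, ionic: 1); 1 DNA-proximal residue(s)
contactTable(m)
#>   structure_id chain_a seq_a resname_a chain_b seq_b resname_b        type distance_angstrom ...
#> 1         demo       B    51       ARG       C    10       ASP       ionic               5.0
#> 2         demo       B    54       LEU       C    13       LEU hydrophobic               4.5
#> 3         demo       B    56       LYS       C    15       PHE   cation_pi               5.0
```

Each planted pair is recovered as exactly one typed contact at its
target distance, and the serine placed 4 Å from the DNA stub is the
single DNA-proximal residue.

The packaged construct registry reproduces the QQS truncation design;
its derived minimal binding regions for AtNF-YC4 are the two
experimentally mapped sites:

```r
bindingSummary(defaultFragmentRegistry(), "AtNF-YC4")$minimalRegions
#>   start end
#> 1     1  12
#> 2    41  59
```

Class-aware ungapped alignment scores identity 2, same polarity class
1 (here `REQEIYV` against a target containing `RDQDAWL`):

```r
alignSegment("REQEIYV", "GGRDQDAWLGG")
#> segmentAlignment peptide vs target (offset 3, score 9)
#>   GGRDQDAWLGG
#>     REQEIYV
#>     |:|::::
```

`runPipeline()` chains the stages — selection, per-structure contact
maps, cross-structure comparison, peptide alignment, binding-site
transfer, linker report, interface character — from a single YAML
configuration and writes every intermediate as TSV plus a run log
(see the vignette in `vignettes/`).

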