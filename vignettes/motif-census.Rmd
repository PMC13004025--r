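---
title: "A topology-aware census of short recycling motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A topology-aware census of short recycling motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomotif)
```

## The problem

Many membrane proteins escape lysosomal degradation after endocytosis
because short linear motifs in their cytoplasmic C-terminal regions are
recognized by endosomal recycling complexes. The canonical examples are the
Retromer consensus [F/Y/W]x[L/M/V], the SNX17/Retriever motif N[P/x]xY, the
ESCPE-1 consensus Φx[F/Y/V]x[F/Y], and the C-terminal class I PDZ-binding
motif [D/E][S/T]xΦ-COOH. A bileucine core, LxxL, has more recently emerged
as a distinct route into Retromer-dependent recycling — the mu opioid
receptor's LENL and the glucose transporter GLUT4's LEYL are worked
examples. `topomotif` implements the proteome-census side of that biology:
given protein sequences with UniProt-style topology annotations, it finds
every occurrence of these motifs under the positional constraints that make
a motif plausibly functional, and tallies the candidate proteins per motif.

## The procedure and its assumptions

The census applies, in order:

1. **Cytoplasmic-tail filter.** A protein is retained only when its final
   residue lies inside a `TOPO_DOM` feature whose note begins with
   "Cytoplasmic". Proteins with extracellular, otherwise-annotated
   (e.g. "Lumenal"), or missing C-terminal annotation are dropped; the
   class breakdown is recorded in provenance. Prefix matching on the note
   tolerates qualifiers ("Cytoplasmic; in dimer").
2. **Windowed scan.** Non-anchored motifs are searched in the last
   `windowLen` residues (default 100; the whole sequence when shorter),
   and the *entire* match must lie inside the window — a motif half
   outside the stated region is not "found in" it. All overlapping
   occurrences are reported. C-terminally anchored motifs (the PDZ class)
   are instead evaluated against the final residues of the protein,
   independent of the window: anchoring is a property of the motif, not a
   window trick, so the PDZ search always means "the last four residues".
3. **Extracellular exclusion.** A match passes only when some cytoplasmic
   `TOPO_DOM` fully contains it. Matches in cytoplasmic *loops* of
   multi-pass proteins count, mirroring an exclusion of extracellular
   matches rather than a restriction to the final domain. A match
   straddling a transmembrane boundary has no enclosing domain and fails.
4. **Membrane distance.** Retromer engagement requires the motif to sit at
   least 15 residues from the membrane. Distance is counted as the
   residues *strictly between* the motif and the nearest flanking
   `TRANSMEM`/`INTRAMEM` boundary, minimized over both flanks (relevant in
   cytoplasmic loops). This strict-gap convention is a design choice: a
   motif starting immediately after a membrane segment has distance 0, a
   motif overlapping one has distance 0, and the published "at least 15
   amino acids away" is read as `distance >= 15`. Where the annotation has
   no membrane segment at all (peripheral or lipid-anchored proteins) the
   distance is *undefined*: such matches pass the distance filter but are
   flagged (`distanceUndefined`), because silently excluding unannotated
   proteins would hide data.
5. **Deduplication.** Census counts are per unique protein. The summary
   reports, per motif, the number of matches and unique proteins passing
   filters 1–3, and separately the unique proteins that also satisfy the
   distance criterion — reproducing the two-stage parse in which a
   bileucine list is first deduplicated and then distance-filtered. The
   per-protein representative is the most C-terminal passing match, and a
   free-text `proteinClass` column is left empty for external annotation
   (e.g. PANTHER), which is out of scope here.

The pattern grammar is deliberately minimal — literal residues, `@` for
any residue, bracketed residue classes; no repetition, alternation or
negation — because that is exactly the grammar of the five published
patterns. Ambiguity codes (X, U, ...) satisfy `@` but never an explicit
class: an ambiguous residue should not count as evidence for a specific
consensus position.

```{r}
p <- parsePattern("L@@L")
scanSequence(p, "TELEYLGP", offset = 498)
```

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `windowLen` | 100 | residues | the published census searched the last 100 aa; large enough to cover C-terminal tails, small enough to keep the "C-terminal" claim meaningful |
| `requireCytoplasmic` | `TRUE` | — | the filters exist to exclude topologically impossible matches |
| `minMembraneDistance` | `NA` (off); 15 for the LxxL pattern | residues | the published Retromer-engagement bound; carried per pattern so the comparison motifs are tallied without it |
| `dedupe` | `TRUE` | — | census counts are per protein |
| `tmLen` (generator) | 21 | residues | a typical single-pass helix span |
| `rareWeight` (generator) | 0.35 | relative weight | see below |

## What the synthetic generator emulates — and what it does not

`generateLibrary()` emits single- and multi-pass proteins with alternating
Cytoplasmic/Extracellular domains, `TRANSMEM` segments of 21 residues,
proteins with extracellular C termini, and peripheral proteins with no
membrane segment, in stated proportions (`defaultArchetypeMix()`). Motifs
are planted at controlled distances from the membrane, so the 14-vs-15
threshold boundary can be pinned exactly. Background residues are drawn
i.i.d. from a composition that down-weights the motif-critical residues
(L, F, Y, W, V, M, N, D, E, S, T at weight 0.35 relative to 1) so that
accidental motif occurrences are rare but non-zero; ground truth is then
*recomputed* from the emitted sequences by an independent route
(regular-expression scan plus the interval predicates), never assumed
accident-free.

What this does not emulate: real amino-acid composition and correlation
structure, isoforms, signal peptides, annotation errors, and the
release-dependence of a real UniProt keyword query. Passing tests
therefore certify the *logic* of the census — parsing, windowing,
topology constraints, distance arithmetic, deduplication — on annotation
structures shaped like real ones; they do not certify any particular
proteome-wide count. Published counts from a live proteome (4019 keyword
entries, 2359 cytoplasmic tails, 692/430 bileucine proteins, and so on)
depend on the annotation release and are deliberately not asserted
anywhere in the test suite. The six worked-example records shipped by
`syntheticPeptideFixtures()` are synthetic scaffolds (deterministic
glycine/serine filler) that embed published peptides at their published
coordinates; they certify coordinate handling, not native sequence
context.

```{r}
lib <- generateLibrary(seed = 42, n = 50)
res <- runCensus(lib$records)
res$summary$summary
```

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere, matching UniProt and the
  position-motif notation ("500-LEYL"); no half-open intervals appear in
  the public model.
* A sequence shorter than a pattern yields an empty result, not an error.
* Overlapping same-kind features are an ingest *error* (real annotations
  keep them disjoint; corruption should be loud); a `TOPO_DOM`
  overlapping a membrane segment is tolerated with a warning.
* Output ordering is fixed (accession, pattern, start; radix order), and
  provenance JSON carries no timestamps, so identical inputs give
  byte-identical outputs.
* Trafficking metrics return out-of-range values (negative
  internalization, recycling above 100%) unclamped, with a warning:
  assay noise is real and clamping would hide it. Recycling with equal
  total and internalized means is an error, because the assay
  precondition (measurable internalization) failed. The geometric-mean
  helper rejects non-positive events and reports how many it dropped.
* Neuron recycling is fixed as ratio(post-antagonist) minus
  ratio(post-agonist); the two published phrasings ("after antagonist vs
  before antagonist" and "after antagonist vs after agonist") coincide
  because the pre-antagonist state is the post-agonist state.

## Design decisions that were genuinely open

* **Distance convention.** The literature states only "at least 15 amino
  acids away from the membrane"; whether that is measured to the motif
  start, end, or with another off-by-one is unstated. This package fixes
  the strict gap to the motif's nearest residue, minimized over flanks,
  and pins it with boundary fixtures (distance 14 fails, 15 passes).
* **Unannotated gaps and undefined distances.** Matches in proteins with
  no membrane segments pass the distance filter flagged rather than being
  dropped or failed; C termini not covered by any topological domain are
  classified `UNANNOTATED` and excluded by the tail filter (they are not
  cytoplasmic *by annotation*), with the breakdown surfaced in provenance.
* **Overlap counting.** Whether overlapping occurrences were counted
  separately before deduplication is immaterial to per-protein counts;
  match-level output reports all overlaps and the summary deduplicates.
* **Live retrieval.** A census of a current proteome requires a UniProt
  keyword query (reviewed human entries, keyword "Cell Membrane"); the
  package consumes the TSV dialect such an export produces but does not
  fetch it, keeping the build and tests fully offline and reproducible.

## Problem sizes used in the shipped checks

The test suite and the verification script work at desk scale, chosen so
the whole suite runs in about two minutes on one CPU: property tests use
hundreds of random patterns on sequences up to a few hundred residues;
the census-versus-oracle equivalence uses 50 random libraries of 20–120
proteins each (seeds fixed in the tests); the determinism checks compare
byte-for-byte outputs of repeated 40-protein runs. The worked-example
coordinates (500-LEYL, 554/557 in QPELYLL, 407–410 in QLENLE) are exact
assertions, not tolerances.

## Known limitations

* Topology must come from annotation; nothing is predicted for
  unannotated proteins.
* The grammar cannot express mismatch tolerance, position weights, or
  negated classes — deliberately out of scope.
* Census counts on a real proteome inherit every bias of its topology
  annotation (multi-pass loops are annotated unevenly in practice).
* The trafficking metrics take summary statistics (geometric means,
  integrated intensities) as inputs; gating, FCS parsing and curve
  fitting belong to upstream tools.
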