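# topomotif

Topology-aware census of short recycling motifs in the cytoplasmic
C-terminal regions of membrane proteins.

## The problem

After endocytosis, membrane proteins are either recycled back to the cell
surface or delivered to lysosomes for degradation. The choice is often made
by short linear motifs in the cytoplasmic C-terminal tail that endosomal
recycling complexes recognize: the Retromer consensus [F/Y/W]x[L/M/V], the
Retriever motif N[P/x]xY, the ESCPE-1 consensus Φx[F/Y/V]x[F/Y], the
C-terminal class I PDZ-binding motif [D/E][S/T]xΦ-COOH — and the bileucine
core **LxxL**, a distinct route into Retromer-dependent recycling used by
the mu opioid receptor (LENL) and the glucose transporter GLUT4 (LEYL).

`topomotif` is for cell biologists who want to ask: *which membrane
proteins carry a candidate recycling motif where it could actually work?*
It scans annotated proteomes for these motifs under positional constraints
— cytoplasmic C terminus, last-100-residue window, exclusion of
extracellular matches, a minimum sequence distance from the membrane
(≥ 15 residues for Retromer engagement), per-motif deduplication — and it
implements the standard formulas for quantifying receptor internalization,
recycling, down-regulation and surface expression from fluorescence
measurements.

Patterns are written in a compact grammar: a residue letter matches
itself, `@` matches any residue, `[FYW]` matches any listed residue. The
five motifs above ship built in (`recyclingPatterns()`), and matches are
reported in the position-motif notation of the field ("500-LEYL").

## Worked example

Scanning the GLUT4 C-terminal peptide, numbered as in the full-length
transporter:

```r
library(topomotif)
p <- parsePattern("L@@L")
scanSequence(p, "TELEYLGP", offset = 498)
#>   start end matched
#> 1   500 503    LEYL
```

The bileucine sits at residues 500–503: the "500-LEYL" of the GLUT4 tail.
The same coordinates fall out of the full pipeline on bundled synthetic
scaffolds that embed the published worked-example peptides
(`syntheticPeptideFixtures()`).

An end-to-end census on a synthetic 50-protein membrane proteome with
planted motifs and exact ground truth:

```r
lib <- generateLibrary(seed = 42, n = 50)
res <- runCensus(lib$records)
res$summary$summary
#>       pattern nMatches nUniqueProteins nUniqueProteinsDistanceFiltered
#>          LxxL       24              22                              18
#>          NxxY        4               4                              NA
#>  Retromer_FxL       18              15                              NA
#>        ESCPE1        7               7                              NA
#>           PDZ        8               8                              NA
```

Here 44 of the 50 proteins pass the cytoplasmic-tail filter; 22 unique
proteins carry an in-window, cytoplasmically disposed LxxL, of which 18
also sit at least 15 residues from the nearest membrane segment (the
Retromer-engagement criterion; the comparison motifs are tallied without
a distance rule). `res$matches` keeps every occurrence — including
failing ones, with reasons — for audit, and `lib$truth` holds the
oracle-recomputed ground truth the tests check the census against.

Trafficking quantification uses the field's formulas directly:

```r
recyclingPct(gmTotal = 1000, gmInternalized = 500, gmRecycled = 790)
#> [1] 58
```

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/topomotif.R census --records records.tsv --out-dir out/
Rscript inst/cli/topomotif.R search --pattern 'L@@L' --sequence TELEYLGP --offset 498
Rscript inst/cli/topomotif.R simulate --seed 42 --n 200 --out-dir sim/
Rscript inst/cli/topomotif.R metrics --measurements measurements.tsv
```

`census` accepts a UniProt-style TSV export (`Entry`, `Sequence`,
`Topological domain`, `Transmembrane`, ...) or FASTA plus a sidecar
feature TSV, and writes `matches.tsv`, `summary.tsv`, `proteins.tsv`
(with an empty protein-class column reserved for external annotation)
and `provenance.json`. Outputs are byte-identical across repeated runs.

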