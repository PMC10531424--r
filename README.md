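# dastm — dense alignment surface prediction of transmembrane helices

`dastm` predicts α-helical transmembrane (TM) segments in a protein from
its amino acid sequence alone, and classifies the protein as TM or
non-TM.  It is aimed at sequence analysts who need a fast, transparent,
physico-chemistry-based TM predictor — no learned model, no homology
search, no topology priors — plus a benchmarking harness for evaluating
per-segment predictions against six-state topology annotations.

## The method

TM helices are stretches of roughly 15–30 predominantly hydrophobic
residues.  Any TM helix therefore resembles any other TM helix under a
hydrophobicity similarity measure, even when the two are shifted
relative to each other.  `dastm` exploits this with a dot-plot style
*dense alignment surface* between the query and each member of a small
reference library of known TM proteins:

- **Pair scoring matrix.** `M(a,b) = c·n(a)·n(b)`, where `n` is the
  min-max-normalized Kyte–Doolittle hydropathy and `c` is fixed so the
  background-weighted mean score is 1 — every score is a multiple of the
  random-pair expectation.
- **Alignment surface.** `S[i,j]` is the mean of `M` over a gapless
  diagonal window (length 15 by default, shrinking at the ends) centred
  on query position `i` and reference position `j`.  TM×TM
  intersections appear as dense high-scoring blocks.
- **Cross-weighted cumulative score profile.** The surface is projected
  onto the query axis with each reference column `j` weighted by the
  reference's own cumulative score `c_r[j] = mean_i S[i,j]`:
  `C[i] = Σ_j S[i,j]·c_r[j] / Σ_j c_r[j]`, emphasizing alignment
  against the reference's TM regions.
- **Global DAS profile.** `D[i]` is the mean of the cross-weighted
  profiles over all library members (8 by default; 16/24/32 supported).
  Maximal runs with `D ≥ 2.5` are the predicted TM segments.

Segments starting within the first 25 residues get a *possible signal
peptide* warning (cleavable signal peptides are biophysically
TM-helix-like and are flagged, not suppressed); consecutive segments
separated by ≤ 4 residues get a *twin peak* warning.  A protein with
two or more segments is classified TM; with none, non-TM; with exactly
one, a quality value (the maximum segment peak) decides against a
threshold of 3.0.

The benchmark module scores predictions per segment: a predicted
segment overlapping an annotated helix by ≥ 3 residues is a true
positive (one-to-one greedy matching by descending overlap); unmatched
predictions overlapping an annotated signal peptide are discarded
rather than counted as false positives; `recall = TP/(TP+FN)`,
`precision = TP/(TP+FP)`.

## Worked example

```r
library(dastm)

lib <- load_library(size = 8)            # bundled synthetic TM library
q   <- synth_tm_protein(n_segments = 3, seed = 42)

annotation_segments(q$labels, c("H", "h"))   # planted ground truth
#>   start end
#> 1    47  62
#> 2    74  88
#> 3   126 153

das_predict(q, lib)
#> DAS prediction for synTM_seed42: TM
#>   TM segment 1: 50-57  peak 2.95
#>   TM segment 2: 78-84  peak 3.08
#>   TM segment 3: 131-149  peak 3.00
```

All three planted helices are recovered (each predicted segment
overlaps its annotated helix by well over the 3-residue criterion); the
peaks are the maximum of the global DAS profile inside each segment, in
units of the random-background score, and the protein is classified TM
by the multi-segment rule.

The same pipeline is available from the shell via the installed
launcher (`system.file("scripts", "dastm", package = "dastm")`):

```sh
dastm synth --tm 5 --globular 5 --signal 2 --seed 7 -o demo.fa
dastm predict -i queries.fasta --library-size 8 --output short
dastm evaluate --dataset demo.fa --min-overlap 3
dastm library-validate
```

`predict --output long` additionally writes a per-query profile TSV and
an SVG plot (cutoff line at 2.5; `--scale fixed` clamps the y-axis to
\[0, 5\] so different proteins are directly comparable).

## Limitations

- β-barrel TM segments are out of scope by design: the method evaluates
  hydrophobicity of localized patterns, which β strands do not share.
- Signal peptides are biophysically indistinguishable from TM helices
  at this level; use a dedicated signal peptide predictor upstream if
  that distinction matters.
- The bundled reference library is synthetic (generated polytopic TM
  caricatures, see `?load_library`); substitute a FASTA of trusted real
  TM proteins via `load_library(source = ...)` or `--library` for
  production use.
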