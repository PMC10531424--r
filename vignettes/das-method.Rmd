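---
title: "The dense alignment surface method: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dense alignment surface method: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dastm)
```

## The model

Membrane-spanning α-helices are, to first order, runs of 15–30
predominantly hydrophobic residues.  The dense alignment surface (DAS)
approach turns this into a prediction rule without any trained model:
if hydrophobicity is what makes a TM helix a TM helix, then any TM
helix in a query should score highly against any TM helix in a known
TM protein, under a similarity measure built purely from
hydrophobicity, and it should keep scoring highly under relative
shifts of the two segments.

Concretely, for a query `q` and a reference `r`:

1. **Pair matrix.**  Residue pairs score
   `M(a, b) = c · n(a) · n(b)`, with `n` the min-max-normalized
   Kyte–Doolittle hydropathy (so `n(I) = 1`, `n(R) = 0`) and `c` the
   unique constant making the background-weighted mean score equal 1
   over standard database residue frequencies
   (`c = 1 / nbar²` with `nbar = Σ f(a) n(a) ≈ 0.473`, giving
   `c ≈ 4.46`).  The product form means the matrix has rank one: a
   pair scores highly only if *both* residues are hydrophobic, which
   is exactly the dot-plot contrast the method needs.  The
   normalization gives every downstream score the same unit —
   multiples of the expected score of two random residues — which is
   what makes a universal calling cutoff meaningful.
2. **Alignment surface.**  `S[i, j]` is the mean of `M` along a
   gapless diagonal window of length `W` centred on `(i, j)`,
   restricted to offsets where both sequences have residues (the
   window shrinks at the ends; zero-padding would systematically
   depress the termini, where the signal-peptide warning operates).
3. **Cross-weighted profile.**  The plain projection
   `c_r[j] = mean_i S[i, j]` is itself a windowed hydrophobicity curve
   for the reference.  Re-projecting the surface onto the query with
   those values as weights,
   `C[i] = Σ_j S[i, j] · c_r[j] / Σ_j c_r[j]`,
   asks a sharper question: *how does query position `i` score
   specifically against the reference's hydrophobic (TM) regions?*
   If the whole surface is zero the profile is defined as zero.
4. **Global DAS profile.**  `D[i]` averages `C[i]` over all reference
   library members (excluding any member whose id equals the query's,
   so library members can be scored against the rest without a trivial
   self-match).  Averaging over 8 independent references suppresses
   the idiosyncrasies of any single reference sequence.

Maximal runs with `D[i] ≥ cutoff` are the predicted segments.  No
minimum length is imposed and nothing is merged: short predicted
segments can be genuine (helix–helix contacts inside a bundle make the
buried faces less hydrophobic, so real helices can surface only partly
above the cutoff), and boundary residues of annotated helices are
experimentally soft, so aggressive post-processing would optimize
against noise.  Ambiguity letters (X, B, Z, U, O) score at the
background-mean hydrophobicity: degenerate inputs dilute the signal
rather than crash the run.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `window` | 15 | residues | diagonal window of the surface; a typical TM-core span.  Wider windows smooth the profile and blur closely spaced helices; narrower ones get noisy. |
| `cutoff` | 2.5 | background-score multiples | calling threshold on `D`. |
| `quality_threshold` | 3.0 | background-score multiples | TM/non-TM decision for single-segment queries. |
| `signal_window` | 25 | residues | a segment starting at or before this position is flagged *possible signal peptide*. |
| `twin_gap` | 4 | residues | consecutive segments with a linker this short (or shorter) are both flagged *twin peak*. |
| `plot_cap` | 5 | background-score multiples | y-axis bound of fixed-scale plots, so profiles of different proteins are directly comparable. |
| `min_overlap` | 3 | residues | predicted/annotated overlap required for a true positive in evaluation. |
| library size | 8 | members | 8 is recommended; 16/24/32 are nested prefixes kept as a compatibility knob (runtime is linear in size). |

The cutoff, plot cap, signal window, overlap rule and library sizes
are fixed, published operating points of the method; the window
length, quality threshold and twin gap are exposed because they are
reconstruction choices (below).

## Reconstruction decisions

The original scoring matrix and several procedural details were never
published in full, so this implementation fixes them as explicit,
replaceable design choices:

- **Matrix.**  Rebuilt from the Kyte–Doolittle scale as the rank-one
  product form above.  The background-mean-1 normalization is what
  makes "cutoff 2.5" interpretable as 2.5× random expectation.  The
  matrix is an ordinary configuration object (serializable as `A B
  score` text triples), so an externally derived table can be dropped
  in without code changes.
- **Cross-weighting.**  Defined as a single pass weighted by the
  partner axis's raw cumulative profile.  This is the simplest
  definition that makes the cross-weighted curve genuinely different
  from the plain projection, and it is linear in the matrix — scaling
  `M` by `k` scales every profile by exactly `k`, a property the test
  suite asserts.
- **Quality value.**  Defined as the maximum segment peak: the
  simplest statistic that is monotone in prediction strength and
  reduces to "how high did the profile get" for single-segment
  queries, which is the only case where it decides anything.  Whether
  the historical implementation also used segment length is not
  recoverable; the decision threshold is therefore a parameter.
- **Signal-peptide rule.**  "A peak within the first 25 residues" is
  implemented as *segment start ≤ 25* (a `signal_rule = "peak"`
  variant tests the peak position instead).  Segment start is the
  stricter reading for N-terminal features and is independent of
  profile shape inside the segment.
- **Twin-peak gap.**  "Short linker" is fixed at ≤ 4 residues — a
  known single-residue-linker artifact case motivates the warning, and
  4 is a conservative margin above it.  Warnings never change the
  segment list or the classification; they mark cases where automated
  bookkeeping is known to mislabel hits so a user can adjudicate.
- **Matching.**  Evaluation matches predicted to annotated segments
  one-to-one, greedily by descending overlap (ties: earlier annotated
  start, then earlier predicted start).  Greedy matching is *not*
  maximum matching — crossing twin-peak configurations exist where it
  concedes a pair — but it mirrors fully automated evaluation
  practice, and the per-record report surfaces twin-peak cases rather
  than silently optimizing them away.  Signal-peptide overlaps are
  excluded at the matcher, not the caller, so predictions reaching the
  user are unfiltered.

## The synthetic generators

The generators exist to give every module exact, seeded ground truth
without any external download.  They *caricature* membrane proteins
rather than imitate them:

- TM proteins alternate polar loops (10–60 residues, labels `1`/`2`
  alternating across the membrane) with hydrophobic segments (15–30
  residues, label `H`) drawn from an I/L/V/F/M/A-dominated
  composition.
- Globular proteins draw from database background frequencies, with
  rejection sampling forbidding runs of ≥ 9 consecutive strongly
  hydrophobic residues — so the globular class cannot accidentally
  contain a planted TM and poison false-positive counts.
- Signal-peptide proteins carry a 7–15 residue hydrophobic core
  (label `S`) starting within the first 5 positions, then a globular
  body.
- Reference libraries are generated with 4–7 segments per member and
  *short* loops (8–25 residues), emulating polytopic membrane proteins
  (real reference sets are built from proteins like cytochrome oxidase
  subunits, which are more than half membrane-embedded).  This matters
  structurally: the cross-weighting is informative exactly to the
  degree that the reference's own profile is dominated by TM regions,
  and with long globular-style loops the whole score range compresses
  toward the cutoff, leaving the published thresholds (2.5 / 3.0 / 5)
  outside the achievable dynamic range.

All randomness flows from one explicit seed per call (datasets derive
per-record sub-seeds from a master seed); the global RNG state is
saved and restored, so generators are pure functions of their
arguments.

Because the synthetic classes are deliberately high-contrast, passing
the parameter-recovery gate (recall and precision ≥ 0.9 on a seeded
50 TM + 50 globular dataset, ≥ 90% of globular records classified
non-TM) demonstrates that the pipeline's machinery — scoring,
projection, averaging, calling, matching — recovers planted structure
under its stated conditions.  It does *not* certify accuracy on real
proteomes, where compositions are noisier, helices are amphipathic,
and annotation boundaries are soft; benchmarking against a real
labeled dataset (e.g. a six-state-annotated TM protein collection in
the labeled-FASTA dialect) through `evaluate` is the corresponding
real-data check.

## Numerical notes

- Library averaging iterates members in a canonical (id-sorted) order,
  so predictions are bit-identical under permutation of the library
  file.
- The calling boundary is inclusive (`D ≥ cutoff` is called), and
  segment maximality is asserted directly in the tests: every called
  residue is at or above the cutoff, every adjacent uncalled residue
  below.
- Undefined metric denominators (no annotated or no predicted
  segments) are reported as absent (`NA`), never as 0.
- Display rounding is 3 decimals for recall/precision and 1 decimal
  for per-protein percentages; all stored values are unrounded.
- Problem sizes in the shipped checks: exhaustive profile-oracle
  comparison over all 9,840 toy-alphabet sequences up to length 8
  against a two-member library; exhaustive matcher comparison over all
  4,096 predicted-segment configurations of a length-12 sequence
  against four annotated configurations; 100-record end-to-end
  recovery datasets.

## Known limitations

- β-barrel TM segments are invisible to the method by construction.
- Signal peptides score as TM helices; discrimination is advisory
  (the warning), not statistical.  Roughly half of signal-peptide
  proteins can be expected to be called TM.
- Topology orientation (in/out sidedness), re-entrant helices and
  per-residue confidence are out of scope.
- The product-form matrix is a reconstruction; users with access to an
  authentic historical scoring table can substitute it via the
  text-triple format and `read_pair_matrix()`.
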