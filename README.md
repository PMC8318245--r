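# ssepssm

Position-specific scoring matrices over **secondary structure element
(SSE) codes** for protein secondary structure prediction, with the full
evaluation suite the field reports (Q3/Q8, SOV3/SOV8, boundary/internal
accuracy, pairwise misclassification rates).

## The problem and the method

Secondary structure predictors classify every residue of a protein
sequence as helix (H), strand (E) or coil (C) — or into the eight DSSP
states G, H, I, E, B, T, S, C. Since the late 1990s their main input
feature has been the amino-acid PSSM: per residue, 20 log-odds scores
summarizing which amino acids the query's homologs tolerate at that
position. This package builds the analogous matrix over SSE codes.
Given a query, a target set of proteins with known secondary structure,
and the pairwise alignments between them:

1. each hit alignment is **SSE-transformed** — aligned hit residues are
   replaced by the hit's SSE codes, gaps preserved (`"IL-GW--L"` with
   hit SSE `"CHHEE"` → `"CH-HE--E"`);
2. identity-weighted code occurrences are counted per query position,
   `Occ(c, p) = Σ_h 1[code_h(p) = c] · W(h)`;
3. rows are normalized into a position propensity matrix (PPM), with a
   substitution-matrix-driven pseudocount mixture for sparse columns;
4. the PSSM is the log-odds `log2(PPM(c, p) / B_c)` against the
   reference library's background frequencies `B`.

Because homologs conserve structure better than sequence, and because 3
or 8 codes give far fewer zero cells than 20, the SSE matrix is a
denser, more conformation-relevant feature set than the amino-acid one —
which this package can also build, through the *same* machinery, for
side-by-side comparison. Windowed PSSM rows (plus a single-integer
amino-acid-type encoding) feed a seeded bootstrap-vote ensemble whose
class probabilities are vote fractions. A BLOSUM-style estimator builds
SSE substitution matrices from any corpus of aligned SSE string pairs. A
seeded synthetic family generator makes the whole pipeline testable with
no database access, and hits from real search engines can be injected
as a plain alignment TSV.

## Worked example

```r
library(ssepssm)

fam   <- generate_family(family_params(seed = 42, alphabet = "dssp8"))
query <- setNames(fam$query$seq, fam$query$id)

hits <- search_homologs(query, fam$targets)
head(hits[, c("hit_id", "identity", "score")], 3)
#>   hit_id  identity score
#> 1  q1_t3 0.7916667   132
#> 2  q1_t4 0.7604167   123
#> 3  q1_t1 0.7187500   111

bg <- compute_background(fam$target_sse, "dssp8")
sm <- build_substitution_matrix(
  lapply(1:7, function(i) c(fam$target_sse[[i]], fam$target_sse[[i + 1]])),
  "dssp8")
prof <- build_profile(query, hits, fam$target_sse, "dssp8", bg,
                      subst = sm, tau = 0.5)
prof
#> SSE profile for 'q1': 96 residues x 8 codes ('dssp8'), tau = 0.5,
#> 0 background-fallback position(s)
round(prof$pssm[1:3, ], 2)
#>          G      H     I     E      B     T     S     C
#> [1,] -4.20 -12.93 -3.37 -5.55 -13.74 -2.86 -2.59  2.48
#> [2,] -4.43 -13.16 -3.60 -5.78 -13.97 -3.09 -2.82  2.49
#> [3,] -6.20  -7.76 -4.46  1.15  -2.82 -4.14 -3.89 -0.08
```

The first two query residues score strongly positive only for coil
(+2.5 bits for C, negative elsewhere) and residue 3 for strand — the
log-odds of each conformation at that position relative to its
background frequency in the reference library. Taking the per-position
argmax of the PPM as a naive prediction and scoring it against the
planted truth:

```r
pred <- colnames(prof$ppm)[apply(prof$ppm, 1, which.max)]
evaluate_predictions(setNames(fam$query$sse, "q1"),
                     setNames(paste(pred, collapse = ""), "q1"), "dssp8")
#> Evaluation over 1 query/ies (96 residues, 8-state):
#>   Q8  macro 0.990 | micro 0.990
#>   SOV8 0.990 | boundary Q 0.980 | internal Q 1.000
#>   misclassification (3-state): H<->E 0.000  H<->C 0.000  E<->C 0.000
```

95 of 96 residues are called correctly (Q8 = 0.990) with the one error
at a segment terminus (boundary Q 0.980, internal 1.000) and no
helix/strand/coil-level confusion — on this family the homologs' SSE
strings alone nearly determine the query's structure, which is exactly
the premise the feature set encodes. Full train/predict/evaluate runs
over generated benchmarks are wrapped by `generate_benchmark()` and
`run_benchmark()`; `inst/cli/sse-pssm` exposes the same steps as shell
subcommands (`fixtures`, `search`, `build-pssm`, `train`, `predict`,
`evaluate`, ...).

## Layout

- `R/alphabets.R` — SSE alphabets, reductions (8-state → 3-state).
- `R/formats-io.R` — FASTA, alignment/PSSM TSV dialects, substitution-matrix text format.
- `R/search.R` — local affine-gap homolog search and hit weights.
- `R/sse-assignment.R` — representative SSE synthesis by weighted vote.
- `R/pssm.R` — transformation, occurrences, PPM/PSSM, pseudocounts, BLOSUM-style SSE matrices.
- `R/features.R` — windowing, amino-acid-type encoding, merging, external-prediction import.
- `R/predictor.R` — bootstrap-vote ensemble.
- `R/metrics.R` — Q, SOV (1999 revision), boundary/internal, misclassification.
- `R/fixtures.R` — synthetic families and benchmarks.
- `R/pipeline.R` — query-to-features and benchmark wrappers.
- `vignettes/sse-pssm-methods.Rmd` — model, parameter and design notes.
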