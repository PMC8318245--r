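---
title: "Secondary-structure-element PSSMs: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary-structure-element PSSMs: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssepssm)
```

## The idea

Classic secondary structure predictors feed a machine-learning model the
amino-acid position-specific scoring matrix (AA-PSSM) of the query: for
every residue, 20 log-odds scores describing which amino acids its
homologs tolerate there. This package builds the same kind of matrix over
*secondary structure element* (SSE) codes instead. The query is searched
against a set of target proteins whose secondary structure is known (or
can be synthesized); each hit alignment is *SSE-transformed* — the
aligned hit residues are replaced by that hit's SSE codes, gaps kept in
place — and the per-position code counts become a propensity matrix and
then a log-odds PSSM. Because homologs conserve structure better than
sequence, and because 3 or 8 SSE codes spread the same number of
observations over far fewer cells than 20 amino acids, the SSE matrix is
denser and more directly informative about conformation than the
amino-acid one.

The pipeline, module by module:

1. **Search** (`search_homologs()`): best local alignment of the query
   against every target, affine gap penalties, hits filtered by identity
   and aligned length, ordered by score then hit id.
2. **SSE acquisition** (`get_sse()` / `assign_sse()`): a hit with a known
   structure takes its SSE string from the library; an unannotated hit
   gets a representative string synthesized by position-specific weighted
   voting over its own homologs from an annotated reference set.
3. **Transformation** (`transform_alignment()`): `"IL-GW--L"` with hit
   SSE `"CHHEE"` becomes `"CH-HE--E"`.
4. **Occurrences**: `Occ(c, p) = sum_h 1[code_h(p) = c] * W(h)`, with the
   weight `W(h)` the hit's alignment identity fraction.
5. **PPM**: per-position normalization `PPM(c, p) = Occ(c, p) / N_p`,
   with a pseudocount mixture when requested (below).
6. **PSSM**: `log2(PPM(c, p) / B_c)` against the background frequencies
   `B` of the reference library.
7. **Features** (`window_features()`, `merge_features()`): a centered
   window of PSSM rows per residue, optionally merged with the AA-PSSM
   (built by the *same* profile machinery over the 20-letter alphabet)
   and a single-integer amino-acid-type code.
8. **Prediction** (`fit_sse_ensemble()`): a seeded bootstrap-vote
   ensemble whose per-residue class probabilities are vote fractions.
9. **Evaluation** (`evaluate_predictions()`): Q3/Q8 with macro and micro
   averaging, SOV3/SOV8, boundary/internal accuracy, pairwise
   misclassification rates.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `tau` (pseudocount mass) | 0.5 | Small positive mass keeps all PPM cells positive without drowning observed counts; 0 disables smoothing entirely. |
| `window_size` | 5 residues | Segment-overlap accuracy peaks around 5 in window sweeps while each extra residue adds a full alphabet-width of features. Sizes 1–21 are supported. |
| `search_params()` | match +2, mismatch −1, gap −11/−1, `min_aligned_length` 10, `max_hits` 500 | BLAST-like behaviour at toy scale; all overridable, and precomputed alignment TSVs bypass the aligner entirely. |
| `ensemble_params()` | 20 tree members, feature fraction 0.7 | Small enough for routine runs; `n_members = 100, member_kind = "mixed"` reproduces the 50-trees + 50-networks layout. |
| `uncovered_code` | `"C"` | Coil is the least structurally committed call for residues no homolog covers. |
| PSSM floor | −10 bits | Finite stand-in for `log2(0)` so matrices stay serializable; only reachable at `tau = 0`. |

Weights: the hit weight `W(h)` is realized as the alignment identity
fraction. "Similarity" is not given a formula by convention in this
setting; identity is the simplest faithful reading, it is the quantity
non-redundancy thresholds are phrased in, and `hit_weight()` is the
single place a different weighting could be plugged in. The same weight
is used for the representative-SSE vote (a flag in `vote_params()`
switches to unweighted voting).

## The pseudocount mixture

Sparse columns are smoothed Henikoff-style:

\[ f'_c = \frac{N_p f_c + \tau g_c}{N_p + \tau}, \qquad
   g_c = \sum_{c'} f_{c'}\, T(c \mid c') \]

where `T(c | c')` are conditional substitution probabilities recovered
from an SSE substitution matrix by inverting its log-odds against its
background. Unlike the amino-acid case, the query's own SSE code is the
thing being predicted, so it cannot seed a substitution-row prior; a
column with `N_p = 0` therefore falls back to the background
distribution outright, and those positions are recorded in
`pseudocount_positions`.

The substitution matrix itself is built by
`build_substitution_matrix()`: the BLOSUM estimation procedure (observed
unordered pair frequencies over gap-free aligned columns, expected
frequencies from the marginals, `log2` ratio) applied to any corpus of
aligned SSE string pairs. No clustering-based sequence weighting is
applied: the intended input is an already non-redundant set of
structure-alignment pairs. Never-observed pairs get the same −10 floor
as the PSSM.

## The SOV variant

Two segment-overlap definitions circulate (the original 1994 score and
the 1999 revision). This package implements the 1999 revision: per
state, every overlapping actual/predicted segment pair contributes
`(minov + delta) / maxov * len(s1)` with
`delta = min(maxov − minov, minov, len(s1) %/% 2, len(s2) %/% 2)`, and
the normalization adds the lengths of unmatched actual segments. The
choice is pinned by worked examples in the test suite: on the three
frameshift pairs shipped in `inst/extdata/frameshift_pairs.tsv`, the
1999 form gives SOV3 = 0.441, 0.526 and 0.462 (the 1994 form gives
0.521, 0.678 and 0.565 and is not what the reference values describe).

The boundary/internal split has no canonical definition; here a residue
is *boundary* iff it is the first or last residue of a maximal same-code
segment of the **actual** string. This is the simplest deterministic
rule; it is a documented design choice, not a community standard, and an
empty partition reports `NaN` rather than a made-up number.

Micro vs macro averaging: `average_q()` returns both. The macro average
(mean of per-query accuracies) over-weights small proteins; the micro
average (pooled correct residues over pooled residues) is the one to
report when query sizes vary, and `evaluate_predictions()` pools SOV the
same residue-weighted way (summed numerators over summed denominators).

## The amino-acid-type encoding

`encode_amino_acid()` maps the 20 standard residues onto 1..20 so that
physiochemically similar residues receive nearby integers: five
side-chain classes (nonpolar aliphatic, aromatic, polar uncharged,
positively charged, negatively charged), classes ordered by mean
Kyte–Doolittle hydropathy high → low, residues within a class by
Swiss-Prot natural abundance low → high; `X` is the 0 sentinel. The
table is *regenerated from this procedure in code*
(`amino_acid_encoding()` exposes it with its determining columns); it is
a reconstruction from the stated construction recipe, with the class
scheme, hydropathy scale and abundance source fixed here as the
package's own choices, not a claim of bit-equality with any externally
published table.

## What the synthetic generator does and does not emulate

`generate_family()` plants exactly the structure the method exploits: a
query drawn from a segment grammar (helix/strand/coil segments with
class-specific length ranges, no two consecutive segments of the same
class) and per-class residue emissions; homologs that are
substitution-only mutants at a requested identity whose mutated residues
are re-drawn from the *same class emissions*, so sequence diverges while
structure stays encoded; homolog SSE equal to the query's up to
segment-end jitter (boundaries shift by ≤ 2, segment structure is
preserved — real homologs lengthen and shorten elements rather than
flipping isolated residues). Defaults: length 60–100, 8 homologs,
identity 0.35–0.8, jitter probability 0.1 — a deliberately
structure-conserved, sequence-diverged regime. The eight-state mode
refines three-state segments deterministically (G/I helix caps, B
bridges for one-residue strands, T/S coil caps), so eight-state truths
reduce exactly to their three-state counterparts.

What it does not emulate: real segment-length and class statistics of
the PDB, chain breaks, indel evolution (homologs are gapless mutants, so
true alignments are trivial), long-range strand pairing constraints, or
class/size-balanced dataset curation. Consequently, passing tests show
the machinery is correct and the method's premise (structure conserved
under sequence divergence ⇒ SSE profiles dominate amino-acid profiles)
is realized *on data built to have that premise* — they do not certify
accuracy magnitudes on real proteins.

`generate_benchmark()` additionally enforces a cross-set identity
ceiling between test and training queries, with identity measured as
matched columns of the best local alignment over the shorter sequence
length (the coverage-corrected convention of non-redundancy pipelines —
raw local-alignment identity over a 10-residue patch would make low
ceilings unsatisfiable even for unrelated random sequences).

## Numerical and degenerate-input choices

- All-zero occurrence columns → background PPM, zero PSSM, position
  recorded; zero hits → the whole profile is background.
- PPM cells equal to 0 (only at `tau = 0`) → −10-bit floor in the PSSM.
- Vote ties → the configured `tie_break_order`; by default codes sorted
  by descending background frequency of the reference library, then
  alphabetically (prefer the a-priori likelier conformation).
- Prediction ties → earliest code in alphabet order (`which.max`).
- Search ties → score descending, then hit id ascending; one best local
  alignment per target, no multi-region handling.
- Background frequencies are add-one smoothed only when a code is absent
  from the library, keeping the log-odds denominator positive.
- Separate three- and eight-state models are treated as distinct
  artifacts: an eight-state prediction *can* be reduced to three states,
  but for three-state work a native three-state model is trained.

## Problem sizes used by the test suite

The shipped tests run entirely on generated data: families of one query
(60–100 residues) with 8 homologs, benchmarks of 12 queries (8 train / 4
test) over a pooled library of 96 annotated sequences, and oracle checks
on instances of ≤ 10 residues × ≤ 5 hits, where naive loop references,
exhaustive dynamic programming and hand pair-counting are feasible. The
end-to-end check asserts the directional claim only — SSE-PSSM features
strictly beat AA-PSSM features in micro-Q3 on the structure-conserved
benchmark — never magnitudes.

## Known limitations

- The aligner is a plain affine-gap local aligner: no iterated profile
  search, no E-values, no multi-region hits. Real PSI-BLAST/HHBlits
  output can be injected as an alignment TSV instead.
- SSE strings must be supplied (or synthesized by vote); the package
  does not compute secondary structure from 3-D coordinates.
- The ensemble is a deliberately simple bootstrap-vote layout; it is the
  evaluation vehicle for the feature sets, not a competitive predictor.
- Only the `q3` and `dssp8` alphabets ship with tables; other alphabets
  can be registered from a config file but bring no built-in reductions.
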