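---
title: "Classifying and profiling LEA proteins with leaptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and profiling LEA proteins with leaptools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaptools)
```

## The problem

Late Embryogenesis Abundant Proteins (LEAPs) are hydrophilic, mostly
intrinsically disordered proteins associated with desiccation and abiotic
stress tolerance in plants and anhydrobiotic organisms. Because experimental
structures are scarce, sequence-level analysis carries most of the weight:
LEAPs can be partitioned into twelve non-overlapping classes, each defined by
a short sequence motif, and the classes differ systematically in
physico-chemical properties and amino-acid usage. `leaptools` implements that
analysis as a reusable pipeline: motif classification, a per-sequence
descriptor suite, usage profiling against a background proteome, binary class
signatures, charge–hydropathy order/disorder planes, and a nonparametric
statistical battery — plus a synthetic corpus generator so that every stage is
testable without access to the original database.

## The motif dialect

Class signatures are written in a compact dialect: literal residues, `.`
(any amino acid), residue sets `[XY]` and negated sets `[^XY]`, repetitions
`{n,}` and `{n,m}`, optional tokens `?`, alternation `(M1)|(M2)`, and an end
anchor `$`. A motif matches when at least one occurrence is found anywhere in
the sequence (or ending at the last residue, for anchored motifs).

Two semantic decisions are worth spelling out:

* `.` and negated sets expand to *explicit canonical residue classes* rather
  than regex wildcards. The ambiguity letter `X`, tolerated under the
  permissive input policy, therefore never satisfies a motif position — "any
  amino acid" means any of the twenty.
* A sequence is assigned to a class only when **exactly one** class motif
  matches. Multi-motif sequences are labelled `ambiguous` and zero-motif
  sequences `unclassified`; neither is silently assigned, because on curated
  data the motif set is mutually exclusive, so any overlap is a data-quality
  signal worth surfacing (`audit_nonoverlap()`).

The compiler translates the dialect to PCRE for matching. Its correctness is
not taken on faith: the test suite carries an independent brute-force
interpreter (an explicit position-set automaton walked over every start
position) and checks agreement on a thousand randomized pattern × sequence
cases per run, alongside the fixed corner cases.

## The descriptor suite

All descriptors are composition-determined (no windowing, no pair terms):

* **Scale means.** GRAVY (Kyte–Doolittle), mean hydrophilicity (Hopp–Woods),
  mean hydrophobicity ⟨H⟩ (Eisenberg consensus), mean bulkiness (Zimmerman),
  mean flexibility (Bhaskaran–Ponnuswamy), mean molar fractions of accessible
  and buried residues (Janin), and mean transmembrane tendency (Zhao–London)
  are all arithmetic means of per-residue table values. The eight scales ship
  as plain tabular data with citation tags; tests assert completeness and
  spot-check values against the cited publications. `X` positions are
  excluded from numerator and denominator alike.
* **Molecular weight** uses average residue masses plus one water, the
  convention of sequence-database property calculators. `MW/length` is the
  mass per α-carbon backbone position, which separates "light" from "heavy"
  classes independently of chain length.
* **Net charge and pI.** Henderson–Hasselbalch summation over D, E, C, Y, H,
  K, R side chains and both free termini. The pKa set is pinned and packaged
  (N-terminus 9.0, C-terminus 2.0, standard side-chain values): published
  analyses of this kind rarely name their constants, and reproducibility
  requires pinning one set. Because total charge is strictly decreasing in
  pH, the isoelectric point is found by bisection on [0, 14] to a tolerance
  of 1e-4 pH units.
* **FoldIndex.** The whole-sequence disorder predictor
  `FI = 2.785·⟨H⟩ₙ − |⟨R⟩| − 1.151`, with ⟨H⟩ₙ the Kyte–Doolittle mean
  rescaled per residue by `(v + 4.5)/9` and ⟨R⟩ the mean net charge at pH 7.
  One value per protein; negative values indicate disorder.

## Charge–hydropathy planes

Each sequence is placed at `(r, h)`: `h` is the mean hydropathy min–max
normalized over its scale's range, and two plane variants are computed from
the same `r` — the Eisenberg ⟨H⟩ plane with boundary `h = 0.560·r + 0.645`
and the GRAVY plane with boundary `h = 0.359·r + 0.413`. Points on or above
the boundary are called folded, below unfolded (the boundary itself is
assigned to the folded side; equality has to go somewhere and "above" is the
published folded side).

The normalization of ⟨R⟩ "between 0 and 1" is genuinely underdetermined in
the literature this convention comes from; a dataset min–max would make
labels depend on which other sequences happen to be analyzed. We therefore
define `r = min(|mean net charge at pH 7|, 1)`, which is dataset-independent
and matches the charge–hydropathy plot convention of the original disorder
literature. This choice is deliberate and worth knowing about when comparing
against plots produced with other normalizations.

Note an algebraic identity: multiplying the GRAVY boundary by 2.785 gives
`2.785·h − r − 1.150`, i.e. FoldIndex's sign is (up to rounding of the
published coefficients) *the same inequality* as the GRAVY-plane call for
`r ≤ 1`. The concordance test between FoldIndex sign and plane label
therefore uses the Eisenberg variant, where agreement is an empirical
property of the two scales rather than an identity; on the synthetic corpus
it holds for every sequence further than 0.1 from the boundary (83 of 710 at
the default generator settings, essentially all on the unfolded side — the
generated corpus, like the protein family it emulates, is predominantly
disordered).

Pre-sequence handling: given a table of 1-based cleavage positions from
external targeting-peptide predictors, `trim_presequence()` produces the
putative mature sequences and the plane analysis is re-run on them; the
package deliberately does not predict cleavage sites itself.

## Usage profiles and binary signatures

Usage ratios divide each sequence's amino-acid percentages by a background
proteome composition. The packaged background emulates the early-2010s
UniProtKB/Swiss-Prot release composition and is explicitly a configuration
input (tabular, user-overridable, carrying a release tag) rather than a
constant baked into code.

Binary class signatures summarize each class by its median (the boxplot
center) and encode +1/−1 against a reference:

* physico-chemical variables with a natural fixed reference use it — 7 for
  pI, 0 for mean net charge, hydrophilicity, GRAVY, FoldIndex and ⟨H⟩;
* the remaining variables (MW/length, bulkiness, flexibility,
  buried/accessible fractions, transmembrane tendency) use the overall
  median over the whole input dataset;
* usage ratios compare against unity.

Ties encode as −1 by documented convention; for continuous data they are
measure-zero. The class summary is the median rather than the mean for
robustness and consistency with the boxplot convention.

The consensus gap arithmetic (`consensus_gap_metrics()`) recomputes the
percent-gap and percent-similarity columns of the class table from its raw
character and gap counts: `100·gaps/total` rounded to one decimal, with
similarity its complement of the rounded value, so the pair sums to exactly
100.

## The statistical battery

The variable matrix holds, per sequence, 12 physico-chemical variables, 20
usage ratios and the packaged combination fractions ([K+R], [D+E],
[D+E+K+R], [D+E−K−R], [N+Q], [A+I+L+V], [R+E+S+P], [C+F+Y+W]) — 40 columns
with the default combination set. The analyses that consume it:

* **Normality screening** (Shapiro–Wilk plus Kolmogorov–Smirnov against a
  normal with estimated moments) motivates the nonparametric choices below;
  most variables of this kind fail it decisively.
* **Kruskal–Wallis** with the class factor, tie-corrected, chi-square
  approximation with `df = k − 1`. An all-equal sample returns `H = 0, p = 1`
  rather than 0/0. At tiny n the chi-square approximation is known to be
  anti-conservative for mid-range p; the test suite verifies agreement with
  an exact permutation oracle (full enumeration at n = 12) to within 0.02 in
  the significance regime where the test is actually used, and bounds the
  gap across the whole p range.
* **Nemenyi post-hoc** all-pairs comparisons on rank sums, implemented here
  via the studentized-range approximation (`ptukey`), with the tie-corrected
  chi-square variant switchable. No packaged implementation is imported; the
  implementation is ~20 lines over base distribution functions and is tested
  for symmetry, ordering and null behavior.
* **Spearman correlation groups**: link variable pairs with `|ρ| ≥ 0.75`
  (the threshold is a parameter) and report connected components of size ≥ 2.
  "Sets of highly inter-correlated variables" is ambiguous between cliques
  and components; components were chosen, and each group reports its minimum
  and maximum intra-group |ρ| so that clique violations are visible rather
  than hidden.
* **PCA** on z-scored columns (correlation PCA) — the variables mix daltons,
  pH units and dimensionless ratios, so covariance PCA would be dominated by
  scale. Eigen-fractions are shares of total inertia; scree retention is
  reported but the number of axes kept for clustering is a parameter
  (default 3).
* **Ward clustering** (`ward.D2`, i.e. proper Ward inertia on Euclidean
  distances) on the leading PCA score columns.

## The synthetic corpus generator

The generator emulates the *structure* of the curated LEAP corpus, not its
sequences: per-class counts (145, 65, 20, 63, 58, 125, 30, 35, 64, 68, 20,
17 — 710 in total) and length ranges from the packaged class table; exactly
one implanted expansion of the class motif per sequence (at the end for
anchored motifs); background residues drawn from the packaged composition
reweighted by the class usage signs (+1 → ×1.6, −1 → ×0.6); and hard
rejection of any sequence matching a foreign class motif (budget 200 tries
per sequence, which is never approached in practice). Class-specific
refinements mirror reported composition extremes: His ×6 for class 3, and
C/F/W forced absent where classes are reported to lack them. Motif
expansions sample repetition counts uniformly (open-ended `{n,}` capped at
`n + 10`) and draw free positions from the canonical alphabet minus the
class's forbidden residues. Lengths are sampled uniformly within each
class's range — the real within-range length distributions are unknown, and
uniform is the honest stand-in.

Control sets mimic the two published comparison datasets: `idp_like` draws
are enriched in charged and flexibility-promoting residues and
rejection-filtered to FoldIndex ≤ 0; `fs_like` draws are hydrophobic-enriched
and filtered to FoldIndex > 0.

What passing tests on this corpus do and do not show: they validate the
pipeline's mechanics (classification is exact, usage-sign recovery ≥ 18/20
residues per class, strongly biased variables separate classes at
p < 0.001) under a corpus whose biases are *constructed*. They do not
certify the real corpus's per-class medians, its PCA inertia shares, or its
correlation-group membership — those depend on the real sequences. The
generator's i.i.d. residue draws also lack the tandem repeats and
low-complexity runs typical of real LEAP sequences, which is why, for
example, the synthetic corpus's folded fraction (~4%) is not a family-level
estimate.

## Problem sizes and determinism

The test suite runs the full 710-sequence corpus for corpus-level checks and
a ~1/5-scale corpus (159 sequences) for the heavier statistics; the
randomized compiler-vs-oracle property uses 1000 cases per run; permutation
oracles enumerate all relabelings at n = 12. The whole suite completes in
about a minute on one CPU. All randomness flows from explicit seeds: the
corpus generator, the control generators and `run_pipeline()` each take one,
and a fixed seed reproduces output bundles byte for byte.

## Known limitations

* Descriptors are global; no windowed disorder profiles or secondary
  structure prediction.
* pI and net charge depend on the packaged pKa set; other calculators'
  values will differ by up to a few tenths of a pH unit.
* The background composition is an emulated snapshot, not a live database
  query; supply your own table for a different release.
* Motif classification is binary per class — no partial-match scoring, no
  HMM search, no motif discovery.
* Consensus alignment itself (and phylogram construction) is out of scope;
  only the gap/similarity arithmetic on alignment summaries is implemented.
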