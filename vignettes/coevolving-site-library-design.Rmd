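---
title: "Detecting coevolving sites and designing focused NNK libraries"
author: "coevolib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coevolving sites and designing focused NNK libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevolib)
```

## The problem

Directed protein evolution lives or dies by where the mutations go. Most
focused-library strategies pick hotspot residues from conservation or from
active-site geometry. An alternative signal is *coevolution*: pairs of
alignment positions whose residues vary in a correlated way across a protein
family, typically because substitutions at one site are compensated at the
other. Randomizing both members of a coevolving pair simultaneously — rather
than one site at a time — lets the library explore coordinated replacements
that single-site saturation can never reach.

coevolib implements the computational side of that strategy end to end:

1. score all pairs of alignment columns with mutual information and a
   row-and-column weighting that damps promiscuously high-scoring positions;
2. select the standout pairs, reported in the query protein's residue
   numbering;
3. design the degenerate (NNK) mutagenic primers that randomize a pair of
   sites, with the library's combinatorial accounting;
4. tally and classify the sequenced variants that come back from screening.

The wet-lab half of the strategy — transformation, activity screening,
thermostability assays — is of course out of scope; the package stops at
sequences, scores and primer designs, and picks up again when variant
sequences return.

## Scoring model

### Mutual information with a base-20 logarithm

For alignment columns $A$ and $B$ with observed amino-acid frequencies
$P(a_i)$, $P(b_j)$ and joint frequencies $P(a_i, b_j)$,

$$MI(A:B) = \sum_i \sum_j P(a_i, b_j)\,\log_{20}
\frac{P(a_i, b_j)}{P(a_i)\,P(b_j)}.$$

The base of the logarithm is the size of the amino-acid alphabet, so the
score of a perfectly coupled, maximally diverse pair is exactly 1 and all
scores live on a $[0, 1]$ scale. Frequencies are the observed counts — no
pseudocounts by default (a Laplace `pseudocount` argument exists for very
small alignments, default 0).

Handling of incomplete data follows from the 20-letter alphabet: rows with a
gap (`-`) or missing residue (`X`, to which all ambiguity letters B, Z, J,
U, O are normalized) at *either* column are excluded from that pair's
counts. Marginals are recomputed on the same row subset, so the joint and
marginal tables are always consistent and $0 \le MI \le \min(H_{20}(A),
H_{20}(B))$ holds exactly, where $H_{20}$ is the column entropy with base-20
logarithm on those rows. A pair with fewer than two jointly observed rows is
recorded as a missing entry in the matrix rather than an error.

The matrix diagonal is not computed. Self-information is a column entropy,
not a coevolution signal, and including it in the weighting sums below would
systematically distort the weighting in favour of low-entropy columns.

### Row-and-column weighting

Raw MI conflates genuine covariation with positions that score highly
against *everything* — highly entropic columns and shared phylogenetic
signal. The weighting used here divides each pair's score by the average
score of its own row and column:

$$RCW(A:B) = \frac{MI_{ij}}{\left(MI_{i.} + MI_{.j} - 2\,MI_{ij}\right) / (n - 1)}$$

with $MI_{i.}$ and $MI_{.j}$ summed over off-diagonal entries. A pair stands
out only if it outperforms the background level of its two positions.

The normalization count $n$ deserves a note. `rcwMatrix()` defaults to the
number of alignment sequences (`nMode = "sequences"`); the convention in
parts of the covariation literature is the number of columns, and both are
available. Because $n$ enters as one common positive factor $(n-1)$ across
all pairs, the *ranking* of pairs — which is all that selection uses — is
identical under either convention, and the test suite asserts this.

When a pair's denominator is zero there is no information anywhere in its
row and column against which to weight; the score is defined as 0 ("no
comparative signal"). This convention also covers the degenerate two-column
matrix, where the denominator is always zero; three or more scored columns
are needed for the weighting to be meaningful.

### Pair selection

`selectCoevolvingPairs()` ranks pairs by descending weighted score, breaking
ties deterministically by (lower first site, lower second site), and applies
one of two rules:

* `zscore` (default): keep pairs scoring above mean + $z\cdot$SD of all
  finite off-diagonal weighted scores, $z = 2$ by default. The upstream
  web services that popularized this weighting do not publish their exact
  significance rule, so a conventional two-sigma outlier cut is used as the
  package's own default, with the threshold exposed.
* `topk`: keep the best $k$ pairs — useful when the screening budget, not a
  significance level, dictates library count.

Sites are reported in the query's 1-based ungapped residue numbering with
the query's wild-type residues, since those residue numbers are the
mutagenesis targets. Columns where the query is gapped cannot be named as
query sites and are skipped with a message.

## Alignment preparation

Gapped columns starve the frequency estimates, so two preparation steps run
before scoring.

**Sequence dropping.** `maxAlignReduce()` removes whole sequences to
maximize the area objective: (kept sequences) × (columns with no gap in any
kept sequence). The implementation is a greedy steepest-ascent loop — apply
the single removal with the largest strict area gain until none improves —
extended with a two-removal lookahead for the common local optimum where two
gappy sequences share their gap columns and only removing *both* pays off.
The loop never accepts a worsening step, so the output area is never below
the input's. On alignments of up to 12 sequences the test suite compares the
greedy result against the exhaustive subset optimum and requires at least
90% of it across a seeded fixture suite. The query sequence is never
removed (its sites are the targets), and reduction below `minSeqs`
(default 10) raises an error rather than silently thinning the family.

**Column pruning.** `dropGappedColumns()` then removes columns whose gap
fraction strictly exceeds `maxGapFraction` (default 0.5 — with half the
rows absent, pair frequency estimates are no longer trustworthy; there is
no field-wide consensus value, so it is exposed as a parameter). A column exactly at the threshold is kept; all-gap columns
are always removed. Site labels downstream always refer to the *original*
query numbering: the pipeline composes the pruned column indices with the
pre-pruning map.

An optional `dedup` flag on `readAlignment()` drops exact duplicate rows
(default off): duplicated homologs inflate apparent covariation, but
whether to remove them is a corpus-curation decision left to the user.

## Library design

### NNK algebra

An NNK codon (N = any base at positions 1–2, K = G/T at position 3) expands
to $4 \times 4 \times 2 = 32$ codons that encode all 20 amino acids and
exactly one stop (the amber TAG). `expandDegenerateCodon()` implements the
general IUPAC expansion (any of the 15 degeneracy letters at any position),
`translateCodonSet()` its image under the standard genetic code, both via
Biostrings' `IUPAC_CODE_MAP` and `GENETIC_CODE`. Treating the two sites of a
pair as independent NNK draws gives $32^2 = 1024$ codon combinations and
$20^2 = 400$ amino-acid combinations per two-site library, with an expected
stop-containing fraction of $1 - (31/32)^2 \approx 6.1\%$.

`minCodonChanges()` — the positionwise Hamming distance between codons —
quantifies why saturation matters: most substitutions recovered from such
libraries need two or three base changes within one codon, which error-prone
PCR essentially never delivers.

`libraryCoverage()` gives the coupon-collector expectation
$V(1 - (1 - 1/V)^L)$ for the number of distinct codon combinations seen
after screening $L$ clones of a library with $V$ combinations, for planning
screening effort.

### Primers

`designPrimerPair()` builds complementary oligos for whole-plasmid
(QuikChange-style) mutagenesis: total length 33–35 nt, flanks copied
verbatim from the coding sequence, one in-frame degenerate codon replacing
the wild-type codon, reverse strand the exact reverse complement. Two
conventions are the package's own (the protocol this mirrors does not fix
them): the degenerate codon is centered, with the extra base on the 5' side
when the flank total is odd; and the melting temperature is estimated with
the mutagenesis-kit formula $T_m = 81.5 + 0.41\,(\%GC) - 675/N$, counting
degenerate positions at their expected GC (0.5 for both N and K). Primers
estimated below 78 °C are warned about, not rejected — flank length, not
rejection, is the practical remedy, and the length is a parameter.

Each site of a pair gets its own primer pair; placing two degenerate codons
on a single oligo (for sites close in sequence) is deliberately out of
scope.

## Variant analysis

Sequenced variants arrive as per-site codon observations. Classification
counts the designed sites whose *translated* residue differs from wild type:
none → `unchanged_or_synonymous` (synonymous DNA changes are deliberately
grouped here — at the protein level the variant is a false positive), one →
`single_missense`, two or more → `double_missense`, any designed-site stop →
`contains_stop`. Percentages are rounded half-up to one decimal.

`tallyVariants()` counts every codon-changed observation per site
(synonymous codon changes included: they are real DNA-level substitutions
whose residue happens to be wild type) and annotates each codon with its
minimum nucleotide changes from wild type. Per-site diversity is the number
of distinct amino acids among those entries.

For re-entering published screen tables, `readSubstitutionTable()` reads
rows of (site, amino-acid call, codon, count). Published tables sometimes
contain internally inconsistent rows whose printed codon does not translate
to the printed residue. The package *trusts the recorded amino-acid call* —
it is the datum the table asserts — and surfaces every disagreement in the
table's `conflicts` slot with a message, rather than silently recomputing
residues and changing the table's totals. The bundled
`amy7c_substitutions.tsv` fixture (a transcription of a published α-amylase
screen summary over sites G89, D95, H100, D144, T147 and N197) exercises
exactly this: with recorded calls trusted, its per-site diversities are
11, 2, 6, 5, 6 and 9.

## The synthetic-data generator

`simulateCoevolvingAlignment()` is the package's test bed, and its defaults
define the validation conditions rather than being tuning knobs.

* Rows are i.i.d.; background columns draw independently from a residue
  profile (uniform over the 20 amino acids by default; an empirical profile
  can be supplied).
* A planted pair couples its second column to its first through a fixed
  random residue bijection, applied per row with probability `coupling`.
  This is deliberately the simplest mechanism with a known answer: at
  coupling 1 the pair's MI equals the first column's empirical entropy
  (base 20), which the tests check to 1e-12, and at coupling 0 the pair is
  statistically indistinguishable from background.
* Gaps are injected independently per cell at `gapRate`, planted columns
  included, so the pairwise-exclusion rule is exercised.
* The same seed reproduces the output byte for byte.

What the generator does *not* emulate — and therefore what passing recovery
tests do and do not show — is phylogenetic structure: real homolog families
are trees, not i.i.d. samples, and shared ancestry produces correlated
columns that the weighting only partially suppresses. Recovery rates on
these synthetics are an upper bound on real-data behaviour; the package's
claim is correctness of the computation, not a benchmark of the detector
against structural contacts.

`simulateVariantPool()` draws designed-site codons uniformly from the
degenerate expansion — the idealized, screening-bias-free library content —
and returns ground-truth tallies for round-trip testing.

### Validation problem sizes

The recovery checks run at 300 sequences × 50 columns with 3 planted pairs
over 20 seeded replicates (planted pairs must hold the top-3 weighted ranks
in at least 95% of replicates), plus a coupling sweep over
$\{0, 0.25, 0.5, 0.75, 1\}$ at the same size. With three planted pairs the
mean planted rank has a floor of 2 (ranks 1–3), so "improves with coupling"
is asserted as weakly decreasing with a strict overall gain. Oracle
agreement (brute-force per-pair MI) is checked to 1e-12 on 10-column
alignments, and the $[0,1]$ bounds on thousands of sampled pairs from a
1,000-column alignment. These sizes were chosen as the smallest at which
the stochastic properties are stable across seeds.

## Numerical and degenerate-input choices

* MI values are clamped at 0 against floating-point rounding of analytically
  zero sums; symmetry is exact by construction (each pair computed once).
* Ranking ties (identical weighted scores) break by (site A, site B) so all
  outputs are deterministic.
* TSV/JSON outputs use fixed 6-decimal formatting, and the per-run
  provenance record deliberately omits timestamps, so identical inputs and
  parameters produce byte-identical output files.
* Errors are classed conditions (`coevolib_*_error`) so callers and the CLI
  can dispatch on them; the CLI converts any of them into a message on
  stderr and a nonzero exit status.

## Known limitations

* No correction for phylogenetic relatedness beyond the row-column
  weighting, and no average-product correction or direct-coupling analysis;
  on deep, structured families the selected pairs will include lineage
  artefacts.
* The selection cutoff is a convention (two-sigma); reproducing the exact
  pair count of any published analysis requires knowing that analysis'
  cutoff.
* The greedy area reduction is a heuristic with a two-step lookahead, not
  the exact branch-and-bound of the published gap-trimming tool; it ties
  the optimum on most small instances and is bounded below only empirically.
* Primer Tm is the mutagenesis-kit estimate, not a nearest-neighbour model;
  it is reported for triage, not thermodynamic accuracy.
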