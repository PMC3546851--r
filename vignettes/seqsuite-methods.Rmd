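---
title: "seqsuite: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqsuite: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsuite)
```

seqsuite is a scriptable toolkit for routine DNA/RNA/protein sequence work:
format conversion, translation and reverse translation, sequence statistics,
information-theoretic motif search and discovery, text consensus logos, and
pairwise alignment. This vignette explains the models behind each tool, the
parameters that matter, and the design choices made where more than one
defensible convention exists.

## The sequence model

A `bioseq` stores an identifier, a description, the residue string (upper
case) and an alphabet, `NUCLEIC` or `PROTEIN`. The alphabet is fixed at
construction; operations cross-check it and refuse, say, complementing a
protein.

**Alphabet detection.** A sequence is classified nucleic when the fraction of
its characters in `{A, C, G, T, U}` reaches a threshold (default 0.85). The
threshold is a user parameter because no single value is right for every
input: ambiguity codes and sequencing `N`s depress the nucleic fraction of
genuine DNA, while several amino-acid one-letter codes are also nucleotide
codes. 0.85 tolerates realistic densities of IUPAC codes while rejecting
proteins, whose nucleic fraction (A, C, G, T as amino acids) rarely exceeds
0.4. Detection is monotone in the threshold by construction.

**RNA handling.** `U` is mapped to `T` at construction so that every
algorithm downstream (search, translation, complement) has a single code
path; an `is_rna` flag restores `U` on output. A sequence is flagged RNA
only when it contains `U` and no `T` — for the degenerate mixed case there is
no well-defined per-position restoration, and the input is normalised to DNA.

**Coordinates.** All reported positions are 1-based inclusive on the forward
strand, the convention biologists read; internal computation is 0-based
half-open. BED export converts to 0-based half-open as that format requires.

## Formats

FASTA, GenBank flat file and raw text are parsed and written; round-trips
preserve identifiers and residues exactly. The GenBank writer is deliberately
minimal (`LOCUS`, `DEFINITION`, `ORIGIN`, `//`, 60 residues per line in
10-residue groups): the toolkit's job is sequence-centric conversion, not
feature-table curation, and parsed GenBank features are ignored. Raw parsing
strips whitespace, digits and `\ / |`, the characters that survive pasting a
numbered ORIGIN block. Malformed records (GenBank without ORIGIN, FASTA
records with empty bodies) fail fast with the offending identifier named.

Codon usage tables are read in the GCG Wisconsin layout used by the Codon
Usage Database (`AmAcid Codon Number /1000 Fraction` rows). Missing codons
are filled with count 0 and per-amino-acid fractions are renormalised
whenever they do not sum to 1, so a table missing the sole tryptophan codon
still assigns it fraction 1. Substitution matrices use the NCBI text layout;
the standard BLOSUM62 matrix ships with the package.

## Translation and ORFs

Translation is frame-dependent (frames 1-3, and all six via the reverse
complement for ORF scans and maps). Codons containing IUPAC ambiguity codes
translate to the unique amino acid when every expansion agrees (`GCN` → `A`)
and to `X` otherwise. Translation maps place each amino-acid letter under the
middle base of its codon; negative frames are translated on the reverse
complement and therefore read right-to-left under the forward sequence.

**Reverse translation** has two modes. The uniform mode emits, per residue,
the minimal single IUPAC-degenerate codon covering all of that residue's
codons: the per-position union of bases, which is the smallest product-form
cover. For leucine, arginine and serine (split codon families) no exact
single-codon cover exists, so the cover overgenerates (e.g. `L` → `YTN`,
8 codons covering 6); the result carries a per-residue `exact` flag so the
overgeneration is visible. The usage-driven mode either picks the modal
codon (deterministic) or samples codons by their fractions (seeded); both
modes translate back to the input exactly, which the tests assert as an
inverse property.

**ORFs** run from a start codon (default `ATG` only; configurable, since
alternative starts are organism-dependent) to the nearest in-frame stop, stop
included, so lengths are divisible by 3. Nested starts sharing a stop are all
reported. With a codon usage table each ORF gets a usage score, the mean over
its codons of `log2(fraction)` with fractions floored at 1e-4 to avoid
minus infinity; ranking is then by usage score, then length. The floor and
the log scale make the score smooth and scale-free; the combination rule
(sort by usage, break ties by length) is a declared choice — the tools it
emulates do not document one.

## PSFMs, information content and logos

A position-specific frequency matrix (PSFM) is estimated from n aligned
sites as

    f(b, j) = (count(b, j) + alpha * p(b)) / (n + alpha)

with pseudocount `alpha` distributed according to the background `p`.
`alpha = 0` gives maximum-likelihood frequencies; discovery and scanning
default to `alpha = 1` so that log frequencies stay finite. PSFMs can also be
built from IUPAC consensus strings (uniform mass over each position's
expansion).

Two per-position conservation measures are provided, both in bits:

* mutual information: `IC(j) = log2 |A| − H(j)`, maximum 2 bits for DNA and
  `log2 20 ≈ 4.32` bits for protein;
* relative entropy: `IC(j) = Σ_b f(b,j) log2(f(b,j)/p(b))`.

They coincide exactly when the background is uniform (an analytic identity
the tests check to 1e-9). Candidate sites are scored by individual
information, `Ri = Σ_j (log2 |A| + log2 f(s_j, j))` (or the relative-entropy
analogue); a zero frequency yields `-Inf` rather than an error, which is the
correct sentinel for "this site is impossible under the model". An ambiguous
subject character such as `N` scores the background-weighted mean of
`f(·, j)` over its expansion, so scans over real contigs are defined
everywhere.

**Consensus logos.** Sequence logos are graphics; the text consensus logo
conveys the same positional conservation in plain text. Letters are placed on
a fixed grid of rows (default 10) at height `round(IC(j)/max_bits * rows)`,
with a vertical-bar y-axis whose maximum (2 bits for DNA) is printed at the
top and the flat consensus underneath. Ties in the consensus letter are
broken by alphabet order for determinism. Both the grid and the numeric
per-position heights are returned, so no information is lost to the
rendering.

## Motif discovery

Both discovery algorithms assume one site per sequence and report the site
configuration with the largest information content seen anywhere in the run;
`iterations` counts random restarts.

**Gibbs sampling.** Each restart draws random initial positions, then
repeatedly holds out one sequence (round-robin, which has lower variance
than random hold-out), builds a pseudocount-smoothed PSFM from the rest, and
resamples the held-out site with probability proportional to
`Π_j f(s_j, j)/p(s_j)`. Default inner steps: `100 × n` sequences. After each
full round-robin pass the sampler additionally tries sliding the entire
configuration one position left or right and accepts the slide when
information content improves. This phase-shift move is the standard remedy
for the best-known failure mode of plain site samplers — converging to a
motif offset by one or two columns — which refinement of one sequence at a
time cannot escape (moving a single site off a shifted consensus always
looks worse). The move is deterministic given the state, so seeded runs stay
reproducible.

**Greedy search.** Each restart shuffles the sequence order, seeds the
alignment with a random window of the first sequence, then adds for every
subsequent sequence the window that maximises the alignment's information
content; refinement passes re-choose each site with the others held fixed
until nothing changes (at most 10 passes), followed by the same phase-shift
hill climb. The exact update schedule of a greedy motif search is a design
space (seeded growth vs. all-pairs seeding); this variant is declared, not
inherited.

Searches run on the given strand by default; `both_strands = TRUE` adds
reverse-complement windows as candidates (DNA only). A motif and its reverse
complement are equivalent solutions in that mode.

**Dyad discovery** is string-based and exhaustive: all occurrences of
direct or inverted repeats with half-site length `dyad_len ± d_tol`, spacer
`spacer ± s_tol` and at most `max_mismatch` IUPAC-aware mismatches, scored by
mismatch count. Both half-sites share the same sampled length; allowing
unequal halves would square the search space for little practical gain.

## Search tools

Substring search counts IUPAC-aware mismatches (two characters match when
their expansions intersect, at zero cost); protein searches may instead use a
substitution matrix with a score floor. Gapped search places two substring
patterns with a variable spacer and filters on the summed mismatch count.
Site search scans every window (both strands on request; reverse-strand
windows scored on their reverse complement, reported with forward
coordinates) against a PSFM threshold in bits. Dyad pattern search sums the
Ri scores of two half-site placements; by default only the combined
threshold filters (the per-half floor is `-Inf` and exposed as a parameter).
All four are exhaustive by construction and are tested against naive
brute-force enumerations on random sequences; hit lists are monotone in
their thresholds.

Search output is a plain data frame renderable as TSV, BED6 (scores scaled
0-1000) or annotated FASTA (hits upper-case, context lower-case) — the
text equivalents of highlighting hits inside a document.

## Pairwise alignment

Needleman-Wunsch (global) and Smith-Waterman (local) with a linear
per-character gap penalty. Defaults: DNA match +1 / mismatch −1 / gap −2;
with BLOSUM62, gap −4. Affine gaps are out of scope for this version — the
linear model keeps the DP single-matrix and is sufficient for the
desk-scale comparisons the toolkit targets. The DP is filled row-wise with
the intra-row gap chain resolved by a running cumulative maximum, which
keeps the fill vectorised; traceback pointers are recovered from the score
matrix with the fixed tie order diagonal > up > left, so alignments are
deterministic. Scores and tracebacks are validated three ways: exhaustive
recursion on short pairs, re-scoring the traceback column by column, and an
independent implementation. Two 2,500-residue proteins align in seconds in
a few hundred MB, the capacity envelope the package promises.

For Smith-Waterman the empty alignment (score 0) is legal output; span
fields are `NA` in that case.

## Synthetic data and what the tests show

`generate_planted()` draws i.i.d. background residues and inserts exactly one
motif instance per sequence (a literal string or a PSFM sample), returning a
truth table for recovery scoring; `generate_random_genome()` additionally
plants ORFs and dyads at recorded positions. Both are pure functions of
their arguments, seed included.

The discovery benchmark plants a perfectly conserved 8-mer in ten 100-bp
uniform-background sequences and asks each algorithm to recover at least 9 of
10 sites, in at least 95% of 50 seeded trials (Gibbs: 20 restarts; greedy:
100 restarts). These synthetic conditions isolate algorithmic correctness:
uniform background and a perfectly conserved motif are easier than real
promoters, which have composition bias, partially degenerate motifs and
sometimes zero or multiple sites per sequence. Passing therefore shows the
machinery finds strong signals reliably, not that it matches specialised
discovery servers on real regulons.

Problem sizes used by the checks — 1 kb sequences for search oracles, length
≤ 8 for alignment path enumeration, 50 discovery trials, one 2,500-residue
alignment — were chosen so the whole suite recomputes everything from
scratch in a few minutes on a single core.

## Known limitations

* Linear gap penalties only; no affine gaps, banding or linear-space
  traceback.
* GenBank features are parsed over, not preserved.
* No statistical significance (E-values) for motif or search scores; scores
  are information-theoretic only.
* Discovery assumes exactly one site per sequence; multiple motifs are found
  by re-running with previously found sites masked by the caller.
* No genome-scale indexing; all searches are exhaustive scans.
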