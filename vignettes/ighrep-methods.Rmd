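---
title: "IgH repertoire analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IgH repertoire analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ighrep` reconstructs an analysis pipeline for barcoded paired-end IgH
amplicon sequencing, from raw read pairs to clonotype tables and
repertoire statistics, together with a simulator that generates every
input the pipeline consumes. The amplicons span CDR2 through CDR3 into
the start of the constant region, with a 6-nt sample barcode at the 5'
end of the constant-region mate. This vignette documents the models, the
parameters that matter, and the choices made where the design was
genuinely open. The numbered scripts under `analysis/` are the
narrative drivers; all computation lives in the package and is exercised
by the test suite.

# Preprocessing model

**Demultiplexing** assigns a read pair to a sample iff the
constant-region mate begins with an *exact* barcode; there is no
1-mismatch rescue. Barcodes are designed with pairwise Hamming distance
≥ 3, so with a per-position synthesis error around 5% the chance of one
barcode converting into another is about $0.05^3 = 1/8000$ — this single
number is reused as the cross-contamination rate $\mu$ of the artifact
filter, and error-correcting demultiplexing would silently change it.
That is why the exact-match rule is load-bearing, not a simplification.

**Quality trimming** slides a 2-base window (`window = 2`) left to
right; at the first window containing any quality below Q20
(`threshold = 20`) the read is truncated from that window to the 3' end.
The rule is applied literally, so a low first base discards the whole
read. Reads shorter than 100 nt after trimming are dropped with a logged
count; the length floor is a configuration value, not part of the
trimming rule itself.

**Merging** reverse-complements the second mate and scans every relative
shift of the two reads, scoring matches minus mismatches (gap-free). The
best-scoring overlap is accepted only if it is mismatch-free and at
least `min_overlap = 15` nt; otherwise the pair is discarded with a
reason code (`NO_OVERLAP`, `MISMATCH`, `TOO_SHORT`). Because acceptance
requires a perfect overlap, any maximal-overlap search is behaviourally
identical to a banded global aligner here; the exhaustive shift scan was
chosen because it is trivially correct and runs in compiled code.
There is no quality-aware consensus in the overlap: a disagreement
discards the pair rather than voting.

# Annotation model

**Segment assignment** uses affine-gap Smith–Waterman local alignment
(match +2, mismatch −2, gap open −5, gap extend −1; a gap of length
$L$ costs $5 + (L-1)$). The scheme is standard for nucleotide work; on
error-free data the calls are scheme-insensitive, and the aligner is
pinned to an independently written dynamic-programming oracle in the
tests, including boundary and tie-break behaviour (ties resolve to the
earliest query start, then reference start, then query end, then
reference end). The V call is the best local hit among V segments; J is
searched strictly downstream of the V alignment, and the constant
region (isotype call) downstream of J. Score floors (V ≥ 60, J ≥ 30,
C ≥ 30) mark reads unmappable rather than guessing; the floors are
configuration values since the upstream study does not state a
mapping-quality cutoff, and the clean-read accounting is therefore
implementation-relative.

**CDR3 migration** projects the V segment's CDR3 start mark and the J
segment's CDR3 end mark through the alignment edit strings onto the
read, extrapolating linearly outside the aligned block. Coordinates are
1-based inclusive throughout, the native convention of R and of
IRanges-style containers. The CDR3 is translated in the V reading
frame; junctions whose length is not a multiple of three, or whose
peptide contains a stop, are flagged non-productive and excluded from
peptide-level statistics.

**Junction decomposition** is reported in *canonical template-maximal
form*: V and J templates are extended by exact germline matching from
the CDR3 anchors, the D segment is placed at the longest exact substring
shared with any germline D, palindromic (P) additions of up to 2 nt are
recognized at untrimmed segment ends, and whatever remains is counted as
nontemplated N (split into the V–DJ and D–J joins). A junction base that
could equally be template or N is always attributed to template. This
biases N counts low relative to the unknowable biological event — but
the alternative decompositions of the same nucleotide string are
mathematically indistinguishable, so the simulator's ground-truth tables
record the same canonical decomposition of each realized sequence. The
recovery tests therefore measure the pipeline's ability to reconstruct a
well-defined quantity, and the convention is stated here rather than
hidden. A D call requires at least 5 consecutively matching nucleotides;
below that, D segments are statistically unidentifiable and the bases
are absorbed into a single N stretch.

**Mutation calling** compares the read to its best-aligned germline V
inside the window from the start of CDR2 to the start of CDR3 — the
amplicon's forward primer sits in framework 2, so positions upstream of
CDR2 are primer-templated and unusable, and the junction itself is
excluded because junctional diversity is not hypermutation. Only
sequences observed in more than 4 copies enter mutation statistics:
isolated sequencing errors rarely recur identically, so the copy floor
suppresses them without modelling the error process. Each mutation is
annotated with its germline hotspot context: a position is `DGYW` if any
4-mer window covering it matches D-G-Y-W (IUPAC D = A/G/T, Y = C/T,
W = A/T), else `WRCH` (R = A/G, H = A/C/T), else `none`; DGYW takes
precedence where both match. Insertions and deletions are not counted
as hypermutation events, only substitutions.

# Artifact filters

The filter order is fixed: related-read collapse, then singleton
removal, then the cross-contamination test. Counts are non-increasing at
every stage and each stage logs what it removed.

**V relatedness.** Two germline V sequences are related iff their local
alignment has more than 200 matched bases and fewer than 6 mismatches —
both thresholds strict, which the tests pin at exactly 200 matched and
exactly 6 mismatches. Two *reads* are related if their V calls are
related (identical calls trivially so) and their CDR3s have equal length
and at most 1 mismatch. The stated rule "less than 1 mismatch" would
literally mean 0, but a 0-mismatch rule could never absorb
sequencing-error variants, which is the filter's purpose; the default is
≤ 1 with 0 available by configuration, and the ambiguity is surfaced
here rather than silently resolved.

**Collapse.** Among related records, a minor whose count is strictly
below 5% of the major is *removed* — its copies are dropped, not merged
into the major, matching the removal semantics of the procedure this
implements. Records are processed in descending copy order with
lexicographic CDR3 tie-breaks, so removals cascade deterministically.
A minor at exactly 5% survives.

**Singletons.** Every CDR3 nucleotide sequence with total count 1 is
removed.

**Cross-contamination.** For a CDR3 with $n$ copies in one sample and
$N$ copies in another sample of the same run, the probability that the
$n$ copies arose by barcode conversion is the Poisson upper tail
$$P(X \ge n) = 1 - \sum_{k=0}^{n-1} e^{-\lambda}\lambda^k/k!,
\qquad \lambda = N\mu,\ \mu = 1/8000 .$$
The CDR3 is retained in that sample iff $P < 0.001$. The sum starts at
$k = 0$: a lower index of 1 would make $P(X \ge 1)$ identically 1 and
contradict the definition of "occurs $n$ or more times"; the $k=1$
variant is available behind a flag (`printed_formula = TRUE`) for
comparison. When several other samples carry the CDR3, $N$ is the
largest co-occurring count — the most conservative single-source model,
since the source sample is not identified by the assay. The tail is
evaluated with `ppois` and cross-checked in the tests against an
explicit partial-sum oracle.

# Repertoire statistics

* **D50**: with per-CDR3 abundances ranked $r_1 \ge \dots \ge r_S$
  summing to $J$ reads, $C$ is the smallest number of top clones whose
  cumulative abundance reaches $J/2$, and $D50 = 100\,C/S$. Uniform
  repertoires over an even number of clones give exactly 50; a repertoire
  dominated by one clone approaches $100/S$. When $r_1$ alone reaches
  $J/2$, $C = 1$ by the prefix-sum definition. Rank ties break
  lexicographically so the statistic is deterministic.
* **Pairwise sharing** is computed on distinct CDR3 *peptides*,
  unweighted by copies: $p_{A \to B}$ is the percentage of A's peptides
  also present in B. A nucleotide-level variant exists but is not the
  default, since peptide-level sharing is what convergent selection acts
  on.
* **VH usage** is normalized by default: each distinct CDR3 nucleotide
  sequence counts once under its V gene, regardless of copy number, and
  the output is ordered 5'→3' by chromosomal rank. A copy-weighted mode
  is available.
* **N-insertion profiles** bin the total nontemplated bases per unique
  sequence into {0, 1–2, 3–4, 5–7, ≥8}.
* **Convergence entropy**: a CDR3 peptide encoded by $n$ distinct
  V(D)J nucleotide recombinations with frequencies $P_i$ gets
  $E = -\sum P_i \log_2 P_i$, binned into [0, 0.5), [0.5, 1.5),
  [1.5, 2.5), [2.5, ∞). Recombination identity is the distinct
  (V, D, J, CDR3-nt) tuple. $P_i$ is copy-weighted by default — read
  frequency is the natural reading of "frequency" — with a
  unique-sequence weighting available; bin fractions are reported both
  over distinct peptides (default) and read-weighted, since either
  denominator is defensible.
* **Mutation summaries** report the percentage of eligible unique
  sequences with ≥ 1, ≥ 2, ≥ 4 mutations and the rate per $10^4$ bp of
  analysis window, over unique sequences (not copy-weighted; the choice
  is documented and switchable by filtering the table). With no eligible
  records the summary is absent (`NA`), not zero.
* **Isotype-by-mutation** stratifies eligible sequences into mutation
  counts {0, 1, 2, 3, 4, ≥5}; class-switched means neither IgM nor IgD.

# Treemaps

The canvas is divided first into V rectangles, each into V–J
rectangles, each into V–J–CDR3 leaves, with areas exactly proportional
to read frequency at every level. Within a level, rectangles are packed
with the squarified heuristic in descending area and the finished layout
is mirrored so the largest rectangle sits at the bottom right and the
smallest at the top left; the packing algorithm itself is a free choice
(only the ordering and proportionality rules are fixed), and
squarification was picked for visual parity with published maps — areas
are exact, shapes are not prescribed. Corners are rounded and colors
drawn from a seeded generator, so a fixed seed gives byte-identical SVG
while palettes differ between plots.

# The simulator: what it emulates, and what it does not

The generator stands in for the study's unreleased sequencing data. It
emulates, per clonotype: uniform V/D/J choice; exonuclease trimming
(geometric-ish deletions, V ≤ 6, D ends ≤ 4 each, J chosen to keep the
CDR3 in frame); P additions of ≤ 2 nt at untrimmed ends; N additions
with geometric lengths whose mean is `n_insertion_rate` (0 reproduces
Tdt-negative neonatal junctions); hotspot-biased substitutions at
`shm_rate` per bp with multiplier `hotspot_bias` at DGYW/WRCH positions,
renormalized so the average rate equals `shm_rate`; class switching with
probability `switch_prob`; and Zipf clone sizes with exponent
`abundance_law`. Reads carry per-base errors at `seq_error_rate` with a
two-component quality model (high ≈ Q33–40, low ≈ Q10–19) in which
injected-error positions are preferentially low-quality, so the trimming
rule has something real to do.

Defaults: `n_insertion_rate = 2.5` (adult junctions carry a few
nontemplated bases per join), `hotspot_bias = 5`, `switch_prob = 0.1`,
`abundance_law = 1.2`, `read_length = 250` (MiSeq-like, comfortably
spanning a ~330 nt amplicon from both ends). The upstream study gives no
quantitative clone-size or switch-rate parameters; these values are
placeholders chosen once to look like a generic adult murine sample, are
labelled as such, and are not tuned against any measured outcome.

Deliberate simplifications, hence what passing tests do *not* show about
real data: no PCR amplification bias or chimera formation, no light
chains, no allele-level (\*01/\*02) variation, no indel sequencing
errors, uniform segment usage rather than the strongly non-uniform usage
of real repertoires, and somatic mutations confined to the CDR2→CDR3
analysis window (mutations elsewhere would be invisible to the mutation
caller by construction, but would also make the `shm_rate` parameter
mean something other than what the pipeline measures). Junction
ground truth is recorded in canonical template-maximal form, as
explained above. Two structural choices keep ground truth well-defined:
simulated D segments are 14–24 nt so that maximal trimming still leaves
≥ 6 identifiable template bases, and V-family divergence is placed
inside the amplicon so that related V genes remain distinguishable by
alignment.

# Numerical and degenerate-input behaviour

Probabilities are clamped to [0, 1] against floating-point drift; the
Poisson tail uses `ppois` rather than naive summation. Empty tables
error on metrics that have no meaningful value and pass through filters
unchanged. An empty merge, a read shorter than the trimming window, a
junction whose boundaries project outside the read, and a zero-area
treemap canvas are each handled explicitly (unchanged read, logged
rejection, logged migration failure, error). All randomness flows
through caller-supplied seeds and restores the caller's RNG state, so
identical configuration and seed give identical outputs end to end,
byte-for-byte for FASTQ and SVG.

# Problem sizes

The test suite exercises the pipeline at sizes chosen to make its
statistical checks sharp while staying desk-scale: the lossless
round-trip runs two samples of 2,500 error-free reads each (~200
clonotypes per sample); parameter recovery uses 5,000 clonotypes, where
the N-insertion bins are recovered within ±2 percentage points and the
mutation rate within 20% relative; the Poisson filter calibration draws
10⁴ recipient counts; the alignment oracle comparison covers 200 random
pairs up to 30 nt. The `analysis/` scripts run a four-sample, ~10,000
read-pair study in about two minutes.

# Known limitations

Segment assignment is exhaustive alignment against the catalog — fine
for a dozen V genes, quadratic-feeling for hundreds; a seeding
prefilter would be the first optimization for a full IMGT catalog. The
contamination test conditions on the largest co-occurring sample only,
not the sum of sources. Mutation statistics assume substitutions only.
The treemap guarantees exact areas but not the exact rectangle shapes
of any particular published figure.
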