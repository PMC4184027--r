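---
title: "Read mapping with the q-group index: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read mapping with the q-group index: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgroupmap)
```

qgroupmap is a filtration-plus-validation short-read mapper. Cheap exact
q-gram matching proposes candidate loci; a banded unit-cost alignment
confirms or rejects them; surviving hits are grouped into percent-identity
strata, optionally paired, annotated with a Bayesian mapping quality and
written as SAM. This vignette explains the data structure and the model,
the tunables and their defaults, what the bundled simulator does and does
not emulate, and the numerical choices made where the design was open.

## The q-group index

A classical q-gram index stores an address table `A` of `4^q` integers and
a position table `P` of `|T|` integers: `P[A[g] .. A[g+1])` holds the
occurrences of the q-gram with numeric code `g`. For q = 16 the address
table alone is 4^16 = 4.3e9 entries, regardless of how small the indexed
text is — hopeless when the text is a batch of reads of a few hundred
kilobases.

The q-group index replaces the address table by four arrays:

* `I` — one *bit* per possible q-gram, packed into groups of `w`
  consecutive codes per machine word: bit `j` of `I[i]` says whether
  q-gram `g = i*w + j` occurs in the text at all.
* `S` — exclusive cumulative popcount of `I`, i.e. `S[i]` is the number
  of occurring q-grams in groups before `i`.
* `S'` — one offset per *occurring* q-gram, indexed by the rank
  `S[i] + j'`, where `j' = popcount(I[i] & (2^j − 1))` is the rank of bit
  `j` inside its group word.
* `O` — the occurrence positions, concatenated in numeric q-gram order.

Lookup of `g` costs two array reads and one popcount:
`i = floor(g/w)`, `j = g mod w`, and if bit `j` of `I[i]` is set, the
occurrences are `O[S'[S[i]+j'] .. S'[S[i]+j'+1])`. That is constant time
per retrieved position, like the classical index.

The memory story: `I` and `S` need `ceil(4^q/w)` words each, `S'` at most
`min(4^q, |T|)` words, `O` exactly `|T|` words — in total at most
`2/w·4^q + min(4^q,|T|) + |T|` words against `4^q + |T|` for the classical
layout. Writing `K = 4^q/|T|`, the worst-case ratio is
`(K/h + K + 1)/(K + 1)` for `K ≤ 1` and `(2 + K/h)/(1 + K)` for `K > 1`
(with `h = w/2 = 16`): a 3% overhead when `K = 1`, break-even at
`K = 16/15`, and an asymptotic 16-fold saving for sparse q-gram spaces.
`size_ratio()` and `worst_case_words()` expose these closed forms, and the
test suite checks measured array sizes of built indexes against the bound.

Construction (`build_qgroup_index()`) mirrors the count/scan/scatter
pattern the structure was designed around: set occurrence bits, cumulative
popcount into `S`, count occurrences per occurring q-gram, cumulative sum
into `S'`, then scatter positions into `O`. The order of positions
*within* one q-gram's interval of `O` is deliberately unspecified (set
semantics); `save_qgroup_index()` sorts each interval so on-disk artifacts
are canonical.

Two storage choices are worth stating. First, group words are held in R
integer vectors, which are 32-bit; group widths `w` from 1 to 32 are
supported and 64 is not, because a 64-bit group word has no honest carrier
in that representation (the analytic size functions do accept `w = 64`).
Second, q-gram codes can exceed `2^31 − 1` at q = 16, so codes are carried
as doubles at the R boundary (exact up to 2^53) and as unsigned 64-bit
integers inside the C++ kernels. An optional half-sampled `S`
(`half_sample = TRUE`) stores only the even-group entries and reconstructs
odd ones with one extra popcount per lookup.

## Filtration: index the reads, stream the reference

Building the index over the reference would mean rebuilding (or storing)
it per chromosome for every batch of reads. The pipeline therefore indexes
the *reads*: a batch is concatenated into fixed-length slots
(`slot_length` = longest read in the batch), so an occurrence position `o`
in the concatenation decodes to read `o div slot_length` and in-read
offset `o mod slot_length` with one division. Slot padding is never
indexable, and no q-gram window can span two reads.

The reference side is a precomputed, serialisable stream
(`build_reference_index()`): per chromosome the sorted list `P` of
(q-gram, position) pairs, with exceedingly frequent q-grams masked out.
"Exceedingly frequent" is quantified as a per-chromosome occurrence count
above `max(absolute_cap, ceil(frequency_cap * chromosome_length))`,
defaults 1000 and 1e-4; both caps are exposed and `Inf` disables masking.
Masking trades a bounded loss of (repetitive) seeds for a hard bound on
candidate volume; the conservation test checks that retained plus masked
positions account for every q-gram start.

Streaming `P` against the batch index (`generate_hits()`) keeps the
two-pass structure: count hits per pair, exclusive prefix sum, scatter
each (read id, diagonal) into its interval — output capacity equals the
summed counts by construction. The *diagonal* `p − offset` is the putative
0-based start of the read on the forward reference.

Strands: each chromosome is streamed twice, forward and
reverse-complemented, against the one batch index; minus-strand diagonals
are mapped back to forward coordinates as `chrom_len − diagonal −
read_len`. Candidate deduplication collapses identical (read, strand,
chromosome, diagonal) triples and merges diagonals within `delta`
(default 3) of each other into the best-supported representative, to
tolerate small indels shifting seed diagonals. Negative diagonals are
clamped to 0; the validation window absorbs the overhang.

The pigeonhole lemma sets the guaranteed regime: a read of length `n`
with `e < (n+1)/q − 1` errors must share an exact q-gram with its origin,
so with `n = 100`, `q = 16` up to 5 errors cannot escape filtration
(masking aside). The property test plants 4 substitutions in 40-mers at
q = 8 (the same regime) and asserts the true diagonal always survives.

## Validation: bit-parallel banded edit distance

Each candidate is expanded to the window `[diagonal − pad, diagonal +
|r| + pad)` with `pad = band_width/2` (default 16), clipped to the
chromosome. The window *is* the band: no semi-global alignment inside it
can drift more than `pad` off the candidate diagonal, so scoring full
columns of the window equals the band-restricted optimum — and equals the
unbanded optimum whenever the true path's excursion is within the band.
The window formula is a documented choice; nothing in the problem pins the
exact pad, and symmetric slack is the simplest rule that covers indel
drift on both sides.

Columns are computed with Myers' bit-parallel recurrence: the read is the
pattern, the current column's vertical deltas live in `VP`/`VN` words, and
one column transition is a constant number of word operations. Reads
longer than 64 bases use the blocked variant with horizontal carries
between words — identical semantics, `O(|window| · ceil(|r|/64))` time.
The score tracked at the bottom row is the minimal distance of the whole
read against any window substring ending at that column; the smallest end
attaining the minimum is kept. A second, backward pass over the reversed
prefix locates the alignment start; among tied backward ends the largest
is taken, so ties resolve toward the smallest reference start.

Percent identity is `s = 100·(|r| − k)/|r|`; hits below the threshold
(default 80) are discarded. Equal-`s` comparisons downstream never use
float equality: within one read `s` ties are `k` ties, and paired sums are
compared by integer cross-multiplication.

The band bounds the largest recoverable indel; larger indels surface, if
at all, as partial matches under the semi-global score. There is no
dedicated split-read path, no affine gaps, and base qualities do not enter
the score — all deliberate scope bounds.

## Postprocessing: strata, pairing, mapping quality, SAM

Validated hits of a read are grouped into strata of equal percent
identity, ranked best first. `mode = "all"` reports every stratum,
`mode = "best-stratum"` only rank 1. In paired mode, hits of the two
mates are joined into *units*: proper pairs (same chromosome, FR
orientation, template length within `[insert_min, insert_max]`, greedily
matched by summed identity with exact integer keys), followed by leftover
lone-mate placements ranked after all pairs.

The mapping quality approximates the posterior that a hit is the read's
true origin. The sampling likelihood of a hit with identity `s` is modeled
as `C·exp(−λ·(100 − s))` (defaults `λ = C = 1`): every edit, whether
variant or sequencing error, is roughly equally unlikely, so the
likelihood decays exponentially in the edit count. The posterior
normalises over the read's *validated* hits — hits discarded at validation
are taken as zero likelihood, which is exactly what the threshold
justifies. The PHRED value is `min(floor(−10·log10(1 − Pr)), 60)`: a
unique hit has posterior 1 and reports the cap 60; two or more hits tied
at the best identity are *forced to 0*, matching what downstream callers
expect of ambiguous placements. Flooring is the conservative rounding
choice. In paired mode the posterior is taken over a fragment's units,
with a lone mate's missing partner counted as fully erroneous so that
proper pairs dominate — the package's own extension of the single-end
model, stated here because the pairing posterior is not otherwise
constrained.

Tracebacks recompute the unit-cost path over the located span; the CIGAR's
edit count equals `k` for semi-global output (re-checked against a DP
oracle for every emitted alignment in the test suite). `local` style
soft-clips read ends whose retention lowers a simple +1/−2 score, and
clipped bases leave NM. SAM output is 1-based, primary hits are the
rank-1, lowest-chromosome, leftmost records, all others carry flag 0x100,
and the `@PG` line echoes the full configuration; with a fixed seed the
SAM body is byte-reproducible.

## The simulator, and what passing tests do (and do not) show

`simulate_genome()` draws i.i.d. uniform ACGT — maximally informative
sequence with no repeat structure. `simulate_reads()` samples origins
uniformly over positions and strands, plants an exact, recorded number of
substitutions (always to a different base) and short indels, and in paired
mode draws FR fragments with Normal insert length. The truth table drives
`evaluate_mapping()`: a hit is correct within ±5 bp of the origin on the
same chromosome and strand; sensitivity counts reads with any correct
reported hit, recall reads with a correct primary, precision the correct
fraction among unambiguously (single-hit) mapped reads.

A uniform genome means q-gram matches off the true diagonal are rare, so
the simulator exercises correctness of the machinery, not robustness to
repeats; the `repeat_segment` option and the two-chromosome duplicate used
in the acceptance checks probe the ambiguity path (MAPQ 0) explicitly.
Real genomes add repeat families, context-dependent error profiles and
indel-rich loci that the uniform model does not represent — 100%
sensitivity here demonstrates the pigeonhole regime works as analysed, not
field performance on human data.

Problem sizes: the headline sensitivity check runs the stated condition in
full — a 1 Mb genome and 1,000 length-100 reads with at most 4
substitutions at q = 16 (about 15 s and 1.1 GB for the group arrays).
Structural unit tests use 5–100 kb genomes and q = 4..8, where the checks
are scale-free; the oracle-equivalence suites run ~1,000 randomized texts
and ~1,300 random alignment pairs.

## Known limitations

* Group words are 32-bit; `w = 64` exists only in the analytic size model.
* One alignment cannot contain an indel larger than the band pad
  (default 16); no split-read or chimeric reporting.
* Unit edit costs only; base qualities are carried through to SAM but do
  not influence scores.
* SAM text output only (no BAM/CRAM); conversion is downstream work.
* The mapping-quality model is deliberately coarse: it is conservative and
  comparable across hits, not a calibrated probability; `lambda` and `C`
  can be refit per dataset.
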