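---
title: "Reference-free organelle genome extraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free organelle genome extraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Mitochondria (and plastids) carry their own small, usually circular genomes
and are present at roughly 10--100 copies per cell. In whole-genome shotgun
data the organelle therefore appears at 10--100 times the nuclear read
depth. Seed- and reference-based extractors exploit known organelle
sequence; this package instead exploits only that depth contrast, so it
works on organisms whose organelle genomes are entirely unknown.

The separation statistic is the k-mer depth. A read of length $L$
contributes $L - k + 1$ k-mers, so genome depth $N$ and pool-wide k-mer
depth $M$ are related by

$$N = M \cdot \frac{L}{L - k + 1}, \qquad k < L + 1,$$

and a read whose most frequent k-mer implies a genome depth far above the
nuclear depth is very unlikely to be nuclear. The pipeline:

1. trim reads (built-in 3' adapter/quality trimmer, minimum surviving
   length 30 bp) and assemble the whole pool;
2. map reads back to a nuclear anchor contig (first 100,000 bp only) and
   set the **nuclear depth (ND) threshold** to
   $$\mathrm{ND} = 5 \cdot \frac{\sum_{i = 25\text{th pct}}^{75\text{th pct}} d_i}{n},$$
   the trimmed mean of the sorted non-zero per-base depths $d_i$ between
   the 25th and 75th percentiles ($n$ = slice size), times 5;
3. count canonical 31-mers across the pool in a Count-Min Sketch and keep
   every read with at least one k-mer strictly above the threshold
   (converted to k-mer-count units);
4. reassemble the retained pool and select the longest contig as the
   organelle candidate;
5. trim the candidate's duplicated circular terminus and validate it by
   comparing its read depth with the nuclear background.

The multiplier 5 sits between the nuclear depth (1x) and the lowest
organelle copy number reported in the literature (10x). Organisms with
unusually few organelle copies defeat the automatic estimate; the manual
`nd_threshold` argument exists for exactly that case.

## Why a Count-Min Sketch

The k-mer multiset of a large pool may not fit in memory as an exact table.
A Count-Min Sketch stores `depth` rows of `width` counters; insertion
increments one counter per row (independent seeded hashes of the 2-bit
encoded canonical k-mer) and a query returns the *minimum* across rows.
Collisions can only inflate counts, never deflate them, so the error is
one-sided: a nuclear read may be binned by mistake (it yields a harmless
small contig), but **no read above the true threshold can ever be lost**.
That asymmetry is what makes an approximate counter acceptable here, and it
is asserted directly in the test suite against an exact-table oracle.

Counting is canonical (the lexicographically smaller of k-mer and reverse
complement) because shotgun reads sample both strands and the depth
argument assumes strand-pooled counts. Windows containing `N` are skipped
entirely: an ambiguous base makes the k-mer's identity unknowable. k is
capped at 31 by the 2-bit/64-bit encoding; 31 is also the method's working
value.

**Sizing.** The package default is width $2^{22}$ x 3 rows (64 MiB of
counters), adequate for genome-derived pools where distinct k-mers number
in the hundreds of thousands. For a load of $\lambda$ distinct k-mers per
counter, a queried k-mer returns its exact count unless every row's cell is
shared, which happens with probability $(1 - e^{-\lambda})^d$. At the
acceptance suite's hardest setting -- 50,000 uniform-random 100 bp reads,
$\sim$3.5M distinct 31-mers, width $2^{22}$, so $\lambda \approx 0.83$ --
a 99.9% exactness target requires
$d \ge \ln(0.001)/\ln(1 - e^{-0.83}) \approx 12.1$; the suite uses
$d = 13$. This sizing was derived from the formula above before the test
was ever run, not tuned to it. For real WGS pools, prefer width $2^{26}$.

## The nuclear anchor

The depth threshold needs a contig that is confidently nuclear. The
classical choice is the longest contig of the initial whole-pool assembly:
on real data the nuclear genome is orders of magnitude longer than the
organelle, so some nuclear contig always outgrows it. At desk scale that
logic inverts -- a 16 kb organelle at 200x assembles into one perfect
contig while a 50 kb nuclear sequence at 10x fragments into shorter pieces
-- and anchoring on the organelle would push the threshold to organelle
depth and empty the bin.

`select_anchor()` therefore takes the longest contig whose depth is
*typical*. Per-contig depth is estimated cheaply from the sketch (median
k-mer count over sampled windows, converted to genome-depth units), the
typical depth is the length-weighted median across contigs (most assembled
bases are nuclear), and contigs above 3x that value are excluded. The
bound of 3 sits deliberately below the threshold multiplier 5: anything at
organelle-like depth ($\ge$ 10x nuclear) is excluded with margin, while
ordinary two- to three-fold repeats still qualify. Supplying an explicit
`anchor` bypasses the heuristic and restores the classical behaviour.

## Percentile convention

With $m$ sorted non-zero depths, the trimmed slice is indices
$\lfloor 0.25(m-1) \rfloor$ through $\lfloor 0.75(m-1) \rfloor$ (0-based,
inclusive, no interpolation). The convention was chosen so that a fully
covered contig yields $n \approx m/2$ -- "half the contig length" -- and it
is the same convention the brute-force test oracle implements. Whether the
original tool used inclusive or interpolated bounds is unknown; for any
profile that is not pathologically small the difference is far below the
factor-5 scale of the threshold.

## Threshold units

Step 3's rule compares a read's maximum k-mer *count* against the ND
threshold, which is measured in read-*depth* units. The package converts
the threshold into k-mer-count units via the inverse depth relation
(multiplying by $(L-k+1)/L \le 1$) before comparing -- the unit-consistent
reading -- with `depth_conversion = FALSE` available for the literal
raw-count comparison. Both readings are conservative for recall: the
conversion can only lower the threshold. $L$ is the modal post-trim read
length (ties to the smaller value, again the conservative direction).

## The built-in assembler

A minimal canonical de Bruijn unitig assembler: keep k-mers with count
$\ge$ `min_kmer_count`, pop tips shorter than $2k$ (a tip has exactly one
dead end), compact unbranched paths, and feed each k's unitigs into the
next larger k as pseudo-reads whose k-mers enter unconditionally (the
iterative-k strategy of multi-k assemblers, without their internals).
There is no bubble popping, scaffolding or paired-end resolution. Start
k-mers are iterated in sorted order, so output is invariant under read
permutation; odd k avoids palindromic k-mers entirely. A clean circular
genome compacts into a single unitig running once around the circle plus a
duplicated $k-1$ bp terminus -- precisely the signature the circularity
check consumes (final $k = 61$ gives a 60 bp terminus, above the 50 bp
detection minimum).

In the pipeline's *second* assembly, `min_kmer_count` is raised to
$\max(2, \lceil \mathrm{threshold}/4 \rceil)$. Binned reads carry k-mers
above the threshold ($\approx 5\times$ nuclear k-mer depth), so a floor at
$\approx 1.25\times$ nuclear k-mer depth removes recurrent sequencing-error
k-mers -- which at 200x organelle depth easily reach counts of 2--5 and
would otherwise riddle the graph with bubbles -- while sitting at least
8-fold below the weakest qualifying organelle depth (copy ratio $\ge$ 10).

## Circularity and validation

Overlap lengths from $\min(\lfloor \text{len}/2 \rfloor, 2000)$ down to 50
are scanned for a prefix/suffix match with at most 2% mismatches; the
longest match wins and its suffix copy is cut. Fifty exact-ish base pairs
of chance agreement on random sequence has probability far below
$10^{-20}$, and the 2% allowance absorbs end-of-assembly errors. Matching
is exact-first rather than alignment-based: both copies of a genuine
terminal duplication come from the same circle and are near-identical.

Validation maps the full read pool to the candidate and to a same-length
section of the nuclear anchor and reports both profiles (as a TSV -- data
is testable, pixels are not) plus their mean-depth ratio; a ratio at
organelle copy-number levels (default support threshold 5) yields a
`supported` verdict. The built-in mapper is deliberately crude -- exact
21-mer seeds at three offsets, diagonal voting, ungapped verification
(mismatch fraction $\le$ 0.2, overlap $\ge$ 25 bp), one best placement per
read -- because depth estimation at desk scale tolerates it; production
runs can substitute an external mapper's profile.

## The synthetic world

`simulate_dataset()` draws uniform-composition random nuclear and organelle
sequences; paired fragments are sampled uniformly (the organelle circular,
so fragments wrap the origin) in numbers proportional to length x depth
with depth(organelle) = `copy_ratio` x `nuclear_depth`; substitution
errors are i.i.d.; qualities are constant Phred 35; optional NUMTs are
verbatim organelle copies pasted into the nuclear sequence -- the
worst-case, 100%-identity form of that contamination. Defaults state the
world the method assumes: nuclear 50 kb at 10x, organelle 16 kb, copy
ratio 20 (inside the 10--100 range), 100 bp reads, 300 +/- 30 bp inserts,
0.5% substitution error, no NUMTs unless requested.

What a green end-to-end test does establish: the depth model, threshold,
sketch, binning, assembly and circularity machinery compose correctly and
recover the planted genome exactly. What it does not establish: robustness
to indels, GC-biased coverage, platform error profiles, PCR duplicates
(which flatten the depth contrast the method depends on), real repeat
structure, or divergent NUMTs -- none of which the generator emulates.

## Numerical and degenerate-input choices

* All-zero depth profiles are an error instructing a manual threshold;
  empty read streams profile to zeros with a warning.
* Binning uses strict inequality ("greater than the threshold") at the
  boundary.
* Reads shorter than k contribute no windows and a maximum count of 0.
* Contig-length ties break to the lexicographically smaller sequence;
  modal-read-length ties break downward; both are documented, arbitrary,
  and fixed.
* The discard of a read during trimming is an outcome, not an error; a
  surviving mate is re-emitted unpaired rather than dropped, maximising
  recall of high-copy reads.
* Determinism: sketch hashes derive from a recorded seed; the assembler
  and mapper are seed-free and deterministic; the simulator restores the
  caller's RNG state.

## Known limitations

The built-in assembler and mapper are desk-scale stand-ins for the
external tools a production run would use (multi-k assemblers, `bwa mem`);
adapters for both are provided. Chloroplast-bearing samples bin plastid
and mitochondrial reads together -- selecting among the resulting contigs
is what the annotation hook is for. Repeats spanning the insert size,
multi-chromosome organelle genomes, and low-copy-number organisms remain
out of reach of the depth signal itself, and the control-region
hypervariability seen in real mitogenomes is neither simulated nor
corrected.
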