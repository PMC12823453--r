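---
title: "Control-normalized CLIP-seq analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-normalized CLIP-seq analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipfold)
```

## The problem

CLIP-seq (UV crosslinking and immunoprecipitation followed by sequencing)
maps where an RNA-binding protein contacts RNA: crosslinked fragments are
immunoprecipitated, sequenced and aligned, and the protein's "footprints"
appear as local excesses of read density. The raw density is not
interpretable on its own — library depth, RNA abundance and nonspecific
background all shape it — so every quantity this package computes is a
ratio against a matched negative control:

1. **rRNA enrichment track** (per-nucleotide resolution, one reference):
   IP coverage over 18S ribosomal RNA divided by the coverage of a
   *truncation control*, a construct lacking the ribosome-binding region,
   which captures nonspecific crosslinking. This is the track on which
   ribosomal expansion-segment footprints (ES7, bases 1117–1195; ES6b/c,
   bases 710–766) are read off against a twofold-enrichment line.
2. **Transcript-locus peaks**: per-transcript runs of positions enriched
   over a *knockout control* (cells without the tagged protein), with a
   one-sided Poisson test and Benjamini–Hochberg FDR.
3. **Metagene profile**: average signal over all transcripts on a
   standardized 300-position 5′UTR/CDS/3′UTR axis, again as a ratio to the
   knockout profile.

The package consumes deduplicated alignments (BED intervals or bedGraph
coverage); UMI extraction, trimming, alignment and deduplication are
upstream of its scope.

## Stage 1 — the rRNA enrichment track

For an IP track $x$ and control track $y$ over the same reference:

1. **RPM**: $x_i \mapsto x_i \cdot 10^6 / N$, with $N$ the sample's total
   deduplicated read count. The library size is a property of the whole
   sample, supplied via the manifest, not the on-reference read count.
2. **Mean scaling**: division by the regional mean, so both tracks have
   mean 1 over 18S. Note mean scaling makes stage 1 invariant to the RPM
   step; RPM is kept because the intermediate tracks are reported.
3. **Pseudocount**: the 0.1-percentile (type-7, linearly interpolated
   quantile) of the mean-scaled control is added to every control
   position. In sparse controls that percentile is exactly 0, which would
   defeat its divide-by-zero purpose, so the implementation falls back to
   the smallest strictly positive control value (or 1 for an all-zero
   control). A non-binding truncation construct yields little rRNA
   coverage, so the sparse regime is the realistic one.
4. **Fold**: $f_i = x_i / (y_i + pc)$.
5. **Low-signal mask**: positions jointly holding less than 3% of the
   cumulative IP coverage are identified by sorting positions by ascending
   coverage (ties by ascending position) and masking the maximal prefix
   whose cumulative sum stays strictly below 3% of the total; their fold
   is set to exactly 1. The mask is computed on the IP RPM track: the IP
   sample is the signal being plotted, and masking it removes the
   positions whose ratio is pure noise.
6. **Smoothing**: centered rolling average, window 10. For even windows
   the window covers $[i-\lceil w/2\rceil+1,\, i+\lfloor w/2\rfloor]$; at
   the track ends it shrinks to the available positions. Masking happens
   before smoothing; smoothing is presentation-layer, and the per-region
   summary reports unsmoothed maxima and means alongside smoothed ones.

With replicates, the fold track is computed per replicate and then
averaged (`average_enrichment()`); a position counts as masked in the
average only when masked in every replicate.

## Stage 2 — peak calling

Transcript loci are handled one canonical transcript at a time, without
mean scaling (transcript abundances differ; the knockout ratio absorbs
them):

- $f_i = \mathrm{IP\ RPM}_i / (\mathrm{KO\ RPM}_i + 5)$, with the global
  pseudocount 5; the same 3%-cumulative filter, applied per locus on IP
  RPM, forces masked positions to fold 1.
- Candidate peaks are maximal runs of consecutive positions with
  $f_i > 2$ (strict), kept when the run is longer than 20 nt (≥ 21) and
  its mean per-position IP RPM strictly exceeds 10. "More than twofold
  over a window of more than 20" is read as contiguous qualifying runs,
  the simplest deterministic reading; all three thresholds are strict
  boundaries and are tested as such.
- Significance: the observed statistic is the number of IP **reads**
  overlapping the run (not the coverage sum — summing coverage
  over-disperses a Poisson by roughly the read length; a coverage-sum
  mode is available behind `count_mode = "coverage"` for comparison). The
  expectation is
  $\lambda = (k_{KO} + 5)\cdot N_{IP}/N_{KO}$, the knockout read count
  over the run, pseudocounted and scaled by the library ratio. The
  one-sided upper tail $P(X \ge k)$ of $\mathrm{Poisson}(\lambda)$ gives
  the p-value; Benjamini–Hochberg adjustment runs across all candidate
  peaks of a condition (the conservative, standard choice of test set),
  and peaks are reported at $q < 0.05$.

"Average RPM above 10" is interpreted as the mean per-position IP RPM
over the run (not the run total), the stricter and scale-free reading.

## Stage 3 — the metagene

Canonical transcripts with CDS ≥ 300 nt are retained (two canonical
transcripts for one gene is a hard error). Per transcript, the 5′UTR, CDS
and 3′UTR coverage segments are each rescaled to 100 positions by
sampling 100 evenly spaced points over $[0, L-1]$ with linear
interpolation (identity when $L = 100$; broadcast when $L = 1$; an empty
UTR yields zeros with a warning, an empty CDS is an error). The three
segments concatenate to a 300-bin axis with half-open region boundaries
$[0,100)$, $[100,200)$, $[200,300)$. Transcripts are averaged
unweighted — the fixed-length alignment across genes implies equal
weight, and no expression weighting is applied. The condition profile is
divided bin-wise by the knockout profile plus a pseudocount (the same
0.1-percentile rule as stage 1, reused for a consistent divide-by-zero
policy) and smoothed with window 5.

## The synthetic-data generator

Every stage is verified against planted truth, so the generator is
first-class, tested code. It emulates the statistical structure of the
study design: a flat background read-start rate over an 18S-length
(1869 nt) reference, multiplicative footprint enrichment of IP samples in
the footprint's conditions, library-size differences between samples, and
flat truncation/knockout backgrounds that never carry enrichment.

Choices, made once:

- **Multinomial allocation**: each sample's library size is allocated
  exactly over positions proportional to the per-position rates, rather
  than drawing independent Poisson counts. Library sizes are then exact,
  which makes RPM normalization exactly invertible in tests.
- **Reads**: single-end, plus strand, fixed 20 nt by default — a typical
  RNase-trimmed CLIP footprint length — clipped at the reference end.
  Coverage uses full-read-span depth semantics, so a planted footprint's
  *coverage* contrast is slightly edge-diluted relative to its
  *start-rate* fold (by about $(\mathrm{fold}-1)(\ell-1)/2W$ at width
  $W$ and read length $\ell$); the tests therefore validate coverage
  against the exact expected-coverage convolution of the truth rates, and
  start rates against the planted fold directly.
- **Default design** (`default_rrna_config()`): IP libraries of $10^5$
  reads on the rRNA reference; truncation/knockout libraries of 800
  reads, reflecting that a non-ribosome-binding construct contributes
  only sparse rRNA coverage — the regime in which the 0.1-percentile
  pseudocount is small relative to typical control values. Footprints:
  ES7 (1117–1195) at threefold in both conditions; ES6b/c (710–766) at
  threefold only under treatment, mirroring the collision-specific
  contact.
- **Transcript loci**: one canonical transcript per gene with 5′UTR, CDS
  and 3′UTR lengths sampled from typical human mRNA ranges (60–180,
  450–1200 in multiples of 3, 100–300 nt); optional non-canonical decoys
  duplicate the canonical models and must vanish from all downstream
  output. Planted transcript footprints default to 40 nt centered in the
  CDS.

What the generator does **not** emulate: sequence content (no FASTQ, no
crosslink-site nucleotide bias), position-specific background structure
(real rRNA background is highly non-uniform from RNase accessibility),
UMI duplication (outputs represent post-dedup reads), paired ends, and
minus-strand bookkeeping. Passing tests therefore demonstrate that the
*computation* is correct under the stated statistical model, not that the
model captures every feature of real libraries.

## Numerical conventions and degenerate inputs

- Internal coordinates are 0-based half-open (BED convention); all
  user-facing rRNA and peak coordinates are 1-based inclusive. The
  conversion lives at the IO boundary.
- Quantiles are type 7 (linear interpolation), R's default.
- Ties in the low-signal sort are broken by ascending position, and the
  cumulative criterion is a strict inequality, so the mask is fully
  deterministic; on a constant track of length 100 with fraction 0.03,
  exactly two positions are masked.
- Even smoothing windows are left-heavy as defined above; a fixed
  convention is required for bit-reproducibility.
- Degenerate inputs fail loudly: empty libraries, all-zero tracks under
  mean scaling, length mismatches, footprints outside the reference,
  zero-length CDS, duplicate canonical transcripts and non-positive
  parameters are all named errors.
- Determinism: a `sim_config` seed fully determines the generator's
  output (asserted byte-wise on the BED files), and the end-to-end
  pipeline rerun with the same configuration is byte-identical.

## Problem sizes used in the checks

The bundled verification runs are scaled-down reconstructions chosen to
estimate each property stably: 10–20 seeds for the rRNA footprint
recovery and metagene localization, 50–100 seeds of 4-gene null
experiments for the false-positive rate, and 20 seeds of 6-gene
experiments (libraries of $2\times10^5$) for planted-peak recovery. At
these sizes the planted-peak Jaccard concentrates near its analytic
expectation of $(W - \lceil \ell/3\rceil + 1)/(W + \ell -
\lceil \ell/3\rceil)$ ≈ 0.64 for $W = 40$, $\ell = 20$ — the footprint is
recovered, with boundaries blurred by read length, which is the expected
behaviour of depth-semantics coverage, not an estimation error.

## Known limitations

- The Poisson model treats reads as independent; biological replicates
  and crosslink hotspots over-disperse real data, so genome-wide q-values
  on real libraries are anti-conservative to an unknown degree. The
  null-rate guarantee verified here holds under the generator's model.
- The truncation-control pseudocount couples the enrichment scale to
  control sparsity: with a deep, uniform control the 0.1-percentile
  approaches the control mean and all folds compress toward half their
  sparse-control values. Interpret absolute fold values only together
  with the control's coverage distribution.
- Minus-strand transcripts must be reversed to 5′→3′ before entering the
  metagene; the package does not do genome-coordinate arithmetic.
- BAM input is not part of the contract; convert to BED/bedGraph
  upstream.
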