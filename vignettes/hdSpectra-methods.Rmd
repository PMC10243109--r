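---
title: "Clustering tandem mass spectra in hyperdimensional space"
author: "hdSpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering tandem mass spectra in hyperdimensional space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdSpectra)
```

## The problem

Large proteomics and metabolomics experiments acquire millions of MS/MS
spectra, many of which are repeated measurements of the same peptide or
metabolite. Grouping near-identical spectra before database searching
reduces redundancy and improves identification throughput. The obstacle is
scale: all-pairs similarity over n spectra is quadratic, and spectra are
high-dimensional, noisy peak lists.

hdSpectra attacks both axes. Spectra are first reduced to a compact,
fixed-size representation — a D-bit binary hypervector — on which
similarity is a popcount-and-divide; and the all-pairs computation is
confined to precursor-mass buckets, inside which spectra could plausibly be
the same analyte.

## The procedure

**1. Preprocessing.** Per spectrum, peaks within ±1.5 Da of the precursor
m/z and peaks below 1% of the base-peak intensity are removed; spectra with
fewer than 5 surviving peaks or under a 250 Da m/z span are rejected; at
most the 50 highest-intensity peaks are retained and intensities are
L2-normalized. The intensity filter runs after precursor/range removal so
the base peak is always a surviving peak — the alternative order is
ambiguous in the literature and this one is stricter and deterministic.
Rejection is a tagged result with exactly one first-failing reason, so
pipeline summaries can account for every input spectrum.

**2. Bucket division.** Each spectrum maps to the integer
`floor(z * (m/z − 1.00794) / 1.0005079)`: charge-scaled neutral mass over
the 1.0005079 Da spacing between centers of adjacent clusters of physically
possible peptide masses. We floor rather than round (the convention is not
universal); flooring makes buckets left-closed intervals of width
1.0005079 Da in neutral-mass space, and a `rounding = "round"` switch
exists for sensitivity checks. Charges are bucketed separately by default.
Spectra falling just across a bucket boundary are accepted losses — there
is deliberately no cross-bucket neighbor search.

**3. Hyperdimensional encoding.** The preprocessed peaks are quantized to
(m/z-bin, intensity-level) pairs on a grid of `f = ceiling((maxMz −
minMz)/binSize)` bins (defaults 101–1500 Da at 0.05 Da, so f = 27980) and
Q = 16 levels via `level = min(Q, max(1, ceiling(intensity * Q)))` — a
monotone mapping surjective onto [1, Q]; a square-root or other scaling can
be substituted by transforming intensities first. When two peaks collide in
a bin the higher-intensity peak wins, so each bin contributes one pair.

Two codebooks translate pairs into D-bit vectors: f ID hypervectors and Q
level hypervectors, generated iteratively — a uniform random first row,
each next row flipping a fixed number of uniformly chosen bits of its
predecessor. Nearby bins (levels) therefore get similar hypervectors while
distant ones approach the ~D/2 distance of unrelated random vectors. The
default flip counts are `max(1, round(D/(2f)))` and `max(1, round(D/(2Q)))`,
chosen so the ends of each codebook approach orthogonality — the standard
locality-preserving design; both are configurable. Each peak binds its ID
and level vector by XOR, and the pointwise majority over all bound vectors
is the spectrum hypervector. Majority votes can tie at even peak counts; a
tie-break hypervector drawn from the same seeded stream supplies those
bits, keeping the encoding deterministic and unbiased (equivalently, the
tie vector is appended once to every bundle). One seed governs codebooks
and tie-break vector, and the whole pipeline is bit-reproducible from it:
flip positions are sampled without replacement per step from the seeded
generator, and bits map to packed words as position p → word p/32, bit
p mod 32 (little-endian within word) — file-level bit-exactness depends on
this convention.

**4. Distance computation.** Hypervectors are stored bit-packed, 32 bits
per word (`ceiling(D/32)` words; exactly 1/8 the bytes of byte-per-bit
storage), and the normalized Hamming distance `popcount(a XOR b)/D` costs
`ceiling(D/32)` word operations per pair. Per bucket this yields a
condensed n(n−1)/2 distance vector, returned as a `stats::dist` object.

**5. Clustering.** Two algorithms per bucket, both deterministic and
order-invariant up to relabeling:

* *hierarchical* (default): complete-linkage agglomeration cut at height
  eps, which guarantees every cluster's maximum intra-cluster distance
  ≤ eps; resulting singletons are relabeled −1 so "clustered" means the
  same thing under both algorithms.
* *dbscan*: density clustering on the precomputed matrix with radius eps
  and minimum neighborhood size 2 (the smallest value letting a pair form
  a cluster; with it, clusters are the connected components of the ≤ eps
  graph and noise the isolated points). Points are scanned in ascending
  ordinal order so border assignment is reproducible.

Per-bucket labels are offset to global uniqueness. The default threshold
eps = 0.25 with D = 2048 and Q = 16 is the typical operating point; useful
thresholds span roughly 0.2–0.45. A medoid representative (member
minimizing summed distance to the rest, ties to the lowest ordinal) stands
in for consensus-spectrum construction, which is out of scope.

## Quality metrics

With a peptide-label table, three metrics summarize a clustering:

* **clustered spectra ratio** — spectra in clusters of size ≥ 2 over all
  input spectra (rejected ones included in the denominator);
* **incorrect clustering ratio** — clustered-and-identified spectra whose
  label deviates from their cluster's most frequent label, over all
  clustered-and-identified spectra (tie choices do not change the count);
* **completeness** — `1 − H(C|P)/H(C)` in nats (the base cancels) from
  empirical joint counts over clustered-and-identified spectra; 1 when
  each peptide occupies a single cluster, and 1 by convention when
  H(C) = 0. Unlabeled spectra are excluded from the label-dependent
  metrics but not from the clustered ratio, matching the
  "clustered and identified" denominator definition.

A caution discovered while testing: "splitting clusters never increases
completeness" is *not* a theorem — splitting a label-mixed cluster can
raise H(C) faster than H(C|P). It does hold for splits of label-pure
clusters (both entropies rise by the same amount), and that restricted
property is what the test suite asserts, alongside equality with a
brute-force entropy computation.

## The synthetic-data generator

Real benchmark corpora run to tens of millions of spectra; the package
instead ships a seeded generator of labeled MGF datasets with planted
structure. Each template (one synthetic peptide) has uniform-random peak
m/z, log-normal intensities (meanlog 0, sdlog 1 — right-skewed like real
fragment intensities), a precursor uniform in 400–1200 Da (a typical
tryptic 2+/3+ window) and charge 2 or 3. Replicates perturb the template
with Gaussian m/z jitter (SD 0.01 Da), multiplicative log-normal intensity
noise (CV 0.2), 10% peak dropout, 0–5 spurious peaks (log-normal
intensities damped ×0.5), and precursor jitter (SD 0.001 Da) — small
against the 1.0005079/z bucket width, so replicates co-bucket except for
the rare template sitting at a boundary; widening the jitter deliberately
exercises that loss mode.

What the generator does *not* emulate: physically realistic fragmentation
(b/y ion series, isotopes, neutral losses), chimeric spectra, and
peptide-similarity structure between templates (templates are mutually
random, hence easier to separate than co-eluting near-isobaric peptides).
Passing the recovery tests therefore demonstrates the pipeline's mechanics
— bucketing, encoding locality, distance computation and clustering — not
identification-grade performance on real data.

## Numerical choices and problem sizes

* Bin boundary and level mapping use `floor`/`ceiling` with clamping to
  [0, f−1] and [1, Q]; intensity exactly at the 1% filter threshold is
  kept (strictly-below is removed).
* Top-peak selection breaks intensity ties toward lower m/z; bin
  collisions keep the higher-intensity peak.
* Buckets of size 0–1 skip distance computation; their members are −1.
* The recovery checks run 100 templates × 20 replicates (2000 spectra) at
  D = 2048 — a few seconds end to end — and the dimension-trend check
  repeats the run at D = 128, where the coarser codebook geometry measurably
  degrades completeness. Analytic and oracle checks use D ∈ {32 … 2048}
  and buckets of n ≤ 50 where brute force is exact.

## Worked example

```{r example}
p <- fixtureParams(nTemplates = 10L, replicatesPerTemplate = 5L, seed = 7L)
mgf <- tempfile(fileext = ".mgf"); lab <- tempfile(fileext = ".tsv")
generateDataset(generateTemplates(p), p, mgf, lab)

cfg <- pipelineConfig(input = mgf, labels = lab, D = 512L, seed = 3L)
res <- runPipeline(cfg)
res$summary
unlist(res$metrics[c("clustered_ratio", "incorrect_ratio", "completeness")])
```

## Known limitations

* No cross-bucket neighbor search: near-boundary analytes can split.
* The MGF reader targets the two dominant dialects (`CHARGE=2+`/`CHARGE=2`,
  first `PEPMASS` number); exotic dialects are skipped-and-counted.
* Identifiers must be unique across the input for label joining and
  input-order restoration.
* The medoid representative is a stand-in, not a consensus spectrum.
* All computation is CPU; the batch encoder defines the batching contract
  (bit-identical to the scalar path) rather than exploiting accelerators.
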