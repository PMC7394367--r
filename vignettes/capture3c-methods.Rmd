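---
title: "capture3c: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capture3c: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capture3c)
```

This vignette is the package's own account of its science: the
statistical model and its assumptions, the tunable parameters with
their defaults and units, what the synthetic-data generator emulates
(and deliberately does not), the numerical choices, and the design
decisions taken where the design was genuinely open. No empirical claim
is made here that the test suite or the acceptance script does not
itself compute.

## 1. The measurement and its noise structure

A capture 3C library anchors every informative read pair at one chosen
locus: the **bait region**, the genomic footprint of a biotinylated
dCas9/sgRNA complex. A paired-end tag (PET) whose two ends map to two
different loci is evidence that those loci were ligated, i.e. spatially
proximal. Three PET populations coexist:

* **self-ligated** PETs (both ends in the bait) — typically the vast
  bulk of a well-targeted library; they certify capture efficiency but
  carry no interaction information and are discarded from calling;
* **bait contacts** (exactly one end in the bait) — the signal,
  split into cis (same chromosome) and trans;
* **background** PETs (neither end in the bait) — random ligation
  and off-target capture; these are precisely the observations the
  noise models are fitted on.

Cis noise decays with genomic distance (polymer physics), so the model
is distance-stratified; trans noise depends on which chromosome pair
shares nuclear territory, so it is stratified by chromosome.

## 2. Read processing

* **DpnII rescue** (`trim_at_dpnii`): ligation junctions contain the
  DpnII site `GATC`, so an unmapped read can be a chimera of two loci.
  The read is split at the start of every `GATC`; the longest fragment
  is kept when strictly longer than `min_fragment = 20` bp. Because
  DpnII cuts 5′ of `GATC`, downstream fragments keep the motif at their
  5′ end (`keep_site = TRUE`; the drop-site variant is available). When
  several fragments exceed the threshold only the longest is remapped —
  the conservative reading of the protocol; remapping both is a
  documented alternative we did not take, since it risks counting one
  molecule twice.
* **MAPQ filter** (`filter_mapq`): strictly greater than 30, applied
  per end after merging original and rescued alignments. This is the
  sole multi-mapping control; only primary alignments are read at all.
* **Pairing and deduplication**: mates are joined on read id (mate
  suffixes stripped); PETs sharing both end positions *and strands* are
  PCR duplicates and collapse to one representative. Strand inclusion
  is the package's choice — the narrower position-only key is available
  (`use_strand = FALSE`) but collapses genuinely distinct molecules on
  opposite strands. Output is sorted by the duplicate key, making the
  stage deterministic and order-free.

## 3. Bait definition

The bait interval is computed from the read-depth signal itself
(`define_bait`), with an external peak BED accepted as an override
(`bait_from_bed`); peak callers such as MACS2 are never run here.

Parameters (units bp): local background window `window = 100000`,
centred on the sgRNA target site — "surrounding region" is ambiguous
between centred and per-side flanks; we centre one 100 kb total window
and expose the width. Smoothing half-window `halfwin = 50` (a 101-base
mean). Extension proceeds outward from the target site over positions
whose smoothed depth is **strictly** greater than the background mean,
stopping per direction at the first failure (`gap = 0`; a gap allowance
is exposed but off by default, as no stopping rule for gaps is part of
the published procedure). Two guards are package additions: a
`max_extent = 20000` cap per direction, because an unbounded bait
breaks the binning model, and a fixed `fallback_size = 2000` bin
centred on the target when no enrichment is found — 2 kb echoing the
fixed bins of earlier capture assays. The bait depth itself is included
in the background mean (the literal reading); excluding it would raise
sensitivity slightly.

The realized bait width carries an intrinsic uncertainty of up to
`halfwin` bases per edge: smoothing drags the depth shoulder outward,
so a rectangular peak of width *w* is recovered within about
`2*(halfwin + 1)` of *w* (this is asserted, against a brute-force
smoothed-track scan, in the test suite).

## 4. Binning and classification

The bait chromosome is tiled from coordinate 0 in steps of the bait
width `l`; the bait replaces the tiles it overlaps and the clipped
remainders stay as partial bins. Anchoring at 0 rather than at the bait
is a reproducibility choice (any phase is equally defensible; 0 matches
common practice). The distance multiplier of a bin is
`d = round(|bin centre − bait centre| / l)`, floored at 1;
bait-adjacent partial bins get `d = 1`. Other chromosomes are tiled at
1 Mb. Bait membership of a read is its stored 5′ mapped position inside
the half-open bait interval (span overlap is available via
`overlap = TRUE`).

## 5. Background models

For each stratum the package samples `n = 10000` bin pairs uniformly
(without replacement when enough candidates exist, with replacement
otherwise), counts linking background PETs, and fits the negative
binomial in the parameterization

$$P(X = x) = \binom{x + r - 1}{x}(1-p)^r p^x,$$

whose variance/mean ratio is $1/(1-p) > 1$ — the overdispersion
identity asserted throughout the tests. This maps onto R's
`dnbinom(x, size = r, prob = 1 - p)`; the conversion happens in exactly
one place (`nb_pmf`/`nb_cdf`), all other code speaks (r, p).

**Fitting** (`fit_nb`): for fixed *r* the likelihood is maximized in
closed form by `p = S/(nr + S)` (S the count sum), so the MLE is a 1-D
profile optimization over log *r* (golden-section, tolerance 1e-8 on
the log-likelihood, bracketed four decades around the method-of-moments
start). Samples with variance ≤ mean return a **Poisson fallback** —
the p → 0 limit of the family — rather than failing, because sparse
background strata frequently show var ≈ mean; all-zero samples return a
**degenerate** model under which any positive count has left-tail
probability 1, flagged loudly since it usually means the background was
under-sampled. Strata with fewer than `min_obs = 30` observations fall
back to the pooled model.

**Stratification**: one model per `d` with `d·l ≤ 20000` bp
(inclusive — the boundary distance gets its own model), one pooled
model beyond, built by drawing the far distance uniformly and then a
pair at that distance. One model per partner chromosome for trans
contacts on the 1 Mb grid, excluding the bait-containing 1 Mb bin.
Sampled backgrounds are cached with their seed via JSON serialization
(`background_to_json`), not resampled per calling run. The construction
is a set of stratified NB fits; no mixture weights exist in the
published description despite the "mixture" name, and none are
implemented.

## 6. Significance

The left-tail statistic `p_left = P(X_d < x_d)` is **inverted relative
to convention** — larger means more significant. It is preserved
verbatim, and the conventional survival probability
`p_survival = P(X_d ≥ x_d)` is always reported alongside (computed from
the upper tail directly, so the pair sums to 1 within 1e-12 and the
deep tail keeps precision).

The published decision statistic is a Bayes factor with prior odds
P(H1)/P(H0) = 0.001 and a high-confidence threshold of BF > 20, but the
likelihood construction behind the BF is not specified (and the stated
hypothesis labels conflict with the prior-odds rationale). The package
therefore defines, in one swappable function:

$$\mathrm{BF} = 0.001 \cdot \frac{p_\mathrm{left}}{1 - p_\mathrm{left}}$$

using only quantities the model defines. The algebra makes BF > 20
equivalent to `p_survival < 1/20001 ≈ 5e-5`, a stringent tail criterion
consistent with "high confidence" and with only a couple of calls
passing in a typical sparse library. `p_left = 1` maps to a sentinel of
1e12 rather than infinity. No multiple-testing correction is applied by
default (the BF threshold is itself the error control); bins with zero
PETs are never evaluated (`min_count = 1`), and the bait bin is never
called. Calls against a degenerate background are maximally significant
by construction — the loud warning at fit time is the guard.

## 7. What the simulator emulates — and what it does not

`simulate_pets` draws, under one mandatory seed:

* a 3 × 10 Mb genome with a 2.5 kb bait at the centre of chr1 (the
  default bait start is a multiple of the width, so the bait is its own
  tiling bin; unaligned baits are exercised through the
  heuristic-defined bait in the end-to-end tests);
* a self-ligated bulk sized to a 11,692-PET bait library at 98.5%
  self-ligation — the composition a well-targeted real library shows;
* cis bin-pair noise NB(r_d, p) with `variance/mean = 1.5`
  (p = 1/3) and geometrically decaying means
  `mu_d = 3 · 0.5^(d-1)` per pair, floored at a flat far noise
  of `lambda_far = 0.001` per pair beyond 20 kb. The geometric decay
  runs *into* the flat floor, so noise really is flat past the cutoff —
  which is exactly the assumption the pooled far model rests on; a hard
  cliff at 20 kb would be both unrealistic and unfair to any bait whose
  realized width shifts the stratum boundary by a few percent;
* trans noise at `lambda_inter = 2` PETs per 1 Mb bin pair (Poisson;
  per-chromosome rates accepted as a named vector);
* bait-anchored noise drawn from the *same* truth per bin — the exact
  null hypothesis of the caller, which is what makes the
  false-positive-rate criterion an algebraic consequence of the BF
  threshold rather than a tuning outcome;
* optional spiked true interactions as (anchor, extra count) with the
  PETs clustered within ±50 bp of the anchor (loop anchors are sharp;
  clustering also keeps a spike from being halved by an arbitrary bin
  boundary, which at 10× strength would sit exactly at the detection
  edge);
* PCR duplicates at 10% of records, two-point MAPQ {42: 90%, 10: 10%}
  per end to exercise the strict filter, and 2% chimeric mate-2 reads
  built as `fragment + GATC + fragment` with the longer, GATC-leading
  fragment's true coordinates recorded, so the rescue path is testable
  without an aligner.

In `"fractions"` mode the self/cis/trans totals are multinomial at
(0.985, 0.010, 0.005) and cis PETs follow an empirical placement
profile (81% within ±1 Mb, 2:1 downstream) — used to emulate published
library composition for QC tests, not for calibration.

Not emulated, hence outside what a green test establishes: sequence
content (GC, mappability), ligation biochemistry, off-target dCas9
binding structure, genome-scale chromosome counts, base qualities, and
any biology of specific loci. Background noise is generated on the bait
chromosome only (the caller never consults background PETs elsewhere).
A passing end-to-end test certifies the statistical machinery on data
that satisfies the model's assumptions; it says nothing about model
adequacy on real chromatin.

## 8. Numerical and determinism choices

* Coordinates are 0-based half-open everywhere; SAM's 1-based POS is
  converted at ingest and nowhere else.
* All sampling takes explicit seeds; sub-seeds are derived
  arithmetically (kept below 2³¹) so one master seed fixes the whole
  run, and `with_seed` restores the caller's RNG state.
* Tail probabilities use the stats distribution functions (log-space
  accumulation); the test oracles recompute them by explicit
  `lchoose`-based summation to 1e-9.
* Ties in DpnII fragment length resolve to the 5′-most fragment;
  `which.max` supplies that deterministically.
* Duplicate removal keeps the first record per key and sorts output by
  key, so results are independent of input order.
* The WashU longrange score is the BF rounded to two decimals with a
  single trailing zero dropped ("25.0"), matching browser convention.

## 9. Known limitations

* The pooled far-cis model assumes flat noise beyond 20 kb; if real
  noise still decays there, bins just past the cutoff are evaluated
  against a slightly too-cold background (anti-conservative). The
  per-stratum range can be widened via `D_max`.
* Bait-edge estimation error of up to ~50 bp per side lets a sliver of
  self-ligated mass leak into the flanking partial bin, which can
  surface as a spurious `d = 1` call; inspect calls overlapping the
  bait's immediate flanks. The simulator's scorer excludes
  true-bait-overlapping bins for exactly this reason.
* One bait per run; multi-bait designs are processed independently, and
  bait-to-bait contact matrices are out of scope.
* Replicate merging is supported before pairing (merge-before-dedup,
  the default reading) — merging after dedup is possible by
  concatenating PET tables but double-counts duplicates shared between
  replicates.
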