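---
title: "Quantifying piRNA ping-pong activity in small RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying piRNA ping-pong activity in small RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pingpongr)
library(dplyr)
```

## The biological question and the statistic

In the *Drosophila* germline, piRNAs silence transposable elements (TEs).
Primary piRNAs antisense to a TE guide cleavage of the TE mRNA; cleavage
products become secondary, sense-oriented piRNAs, which in turn guide
cleavage of precursors to regenerate antisense piRNAs. This reciprocal
"ping-pong" amplification leaves a precise sequence fingerprint: sense and
antisense piRNA pairs whose 5' ends overlap by exactly 10 nt, with the
antisense partner biased toward a 5' uridine (1U) and the sense partner
toward an adenine at position 10 (10A).

`pingpongr` quantifies this fingerprint in small RNA sequencing libraries.
For a transposon \(f\), let \(S_f(x)\) and \(A_f(x)\) be the aligned read
weight whose biological 5' end sits at plus-strand position \(x\) in sense
and antisense orientation. The overlap histogram is

\[ H_f(o) \;=\; \sum_x S_f(x)\, A_f(x + o - 1), \qquad o = 1, \dots, o_{max}, \]

so an exact ping-pong duplex contributes to bin \(o = 10\). A (sense,
antisense) pair *qualifies* when the overlap is exactly 10 **and** the
sense read carries A at its 10th position **or** the antisense read starts
with U (the condition is a literal OR; both base checks are made on the
read's own sequence, not the reference, since the signature is a property
of the piRNA molecule). The per-transposon ping-pong ratio is

\[ r_f \;=\; \frac{\text{weight of piRNA reads participating in} \ge 1
\text{ qualifying pair}}{\text{total piRNA weight on } f}. \]

Because numerator and denominator scale identically with sequencing depth,
\(r_f\) needs no library-size normalisation; this invariance is exercised
directly by the test suite (duplicating every read leaves every \(r_f\)
unchanged bit-for-bit).

Two readings of the numerator are defensible — reads participating in at
least one qualifying pair, or the (weighted) number of qualifying pairs
itself. The package counts *reads* by default, which bounds the ratio by 1;
`numerator = "pairs"` selects the alternative. Likewise the denominator is
per-transposon by default (ratios are reported per transposon) with
`scope = "library"` as the alternative.

## Pipeline structure

Stages run in a fixed order, mirroring standard small RNA practice:

1. **Adapter clipping** (`clip_adapter()`): truncate at the leftmost exact
   occurrence of the first `min_match = 8` adapter bases; discard inserts
   shorter than `min_insert = 18` nt. Both defaults are ordinary small-RNA
   choices and are plain arguments, since adapter chemistry varies between
   protocols.
2. **Depletion** (`deplete_matching()`): reads that align end-to-end, on
   either strand, with at most 1 substitution to any rRNA or miRNA-hairpin
   reference are removed. Hairpin-depleted reads are counted: that total is
   the between-library normaliser, chosen because miRNA abundance is
   independent of the piRNA pathway.
3. **Length classification** (`classify_by_length()`): 23–29 nt reads are
   piRNAs, 20–22 nt are siRNAs, everything else `other`. Only piRNA-class
   reads enter the ping-pong analysis.
4. **Alignment** (`align_reads()`): every end-to-end placement on the
   transposon / piRNA-cluster / gene references with at most 1 substitution
   is found by exhaustive scan (compiled kernel); only placements at the
   read's minimum mismatch count are kept (best stratum), emulating short
   ungapped alignment without heuristics. Coordinates are 0-based; an
   antisense read's biological 5' end is `start + length - 1`, which makes
   the overlap a single subtraction.
5. **Multi-mapper weighting**: `fractional` (default) spreads weight 1/k
   over the k best placements, the closest simple analogue of
   EM-style apportioning; `unique_only` is retained for sensitivity
   analysis. On uniquely-mapping data the two policies coincide (tested).
6. **Quantification** (`count_by_feature()`, `class_summary()`,
   `density_profile()`): weighted sense/antisense counts per feature, with
   two normalisers carried side by side and never mixed silently —
   miRNA-hairpin reads per million for per-feature abundance and density
   tracks, total library reads for per-class summaries. Density tracks
   default to full-read coverage (`mode = "five_prime"` gives 5'-end
   counts); coverage was chosen as the default because it admits a strict
   conservation check (track sum = Σ weight × read length).
7. **Ping-pong** (`pingpong_stats()`) and **differential**
   (`differential_abundance()`, `class_differential()`,
   `compare_ratios()`).

## The differential battery

Per-feature differential abundance deliberately replaces a negative-
binomial count model with a transparent test battery on hairpin-normalised
abundances: pseudocounted log2 fold change (pseudocount 1.0 handles
zero-count TEs), an equal-variance Student's t on
log2(abundance + pseudocount) across replicates (Welch via
`var_equal = FALSE`), Benjamini–Hochberg adjustment, and calls at
fold > 1.5 and FDR < 0.1 (both plain arguments; stricter FDR conventions
such as 0.01 are a configuration choice, not a constant). A global Wilcoxon
signed-rank test over per-feature log2 fold changes summarises direction.

The signed-rank test is implemented exactly for n ≤ 25 by convolving the
sign distribution over (mid-)ranks — zeros dropped, ties mid-ranked — and
by normal approximation with continuity and tie correction above; the test
suite checks it against literal 2^n sign enumeration and against
`stats::wilcox.test` where the latter is exact.

## What the synthetic generator emulates

`generate_reference_set()` + `simulate_library()` produce libraries whose
statistical structure matches what the analysis assumes, with full
ground-truth bookkeeping:

* a read-class mixture over TE/cluster piRNAs (23–29 nt), endo-siRNAs
  (20–22 nt, placed on genes), miRNA-hairpin fragments and rRNA fragments.
  Defaults (`te_piRNA` 0.35, `siRNA` 0.15, `miRNA_hairpin` 0.40, `rRNA`
  0.10; 30% of the piRNA stream from clusters) describe a testis-like
  library in which hairpin reads are plentiful enough to be a stable
  normaliser;
* the 1U bias of antisense (primary) piRNAs: the first base is U with
  probability `u1_bias` (default 0.8, a typical observed 5'U fraction) and
  otherwise uniform over A/C/G, so the emitted U fraction equals the
  parameter exactly and can be recovered from the 5' profile;
* ping-pong pairs: a fraction `pingpong_fraction` (default 0.4) of
  transposon piRNA reads is emitted in (sense, antisense) pairs with 5'
  ends exactly 10 nt apart, the sense 10th base forced to A with
  probability `a10_bias` (default 0.7) and the antisense first base to U
  with probability `u1_bias`;
* discrete 5' start sites. Real piRNA 5' ends are discrete and highly
  reproducible, and ping-pong activity concentrates at a modest number of
  dominant loci per transposon. The generator therefore draws 5' ends from
  per-feature site pools: a small pool of ping-pong duplex hotspots
  (12 per TE) and larger background sense/antisense pools (30 per kb per
  strand) constructed so background sites never sit at an exact 10-nt
  offset. Two consequences matter for validation: (i) background reads
  cannot create accidental qualifying pairs, and (ii) at realistic depth
  each hotspot hosts several pairs, so a pair whose own bases miss the
  10A/1U condition is almost surely rescued by a co-located partner — the
  qualifying fraction, and hence the ratio, is then insensitive to depth,
  which is exactly the property that makes the ratio comparable across
  libraries without size normalisation. A `position_model = "uniform"`
  mode places 5' ends uniformly instead and is used for null calibration
  of the overlap histogram;
* two-condition replicate designs (`simulate_condition_pair()`): condition
  B rescales the expected transposon (and optionally cluster / siRNA)
  stream by per-class fold factors while holding the absolute hairpin and
  rRNA emission fixed; replicate seeds derive deterministically from the
  root seed (`seed + i` for A, `seed + n_replicates + i` for B), so truth
  tables are reproducible.

Ground truth records every emission (feature, orientation, true start, 5'
position, pair membership) and, per feature, the *definitional* qualifying
read count computed from the emitted positions and sequences. With
error-free reads the full pipeline recovers these counts exactly — any
discrepancy would indicate an alignment or pairing defect, and the
equality is asserted at n = 20,000 reads in the tests.

What the generator does **not** emulate: sequencing errors beyond an
optional uniform substitution rate (default 0), adapter chemistry beyond
an optional fixed 3' adapter, kinetic models of the amplification cycle,
genomic multi-mapping between near-identical TE families, and biological
overdispersion between replicates beyond multinomial sampling. Passing
tests therefore demonstrate correctness of the computation on data that
satisfies the stated assumptions, not robustness to artefacts of real
libraries — in particular, replicate variance in real data is larger, so
real-data power will be lower than in the recovery tests.

## Numerical and edge-case choices

* DNA alphabet internally; U is converted to T on input and reported as U
  in base-identity outputs.
* Depletion and alignment are substitution-only and end-to-end (no
  indels), appropriate for 20–30-mers at ≤1 mismatch.
* A read shorter than 10 nt can never satisfy a sense-role base check; such
  reads are excluded from pairing with a warning (they cannot be
  piRNA-class anyway).
* `ratio = 0` when a feature has zero piRNA weight or lacks one
  orientation; an empty depletion set warns and flags the library
  unnormalizable (hairpin total 0 raises an explicit error at
  normalisation time).
* Ties in the alignment best stratum are all reported; determinism is
  end-to-end (fixed seeds, no hash-order dependence), and re-running a
  pipeline config reproduces byte-identical tables.

## Problem sizes used by the validation suite

The tests and the acceptance script size their simulations to be decisive
yet desk-scale: brute-force cross-checks on 50 libraries of ≤500 reads
against 3 transposons; exact truth recovery at 20,000 reads against the
default reference set (8 TEs of 1.5 kb, 3 clusters, 3 genes, 10 hairpins,
1 rRNA decoy); fold-change recovery at 50,000 reads × 3 replicates × 2
conditions; null calibration over 20 seeds (overlap histogram) and 25–50
seeds (differential call rate at all-unit folds); and ratio-stability
under threefold upregulation over 20 seeds at 3,000 reads per library.

## Worked example

```{r example, eval = FALSE}
refs <- generate_reference_set(seed = 1)
params <- library_params(n_reads = 20000, pingpong_fraction = 0.4, seed = 2)
lib <- simulate_library(params, refs)

res <- process_library(lib$reads, refs)
tidy(res$pingpong)      # per-TE qualifying weight, total weight, ratio
glance(res$pingpong)    # pooled ratio and bin-10 share of the histogram
autoplot(res$pingpong)  # overlap histogram with the signature bin marked
```

A two-condition experiment, from simulation to differential calls:

```{r example2, eval = FALSE}
dir <- tempfile()
cfg <- simulate_dataset(dir, params = library_params(n_reads = 20000, seed = 1),
                        fold_by_class = c(transposon = 3), n_replicates = 3)
out <- run_pipeline(cfg)
tidy(out$differential)        # per-TE log2FC, p, BH q, up/down calls
out$ratio_comparison$p        # signed-rank p for ping-pong ratio shift
```

## Known limitations

* Transcript-level consensus references only: no genome alignment, no
  spliced alignment, and the genomic-class breakdown is delegated to the
  annotation table.
* No EM re-estimation of multi-mapper placement; `fractional` weighting is
  a deliberate, simpler stand-in whose behaviour is fully testable.
* The differential battery does not model count overdispersion; with few
  replicates and low counts its calls are conservative rather than
  shrunken.
* The z10-style standardised ping-pong score is out of scope; the ratio
  and the raw histogram are the reported statistics.
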