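---
title: "Profiling retron RT-DNA termination: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling retron RT-DNA termination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroterm)
```

## The measurement problem

A retron reverse transcriptase copies the msd region of its non-coding RNA
into a short single-stranded RT-DNA. Where synthesis *stops* is controlled
by the host RNase H1, which degrades the RNA strand of the growing DNA:RNA
hybrid: with RNase H1 present the 3′ ends of the products pile up on one
canonical site (a majority of molecules within a span of ≤ 3 bases), and
without it the RT runs past the normal stop, producing longer and
heterogeneous molecules. `retroterm` turns multiplexed sequencing of these
molecules into three quantitative read-outs — length distributions,
per-nucleotide coverage with 5′/3′ end-site histograms, and a
majority-termination-span statistic — plus the statistics and phenotype
ratios used to interpret them.

The library chemistry dictates the read structure the pipeline must undo.
The single-stranded RT-DNA 3′ end is extended by terminal deoxynucleotidyl
transferase with dATP, aiming at ~25 adenosines; a second strand is primed
with an adapter, nine thymines and a non-T (V) anchor; adapters are then
ligated. A sense read is therefore

```
adapter_A + RT-DNA (5'→3') + poly(A) tail + adapter_B
```

and an antisense read is its reverse complement, with the poly-T image in
front of the molecule complement.

## Coordinates and orientation

All coordinates are 1-based inclusive (the R/Bioconductor convention); the
on-disk region annotation is BED-like 0-based half-open and converted on
load/write. Because the RT reads its template 3′→5′, the RT-DNA 3′ terminus
maps to the *lower* reference coordinate by default
(`rtdna_five_prime_at_high_coord = TRUE`); the flag is configurable per
reference and is recorded in every end-site profile, since a silent
convention mismatch would swap the 5′ and 3′ histograms.

## Read processing

**Adapter removal.** Each adapter (and its reverse complement) is searched
with at most one substitution per 10 adapter bases; matches anchored at a
read end are removed, and a truncated adapter hanging off the 3′ end is
accepted as a prefix match of ≥ 8 bases. Adapters are removed before tail
trimming; both orders were defensible, and adapter-first means the tail is
always terminal when it is inspected.

**Tail trimming.** The maximal terminal A run (or leading T run, for
antisense reads) of ≥ `polyA_min_run` bases (default 5) is removed. Two
numerical details matter. First, a substitution error inside the tail would
split the run, so the run may bridge an isolated non-A base when at least
four tail bases continue beyond it — the four-base anchor guarantees that a
junction base is never absorbed through bridging alone. Second, the strip is
iterated to a fixpoint, because a tail carrying several errors can exceed
one pass's skip budget; the fixpoint makes trimming idempotent, which the
test suite asserts as an invariant. The unavoidable limitation is shared
with any maximal-run rule: a *template-encoded* A adjacent to the tail
junction is indistinguishable from the tail and is absorbed, shortening that
molecule's apparent length by one. Reads shorter than 15 bases after
trimming are discarded to prevent spurious probe hits.

**Classification.** A read is assigned to a retron when at least one of its
three 10-base probes occurs on either strand with at most one substitution
(Hamming distance; the wording "one mismatch" is interpreted as
substitution-only, which is reproducible and fast for fixed-length probes).
Reads matching no probe set are `unassigned`; reads matching more than one
are `ambiguous` and excluded from profiles but counted in the QC summary —
the original single-retron-per-sample design never faced this case, so the
policy is ours. Probe sequences are user configuration: they are
retron-specific and not derivable from the reference, so `validate_probes()`
checks them against the expected RT-DNA (reverse complement of msd) before
use.

## Profiling

**Length profiles** are counts per trimmed length normalized by the total
RT-DNA reads of that retron. **Alignment** is ungapped minimal-Hamming
placement of the read (both strands) at every reference offset, reported
when the mismatch fraction is ≤ 0.1, with ties broken by the lowest
reference start and then the sense strand; ungapped is a modelling choice,
not an approximation — the RT-DNA is a contiguous reverse transcript
without duplications or deletions, so indel-tolerant alignment would only
add degrees of freedom. **Coverage** at a position is the fraction of
aligned reads covering it; alignment boundaries are mapped to 5′/3′ termini
through the orientation flag.

**The majority termination span** is the smallest contiguous window of
3′-end positions whose summed frequency strictly exceeds 0.5 ("majority" is
operationalized as a strict majority, since no printed threshold exists),
ties broken leftmost. Positions with zero counts inside a window count
toward its width. One property worth stating precisely: adding mass at the
modal 3′ site never widens the span *when the mode lies inside the current
majority window* (the window gains the added mass faster than the
threshold rises). For a multimodal histogram whose mode sits outside the
window the guarantee can fail — adding mass there raises the majority
threshold without any small window crossing it — so the property test
asserts monotonicity only in the covered-mode regime.

Histogram bins are 1 base wide internally; any rebinning is cosmetic.

## Statistics

**Mann–Whitney U** compares two per-read length samples. U is computed from
midranks. For nA·nB ≤ 64 the two-sided p is exact, by enumerating all
C(nA+nB, nA) assignments of the pooled observations to group A — this
conditions on the observed ties, which matters because length data are
heavily tied. Above that, a normal approximation with tie correction and a
0.5 continuity correction is used; the method applied is recorded in the
result. P-values are two-sided throughout, and no multiple-testing
correction is applied across retrons (matching per-panel reporting); both
choices are stated in the output rather than silently assumed.

**Terminal-base bias.** The tailing enzyme can extend different terminal
bases at different rates, which would bias any quantitative claim about
3′ ends. The control sequences an equimolar mix of four oligos identical
except at their final base; each read is matched against the common oligo
body with the terminal position wildcarded, at edit distance ≤ 2
(Levenshtein — full-oligo matching mirrors a fuzzy-search over a longer,
variable context, unlike the fixed-length 10-mer probes where Hamming is
used). Matched reads are binned by the observed terminal base and tested
against equimolarity by chi-square. The implementation first tries a
substitution-only scan (cheap, covers the vast majority of reads) and falls
back to a windowed Levenshtein scan so that indel-containing matches are
still found.

## Phenotype metrics

The neutralization ratio, (full-operon OD600 induced/uninduced) ÷
(accessory-only OD600 induced/uninduced), and phage sensitivity, PFU/mL on
the full-operon strain ÷ PFU/mL on the ncRNA/RT strain, are computed
*within* each biological replicate and then summarized as mean ± SD. Pooling
before ratio-taking would introduce ratio-of-means bias, so replicate
pairing keys are required in the input tables. Sensitivity 1 means no
retron-based defense, 0 total defense; values above 1 are reported as-is
(the definition is a plain ratio). Undefined ratios (a zero denominator)
raise errors with context instead of returning infinities.

## The synthetic-data generator

Every stage is tested against simulated data with per-read ground truth.
The generator emulates:

* **Termination**: `"+rnaseH1"` is a point mass on the canonical site;
  `"-rnaseH1"` is a discretized normal with sd 4 bases whose centre is
  displaced one sd beyond the canonical site toward the template 5′ end —
  run-through past the normal stop produces longer, heterogeneous products.
  The real in-vivo distribution shape is unknown; the presets are
  illustrative, and the tests rely on parameter recovery, not on
  distributional realism.
* **Tails**: discretized normal, mean 25, sd 5, floored at 5 (the prep aims
  at ~25 adenosines; only the aim is stated, so the spread is our choice of
  a realistic enzymatic dispersion).
* **Reads**: both orientations (default 50/50), uniform per-base
  substitution errors, constant quality strings (the analysis uses no
  quality information), full-length TruSeq-style adapters. Simulated
  molecules are emitted debranched, as the sequencing prep enzymatically
  debranches and strips RNA before tailing. No PCR duplicates, no indels,
  no quality realism — none of which the pipeline consumes.
* **Phenotypes**: OD600 = design mean × unit-mean lognormal noise of chosen
  CV; plaque counts are Poisson around the design mean.

All generators draw from one seeded RNG stream with a fixed draw order and
restore the caller's RNG state, so outputs are bit-identical across runs
and machines.

The bundled `synthetic_retron()` builds the reference the test suite and
the acceptance script run on: a 190-nt ncRNA with a1/msr/msd/a2 regions and
an 85-base canonical RT-DNA (Eco1-like; 45 gives an Eco6-like product). Two
sequence constraints keep the study conditions clean. The sequence contains
no homopolymer run of ≥ 4 bases, so tolerant tail trimming can never bridge
into template; and no T appears within ±12 of the canonical termination
site, so wherever a 3′ end lands under either preset the junction base is
not an A and length recovery is exact. Real references obey neither
constraint, which is exactly why the A-junction absorption limitation is
documented above: on real data, termination sites adjacent to
template-encoded A runs are measured with a one-base uncertainty, and
passing synthetic tests cannot rule that out.

## Problem sizes and what the tests show

The suite verifies, among others: fuzzy matching and placement against
brute-force Hamming oracles (1,000 and 100 randomized instances); exact
histogram recovery for 10,000 error-free reads and total-variation distance
< 0.05 at a 1% substitution rate; span 1 under the tight preset and span
> 3 in ≥ 95% of 100 replicates of 300 reads under the broad preset; exact
Mann–Whitney p equal to permutation enumeration over 500 random small
samples; equimolar spike fractions within 3σ of 0.25 with an injected 2×
bias detected at n = 4,000; and phenotype metrics recovering designed
effects within 3 standard errors over 200 replicates. These sizes were
chosen so each statistic is measured at a stable operating point.
What passing them shows is that the *pipeline* is correct under the modelled
chemistry; it does not certify behavior on features the generator omits
(indels, PCR duplicates, quality artifacts, references with terminal A
runs).

## Known limitations

* Template-encoded A bases at the tail junction are absorbed into the tail
  (one-base length underestimate for such molecules).
* Alignment is ungapped; a hypothetical RT-DNA with internal duplications
  or deletions would go unaligned rather than be characterized.
* Reads are treated as single-end; no UMI or duplicate handling.
* The exact Mann–Whitney enumeration is limited to nA·nB ≤ 64 by design;
  beyond it the corrected normal approximation is used.
* Probe sets must be supplied by the user per retron; the package validates
  but cannot invent them.
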