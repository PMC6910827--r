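---
title: "Methods: simulating and dissecting rearrangements of a transferred chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and dissecting rearrangements of a transferred chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoshatter)
```

## The system being modeled

When a single chromosome is moved between cell lines through a micronucleus
(microcell-mediated chromosome transfer), the transferred homolog can be
damaged in transit and rejoined incorrectly. A derived trisomic clone then
carries two intact endogenous homologs plus one transferred homolog of a
distinct haplotype that may be shattered and reassembled (chromothripsis-like)
or rebuilt by aberrant replication with serial template switching
(chromoanasynthesis-like). Three signal layers make this dissectable without
phased reference data:

1. **Total copy number.** Binned sequencing produces a per-segment *quantal*
   value (~2 at disomy). Losing the transferred copy of a region drops the
   aneuploid chromosome from 3 to 2; duplications raise it to 4 or more.
2. **B-allele frequency (BAF).** At SNPs where the parental line is
   homozygous and the transferred homolog carries the other allele
   (*phase-informative* SNPs), the intact trisomic baseline sits at 1/3 or
   2/3. Every local copy change moves the BAF in a homolog-specific
   direction, so the affected homolog is readable from the shift.
3. **Junction sequence.** Assembled junction-spanning contigs reveal the
   repair mode: blunt joins, microhomology, non-templated insertions, or
   short templated fragments copied from elsewhere on the chromosome.

The package implements the full analysis over these layers, and a simulator
that generates all of them from a known ground truth so every step has an
oracle.

## The simulator

`genome_spec()` defaults to three 10 Mb chromosomes with one SNP per 5 kb
and 30% informative SNPs, chr1 trisomic. These defaults are the package's
desk-scale study conditions: small enough that a full simulation runs in
seconds, dense enough that a 100 kb CNA contains several informative SNPs.
The simulator deliberately emulates *processed* signals — SNP tables,
quantal segments, contigs, allele counts — not reads; read mapping, SV
calling and assembly are upstream tools whose outputs it mimics directly.

`simulate_shattering()` cuts the transferred homolog at `k` uniform
positions, deletes each fragment independently with probability
`deletion_fraction`, and reassembles the survivors in uniform random order
with independent 50% inversion. The outcome pattern (copy oscillation
between two states, all four junction orientations) is what the biology
prescribes; the uniform generative law is a modeling choice, since nothing
constrains the true fragment-count or deletion distributions in
micronuclei. Fragment lengths are conserved exactly (retained + deleted =
chromosome length), which the tests assert.

`simulate_chromoanasynthesis()` performs `n` serial template switches, each
inserting an extra copy of a random 0.2–1 Mb segment at a random position of
the derived chromosome. Overlapping copies create triplications, so the
profile shows more than two copy states — the replicative signature.

Junction features are planted per `junction_feature_config()`:
microhomology 1–15 bp, non-templated insertions 1–30 bp, templated
insertions 50–200 bp copied from the transferred homolog. Microhomology and
insertion are mutually exclusive at one junction by default so the ground
truth is unambiguous. Microhomology is realized by *editing the reference*
so the right-hand context's junction-proximal bases equal the left-hand
context's final bases; the homology tract then appears once in the contig
(length `2*flank − h`), and the junction placement is ambiguous across
`h + 1` split positions, which is exactly what the classifier measures. A
planted edit whose region would collide with another junction's flank is
demoted to blunt and recorded as such, keeping the truth truthful.

Rendering is exact at zero noise: BAF is the true B-allele fraction over
all local copies, LRR is `log2(cn/2)`, quantal equals the true total copy
number with boundaries snapped to the bin grid. Noise is additive Gaussian
(BAF clipped to [0,1]); the default BAF noise of 0.03 is typical of array
data and leaves the 1/3 vs 1/2 vs 1/4 targets separable at ±0.08 windows
(2.7 standard deviations).

What the simulator does **not** emulate: wavy LRR baselines and GC bias,
genotyping error at the SNP level, mosaicism, breakage–fusion–bridge
cycles, a murine donor background, or read-level artifacts. Passing tests
therefore demonstrate correctness of the *analysis logic* under clean
generative assumptions, not robustness to every artifact of real arrays or
sequencing.

## Copy-number calling

Quantal thresholds are strict: corrected quantal `< 1.5` is a loss,
`> 2.5` a gain, values at the thresholds are neutral. On the aneuploid
chromosome the quantal is first corrected by subtracting one, so the
trisomic baseline reads as neutral. Consecutive same-state calls merge when
their summed lengths cover more than 90% of the joint span (gap bases count
against coverage; the alternative reading, gaps counting as covered, is not
used). Merging is greedy left-to-right to a fixpoint, with the merged
quantal the length-weighted mean. "Similar quantal" is operationalized as
state identity; a numeric quantal-difference tolerance would be an
additional knob with no stated value, so it defaults to unbounded within a
state. The size floor is strict (`> 100 kb`), as is the uniqueness rule: a
call is unique iff its reciprocal overlap — the minimum of the two mutual
coverage fractions, the dominant CNV-literature convention — is below 0.70
against every call of every other clone and every parental call. A call
never competes with calls of its own clone.

One consequence of the 90% merge rule matters for evaluation: two true CNAs
separated by a gap under 10% of their joint span are *by design* reported
as one call. The recovery study therefore defines its expected output as
the truth profile snapped to the bin grid with the same merge rule applied,
and then requires one-to-one correspondence within one bin.

## Haplotype assignment

Phase-informative SNPs are found by comparing the parental table (BAF
< 0.05 or > 0.95, homozygous) against an *unrearranged* trisomic baseline
(BAF within ±0.12 of 1/3 or 2/3). The baseline must come from unrearranged
signal — a sibling intact clone, or the clone itself outside called CNAs —
because inside a rearranged interval the diagnostic shift is destroyed;
that destruction is precisely the evidence the assignment step reads.

Within a CNA, each informative SNP votes. For a loss: BAF returned beyond
the 0.15/0.85 shift thresholds on the parental side means the transferred
copy is gone; BAF near the one-parental-copy target (0.5 in a trisomy,
±0.08) means an endogenous copy is gone. For a gain: BAF at the
transferred-duplication target (0.5, AABB) versus the
endogenous-duplication targets (0.25/0.75, AAAB/ABBB). Targets are computed
from allele-count pairs generally, so tetrasomic baselines need no special
casing. The verdict is the majority of votes with a minimum-evidence floor
(`min_snps = 3`) and a 2/3 majority margin; anything weaker is *ambiguous*
rather than a guess. The per-SNP vote plus majority rule is this package's
operationalization — the underlying per-interval calls in real studies are
typically curated by eye — and it is deterministic and testable, with label
symmetry (swapping A/B everywhere flips BAF to 1−BAF and changes no
verdict) asserted as a property.

Junction-level assignment pools transferred/endogenous allele counts among
junction-supporting discordant read pairs over nearby informative SNPs and
applies a one-sided exact binomial test against 0.5 (α = 0.05, minimum 5
pairs). An informal "all pairs agree" rule would behave identically on
clean data but has no defined behavior on mixtures.

## Junction forensics

Breakend *sides* encode where retained sequence continues: `head` toward
higher coordinates, `tail` toward lower. BEDPE strand `+` maps to `tail`
and `−` to `head`, which makes a simple deletion a tail-head junction, a
tandem duplication head-tail, and an inversion one head-head plus one
tail-tail junction. Junctions are canonicalized (lower breakend first) so
the orientation label is order-invariant.

Microhomology is defined as junction-shift ambiguity: the number of
distinct exact splits of the contig into left-flank match + right-flank
match, minus one. The classifier finds the maximal anchored split
(largest `|L| + |R|`, ties resolved toward the smaller insertion); a side
anchoring under 20 bp renders the junction unclassifiable rather than
miscalled. Matching is exact by default (mismatch tolerance 0); the flanks
must be extracted at the same flank length used to assemble the contig so
the outer ends align — real variable-length contigs would need a prior
alignment step, which is out of scope. Under this contract the planted
homology/insertion lengths are recovered exactly in 100% of zero-mismatch
cases, which the suite checks against a brute-force try-every-split oracle
on ~500 simulated junctions.

Templated insertions are detected by exact full-length search of the insert
and its reverse complement against the reference (≥ 20 bp to call), with
the first hit by coordinate reported and ties flagged. The >10 kb span
filter applies in spectrum and report steps only, not at ingestion.

The orientation spectrum is tested against uniform 25% per class with a
chi-square statistic (df = 3); totals under 20 use full enumeration of
multinomial outcomes (inclusive of equality at the observed statistic), and
pooling across clones sums counts rather than combining p-values, because
pooled data — not pooled tests — is what the underlying question asks.
Whether small-sample studies use exact or asymptotic p here is usually
unstated; both are exposed via `method =`.

## Enrichment test

Each unique CNA is reassigned to a chromosome with probability proportional
to chromosome weight; the default weighting is length × copy number (3 or 4
on the clone's aneuploid chromosome, 2 elsewhere), with `length_only`
available for sensitivity analysis. CNAs are resampled as chromosome labels,
not length-preserving placements — in these toy genomes no CNA outsizes a
chromosome, and a placement mode would change nothing here. The statistic is
the number of CNAs landing on their own clone's aneuploid chromosome; the
empirical p uses the add-one correction, so p is never zero and is slightly
conservative. A dynamic-programming Poisson-binomial tail
(`enrichment_exact_tail()`) provides the exact reference for small cases;
the permutation engine is required to agree within Monte-Carlo error.

Calibration: the permutation statistic is discrete, so within any single
scenario the attained p-values form a staircase and a uniformity check
would reject the discreteness itself. The calibration study therefore
draws each null dataset's genome (3–8 chromosomes of 2–50 Mb), clone count
(2–5), ploidies (3/4) and CNA counts (3–20 per clone) independently and
checks the mixture: across 200 such datasets the p-values pass a KS
uniformity check and the type-I error at 0.05 stays in a band around
nominal (the add-one correction keeps it at or below nominal).

Power: with all CNAs planted on the aneuploid chromosome, the study's power
check uses a 12/10/8 Mb genome with the smallest chromosome trisomic
(landing probability 24/68 per CNA), where five hits give an exact tail of
0.0054. With three *equal* 10 Mb chromosomes the same configuration gives
(3/7)^5 = 0.0145 — a reminder that enrichment evidence depends on the
weight of the aneuploid chromosome, which is why real studies account for
chromosome size.

CNA sizes between the transferred and other chromosomes are compared with a
two-sided rank-sum test (the groups are unpaired): exact enumeration when
both groups are ≤ 10 without ties, normal approximation with tie
correction otherwise, and a fully tie-degenerate comparison reports p = 1.

## Study sizes and numerical choices

The test suite and the acceptance script run, by design, at desk scale:
end-to-end shattering recovery on the default 3 × 10 Mb genome (k = 20,
40% deletion, 50 kb bins, zero noise); haplotype parameter recovery with
100 planted 200 kb CNAs on a 30 Mb aneuploid chromosome, keeping windows
with at least 5 informative SNPs (the study condition), at BAF noise 0.03
and at zero noise; junction forensics over ~500 junctions from a k = 560
shattering of a 10 Mb chromosome with 300 bp flanks; 50 small
permutation-vs-exact comparisons at 10^4 permutations plus the
two-chromosome closed-form case (exact tail 0.6) at 10^5; and 200-dataset
calibration. Coordinates are 0-based half-open internally and on disk
(BED/BEDPE), 1-based inclusive in human-readable reports; SNP positions
follow the same convention, fixed here rather than guessed from any
particular array platform.

## Known limitations

* The haplotype baseline requires unrearranged trisomic signal; a clone
  rearranged across its entire aneuploid chromosome would need a sibling
  clone for SNP discovery.
* Junction classification assumes exact flank alignment at a known flank
  length; it does not align variable-length or error-containing contigs.
* The simulator's noise model is additive Gaussian only; no GC waves,
  genotyping error, or mosaicism.
* The enrichment null treats CNAs as exchangeable points; gene-density or
  replication-timing structured nulls are out of scope.
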