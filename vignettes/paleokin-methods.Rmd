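---
title: "Methods: coverage-based karyotyping, mismatch-rate kinship and damage-aware variant screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based karyotyping, mismatch-rate kinship and damage-aware variant screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

paleokin analyzes shotgun-sequenced ancient-DNA cohorts genotyped on a fixed
SNP panel (a 1240k-style capture set). Coverages in this regime run from
below 0.01x to a few x, which rules out diploid genotype calling: the working
representation is the pseudohaploid call — one randomly sampled read allele
per site, encoded homozygous-or-missing ({0, 2, 9} in EIGENSTRAT
reference-dose convention, never 1). This document explains the three
analytical methods, the synthetic-data model used to validate them, the
tunable parameters, and what the validation does and does not demonstrate.

## Coverage-based ploidy and karyotype estimation

For a sample with `reads_c` reads over `sites_c` panel sites on chromosome
`c`, the normalized coverage ratio is

    ratio_c = (reads_c / sites_c) / (sum_autosomal reads / sum_autosomal sites)

so a disomic autosome sits at 1, a single-copy X at 0.5 and a trisomic
chromosome near 1.5. (Exactly at 1.5 it is not: the extra copy also inflates
the autosomal baseline, by ~2% for chromosome 21; copy-number rounding
absorbs this drift.)

A set of reference genomes, each declared karyotypically normal (XX or XY),
is converted to *per-copy* units: each reference contributes
`ratio_c / copies_c` for every chromosome where its declared karyotype gives
`copies_c > 0`. This lets XX and XY references be pooled — an XY genome's X
at ratio 0.5 over 1 copy and an XX genome's X at 1.0 over 2 copies both
yield a per-copy expectation of 0.5 — and Y statistics simply come from the
XY references only. Per chromosome the references give a per-copy mean `m_c`
and standard deviation `s_c` (both must come from at least two informative
references; a zero SD is refused because a z-score would be meaningless).

A test sample's copy number is `round(ratio_c / m_c)`, and its z-score is
measured against the normal-genome expectation,
`z_c = (ratio_c - k m_c) / (k s_c)` with `k = 2` for autosomes. An autosome
is flagged as a putative aneuploidy only when both the rounded copy number
differs from 2 *and* `|z|` exceeds the threshold (default 3, the
conventional outlier bound; across 24 chromosome tests per genome this keeps
expected false flags far below one). Requiring both conditions matters at
very low coverage: the sample's own Poisson noise is then much larger than
the reference spread, so `|z| > 3` alone would fire constantly, while the
rounding step alone has no notion of confidence.

Sex chromosomes are handled structurally rather than flagged: the rounded X
and Y copies assemble a gonosomal string ("X"×nX + "Y"×nY, with X0 for a
single X), genetic sex is male iff at least one Y copy is present and female
iff the string is XX or XXX (X0 is reported with undetermined sex — the
copy-number evidence alone should not overrule a karyotype that is its own
clinical entity). When the combined X+Y read count falls below `min_reads`
(default 100 — enough to keep the binomial error of the X:Y split below one
copy unit) the karyotype is undetermined rather than guessed. Rounding ties
at exactly .5 resolve toward 2 copies on autosomes and toward the smaller
copy number on gonosomes: both choices are conservative against calling an
aneuploidy from borderline evidence.

Design choices that were genuinely open: z-scores are computed on linear
ratios, not log-ratios — at 0.01x a small chromosome collects tens of reads
and log-ratios would be badly skewed near zero counts. Depth is counted over
panel sites, not genome-wide windows, matching the capture-centric workflow;
no GC or mappability correction is applied (an extension point — references
and samples processed identically absorb shared bias to first order).

Validation uses depth tables simulated as Poisson reads,
`reads_c ~ Poisson(sites_c × coverage × copies_c / 2)`, on a ~1.15M-site map
with per-chromosome site counts proportional to GRCh37 chromosome lengths.
With 20 references (10 XX, 10 XY) at 0.1x and 50 replicates per karyotype,
correct-call rates across XX, XY, XYY and trisomy-21 first reach ≥95% at
0.01x coverage (0.005x fails, mostly through trisomy-21 misses and false
flags on the two smallest autosomes — consistent with a closed-form check:
at 0.005x chromosome 21 collects ~90 reads, putting the 1.25 rounding
boundary only ~2.5 SD away).

## Pairwise-mismatch kinship

For samples a and b, `pmr = mismatches / overlap` over sites where both
calls are non-missing. Under random-allele pseudohaploidization with
independent sites, the probability two sampled alleles differ is
`(1 - phi) × B`, where `phi` is the kinship coefficient (the probability
that randomly drawn alleles are identical by descent) and B the mismatch
rate of an unrelated pair in the same cohort. The normalized score
`norm = pmr / B` therefore has expectation `1 - phi`:

| relationship                                | phi  | E[norm] |
|---------------------------------------------|------|---------|
| same individual / monozygotic twins          | 1/2  | 0.5     |
| parent-offspring, full siblings, dizygotic twins | 1/4 | 0.75 |
| half-siblings, avuncular, grandparental      | 1/8  | 0.875   |
| unrelated                                    | 0    | 1       |

Degree classes are cut at the midpoints of adjacent expectations —
0.625, 0.8125, 0.90625 — the unique boundaries implied by this algebra;
intervals are closed below, so ties are deterministic. The package pools
mismatches per site across the genome (no window averaging): with
independent panel sites the per-site pool is the minimum-variance estimate,
and uncertainty is recovered separately by a delete-one block jackknife over
contiguous 20 Mb windows (long enough to decorrelate linkage at 1240k
density; the last window per chromosome may be short, empty windows are
dropped; fewer than two non-empty windows yields a missing SE, never a
refusal to classify).

B defaults to the cohort median of eligible pairwise rates, which assumes a
mostly unrelated cohort; a user-supplied expected-unrelated rate is the
alternative. A structural caveat discovered while testing: when more than
half the pairs are truly related, median normalization does not merely
degrade — it *cannot* warn from its own output, because norms below the
related cutoff are a subset of rates below the median, capping the
apparent related fraction at 50%. The package warns when more than half the
pairs classify as related (reachable with a supplied background) and
documents here that a majority-related cohort under median mode will be
silently mis-normalized: supply an external background for family-dominated
cohorts.

Pairs with overlap below `min_overlap` (default 1,000 sites) are reported
`insufficient`: at 1,000 sites the binomial SE of pmr (~0.014 at B ≈ 0.25)
is marginal against the ~0.03 pmr spacing of adjacent classes. The
relatedness network keeps only edges of second degree or closer. No attempt
is made to separate second from third degree, to orient first-degree edges
(parent vs sibling), or to infer IBD segments — the independent-sites model
underlying both the method and the simulator carries no segment information.

Validated properties (fixed seeds): norms within ±0.02 of expectation at
50k overlapping sites for phi in {0, 1/8, 1/4, 1/2}; ≥95% correct degree
assignment per class over 100 replicates at ≥10k overlap (dizygotic twins
classified first degree); invariance to sample/SNP permutation and to 50%
random masking; and a 3% deamination rate inflates pmr but moves norm by
<0.02, because background and pair rates rise together.

## Damage-aware variant screening

Post-mortem cytosine deamination produces C→T (and, read on the other
strand, G→A) artifacts, so a transition supported by few reads is
indistinguishable from damage in a single sample. The screen joins pileup
evidence to a variant panel on (chromosome, position), reports depth, alt
depth and allele fraction per site, and then applies the retention rule: a
transition hit with fewer than `min_alt_reads` alt reads (default 2 — a
single read hit is the canonical exclusion) is flagged
`low_coverage_transition` and excluded, unless the identical allele carries
alt evidence in at least two samples (`multi_sample_corroborated`) or an
explicit per-hit override marks independent phenotypic support
(`phenotype_corroborated` — e.g. skeletal features consistent with the
condition; this cannot be computed, so it is an input). Transversions are
never excluded by this filter: deamination cannot produce them.

The filter recomputes flags from scratch on every call (idempotent), and
raising `min_alt_reads` can only shrink the retained set (monotone). On an
all-transition 5,000-site panel with no true variants, a 3% damage rate and
0.3x coverage — a typical shotgun aDNA depth — the expected number of
falsely retained hits per sample at the default threshold is ~0.2
(alt reads are Poisson(0.3 × 0.03), so two independent damage reads at one
site are rare); the test suite asserts the empirical mean over ten seeds is
below one. At 1x the same expectation rises above two: the single-sample
screen is honest only at low coverage or with cross-sample corroboration,
which is why the multi-sample rule exists.

Panels ship as plain TSV (rsID, chrom, pos, ref, alt, significance,
condition) with the transition/transversion class always recomputed from
the alleles. The bundled clinical and pigmentation panels are small
demonstration stand-ins (partly synthetic, see `inst/extdata/README.md`);
the mtDNA panel uses canonical rCRS coordinates. Pigmentation screening
reports genotypes only; phenotype-probability models are out of scope.

## The synthetic-data model

Genotypes: founders are drawn site-wise from Hardy–Weinberg proportions at
an alt-allele frequency sampled uniformly from [0.05, 0.95] (a flat,
ascertainment-neutral default for a genotyping panel; the exact frequency
spectrum only shifts B, which every downstream quantity normalizes away).
Children inherit one uniformly chosen allele per parent per site; duplicates
copy a genome exactly. Sites are independent — no linkage or recombination —
which preserves every expectation used above but makes the simulator
unsuitable for segment-based methods. Pseudohaploidization covers each site
with probability min(coverage, 1) (the single-read regime: at ≤1x most
covered sites hold one read), samples one allele, applies damage (a sampled
C observed as T, G as A, with probability `damage_rate`; the half-UDG
default used in the tests is 0.02–0.03) and then a random allele flip with
probability `error_rate`. A damaged base matching neither panel allele is
recorded missing, as a biallelic caller would drop it. Damage is applied
uniformly across sites — real damage concentrates at read termini, but
genotype-level simulation has no read coordinates; this makes the simulated
damage a worst case at equal rate.

Depth tables are Poisson per chromosome as described above; karyotype
strings combine a gonosomal token with autosomal gains/losses ("XY+21",
"XX-18"), and "trisomy-21" is an alias for "XX+21" (the gonosomal context
of that token is otherwise unspecified; tests always check the full
configuration they simulate). Pileups draw Poisson depth per panel site and
sample alleles per read with the same damage/error chain.

All generators are deterministic under a single integer seed; the
pseudohaploidization and pileup stages offset the seed so genotype and read
randomness are independent streams.

## What the validation shows — and does not

Test and acceptance problem sizes were chosen as the smallest at which the
statistical claims are sharp: ~1.15M-site depth maps with 50 replicates per
karyotype for ploidy; 50k-site cohorts for kinship expectations and 100
12k-site replicates per class for classification; 5k-site panels for the
damage filter. The simulators emulate sampling noise, missingness,
deamination and pedigree structure, but not reference bias, contamination,
GC/mappability structure, linkage, or ascertainment of real panels. Passing
tests therefore demonstrate the estimators' correctness under their stated
models and their internal consistency — not performance on any particular
archaeological dataset. Known limitations worth restating: median background
normalization fails silently on majority-related cohorts (supply a
background); X0 karyotypes are reported with undetermined genetic sex;
single-sample transition evidence at ≥1x coverage needs corroboration; and
no contamination estimate is produced.
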