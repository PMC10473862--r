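# paleokin

Kinship, ploidy and clinical variant screening for low-coverage ancient
genomes.

Shotgun-sequenced ancient-DNA cohorts typically yield 0.008–2x genomic
coverage on a fixed SNP panel (a 1240k-style capture set) — far too little
for diploid genotype calling. paleokin implements three estimators built for
that regime, plus the synthetic data needed to test them without access to
real samples:

- **Coverage-based karyotyping.** Per-chromosome normalized coverage
  ratios, `ratio_c = (reads_c/sites_c) / (Σ reads / Σ sites)` over
  autosomes, are compared against per-copy statistics from a set of
  reference genomes; copy number is `round(ratio_c / m_c)` and a z-score
  `z_c = (ratio_c − k·m_c)/(k·s_c)` gates aneuploidy flags. This yields
  genetic sex, sex-chromosome aneuploidies (XYY, XXY, X0, …) and autosomal
  trisomies down to ~0.01x coverage.
- **Pairwise-mismatch kinship.** For each sample pair, the pseudohaploid
  mismatch rate `pmr = mismatches/overlap` is normalized by the cohort's
  unrelated background B; `norm = pmr/B` has expectation `1 − φ` (kinship
  coefficient φ), so identical genomes sit at 0.5, first-degree pairs at
  0.75, second-degree at 0.875, unrelated at 1. Classes are cut at the
  midpoints {0.625, 0.8125, 0.90625}, with a 20 Mb block-jackknife SE and an
  igraph relatedness network.
- **Damage-aware variant screening.** Pileup evidence is screened against
  clinical / pigmentation / mtDNA panels; transition hits with fewer than
  `min_alt_reads` supporting reads are excluded as putative deamination
  damage unless the same allele appears in a second sample or an explicit
  phenotype override corroborates it. Transversions are never excluded.

The synthetic-data module generates pedigree genotypes by gene dropping
(Hardy–Weinberg founders, Mendelian inheritance, exact duplicates),
pseudohaploidizes them under a single-read coverage model with C→T/G→A
deamination, and draws Poisson depth tables and pileups per karyotype.

See `vignettes/paleokin-methods.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

```r
library(paleokin)

# --- karyotyping a simulated XYY individual at 0.01x ---------------------
sm  <- default_site_map(1150000)          # 1240k-like site counts
kts <- setNames(c(rep("XX", 10), rep("XY", 10)), sprintf("ref%02d", 1:20))
refs <- lapply(names(kts), function(s)
  simulate_depth_table(kts[[s]], sm, coverage = 0.1,
                       seed = match(s, names(kts)), sample = s))
rs <- build_reference_stats(refs, kts)

d     <- simulate_depth_table("XYY", sm, coverage = 0.01, seed = 99,
                              sample = "S10")
calls <- estimate_ploidy(d, rs)
call_karyotype(calls)
#> karyotype_call: S10  gonosomal=XYY  sex=M
round(calls[calls$chromosome %in% c("1", "21", "X", "Y"),
            c("ratio", "z", "copies")], 3)
#>    ratio      z copies
#> 1  1.009  1.222      2
#> 21 0.987 -0.296      2
#> 23 0.521  2.910      1
#> 24 0.963 -0.821      2
```

The X ratio ~0.5 (one copy) with a Y ratio ~1.0 (two per-copy units) is the
XYY configuration; all autosomes round to 2 copies with |z| below the flag
threshold.

```r
# --- kinship in a simulated family --------------------------------------
ped <- pedigree_spec(
  founders = c("u1", "u2", "u3", "u4", "u5", "u6"),
  matings  = data.frame(parent_a = c("u1", "u1", "u1"),
                        parent_b = c("u2", "u2", "u3"),
                        child    = c("s1", "s2", "h1")))
cfg <- sim_config(n_sites = 50000, coverage = 1, seed = 9)
mat <- pseudohaploidize(simulate_pedigree_genotypes(ped, cfg), cfg)
est <- kin_matrix(mat, min_overlap = 10000)
head(est[est$degree != "unrelated", ], 5)
#>    sample_a sample_b overlap   pmr  norm      se degree
#> 6        s1       u1   50000 0.276 0.758 0.00593  first
#> 7        s2       u1   50000 0.273 0.751 0.00554  first
#> 8        h1       u1   50000 0.273 0.748 0.00571  first
#> 13       s1       u2   50000 0.271 0.743 0.00530  first
#> 14       s2       u2   50000 0.276 0.757 0.00553  first
attr(est, "background")
#> [1] 0.3641
```

Parent–offspring pairs land at norm ≈ 0.75 as expected; `build_network(est)`
turns the ≤2nd-degree pairs into an igraph graph. Full siblings s1/s2
(a dizygotic-twin configuration) and half-siblings s1/h1 appear at 0.75 and
0.875 respectively further down the table.

A command-line front end wrapping these functions (subcommands `ploidy`,
`kinship`, `screen`, `run`) is installed at
`system.file("cli", "paleokin", package = "paleokin")`, and
`run_pipeline()` drives the full simulate → ploidy → kinship → screen →
report chain from one declarative config.

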