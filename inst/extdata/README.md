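# Bundled demonstration data

All files here are small, format-true demonstration fixtures, not curated
reference panels.

- `clinical_panel_demo.tsv` — clinical screening panel in the package's TSV
  dialect. A few rows use well-known rsIDs with approximate GRCh37
  coordinates; the `rsS*` rows are synthetic fillers. A production panel is
  built from a ClinVar release: keep single-nucleotide variants marked
  "pathogenic" or "likely pathogenic", drop deletions/duplications/CNVs and
  entries with conflicting reports, and export rsID/chrom/pos/ref/alt/
  significance/condition.
- `mtdna_panel_demo.tsv` — canonical pathogenic mtDNA sites (rCRS
  coordinates).
- `pigmentation_panel_synthetic.tsv` — a 58-site pigmentation genotyping
  panel; ten well-known pigmentation SNPs plus synthetic `rsP*` placeholders
  standing in for the remainder of a HIrisPlex-style set.
- `demo_cohort_sexes.tsv` — per-sample genetic-sex calls for a demonstration
  Bronze Age cohort grouped into site phases; input for `aggregate_sex()`.
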