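# Bundled reference tables

Small plain-text reference tables from a published maize seed-coat
hybrid–parent triad survey (hybrid Yudan888 and its parental lines), used
by the worked examples, the test suite and `scripts/acceptance.R` to check
the package's summary arithmetic against published values.

- `table1_reference_counts.tsv` — per-class gene counts of the 13-way
  expression-pattern classification at 3 and 8 DAP. Category totals
  (additive 19,714 / 19,460; ELD_M 1,412 / 1,763; ELD_P 1,914 / 1,237;
  transgressive up 22 / 17; down 82 / 32) are as published; the split of a
  category's total across its directional variants follows this package's
  canonical class ordering, since the published class numbering is not
  machine-readable. All derived percentages depend only on the category
  totals.
- `deg_updown_reference_counts.tsv` — published up-/downregulated DEG
  counts for the hybrid-vs-parent contrasts at 3 and 8 DAP.
- `expressed_overlap_reference_counts.tsv` — published per-genotype totals
  of expressed genes over six time points and the six-way core overlap.
- `cell_density_reference.tsv` — published seed-coat cell densities
  (cells per 0.1 mm², 8 DAP) per genotype.
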