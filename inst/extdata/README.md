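# Packaged plain-text data

- `cd34_top40_hotspots.tsv` — the 40 top-ranking published comparative
  integration hotspots (HIV vs MLV vectors in human CD34+ hematopoietic
  progenitor cells): location, width, oriented odds ratio, Holm-adjusted
  p-value and gene count. Used by the tests to check interval-width
  arithmetic and output-table conventions.
- `cd34_histone_density.tsv` — published per-track histone-mark density
  comparison between HIV- and MLV-preferred hotspots: group means/SDs,
  raw permutation p-values and Holm-adjusted p-values for ten chromatin
  tracks. Used by the tests to check that the package's Holm step-down
  reproduces the published significance pattern from the raw p column.
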