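# comphot

Comparative retroviral integration hotspot detection.

Retroviral gene-transfer vectors do not integrate into the host genome at
random: HIV-derived lentiviral vectors and MLV-derived gammaretroviral
vectors recognise different chromatin features, and the difference matters
for the genotoxic risk profile of clinical gene therapy. `comphot`
implements a statistical method for finding **comparative hotspots** —
genomic segments where the integration-site densities of *two* vectors
differ — as opposed to single-vector enrichment hotspots. It answers the
question "where do these two vectors behave differently?", not "where does
either vector like to integrate?".

## Method

Given two sets of mapped integration sites (e.g. HIV and MLV in CD34+
hematopoietic progenitor cells), the analysis runs separately for every
(chromosome, arm, strand) unit:

1. **Blind regions.** Restriction-digest library preparation cannot detect
   an integration whose distance to its anchoring cut site (TTAA / MseI by
   default) is below the minimum alignable read length (20 bp) or above
   the maximum sequenced fragment length (500 bp). These blind stretches —
   typically 10–40% of an arm — are computed from the genome sequence,
   cut out, and the detectable segments concatenated into a *collapsed*
   coordinate axis. Found hotspots are mapped back at the end.
2. **Density estimation.** Each vector's sites `x_1..x_n` on the collapsed
   axis are treated as i.i.d. draws from an unknown density `f`, estimated
   with a Gaussian kernel,
   `f̂(x) = (1/nh) Σ_i K((x − x_i)/h)`,
   with the bandwidth `h_opt` chosen per vector by unbiased (least-squares,
   leave-one-out) cross-validation.
3. **Variability bands.** On the square-root scale the estimator's variance
   is approximately free of the unknown density, so a constant half-width
   `w = z_((1+α)/2) · sqrt(R(K)/(4nh))`, `R(K) = 1/(2√π)`,
   is placed around `√f̂` and back-transformed (lower edge clipped at
   zero). The default level is α = 0.99. The band reflects estimator
   variability, not bias: it is *not* a confidence band.
4. **Candidates.** Maximal segments where one vector's band lies entirely
   above the other's are candidate comparative hotspots; a sensitivity
   scan re-runs the comparison at `h = h_opt·s` for `s ∈ [0.05, 20]` to
   show which candidates are robust to the smoothing level.
5. **Confirmation.** Each candidate gets a 2×2 table of inside/outside
   counts per vector, an oriented cross-product odds ratio (≥ 1, the
   dominant vector is the "winner"), a two-sided Fisher exact p-value and
   a 0.95 CI; all candidates from one genome-wide run form a single
   Bonferroni–Holm family, confirmed at adjusted p ≤ 0.05.
6. **Annotation.** Confirmed hotspots can be annotated with gene counts
   and length-normalised gene density, expression (present/absent)
   enrichment against the genomic background, and per-track read densities
   (e.g. histone-mark ChIP-seq) compared between HIV- and MLV-preferred
   hotspots by permutation Welch or Mann–Whitney tests under Holm
   correction.

A fully seeded synthetic-data generator (`scenario_spec()`,
`make_scenario()`) produces genomes with planted restriction motifs and
site samples with planted intensity bumps of known odds ratio, so the
whole pipeline is testable end to end without any external data.

## Worked example

```r
library(comphot)

spec <- scenario_spec(unit_length = 1e6,
                      n_sites = c(HIV = 1200, MLV = 1200),
                      bumps = data.frame(center = c(0.3, 0.7),
                                         width  = c(0.04, 0.03),
                                         vector = c("HIV", "MLV"),
                                         or     = c(8, 10)),
                      seed = 7)
files <- make_scenario(spec, "demo")
cfg <- run_config(files$fasta, files$arms, files$sites,
                  grid_size = 4096, seed = 7, out_dir = "demo_out")
res <- run_pipeline(cfg)
#> sim1:q:+: n = 1200/1200, h_opt = 5337.1/4373.2, 2 candidate(s)

res$blind_summary
#>      unit unit_length collapsed_length blind_fraction
#>  sim1:q:+       1e+06           686779       0.313221

res$confirmed[, c("id", "winner", "start", "end", "length", "or", "p_adj")]
#>     id winner  start    end length    or     p_adj
#>  mlv_1    MLV 676338 729116  52778 8.175 1.144e-57
#>  hiv_1    HIV 270527 337658  67131 7.397 3.126e-53
```

31% of the simulated arm is blind under the 20/500 bp rule; both planted
bumps (HIV at 0.3 of the detectable axis with in-bump odds ratio 8, MLV at
0.7 with odds ratio 10) come back as confirmed hotspots, with oriented
odds ratios near the planted values and Holm-adjusted p-values from the
Fisher exact test. `start`/`end` are genomic (blind regions re-inserted);
`length = end − start` always holds in the output tables.

A thin command-line wrapper is installed as `exec/comphot`
(`comphot run|blindmap|simulate ...`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a seeded synthetic scenario, runs the installed package's
full pipeline on it (blind map, bandwidth selection, bands, candidate
detection, confirmation, annotation, sensitivity scan), reports the
planted-bump recovery on stderr, and writes the acceptance JSON to
`--out`.
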