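---
title: "Comparative integration hotspots: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative integration hotspots: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The statistical model

Integration of a retroviral vector is modelled as a stochastic process on a
genomic region: each vector's mapped integration positions within one
analysis unit — a (chromosome, arm, strand) triple — are treated as an
i.i.d. sample from that vector's unknown integration density. Comparing the
integration preferences of two vectors is then the problem of comparing two
unknown densities on the same domain from two independent samples of
(possibly different) sizes. Every integration is assumed independent of
every other; clonal expansion, if present in the data, violates this and is
the user's responsibility to handle upstream.

Working per arm keeps the centromere — effectively a giant undetectable
region — out of every unit; arms are supplied as a BED file rather than
computed from sequence. Working per strand is necessary because the
detectability geometry of the library preparation (next section) is strand
specific. Candidates on opposite strands at the same locus are deliberately
reported separately and never merged: a difference present on one strand
only can reflect a preferential integration orientation.

# Blind regions and the collapsed coordinate axis

Restriction-digest library preparation with fragment size selection cannot
see every basepair. An integration is detectable only when the distance to
its anchoring cut site lies in a window bounded below by the minimum
alignable read length (`min_read`, default 20 bp) and above by the maximum
fragment length surviving size selection (`max_frag`, default 500 bp). With
the default TTAA (MseI) motif the rule, applied within each gap between
consecutive motif starts $(p, q)$:

* `+` strand (fragment anchored at the left site): $[p,\ \min(p+20, q))$
  and $[\min(p+500, q),\ q)$ are blind;
* `-` strand: the mirror image anchored at the right site.

Three further conventions close the gaps the rule leaves open, each chosen
to be conservative (call a basepair blind when in doubt):

* the spans of a unit before its first and after its last motif are blind —
  no anchoring site is reachable there;
* the motif's own footprint is blind (it falls inside the
  `min_read` exclusion);
* runs of `N` of at least 1000 bp are added to the blind set. `N` cannot
  contain a motif, so an assembly gap would otherwise masquerade as a long
  motif-free stretch and produce a spurious zero-density valley.

All coordinates are 0-based and half-open (BED convention) throughout.

Density estimation happens on the *collapsed* axis obtained by deleting
blind intervals and concatenating the detectable segments; the density is
assumed smooth across the mending points, which is reasonable while
individual blind stretches are short compared with the bandwidth. Found
hotspots are expanded back to genomic coordinates, re-inserting any
interior blind stretches, so a genomic hotspot is never shorter than its
collapsed image. The collapse is strictly increasing on detectable
positions and exactly invertible; both properties are asserted by
round-trip tests on tens of thousands of random positions.

# Density estimation and variability bands

The estimator is the Gaussian-kernel density estimate
$\hat f(x) = \frac{1}{nh}\sum_i K\!\left(\frac{x - x_i}{h}\right)$
evaluated on an equally spaced grid (default $2^{14}$ points per unit,
roughly 15 kb resolution on the largest human arm — much finer than any
reported hotspot) and interpolated between grid points by a natural cubic
spline. No boundary correction is applied at the arm ends. The domain is
discrete at basepair resolution; the continuous approximation is taken as
negligible at chromosome scale.

The bandwidth is chosen per vector by unbiased cross-validation: minimise
$\mathrm{UCV}(h) = \int \hat f^2 - \frac{2}{n}\sum_i \hat f_{-i}(x_i)$,
an unbiased estimate of the first two terms of the integrated squared
error, using the closed form available for the Gaussian kernel. Two
numerical choices are disclosed because the method's sources leave them
open:

* **search range and optimiser** — a 200-point log-spaced grid on
  $[2\cdot\mathrm{median\ NN\ spacing},\ L/4]$ (L = collapsed unit length)
  followed by golden-section refinement around the grid minimum. A flat
  objective (all values within 1e-12) falls back to Silverman's rule with
  a warning.
* **large-sample evaluation** — for $n > 500$ the pairwise sums are
  accumulated over a $2^{17}$-bin pair-distance histogram, each bin
  represented by its mean distance. The error is second order in the bin
  width (measured: ~4e-5 relative at $n = 2000$), far below the
  optimiser's tolerance; for $n \le 500$ the sums are exact, and the
  exact path is what the 1e-6 oracle-equivalence test exercises.

The pointwise variability band exploits the fact that on the square-root
scale the estimator's asymptotic variance does not involve the unknown
density: with $R(K) = \int K^2 = 1/(2\sqrt\pi)$, the half width
$w = z_{(1+\alpha)/2}\sqrt{R(K)/(4nh)}$ is constant in $x$; the edges
$(\sqrt{\hat f} \pm w)^2$ are transformed back, the lower edge clipped at
zero. The band accounts for variability only and ignores smoothing bias —
it is **not** a confidence band and has no nominal coverage probability.
Bias diminishes modes and fills valleys, so where a candidate arises from a
peak in one density against a flat stretch in the other, ignoring the bias
is conservative. Empirically, at the cross-validated bandwidth the 0.99
band covers the true density at a fixed interior point in well over 90% of
simulated replicates (asserted by a seeded test; nominal 99% is not
claimed). The default level is $\alpha = 0.99$.

# Candidate detection and the sensitivity scan

Candidates are maximal runs of consecutive grid points where one band's
lower edge exceeds the other's upper edge. Endpoints are reported at grid
resolution — no sub-grid root finding — because reported hotspots are
orders of magnitude wider than the grid spacing. No minimum length is
imposed: single-grid-point candidates survive detection and are left to
the confirmation test to prune, which keeps the detection stage free of a
tuning parameter.

Robustness to the smoothing level is probed by re-running detection at
$h = h_{\mathrm{opt}} \cdot s$ with the *same* factor $s$ applied to both
vectors' cross-validated bandwidths, over a user grid inside
$[0.05, 20]$ containing 1. Candidates that persist just above and below
$s = 1$ are considered solid; candidates appearing only at small $s$ are
typically spurious fine structure, and heavy oversmoothing either
suppresses candidates or yields unit-scale ones with no sharp localisation.

# Confirmation

For each candidate $H$, $n^{in}$ counts a vector's sites on the hotspot's
strand within $[start, end)$ and $n^{out}$ is that vector's *genome-wide*
total (all units, both strands) minus $n^{in}$. The genome-wide reading of
"outside" keeps the table margins identical across candidates and casts
each test as one comparison of genome-wide propensities; whether "outside"
should instead be per-strand is not derivable from the method's sources
and is fixed here by this choice. The cross-product odds ratio is oriented
to be $\ge 1$ (infinite when the losing vector has no inside counts), the
p-value is the two-sided Fisher exact test, and the 0.95 CI — reported,
never used for significance — is the conditional exact CI when any cell is
$\le 5$ and logit-Wald otherwise. All candidates of one genome-wide run
form a single Bonferroni–Holm family across strands, chromosomes and
winners; ties in p are ordered stably by candidate id. Output is sorted by
adjusted p.

# Annotation

Gene counting is strand-agnostic (1 bp overlap suffices), while site
counting is strand-aware; a targeted fixture asserts the asymmetry. Gene
density is count over genomic length. Expression enrichment compares
present/absent frequencies inside each hotspot against genes outside *all*
confirmed hotspots (the alternative — excluding only the hotspot under
test — is a defensible reading; the all-hotspot background is the one
implemented), Fisher exact with Holm across hotspots; hotspots with no
genes are reported as NA and excluded from the family. Oncogene annotation
is the same machinery with an oncogene/other flags track; no external
census is fetched.

Track densities (reads per bp per hotspot) are compared between HIV- and
MLV-preferred hotspots with either the Welch statistic (default for track
densities; it does not assume equal group variances) or the centred
Mann–Whitney rank sum (default for hotspot lengths), with two-sided
permutation p-values under label shuffling: exhaustive enumeration when
the number of label partitions is at most 20000 (p = count/total),
otherwise `n_perm` random permutations with the add-one estimator
$(1 + \#\{|T^*| \ge |T|\})/(n_{perm}+1)$. The default `n_perm` is 100000
and the seed is recorded in the output metadata. Holm is applied across
tracks.

# The synthetic-data generator

The generator states the world the method assumes, not a tuned fixture:

* **genome** — motif starts at geometric gaps (mean `mean_gap`, default
  370 bp, which yields ≈30% blind sequence under the 20/500 rule — the
  order observed on real chromosomes); all other positions are drawn from
  the motif-free alphabet {A, C, G}, so a scan recovers exactly the
  planted motifs. Defaults: unit length 1e8 bp (a large human arm) and
  1500 sites per vector per unit, the per-arm order of magnitude of a
  ~30,000-site genome-wide screen.
* **sites** — each vector samples from a uniform background over the
  collapsed axis times Gaussian-shaped intensity multipliers
  $1 + (or - 1)\,e^{-(x-c)^2/2\sigma^2}$. With this parameterisation the
  in-bump odds ratio between the bumped and the flat vector equals `or`;
  the truth interval is the full-width-at-half-maximum window, which keeps
  recovery scoring well defined. Bump centers and widths are fractions of
  the collapsed length, so a scenario is invariant to the particular
  genome realisation. Sampling on the collapsed axis and expanding places
  every site in a detectable region by construction.

What the generator does **not** emulate: real base composition and
restriction-site clustering (real gaps are overdispersed relative to
geometric), mappability structure, clonal site recovery, chromatin-driven
background inhomogeneity, and sequencing error. A green planted-recovery
test therefore establishes that the detection-confirmation chain has the
claimed power and false-call behaviour *under the stated sampling model* —
not that real libraries meet that model.

Every generator is deterministic given (spec, seed); all randomness flows
from the single scenario seed.

# Numerical and degenerate-input conventions

* Units where either vector has fewer than `min_sites` (default 10)
  collapsed sites are skipped with a log message: band overlap there would
  reflect lack of data, not equality of densities.
* Fully blind units are flagged degenerate and skipped.
* Sites falling in blind regions of their unit (possible with real data
  and imperfect annotations) are dropped with a count in the log.
* Fisher p-values are clipped at 1 (floating-point overshoot).
* Band edges are recomputed from interpolated $\sqrt{\hat f}$, preserving
  the ordering lower $\le \hat f \le$ upper under interpolation.
* Re-running a configuration reproduces every output byte for byte; each
  table carries the package version, an MD5 configuration hash and the
  seed in `#` header lines.

# Scale of the shipped tests

The test suite runs the stated simulation designs (e.g. 200 null
replicates at n = 1000 per vector for the false-call bound, 100 replicates
at n = 2000 for planted recovery at odds ratio 5 and 2% width) on 1 Mb
units rather than full-size arms, and module tests use 1024–4096-point
grids rather than the $2^{14}$ production default; both scalings are
stated where they occur. The method is scale equivariant (multiplying
positions and bandwidths by a constant changes nothing), so unit length is
a compute knob, not a power knob — power is governed by n, the bump odds
ratio and its width relative to the unit.

# Known limitations

* The band comparison is pointwise; no simultaneous (FDR-style) band
  inference is attempted.
* Bias is ignored by construction; a difference masked by smoothing bias
  stays undiscovered (false negatives in data-poor regions).
* One enzyme, one motif: multi-enzyme digestion unions are out of scope.
* Mappability is not modelled — acceptable for a *comparative* analysis
  where both vectors share the mapping pipeline, not for absolute
  integration-preference estimates.
* The Fisher test treats sites as independent; over-dispersed or clonal
  data will anti-conservatively narrow the confirmation p-values.
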