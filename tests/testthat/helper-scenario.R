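# Small in-code fixtures: units, blind maps and planted-bump scenarios.

identity_map <- function(L = 1e6, strand = "+") {
  u <- analysis_unit("sim1", "q", strand, 0, L)
  build_blind_map(data.frame(start = numeric(0), end = numeric(0)), u)
}

genome_map <- function(L = 1e6, mean_gap = 370, seed = 1, strand = "+") {
  genome <- simulate_motif_genome(L, mean_gap, seed)
  u <- analysis_unit("sim1", "q", strand, 0, L)
  list(genome = genome,
       map = blind_map_from_sequence(genome, u))
}

bump_spec <- function(L, n = 2000, or = 8, width = 0.02, center = 0.5,
                      vector = "A", seed = 1) {
  scenario_spec(
    unit_length = L, n_sites = c(A = n, B = n),
    bumps = data.frame(center = center, width = width, vector = vector,
                       or = or, stringsAsFactors = FALSE),
    vectors = c("A", "B"), seed = seed)
}

null_spec <- function(L, n = 1000, seed = 1) {
  scenario_spec(unit_length = L, n_sites = c(A = n, B = n),
                bumps = data.frame(center = numeric(0), width = numeric(0),
                                   vector = character(0), or = numeric(0),
                                   stringsAsFactors = FALSE),
                vectors = c("A", "B"), seed = seed)
}

# Fraction of each truth interval covered by candidates of the right winner
# (collapsed scale).
truth_coverage <- function(candidates, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    cand <- candidates[candidates$winner == tr$vector, , drop = FALSE]
    if (nrow(cand) == 0L) return(0)
    ov <- pmax(pmin(cand$cend, tr$cend) - pmax(cand$cstart, tr$cstart), 0)
    sum(ov) / (tr$cend - tr$cstart)
  }, numeric(1))
}

# Constant-value variability band over a shared grid (for band-comparison
# unit tests).
const_band <- function(lower, upper, label, L = 1000, m = 128,
                       strand = "+") {
  u <- analysis_unit("c", "q", strand, 0, L)
  est <- structure(list(grid = seq(0, L, length.out = m),
                        values = rep((lower + upper) / 2, m), h = 1,
                        n = 100, unit = u, vector = label,
                        collapsed_length = L),
                   class = "density_estimate")
  b <- structure(list(estimate = est, level = 0.99,
                      half_width_sqrt_scale = NA_real_,
                      lower = rep(lower, m), upper = rep(upper, m)),
                 class = "variability_band")
  b
}
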