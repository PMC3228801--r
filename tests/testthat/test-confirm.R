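# 2x2 odds-ratio exact testing, Holm correction, genome-wide confirmation.

test_that("count_sites is strand-aware and half-open", {
  sites <- data.frame(
    chrom = "c", pos = c(10, 50, 90, 100, 30),
    strand = c("+", "+", "+", "+", "-"),
    vector = c("A", "A", "A", "A", "A"), stringsAsFactors = FALSE)
  hs <- list(chrom = "c", strand = "+", start = 0, end = 100)
  cnt <- count_sites(hs, sites, vectors = "A")
  expect_equal(unname(cnt$A), c(3, 2))  # pos 100 is outside; "-" site outside
  hs2 <- list(chrom = "c", strand = "+", start = 100, end = 200)
  cnt2 <- count_sites(hs2, sites, vectors = "A")
  expect_equal(unname(cnt2$A), c(1, 4))
})

test_that("odds ratio test matches hand-computed OR and enumeration p", {
  r <- odds_ratio_test(10, 90, 10, 90)
  expect_equal(r$or_value, 1)
  expect_equal(r$p_raw, 1)

  r2 <- odds_ratio_test(20, 80, 5, 95)
  expect_equal(r2$or_value, 4.75)
  expect_equal(r2$p_raw, oracle_fisher_p(20, 80, 5, 95), tolerance = 1e-10)
  expect_equal(r2$winner, "A")

  r3 <- odds_ratio_test(5, 95, 0, 100)
  expect_equal(r3$or_value, Inf)
  expect_equal(r3$p_raw, oracle_fisher_p(5, 95, 0, 100), tolerance = 1e-10)

  expect_error(odds_ratio_test(0, 0, 5, 5), "zero total")
  expect_error(odds_ratio_test(-1, 5, 5, 5), "negative")
})

test_that("Fisher p equals hypergeometric enumeration across margins", {
  with_seed(19, {
    margins <- expand.grid(m = c(3, 10, 25, 60), n = c(4, 12, 60),
                           k_frac = c(0.2, 0.5, 0.8))
    for (i in seq_len(nrow(margins))) {
      m <- margins$m[i]; n2 <- margins$n[i]
      k <- max(1, round(margins$k_frac[i] * (m + n2) / 2))
      for (a in max(0, k - n2):min(k, m)) {
        b <- m - a; cc <- k - a; d <- n2 - cc
        got <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
        expect_equal(got, oracle_fisher_p(a, b, cc, d), tolerance = 1e-9,
                     info = sprintf("table %d %d %d %d", a, b, cc, d))
      }
    }
  })
})

test_that("orientation: swapping vectors preserves OR and p, flips winner", {
  with_seed(29, {
    for (rep in 1:10) {
      cnts <- rpois(4, 30) + c(5, 1, 1, 1)
      r1 <- odds_ratio_test(cnts[1], cnts[2], cnts[3], cnts[4],
                            labels = c("A", "B"))
      r2 <- odds_ratio_test(cnts[3], cnts[4], cnts[1], cnts[2],
                            labels = c("A", "B"))
      expect_equal(r1$or_value, r2$or_value)
      expect_equal(r1$p_raw, r2$p_raw)
      expect_gte(r1$or_value, 1)
      if (r1$or_value > 1) expect_false(r1$winner == r2$winner)
    }
  })
})

test_that("Holm step-down matches hand execution and p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  with_seed(37, {
    for (rep in 1:20) {
      p <- runif(sample(1:40, 1))
      adj <- holm_adjust(p)
      expect_equal(adj, p.adjust(p, "holm"))
      m <- length(p)
      # bounded by plain Bonferroni, bounded below by rank-divided Bonferroni
      expect_true(all(adj <= pmin(p * m, 1) + 1e-12))
      expect_true(all(adj >= p - 1e-12))
    }
  })
})

test_that("confirm runs one genome-wide Holm family sorted by adjusted p", {
  # three planted bumps (two for A, one for B) on two strands
  L <- 1e6
  cands <- NULL; all_sites <- NULL
  for (std in c("+", "-")) {
    map <- identity_map(L, strand = std)
    spec <- scenario_spec(
      unit_length = L, n_sites = c(A = 1500, B = 1500),
      bumps = if (std == "+")
        data.frame(center = c(0.25, 0.7), width = c(0.03, 0.025),
                   vector = c("A", "B"), or = c(8, 10))
      else
        data.frame(center = 0.5, width = 0.03, vector = "A", or = 8),
      vectors = c("A", "B"), seed = 404)
    sim <- simulate_sites(spec, map, seed = 404 + (std == "-"))
    res <- detect_unit(sim$sites$A, sim$sites$B, grid_size = 2048)
    cands <- rbind(cands, to_genomic(res$candidates, map))
    all_sites <- rbind(all_sites, sim$genomic)
  }
  cands <- assign_candidate_ids(cands)
  conf <- confirm(cands, all_sites, alpha = 0.05)
  # family size equals the candidate count (bookkeeping)
  expect_equal(nrow(conf), nrow(cands))
  expect_true(all(conf$p_adj >= conf$p_raw))
  expect_false(is.unsorted(conf$p_adj))
  # all three planted bumps confirmed, no false confirmation
  sig <- conf[conf$significant, ]
  truth <- rbind(
    data.frame(strand = "+", lo = 0.25 - 0.015, hi = 0.25 + 0.015, w = "A"),
    data.frame(strand = "+", lo = 0.7 - 0.0125, hi = 0.7 + 0.0125, w = "B"),
    data.frame(strand = "-", lo = 0.5 - 0.015, hi = 0.5 + 0.015, w = "A"))
  truth$lo <- truth$lo * L; truth$hi <- truth$hi * L
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(sig$strand == truth$strand[i] & sig$winner == truth$w[i] &
        sig$start < truth$hi[i] & sig$end > truth$lo[i])
  }, logical(1))
  expect_true(all(hit))
  covered <- vapply(seq_len(nrow(sig)), function(j) {
    any(truth$strand == sig$strand[j] & truth$w == sig$winner[j] &
        sig$start[j] < truth$hi & sig$end[j] > truth$lo)
  }, logical(1))
  expect_true(all(covered))
  # length column arithmetic
  expect_equal(conf$length, conf$end - conf$start)
})

test_that("label-shuffled null yields no confirmations in >= 95% of runs", {
  # scaled world: n = 600 per vector on a 1 Mb unit, 100 replicates
  L <- 1e6
  map <- identity_map(L)
  n_conf <- with_seed(55, replicate(100, {
    x <- runif(1200, 0, L)
    lab <- sample(rep(c("A", "B"), each = 600))
    sa <- site_set(map$unit, "A", x[lab == "A"], L)
    sb <- site_set(map$unit, "B", x[lab == "B"], L)
    res <- detect_unit(sa, sb, grid_size = 1024)
    cand <- assign_candidate_ids(to_genomic(res$candidates, map))
    if (nrow(cand) == 0L) return(0L)
    sites <- data.frame(chrom = "sim1", pos = floor(x), strand = "+",
                        vector = lab, stringsAsFactors = FALSE)
    sum(confirm(cand, sites)$significant)
  }))
  expect_gte(mean(n_conf == 0L), 0.95)
})

test_that("confirm handles an empty candidate list", {
  sites <- data.frame(chrom = "c", pos = c(1, 2), strand = "+",
                      vector = c("A", "B"), stringsAsFactors = FALSE)
  cand <- assign_candidate_ids(
    data.frame(chrom = character(), arm = character(), strand = character(),
               cstart = numeric(), cend = numeric(), winner = character(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE))
  out <- confirm(cand, sites)
  expect_equal(nrow(out), 0L)
})
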