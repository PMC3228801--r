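# Gene overlap statistics, expression enrichment, track densities and
# permutation group comparisons.

test_that("gene counts and normalized density follow the overlap rule", {
  hs <- data.frame(id = "h1", chrom = "c", start = 0, end = 1e6,
                   stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "c", start = seq(1000, by = 10000,
                                               length.out = 50),
                      end = seq(1000, by = 10000, length.out = 50) + 5000,
                      stringsAsFactors = FALSE)
  out <- overlap_stats(hs, genes)
  expect_equal(out$n_genes, 50L)
  expect_equal(out$gene_density, 5e-5)
  # a gene straddling the boundary counts once
  hs2 <- data.frame(id = "h2", chrom = "c", start = 100, end = 200)
  g2 <- data.frame(chrom = "c", start = 150, end = 500)
  expect_equal(overlap_stats(hs2, g2)$n_genes, 1L)
  # zero-overlap gene does not count (half-open: touching is not overlap)
  g3 <- data.frame(chrom = "c", start = 200, end = 500)
  expect_equal(overlap_stats(hs2, g3)$n_genes, 0L)
})

test_that("indexed overlap counting agrees with a quadratic scan", {
  with_seed(61, {
    L <- 1e6
    hs <- data.frame(id = paste0("h", 1:40), chrom = "c",
                     start = s <- floor(runif(40, 0, L - 1e4)),
                     end = s + floor(runif(40, 100, 1e4)),
                     stringsAsFactors = FALSE)
    genes <- data.frame(chrom = "c",
                        start = gs <- floor(runif(1000, 0, L - 5000)),
                        end = gs + floor(runif(1000, 50, 5000)),
                        stringsAsFactors = FALSE)
    got <- overlap_stats(hs, genes)$n_genes
    brute <- vapply(seq_len(nrow(hs)), function(i) {
      sum(genes$start < hs$end[i] & genes$end > hs$start[i])
    }, numeric(1))
    expect_equal(as.numeric(got), brute)
  })
})

test_that("expression enrichment: symmetric and degenerate 2x2 cases", {
  hs <- data.frame(id = c("h1"), chrom = "c", start = 0, end = 1000,
                   stringsAsFactors = FALSE)
  mk_genes <- function(n_in_p, n_in_a, n_out_p, n_out_a) {
    n <- n_in_p + n_in_a + n_out_p + n_out_a
    data.frame(
      chrom = "c",
      start = c(seq_len(n_in_p + n_in_a) * 2,            # inside [0,1000)
                5000 + seq_len(n_out_p + n_out_a) * 10), # outside
      end = c(seq_len(n_in_p + n_in_a) * 2 + 1,
              5000 + seq_len(n_out_p + n_out_a) * 10 + 1),
      name = paste0("g", seq_len(n)), stringsAsFactors = FALSE)
  }
  flags_for <- function(genes, n_in_p, n_in_a, n_out_p, n_out_a) {
    data.frame(name = genes$name,
               flag = c(rep("present", n_in_p), rep("absent", n_in_a),
                        rep("present", n_out_p), rep("absent", n_out_a)),
               stringsAsFactors = FALSE)
  }
  g <- mk_genes(30, 10, 3000, 1000)
  f <- flags_for(g, 30, 10, 3000, 1000)
  out <- expression_enrichment(hs, g, f)
  expect_equal(out$or, 1)
  expect_equal(out$p_raw, 1)

  g2 <- mk_genes(40, 0, 500, 500)
  f2 <- flags_for(g2, 40, 0, 500, 500)
  out2 <- expression_enrichment(hs, g2, f2)
  expect_equal(out2$or, Inf)
  expect_equal(out2$p_raw, oracle_fisher_p(40, 0, 500, 500),
               tolerance = 1e-9)

  # hotspot with zero genes: NA, excluded from the Holm family
  hs3 <- rbind(hs, data.frame(id = "h_empty", chrom = "c",
                              start = 2000, end = 2100))
  out3 <- expression_enrichment(hs3, g, f)
  expect_true(is.na(out3$p_raw[out3$id == "h_empty"]))
  expect_true(is.na(out3$p_adj[out3$id == "h_empty"]))
  expect_false(any(is.na(out3$p_adj[out3$id != "h_empty"])))
})

test_that("uniform expression flags produce <= 5% raw-significant hotspots", {
  with_seed(71, {
    L <- 1e7
    hs <- data.frame(id = paste0("h", 1:40), chrom = "c",
                     start = s <- seq(0, L - 3e5, length.out = 40),
                     end = s + 2e5, stringsAsFactors = FALSE)
    n_genes <- 4000
    genes <- data.frame(chrom = "c",
                        start = gs <- floor(runif(n_genes, 0, L - 1000)),
                        end = gs + 900,
                        name = paste0("g", seq_len(n_genes)),
                        stringsAsFactors = FALSE)
    reps <- replicate(10, {
      flags <- data.frame(name = genes$name,
                          flag = ifelse(runif(n_genes) < 0.7, "present",
                                        "absent"), stringsAsFactors = FALSE)
      out <- expression_enrichment(hs, genes, flags)
      mean(out$p_raw <= 0.05, na.rm = TRUE)
    })
    expect_lte(mean(reps), 0.05)
  })
})

test_that("track density counts read positions per basepair", {
  hs <- data.frame(id = "h1", chrom = "c", start = 0, end = 150000,
                   stringsAsFactors = FALSE)
  reads <- data.frame(chrom = "c", start = seq(0, 149500, length.out = 300))
  expect_equal(track_density(hs, reads), 0.002)
  reads_out <- data.frame(chrom = "c", start = reads$start + 200000)
  expect_equal(track_density(hs, reads_out), 0)
  expect_equal(track_density(hs, reads[0, , drop = FALSE]), 0)
})

test_that("permutation comparison matches exhaustive enumeration", {
  cmp <- compare_group_densities(c(1, 2, 3), c(4, 5, 6), "mannwhitney")
  expect_true(cmp$exhaustive)
  expect_equal(cmp$p_perm, 2 / 20)
  # identical groups: p = 1
  cmp2 <- compare_group_densities(c(1, 2), c(1, 2), "mannwhitney")
  expect_equal(cmp2$p_perm, 1)
  # group of size 1 with welch falls back with a warning
  expect_warning(cmp3 <- compare_group_densities(1, c(2, 3), "welch"),
                 "Mann-Whitney")
  expect_equal(cmp3$statistic, "mannwhitney")
  expect_error(compare_group_densities(numeric(0), 1:3), "non-empty")
})

test_that("exhaustive Mann-Whitney permutation p equals the exact test", {
  with_seed(83, {
    for (rep in 1:10) {
      na <- sample(3:5, 1); nb <- sample(3:5, 1)
      a <- sample(1:100, na); b <- sample(101:200, nb) - sample(0:150, nb)
      # force distinct values for the exact reference
      v <- unique(c(a, b)); if (length(v) < na + nb) next
      a <- v[1:na]; b <- v[(na + 1):(na + nb)]
      got <- compare_group_densities(a, b, "mannwhitney")$p_perm
      ref <- wilcox.test(a, b, exact = TRUE)$p.value
      expect_equal(got, ref, tolerance = 1e-12)
    }
  })
})

test_that("welch permutation test detects a 2-sigma shift across tracks", {
  # 10 tracks, one shifted by 2 SD (n = 40 per group); Holm across tracks
  with_seed(91, {
    hits <- replicate(20, {
      dens <- do.call(rbind, lapply(1:10, function(tr) {
        delta <- if (tr == 1) 2 else 0
        data.frame(track = paste0("t", tr),
                   group = rep(c("A", "B"), each = 40),
                   value = c(rnorm(40, delta), rnorm(40)),
                   stringsAsFactors = FALSE)
      }))
      out <- compare_tracks(dens, statistic = "welch", n_perm = 1999,
                            seed = sample.int(1e6, 1))
      out$p_adj[out$track == "t1"] < 0.01
    })
    expect_gte(mean(hits), 0.95)
  })
})

test_that("length statistics: medians per winner and permutation p", {
  conf <- data.frame(
    winner = c(rep("hiv", 3), rep("mlv", 3)),
    start = rep(0, 6), end = c(2, 4, 6, 1, 3, 5),
    stringsAsFactors = FALSE)
  ls <- length_stats(conf)
  expect_equal(ls$stats$median[ls$stats$winner == "hiv"], 4)
  expect_equal(ls$stats$median[ls$stats$winner == "mlv"], 3)
  # even group size: median is the mean of the middle pair
  conf2 <- data.frame(winner = rep("hiv", 4), start = 0, end = c(1, 2, 3, 10))
  expect_equal(length_stats(conf2)$stats$median, 2.5)
  expect_true(is.na(length_stats(conf2)$p_perm))
})

test_that("gene counting is strand-agnostic; site counting is strand-aware", {
  hs <- data.frame(id = "h1", chrom = "c", strand = "+", start = 0,
                   end = 1000, stringsAsFactors = FALSE)
  # a gene on the minus strand still counts
  genes <- data.frame(chrom = "c", start = 100, end = 200, strand = "-",
                      stringsAsFactors = FALSE)
  expect_equal(overlap_stats(hs, genes)$n_genes, 1L)
  # a site on the minus strand does not
  sites <- data.frame(chrom = "c", pos = 150, strand = "-", vector = "A",
                      stringsAsFactors = FALSE)
  expect_equal(unname(count_sites(hs, sites, "A")$A), c(0, 1))
})
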