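## Seeded synthetic-data generation: genomes with planted restriction
## motifs, two-vector site samples from a smooth background plus localized
## intensity bumps, and complete on-disk scenarios runnable end to end.

#' Scenario specification for the synthetic generator
#'
#' The stated world the generator emulates: one chromosome arm of
#' `unit_length` bp, restriction motifs at geometric gaps (giving roughly
#' 30% blind sequence at the default 20/500 detectability rule for the
#' default `mean_gap`), and, per strand, an i.i.d. integration sample for
#' each of two vectors drawn from a uniform background over detectable
#' positions times Gaussian-shaped intensity bumps.  A bump of odds ratio
#' `or` multiplies the intensity of *one* vector by up to `or` at its
#' center; its truth interval is the full-width-at-half-maximum window.
#'
#' @param unit_length Arm length in bp (default 1e8, the scale of a large
#'   human chromosome arm).
#' @param mean_gap Mean motif gap in bp (>= 24; default 370, which yields
#'   about 30% blind sequence under the 20/500 rule).
#' @param n_sites Named pair: sites per vector per unit (default 1500
#'   each, the order of magnitude of per-arm counts in a ~30,000-site
#'   genome-wide screen).
#' @param bumps Data.frame with columns `center`, `width` (fractions of
#'   the *collapsed* length in (0,1); `width` is the FWHM), `vector`
#'   (label), `or` (> 1).
#' @param vectors Character pair of vector labels.
#' @param strands Strands to simulate sites on (default `"+"`).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(unit_length = 1e8, mean_gap = 370,
                          n_sites = c(HIV = 1500, MLV = 1500),
                          bumps = data.frame(
                            center = c(0.25, 0.60, 0.85),
                            width = c(0.040, 0.030, 0.025),
                            vector = c("HIV", "MLV", "HIV"),
                            or = c(8, 10, 6),
                            stringsAsFactors = FALSE),
                          vectors = c("HIV", "MLV"),
                          strands = "+", seed = 1L) {
  stopifnot(mean_gap >= 24, unit_length > 0)
  if (nrow(bumps)) {
    stopifnot(all(bumps$or > 1), all(bumps$width > 0),
              all(bumps$center > 0 & bumps$center < 1),
              all(bumps$vector %in% vectors))
  }
  structure(
    list(unit_length = unit_length, mean_gap = mean_gap,
         n_sites = n_sites, bumps = bumps, vectors = vectors,
         strands = strands, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Simulate a genome with restriction motifs at geometric gaps
#'
#' Motif (TTAA) start positions are placed with inter-start distances
#' `4 + Geometric(1 / (mean_gap - 3))`, so consecutive motifs never
#' overlap and the mean gap is `mean_gap`.  All other positions are drawn
#' from the motif-free alphabet `{A, C, G}`: with no `T` outside planted
#' motifs, no accidental TTAA can arise, so a motif scan recovers exactly
#' the planted positions.
#'
#' @param length Sequence length in bp.
#' @param mean_gap Mean distance between consecutive motif starts (>= 24).
#' @param seed Integer seed.
#' @return A character string of length `length`.
#' @export
simulate_motif_genome <- function(length, mean_gap = 370, seed = 1L) {
  stopifnot(mean_gap >= 24)
  set.seed(seed)
  length <- as.numeric(length)
  # motif start positions, 0-based
  p <- 1 / (mean_gap - 3)
  n_exp <- ceiling(length / mean_gap * 1.3) + 10L
  gaps <- 4 + rgeom(n_exp, p)
  pos <- cumsum(c(rgeom(1L, p), gaps))
  while (pos[base::length(pos)] < length) {
    pos <- c(pos, pos[base::length(pos)] + cumsum(4 + rgeom(n_exp, p)))
  }
  pos <- pos[pos + 4 <= length]

  bases <- c("A", "C", "G")
  chunk <- 1e7
  nchunks <- ceiling(length / chunk)
  parts <- character(nchunks)
  for (ci in seq_len(nchunks)) {
    from <- (ci - 1) * chunk            # 0-based chunk window [from, to)
    to <- min(from + chunk, length)
    raw_chunk <- charToRaw(paste(bases, collapse = ""))[
      sample.int(3L, to - from, replace = TRUE)]
    # overwrite planted motifs intersecting this chunk
    for (s in pos[pos + 4 > from & pos < to]) {
      mo <- charToRaw("TTAA")
      for (k in 0:3) {
        g <- s + k
        if (g >= from && g < to) raw_chunk[g - from + 1] <- mo[k + 1]
      }
    }
    parts[ci] <- rawToChar(raw_chunk)
  }
  paste(parts, collapse = "")
}

# Mixture density on the collapsed axis [0, L): uniform background plus
# Gaussian intensity multipliers 1 + (or-1) * exp(-(x-c)^2 / (2 sigma^2)).
# width is the FWHM, so sigma = width / (2 sqrt(2 log 2)).
bump_params <- function(bumps, L) {
  if (is.null(bumps) || nrow(bumps) == 0L)
    return(data.frame(center = numeric(0), sigma = numeric(0),
                      vector = character(0), or = numeric(0),
                      weight = numeric(0)))
  data.frame(
    center = bumps$center * L,
    sigma = bumps$width * L / (2 * sqrt(2 * log(2))),
    vector = bumps$vector,
    or = bumps$or,
    weight = (bumps$or - 1) * bumps$width * L /
      (2 * sqrt(2 * log(2))) * sqrt(2 * pi),
    stringsAsFactors = FALSE
  )
}

#' Simulate integration sites for two vectors on one unit
#'
#' Draws each vector's sample from its mixture (uniform background over
#' the collapsed axis plus that vector's bumps), rounds to whole
#' basepairs, and expands to genomic positions, so every site lies in a
#' detectable (non-blind) region by construction.
#'
#' @param spec A [scenario_spec()].
#' @param map The unit's [build_blind_map()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return List with `sites` (named list of [site_set()]s), `genomic`
#'   (data.frame `chrom`, `pos`, `strand`, `vector`) and `truth`
#'   (data.frame of FWHM truth intervals: `vector`, `cstart`, `cend`,
#'   `start`, `end`).
#' @export
simulate_sites <- function(spec, map, seed = spec$seed) {
  L <- map$collapsed_length
  if (L <= 0) stop("simulate_sites: unit has no detectable length")
  if (any(spec$n_sites > 10 * L))
    stop("simulate_sites: requested n exceeds 10x the detectable length")
  set.seed(seed)
  bp <- bump_params(spec$bumps, L)
  out_sites <- list(); out_gen <- NULL
  for (v in spec$vectors) {
    n <- spec$n_sites[[v]]
    vb <- bp[bp$vector == v, , drop = FALSE]
    w <- c(L, vb$weight)             # component weights: background, bumps
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    x <- numeric(n)
    bg <- comp == 1L
    x[bg] <- runif(sum(bg), 0, L)
    for (j in seq_len(nrow(vb))) {
      sel <- comp == j + 1L
      m <- sum(sel)
      if (m) {
        draw <- rnorm(m, vb$center[j], vb$sigma[j])
        # bumps sit well inside the unit; re-draw the rare escapees
        while (any(bad <- draw < 0 | draw >= L))
          draw[bad] <- rnorm(sum(bad), vb$center[j], vb$sigma[j])
        x[sel] <- draw
      }
    }
    cx <- pmin(floor(x), L - 1)
    out_sites[[v]] <- site_set(map$unit, v, cx, L)
    out_gen <- rbind(out_gen, data.frame(
      chrom = map$unit$chrom, pos = expand_position(map, sort(cx)),
      strand = map$unit$strand, vector = v, stringsAsFactors = FALSE))
  }
  truth <- NULL
  if (nrow(bp)) {
    hw <- bp$sigma * sqrt(2 * log(2))          # FWHM half-width
    truth <- data.frame(vector = bp$vector,
                        cstart = pmax(bp$center - hw, 0),
                        cend = pmin(bp$center + hw, L),
                        stringsAsFactors = FALSE)
    gi <- t(vapply(seq_len(nrow(truth)), function(i)
      expand_interval(map, c(truth$cstart[i], truth$cend[i])), numeric(2)))
    truth$start <- gi[, 1L]; truth$end <- gi[, 2L]
  }
  list(sites = out_sites, genomic = out_gen, truth = truth)
}

#' Write a complete self-consistent scenario to disk
#'
#' Generates the genome FASTA, arm definitions, per-strand site samples,
#' a random gene track with expression flags, a background read track,
#' and the truth table of planted bumps, all consumable by the package's
#' own readers and by [run_pipeline()].
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @param chrom Chromosome name (default `"sim1"`).
#' @param n_genes Genes in the synthetic gene track (default 200).
#' @param gene_length Gene length in bp (default `unit_length / 500`).
#' @param n_reads Read positions in the synthetic read track (default 5000).
#' @param min_read,max_frag,motif Blind-region parameters used to place
#'   sites in detectable regions.
#' @return Named list of written file paths, invisibly; also returns the
#'   per-strand `blind_map`s and truth in the `objects` element.
#' @export
make_scenario <- function(spec, dir, chrom = "sim1", n_genes = 200,
                          gene_length = spec$unit_length / 500,
                          n_reads = 5000, min_read = 20, max_frag = 500,
                          motif = "TTAA") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_motif_genome(spec$unit_length, spec$mean_gap, spec$seed)
  fasta <- file.path(dir, "genome.fa")
  dss <- Biostrings::DNAStringSet(genome)
  names(dss) <- chrom
  Biostrings::writeXStringSet(dss, fasta)

  arms <- file.path(dir, "arms.bed")
  write_bed6(data.frame(chrom = chrom, start = 0, end = spec$unit_length,
                        name = "q", stringsAsFactors = FALSE), arms)

  ms <- scan_motif(genome, motif)
  all_gen <- NULL; maps <- list(); truth_all <- NULL
  for (k in seq_along(spec$strands)) {
    std <- spec$strands[k]
    unit <- analysis_unit(chrom, "q", std, 0, spec$unit_length)
    blind <- derive_blind_intervals(ms, unit, min_read, max_frag)
    map <- build_blind_map(blind, unit)
    sim <- simulate_sites(spec, map, seed = spec$seed + k)
    all_gen <- rbind(all_gen, sim$genomic)
    maps[[unit_id(unit)]] <- map
    if (!is.null(sim$truth))
      truth_all <- rbind(truth_all, cbind(chrom = chrom, strand = std,
                                          sim$truth))
  }
  sites <- file.path(dir, "sites.bed")
  write_bed6(data.frame(chrom = all_gen$chrom, start = all_gen$pos,
                        end = all_gen$pos + 1, name = all_gen$vector,
                        strand = all_gen$strand, stringsAsFactors = FALSE),
             sites)

  # annotation tracks: genes uniform over the unit, flags and reads random
  set.seed(spec$seed + 1000L)
  gs <- sort(runif(n_genes, 0, spec$unit_length - gene_length))
  genes_df <- data.frame(chrom = chrom, start = floor(gs),
                         end = floor(gs) + gene_length,
                         name = sprintf("gene_%04d", seq_len(n_genes)),
                         stringsAsFactors = FALSE)
  genes <- file.path(dir, "genes.bed")
  write_bed6(genes_df, genes)
  flags <- file.path(dir, "expression.tsv")
  write.table(data.frame(name = genes_df$name,
                         flag = ifelse(rbinom(n_genes, 1, 0.7) == 1,
                                       "present", "absent")),
              flags, sep = "\t", quote = FALSE, row.names = FALSE)
  reads <- file.path(dir, "reads.bed")
  rp <- floor(runif(n_reads, 0, spec$unit_length - 1))
  write_bed6(data.frame(chrom = chrom, start = rp, end = rp + 1,
                        name = "read", stringsAsFactors = FALSE), reads)

  truth <- file.path(dir, "truth.tsv")
  if (!is.null(truth_all))
    write.table(truth_all, truth, sep = "\t", quote = FALSE,
                row.names = FALSE)

  invisible(list(fasta = fasta, arms = arms, sites = sites, genes = genes,
                 expression = flags, reads = reads, truth = truth,
                 objects = list(maps = maps, truth = truth_all)))
}
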