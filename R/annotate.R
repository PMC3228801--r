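## Annotation of confirmed hotspots against interval tracks: gene counts
## and densities, expression enrichment, chromatin-mark densities and
## length statistics.  Gene counting is strand-agnostic (a gene counts for
## a hotspot on either strand); site counting in the confirmation step is
## strand-aware.

hotspots_granges <- function(hotspots) {
  GenomicRanges::GRanges(
    seqnames = hotspots$chrom,
    ranges = IRanges::IRanges(start = hotspots$start + 1, end = hotspots$end)
  )
}

track_granges <- function(track) {
  end <- if ("end" %in% names(track)) track$end else track$start + 1
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1, end = end)
  )
}

#' Per-hotspot gene counts and normalized gene density
#'
#' A gene counts when it overlaps the hotspot by at least 1 bp, regardless
#' of gene strand; density is the count divided by the hotspot's genomic
#' length (genes per bp).
#'
#' @param hotspots Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `id`.
#' @param genes Data.frame of gene intervals: `chrom`, `start`, `end`
#'   (0-based half-open), optionally `name`.
#' @return The hotspot data.frame with `n_genes` and `gene_density` added.
#' @export
overlap_stats <- function(hotspots, genes) {
  if (nrow(hotspots) == 0L) {
    hotspots$n_genes <- integer(0); hotspots$gene_density <- numeric(0)
    return(hotspots)
  }
  cnt <- GenomicRanges::countOverlaps(hotspots_granges(hotspots),
                                      track_granges(genes))
  hotspots$n_genes <- as.integer(cnt)
  hotspots$gene_density <- cnt / (hotspots$end - hotspots$start)
  hotspots
}

#' Expression enrichment of hotspot genes versus the genomic background
#'
#' For each hotspot, compares the frequency of expressed (`present`) genes
#' inside the hotspot with the frequency among genes outside *all*
#' hotspots, by a two-sided Fisher exact test; Holm correction across the
#' hotspots.  Hotspots containing zero genes are reported with `NA` and
#' excluded from the Holm family.
#'
#' @param hotspots Data.frame with `id`, `chrom`, `start`, `end`.
#' @param genes Gene track data.frame (`chrom`, `start`, `end`, `name`).
#' @param flags Data.frame of per-gene expression calls: `name`,
#'   `flag` in `{"present", "absent"}`.
#' @return Data.frame per hotspot: `id`, `n_present_in`, `n_absent_in`,
#'   `n_present_out`, `n_absent_out`, `or`, `p_raw`, `p_adj`.
#' @export
expression_enrichment <- function(hotspots, genes, flags) {
  if (!all(flags$flag %in% c("present", "absent")))
    stop("expression_enrichment: flags must be 'present' or 'absent'")
  genes <- merge(genes, flags, by = "name", sort = FALSE)
  gg <- track_granges(genes)
  hg <- hotspots_granges(hotspots)
  ov <- GenomicRanges::findOverlaps(gg, hg)
  in_any <- rep(FALSE, nrow(genes))
  in_any[S4Vectors::queryHits(ov)] <- TRUE
  present <- genes$flag == "present"
  bg_present <- sum(present & !in_any)
  bg_absent <- sum(!present & !in_any)

  rows <- lapply(seq_len(nrow(hotspots)), function(i) {
    hit <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]
    a <- sum(present[hit]); b <- length(hit) - a
    if ((a + b) == 0L) {
      return(data.frame(id = hotspots$id[i], n_present_in = 0L,
                        n_absent_in = 0L, n_present_out = bg_present,
                        n_absent_out = bg_absent, or = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    or <- (a / b) / (bg_present / bg_absent)
    p <- min(fisher.test(matrix(c(a, b, bg_present, bg_absent), nrow = 2,
                                byrow = TRUE))$p.value, 1)
    data.frame(id = hotspots$id[i], n_present_in = a, n_absent_in = b,
               n_present_out = bg_present, n_absent_out = bg_absent,
               or = or, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adj[ok] <- holm_adjust(out$p_raw[ok])
  out
}

#' Read density of a positional track within hotspots
#'
#' E.g. ChIP-seq reads of a histone modification: the number of read
#' positions falling in the hotspot divided by the hotspot's genomic
#' length.
#'
#' @param hotspots Data.frame with `chrom`, `start`, `end`.
#' @param reads Data.frame of read positions: `chrom`, `start` (0-based
#'   bp; an `end` column, if present, is ignored and reads counted by
#'   their start).
#' @return Numeric density per hotspot (reads per bp).
#' @export
track_density <- function(hotspots, reads) {
  if (nrow(hotspots) == 0L) return(numeric(0))
  rg <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1, width = 1))
  cnt <- GenomicRanges::countOverlaps(hotspots_granges(hotspots), rg)
  cnt / (hotspots$end - hotspots$start)
}

welch_stat <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) +
                             stats::var(b) / length(b))
}

mw_stat <- function(a, b) {
  # rank-sum statistic centred at its null mean (equivalent to U - nA*nB/2)
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + length(b) + 1) / 2
}

#' Permutation two-group comparison (Welch or Mann-Whitney)
#'
#' Two-sided permutation test under label shuffling.  When the number of
#' distinct label partitions is at most `max_exhaustive`, all partitions
#' are enumerated and `p = #\{|T_perm| >= |T_obs|\} / #partitions`;
#' otherwise `n_perm` random permutations give
#' `p = (1 + #\{|T_perm| >= |T_obs|\}) / (n_perm + 1)`.
#'
#' @param values_a,values_b Numeric group values (both non-empty).
#' @param statistic `"welch"` (unequal-variance t) or `"mannwhitney"`
#'   (centred rank sum).  A group of size 1 forces `"mannwhitney"` with a
#'   warning (the Welch statistic needs a variance per group).
#' @param n_perm Random permutations (default 100000).
#' @param seed Optional integer seed for the random permutations.
#' @param max_exhaustive Enumeration threshold (default 20000 partitions).
#' @return An object of class `group_comparison`: list with `statistic`,
#'   `t_obs`, `p_perm`, `exhaustive`, group `means`, `sds` and `n`.
#' @export
compare_group_densities <- function(values_a, values_b,
                                    statistic = c("welch", "mannwhitney"),
                                    n_perm = 100000, seed = NULL,
                                    max_exhaustive = 20000) {
  statistic <- match.arg(statistic)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (!length(a) || !length(b))
    stop("compare_group_densities: both groups must be non-empty")
  if (statistic == "welch" && (length(a) == 1L || length(b) == 1L)) {
    warning("group of size 1: falling back to Mann-Whitney")
    statistic <- "mannwhitney"
  }
  stat <- if (statistic == "welch") welch_stat else mw_stat
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  t_obs <- stat(a, b)

  n_comb <- choose(n, na)
  if (n_comb <= max_exhaustive) {
    idx <- utils::combn(n, na)
    perm <- apply(idx, 2L, function(k) stat(pool[k], pool[-k]))
    p <- sum(abs(perm) >= abs(t_obs) - 1e-12) / n_comb
    exhaustive <- TRUE
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    hits <- 0L
    for (r in seq_len(n_perm)) {
      k <- sample.int(n, na)
      if (abs(stat(pool[k], pool[-k])) >= abs(t_obs) - 1e-12)
        hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    exhaustive <- FALSE
  }
  structure(
    list(statistic = statistic, t_obs = t_obs, p_perm = p,
         exhaustive = exhaustive,
         means = c(a = mean(a), b = mean(b)),
         sds = c(a = sd(a), b = sd(b)),
         n = c(a = na, b = length(b))),
    class = "group_comparison"
  )
}

#' Compare track densities between hotspot groups across several tracks
#'
#' Computes, for each track, the per-group mean and SD of the per-hotspot
#' densities and a permutation p-value, then applies Holm across tracks.
#'
#' @param densities Long data.frame: `track`, `group`, `value` with
#'   exactly two groups.
#' @param statistic,n_perm,seed Passed to [compare_group_densities()].
#' @return Data.frame per track: `track`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `p_perm`, `p_adj` (groups in alphabetical order).
#' @export
compare_tracks <- function(densities, statistic = "welch",
                           n_perm = 100000, seed = NULL) {
  groups <- sort(unique(densities$group))
  if (length(groups) != 2L)
    stop("compare_tracks: need exactly two groups")
  tracks <- unique(densities$track)
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[i]
    va <- densities$value[densities$track == tr & densities$group == groups[1L]]
    vb <- densities$value[densities$track == tr & densities$group == groups[2L]]
    cmp <- compare_group_densities(va, vb, statistic = statistic,
                                   n_perm = n_perm,
                                   seed = if (is.null(seed)) NULL
                                          else seed + i)
    data.frame(track = tr, mean_a = cmp$means[["a"]], sd_a = cmp$sds[["a"]],
               mean_b = cmp$means[["b"]], sd_b = cmp$sds[["b"]],
               p_perm = cmp$p_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_adjust(out$p_perm)
  out
}

#' Length statistics of confirmed hotspots per winner
#'
#' Medians (plus min/max) of genomic lengths per winner group and a
#' Mann-Whitney permutation p-value for the group difference.
#'
#' @param confirmed A [confirm()] table (uses rows with
#'   `significant == TRUE` when that column exists).
#' @param n_perm,seed Passed to [compare_group_densities()].
#' @return List with `stats` (data.frame per winner: `winner`, `n`,
#'   `median`, `min`, `max`) and `p_perm` (NA when a group is empty).
#' @export
length_stats <- function(confirmed, n_perm = 100000, seed = NULL) {
  if ("significant" %in% names(confirmed))
    confirmed <- confirmed[confirmed$significant, , drop = FALSE]
  len <- confirmed$end - confirmed$start
  winners <- sort(unique(confirmed$winner))
  st <- do.call(rbind, lapply(winners, function(w) {
    l <- len[confirmed$winner == w]
    data.frame(winner = w, n = length(l), median = median(l),
               min = min(l), max = max(l), stringsAsFactors = FALSE)
  }))
  p <- NA_real_
  if (length(winners) == 2L) {
    p <- compare_group_densities(len[confirmed$winner == winners[1L]],
                                 len[confirmed$winner == winners[2L]],
                                 statistic = "mannwhitney",
                                 n_perm = n_perm, seed = seed)$p_perm
  }
  list(stats = st, p_perm = p)
}
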