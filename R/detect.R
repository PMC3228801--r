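## Candidate comparative hotspots: maximal segments where two vectors'
## variability bands are disjoint, plus the smoothing-sensitivity scan.

#' Find candidate comparative hotspots from two variability bands
#'
#' A candidate is a maximal run of consecutive grid points where one band's
#' lower edge lies strictly above the other band's upper edge.  Runs of a
#' single grid point are retained (no length filter: weak candidates are
#' pruned by the confirmation test, not here).  Boundaries are reported at
#' grid resolution: a run over grid points `i..j` becomes the collapsed
#' interval `[grid[i], grid[j] + spacing)` clipped to the unit.
#'
#' @param band_a,band_b [variability_band()]s on the same grid (same unit).
#' @return A data.frame of candidates on the collapsed scale with columns
#'   `chrom`, `arm`, `strand`, `cstart`, `cend`, `winner`.
#' @export
find_candidates <- function(band_a, band_b) {
  ga <- band_a$estimate$grid; gb <- band_b$estimate$grid
  if (length(ga) != length(gb) || any(ga != gb))
    stop("find_candidates: bands must share the same grid")
  unit <- band_a$estimate$unit
  la <- band_a$estimate$vector; lb <- band_b$estimate$vector
  L <- band_a$estimate$collapsed_length
  spacing <- ga[2L] - ga[1L]

  runs_of <- function(mask, winner) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(
      chrom = unit$chrom, arm = unit$arm, strand = unit$strand,
      cstart = ga[starts[keep]],
      cend = pmin(ga[ends[keep]] + spacing, L),
      winner = winner, stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    runs_of(band_a$lower > band_b$upper, la),
    runs_of(band_b$lower > band_a$upper, lb)
  )
  if (is.null(out))
    return(data.frame(chrom = character(), arm = character(),
                      strand = character(), cstart = numeric(),
                      cend = numeric(), winner = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$cstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map candidates from collapsed to genomic coordinates
#'
#' Endpoints are expanded through the unit's blind map; interior blind
#' stretches are re-inserted, so the genomic length is at least the
#' collapsed length.
#'
#' @param candidates A [find_candidates()] data.frame.
#' @param map The unit's [build_blind_map()].
#' @return The data.frame with genomic `start`, `end` columns added.
#' @export
to_genomic <- function(candidates, map) {
  if (nrow(candidates) == 0L) {
    candidates$start <- numeric(0); candidates$end <- numeric(0)
    return(candidates)
  }
  gi <- t(vapply(seq_len(nrow(candidates)), function(i) {
    expand_interval(map, c(candidates$cstart[i], candidates$cend[i]))
  }, numeric(2)))
  candidates$start <- gi[, 1L]
  candidates$end <- gi[, 2L]
  candidates
}

#' Detect candidates for one unit from two site sets
#'
#' Convenience wrapper running bandwidth selection (one `h_opt` per
#' vector), band construction and band comparison; the shared sensitivity
#' factor `s` rescales both bandwidths jointly (`h = h_opt * s`).
#'
#' @param sites_a,sites_b [site_set()]s of the two vectors on the same unit.
#' @param level Band level (default 0.99).
#' @param grid_size Grid points per unit (default `2^14`).
#' @param s Sensitivity factor (default 1).
#' @param h_a,h_b Optional fixed bandwidths; when `NULL`, selected by UCV.
#' @return List with `candidates` (collapsed scale), `band_a`, `band_b`,
#'   `h_opt` (named pair).
#' @export
detect_unit <- function(sites_a, sites_b, level = 0.99, grid_size = 2^14,
                        s = 1, h_a = NULL, h_b = NULL) {
  if (is.null(h_a)) h_a <- select_bandwidth(sites_a)$h_opt
  if (is.null(h_b)) h_b <- select_bandwidth(sites_b)$h_opt
  band_a <- variability_band(estimate_density(sites_a, h_a * s, grid_size), level)
  band_b <- variability_band(estimate_density(sites_b, h_b * s, grid_size), level)
  list(candidates = find_candidates(band_a, band_b),
       band_a = band_a, band_b = band_b,
       h_opt = setNames(c(h_a, h_b), c(sites_a$vector, sites_b$vector)))
}

#' Smoothing-sensitivity scan of candidate hotspots
#'
#' Re-runs estimation, band construction and band comparison with both
#' bandwidths jointly rescaled to `h_opt * s` for each `s`, to show which
#' candidates persist at more and at less smoothing.  Candidates that
#' appear only at small `s` are typically spurious; very large `s`
#' flattens the bands and either suppresses candidates or yields huge
#' uninterpretable ones.
#'
#' @inheritParams detect_unit
#' @param s_grid Multipliers within `[0.05, 20]`, must contain 1.
#' @param map Optional [build_blind_map()]; when given, genomic
#'   coordinates are added.
#' @return An object of class `sensitivity_scan`: list with `table` (long
#'   data.frame: `s`, `chrom`, `arm`, `strand`, `cstart`, `cend`,
#'   [`start`, `end`,] `winner`) and `h_opt`.
#' @export
sensitivity_scan <- function(sites_a, sites_b, s_grid, level = 0.99,
                             grid_size = 2^14, map = NULL) {
  s_grid <- sort(unique(as.numeric(s_grid)))
  if (any(s_grid < 0.05 | s_grid > 20))
    stop("sensitivity_scan: s_grid must lie within [0.05, 20]")
  if (!any(s_grid == 1))
    stop("sensitivity_scan: s_grid must contain 1")
  h_a <- select_bandwidth(sites_a)$h_opt
  h_b <- select_bandwidth(sites_b)$h_opt
  tabs <- lapply(s_grid, function(s) {
    res <- detect_unit(sites_a, sites_b, level = level,
                       grid_size = grid_size, s = s, h_a = h_a, h_b = h_b)
    cand <- res$candidates
    if (!is.null(map)) cand <- to_genomic(cand, map)
    if (nrow(cand)) cbind(s = s, cand) else NULL
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab)) {
    tab <- data.frame(s = numeric(), chrom = character(), arm = character(),
                      strand = character(), cstart = numeric(),
                      cend = numeric(), winner = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  structure(list(table = tab, s_grid = s_grid,
                 h_opt = setNames(c(h_a, h_b),
                                  c(sites_a$vector, sites_b$vector))),
            class = "sensitivity_scan")
}

#' Assign stable ids to candidates across a genome-wide scan
#'
#' Ids follow the winner label plus discovery order within the scan, e.g.
#' `hiv_1`, `mlv_1`, `hiv_2`, ...
#'
#' @param candidates Combined candidate data.frame (genomic coordinates).
#' @return The data.frame with an `id` column prepended.
#' @export
assign_candidate_ids <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(cbind(data.frame(id = character(), stringsAsFactors = FALSE),
                 candidates))
  }
  lab <- tolower(candidates$winner)
  idx <- stats::ave(seq_along(lab), lab, FUN = seq_along)
  cbind(data.frame(id = paste(lab, idx, sep = "_"),
                   stringsAsFactors = FALSE),
        candidates)
}
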