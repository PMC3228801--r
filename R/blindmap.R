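## Blind-region modelling and the genomic <-> collapsed coordinate system.
##
## An integration library built with a restriction enzyme plus fragment
## size-selection cannot see every basepair: an integration whose fragment
## (from the integration to its anchoring cut site) is shorter than the
## minimum alignable read length, or longer than the maximum sequenced
## fragment, is undetectable.  Those stretches are "blind regions".  All
## density estimation happens on a coordinate system from which the blind
## regions have been cut out and the remaining detectable segments
## concatenated ("collapsed" coordinates); found hotspots are mapped back.

#' Scan a sequence for restriction-motif occurrences
#'
#' Finds every (possibly overlapping) occurrence of `motif` in `sequence`,
#' 0-based.  Ambiguity codes in the subject (e.g. `N`) never match.  The
#' default enzyme motif TTAA (MseI) is its own reverse complement, so one
#' scan serves both strands; for a non-palindromic motif set
#' `both_strands = TRUE` to include occurrences of the reverse complement.
#'
#' @param sequence A character string or [Biostrings::DNAString].
#' @param motif Non-empty motif string (default `"TTAA"`).
#' @param both_strands Also scan for the reverse complement of `motif`.
#' @return An object of class `motif_sites`: list with sorted 0-based
#'   `positions` and the `motif`.
#' @examples
#' scan_motif("TTAATTAA", "TTAA")$positions  # 0, 4
#' @export
scan_motif <- function(sequence, motif = "TTAA", both_strands = FALSE) {
  if (!nzchar(motif)) stop("scan_motif: motif must be non-empty")
  subj <- if (methods::is(sequence, "DNAString")) sequence
          else Biostrings::DNAString(toupper(as.character(sequence)))
  hits <- Biostrings::start(
    Biostrings::matchPattern(toupper(motif), subj, fixed = TRUE)) - 1L
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(toupper(motif))))
    if (rc != toupper(motif)) {
      hits2 <- Biostrings::start(
        Biostrings::matchPattern(rc, subj, fixed = TRUE)) - 1L
      hits <- sort(unique(c(hits, hits2)))
    }
  }
  structure(list(positions = as.numeric(sort(hits)), motif = toupper(motif)),
            class = "motif_sites")
}

#' Blind intervals implied by restriction sites on one strand
#'
#' Within each gap between consecutive restriction sites `(p, q)` the
#' detectable window is bounded below by the minimum alignable read length
#' and above by the maximum fragment length that survives size selection.
#' On the `+` strand the fragment is anchored at the left site `p`:
#' `[p, min(p + min_read, q))` and `[min(p + max_frag, q), q)` are blind.
#' On the `-` strand the rule is mirrored within each gap and anchored at
#' the right site `q`.  The spans of the unit before the first and after
#' the last restriction site are blind (no anchoring cut site is reachable).
#' Gaps shorter than `min_read` are entirely blind.
#'
#' @param sites A [scan_motif()] result, or a numeric vector of sorted
#'   0-based site positions (genomic).
#' @param unit The [analysis_unit()]; its `strand` selects the rule.
#' @param min_read Minimum alignable read length in bp (default 20).
#' @param max_frag Maximum sequenced fragment length in bp (default 500).
#' @return A data.frame of merged, disjoint half-open blind intervals with
#'   columns `start`, `end` (genomic bp).
#' @export
derive_blind_intervals <- function(sites, unit, min_read = 20, max_frag = 500) {
  if (inherits(sites, "motif_sites")) sites <- sites$positions
  sites <- as.numeric(sites)
  if (is.unsorted(sites, strictly = FALSE))
    stop("derive_blind_intervals: sites must be sorted")
  if (!(min_read < max_frag))
    stop("derive_blind_intervals: need min_read < max_frag")
  s0 <- unit$start; s1 <- unit$end
  sites <- sites[sites >= s0 & sites <= s1]

  starts <- numeric(0); ends <- numeric(0)
  add <- function(a, b) if (a < b) { starts <<- c(starts, a); ends <<- c(ends, b) }

  if (length(sites) == 0L) {
    add(s0, s1)
  } else {
    add(s0, sites[1L])                       # before first site
    add(sites[length(sites)], s1)            # after last site
    if (length(sites) >= 2L) {
      p <- sites[-length(sites)]; q <- sites[-1L]
      if (unit$strand == "+") {
        a1 <- p; b1 <- pmin(p + min_read, q)
        a2 <- pmin(p + max_frag, q); b2 <- q
      } else {
        a1 <- pmax(q - min_read, p); b1 <- q
        a2 <- p; b2 <- pmax(q - max_frag, p)
      }
      keep1 <- a1 < b1; keep2 <- a2 < b2
      starts <- c(starts, a1[keep1], a2[keep2])
      ends <- c(ends, b1[keep1], b2[keep2])
    }
  }
  merge_intervals(data.frame(start = starts, end = ends))
}

#' Merge possibly overlapping half-open intervals
#'
#' @param iv Data.frame with `start`, `end`.
#' @return Data.frame of sorted, disjoint intervals (touching intervals are
#'   joined).
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(iv$start, iv$end)
  s <- iv$start[o]; e <- iv$end[o]
  ms <- s[1L]; me <- e[1L]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

#' Long assembly-gap (N) runs of a sequence, as blind intervals
#'
#' Runs of `N` of at least `min_run` bp are treated as blind: `N` cannot
#' contain a restriction motif and long N runs are unmappable, so leaving
#' them in would create spurious zero-density valleys.
#'
#' @param sequence Character string or `DNAString` of the unit.
#' @param offset Genomic coordinate of the first base of `sequence`.
#' @param min_run Minimum run length in bp (default 1000).
#' @return Data.frame of half-open blind intervals (`start`, `end`).
#' @export
n_run_intervals <- function(sequence, offset = 0, min_run = 1000) {
  s <- toupper(as.character(sequence))
  m <- gregexpr("N+", s)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  len <- attr(m, "match.length")
  keep <- len >= min_run
  data.frame(start = as.numeric(m[keep]) - 1 + offset,
             end = as.numeric(m[keep]) - 1 + len[keep] + offset)
}

#' Build the invertible genomic/collapsed coordinate map of a unit
#'
#' Blind regions are skipped and successive non-blind parts connected: the
#' collapsed coordinate of a non-blind genomic position is the number of
#' non-blind basepairs of the unit strictly below it.
#'
#' @param blind Data.frame of disjoint, sorted half-open blind intervals
#'   (columns `start`, `end`), all within the unit.
#' @param unit The [analysis_unit()].
#' @return An object of class `blind_map` with elements `unit`, `blind`,
#'   `collapsed_length`, `degenerate` (TRUE when the whole unit is blind)
#'   and internal offset tables.
#' @export
build_blind_map <- function(blind, unit) {
  blind <- blind[order(blind$start), , drop = FALSE]
  if (nrow(blind)) {
    if (any(blind$end <= blind$start))
      stop("build_blind_map: empty or inverted blind interval")
    if (any(blind$start < unit$start | blind$end > unit$end))
      stop("build_blind_map: blind intervals outside the unit")
    if (nrow(blind) > 1L &&
        any(blind$start[-1L] < blind$end[-nrow(blind)]))
      stop("build_blind_map: blind intervals overlap")
  }
  # non-blind segments in genomic coordinates
  seg_start <- c(unit$start, blind$end)
  seg_end <- c(blind$start, unit$end)
  keep <- seg_start < seg_end
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  seg_len <- seg_end - seg_start
  seg_cstart <- c(0, cumsum(seg_len))[seq_along(seg_len)]
  collapsed_length <- sum(seg_len)
  structure(
    list(unit = unit, blind = blind,
         collapsed_length = collapsed_length,
         degenerate = collapsed_length == 0,
         seg_start = seg_start, seg_end = seg_end, seg_cstart = seg_cstart),
    class = "blind_map"
  )
}

#' @export
print.blind_map <- function(x, ...) {
  cat(sprintf(
    "<blind_map> %s  %d blind interval(s), blind fraction %.3f, %.0f collapsed bp\n",
    unit_id(x$unit), nrow(x$blind), blind_fraction(x), x$collapsed_length))
  invisible(x)
}

#' Collapse genomic positions onto the detectable coordinate axis
#'
#' @param map A [build_blind_map()] result.
#' @param x Numeric vector of genomic positions; every position must be
#'   non-blind and inside the unit.
#' @return Collapsed coordinates in `[0, collapsed_length)`.
#' @export
collapse_position <- function(map, x) {
  x <- as.numeric(x)
  if (any(x < map$unit$start | x >= map$unit$end))
    stop("collapse_position: position outside the unit")
  i <- findInterval(x, map$seg_start)
  bad <- i == 0L | x >= map$seg_end[pmax(i, 1L)]
  if (any(bad))
    stop(sprintf("collapse_position: %d position(s) fall in blind regions",
                 sum(bad)))
  map$seg_cstart[i] + (x - map$seg_start[i])
}

#' Is a genomic position blind?
#'
#' @param map A [build_blind_map()] result.
#' @param x Genomic positions inside the unit.
#' @return Logical vector: TRUE where the position is blind.
#' @export
is_blind <- function(map, x) {
  x <- as.numeric(x)
  i <- findInterval(x, map$seg_start)
  i == 0L | x >= map$seg_end[pmax(i, 1L)]
}

#' Expand collapsed positions back to genomic coordinates
#'
#' @param map A [build_blind_map()] result.
#' @param cx Collapsed coordinates in `[0, collapsed_length)`.
#' @return Genomic positions (always non-blind).
#' @export
expand_position <- function(map, cx) {
  cx <- as.numeric(cx)
  if (any(cx < 0 | cx >= map$collapsed_length))
    stop("expand_position: collapsed coordinate out of range")
  i <- findInterval(cx, map$seg_cstart)
  map$seg_start[i] + (cx - map$seg_cstart[i])
}

#' Expand a collapsed half-open interval to genomic coordinates
#'
#' The genomic interval runs from the genomic image of the interval's first
#' base to one past the image of its last base, so interior blind stretches
#' are re-inserted and the genomic length is at least the collapsed length.
#'
#' @param map A [build_blind_map()] result.
#' @param interval Numeric `c(a, b)` with `0 <= a < b <= collapsed_length`.
#' @return Numeric `c(start, end)`, half-open genomic interval.
#' @export
expand_interval <- function(map, interval) {
  a <- interval[1L]; b <- interval[2L]
  if (!(a < b) || a < 0 || b > map$collapsed_length)
    stop("expand_interval: need 0 <= a < b <= collapsed_length")
  lo <- floor(a)
  hi <- ceiling(b) - 1
  c(expand_position(map, lo), expand_position(map, hi) + 1)
}

#' Fraction of a unit that is blind
#'
#' @param map A [build_blind_map()] result.
#' @return Blind basepairs divided by unit length, in `[0, 1]`.
#' @export
blind_fraction <- function(map) {
  tot <- unit_length(map$unit)
  (tot - map$collapsed_length) / tot
}

#' Compute the blind map of one unit directly from sequence
#'
#' Convenience wrapper: scans the motif, applies the strand-specific blind
#' interval rule, adds long assembly-gap (N >= `n_run_min` bp) runs, and
#' builds the coordinate map.
#'
#' @inheritParams derive_blind_intervals
#' @param sequence Sequence of the *unit* (character or `DNAString`); its
#'   first base has genomic coordinate `unit$start`.
#' @param motif Restriction motif (default TTAA / MseI).
#' @param both_strands Passed to [scan_motif()] for non-palindromic motifs.
#' @param n_run_min Minimum N-run length treated as blind.
#' @return A `blind_map`.
#' @export
blind_map_from_sequence <- function(sequence, unit, motif = "TTAA",
                                    min_read = 20, max_frag = 500,
                                    both_strands = FALSE, n_run_min = 1000) {
  ms <- scan_motif(sequence, motif, both_strands = both_strands)
  ms$positions <- ms$positions + unit$start
  blind <- derive_blind_intervals(ms, unit, min_read = min_read,
                                  max_frag = max_frag)
  nr <- n_run_intervals(sequence, offset = unit$start, min_run = n_run_min)
  if (nrow(nr)) blind <- merge_intervals(rbind(blind, nr))
  build_blind_map(blind, unit)
}
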