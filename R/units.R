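#' Analysis unit: one (chromosome, arm, strand) triple
#'
#' Densities, bands and candidate hotspots are computed per analysis unit,
#' i.e. separately for each chromosome arm and each strand.  Working per arm
#' keeps the centromere (a giant blind region) out of every unit; working per
#' strand is required because restriction-digest blind regions are strand
#' specific.
#'
#' @param chrom Chromosome name.
#' @param arm Arm label, `"p"` or `"q"`.
#' @param strand `"+"` or `"-"`.
#' @param start,end Half-open genomic interval `[start, end)` in bp,
#'   0-based (BED convention).
#' @return An object of class `analysis_unit`.
#' @examples
#' analysis_unit("chr1", "p", "+", 0, 1e6)
#' @export
analysis_unit <- function(chrom, arm, strand, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  arm <- match.arg(arm, c("p", "q"))
  strand <- match.arg(strand, c("+", "-"))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) stop("analysis_unit: need start < end")
  structure(
    list(chrom = chrom, arm = arm, strand = strand, start = start, end = end),
    class = "analysis_unit"
  )
}

#' @export
print.analysis_unit <- function(x, ...) {
  cat(sprintf("<analysis_unit> %s  [%s, %s)  %.0f bp\n",
              unit_id(x), format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), x$end - x$start))
  invisible(x)
}

#' Stable identifier of an analysis unit
#'
#' @param unit An [analysis_unit()].
#' @return A string like `"chr1:p:+"`.
#' @export
unit_id <- function(unit) {
  paste(unit$chrom, unit$arm, unit$strand, sep = ":")
}

unit_length <- function(unit) unit$end - unit$start

#' Integration sites of one vector within one analysis unit
#'
#' Holds the sample \eqn{x_1, \dots, x_n} of a vector's integration
#' positions, expressed in *collapsed* coordinates (blind regions removed,
#' see [build_blind_map()]).  Each integration is assumed independent of any
#' other, so the sample is treated as i.i.d. draws from the vector's unknown
#' integration density on the unit.
#'
#' @param unit The [analysis_unit()] the sites belong to.
#' @param vector Vector label (e.g. `"HIV"`, `"MLV"`).
#' @param positions Numeric vector of collapsed coordinates in
#'   `[0, collapsed_length)`; stored sorted.
#' @param collapsed_length Length of the collapsed coordinate range in bp.
#' @return An object of class `site_set` with elements `unit`, `vector`,
#'   `positions`, `n`, `collapsed_length`.
#' @export
site_set <- function(unit, vector, positions, collapsed_length) {
  positions <- sort(as.numeric(positions))
  if (length(positions) &&
      (positions[1L] < 0 || positions[length(positions)] >= collapsed_length))
    stop("site_set: positions must lie in [0, collapsed_length)")
  structure(
    list(unit = unit, vector = vector, positions = positions,
         n = length(positions), collapsed_length = as.numeric(collapsed_length)),
    class = "site_set"
  )
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set> %s  %s  n = %d on %.0f collapsed bp\n",
              x$vector, unit_id(x$unit), x$n, x$collapsed_length))
  invisible(x)
}

## ---- file I/O --------------------------------------------------------------

#' Read chromosome-arm definitions from a BED file
#'
#' Expects BED4+: chrom, start, end, name where name is `p` or `q`.
#'
#' @param path Path to the arms BED file.
#' @return A data.frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
read_arms_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || !all(nm %in% c("p", "q")))
    stop("arms BED must carry a name column with values 'p' or 'q'")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    arm = nm,
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read integration sites from a BED6 file
#'
#' One record per integration: start = position (0-based), end = start + 1,
#' name = vector label, strand used.
#'
#' @param path Path to the sites BED file.
#' @return A data.frame with columns `chrom`, `pos` (0-based genomic bp),
#'   `strand`, `vector`.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      strand = character(), vector = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    vector = S4Vectors::mcols(gr)$name,
    stringsAsFactors = FALSE
  )
}

#' Write half-open intervals as a BED6 file
#'
#' @param df Data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  n <- nrow(df)
  out <- data.frame(
    chrom = df$chrom,
    start = format(df$start, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(df)) df$name else rep(".", n),
    score = if ("score" %in% names(df)) df$score else rep(0L, n),
    strand = if ("strand" %in% names(df)) df$strand else rep(".", n),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
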