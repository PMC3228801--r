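## Pipeline orchestration: configuration, per-unit execution of
## blindmap -> density -> detect -> confirm (-> annotate), and TSV/JSON
## output with reproducibility metadata.

#' Build a pipeline run configuration
#'
#' Houses the method defaults: band level 0.99, familywise alpha 0.05,
#' detectability rule 20/500 bp (minimum alignable read / maximum
#' sequenced fragment), TTAA (MseI) motif, sensitivity factors within
#' `[0.05, 20]`.
#'
#' @param fasta,arms,sites Paths to the genome FASTA, arm BED4 and site
#'   BED6 files.
#' @param genes,expression,reads Optional annotation tracks: gene BED,
#'   expression flag TSV (`name`, `flag`), read-position BED (a single
#'   track or a named list of paths for several tracks).
#' @param motif Restriction motif (default `"TTAA"`).
#' @param both_strands Scan the motif's reverse complement too (needed
#'   only for non-palindromic enzymes).
#' @param min_read,max_frag Blind-region rule in bp (defaults 20 / 500).
#' @param level Variability-band level (default 0.99).
#' @param grid_size Grid points per unit (default `2^14`).
#' @param s_grid Optional sensitivity factors (must contain 1) to emit a
#'   robustness table.
#' @param alpha Familywise significance level (default 0.05).
#' @param n_perm Permutations for annotation group tests (default 1e5).
#' @param seed Integer seed recorded in output metadata.
#' @param min_sites Units with fewer sites than this for either vector
#'   are skipped with a warning (default 10; band overlap there would
#'   reflect lack of data, not equality of densities).
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fasta, arms, sites, genes = NULL, expression = NULL,
                       reads = NULL, motif = "TTAA", both_strands = FALSE,
                       min_read = 20, max_frag = 500, level = 0.99,
                       grid_size = 2^14, s_grid = NULL, alpha = 0.05,
                       n_perm = 1e5, seed = 1L, min_sites = 10L,
                       out_dir = "comphot_out") {
  stopifnot(level > 0, level < 1, alpha > 0, alpha < 1,
            min_read < max_frag)
  structure(
    list(fasta = fasta, arms = arms, sites = sites, genes = genes,
         expression = expression, reads = reads, motif = motif,
         both_strands = both_strands, min_read = min_read,
         max_frag = max_frag, level = level, grid_size = grid_size,
         s_grid = s_grid, alpha = alpha, n_perm = n_perm,
         seed = as.integer(seed), min_sites = min_sites,
         out_dir = out_dir),
    class = "run_config"
  )
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

write_tsv_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  write.table(format(df, trim = TRUE, digits = 15),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by the pipeline (skipping `#` metadata lines)
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv_meta <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Run the full comparative-hotspot pipeline
#'
#' Stages, in order and per (chromosome, arm, strand) unit: blind-region
#' computation from sequence; collapse of sites onto detectable
#' coordinates; per-vector UCV bandwidth selection, density estimation
#' and variability bands; band comparison into candidate hotspots;
#' genome-wide Fisher/Holm confirmation; optional annotation and
#' sensitivity scan.  All tables are written with `#` metadata headers
#' (package version, config hash, seed).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `blind_summary`, `candidates`,
#'   `confirmed`, `robustness` (or NULL), `annotation` (or NULL) and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = "comphot",
               version = as.character(utils::packageVersion("comphot")),
               config = config_hash(config), seed = config$seed)

  genome <- Biostrings::readDNAStringSet(config$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  arms <- read_arms_bed(config$arms)
  sites <- read_sites_bed(config$sites)

  if (nrow(sites)) {
    bad <- setdiff(unique(c(arms$chrom, sites$chrom)), names(genome))
    if (length(bad))
      stop("chromosome names missing from FASTA: ",
           paste(bad, collapse = ", "))
  } else {
    warning("empty sites file: emitting empty outputs")
  }
  vectors <- sort(unique(sites$vector))

  blind_rows <- list(); cand_rows <- list(); maps <- list()
  site_sets <- list(); rob_rows <- list()
  for (i in seq_len(nrow(arms))) {
    for (std in c("+", "-")) {
      unit <- analysis_unit(arms$chrom[i], arms$arm[i], std,
                            arms$start[i], arms$end[i])
      uid <- unit_id(unit)
      seq_u <- Biostrings::subseq(genome[[unit$chrom]],
                                  unit$start + 1, unit$end)
      map <- blind_map_from_sequence(seq_u, unit, motif = config$motif,
                                     min_read = config$min_read,
                                     max_frag = config$max_frag,
                                     both_strands = config$both_strands)
      maps[[uid]] <- map
      blind_rows[[uid]] <- data.frame(
        unit = uid, unit_length = unit_length(unit),
        collapsed_length = map$collapsed_length,
        blind_fraction = blind_fraction(map), stringsAsFactors = FALSE)
      if (map$degenerate) {
        message(uid, ": fully blind unit, skipped")
        next
      }
      usites <- sites[sites$chrom == unit$chrom & sites$strand == std &
                      sites$pos >= unit$start & sites$pos < unit$end, ,
                      drop = FALSE]
      sets <- list()
      enough <- TRUE
      for (v in vectors) {
        pos <- usites$pos[usites$vector == v]
        ok <- !is_blind(map, pos)
        if (any(!ok))
          message(uid, ": dropped ", sum(!ok), " ", v,
                  " site(s) in blind regions")
        cx <- collapse_position(map, pos[ok])
        sets[[v]] <- site_set(unit, v, cx, map$collapsed_length)
        if (sets[[v]]$n < config$min_sites) enough <- FALSE
      }
      if (length(vectors) < 2L || !enough) {
        if (length(vectors) == 2L)
          message(uid, ": fewer than ", config$min_sites,
                  " sites for a vector, unit skipped")
        next
      }
      site_sets[[uid]] <- sets
      res <- detect_unit(sets[[1L]], sets[[2L]], level = config$level,
                         grid_size = config$grid_size)
      cand <- to_genomic(res$candidates, map)
      message(sprintf("%s: n = %d/%d, h_opt = %.1f/%.1f, %d candidate(s)",
                      uid, sets[[1L]]$n, sets[[2L]]$n,
                      res$h_opt[1L], res$h_opt[2L], nrow(cand)))
      if (nrow(cand)) cand_rows[[uid]] <- cand
      if (!is.null(config$s_grid)) {
        sc <- sensitivity_scan(sets[[1L]], sets[[2L]], config$s_grid,
                               level = config$level,
                               grid_size = config$grid_size, map = map)
        if (nrow(sc$table)) rob_rows[[uid]] <- sc$table
      }
    }
  }

  blind_summary <- do.call(rbind, c(blind_rows, list(
    data.frame(unit = character(), unit_length = numeric(),
               collapsed_length = numeric(), blind_fraction = numeric(),
               stringsAsFactors = FALSE))))
  candidates <- do.call(rbind, cand_rows)
  if (is.null(candidates))
    candidates <- data.frame(chrom = character(), arm = character(),
                             strand = character(), cstart = numeric(),
                             cend = numeric(), winner = character(),
                             start = numeric(), end = numeric(),
                             stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  candidates <- assign_candidate_ids(candidates)

  confirmed <- if (length(vectors) == 2L) confirm(candidates, sites,
                                                  alpha = config$alpha)
               else NULL

  annotation <- NULL
  if (!is.null(config$genes) && !is.null(confirmed) && nrow(confirmed)) {
    genes <- read_sites_like_bed(config$genes)
    sig <- confirmed[confirmed$significant, , drop = FALSE]
    annotation <- list(genes = overlap_stats(sig, genes))
    if (!is.null(config$expression)) {
      flags <- read.table(config$expression, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      annotation$expression <- expression_enrichment(sig, genes, flags)
    }
    if (!is.null(config$reads)) {
      rd <- config$reads
      if (!is.list(rd)) rd <- list(track = rd)
      dens <- lapply(rd, function(p) track_density(sig,
                                                   read_sites_like_bed(p)))
      annotation$track_density <- data.frame(
        id = rep(sig$id, times = length(dens)),
        winner = rep(sig$winner, times = length(dens)),
        track = rep(names(dens), each = nrow(sig)),
        density = unlist(dens, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
    annotation$lengths <- length_stats(sig, n_perm = config$n_perm,
                                       seed = config$seed)
  }

  paths <- list(
    blind = file.path(config$out_dir, "blind_summary.tsv"),
    candidates = file.path(config$out_dir, "candidates.tsv"),
    confirmed = file.path(config$out_dir, "confirmed.tsv"),
    summary = file.path(config$out_dir, "summary.json")
  )
  write_tsv_meta(blind_summary, paths$blind, meta)
  write_tsv_meta(candidates, paths$candidates, meta)
  if (!is.null(confirmed)) write_tsv_meta(confirmed, paths$confirmed, meta)
  robustness <- NULL
  if (length(rob_rows)) {
    robustness <- do.call(rbind, rob_rows)
    rownames(robustness) <- NULL
    paths$robustness <- file.path(config$out_dir, "robustness.tsv")
    write_tsv_meta(robustness, paths$robustness, meta)
  }
  summary <- list(
    meta = meta, n_units = nrow(arms) * 2L,
    n_sites = as.list(table(sites$vector)),
    n_candidates = nrow(candidates),
    n_confirmed = if (is.null(confirmed)) 0L else sum(confirmed$significant))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(blind_summary = blind_summary, candidates = candidates,
                 confirmed = confirmed, robustness = robustness,
                 annotation = annotation, maps = maps,
                 site_sets = site_sets, paths = paths))
}

# BED reader for interval tracks (genes, reads): 0-based half-open output.
read_sites_like_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(S4Vectors::mcols(gr)$name))
      S4Vectors::mcols(gr)$name else NA_character_,
    stringsAsFactors = FALSE
  )
}
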