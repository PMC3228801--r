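## Confirmation of candidate hotspots: 2x2 odds-ratio Fisher exact tests
## with Bonferroni-Holm familywise-error control over the whole genome-wide
## candidate list.

#' Count integrations inside and outside a hotspot, per vector
#'
#' `n_in` counts a vector's sites on the hotspot's strand and chromosome
#' within the half-open interval `[start, end)`; `n_out` is the vector's
#' genome-wide total (all units, both strands) minus `n_in`, so that the
#' margins of the 2x2 table are the two vectors' total sample sizes.
#'
#' @param hotspot One-row data.frame (or list) with `chrom`, `strand`,
#'   `start`, `end`.
#' @param sites Data.frame of genomic sites: `chrom`, `pos`, `strand`,
#'   `vector` (as from [read_sites_bed()]).
#' @param vectors Character pair of vector labels; default both labels
#'   found in `sites`.
#' @return Named list of `c(n_in, n_out)` per vector.
#' @export
count_sites <- function(hotspot, sites, vectors = NULL) {
  if (is.null(vectors)) vectors <- sort(unique(sites$vector))
  inside <- sites$chrom == hotspot$chrom &
    sites$strand == hotspot$strand &
    sites$pos >= hotspot$start & sites$pos < hotspot$end
  lapply(setNames(vectors, vectors), function(v) {
    sel <- sites$vector == v
    n_in <- sum(inside & sel)
    c(n_in = n_in, n_out = sum(sel) - n_in)
  })
}

#' Oriented odds-ratio exact test of a 2x2 integration table
#'
#' The cross-product odds ratio
#' \eqn{(n^{in}_A / n^{out}_A) / (n^{in}_B / n^{out}_B)} is oriented to be
#' at least 1 (the dominant vector is the winner; `Inf` when the losing
#' vector has no inside counts).  The p-value is the two-sided Fisher
#' exact (hypergeometric) test.  The 0.95 CI is the conditional exact CI
#' when any cell is <= 5, else logit-Wald (with 0.5 continuity correction
#' on zero cells); the CI is reporting-only, significance uses the p-value.
#'
#' @param n_in_a,n_out_a,n_in_b,n_out_b Non-negative counts; both row
#'   totals (per-vector totals) must be positive.
#' @param labels Character pair naming vectors A and B.
#' @param conf_level CI level (default 0.95).
#' @return List with `or_value` (>= 1), `winner`, `ci95` = `c(lo, hi)`,
#'   `p_raw`.
#' @export
odds_ratio_test <- function(n_in_a, n_out_a, n_in_b, n_out_b,
                            labels = c("A", "B"), conf_level = 0.95) {
  counts <- c(n_in_a, n_out_a, n_in_b, n_out_b)
  if (any(counts < 0)) stop("odds_ratio_test: negative count")
  if ((n_in_a + n_out_a) == 0 || (n_in_b + n_out_b) == 0)
    stop("odds_ratio_test: a vector has zero total sites (undefined test)")
  or_ab <- (n_in_a / n_out_a) / (n_in_b / n_out_b)
  # orient: winner is the vector with the larger inside odds
  flip <- !is.nan(or_ab) && or_ab < 1
  if (flip) {
    tmp <- c(n_in_b, n_out_b, n_in_a, n_out_a)
    n_in_a <- tmp[1L]; n_out_a <- tmp[2L]
    n_in_b <- tmp[3L]; n_out_b <- tmp[4L]
    labels <- rev(labels)
  }
  or_value <- (n_in_a / n_out_a) / (n_in_b / n_out_b)
  if (is.nan(or_value)) or_value <- 1  # 0/0: no information either way
  tab <- matrix(c(n_in_a, n_out_a, n_in_b, n_out_b), nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab, conf.level = conf_level)
  if (any(tab <= 5)) {
    ci <- unname(ft$conf.int)
  } else {
    lo <- log(or_value)
    se <- sqrt(1 / n_in_a + 1 / n_out_a + 1 / n_in_b + 1 / n_out_b)
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(c(lo - z * se, lo + z * se))
  }
  list(or_value = or_value, winner = labels[1L], ci95 = ci,
       p_raw = min(ft$p.value, 1))  # guard FP overshoot above 1
}

#' Bonferroni-Holm step-down adjustment
#'
#' Sort p-values ascending, multiply the k-th smallest by (m - k + 1),
#' enforce a monotone non-decreasing cumulative maximum, cap at 1, and
#' return in the input order.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("holm_adjust: p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  adj[order(o)]
}

#' Confirm candidate hotspots by exact testing with Holm correction
#'
#' Counts integrations per candidate, runs the oriented odds-ratio Fisher
#' exact test, and adjusts all raw p-values in *one* Holm family spanning
#' the entire genome-wide candidate list (both strands, both winners).  A
#' candidate is confirmed when its adjusted p is at most `alpha`.
#'
#' @param candidates Data.frame of candidates in genomic coordinates with
#'   columns `id`, `chrom`, `arm`, `strand`, `start`, `end`, `winner`
#'   (see [assign_candidate_ids()]).
#' @param sites Genome-wide site data.frame (`chrom`, `pos`, `strand`,
#'   `vector`).
#' @param alpha Familywise significance level (default 0.05).
#' @param conf_level CI level for reporting (default 0.95).
#' @return Data.frame sorted by adjusted p with columns `id`, `winner`,
#'   `chrom`, `arm`, `strand`, `start`, `end`, `length`, per-vector
#'   `n_in_*`/`n_out_*`, `or`, `ci_lo`, `ci_hi`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
confirm <- function(candidates, sites, alpha = 0.05, conf_level = 0.95) {
  vectors <- sort(unique(sites$vector))
  if (length(vectors) != 2L)
    stop("confirm: sites must carry exactly two vector labels")
  if (nrow(candidates) == 0L) {
    out <- data.frame(
      id = character(), winner = character(), chrom = character(),
      arm = character(), strand = character(), start = numeric(),
      end = numeric(), length = numeric(), stringsAsFactors = FALSE)
    out[[paste0("n_in_", vectors[1L])]] <- numeric(0)
    out[[paste0("n_out_", vectors[1L])]] <- numeric(0)
    out[[paste0("n_in_", vectors[2L])]] <- numeric(0)
    out[[paste0("n_out_", vectors[2L])]] <- numeric(0)
    out$or <- numeric(0); out$ci_lo <- numeric(0); out$ci_hi <- numeric(0)
    out$p_raw <- numeric(0); out$p_adj <- numeric(0)
    out$significant <- logical(0)
    return(out)
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    hs <- candidates[i, ]
    cnt <- count_sites(hs, sites, vectors)
    a <- cnt[[1L]]; b <- cnt[[2L]]
    tst <- odds_ratio_test(a["n_in"], a["n_out"], b["n_in"], b["n_out"],
                           labels = vectors, conf_level = conf_level)
    data.frame(
      id = hs$id, winner = tst$winner, chrom = hs$chrom, arm = hs$arm,
      strand = hs$strand, start = hs$start, end = hs$end,
      length = hs$end - hs$start,
      n_in_a = unname(a["n_in"]), n_out_a = unname(a["n_out"]),
      n_in_b = unname(b["n_in"]), n_out_b = unname(b["n_out"]),
      or = tst$or_value, ci_lo = tst$ci95[1L], ci_hi = tst$ci95[2L],
      p_raw = tst$p_raw, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "n_in_a"] <- paste0("n_in_", vectors[1L])
  names(out)[names(out) == "n_out_a"] <- paste0("n_out_", vectors[1L])
  names(out)[names(out) == "n_in_b"] <- paste0("n_in_", vectors[2L])
  names(out)[names(out) == "n_out_b"] <- paste0("n_out_", vectors[2L])
  out$p_adj <- holm_adjust(out$p_raw)
  out$significant <- out$p_adj <= alpha
  # Table-1-style ordering: by adjusted p, ties broken by raw p then id
  out <- out[order(out$p_adj, out$p_raw, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
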