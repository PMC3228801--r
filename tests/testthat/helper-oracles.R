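# Independent oracles used across the suite.  These deliberately use
# brute force / enumeration / numeric integration, never the package's own
# code paths.

# Per-base detectability simulation of the blind-region rule.
# + strand: a position x is detectable iff the nearest restriction site at
# or below x is at distance in [min_read, max_frag); - strand mirrors with
# the nearest site strictly above (distance in (min_read, max_frag]).
oracle_blind_mask <- function(sites, unit, strand, min_read = 20,
                              max_frag = 500) {
  xs <- seq(unit$start, unit$end - 1)
  sites <- sites[sites >= unit$start & sites <= unit$end]
  blind <- rep(TRUE, length(xs))
  if (length(sites) == 0L) return(blind)
  if (strand == "+") {
    i <- findInterval(xs, sites)           # nearest site <= x
    has <- i >= 1L
    d <- xs[has] - sites[pmax(i[has], 1L)]
    blind[has] <- !(d >= min_read & d < max_frag)
    blind[xs > sites[length(sites)]] <- TRUE   # after last site
  } else {
    i <- findInterval(xs, sites) + 1L      # nearest site strictly above x
    has <- i <= length(sites)
    d <- sites[pmin(i, length(sites))][has] - xs[has]
    blind[has] <- !(d > min_read & d <= max_frag)
    blind[xs < sites[1L]] <- TRUE              # before first site
  }
  blind
}

mask_to_intervals <- function(blind, offset = 0) {
  r <- rle(blind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1 + offset, end = ends[keep] + offset)
}

# Numeric-integration UCV oracle: trapezoid integral of f_hat^2 on a fine
# grid plus an explicit leave-one-out sum.
oracle_ucv <- function(x, h, pad = 10, m = 20001) {
  n <- length(x)
  g <- seq(min(x) - pad * h, max(x) + pad * h, length.out = m)
  fhat <- sapply(g, function(gg) mean(dnorm((gg - x) / h)) / h)
  int_f2 <- sum((fhat[-1]^2 + fhat[-m]^2) / 2 * diff(g))
  loo <- vapply(seq_len(n), function(i) {
    sum(dnorm((x[i] - x[-i]) / h)) / ((n - 1) * h)
  }, numeric(1))
  int_f2 - 2 * mean(loo)
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (point-probability criterion).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Fixed-seed RNG scope helper.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}
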