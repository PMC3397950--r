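# Independent oracles used across the suite. Each recomputes a quantity by
# brute force (full enumeration, pairwise comparison, direct optimization),
# never by calling the implementation path it checks.

# One-sided KS D+ recomputed directly from two samples' ECDFs.
oracle_ks_d <- function(w, b) {
  u <- sort(unique(w))
  max(0, max(vapply(u, function(x) mean(b < x) - mean(w < x), numeric(1))))
}

# Exact permutation tail P(D+ >= d) by full enumeration of all C(m+n, m)
# assignments of the pooled values to the window.
oracle_ks_p <- function(w, b, d) {
  m <- length(w)
  n <- length(b)
  pooled <- c(w, b)
  if (!anyDuplicated(pooled)) {
    # tie-free: D+ of an assignment depends only on the sorted pooled
    # positions of the window values; vectorize over combn columns
    pos <- combn(m + n, m)
    dev <- (pos - seq_len(m)) / n - (seq_len(m) - 1) / m
    ds <- if (m == 1L) as.numeric(dev) else apply(dev, 2L, max)
    return(mean(pmax(ds, 0) >= d - 1e-9))
  }
  idx <- combn(m + n, m)
  ds <- apply(idx, 2L, function(ii) oracle_ks_d(pooled[ii], pooled[-ii]))
  mean(ds >= d - 1e-9)
}

# Exact two-sided Mann-Whitney p by full enumeration of labelings:
# p = P(|U - mn/2| >= |u_obs - mn/2|) over all C(m+n, m) assignments.
oracle_mw_p <- function(a, b) {
  m <- length(a)
  n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- combn(m + n, m)
  us <- apply(idx, 2L, function(ii) sum(r[ii])) - m * (m + 1) / 2
  mean(abs(us - m * n / 2) >= abs(u_obs - m * n / 2) - 1e-9)
}

# AUC as the mean over all case-control pairs of [case > control] with ties
# counted one-half.
oracle_auc <- function(values, labels) {
  x <- values[labels]
  y <- values[!labels]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

# Biweight location as the global minimizer of the Tukey rho objective with
# the scale fixed at the raw MAD about the median (the estimating equation
# the fixed-point iteration solves). The objective is not unimodal, so a
# fine grid brackets the global minimum before local refinement.
oracle_biweight <- function(x, c = 5) {
  med <- median(x)
  s <- median(abs(x - med))
  if (s == 0) return(med)
  rho <- function(u) ifelse(abs(u) < 1, (1 - (1 - u^2)^3) / 6, 1 / 6)
  obj <- function(m) sum(rho((x - m) / (c * s)))
  grid <- seq(min(x), max(x), length.out = 2000)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  optimize(obj, c(lo, hi), tol = 1e-10)$minimum
}

# Small hand-rolled probe table on one chromosome.
make_probes <- function(values, chrom = "chr1", spacing = 100,
                        probe_len = 50, start0 = 0) {
  n <- length(values)
  starts <- start0 + seq(0, by = spacing, length.out = n)
  data.frame(probe_id = sprintf("%s_p%05d", chrom, seq_len(n)),
             chrom = chrom, start = starts, end = starts + probe_len,
             log2_ratio = values, stringsAsFactors = FALSE)
}

# A small valid pooled-MSP matrix builder.
make_pools <- function(genes, n_normal = 4, n_scc = 4, n_ac = 4,
                       blood = TRUE) {
  cols <- c(sprintf("Normal:N%d", seq_len(n_normal)),
            sprintf("SCC:S%d", seq_len(n_scc)),
            sprintf("AC:A%d", seq_len(n_ac)),
            if (blood) "Blood:B1")
  matrix(0L, nrow = length(genes), ncol = length(cols),
         dimnames = list(genes, cols))
}

# Fraction of planted regions overlapped by called regions and fraction of
# called regions not overlapping any planted region, via GRanges.
overlap_stats <- function(regions, truth) {
  if (nrow(regions) == 0L) {
    return(c(recovered = 0, spurious = 0, n_called = 0,
             n_planted = nrow(truth)))
  }
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
  gr_tr <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start + 1, truth$end))
  c(recovered = sum(GenomicRanges::countOverlaps(gr_tr, gr_reg) > 0),
    spurious = sum(GenomicRanges::countOverlaps(gr_reg, gr_tr) == 0),
    n_called = nrow(regions), n_planted = nrow(truth))
}
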