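#' One-sided two-sample Kolmogorov-Smirnov test for a positive shift
#'
#' Tests whether the window values are drawn from a distribution shifted
#' toward more positive values than the background, as used to score tiling
#' probes for methylation enrichment. The statistic is
#' `D+ = sup_x [F_background(x) - F_window(x)]`, which grows as the window's
#' empirical distribution moves to the right of the background's.
#'
#' The p-value is the permutation tail probability `P(D+ >= d)` under random
#' re-assignment of the pooled values to window and background. It is exact
#' when the window has at most `exact_limit` values: for tie-free pooled data
#' via first-passage path counting over the lattice of pooled-order prefixes
#' (cost `O(m^2)` binomial terms), and for tied data via a dynamic program
#' over tie groups. Larger windows use the one-sided asymptotic bound
#' `exp(-2 d^2 m n / (m + n))`, clamped to (0, 1].
#'
#' @param window_values,background_values non-empty numeric vectors.
#' @param exact_limit maximum window size for the exact permutation p-value
#'   (default 10).
#' @return list with `d_plus` (in \[0, 1\]), `p_value` (in (0, 1\]), `score`
#'   (`-log10(p_value)`), and `exact` (logical, which regime was used).
#' @examples
#' ks_one_sided(c(5, 6), c(0, 1, 2))  # complete separation: d_plus = 1
#' @export
ks_one_sided <- function(window_values, background_values, exact_limit = 10L) {
  if (length(window_values) == 0L || length(background_values) == 0L) {
    stop("ks_one_sided: both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(window_values)) || any(!is.finite(background_values))) {
    stop("ks_one_sided: values must be finite", call. = FALSE)
  }
  m <- length(window_values)
  n <- length(background_values)
  d <- ks_d_plus(window_values, background_values)
  if (m <= exact_limit) {
    pooled <- c(window_values, background_values)
    p <- if (anyDuplicated(pooled)) {
      ks_exact_p_ties(window_values, background_values, d)
    } else {
      ks_exact_p_noties(m, n, d)
    }
    exact <- TRUE
  } else {
    p <- exp(-2 * d^2 * m * n / (m + n))
    exact <- FALSE
  }
  p <- min(1, max(p, .Machine$double.xmin))
  list(d_plus = d, p_value = p, score = -log10(p), exact = exact)
}

# D+ = sup_x [F_bg(x) - F_win(x)]. The difference only decreases at window
# jumps, so the supremum is attained at the left limit of some distinct
# window value (or is 0).
ks_d_plus <- function(w, b) {
  m <- length(w)
  n <- length(b)
  u <- sort(unique(w))
  sb <- sort(b)
  sw <- sort(w)
  bg_less <- findInterval(u, sb, left.open = TRUE)
  win_less <- findInterval(u, sw, left.open = TRUE)
  max(0, max(bg_less / n - win_less / m))
}

# Exact P(D+ >= d) for tie-free pooled data by first-passage counting.
# A random assignment is a monotone lattice path reading the pooled sorted
# values: a window value steps i -> i + 1, a background value steps
# j -> j + 1. After any prefix the ECDF difference is j/n - i/m; D+ >= d iff
# the path touches the boundary j = j_i, the smallest j with
# j/n - i/m >= d. Only background steps can enter the boundary, so the
# violating paths are counted by first passage through the points (i, j_i).
ks_exact_p_noties <- function(m, n, d) {
  if (d <= 1e-12) return(1)
  i <- 0:m
  jreq <- n * (d + i / m)
  j_bound <- ceiling(jreq - 1e-9 * pmax(1, abs(jreq)))
  keep <- which(j_bound <= n)
  if (length(keep) == 0L) return(0)
  i <- i[keep]
  j_bound <- pmax(j_bound[keep], 0L)
  k <- length(i)
  b_first <- numeric(k)
  total_viol <- 0
  for (a in seq_len(k)) {
    paths_to <- exp(lchoose(i[a] + j_bound[a], i[a]))
    if (a > 1L) {
      h <- seq_len(a - 1L)
      paths_to <- paths_to -
        sum(b_first[h] *
              exp(lchoose((i[a] - i[h]) + (j_bound[a] - j_bound[h]),
                          i[a] - i[h])))
    }
    b_first[a] <- max(paths_to, 0)
    total_viol <- total_viol +
      b_first[a] * exp(lchoose((m - i[a]) + (n - j_bound[a]), m - i[a]))
  }
  min(1, total_viol / exp(lchoose(m + n, m)))
}

# Exact P(D+ >= d) with ties: dynamic program over tie groups of the pooled
# sorted values. State = number of window values used so far; after each
# group the prefix point (i, j) is checked against the boundary, and
# violating states are removed. Counts non-violating assignments.
ks_exact_p_ties <- function(w, b, d) {
  if (d <= 1e-12) return(1)
  m <- length(w)
  n <- length(b)
  pooled <- sort(c(w, b))
  grp_sizes <- as.integer(table(match(pooled, unique(pooled))))
  ways <- c(1, numeric(m))  # ways[i + 1] = assignments using i window values
  done <- 0L
  for (g in grp_sizes) {
    new_ways <- numeric(m + 1L)
    for (i in 0:min(done, m)) {
      if (ways[i + 1L] == 0) next
      wmax <- min(g, m - i)
      ww <- 0:wmax
      new_ways[i + 1L + ww] <- new_ways[i + 1L + ww] +
        ways[i + 1L] * choose(g, ww)
    }
    done <- done + g
    i_all <- 0:m
    j_all <- done - i_all
    bad <- j_all >= 0 & j_all <= n &
      (j_all / n - i_all / m) >= d - 1e-9 * max(1, abs(d))
    new_ways[bad] <- 0
    ways <- new_ways
  }
  min(1, max(0, 1 - ways[m + 1L] / exp(lchoose(m + n, m))))
}
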