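#' Tukey biweight mean
#'
#' Iterated Tukey biweight location estimate, the robust array-wide center
#' used before enrichment scoring. Starting from the sample median with a
#' fixed scale equal to the (unscaled) median absolute deviation, weights
#' `w_i = (1 - u_i^2)^2` for `|u_i| < 1` (0 otherwise), with
#' `u_i = (x_i - m) / (c * MAD)`, are recomputed around the current estimate
#' until the update falls below `tol`. A zero MAD (half or more of the
#' values tied at the median) degenerates the scale, and the median is
#' returned.
#'
#' @param values numeric vector, at least one finite value.
#' @param c tuning constant for the biweight influence function (default 5).
#' @param tol convergence tolerance on the location update (default 1e-6).
#' @param max_iter iteration cap.
#' @return the biweight location estimate (length-1 numeric).
#' @examples
#' biweight_mean(c(0, 0.1, 0.2, 10))  # outlier is fully downweighted
#' @export
biweight_mean <- function(values, c = 5.0, tol = 1e-6, max_iter = 100L) {
  if (length(values) == 0L) stop("biweight_mean: empty input", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("biweight_mean: all values must be finite numeric", call. = FALSE)
  }
  check_field(is_number(c) && c > 0, "c", "must be a positive number")
  check_field(is_number(tol) && tol > 0, "tol", "must be a positive number")
  m <- median(values)
  s <- median(abs(values - m))   # raw MAD, no consistency constant
  if (s == 0) return(m)
  cs <- c * s
  for (i in seq_len(max_iter)) {
    u <- (values - m) / cs
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    if (sum(w) == 0) return(m)   # all mass rejected; keep current center
    m_new <- sum(w * values) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Center probe log2 ratios by the array biweight mean
#'
#' Subtracts the [biweight_mean()] of all log2 ratios on the array from each
#' probe, adding (or overwriting) a `centered_ratio` column. Centering is
#' shift-equivariant: adding a constant to every log2 ratio leaves the
#' centered values unchanged, so downstream calls are invariant to global
#' intensity offsets.
#'
#' @param probes probe table (`data.frame` with at least `probe_id` and
#'   `log2_ratio`), e.g. from [read_probe_table()] or
#'   [simulate_tiling_groups()].
#' @param biweight_c,biweight_tol estimator tuning constant and tolerance,
#'   defaults as in [peak_caller_config()].
#' @return the probe table with a `centered_ratio` column.
#' @export
center_log2_ratios <- function(probes, biweight_c = 5.0, biweight_tol = 1e-6) {
  stopifnot(is.data.frame(probes), "log2_ratio" %in% names(probes))
  bad <- !is.finite(probes$log2_ratio)
  if (any(bad)) {
    ids <- if ("probe_id" %in% names(probes)) {
      probes$probe_id[bad]
    } else {
      which(bad)
    }
    stop("center_log2_ratios: non-finite log2_ratio for probes: ",
         paste(head(ids, 10L), collapse = ", "),
         if (sum(bad) > 10L) sprintf(" (and %d more)", sum(bad) - 10L) else "",
         call. = FALSE)
  }
  m <- biweight_mean(probes$log2_ratio, c = biweight_c, tol = biweight_tol)
  probes$centered_ratio <- probes$log2_ratio - m
  probes
}
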