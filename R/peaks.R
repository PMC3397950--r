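#' Peak-caller configuration
#'
#' Parameters of the sliding-window enrichment caller. Defaults follow the
#' published analysis settings where stated (window width 500 bp, score
#' cutoff `-log10 P >= 2.0`); region construction parameters mirror the
#' window width.
#'
#' @param window_width sliding-window width in bp; a probe's window is all
#'   probes whose midpoint lies within `window_width / 2` of its own
#'   midpoint on the same chromosome.
#' @param score_cutoff minimum probe score (`-log10` p-value) for a probe to
#'   seed or extend an enriched region.
#' @param min_probes_per_window minimum probes required both to score a
#'   window and to keep a called region.
#' @param merge_gap maximum genomic gap (end of one qualifying probe to
#'   start of the next) across which qualifying probes are merged into one
#'   region; defaults to `window_width`.
#' @param biweight_c,biweight_tol centering estimator tuning, see
#'   [biweight_mean()].
#' @param small_sample_exact_limit largest window size scored with the exact
#'   permutation p-value; larger windows use the asymptotic bound (see
#'   [ks_one_sided()]).
#' @return a `peak_caller_config` list.
#' @export
peak_caller_config <- function(window_width = 500,
                               score_cutoff = 2.0,
                               min_probes_per_window = 2L,
                               merge_gap = window_width,
                               biweight_c = 5.0,
                               biweight_tol = 1e-6,
                               small_sample_exact_limit = 10L) {
  check_field(is_number(window_width) && window_width > 0,
              "window_width", "must be > 0")
  check_field(is_number(score_cutoff) && score_cutoff >= 0,
              "score_cutoff", "must be >= 0")
  check_field(is_count(min_probes_per_window),
              "min_probes_per_window", "must be a count >= 1")
  check_field(is_number(merge_gap) && merge_gap >= 0,
              "merge_gap", "must be >= 0")
  check_field(is_number(biweight_c) && biweight_c > 0,
              "biweight_c", "must be > 0")
  check_field(is_number(biweight_tol) && biweight_tol > 0,
              "biweight_tol", "must be > 0")
  check_field(is_count(small_sample_exact_limit),
              "small_sample_exact_limit", "must be a count >= 1")
  structure(list(window_width = window_width,
                 score_cutoff = score_cutoff,
                 min_probes_per_window = as.integer(min_probes_per_window),
                 merge_gap = merge_gap,
                 biweight_c = biweight_c,
                 biweight_tol = biweight_tol,
                 small_sample_exact_limit =
                   as.integer(small_sample_exact_limit)),
            class = "peak_caller_config")
}

assert_sorted_probes <- function(probes) {
  ord <- order(probes$chrom, probes$start, method = "radix")
  if (!identical(ord, seq_len(nrow(probes)))) {
    stop("probes must be sorted by (chrom, start); ",
         "use read_probe_table() or sort_probes()", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sort a probe table by (chrom, start)
#'
#' @param probes probe table.
#' @return the table sorted by chromosome then start, rownames dropped.
#' @export
sort_probes <- function(probes) {
  out <- probes[order(probes$chrom, probes$start, method = "radix"), ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score probes by the windowed one-sided KS test
#'
#' For each probe, the window is the set of probes on the same chromosome
#' whose interval midpoint lies within `window_width / 2` of the probe's
#' midpoint, and the background is every other probe on the array. The probe
#' score is `-log10` of the one-sided KS p-value ([ks_one_sided()]) testing
#' whether the window's centered log2 ratios are shifted positive relative
#' to the background. Windows with fewer than `min_probes_per_window` probes
#' are not scored (score 0, flagged in `skipped`).
#'
#' @param probes centered probe table (must carry `centered_ratio`), sorted
#'   by (chrom, start).
#' @param cfg a [peak_caller_config()].
#' @return `data.frame` with columns `probe_id`, `d_plus`, `p_value`,
#'   `score`, `skipped`, aligned row-for-row with `probes`. The number of
#'   skipped probes is reported with a message.
#' @export
score_probes <- function(probes, cfg = peak_caller_config()) {
  stopifnot(is.data.frame(probes), inherits(cfg, "peak_caller_config"))
  if (!"centered_ratio" %in% names(probes)) {
    stop("score_probes: probes are not centered; ",
         "run center_log2_ratios() first", call. = FALSE)
  }
  assert_sorted_probes(probes)
  n_all <- nrow(probes)
  vals <- probes$centered_ratio
  sorted_all <- sort(vals)
  has_ties <- anyDuplicated(sorted_all) > 0L
  mid <- (probes$start + probes$end) / 2
  half <- cfg$window_width / 2
  d_plus <- rep(NA_real_, n_all)
  p_value <- rep(1, n_all)
  skipped <- rep(FALSE, n_all)
  p_cache <- new.env(parent = emptyenv())
  chrom_idx <- split(seq_len(n_all), probes$chrom)
  for (idx in chrom_idx) {
    cmid <- mid[idx]
    lo <- findInterval(cmid - half - 1e-9, cmid) + 1L
    hi <- findInterval(cmid + half + 1e-9, cmid)
    for (k in seq_along(idx)) {
      i <- idx[k]
      win_idx <- idx[lo[k]:hi[k]]
      m <- length(win_idx)
      if (m < cfg$min_probes_per_window || m >= n_all) {
        skipped[i] <- TRUE
        next
      }
      w <- sort(vals[win_idx])
      u <- unique(w)
      all_less <- findInterval(u, sorted_all, left.open = TRUE)
      win_less <- findInterval(u, w, left.open = TRUE)
      n_bg <- n_all - m
      d <- max(0, max((all_less - win_less) / n_bg - win_less / m))
      d_plus[i] <- d
      if (m <= cfg$small_sample_exact_limit) {
        if (has_ties) {
          p_value[i] <- ks_exact_p_ties(w, vals[-win_idx], d)
        } else {
          key <- paste0(m, ":", format(d, digits = 15))
          p <- p_cache[[key]]
          if (is.null(p)) {
            p <- ks_exact_p_noties(m, n_bg, d)
            p_cache[[key]] <- p
          }
          p_value[i] <- p
        }
      } else {
        p_value[i] <- exp(-2 * d^2 * m * n_bg / (m + n_bg))
      }
    }
  }
  p_value <- pmin(1, pmax(p_value, .Machine$double.xmin))
  if (any(skipped)) {
    message(sprintf(
      "score_probes: %d probe(s) skipped (window < %d probes), score set to 0",
      sum(skipped), cfg$min_probes_per_window))
  }
  data.frame(probe_id = probes$probe_id,
             d_plus = d_plus,
             p_value = ifelse(skipped, 1, p_value),
             score = ifelse(skipped, 0, -log10(p_value)),
             skipped = skipped,
             stringsAsFactors = FALSE)
}

#' Call enriched regions from probe scores
#'
#' Maximal runs of probes whose score reaches `score_cutoff` are merged into
#' regions when the genomic gap between consecutive qualifying probes (start
#' of the next minus end of the previous) is at most `merge_gap`. A region
#' spans from the first qualifying probe's start to the last qualifying
#' probe's end; its peak score is the maximum member score. Regions
#' supported by fewer than `min_probes_per_window` qualifying probes are
#' dropped.
#'
#' @param scores probe scores from [score_probes()], aligned to `probes`.
#' @param probes the probe table that produced `scores`.
#' @param cfg a [peak_caller_config()].
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `peak_score`, `n_probes`.
#' @export
call_regions <- function(scores, probes, cfg = peak_caller_config()) {
  stopifnot(is.data.frame(scores), is.data.frame(probes))
  if (nrow(scores) != nrow(probes) ||
      !identical(as.character(scores$probe_id),
                 as.character(probes$probe_id))) {
    stop("call_regions: scores are not aligned to probes", call. = FALSE)
  }
  qual <- which(scores$score >= cfg$score_cutoff & !scores$skipped)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_score = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE)
  if (length(qual) == 0L) return(empty)
  q_chrom <- probes$chrom[qual]
  q_start <- probes$start[qual]
  q_end <- probes$end[qual]
  q_score <- scores$score[qual]
  new_run <- c(TRUE,
               q_chrom[-1] != q_chrom[-length(qual)] |
                 (q_start[-1] - q_end[-length(qual)]) > cfg$merge_gap)
  run_id <- cumsum(new_run)
  out <- data.frame(
    chrom = tapply(q_chrom, run_id, `[`, 1L),
    start = as.numeric(tapply(q_start, run_id, min)),
    end = as.numeric(tapply(q_end, run_id, max)),
    peak_score = as.numeric(tapply(q_score, run_id, max)),
    n_probes = as.integer(tapply(q_score, run_id, length)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$n_probes >= cfg$min_probes_per_window, , drop = FALSE]
}

#' Annotate called regions to promoter intervals
#'
#' A gene is enriched if any called region overlaps its promoter interval by
#' at least 1 bp (0-based half-open coordinates on both sides). Genes hit by
#' several regions are reported once with their best peak score and the
#' number of supporting regions.
#'
#' @param regions called regions from [call_regions()].
#' @param promoters promoter annotation: `data.frame` with `chrom`, `start`,
#'   `end`, `gene` (0-based half-open), e.g. from [read_promoter_bed()].
#' @return `data.frame` with columns `gene`, `peak_score` (best over
#'   regions), `n_regions`, sorted by gene.
#' @export
annotate_regions <- function(regions, promoters) {
  stopifnot(is.data.frame(regions), is.data.frame(promoters))
  if (!all(c("chrom", "start", "end", "gene") %in% names(promoters))) {
    stop("annotate_regions: promoters need chrom, start, end, gene columns",
         call. = FALSE)
  }
  empty <- data.frame(gene = character(), peak_score = numeric(),
                      n_regions = integer(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) return(empty)
  unmatched <- setdiff(unique(regions$chrom), unique(promoters$chrom))
  if (length(unmatched) > 0L) {
    stop("annotate_regions: region chromosome(s) absent from annotation: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
  gr_prom <- GenomicRanges::GRanges(
    promoters$chrom, IRanges::IRanges(promoters$start + 1, promoters$end))
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_prom, minoverlap = 1L)
  if (length(hits) == 0L) return(empty)
  gene <- promoters$gene[S4Vectors::subjectHits(hits)]
  score <- regions$peak_score[S4Vectors::queryHits(hits)]
  best <- tapply(score, gene, max)
  nreg <- tapply(score, gene, length)
  out <- data.frame(gene = names(best),
                    peak_score = as.numeric(best),
                    n_regions = as.integer(nreg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
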