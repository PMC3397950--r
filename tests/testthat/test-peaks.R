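test_that("a planted block scores above cutoff and is called as a region", {
  set.seed(5)
  n <- 1000
  vals <- rnorm(n, 0, 0.5)
  block <- 401:410
  vals[block] <- vals[block] + 1.5
  probes <- center_log2_ratios(make_probes(vals))
  scores <- suppressMessages(score_probes(probes))
  # probes whose whole 5-probe window lies inside the block
  interior <- 403:408
  expect_true(all(scores$score[interior] >= 2.0))
  regions <- call_regions(scores, probes)
  block_start <- probes$start[401]
  block_end <- probes$end[410]
  hit <- regions$start < block_end & regions$end > block_start
  expect_equal(sum(hit), 1)
  expect_gte(regions$n_probes[hit], 5)
})

test_that("an isolated probe is skipped with score 0", {
  vals <- c(rnorm(50, 0, 0.5), 3)
  probes <- make_probes(vals[1:50])
  lone <- data.frame(probe_id = "chr9_lone", chrom = "chr9", start = 0,
                     end = 50, log2_ratio = 3, stringsAsFactors = FALSE)
  probes <- sort_probes(rbind(probes, lone))
  probes <- center_log2_ratios(probes)
  expect_message(scores <- score_probes(probes), "skipped")
  lone_row <- which(scores$probe_id == "chr9_lone")
  expect_true(scores$skipped[lone_row])
  expect_equal(scores$score[lone_row], 0)
})

test_that("unsorted probes are rejected", {
  probes <- center_log2_ratios(make_probes(rnorm(10)))
  expect_error(score_probes(probes[c(2, 1, 3:10), ]), "sorted")
})

test_that("null scores are calibrated at the cutoff (small array)", {
  set.seed(99)
  probes <- center_log2_ratios(make_probes(rnorm(2000, 0, 0.5)))
  scores <- score_probes(probes)
  expect_lt(mean(scores$score >= 2), 0.01 + 3 * sqrt(0.01 * 0.99 / 2000))
})

test_that("region merging follows the genomic gap rule", {
  mk_scores <- function(probes, qualifying) {
    data.frame(probe_id = probes$probe_id, d_plus = 0.5, p_value = 0.001,
               score = ifelse(seq_len(nrow(probes)) %in% qualifying, 3, 0),
               skipped = FALSE, stringsAsFactors = FALSE)
  }
  cfg <- peak_caller_config(merge_gap = 500)
  # three qualifying probes at 1000, 1100, 1200 -> one region
  probes <- make_probes(rep(0, 30))
  scores <- mk_scores(probes, 11:13)
  regions <- call_regions(scores, probes, cfg)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$n_probes, 3L)
  expect_equal(regions$start, probes$start[11])
  expect_equal(regions$end, probes$end[13])
  expect_equal(regions$peak_score, 3)
  # two clusters 5000 bp apart -> two regions
  probes2 <- make_probes(rep(0, 100))
  scores2 <- mk_scores(probes2, c(11, 12, 61, 62))
  regions2 <- call_regions(scores2, probes2, cfg)
  expect_equal(nrow(regions2), 2)
  # no probe above cutoff -> empty
  expect_equal(nrow(call_regions(mk_scores(probes, integer(0)), probes, cfg)),
               0)
  # single qualifying probe dropped by min support
  regions3 <- call_regions(mk_scores(probes, 5), probes, cfg)
  expect_equal(nrow(regions3), 0)
})

test_that("calls are invariant under a global intensity shift", {
  set.seed(17)
  vals <- rnorm(800, 0, 0.5)
  vals[101:110] <- vals[101:110] + 2
  p1 <- center_log2_ratios(make_probes(vals))
  p2 <- center_log2_ratios(make_probes(vals + 7))
  s1 <- suppressMessages(score_probes(p1))
  s2 <- suppressMessages(score_probes(p2))
  expect_equal(s1$score, s2$score, tolerance = 1e-9)
  expect_equal(call_regions(s1, p1)[, c("chrom", "start", "end")],
               call_regions(s2, p2)[, c("chrom", "start", "end")])
})

test_that("scoring and calling are deterministic", {
  set.seed(29)
  probes <- center_log2_ratios(make_probes(rnorm(500, 0, 0.5)))
  expect_identical(score_probes(probes), score_probes(probes))
})

test_that("promoter annotation respects half-open overlap", {
  regions <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                        peak_score = 2.5, n_probes = 5L,
                        stringsAsFactors = FALSE)
  prom <- function(s, e, g) data.frame(chrom = "chr1", start = s, end = e,
                                       gene = g, stringsAsFactors = FALSE)
  expect_equal(annotate_regions(regions, prom(1999, 3000, "gA"))$gene, "gA")
  expect_equal(nrow(annotate_regions(regions, prom(2000, 3000, "gB"))), 0)
})

test_that("a gene hit by two regions is listed once with the max score", {
  regions <- data.frame(chrom = "chr1", start = c(1000, 5000),
                        end = c(2000, 6000), peak_score = c(2.5, 4.0),
                        n_probes = c(3L, 4L), stringsAsFactors = FALSE)
  promoters <- data.frame(chrom = "chr1", start = 500, end = 6000,
                          gene = "gX", stringsAsFactors = FALSE)
  ann <- annotate_regions(regions, promoters)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$peak_score, 4.0)
  expect_equal(ann$n_regions, 2L)
})

test_that("chromosome mismatches are reported by name", {
  regions <- data.frame(chrom = "chrX", start = 0, end = 100,
                        peak_score = 3, n_probes = 2L,
                        stringsAsFactors = FALSE)
  promoters <- data.frame(chrom = "chr1", start = 0, end = 100, gene = "g",
                          stringsAsFactors = FALSE)
  expect_error(annotate_regions(regions, promoters), "chrX")
})

test_that("peak caller config validation names the offending field", {
  expect_error(peak_caller_config(window_width = 0), "window_width")
  expect_error(peak_caller_config(score_cutoff = -1), "score_cutoff")
  expect_error(peak_caller_config(min_probes_per_window = 0),
               "min_probes_per_window")
})
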