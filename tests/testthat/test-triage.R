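test_that("cancer-specific set logic", {
  expect_equal(cancer_specific_genes(c("A", "B", "C"), c("B", "C", "D"),
                                     "C"),
               "B")
  expect_equal(cancer_specific_genes(c("A", "B"), c("A", "B"),
                                     c("A", "B", "C")),
               character(0))
  expect_equal(cancer_specific_genes("A", "B", character(0)), character(0))
})

test_that("external evidence integration records which list matched", {
  ev <- integrate_external_evidence(c("g1", "g2", "g3"), "g1", c("g2", "g4"))
  expect_equal(ev$gene, c("g1", "g2"))
  expect_equal(ev$in_expr_down, c(TRUE, FALSE))
  expect_equal(ev$in_tdmr, c(FALSE, TRUE))
  expect_equal(nrow(integrate_external_evidence(c("g1", "g2"),
                                                character(0),
                                                character(0))), 0)
  all_in <- integrate_external_evidence(c("g1", "g2"), c("g1", "g2", "g9"),
                                        character(0))
  expect_equal(all_in$gene, c("g1", "g2"))
})

test_that("re-expression filter applies fold and line thresholds", {
  rec <- data.frame(gene = "g1", cell_line = c("HeLa", "SiHa", "CaSki"),
                    fold_change = c(1.1, 2.5, 0.9), stringsAsFactors = FALSE)
  expect_true(reexpression_filter("g1", rec)$reexpressed)
  rec$fold_change <- c(1.1, 1.5, 0.9)
  expect_false(reexpression_filter("g1", rec)$reexpressed)
  rec$fold_change <- c(2.5, 2.1, 0.9)
  expect_true(reexpression_filter("g1", rec, min_lines = 2L)$reexpressed)
  expect_false(reexpression_filter("g1", rec, min_lines = 3L)$reexpressed)
  expect_warning(out <- reexpression_filter(c("g1", "g2"), rec), "g2")
  expect_false(out$reexpressed[out$gene == "g2"])
})

test_that("msp exclusion partitions input with reasons", {
  pools <- make_pools(c("g1", "g2", "g3"))
  pools["g2", "Normal:N2"] <- 2L
  pools["g3", "Blood:B1"] <- 1L
  res <- msp_exclusion_filter(c("g1", "g2", "g3"), pools)
  expect_equal(res$retained, "g1")
  expect_equal(res$excluded$gene, c("g2", "g3"))
  expect_equal(res$excluded$reason, c("normal pool", "blood"))
  expect_equal(sort(c(res$retained, res$excluded$gene)),
               c("g1", "g2", "g3"))
  # blood flag alone excludes even with clean pools
  res2 <- msp_exclusion_filter("g1", pools,
                               blood_flags = c(g1 = TRUE))
  expect_equal(res2$excluded$reason, "blood")
  # positive_level raises the bar
  res3 <- msp_exclusion_filter("g2", pools, positive_level = 3L)
  expect_equal(res3$retained, "g2")
  expect_error(msp_exclusion_filter("missing", pools), "missing")
})

test_that("prioritization counts cancer pools and breaks ties by gene id", {
  pools <- make_pools(c("gX", "gY", "gZ"))
  pools["gX", 5:10] <- 3L   # 6 cancer pools
  pools["gY", 5:9] <- 2L    # 5
  pools["gZ", 5:8] <- 4L    # 4
  out <- prioritize_candidates(c("gZ", "gX", "gY"), pools,
                               min_cancer_pools = 5L)
  expect_equal(out$gene, c("gX", "gY", "gZ"))
  expect_equal(out$verdict, c("prioritized", "prioritized", "dropped"))
  # ties -> alphabetical
  pools2 <- make_pools(c("gB", "gA"))
  pools2[, 5:9] <- 2L
  out2 <- prioritize_candidates(c("gB", "gA"), pools2, min_cancer_pools = 5L)
  expect_equal(out2$gene, c("gA", "gB"))
  # all-zero matrix prioritizes nothing even at min 1
  pools3 <- make_pools(c("g1", "g2"))
  out3 <- prioritize_candidates(c("g1", "g2"), pools3, min_cancer_pools = 1L)
  expect_true(all(out3$verdict == "dropped"))
})

random_triage_input <- function(seed) {
  set.seed(seed)
  genes <- sprintf("G%03d", 1:60)
  scc <- sample(genes, 35)
  ac <- sample(genes, 35)
  normal <- sample(genes, 12)
  universe <- sort(unique(c(scc, ac, normal)))
  rec <- data.frame(gene = rep(universe, each = 2),
                    cell_line = rep(c("HeLa", "SiHa"), length(universe)),
                    fold_change = exp(rnorm(2 * length(universe), 0.5, 0.7)),
                    stringsAsFactors = FALSE)
  pools <- make_pools(universe)
  pools[, 5:12] <- matrix(sample(0:4, length(universe) * 8, replace = TRUE,
                                 prob = c(0.45, 0.2, 0.15, 0.1, 0.1)),
                          nrow = length(universe))
  pools[, 1:4] <- matrix(sample(0:1, length(universe) * 4, replace = TRUE,
                                prob = c(0.9, 0.1)), nrow = length(universe))
  list(scc = scc, ac = ac, normal = normal,
       expr_down = sample(genes, 20), tdmr = sample(genes, 25),
       reexpression = rec, pools = pools)
}

run_triage <- function(inp) {
  suppressWarnings(
    triage_candidates(inp$scc, inp$ac, inp$normal, inp$expr_down, inp$tdmr,
                      inp$reexpression, inp$pools))
}

test_that("funnel conserves genes and stages are nested", {
  for (seed in 1:5) {
    inp <- random_triage_input(seed)
    out <- run_triage(inp)
    expect_setequal(out$gene, unique(c(inp$scc, inp$ac, inp$normal)))
    f <- attr(out, "funnel")
    expect_true(all(diff(f) <= 0))  # survivors can only shrink
    # every gene carries exactly one verdict with a reason
    expect_true(all(nzchar(out$reason)))
    expect_true(all(out$verdict %in%
                      c("cancer_specific", "evidence_supported",
                        "confirmed_reexpressed", "excluded_normal_or_blood",
                        "prioritized", "dropped")))
    # verdict counts are consistent with the funnel record
    expect_equal(sum(out$verdict == "prioritized"), unname(f["prioritized"]))
  }
})

test_that("triage results are independent of input order", {
  inp <- random_triage_input(11)
  out1 <- run_triage(inp)
  inp2 <- inp
  set.seed(1)
  inp2$scc <- sample(inp2$scc)
  inp2$ac <- sample(inp2$ac)
  inp2$normal <- sample(inp2$normal)
  inp2$expr_down <- rev(inp2$expr_down)
  inp2$reexpression <- inp2$reexpression[rev(seq_len(nrow(inp2$reexpression))), ]
  out2 <- run_triage(inp2)
  expect_equal(out1, out2, ignore_attr = TRUE)
})

test_that("assay-failure drop list removes genes before pool filtering", {
  inp <- random_triage_input(21)
  out0 <- run_triage(inp)
  confirmed <- out0$gene[out0$verdict %in%
                           c("confirmed_reexpressed", "prioritized",
                             "excluded_normal_or_blood", "dropped") &
                           out0$reexpressed]
  expect_gt(length(confirmed), 0)
  drop <- confirmed[1]
  out <- suppressWarnings(
    triage_candidates(inp$scc, inp$ac, inp$normal, inp$expr_down, inp$tdmr,
                      inp$reexpression, inp$pools, msp_failed = drop))
  expect_equal(out$reason[out$gene == drop], "MSP assay failure")
})
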