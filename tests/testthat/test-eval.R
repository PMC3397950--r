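test_that("kruskal-wallis matches the closed form and handles degeneracy", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7,
               tolerance = 1e-12)
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("mann-whitney exact p equals full enumeration", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$statistic, 0)
  # identical multisets: no assignment is more extreme than observed
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(55)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    n <- sample(2:6, 1)
    a <- sample(1:8, m, replace = TRUE)  # ties likely
    b <- sample(1:8, n, replace = TRUE)
    res <- mann_whitney(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("mann-whitney large-sample p matches the corrected normal test", {
  set.seed(60)
  for (i in 1:10) {
    a <- rnorm(15)
    b <- rnorm(20, 0.4)
    res <- mann_whitney(a, b)
    expect_false(res$exact)
    expect_equal(res$p_value,
                 wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("median_ci covers the basics and is seed-stable", {
  const <- median_ci(rep(4.2, 20), seed = 1)
  expect_equal(const$median, 4.2)
  expect_equal(const$ci, c(4.2, 4.2))
  expect_equal(median_ci(1:101, seed = 1)$median, 51)
  tiny <- median_ci(c(1, 2), seed = 1)
  expect_true(tiny$flagged)
  expect_true(all(is.na(tiny$ci)))
  set.seed(70)
  x <- rlnorm(80, 0, 1)
  cis <- vapply(1:10, function(s) median_ci(x, seed = s)$ci, numeric(2))
  expect_lt(max(apply(cis, 1, function(v) diff(range(v)))), 0.05 * IQR(x))
})

test_that("dichotomization schemes split grades as specified", {
  s1 <- dichotomy_scheme("CIN2+/CIN1-")
  expect_equal(s1$case_grades, c("CIN2", "CIN3/CIS", "SCC"))
  expect_equal(s1$control_grades, c("Normal", "CIN1"))
  s3 <- dichotomy_scheme("SCC/SCC-")
  expect_equal(s3$case_grades, "SCC")
  expect_error(dichotomy_scheme("custom", case_grades = c("CIN1", "SCC")),
               "upper order segment")
  res <- data.frame(grade = c("Normal", "CIN2", "SCC"),
                    m_index = c(0.1, 2, 30))
  d <- dichotomize(res, s1)
  expect_equal(d$is_case, c(FALSE, TRUE, TRUE))
  expect_equal(attr(d, "counts"), c(cases = 2L, controls = 1L))
  expect_equal(nrow(dichotomize(res[0, ], s1)), 0)
  expect_error(dichotomize(data.frame(grade = "odd", m_index = 1), s1),
               "odd")
})

test_that("AUC equals the pairwise-comparison oracle, ties half-weighted", {
  expect_equal(auc_with_ci(c(1, 2, 3, 0.1, 0.2),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE))$auc, 1)
  set.seed(81)
  for (i in 1:30) {
    n1 <- sample(2:12, 1)
    n0 <- sample(2:12, 1)
    v <- c(sample(1:6, n1, replace = TRUE), sample(1:6, n0, replace = TRUE))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(auc_with_ci(v, lab)$auc, oracle_auc(v, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC and DeLong interval agree with pROC", {
  set.seed(82)
  v <- c(rnorm(40, 1), rnorm(60))
  lab <- rep(c(TRUE, FALSE), c(40, 60))
  ours <- auc_with_ci(v, lab)
  ref <- pROC::roc(lab, v, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci, ref_ci[c(1, 3)], tolerance = 1e-9)
  expect_error(auc_with_ci(v, rep(TRUE, 100)), "case and one control")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(83)
  v <- rlnorm(50)
  lab <- rep(c(TRUE, FALSE), 25)
  a1 <- auc_with_ci(v, lab)$auc
  a2 <- auc_with_ci(log(v), lab)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("cutoff selection follows Youden with documented tie-breaks", {
  v <- c(10, 20, 1, 2)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(select_cutoff(v, lab), 10)
  cfg_fixed <- eval_config(cutoff_criterion = "fixed", fixed_cutoff = 0.62)
  expect_equal(select_cutoff(v, lab, cfg_fixed), 0.62)
  expect_error(select_cutoff(v, lab, eval_config(cutoff_criterion = "fixed")),
               "fixed_cutoff")
  # identical arms: deterministic result across calls
  v2 <- c(1, 2, 3, 1, 2, 3)
  lab2 <- rep(c(TRUE, FALSE), each = 3)
  expect_identical(select_cutoff(v2, lab2), select_cutoff(v2, lab2))
})

test_that("sensitivity falls and specificity rises with the cutoff", {
  set.seed(84)
  v <- c(rlnorm(30, 1), rlnorm(40))
  lab <- rep(c(TRUE, FALSE), c(30, 40))
  cuts <- sort(unique(v))
  cfg <- eval_config()
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    d <- diagnostics_at_cutoff(v, lab, cuts[i], cfg)
    sens[i] <- d$sensitivity
    spec[i] <- d$specificity
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("diagnostics at a cutoff report Wilson intervals and accuracy", {
  cfg <- eval_config()
  d <- diagnostics_at_cutoff(c(1, 2, 3, 0), c(TRUE, TRUE, TRUE, FALSE),
                             0.5, cfg)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  expect_equal(d$accuracy, 1)
  expect_true(d$sensitivity_ci[1] <= 1 && d$sensitivity_ci[2] >= 1)
  # cutoff above the maximum: nothing positive
  d2 <- diagnostics_at_cutoff(c(1, 2, 3, 0), c(TRUE, TRUE, TRUE, FALSE),
                              99, cfg)
  expect_equal(d2$sensitivity, 0)
  expect_equal(d2$specificity, 1)
  # boundary: a value exactly at the cutoff is positive under 'ge'
  d3 <- diagnostics_at_cutoff(c(2, 1), c(TRUE, FALSE), 2, cfg)
  expect_equal(d3$sensitivity, 1)
})

test_that("power at a cutoff behaves at the extremes and the null", {
  v <- c(rep(1, 50), rep(0, 50))
  lab <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(power_at_cutoff(v, lab, 0.5)$power, 1)
  # equal nondegenerate positivity rates: power ~ alpha
  v2 <- rep(c(1, 0), 50)
  lab2 <- rep(c(TRUE, FALSE), each = 50)
  pw <- power_at_cutoff(v2, lab2, 0.5, alpha = 0.05)
  expect_equal(pw$power, 0.05, tolerance = 0.002)
  # degenerate 0/0 -> undefined, flagged
  pw0 <- power_at_cutoff(c(0, 0), c(TRUE, FALSE), 5)
  expect_true(pw0$flagged)
  expect_true(is.na(pw0$power))
})

test_that("evaluate_marker assembles grade and performance tables", {
  sim <- simulate_qmsp_cohort(cohort_sim_config(seed = 91L))
  mi <- cohort_m_indexes(sim$cohort)
  ev <- evaluate_marker(mi$results, cfg = eval_config(bootstrap_reps = 200L))
  expect_s3_class(ev, "marker_evaluation")
  expect_equal(nrow(ev$grade_summary), 5)
  expect_equal(nrow(ev$performance), 3)
  expect_true(all(ev$performance$auc >= ev$performance$auc_lo &
                    ev$performance$auc <= ev$performance$auc_hi))
  expect_true(all(ev$performance$auc > 0.5))  # severity-increasing marker
  expect_true(is.na(ev$grade_summary$p_vs_normal[
    ev$grade_summary$grade == "Normal"]))
  expect_output(print(ev), "Kruskal-Wallis")
})

test_that("evaluate_marker on an exchangeable cohort gives null AUCs", {
  gp <- data.frame(grade = grade_levels(), median = 1, sdlog = 1)
  sim <- simulate_qmsp_cohort(
    cohort_sim_config(grade_params = gp, n_per_grade = rep(60L, 5),
                      failure_rate = 0, seed = 92L))
  mi <- cohort_m_indexes(sim$cohort)
  ev <- evaluate_marker(mi$results, cfg = eval_config(bootstrap_reps = 200L))
  expect_true(all(abs(ev$performance$auc - 0.5) < 0.12))
  expect_gt(ev$kruskal_wallis$p_value, 0.001)
})

test_that("evaluate_marker refuses single-grade input", {
  res <- data.frame(grade = rep("SCC", 10), m_index = rlnorm(10),
                    valid = TRUE)
  expect_error(evaluate_marker(res), "two grades")
})
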