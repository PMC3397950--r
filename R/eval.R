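#' Evaluation configuration
#'
#' @param alpha type-1 error for power and confidence levels (default 0.05,
#'   two-sided; intervals are reported at `1 - alpha`).
#' @param significance_p reporting threshold for test p-values
#'   (default 0.01, two-sided).
#' @param bootstrap_reps bootstrap resamples for median intervals
#'   (default 2000, minimum 100).
#' @param bootstrap_seed seed for the bootstrap.
#' @param cutoff_criterion `"youden"` (maximize sensitivity + specificity -
#'   1 over observed values) or `"fixed"` (use `fixed_cutoff`, e.g. to
#'   reproduce a published operating point).
#' @param fixed_cutoff M-index cutoff used when `cutoff_criterion` is
#'   `"fixed"`.
#' @param positive_rule call a sample positive when its value is `>=` the
#'   cutoff (`"ge"`, default) or strictly `>` (`"gt"`).
#' @return an `eval_config` list.
#' @export
eval_config <- function(alpha = 0.05,
                        significance_p = 0.01,
                        bootstrap_reps = 2000L,
                        bootstrap_seed = 1L,
                        cutoff_criterion = c("youden", "fixed"),
                        fixed_cutoff = NULL,
                        positive_rule = c("ge", "gt")) {
  check_field(is_number(alpha) && alpha > 0 && alpha < 1,
              "alpha", "must be in (0, 1)")
  check_field(is_number(significance_p) && significance_p > 0 &&
                significance_p < 1, "significance_p", "must be in (0, 1)")
  check_field(is_count(bootstrap_reps, min = 100L),
              "bootstrap_reps", "must be a count >= 100")
  check_field(is_count(bootstrap_seed, min = 0L),
              "bootstrap_seed", "must be a non-negative integer")
  cutoff_criterion <- match.arg(cutoff_criterion)
  positive_rule <- match.arg(positive_rule)
  if (!is.null(fixed_cutoff)) {
    check_field(is_number(fixed_cutoff), "fixed_cutoff", "must be a number")
  }
  structure(list(alpha = alpha,
                 significance_p = significance_p,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 bootstrap_seed = as.integer(bootstrap_seed),
                 cutoff_criterion = cutoff_criterion,
                 fixed_cutoff = fixed_cutoff,
                 positive_rule = positive_rule),
            class = "eval_config")
}

#' Grade dichotomization schemes
#'
#' The three case/control splits of the five ordered grades used in
#' pre-validation: `"CIN2+/CIN1-"` (cases CIN2 and worse), `"CIN3+/CIN2-"`
#' (cases CIN3/CIS and worse), `"SCC/SCC-"` (cases SCC only). Cases are
#' always the upper order segment; cases and controls partition the grades.
#'
#' @param name one of the three preset names, or a custom name if
#'   `case_grades` is given.
#' @param case_grades optional custom case grade set (upper order segment of
#'   [grade_levels()]).
#' @return a `dichotomy_scheme` list with `name`, `case_grades`,
#'   `control_grades`.
#' @export
dichotomy_scheme <- function(name, case_grades = NULL) {
  lv <- grade_levels()
  if (is.null(case_grades)) {
    case_grades <- switch(name,
      "CIN2+/CIN1-" = lv[3:5],
      "CIN3+/CIN2-" = lv[4:5],
      "SCC/SCC-" = lv[5],
      stop("dichotomy_scheme: unknown scheme '", name,
           "'; give case_grades explicitly", call. = FALSE))
  }
  if (!all(case_grades %in% lv)) {
    stop("dichotomy_scheme: case grades outside the five categories: ",
         paste(setdiff(case_grades, lv), collapse = ", "), call. = FALSE)
  }
  ranks <- match(case_grades, lv)
  if (min(ranks) + length(ranks) - 1L != length(lv)) {
    stop("dichotomy_scheme: cases must be the upper order segment",
         call. = FALSE)
  }
  structure(list(name = name,
                 case_grades = lv[lv %in% case_grades],
                 control_grades = lv[!lv %in% case_grades]),
            class = "dichotomy_scheme")
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Midrank-based H with tie correction and a chi-square reference with
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis: need at least two groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) {
    stop("kruskal_wallis: empty group", call. = FALSE)
  }
  if (length(unique(unlist(groups))) == 1L) {
    # no rank variation: H = 0 by convention (tie correction degenerates)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic),
       p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}

# Exact permutation distribution of the Mann-Whitney U statistic on
# midranks: counts of size-m subsets of the pooled midrank multiset by
# (doubled, hence integer) rank sum. Shift-algorithm dynamic program.
mw_exact_dist <- function(rank2, m) {
  smax <- sum(sort(rank2, decreasing = TRUE)[seq_len(m)])
  ways <- matrix(0, nrow = m + 1L, ncol = smax + 1L)
  ways[1L, 1L] <- 1
  for (e in rank2) {
    for (i in seq(m, 1L)) {
      cols <- seq_len(smax + 1L - e)
      ways[i + 1L, cols + e] <- ways[i + 1L, cols + e] + ways[i, cols]
    }
  }
  ways[m + 1L, ]
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where an `a` value exceeds a `b` value, ties counted
#' one-half (equivalently, midrank-based). The two-sided p-value is exact
#' when both samples have at most `exact_limit` values: the full permutation
#' distribution of `U` over all C(m+n, m) labelings is computed by a dynamic
#' program over the pooled midranks (ties included), and
#' `p = P(|U - mn/2| >= |u - mn/2|)`. Larger samples use the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact_limit maximum per-sample size for the exact p-value
#'   (default 8).
#' @return list with `statistic` (U for sample `a`), `p_value`, `exact`.
#' @export
mann_whitney <- function(a, b, exact_limit = 8L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("mann_whitney: both samples must be non-empty", call. = FALSE)
  }
  m <- length(a)
  n <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m <= exact_limit && n <= exact_limit) {
    dist <- mw_exact_dist(as.integer(round(2 * r)), m)
    u_all <- (seq_along(dist) - 1) / 2 - m * (m + 1) / 2
    dev <- abs(u_all - m * n / 2)
    obs <- abs(u - m * n / 2)
    p <- sum(dist[dev >= obs - 1e-9]) / sum(dist)
    return(list(statistic = u, p_value = min(1, p), exact = TRUE))
  }
  ties <- table(r)
  sigma2 <- (m * n / 12) *
    ((m + n + 1) - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1, exact = FALSE))
  z <- (u - m * n / 2 - sign(u - m * n / 2) * 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

#' Median with percentile-bootstrap confidence interval
#'
#' @param values numeric vector.
#' @param reps bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level interval coverage (default 0.95).
#' @return list with `median`, `ci` (length 2; `NA` and `flagged = TRUE`
#'   when fewer than 3 values), `flagged`.
#' @export
median_ci <- function(values, reps = 2000L, seed = 1L, conf_level = 0.95) {
  check_field(is_count(reps, min = 100L), "reps", "must be a count >= 100")
  if (length(values) == 0L) stop("median_ci: empty input", call. = FALSE)
  med <- median(values)
  if (length(values) < 3L) {
    return(list(median = med, ci = c(NA_real_, NA_real_), flagged = TRUE))
  }
  boots <- with_seed(seed, {
    vapply(seq_len(reps),
           function(i) median(sample(values, replace = TRUE)),
           numeric(1))
  })
  qs <- quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                 names = FALSE)
  list(median = med, ci = qs, flagged = FALSE)
}

#' Dichotomize graded results into cases and controls
#'
#' @param results valid QMSP results (`data.frame` with `grade` and
#'   `m_index`; see [cohort_m_indexes()]). All rows must be valid
#'   (detection failures are excluded before evaluation).
#' @param scheme a [dichotomy_scheme()].
#' @return `data.frame` with `value` (M-index) and `is_case`; per-arm counts
#'   attached as attribute `counts`.
#' @export
dichotomize <- function(results, scheme) {
  stopifnot(is.data.frame(results), inherits(scheme, "dichotomy_scheme"))
  if ("valid" %in% names(results) && !all(results$valid)) {
    stop("dichotomize: invalid (detection-failure) rows present; ",
         "exclude them first", call. = FALSE)
  }
  grade <- as.character(results$grade)
  outside <- setdiff(unique(grade), grade_levels())
  if (length(outside) > 0L) {
    stop("dichotomize: grade(s) outside the five categories: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(value = results$m_index,
                    is_case = grade %in% scheme$case_grades,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(cases = sum(out$is_case),
                           controls = sum(!out$is_case))
  out
}

#' AUC with DeLong confidence interval
#'
#' AUC by the Mann-Whitney identity (`U / (n_cases * n_controls)`, ties
#' counted one-half) and its confidence interval by the DeLong placement
#' variance, truncated to \[0, 1\].
#'
#' @param values marker values.
#' @param labels logical, `TRUE` for cases.
#' @param conf_level interval coverage (default 0.95).
#' @return list with `auc`, `ci`, `se`, `n_cases`, `n_controls`.
#' @export
auc_with_ci <- function(values, labels, conf_level = 0.95) {
  stopifnot(length(values) == length(labels), is.logical(labels))
  x <- values[labels]
  y <- values[!labels]
  n1 <- length(x)
  n0 <- length(y)
  if (n1 == 0L || n0 == 0L) {
    stop("auc_with_ci: need at least one case and one control", call. = FALSE)
  }
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  se <- sqrt((if (n1 > 1L) var(v10) / n1 else 0) +
               (if (n0 > 1L) var(v01) / n0 else 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  list(auc = auc, ci = ci, se = se, n_cases = n1, n_controls = n0)
}

sens_spec_at <- function(values, labels, cutoff, positive_rule) {
  pos <- if (positive_rule == "ge") values >= cutoff else values > cutoff
  c(sensitivity = mean(pos[labels]), specificity = mean(!pos[!labels]))
}

#' Select an operating cutoff
#'
#' With criterion `"youden"`, returns the observed marker value maximizing
#' Youden's J (sensitivity + specificity - 1) under the configured positive
#' rule; ties are broken toward higher specificity, then toward the larger
#' cutoff, so the result is deterministic. With `"fixed"`, returns
#' `cfg$fixed_cutoff` unchanged.
#'
#' @param values marker values.
#' @param labels logical, `TRUE` for cases.
#' @param cfg an [eval_config()].
#' @return the cutoff (length-1 numeric).
#' @export
select_cutoff <- function(values, labels, cfg = eval_config()) {
  stopifnot(length(values) == length(labels), is.logical(labels))
  if (cfg$cutoff_criterion == "fixed") {
    if (is.null(cfg$fixed_cutoff)) {
      stop("select_cutoff: criterion 'fixed' requires fixed_cutoff",
           call. = FALSE)
    }
    return(cfg$fixed_cutoff)
  }
  if (!any(labels) || all(labels)) {
    stop("select_cutoff: need both cases and controls", call. = FALSE)
  }
  cand <- sort(unique(values))
  ss <- vapply(cand, function(cv) sens_spec_at(values, labels, cv,
                                               cfg$positive_rule),
               numeric(2))
  j <- ss[1, ] + ss[2, ] - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[ss[2, best] >= max(ss[2, best]) - 1e-12]
  cand[max(best)]
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(successes, n, conf_level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Sensitivity, specificity and accuracy at a cutoff
#'
#' Positivity follows the configured rule (default: positive iff value is
#' at or above the cutoff). Proportion intervals are Wilson score intervals
#' at `1 - alpha`.
#'
#' @param values marker values.
#' @param labels logical, `TRUE` for cases.
#' @param cutoff operating cutoff.
#' @param cfg an [eval_config()].
#' @return list with `sensitivity`, `sensitivity_ci`, `specificity`,
#'   `specificity_ci`, `accuracy`, `tp`, `fp`, `tn`, `fn`.
#' @export
diagnostics_at_cutoff <- function(values, labels, cutoff,
                                  cfg = eval_config()) {
  stopifnot(length(values) == length(labels), is.logical(labels))
  if (!any(labels) || all(labels)) {
    stop("diagnostics_at_cutoff: need both cases and controls",
         call. = FALSE)
  }
  pos <- if (cfg$positive_rule == "ge") values >= cutoff else values > cutoff
  tp <- sum(pos & labels)
  fn <- sum(!pos & labels)
  tn <- sum(!pos & !labels)
  fp <- sum(pos & !labels)
  conf <- 1 - cfg$alpha
  list(sensitivity = tp / (tp + fn),
       sensitivity_ci = wilson_ci(tp, tp + fn, conf),
       specificity = tn / (tn + fp),
       specificity_ci = wilson_ci(tn, tn + fp, conf),
       accuracy = (tp + tn) / length(values),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Power of the two-proportion test at a cutoff
#'
#' Power of the two-sided two-proportion z-test (normal approximation,
#' pooled null standard error) comparing the positivity rates of cases and
#' controls at the observed arm sizes and level `alpha`. When neither arm
#' has any positives (or both are fully positive) the rates are degenerate
#' and equal, the test is undefined, and `NA` is returned with
#' `flagged = TRUE`.
#'
#' @param values marker values.
#' @param labels logical, `TRUE` for cases.
#' @param cutoff operating cutoff.
#' @param alpha two-sided type-1 error (default 0.05).
#' @param positive_rule `"ge"` (default) or `"gt"`.
#' @return list with `power`, `p_case`, `p_control`, `flagged`.
#' @export
power_at_cutoff <- function(values, labels, cutoff, alpha = 0.05,
                            positive_rule = "ge") {
  stopifnot(length(values) == length(labels), is.logical(labels))
  if (!any(labels) || all(labels)) {
    stop("power_at_cutoff: need both cases and controls", call. = FALSE)
  }
  pos <- if (positive_rule == "ge") values >= cutoff else values > cutoff
  n1 <- sum(labels)
  n2 <- sum(!labels)
  p1 <- mean(pos[labels])
  p2 <- mean(pos[!labels])
  delta <- p1 - p2
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (se1 == 0) {
    if (delta == 0) {
      return(list(power = NA_real_, p_case = p1, p_control = p2,
                  flagged = TRUE))
    }
    return(list(power = 1, p_case = p1, p_control = p2, flagged = FALSE))
  }
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  za <- qnorm(1 - alpha / 2)
  pw <- pnorm((delta - za * se0) / se1) + pnorm((-delta - za * se0) / se1)
  list(power = pw, p_case = p1, p_control = p2, flagged = FALSE)
}

#' Evaluate a methylation marker across grades and dichotomization schemes
#'
#' The full evaluation battery: a Kruskal-Wallis test across all grades
#' present, per-grade medians with bootstrap intervals and Mann-Whitney
#' comparisons against Normal (a grade-summary table), then for each
#' dichotomization scheme: AUC with DeLong interval, cutoff selection,
#' sensitivity/specificity/accuracy with Wilson intervals, and power at the
#' cutoff (a performance table). Detection failures (`valid = FALSE` rows)
#' are excluded listwise and counted.
#'
#' @param results QMSP results from [cohort_m_indexes()] (the `results`
#'   element, or any `data.frame` with `grade`, `m_index`, optionally
#'   `valid`).
#' @param schemes list of [dichotomy_scheme()] objects (default: the three
#'   preset schemes).
#' @param cfg an [eval_config()].
#' @return object of class `marker_evaluation`: list with `grade_summary`,
#'   `kruskal_wallis`, `performance` (one row per scheme), `n_excluded`,
#'   `config`.
#' @export
evaluate_marker <- function(results,
                            schemes = lapply(c("CIN2+/CIN1-", "CIN3+/CIN2-",
                                               "SCC/SCC-"),
                                             dichotomy_scheme),
                            cfg = eval_config()) {
  stopifnot(is.data.frame(results),
            all(c("grade", "m_index") %in% names(results)))
  n_excluded <- 0L
  if ("valid" %in% names(results)) {
    n_excluded <- sum(!results$valid)
    results <- results[results$valid, , drop = FALSE]
  }
  grade <- parse_grade(as.character(results$grade))
  m <- results$m_index
  present <- levels(grade)[levels(grade) %in% unique(as.character(grade))]
  if (length(present) < 2L) {
    stop("evaluate_marker: need at least two grades with valid samples",
         call. = FALSE)
  }
  groups <- split(m, grade, drop = TRUE)[present]
  kw <- kruskal_wallis(groups)

  gs_rows <- lapply(seq_along(present), function(i) {
    g <- present[i]
    v <- groups[[g]]
    mc <- median_ci(v, reps = cfg$bootstrap_reps,
                    seed = cfg$bootstrap_seed + i,
                    conf_level = 1 - cfg$alpha)
    mw_p <- if (g != "Normal" && "Normal" %in% present) {
      mann_whitney(v, groups[["Normal"]])$p_value
    } else {
      NA_real_
    }
    data.frame(grade = g, n = length(v), median = mc$median,
               median_lo = mc$ci[1], median_hi = mc$ci[2],
               p_vs_normal = mw_p, stringsAsFactors = FALSE)
  })
  grade_summary <- do.call(rbind, c(gs_rows, list(make.row.names = FALSE)))

  perf_rows <- lapply(schemes, function(sch) {
    d <- dichotomize(data.frame(grade = as.character(grade), m_index = m,
                                stringsAsFactors = FALSE), sch)
    if (!any(d$is_case) || all(d$is_case)) {
      return(NULL)
    }
    roc <- auc_with_ci(d$value, d$is_case, conf_level = 1 - cfg$alpha)
    cutoff <- select_cutoff(d$value, d$is_case, cfg)
    dg <- diagnostics_at_cutoff(d$value, d$is_case, cutoff, cfg)
    pw <- power_at_cutoff(d$value, d$is_case, cutoff, alpha = cfg$alpha,
                          positive_rule = cfg$positive_rule)
    mw_p <- mann_whitney(d$value[d$is_case], d$value[!d$is_case])$p_value
    data.frame(scheme = sch$name, cutoff = cutoff,
               auc = roc$auc, auc_lo = roc$ci[1], auc_hi = roc$ci[2],
               sensitivity = dg$sensitivity,
               sens_lo = dg$sensitivity_ci[1],
               sens_hi = dg$sensitivity_ci[2],
               specificity = dg$specificity,
               spec_lo = dg$specificity_ci[1],
               spec_hi = dg$specificity_ci[2],
               accuracy = dg$accuracy, power = pw$power,
               mw_p = mw_p,
               n_cases = roc$n_cases, n_controls = roc$n_controls,
               stringsAsFactors = FALSE)
  })
  perf_rows <- perf_rows[!vapply(perf_rows, is.null, logical(1))]
  performance <- if (length(perf_rows) > 0L) {
    do.call(rbind, c(perf_rows, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  structure(list(grade_summary = grade_summary,
                 kruskal_wallis = kw,
                 performance = performance,
                 n_excluded = n_excluded,
                 config = cfg),
            class = "marker_evaluation")
}

#' @export
print.marker_evaluation <- function(x, ...) {
  cat("Marker evaluation\n")
  cat(sprintf("  Kruskal-Wallis across grades: H = %.3f, df = %d, p = %.3g\n",
              x$kruskal_wallis$statistic, x$kruskal_wallis$df,
              x$kruskal_wallis$p_value))
  if (x$n_excluded > 0L) {
    cat(sprintf("  Detection failures excluded: %d\n", x$n_excluded))
  }
  cat("\nGrade summary (median M-index, bootstrap CI, Mann-Whitney",
      "vs Normal):\n")
  print(x$grade_summary, digits = 3, row.names = FALSE)
  if (nrow(x$performance) > 0L) {
    cat("\nDiagnostic performance per dichotomization:\n")
    print(x$performance, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
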