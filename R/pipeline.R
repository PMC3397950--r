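#' Pipeline run configuration
#'
#' Bundles the per-stage configurations and one top-level seed. In
#' `"simulate"` mode all inputs are generated; in `"files"` mode `paths`
#' must name every input. Stage seeds are expanded from the top-level seed
#' by the documented rule in the package (see `stage_seeds`), so each stage
#' is independently reproducible. Defaults equal the published analysis
#' values where one exists: window 500 bp, score cutoff 2.0, reference-Cp
#' failure cutoff 36, M-index scale 10000, alpha 0.05.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param seed top-level integer seed.
#' @param tiling a [tiling_sim_config()] (simulate mode). Its `seed` field
#'   is overridden by the derived stage seed.
#' @param peaks a [peak_caller_config()].
#' @param cohort a [cohort_sim_config()] (simulate mode); seed overridden
#'   likewise.
#' @param eval an [eval_config()]; its `bootstrap_seed` is overridden by the
#'   derived stage seed.
#' @param triage list of triage thresholds (`min_fold`, `min_lines`,
#'   `positive_level`, `min_cancer_pools`, `msp_failed`).
#' @param failure_cp reference-gene Cp above which a QMSP reaction is a
#'   detection failure (default 36).
#' @param paths named list of input paths for `"files"` mode: `probes_scc`,
#'   `probes_ac`, `probes_normal`, `promoters`, `expr_down`, `tdmr`,
#'   `reexpression`, `pools`, `cp_table`.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "files"),
                       seed = 1L,
                       tiling = tiling_sim_config(),
                       peaks = peak_caller_config(),
                       cohort = cohort_sim_config(),
                       eval = eval_config(),
                       triage = list(min_fold = 2.0, min_lines = 1L,
                                     positive_level = 1L,
                                     min_cancer_pools = 5L,
                                     msp_failed = character()),
                       failure_cp = 36,
                       paths = list()) {
  mode <- match.arg(mode)
  check_field(is_count(seed, min = 0L), "seed",
              "must be a non-negative integer")
  check_field(is_number(failure_cp) && failure_cp > 0,
              "failure_cp", "must be > 0")
  structure(list(mode = mode, seed = as.integer(seed), tiling = tiling,
                 peaks = peaks, cohort = cohort, eval = eval,
                 triage = triage, failure_cp = failure_cp, paths = paths),
            class = "run_config")
}

#' Simulate triage evidence consistent with tiling ground truth
#'
#' Generates the external inputs the triage funnel consumes, anchored on the
#' simulated tiling truth: an expression-down list and a T-DMR list that
#' each cover part of the truly cancer-specific genes plus decoys,
#' re-expression fold changes in three cell lines (a configurable fraction
#' of evidence-supported genes re-express), and a pooled-MSP matrix
#' (4 Normal, 4 SCC, 4 AC pools plus one blood column) in which a fraction
#' of candidates is methylated across many cancer pools and a small fraction
#' is methylated in normal pools or blood.
#'
#' @param truth tiling truth from [simulate_tiling_groups()].
#' @param genes full gene universe (the promoter annotation's gene column).
#' @param seed integer seed.
#' @param evidence_coverage probability a cancer-specific gene appears in
#'   each evidence list (default 0.6).
#' @param decoy_fraction fraction of non-candidate genes entering each
#'   evidence list (default 0.1).
#' @param reexpression_rate fraction of genes that re-express at >= 2-fold
#'   (default 0.7).
#' @param normal_contamination probability a candidate is methylated in a
#'   normal pool or blood (default 0.2).
#' @return list with `expr_down`, `tdmr`, `reexpression`, `pools`,
#'   `blood_flags`.
#' @export
simulate_triage_evidence <- function(truth, genes, seed = 1L,
                                     evidence_coverage = 0.6,
                                     decoy_fraction = 0.1,
                                     reexpression_rate = 0.7,
                                     normal_contamination = 0.2) {
  genes <- sort(unique(genes))
  scc <- truth$gene[truth$group == "SCC"]
  ac <- truth$gene[truth$group == "AC"]
  nrm <- truth$gene[truth$group == "Normal"]
  target <- cancer_specific_genes(scc, ac, nrm)
  other <- setdiff(genes, target)
  with_seed(seed, {
    expr_down <- sort(c(target[runif(length(target)) < evidence_coverage],
                        other[runif(length(other)) < decoy_fraction]))
    tdmr <- sort(c(target[runif(length(target)) < evidence_coverage],
                   other[runif(length(other)) < decoy_fraction]))
    cell_lines <- c("HeLa", "SiHa", "CaSki")
    reexpression <- data.frame(
      gene = rep(genes, each = length(cell_lines)),
      cell_line = rep(cell_lines, times = length(genes)),
      stringsAsFactors = FALSE)
    responds <- runif(length(genes)) < reexpression_rate
    names(responds) <- genes
    base_fold <- exp(rnorm(nrow(reexpression), log(1.1), 0.3))
    hi_fold <- exp(rnorm(nrow(reexpression), log(4), 0.5))
    use_hi <- responds[reexpression$gene] &
      (seq_len(nrow(reexpression)) %% length(cell_lines) == 1L)
    reexpression$fold_change <- ifelse(use_hi, hi_fold, base_fold)
    pool_names <- c(sprintf("Normal:N%d", 1:4), sprintf("SCC:S%d", 1:4),
                    sprintf("AC:A%d", 1:4), "Blood:B1")
    pools <- matrix(0L, nrow = length(genes), ncol = length(pool_names),
                    dimnames = list(genes, pool_names))
    contaminated <- runif(length(genes)) < normal_contamination
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      if (g %in% target) {
        n_pos <- sample(3:8, 1)
        cancer_cols <- 4L + sample.int(8L, n_pos)
        pools[gi, cancer_cols] <- sample(2:4, n_pos, replace = TRUE)
      } else {
        n_pos <- sample(0:2, 1)
        if (n_pos > 0) {
          pools[gi, 4L + sample.int(8L, n_pos)] <-
            sample(1:2, n_pos, replace = TRUE)
        }
      }
      if (contaminated[gi]) {
        if (runif(1) < 0.5) {
          pools[gi, sample.int(4L, 1)] <- sample(1:3, 1)
        } else {
          pools[gi, 13L] <- sample(1:3, 1)
        }
      }
    }
    blood_flags <- setNames(pools[, 13L] > 0, genes)
    list(expr_down = expr_down, tdmr = tdmr, reexpression = reexpression,
         pools = pools, blood_flags = blood_flags)
  })
}

run_stage <- function(out_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

require_path <- function(paths, key) {
  p <- paths[[key]]
  if (is.null(p) || !file.exists(p)) {
    stop(sprintf("missing input file for '%s': %s", key,
                 if (is.null(p)) "(not given)" else p), call. = FALSE)
  }
  p
}

#' Run the full discovery and pre-validation pipeline
#'
#' Executes simulate (optional) -> center -> score -> call -> annotate ->
#' triage -> M-index -> evaluate, writing per-stage outputs, the effective
#' configuration (`config.yaml`) and a run log to `out_dir`. Stage failures
#' abort with a stage-named error and leave a `FAILED` marker beside the
#' partial outputs. If triage prioritizes no gene, the evaluation stage is
#' skipped with a logged notice. Re-running with the same configuration
#' reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; the run log lists every file written.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  log_lines <- c(sprintf("cervmeth %s | R %s",
                         as.character(packageVersion("cervmeth")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("top-level seed: %d", config$seed),
                 sprintf("mode: %s", config$mode))
  seeds <- stage_seeds(config$seed, 4L)
  log_lines <- c(log_lines,
                 sprintf("stage seeds (tiling, evidence, cohort, bootstrap): %s",
                         paste(seeds, collapse = ", ")))
  cfg_echo <- list(mode = config$mode, seed = config$seed,
                   peaks = unclass(config$peaks),
                   triage = config$triage,
                   failure_cp = config$failure_cp,
                   eval = unclass(config$eval))

  groups <- c("SCC", "AC", "Normal")
  if (config$mode == "simulate") {
    tiling_cfg <- config$tiling
    tiling_cfg$seed <- seeds[1]
    cfg_echo$tiling <- unclass(tiling_cfg)
    sim <- run_stage(out_dir, "simulate", simulate_tiling_groups(tiling_cfg))
    probes <- sim$probes
    promoters <- sim$promoters
    write_tsv(sim$truth, file.path(out_dir, "tiling_truth.tsv"))
    ev <- run_stage(out_dir, "simulate",
                    simulate_triage_evidence(sim$truth, promoters$gene,
                                             seed = seeds[2]))
    for (g in groups) {
      write_probe_table(probes[[g]],
                        file.path(out_dir, sprintf("probes_%s.tsv",
                                                   tolower(g))))
    }
    write_promoter_bed(promoters, file.path(out_dir, "promoters.bed"))
    write_gene_list(ev$expr_down, file.path(out_dir, "expr_down.txt"))
    write_gene_list(ev$tdmr, file.path(out_dir, "tdmr.txt"))
    write_tsv(ev$reexpression, file.path(out_dir, "reexpression.tsv"))
    write_pool_matrix(ev$pools, file.path(out_dir, "pools.tsv"))
  } else {
    p <- config$paths
    probes <- list(SCC = read_probe_table(require_path(p, "probes_scc")),
                   AC = read_probe_table(require_path(p, "probes_ac")),
                   Normal =
                     read_probe_table(require_path(p, "probes_normal")))
    promoters <- read_promoter_bed(require_path(p, "promoters"))
    ev <- list(expr_down = read_gene_list(require_path(p, "expr_down")),
               tdmr = read_gene_list(require_path(p, "tdmr")),
               reexpression = read.delim(require_path(p, "reexpression"),
                                         stringsAsFactors = FALSE),
               pools = read_pool_matrix(require_path(p, "pools")),
               blood_flags = NULL)
  }

  enriched <- list()
  for (g in groups) {
    enriched[[g]] <- run_stage(out_dir, paste0("callpeaks_", g), {
      centered <- center_log2_ratios(probes[[g]],
                                     biweight_c = config$peaks$biweight_c,
                                     biweight_tol = config$peaks$biweight_tol)
      scores <- score_probes(centered, config$peaks)
      regions <- call_regions(scores, centered, config$peaks)
      write_regions_bed(regions,
                        file.path(out_dir, sprintf("regions_%s.bed",
                                                   tolower(g))))
      annotate_regions(regions, promoters)
    })
    log_lines <- c(log_lines,
                   sprintf("%s: %d enriched genes", g,
                           nrow(enriched[[g]])))
  }

  tri <- config$triage
  triage <- run_stage(out_dir, "triage",
    triage_candidates(enriched$SCC$gene, enriched$AC$gene,
                      enriched$Normal$gene,
                      expr_down = ev$expr_down, tdmr = ev$tdmr,
                      reexpression = ev$reexpression, pools = ev$pools,
                      blood_flags = ev$blood_flags,
                      msp_failed = tri$msp_failed %||% character(),
                      min_fold = tri$min_fold %||% 2.0,
                      min_lines = tri$min_lines %||% 1L,
                      positive_level = tri$positive_level %||% 1L,
                      min_cancer_pools = tri$min_cancer_pools %||% 5L))
  write_tsv(triage, file.path(out_dir, "triage.tsv"))
  funnel <- attr(triage, "funnel")
  log_lines <- c(log_lines,
                 paste("triage funnel:",
                       paste(names(funnel), funnel, sep = "=",
                             collapse = " -> ")))

  if (config$mode == "simulate") {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- seeds[3]
    cfg_echo$cohort <- list(grade_params = cohort_cfg$grade_params,
                            n_per_grade = cohort_cfg$n_per_grade,
                            cp_ref_mean = cohort_cfg$cp_ref_mean,
                            cp_ref_sd = cohort_cfg$cp_ref_sd,
                            failure_rate = cohort_cfg$failure_rate,
                            seed = cohort_cfg$seed)
    qsim <- run_stage(out_dir, "simulate_cohort",
                      simulate_qmsp_cohort(cohort_cfg))
    cp_table <- qsim$cohort
    write_cp_table(cp_table, file.path(out_dir, "cohort.tsv"))
  } else {
    cp_table <- read_cp_table(require_path(config$paths, "cp_table"))
  }

  mi <- run_stage(out_dir, "mindex",
                  cohort_m_indexes(cp_table,
                                   failure_cutoff = config$failure_cp))
  write_tsv(mi$results, file.path(out_dir, "mindex.tsv"))
  log_lines <- c(log_lines,
                 sprintf("m-index: %d samples, %d detection failures",
                         nrow(mi$results), sum(!mi$results$valid)))

  n_prioritized <- sum(triage$verdict == "prioritized")
  if (n_prioritized == 0L) {
    log_lines <- c(log_lines,
                   "notice: no prioritized candidates; evaluation skipped")
  } else {
    eval_cfg <- config$eval
    eval_cfg$bootstrap_seed <- seeds[4]
    evaluation <- run_stage(out_dir, "evaluate",
                            evaluate_marker(mi$results, cfg = eval_cfg))
    write_evaluation(evaluation, out_dir)
    log_lines <- c(log_lines,
                   sprintf("evaluation: KW p = %.3g across %d grades",
                           evaluation$kruskal_wallis$p_value,
                           nrow(evaluation$grade_summary)))
  }

  yaml::write_yaml(cfg_echo, file.path(out_dir, "config.yaml"))
  log_lines <- c(log_lines, "defaults applied are echoed in config.yaml")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
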