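#' Tiling-array simulation configuration
#'
#' Study conditions for the synthetic MeDIP tiling array. The simulated
#' array is promoter-dense, as CpG-promoter tiling designs are: promoters of
#' `promoter_width` bp are laid out evenly so they cover most of each
#' chromosome, and each of the three sample groups (SCC, AC, Normal) plants
#' hypermethylation in its own random subset of promoters. Probes inside a
#' planted promoter have their mean log2 ratio raised by `effect_size`;
#' noise is Gaussian with spatial correlation over
#' `fragment_smoothing_bp` (sonication fragments of a few hundred bp make
#' neighbouring probes co-vary; set to 0 for i.i.d. probes).
#'
#' Default planted fractions (0.30 for each carcinoma group, 0.05 for
#' normals) reflect the widespread promoter hypermethylation carcinomas show
#' on promoter arrays, against a low background in normal epithelium.
#'
#' @param n_chromosomes,chrom_length genome layout (bp).
#' @param probe_spacing distance between probe starts, bp (default 100).
#' @param n_promoters total promoters across the genome.
#' @param promoter_width promoter interval width, bp (default 1000).
#' @param planted_fraction_scc,planted_fraction_ac,planted_fraction_normal
#'   proportion of promoters hypermethylated in each group.
#' @param effect_size mean log2-ratio shift inside planted promoters
#'   (default 1.5).
#' @param noise_sd marginal log2-ratio standard deviation (default 0.5).
#' @param baseline_mean baseline log2 ratio (default 0).
#' @param fragment_smoothing_bp correlation length of the noise, bp
#'   (default 400; 0 disables smoothing).
#' @param seed integer seed; identical configurations reproduce identical
#'   output.
#' @return a `tiling_sim_config` list.
#' @export
tiling_sim_config <- function(n_chromosomes = 2L,
                              chrom_length = 125000,
                              probe_spacing = 100,
                              n_promoters = 200L,
                              promoter_width = 1000,
                              planted_fraction_scc = 0.30,
                              planted_fraction_ac = 0.30,
                              planted_fraction_normal = 0.05,
                              effect_size = 1.5,
                              noise_sd = 0.5,
                              baseline_mean = 0,
                              fragment_smoothing_bp = 400,
                              seed = 1L) {
  check_field(is_count(n_chromosomes), "n_chromosomes", "must be a count >= 1")
  check_field(is_number(chrom_length) && chrom_length > 0,
              "chrom_length", "must be > 0")
  check_field(is_number(probe_spacing) && probe_spacing > 0,
              "probe_spacing", "must be > 0")
  check_field(is_count(n_promoters, min = 0L), "n_promoters",
              "must be a count >= 0")
  check_field(is_number(promoter_width) && promoter_width >= probe_spacing,
              "promoter_width", "must be >= probe_spacing")
  for (f in c("planted_fraction_scc", "planted_fraction_ac",
              "planted_fraction_normal")) {
    v <- get(f)
    check_field(is_number(v) && v >= 0 && v <= 1, f, "must be in [0, 1]")
  }
  check_field(is_number(effect_size) && effect_size > 0,
              "effect_size", "must be > 0")
  check_field(is_number(noise_sd) && noise_sd > 0, "noise_sd", "must be > 0")
  check_field(is_number(baseline_mean), "baseline_mean", "must be a number")
  check_field(is_number(fragment_smoothing_bp) && fragment_smoothing_bp >= 0,
              "fragment_smoothing_bp", "must be >= 0")
  check_field(is_count(seed, min = 0L), "seed",
              "must be a non-negative integer")
  check_field(n_promoters * promoter_width <=
                0.9 * n_chromosomes * chrom_length,
              "n_promoters", "do not fit: promoters may cover at most 90% of
the genome")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = chrom_length,
                 probe_spacing = probe_spacing,
                 n_promoters = as.integer(n_promoters),
                 promoter_width = promoter_width,
                 planted_fraction_scc = planted_fraction_scc,
                 planted_fraction_ac = planted_fraction_ac,
                 planted_fraction_normal = planted_fraction_normal,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 fragment_smoothing_bp = fragment_smoothing_bp,
                 seed = as.integer(seed)),
            class = "tiling_sim_config")
}

# Deterministic promoter layout: promoters are distributed round-robin over
# chromosomes and spaced evenly with equal gaps.
promoter_layout <- function(cfg) {
  if (cfg$n_promoters == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  per_chrom <- rep(cfg$n_promoters %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_promoters %% cfg$n_chromosomes
  if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  out <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    gap <- floor((cfg$chrom_length - k * cfg$promoter_width) / (k + 1))
    starts <- gap + (0:(k - 1)) * (cfg$promoter_width + gap)
    out[[ci]] <- data.frame(
      chrom = sprintf("chr%d", ci),
      start = starts,
      end = starts + cfg$promoter_width,
      gene = sprintf("G%04d", gid + seq_len(k)),
      stringsAsFactors = FALSE)
    gid <- gid + k
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Moving-average smoothing of unit-variance noise with the marginal variance
# restored, giving a correlation length of ~k probes.
smooth_noise <- function(z, k) {
  if (k <= 1L || length(z) < 2L) return(z)
  n <- length(z)
  half <- k %/% 2
  cs <- cumsum(c(0, z))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1L
  (cs[hi + 1L] - cs[lo]) / sqrt(cnt)
}

#' Simulate grouped tiling-array probe sets with planted hypermethylation
#'
#' Generates one probe table per sample group (SCC, AC, Normal), each tiling
#' every chromosome at `probe_spacing`, together with the ground truth of
#' planted hypermethylated promoters per group. Probes whose midpoint falls
#' inside a promoter planted for a group have mean log2 ratio
#' `baseline_mean + effect_size` in that group's table; all other probes
#' have mean `baseline_mean`. Output is byte-identical for identical
#' configurations.
#'
#' @param cfg a [tiling_sim_config()].
#' @return list with elements `probes` (named list of per-group probe
#'   tables: `probe_id`, `chrom`, `start`, `end`, `log2_ratio`), `truth`
#'   (`data.frame` of planted regions: `group`, `chrom`, `start`, `end`,
#'   `gene`), `promoters` (full annotation), and `config`.
#' @export
simulate_tiling_groups <- function(cfg = tiling_sim_config()) {
  stopifnot(inherits(cfg, "tiling_sim_config"))
  promoters <- promoter_layout(cfg)
  probe_len <- min(50, cfg$probe_spacing)
  probe_list <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
    starts <- seq(0, cfg$chrom_length - probe_len, by = cfg$probe_spacing)
    data.frame(chrom = sprintf("chr%d", ci),
               start = starts,
               end = starts + probe_len,
               stringsAsFactors = FALSE)
  })
  probes0 <- do.call(rbind, c(probe_list, list(make.row.names = FALSE)))
  probes0$probe_id <- sprintf("%s_P%06d", probes0$chrom,
                              unlist(lapply(probe_list,
                                            function(d) seq_len(nrow(d)))))
  probes0 <- probes0[, c("probe_id", "chrom", "start", "end")]
  mids <- (probes0$start + probes0$end) / 2

  fractions <- c(SCC = cfg$planted_fraction_scc,
                 AC = cfg$planted_fraction_ac,
                 Normal = cfg$planted_fraction_normal)
  k_smooth <- if (cfg$fragment_smoothing_bp > 0) {
    max(1L, as.integer(round(cfg$fragment_smoothing_bp / cfg$probe_spacing)))
  } else {
    1L
  }

  with_seed(cfg$seed, {
    truth_rows <- list()
    tables <- list()
    for (grp in names(fractions)) {
      n_plant <- round(fractions[[grp]] * nrow(promoters))
      planted <- if (n_plant > 0L && !is.null(promoters)) {
        promoters[sort(sample.int(nrow(promoters), n_plant)), , drop = FALSE]
      } else {
        promoters[0L, , drop = FALSE]
      }
      if (nrow(planted) > 0L) {
        truth_rows[[grp]] <- data.frame(group = grp, planted[, 1:3],
                                        gene = planted$gene,
                                        stringsAsFactors = FALSE)
      }
      in_planted <- rep(FALSE, nrow(probes0))
      if (nrow(planted) > 0L) {
        for (r in seq_len(nrow(planted))) {
          in_planted <- in_planted |
            (probes0$chrom == planted$chrom[r] &
               mids >= planted$start[r] & mids < planted$end[r])
        }
      }
      mu <- cfg$baseline_mean + cfg$effect_size * in_planted
      z <- rnorm(nrow(probes0))
      if (k_smooth > 1L) {
        z <- unlist(lapply(split(z, probes0$chrom),
                           smooth_noise, k = k_smooth),
                    use.names = FALSE)
      }
      tab <- probes0
      tab$log2_ratio <- mu + cfg$noise_sd * z
      tables[[grp]] <- tab
    }
    truth <- if (length(truth_rows) > 0L) {
      do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(group = character(), chrom = character(), start = numeric(),
                 end = numeric(), gene = character(), stringsAsFactors = FALSE)
    }
    list(probes = tables, truth = truth, promoters = promoters, config = cfg)
  })
}

#' QMSP cohort simulation configuration
#'
#' Study conditions for the synthetic QMSP cohort. Each diagnosis grade
#' draws its M-index log-normally around a grade median (`meanlog =
#' log(median)`, `sdlog = dispersion`); the reference-gene crossing point
#' Cp_ref is Gaussian, and the target-gene Cp is set to
#' `Cp_ref - log2(M / 10000)` so that the M-index formula inverts the draw
#' exactly. A `failure_rate` fraction of samples get a reference Cp above
#' 36 (a detection failure). Defaults are the published per-grade ZNF582
#' medians and cohort sizes.
#'
#' @param grade_params `data.frame` with columns `grade`, `median`, `sdlog`;
#'   one row per grade in the order Normal, CIN1, CIN2, CIN3/CIS, SCC.
#' @param n_per_grade integer vector of per-grade sample counts, aligned
#'   with `grade_params`.
#' @param cp_ref_mean,cp_ref_sd reference-gene Cp distribution (defaults
#'   30 and 1).
#' @param failure_rate fraction of samples with reference Cp > 36.
#' @param seed integer seed.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(grade_params = data.frame(
                                grade = c("Normal", "CIN1", "CIN2",
                                          "CIN3/CIS", "SCC"),
                                median = c(0.01, 0.06, 0.19, 1.71, 31.95),
                                sdlog = 1.5,
                                stringsAsFactors = FALSE),
                              n_per_grade = c(156L, 55L, 31L, 46L, 39L),
                              cp_ref_mean = 30,
                              cp_ref_sd = 1,
                              failure_rate = 0.01,
                              seed = 1L) {
  check_field(is.data.frame(grade_params) &&
                all(c("grade", "median", "sdlog") %in% names(grade_params)),
              "grade_params", "must have grade, median, sdlog columns")
  check_field(all(grade_params$median > 0), "grade_params",
              "medians must be > 0")
  check_field(all(grade_params$sdlog >= 0), "grade_params",
              "sdlog must be >= 0")
  check_field(length(n_per_grade) == nrow(grade_params) &&
                all(vapply(n_per_grade, is_count, logical(1))),
              "n_per_grade", "must be counts >= 1, one per grade")
  check_field(is_number(cp_ref_mean), "cp_ref_mean", "must be a number")
  check_field(is_number(cp_ref_sd) && cp_ref_sd >= 0,
              "cp_ref_sd", "must be >= 0")
  check_field(is_number(failure_rate) && failure_rate >= 0 &&
                failure_rate < 1,
              "failure_rate", "must be in [0, 1)")
  check_field(is_count(seed, min = 0L), "seed",
              "must be a non-negative integer")
  grade_params$grade <- as.character(grade_params$grade)
  structure(list(grade_params = grade_params,
                 n_per_grade = as.integer(n_per_grade),
                 cp_ref_mean = cp_ref_mean,
                 cp_ref_sd = cp_ref_sd,
                 failure_rate = failure_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a QMSP cohort with grade-structured M-index distributions
#'
#' @param cfg a [cohort_sim_config()].
#' @return list with `cohort` (`data.frame`: `sample_id`, `grade`, `cp_ref`,
#'   `cp_gene`), `truth` (`data.frame` with the drawn `m_index_true` and the
#'   planted `failed` flag per sample), and `config`.
#' @export
simulate_qmsp_cohort <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    rows <- list()
    for (g in seq_len(nrow(cfg$grade_params))) {
      n <- cfg$n_per_grade[g]
      m_true <- exp(rnorm(n, mean = log(cfg$grade_params$median[g]),
                          sd = cfg$grade_params$sdlog[g]))
      cp_ref <- rnorm(n, cfg$cp_ref_mean, cfg$cp_ref_sd)
      failed <- runif(n) < cfg$failure_rate
      cp_ref[failed] <- 36.5 + runif(sum(failed), 0, 4)
      rows[[g]] <- data.frame(grade = cfg$grade_params$grade[g],
                              cp_ref = cp_ref,
                              cp_gene = cp_ref - log2(m_true / 10000),
                              m_index_true = m_true,
                              failed = failed,
                              stringsAsFactors = FALSE)
    }
    all_rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    all_rows$sample_id <- sprintf("S%04d", seq_len(nrow(all_rows)))
    list(cohort = all_rows[, c("sample_id", "grade", "cp_ref", "cp_gene")],
         truth = all_rows[, c("sample_id", "grade", "m_index_true",
                              "failed")],
         config = cfg)
  })
}

#' Closed-form AUC of a simulated cohort under a dichotomization scheme
#'
#' The generator's true AUC: with per-grade log-normal M-index
#' distributions, `P(X_case > X_control)` for grades `c` (case) and `k`
#' (control) is `pnorm((log median_c - log median_k) /
#' sqrt(sdlog_c^2 + sdlog_k^2))`, and the arms are mixtures weighted by the
#' per-grade sample counts.
#'
#' @param cfg a [cohort_sim_config()].
#' @param scheme a [dichotomy_scheme()].
#' @return the true AUC (length-1 numeric in \[0, 1\]).
#' @export
cohort_true_auc <- function(cfg, scheme) {
  stopifnot(inherits(cfg, "cohort_sim_config"),
            inherits(scheme, "dichotomy_scheme"))
  gp <- cfg$grade_params
  is_case <- gp$grade %in% scheme$case_grades
  stopifnot(any(is_case), any(!is_case))
  w_case <- cfg$n_per_grade[is_case] / sum(cfg$n_per_grade[is_case])
  w_ctrl <- cfg$n_per_grade[!is_case] / sum(cfg$n_per_grade[!is_case])
  mu_case <- log(gp$median[is_case])
  mu_ctrl <- log(gp$median[!is_case])
  s_case <- gp$sdlog[is_case]
  s_ctrl <- gp$sdlog[!is_case]
  auc <- 0
  for (a in seq_along(mu_case)) {
    for (b in seq_along(mu_ctrl)) {
      s2 <- s_case[a]^2 + s_ctrl[b]^2
      pr <- if (s2 == 0) {
        (mu_case[a] > mu_ctrl[b]) + 0.5 * (mu_case[a] == mu_ctrl[b])
      } else {
        pnorm((mu_case[a] - mu_ctrl[b]) / sqrt(s2))
      }
      auc <- auc + w_case[a] * w_ctrl[b] * pr
    }
  }
  auc
}
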