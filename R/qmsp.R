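#' Ordered diagnosis grades
#'
#' The five cervical diagnosis grades in severity order:
#' Normal < CIN1 < CIN2 < CIN3/CIS < SCC.
#'
#' @return character vector of grade levels, lowest first.
#' @export
grade_levels <- function() {
  c("Normal", "CIN1", "CIN2", "CIN3/CIS", "SCC")
}

#' Parse diagnosis grades
#'
#' Case-insensitive parsing to the ordered factor of [grade_levels()].
#' Recognized synonyms: `CIS` and `CIN3` map to `CIN3/CIS`; `normal cervix`
#' and `nl` map to `Normal`; `cancer` and `carcinoma` map to `SCC`.
#'
#' @param x character vector of grade labels.
#' @return ordered factor with levels [grade_levels()].
#' @export
parse_grade <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c("normal" = "Normal", "normal cervix" = "Normal", "nl" = "Normal",
           "cin1" = "CIN1", "cin 1" = "CIN1",
           "cin2" = "CIN2", "cin 2" = "CIN2",
           "cin3" = "CIN3/CIS", "cin 3" = "CIN3/CIS", "cis" = "CIN3/CIS",
           "cin3/cis" = "CIN3/CIS",
           "scc" = "SCC", "cancer" = "SCC", "carcinoma" = "SCC")
  out <- map[key]
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop("parse_grade: unparseable grade(s) at row(s) ",
         paste(head(bad, 5L), collapse = ", "), ": ",
         paste(unique(x[head(bad, 5L)]), collapse = ", "), call. = FALSE)
  }
  factor(unname(out), levels = grade_levels(), ordered = TRUE)
}

#' Methylation index (M-index) from QMSP crossing points
#'
#' `M = 10000 * 2^(Cp_ref - Cp_gene)`, the reference-normalized methylation
#' abundance of the target gene (reference gene COL2A). Reactions whose
#' reference Cp exceeds `failure_cutoff` (default 36) are detection failures
#' and return `NA`, never 0: insufficient amplifiable DNA is missing data,
#' not absent methylation. A high *target* Cp is a legitimate
#' low-methylation signal and is not a failure. Vectorized over both Cp
#' arguments.
#'
#' @param cp_ref reference-gene crossing point(s), cycles.
#' @param cp_gene target-gene crossing point(s), cycles.
#' @param failure_cutoff maximum valid reference Cp (default 36).
#' @return numeric M-index values; `NA` marks detection failures (reference
#'   Cp above the cutoff, or a missing Cp).
#' @examples
#' m_index(30, 30)  # 10000
#' m_index(30, 31)  # 5000: one extra target cycle halves the index
#' m_index(36.5, 28)  # NA: detection failure
#' @export
m_index <- function(cp_ref, cp_gene, failure_cutoff = 36) {
  check_field(is_number(failure_cutoff) && failure_cutoff > 0,
              "failure_cutoff", "must be > 0")
  if (length(cp_ref) != length(cp_gene)) {
    stop("m_index: cp_ref and cp_gene must have equal length", call. = FALSE)
  }
  bad <- (!is.na(cp_ref) & cp_ref < 0) | (!is.na(cp_gene) & cp_gene < 0)
  if (any(bad)) {
    stop("m_index: negative Cp value(s) at position(s) ",
         paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  failed <- is.na(cp_ref) | is.na(cp_gene) | cp_ref > failure_cutoff
  as.numeric(ifelse(failed, NA_real_, 10000 * 2^(cp_ref - cp_gene)))
}

#' Compute M-indexes for a whole Cp table
#'
#' Applies [m_index()] row-wise, parses grades, flags invalid rows, and
#' summarizes detection failures per grade. Invalid rows stay in the output
#' (with `m_index = NA`, `valid = FALSE`) but must be excluded from
#' downstream statistics; [evaluate_marker()] does so.
#'
#' @param cp_table `data.frame` with columns `sample_id`, `grade`, `cp_ref`,
#'   `cp_gene` (missing Cp as `NA`).
#' @param failure_cutoff maximum valid reference Cp (default 36).
#' @return list with `results` (`sample_id`, `grade` ordered factor,
#'   `cp_ref`, `cp_gene`, `m_index`, `valid`) and `failure_summary`
#'   (`data.frame`: per grade `n`, `n_failed`).
#' @export
cohort_m_indexes <- function(cp_table, failure_cutoff = 36) {
  stopifnot(is.data.frame(cp_table))
  need <- c("sample_id", "grade", "cp_ref", "cp_gene")
  missing_cols <- setdiff(need, names(cp_table))
  if (length(missing_cols) > 0L) {
    stop("cohort_m_indexes: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cp_table$sample_id)) {
    dup <- unique(cp_table$sample_id[duplicated(cp_table$sample_id)])
    stop("cohort_m_indexes: duplicate sample_id(s): ",
         paste(head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  grade <- parse_grade(cp_table$grade)
  m <- m_index(cp_table$cp_ref, cp_table$cp_gene,
               failure_cutoff = failure_cutoff)
  results <- data.frame(sample_id = as.character(cp_table$sample_id),
                        grade = grade,
                        cp_ref = cp_table$cp_ref,
                        cp_gene = cp_table$cp_gene,
                        m_index = m,
                        valid = !is.na(m),
                        stringsAsFactors = FALSE)
  fs <- data.frame(grade = grade_levels(), stringsAsFactors = FALSE)
  fs$n <- as.integer(table(grade)[fs$grade])
  fs$n_failed <- as.integer(table(grade[!results$valid])[fs$grade])
  fs$n[is.na(fs$n)] <- 0L
  fs$n_failed[is.na(fs$n_failed)] <- 0L
  list(results = results, failure_summary = fs)
}
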