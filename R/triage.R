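#' Cancer-specific enriched genes
#'
#' Genes methylation-enriched in both carcinoma groups but not in normals:
#' `(scc `\eqn{\cap}` ac) \ normal`.
#'
#' @param scc,ac,normal character vectors of enriched gene ids per group.
#' @return sorted character vector of cancer-specific gene ids.
#' @export
cancer_specific_genes <- function(scc, ac, normal) {
  sort(setdiff(intersect(unique(scc), unique(ac)), unique(normal)))
}

#' Intersect candidates with external evidence lists
#'
#' Retains candidates present in at least one of the two evidence lists
#' (expression-down in carcinoma, or tissue-specific differentially
#' methylated region), recording which evidence matched.
#'
#' @param genes candidate gene ids.
#' @param expr_down,tdmr evidence gene lists (one namespace; normalize case
#'   upstream, e.g. via [read_gene_list()]).
#' @return `data.frame` with columns `gene`, `in_expr_down`, `in_tdmr` for
#'   the retained genes, sorted by gene.
#' @export
integrate_external_evidence <- function(genes, expr_down, tdmr) {
  genes <- sort(unique(genes))
  hit_expr <- genes %in% expr_down
  hit_tdmr <- genes %in% tdmr
  keep <- hit_expr | hit_tdmr
  data.frame(gene = genes[keep],
             in_expr_down = hit_expr[keep],
             in_tdmr = hit_tdmr[keep],
             stringsAsFactors = FALSE)
}

#' Filter candidates by re-expression after demethylation treatment
#'
#' A gene is confirmed if its expression fold change
#' (treated/untreated) reaches `min_fold` in at least `min_lines` cell
#' lines. Genes with no re-expression record are not retained and trigger a
#' warning.
#'
#' @param genes candidate gene ids.
#' @param records `data.frame` with columns `gene`, `cell_line`,
#'   `fold_change` (> 0).
#' @param min_fold minimum fold change (> 1; default 2).
#' @param min_lines minimum number of qualifying cell lines (default 1).
#' @return `data.frame` with columns `gene`, `reexpressed`,
#'   `reexpression_max_fold` for all input genes, sorted by gene.
#' @export
reexpression_filter <- function(genes, records, min_fold = 2.0,
                                min_lines = 1L) {
  check_field(is_number(min_fold) && min_fold > 1, "min_fold", "must be > 1")
  check_field(is_count(min_lines), "min_lines", "must be a count >= 1")
  stopifnot(is.data.frame(records),
            all(c("gene", "cell_line", "fold_change") %in% names(records)))
  if (any(records$fold_change <= 0)) {
    stop("reexpression_filter: fold_change must be > 0", call. = FALSE)
  }
  genes <- sort(unique(genes))
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), reexpressed = logical(),
                      reexpression_max_fold = numeric(),
                      stringsAsFactors = FALSE))
  }
  no_record <- setdiff(genes, unique(records$gene))
  if (length(no_record) > 0L) {
    warning("reexpression_filter: no re-expression record for gene(s): ",
            paste(no_record, collapse = ", "), "; not retained",
            call. = FALSE)
  }
  rec <- records[records$gene %in% genes, , drop = FALSE]
  n_qual <- tapply(rec$fold_change >= min_fold, rec$gene, sum)
  max_fold <- tapply(rec$fold_change, rec$gene, max)
  nq <- unname(as.integer(n_qual[genes]))
  nq[is.na(nq)] <- 0L
  data.frame(gene = genes,
             reexpressed = nq >= min_lines,
             reexpression_max_fold = unname(as.numeric(max_fold[genes])),
             stringsAsFactors = FALSE)
}

validate_pool_matrix <- function(pools) {
  if (!is.matrix(pools) || is.null(rownames(pools)) ||
      is.null(colnames(pools))) {
    stop("pool matrix must be a matrix with gene rownames and ",
         "'group:pool' colnames", call. = FALSE)
  }
  grp <- pool_groups(pools)
  ok_groups <- c("Normal", "SCC", "AC", "Blood")
  if (!all(grp %in% ok_groups)) {
    stop("pool matrix column groups must be one of ",
         paste(ok_groups, collapse = ", "), "; got: ",
         paste(setdiff(grp, ok_groups), collapse = ", "), call. = FALSE)
  }
  if (!all(pools %in% 0:4)) {
    stop("pool matrix entries must be ordinal levels 0-4", call. = FALSE)
  }
  invisible(TRUE)
}

pool_groups <- function(pools) {
  vapply(strsplit(colnames(pools), ":", fixed = TRUE), `[`, character(1), 1L)
}

#' Exclude genes methylated in normal pools or blood
#'
#' A gene is excluded when any Normal-pool entry reaches `positive_level`,
#' when any Blood-pool column does, or when its blood flag is set.
#' `retained` and `excluded` partition the input.
#'
#' @param genes gene ids; all must be rows of `pools`.
#' @param pools pooled-MSP matrix: gene rows, columns named
#'   `"group:poolname"` with group one of Normal/SCC/AC/Blood, ordinal
#'   entries 0 (unmethylated) to 4.
#' @param positive_level smallest ordinal level counted as methylated
#'   (1-4; default 1, i.e. any methylation).
#' @param blood_flags optional named logical vector: methylated in blood.
#' @return list with `retained` (character) and `excluded` (`data.frame`:
#'   `gene`, `reason`).
#' @export
msp_exclusion_filter <- function(genes, pools, positive_level = 1L,
                                 blood_flags = NULL) {
  check_field(is_count(positive_level) && positive_level <= 4,
              "positive_level", "must be in 1-4")
  validate_pool_matrix(pools)
  genes <- sort(unique(genes))
  absent <- setdiff(genes, rownames(pools))
  if (length(absent) > 0L) {
    stop("msp_exclusion_filter: gene(s) absent from pool matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  grp <- pool_groups(pools)
  norm_cols <- grp == "Normal"
  blood_cols <- grp == "Blood"
  in_normal <- if (any(norm_cols)) {
    rowSums(pools[genes, norm_cols, drop = FALSE] >= positive_level) > 0
  } else {
    rep(FALSE, length(genes))
  }
  in_blood <- if (any(blood_cols)) {
    rowSums(pools[genes, blood_cols, drop = FALSE] >= positive_level) > 0
  } else {
    rep(FALSE, length(genes))
  }
  if (!is.null(blood_flags)) {
    flagged <- genes %in% names(blood_flags)[blood_flags]
    in_blood <- in_blood | flagged
  }
  reason <- ifelse(in_normal & in_blood, "normal pool; blood",
                   ifelse(in_normal, "normal pool",
                          ifelse(in_blood, "blood", "")))
  excluded <- in_normal | in_blood
  list(retained = genes[!excluded],
       excluded = data.frame(gene = genes[excluded],
                             reason = reason[excluded],
                             stringsAsFactors = FALSE))
}

#' Prioritize candidates by methylation across cancer pools
#'
#' Counts SCC and AC pool entries at or above `positive_level` per gene;
#' genes methylated in at least `min_cancer_pools` cancer pools are
#' prioritized. Output is sorted by (count desc, gene asc).
#'
#' @param retained gene ids retained by [msp_exclusion_filter()].
#' @param pools pooled-MSP matrix (see [msp_exclusion_filter()]).
#' @param min_cancer_pools minimum cancer pools for prioritization
#'   (default 5, i.e. "more than four").
#' @param positive_level smallest ordinal level counted as methylated.
#' @return `data.frame` with columns `gene`, `methylated_cancer_pools`,
#'   `verdict` (`prioritized` or `dropped`).
#' @export
prioritize_candidates <- function(retained, pools, min_cancer_pools = 5L,
                                  positive_level = 1L) {
  check_field(is_count(min_cancer_pools), "min_cancer_pools",
              "must be a count >= 1")
  validate_pool_matrix(pools)
  genes <- sort(unique(retained))
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), methylated_cancer_pools = integer(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  absent <- setdiff(genes, rownames(pools))
  if (length(absent) > 0L) {
    stop("prioritize_candidates: gene(s) absent from pool matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cancer_cols <- pool_groups(pools) %in% c("SCC", "AC")
  counts <- rowSums(pools[genes, cancer_cols, drop = FALSE] >= positive_level)
  out <- data.frame(gene = genes,
                    methylated_cancer_pools = as.integer(counts),
                    verdict = ifelse(counts >= min_cancer_pools,
                                     "prioritized", "dropped"),
                    stringsAsFactors = FALSE)
  out[order(-out$methylated_cancer_pools, out$gene), , drop = FALSE]
}

#' Run the full candidate-triage funnel
#'
#' Chains the discovery funnel: group set logic (enriched in SCC and AC but
#' not Normal), external-evidence intersection, re-expression confirmation,
#' an explicit assay-failure drop list, pooled-MSP exclusion (normal pools
#' or blood), and prioritization by cancer-pool counts. Every input gene
#' appears in the result with a verdict and reason; each stage's survivors
#' are a subset of the previous stage's.
#'
#' @param scc,ac,normal enriched gene ids per group (e.g. the `gene` column
#'   of [annotate_regions()] output).
#' @param expr_down,tdmr external evidence gene lists.
#' @param reexpression re-expression records (see [reexpression_filter()]).
#' @param pools pooled-MSP matrix (see [msp_exclusion_filter()]).
#' @param blood_flags optional named logical vector of blood methylation.
#' @param msp_failed gene ids dropped for MSP assay failure (assay failure
#'   is not computable; this list is user-supplied).
#' @param min_fold,min_lines re-expression thresholds.
#' @param positive_level,min_cancer_pools pooled-MSP thresholds.
#' @return `data.frame` of candidate records (one row per input gene):
#'   evidence flags, pool counts, `verdict` (one of `cancer_specific`,
#'   `evidence_supported`, `confirmed_reexpressed`,
#'   `excluded_normal_or_blood`, `prioritized`, `dropped`) and `reason`.
#'   The per-stage survivor counts are attached as attribute `funnel`.
#' @export
triage_candidates <- function(scc, ac, normal, expr_down, tdmr,
                              reexpression, pools, blood_flags = NULL,
                              msp_failed = character(),
                              min_fold = 2.0, min_lines = 1L,
                              positive_level = 1L, min_cancer_pools = 5L) {
  universe <- sort(unique(c(scc, ac, normal)))
  cand <- data.frame(gene = universe,
                     in_scc = universe %in% scc,
                     in_ac = universe %in% ac,
                     in_normal = universe %in% normal,
                     in_expr_down = FALSE,
                     in_tdmr = FALSE,
                     reexpressed = FALSE,
                     reexpression_max_fold = NA_real_,
                     methylated_cancer_pools = NA_integer_,
                     methylated_normal_pools = NA_integer_,
                     methylated_in_blood = NA,
                     verdict = "dropped",
                     reason = "not cancer-specific",
                     stringsAsFactors = FALSE)
  rownames(cand) <- cand$gene

  stage1 <- cancer_specific_genes(scc, ac, normal)
  cand[stage1, "verdict"] <- "cancer_specific"
  cand[stage1, "reason"] <- "enriched in SCC and AC, not in Normal"

  ev <- integrate_external_evidence(stage1, expr_down, tdmr)
  cand[ev$gene, c("in_expr_down", "in_tdmr")] <- ev[, c("in_expr_down",
                                                        "in_tdmr")]
  stage2 <- ev$gene
  cand[stage2, "verdict"] <- "evidence_supported"
  cand[stage2, "reason"] <- "matched external evidence"
  no_ev <- setdiff(stage1, stage2)
  cand[no_ev, "reason"] <- "no external evidence"

  re <- reexpression_filter(stage2, reexpression, min_fold = min_fold,
                            min_lines = min_lines)
  cand[re$gene, c("reexpressed", "reexpression_max_fold")] <-
    re[, c("reexpressed", "reexpression_max_fold")]
  stage3 <- re$gene[re$reexpressed]
  cand[stage3, "verdict"] <- "confirmed_reexpressed"
  cand[stage3, "reason"] <- "re-expressed after demethylation"
  cand[setdiff(stage2, stage3), "reason"] <- "not re-expressed"

  failed <- intersect(stage3, msp_failed)
  stage3b <- setdiff(stage3, failed)
  cand[failed, "verdict"] <- "dropped"
  cand[failed, "reason"] <- "MSP assay failure"

  if (length(stage3b) > 0L) {
    excl <- msp_exclusion_filter(stage3b, pools,
                                 positive_level = positive_level,
                                 blood_flags = blood_flags)
    norm_cols <- pool_groups(pools) == "Normal"
    cand[stage3b, "methylated_normal_pools"] <- as.integer(
      rowSums(pools[stage3b, norm_cols, drop = FALSE] >= positive_level))
    cand[stage3b, "methylated_in_blood"] <-
      stage3b %in% excl$excluded$gene[grepl("blood", excl$excluded$reason)]
    if (nrow(excl$excluded) > 0L) {
      cand[excl$excluded$gene, "verdict"] <- "excluded_normal_or_blood"
      cand[excl$excluded$gene, "reason"] <-
        paste("methylated in", excl$excluded$reason)
    }
    stage4 <- excl$retained
    prio <- prioritize_candidates(stage4, pools,
                                  min_cancer_pools = min_cancer_pools,
                                  positive_level = positive_level)
    cand[prio$gene, "methylated_cancer_pools"] <-
      prio$methylated_cancer_pools
    winners <- prio$gene[prio$verdict == "prioritized"]
    cand[winners, "verdict"] <- "prioritized"
    cand[winners, "reason"] <- sprintf("methylated in >= %d cancer pools",
                                       min_cancer_pools)
    losers <- prio$gene[prio$verdict == "dropped"]
    cand[losers, "verdict"] <- "dropped"
    cand[losers, "reason"] <- sprintf("methylated in < %d cancer pools",
                                      min_cancer_pools)
  } else {
    stage4 <- character()
    winners <- character()
  }

  rownames(cand) <- NULL
  attr(cand, "funnel") <- c(input = length(universe),
                            cancer_specific = length(stage1),
                            evidence_supported = length(stage2),
                            confirmed_reexpressed = length(stage3),
                            msp_verified = length(stage3b),
                            retained_after_exclusion = length(stage4),
                            prioritized = length(winners))
  cand
}
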