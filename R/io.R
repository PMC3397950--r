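# Readers and writers for the pipeline's on-disk formats: TSV with header
# for tabular data, BED (0-based half-open) for genomic intervals, plain
# text for gene lists. Every writer's output is re-readable by the matching
# reader.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}

#' Read a tiling probe table
#'
#' TSV with header columns `probe_id`, `chrom`, `start`, `end`,
#' `log2_ratio`; coordinates 0-based half-open. The table is validated
#' (numeric coordinates and ratios, `start < end`) and sorted by
#' (chrom, start). Errors name the offending file line (header is line 1).
#'
#' @param path file path.
#' @return sorted probe `data.frame`.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_probe_table: no such file: ", path, call. = FALSE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "log2_ratio")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("read_probe_table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("start", "end", "log2_ratio")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("read_probe_table: non-numeric %s at line %d", col,
                   bad[1] + 1L), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("read_probe_table: missing %s at line %d", col,
                   which(is.na(v))[1] + 1L), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L) {
    stop(sprintf("read_probe_table: start >= end at line %d", bad[1] + 1L),
         call. = FALSE)
  }
  df$probe_id <- as.character(df$probe_id)
  df$chrom <- as.character(df$chrom)
  sort_probes(df[, union(need, names(df))])
}

#' Write a tiling probe table
#'
#' @param probes probe table.
#' @param path destination TSV path.
#' @return the path, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  need <- c("probe_id", "chrom", "start", "end", "log2_ratio")
  stopifnot(all(need %in% names(probes)))
  write_tsv(probes[, need], path)
}

#' Read promoter annotation from BED
#'
#' 6-column BED (or more) with the gene id in the name field; coordinates
#' are kept 0-based half-open internally.
#'
#' @param path BED file path.
#' @return `data.frame` with `chrom`, `start`, `end`, `gene`.
#' @export
read_promoter_bed <- function(path) {
  if (!file.exists(path)) {
    stop("read_promoter_bed: no such file: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name)) {
    stop("read_promoter_bed: every interval needs a gene id in the name ",
         "field", call. = FALSE)
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             gene = gr$name,
             stringsAsFactors = FALSE)
}

#' Write promoter annotation as BED
#'
#' @param promoters `data.frame` with `chrom`, `start`, `end`, `gene`
#'   (0-based half-open).
#' @param path destination BED path.
#' @return the path, invisibly.
#' @export
write_promoter_bed <- function(promoters, path) {
  gr <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(promoters$start + 1, promoters$end),
    name = promoters$gene, score = 0L, strand = "*")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write called regions as BED
#'
#' Standard BED6: name is the annotated gene id (when a `gene` column is
#' present) or a running region id, score is `round(100 * peak_score)`
#' capped at 1000, strand is unset. An empty region set yields an empty
#' file (BED has no header).
#'
#' @param regions called regions from [call_regions()] (0-based half-open).
#' @param path destination BED path.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- if ("gene" %in% names(regions)) {
    regions$gene
  } else {
    sprintf("region_%d", seq_len(nrow(regions)))
  }
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$start + 1, regions$end),
    name = name,
    score = pmin(1000, round(100 * regions$peak_score)),
    strand = "*")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read called regions from BED
#'
#' Inverse of [write_regions_bed()]: the BED score column is mapped back to
#' `peak_score = score / 100` (capped at 10 where the BED cap of 1000 was
#' hit).
#'
#' @param path BED file path.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `peak_score`.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) {
    stop("read_regions_bed: no such file: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      peak_score = numeric(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = gr$name,
             peak_score = gr$score / 100,
             stringsAsFactors = FALSE)
}

#' Read a gene list
#'
#' One gene id per line; `#` starts a comment (whole-line or trailing);
#' blank lines are ignored; ids are upper-cased and deduplicated so all
#' evidence lists share one namespace.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("read_gene_list: no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(toupper(lines[nzchar(lines)]))
}

#' Write a gene list
#'
#' @param genes character vector of gene ids.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a pooled-MSP call matrix
#'
#' TSV whose first column (`gene`) holds gene ids and whose remaining
#' header fields are pool labels of the form `group:poolname` with group
#' one of Normal/SCC/AC/Blood; entries are ordinal methylation levels 0-4.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and pool colnames.
#' @export
read_pool_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("read_pool_matrix: no such file: ", path, call. = FALSE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene") {
    stop("read_pool_matrix: first column must be 'gene'", call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "integer"
  rownames(mat) <- df$gene
  validate_pool_matrix(mat)
  mat
}

#' Write a pooled-MSP call matrix
#'
#' @param pools matrix as in [read_pool_matrix()].
#' @param path destination TSV path.
#' @return the path, invisibly.
#' @export
write_pool_matrix <- function(pools, path) {
  validate_pool_matrix(pools)
  df <- data.frame(gene = rownames(pools), pools, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a QMSP Cp table
#'
#' TSV with header columns `sample_id`, `grade`, `cp_ref`, `cp_gene`;
#' missing Cp values are empty fields (never 0).
#'
#' @param path file path.
#' @return `data.frame` with the four columns; missing Cp as `NA`.
#' @export
read_cp_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_cp_table: no such file: ", path, call. = FALSE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  need <- c("sample_id", "grade", "cp_ref", "cp_gene")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("read_cp_table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$grade <- as.character(df$grade)
  for (col in c("cp_ref", "cp_gene")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df[, need]
}

#' Write a QMSP Cp table
#'
#' @param cp_table `data.frame` with `sample_id`, `grade`, `cp_ref`,
#'   `cp_gene`.
#' @param path destination TSV path.
#' @return the path, invisibly.
#' @export
write_cp_table <- function(cp_table, path) {
  need <- c("sample_id", "grade", "cp_ref", "cp_gene")
  stopifnot(all(need %in% names(cp_table)))
  write_tsv(cp_table[, need], path)
}

#' Write an evaluation report
#'
#' Two TSVs: a grade summary (per-grade n, median with bootstrap CI,
#' Mann-Whitney p versus Normal) and a performance table (one row per
#' dichotomization scheme: cutoff, AUC and interval, sensitivity and
#' specificity with intervals, accuracy, power).
#'
#' @param evaluation a [evaluate_marker()] result.
#' @param dir output directory (created if needed).
#' @return character vector of the two paths, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  stopifnot(inherits(evaluation, "marker_evaluation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "grade_summary.tsv")
  p2 <- file.path(dir, "performance.tsv")
  write_tsv(evaluation$grade_summary, p1)
  write_tsv(evaluation$performance, p2)
  invisible(c(p1, p2))
}
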