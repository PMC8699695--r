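# File formats: TSV for matrices and gene tables, CSV for metadata and time
# series; UTF-8, "." decimal.

check_rectangular <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  bad <- which(nf != nf[1])
  if (length(bad)) {
    stop_schema(sprintf("%s: line %d has %d field(s), expected %d",
                        basename(path), bad[1] + 0L, nf[bad[1]], nf[1]))
  }
  invisible(NULL)
}

require_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_schema(sprintf("%s: missing column(s): %s", basename(path),
                        paste(miss, collapse = ", ")))
  }
  invisible(NULL)
}

#' Read an expression cohort from disk
#'
#' Expression is a TSV with genes in rows (first column `gene`, remaining
#' columns samples); metadata is a CSV with columns `sample_id`, `group`
#' (`ASD`/`CTR`, matched case-insensitively), `age` and optionally
#' `adir_class`. A write/read round trip through [write_cohort()] is
#' lossless up to numeric formatting precision.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the metadata CSV.
#' @return A [cohort_matrix()].
#' @export
read_expression <- function(expr_path, meta_path) {
  for (p in c(expr_path, meta_path)) {
    if (!file.exists(p)) stop_schema(paste0("file not found: ", p))
  }
  check_rectangular(expr_path, "\t")
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  require_columns(expr, "gene", expr_path)
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr$gene
  if (!is.numeric(values)) {
    stop_schema(sprintf("%s: non-numeric expression values",
                        basename(expr_path)))
  }
  check_rectangular(meta_path, ",")
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  require_columns(meta, c("sample_id", "group", "age"), meta_path)
  cohort_matrix(values, meta)
}

#' Write an expression cohort to disk
#'
#' @param m A [cohort_matrix()].
#' @inheritParams read_expression
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(m, expr_path, meta_path) {
  stopifnot(inherits(m, "cohort_matrix"))
  expr <- data.frame(gene = rownames(m$values), m$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(m$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(expr_path, meta_path))
}

#' Read and write binned activity records
#'
#' The on-disk form is a CSV with columns `bin_start_min` and `count`;
#' bins must be uniform.
#'
#' @param path CSV path.
#' @return [read_actogram()] returns an [actogram()].
#' @export
read_actogram <- function(path) {
  if (!file.exists(path)) stop_schema(paste0("file not found: ", path))
  check_rectangular(path, ",")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("bin_start_min", "count"), path)
  starts <- df$bin_start_min
  if (length(starts) > 1) {
    w <- diff(starts)
    if (any(abs(w - w[1]) > 1e-9)) {
      stop_schema(sprintf("%s: bins are not uniform", basename(path)))
    }
    width <- w[1]
  } else {
    width <- 1
  }
  actogram(df$count, bin_minutes = width, start_min = starts[1])
}

#' @rdname read_actogram
#' @param a An [actogram()].
#' @export
write_actogram <- function(a, path) {
  stopifnot(inherits(a, "actogram"))
  df <- data.frame(
    bin_start_min = a$start_min + (seq_along(a$counts) - 1L) * a$bin_minutes,
    count = a$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write mouse DEG tables
#'
#' TSV with columns `gene`, `log2fc`, `pvalue`.
#'
#' @param path TSV path.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop_schema(paste0("file not found: ", path))
  check_rectangular(path, "\t")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("gene", "log2fc", "pvalue"), path)
  df
}

#' @rdname read_deg_table
#' @param tab Data frame with columns `gene`, `log2fc`, `pvalue`.
#' @export
write_deg_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write homolog maps
#'
#' TSV with columns `mouse` and `human`; read back as the named character
#' vector used by [overlap_candidates()].
#'
#' @param path TSV path.
#' @export
read_homolog_map <- function(path) {
  if (!file.exists(path)) stop_schema(paste0("file not found: ", path))
  check_rectangular(path, "\t")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("mouse", "human"), path)
  if (anyDuplicated(df$mouse) || anyDuplicated(df$human)) {
    stop_schema(sprintf("%s: homolog map must be one-to-one", basename(path)))
  }
  stats::setNames(df$human, df$mouse)
}

#' @rdname read_homolog_map
#' @param map Named character vector, mouse symbol to human symbol.
#' @export
write_homolog_map <- function(map, path) {
  utils::write.table(data.frame(mouse = names(map), human = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-gene screening results
#'
#' @param fit A [cohort_deg()] object (or its results data frame).
#' @param path TSV path.
#' @export
write_gene_results <- function(fit, path) {
  df <- if (inherits(fit, "cohort_deg")) fit$results else as.data.frame(fit)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a multi-cohort gene-sharing tally
#'
#' @param vt A [venn_tally()] object.
#' @param path TSV path (`gene`, `cohorts`, `n_cohorts`).
#' @export
write_venn <- function(vt, path) {
  stopifnot(inherits(vt, "venn_tally"))
  utils::write.table(as.data.frame(vt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an importance table
#'
#' @param tab An [importance_scores()] result.
#' @param path TSV path.
#' @export
write_importance <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
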