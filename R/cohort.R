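#' Expression cohort container
#'
#' Bundles a gene-by-sample expression matrix with per-sample metadata
#' (diagnosis group, age in years and, optionally, an ordinal ADI-R severity
#' class). This is the common currency of the DEG-screening and importance
#' functions.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene symbols),
#'   samples in columns (colnames are sample ids).
#' @param meta Data frame with one row per sample and columns `sample_id`,
#'   `group` (levels `ASD`/`CTR`, matched case-insensitively), `age` (years)
#'   and optionally `adir_class` (ordinal severity label; `NA` allowed, e.g.
#'   for controls).
#'
#' @return An object of class `cohort_matrix`: a list with elements `values`
#'   and `meta`.
#' @examples
#' syn <- gen_cohort(cohort_spec(n_asd = 5, n_ctr = 5, n_genes = 10, seed = 1))
#' m <- syn$cohort
#' dim(m$values)
#' @export
cohort_matrix <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_schema("'values' must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_schema("'values' must have gene rownames and sample colnames")
  }
  meta <- as.data.frame(meta)
  need <- c("sample_id", "group", "age")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop_schema(paste0("metadata is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (nrow(meta) != ncol(values)) {
    stop_schema(sprintf("metadata has %d rows but matrix has %d samples",
                        nrow(meta), ncol(values)))
  }
  if (!identical(as.character(meta$sample_id), colnames(values))) {
    stop_schema("metadata sample_id must match matrix column names in order")
  }
  grp <- toupper(trimws(as.character(meta$group)))
  bad <- setdiff(unique(grp), c("ASD", "CTR"))
  if (length(bad)) {
    stop_schema(paste0("unknown group label(s): ", paste(bad, collapse = ", "),
                       " (expected ASD/CTR)"))
  }
  if (!all(grp == as.character(meta$group))) {
    message("group labels normalized to upper case ASD/CTR")
  }
  meta$group <- factor(grp, levels = c("CTR", "ASD"))
  if (nlevels(droplevels(meta$group)) < 2L) {
    stop_schema("both ASD and CTR samples must be present")
  }
  meta$age <- as.numeric(meta$age)
  if (any(!is.finite(meta$age))) stop_schema("ages must all be finite")
  if (!"adir_class" %in% names(meta)) meta$adir_class <- NA_character_
  structure(list(values = values, meta = meta), class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  tab <- table(x$meta$group)
  cat(sprintf("cohort_matrix: %d genes x %d samples (%d ASD / %d CTR)\n",
              nrow(x$values), ncol(x$values), tab[["ASD"]], tab[["CTR"]]))
  cat(sprintf("  age range: %.1f-%.1f years; ADI-R classes: %s\n",
              min(x$meta$age), max(x$meta$age),
              if (all(is.na(x$meta$adir_class))) "none" else
                paste(sort(unique(stats::na.omit(x$meta$adir_class))),
                      collapse = ", ")))
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$values)
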