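#' Map mouse DEGs into a cohort's measured genes
#'
#' Translates mouse symbols through a homolog map and intersects with the
#' set of genes measured in a human cohort. Mouse genes with no entry in the
#' map are skipped; their count is reported via a message and attached as
#' attribute `n_unmapped`.
#'
#' @param mouse_degs Character vector of mouse gene symbols.
#' @param map Named character vector, mouse symbol to human symbol
#'   (e.g. from [gen_homolog_map()]).
#' @param cohort_genes Character vector of genes measured in the cohort.
#' @return Character vector of human symbols measured in the cohort, sorted;
#'   attribute `n_unmapped` carries the number of skipped mouse genes.
#' @examples
#' overlap_candidates("Slc16a9", gen_homolog_map("Slc16a9"),
#'                    c("SLC16A9", "PON1"))
#' @export
overlap_candidates <- function(mouse_degs, map, cohort_genes) {
  mouse_degs <- unique(as.character(mouse_degs))
  unmapped <- setdiff(mouse_degs, names(map))
  if (length(unmapped)) {
    message(sprintf("%d mouse gene(s) without a homolog mapping were skipped",
                    length(unmapped)))
  }
  human <- unname(map[intersect(mouse_degs, names(map))])
  out <- sort(intersect(human, cohort_genes))
  attr(out, "n_unmapped") <- length(unmapped)
  out
}

#' Tally gene sharing across cohorts
#'
#' Given per-cohort DEG sets, records for every gene the cohorts it appears
#' in and counts how many genes appear in exactly and in at least k cohorts.
#'
#' @param per_cohort_degs Named list of character vectors, one per cohort.
#' @return An object of class `venn_tally`: list with `membership` (named
#'   list, gene to sorted cohort names), `exactly` and `at_least` (named
#'   integer vectors over k = 1..number of cohorts) and `n_cohorts`.
#' @examples
#' vt <- venn_tally(list(a = c("X", "Y"), b = c("Y", "Z")))
#' vt$at_least
#' @export
venn_tally <- function(per_cohort_degs) {
  if (!is.list(per_cohort_degs) || length(per_cohort_degs) < 1L ||
      is.null(names(per_cohort_degs)) || any(!nzchar(names(per_cohort_degs)))) {
    stop_input("per_cohort_degs must be a non-empty named list of gene sets")
  }
  cohorts <- sort(names(per_cohort_degs))
  genes <- sort(unique(unlist(per_cohort_degs, use.names = FALSE)))
  membership <- lapply(genes, function(g) {
    sort(cohorts[vapply(cohorts, function(cc)
      g %in% per_cohort_degs[[cc]], logical(1))])
  })
  names(membership) <- genes
  k <- vapply(membership, length, integer(1))
  kk <- seq_along(cohorts)
  exactly <- vapply(kk, function(i) sum(k == i), integer(1))
  at_least <- rev(cumsum(rev(exactly)))
  names(exactly) <- names(at_least) <- kk
  structure(list(membership = membership, exactly = exactly,
                 at_least = at_least, n_cohorts = length(cohorts)),
            class = "venn_tally")
}

#' @export
print.venn_tally <- function(x, ...) {
  cat(sprintf("venn_tally over %d cohorts, %d distinct genes\n",
              x$n_cohorts, length(x$membership)))
  for (k in rev(seq_len(x$n_cohorts))) {
    if (x$exactly[[k]] > 0) {
      genes <- names(x$membership)[vapply(x$membership, length, 1L) == k]
      cat(sprintf("  in exactly %d cohort(s): %d  [%s]\n", k, x$exactly[[k]],
                  paste(utils::head(genes, 8), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.venn_tally <- function(x, ...) {
  data.frame(gene = names(x$membership),
             cohorts = vapply(x$membership, paste, "", collapse = ";"),
             n_cohorts = vapply(x$membership, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
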