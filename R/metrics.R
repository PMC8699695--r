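#' Discrimination index of an exploration trial
#'
#' For novel-object-recognition or object-location trials:
#' `DI = (t_novel - t_familiar) / (t_novel + t_familiar)`, together with the
#' proportion of time at the novel object, `t_novel / (t_novel + t_familiar)`.
#' The two satisfy `DI = 2 * proportion - 1`. Vectorized over trials.
#'
#' @param time_novel,time_familiar Exploration times in seconds, both >= 0;
#'   a trial with both times zero is undefined and raises an error.
#' @return Data frame with columns `di` (in \[-1, 1\]) and `prop_novel`.
#' @examples
#' discrimination_index(30, 10)  # DI = 0.5
#' @export
discrimination_index <- function(time_novel, time_familiar) {
  if (length(time_novel) != length(time_familiar)) {
    stop_input("time_novel and time_familiar must have equal length")
  }
  if (any(!is.finite(time_novel)) || any(!is.finite(time_familiar)) ||
      any(time_novel < 0) || any(time_familiar < 0)) {
    stop_input("exploration times must be finite and non-negative")
  }
  tot <- time_novel + time_familiar
  if (any(tot == 0)) {
    sdc_abort("trial with zero total exploration time: DI undefined",
              "sdc_undefined_metric_error")
  }
  data.frame(di = (time_novel - time_familiar) / tot,
             prop_novel = time_novel / tot)
}

#' Mature and immature dendritic-spine fractions
#'
#' Spines are classified into five morphological categories — A: Thin,
#' B: Stubby, C: Mushroom, D: Filopodia, E: Branched — of which Stubby and
#' Mushroom count as mature and the rest as immature.
#'
#' @param counts Numeric vector of 5 non-negative counts, either named with
#'   `A`..`E` (any order) or unnamed in A..E order; total must be positive.
#' @return Named numeric vector `c(mature, immature)` of fractions summing
#'   to 1.
#' @examples
#' spine_fractions(c(A = 10, B = 5, C = 5, D = 0, E = 0))
#' @export
spine_fractions <- function(counts) {
  cats <- c("A", "B", "C", "D", "E")
  if (length(counts) != 5L || any(!is.finite(counts)) || any(counts < 0)) {
    stop_input("counts must be 5 non-negative numbers (categories A-E)")
  }
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), cats)) {
      stop_input("named counts must use categories A, B, C, D, E")
    }
    counts <- counts[cats]
  }
  tot <- sum(counts)
  if (tot == 0) {
    sdc_abort("zero spines counted: fractions undefined",
              "sdc_undefined_metric_error")
  }
  mature <- unname(counts[2] + counts[3]) / tot
  c(mature = mature, immature = 1 - mature)
}

#' Summary statistics of an undirected interaction network
#'
#' Treats the edge list as a simple undirected graph: self-loops are removed
#' and duplicate edges (in either orientation) collapsed, with counts
#' reported by message. Average node degree is `2 * edges / nodes`.
#'
#' @param edges Two-column data frame or matrix of endpoint labels.
#' @return An object of class `graph_summary`: list with `n_nodes`,
#'   `n_edges`, `avg_degree` (full precision), `avg_degree_display`
#'   (rounded half-even to 2 decimals), `n_self_loops` and `n_duplicates`.
#' @examples
#' graph_summary(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
#' @export
graph_summary <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L || nrow(edges) < 1L) {
    stop_schema("edge list must have at least two columns and one row")
  }
  a <- trimws(as.character(edges[[1]]))
  b <- trimws(as.character(edges[[2]]))
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    stop_schema("malformed edge row: empty or missing endpoint")
  }
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  n_dup <- sum(igraph::which_multiple(g))
  if (n_loops) message(sprintf("%d self-loop(s) removed", n_loops))
  if (n_dup) message(sprintf("%d duplicate edge(s) collapsed", n_dup))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_nodes <- igraph::vcount(g)
  n_edges <- igraph::ecount(g)
  avg <- 2 * n_edges / n_nodes
  structure(list(n_nodes = n_nodes, n_edges = n_edges, avg_degree = avg,
                 avg_degree_display = round(avg, 2),
                 n_self_loops = n_loops, n_duplicates = n_dup),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("graph_summary: %d nodes, %d edges, average node degree %.2f\n",
              x$n_nodes, x$n_edges, x$avg_degree_display))
  invisible(x)
}
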