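#' Train an LVQ1 classifier
#'
#' Learning vector quantization with the classic LVQ1 update: for each
#' training sample the nearest codebook vector is moved toward the sample if
#' their classes agree and away from it otherwise, with a learning rate that
#' decays linearly to zero over the training run. Features are standardized
#' internally (per-gene z-score). The first prototype of each class is
#' initialized at the class mean, so with `epochs = 0` the model reduces to
#' a nearest-class-mean classifier; additional prototypes per class are
#' seeded draws from the class's samples.
#'
#' @param features Numeric sample-by-gene matrix.
#' @param labels Class label per sample (coerced to factor); every class must
#'   have at least one sample and at least two classes must be present.
#' @param k_per_class Codebook vectors per class (default 1).
#' @param epochs Passes over the data (default 30).
#' @param lr0 Initial learning rate (default 0.3).
#' @param seed Integer seed controlling presentation order and extra-prototype
#'   initialization.
#' @return An object of class `lvq_model` with the codebook (`prototypes`,
#'   `proto_class`), the standardization (`center`, `scale`), the class
#'   `levels` and the training `accuracy`.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
#' colnames(x) <- c("g1", "g2")
#' fit <- train_lvq(x, rep(c("a", "b"), each = 20), seed = 1)
#' fit$accuracy
#' @export
train_lvq <- function(features, labels, k_per_class = 1, epochs = 30,
                      lr0 = 0.3, seed = 1) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nrow(features) != length(labels)) {
    stop_input("features and labels must have one entry per sample")
  }
  if (anyNA(labels)) stop_input("labels must not contain NA")
  if (nlevels(labels) < 2L) stop_input("at least two classes are required")
  if (any(table(labels) == 0L)) {
    stop_input("every class must have at least one sample")
  }
  k_per_class <- check_count(k_per_class, "k_per_class", min = 1)
  epochs <- check_count(epochs, "epochs")
  lr0 <- check_number(lr0, "lr0", 0, strict = TRUE)

  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  x <- sweep(sweep(features, 2, center), 2, scale, "/")

  withr::with_seed(seed, {
    protos <- list(); pclass <- character(0)
    for (lev in levels(labels)) {
      idx <- which(labels == lev)
      protos[[length(protos) + 1L]] <- colMeans(x[idx, , drop = FALSE])
      pclass <- c(pclass, lev)
      if (k_per_class > 1L) {
        extra <- sample(idx, k_per_class - 1L, replace = length(idx) < k_per_class)
        for (i in extra) {
          protos[[length(protos) + 1L]] <- x[i, ]
          pclass <- c(pclass, lev)
        }
      }
    }
    m <- do.call(rbind, protos)
    n <- nrow(x)
    total <- epochs * n
    step <- 0L
    if (total > 0L) {
      for (ep in seq_len(epochs)) {
        for (i in sample.int(n)) {
          lr <- lr0 * (1 - step / total)
          d2 <- rowSums(sweep(m, 2, x[i, ])^2)
          w <- which.min(d2)
          dir <- if (pclass[w] == as.character(labels[i])) 1 else -1
          m[w, ] <- m[w, ] + dir * lr * (x[i, ] - m[w, ])
          step <- step + 1L
        }
      }
    }
  })

  model <- structure(list(prototypes = m, proto_class = pclass,
                          center = center, scale = scale,
                          levels = levels(labels),
                          k_per_class = k_per_class, epochs = epochs,
                          lr0 = lr0, seed = seed),
                     class = "lvq_model")
  model$accuracy <- mean(predict(model, features) == labels)
  model
}

#' @export
predict.lvq_model <- function(object, newdata, ...) {
  x <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  idx <- apply(x, 1, function(v)
    which.min(rowSums(sweep(object$prototypes, 2, v)^2)))
  factor(object$proto_class[idx], levels = object$levels)
}

#' @export
print.lvq_model <- function(x, ...) {
  cat(sprintf("lvq_model: %d classes, %d prototypes in %d dims; training accuracy %.3f\n",
              length(x$levels), nrow(x$prototypes), ncol(x$prototypes),
              x$accuracy))
  invisible(x)
}

# Rank-based (Mann-Whitney) AUC of x_pos vs x_neg; ties handled by midranks.
auc_rank <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Per-gene, per-class ROC importance scores
#'
#' Filter-style variable importance: for every gene, the AUC of each pairwise
#' class comparison is computed by the rank statistic, and the score of a
#' gene for a class is the maximum over the pairs involving that class of
#' `|2*AUC - 1|`. The score lies in \[0, 1\]: 0 for a gene carrying no class
#' information (or a constant gene) and 1 for a gene that perfectly separates
#' the class from some other class. Scores are binned into five ordinal
#' labels at fixed edges. Samples with `NA` labels are dropped.
#'
#' The pairwise-maximum convention (rather than one-vs-rest) matters for
#' ordinal class structures: a gene whose value increases with severity
#' separates a middle severity bin perfectly from the extreme bins even
#' though its one-vs-rest AUC for that bin is near 0.5.
#'
#' @param features Numeric sample-by-gene matrix.
#' @param labels Class per sample; `NA`s dropped.
#' @param bin_edges Score thresholds between the five bins
#'   (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @param occurrence Optional named integer vector giving, per gene, the
#'   number of cohorts in which it was called a DEG (reported alongside).
#' @return An object of class `importance_table`: data frame with columns
#'   `gene`, `class`, `score`, `bin` and `occurrence`.
#' @examples
#' x <- cbind(sig = c(rnorm(10, 0), rnorm(10, 4)), noise = rnorm(20))
#' importance_scores(x, rep(c("lo", "hi"), each = 10))
#' @export
importance_scores <- function(features, labels,
                              bin_edges = c(0.2, 0.4, 0.6, 0.8),
                              occurrence = NULL) {
  features <- as.matrix(features)
  keep <- !is.na(labels)
  if (any(!keep)) {
    message(sprintf("%d sample(s) with missing class labels dropped",
                    sum(!keep)))
  }
  features <- features[keep, , drop = FALSE]
  labels <- factor(labels[keep])
  if (nlevels(labels) < 2L) stop_input("at least two classes are required")
  if (any(table(labels) == 0L)) labels <- droplevels(labels)
  if (length(bin_edges) != 4L || is.unsorted(bin_edges)) {
    stop_parameter("bin_edges must be four non-decreasing thresholds")
  }
  classes <- levels(labels)
  genes <- colnames(features)
  if (is.null(genes)) genes <- sprintf("V%d", seq_len(ncol(features)))

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rows <- list()
  for (j in seq_along(genes)) {
    v <- features[, j]
    pair_score <- vapply(pairs, function(p) {
      abs(2 * auc_rank(v[labels == p[1]], v[labels == p[2]]) - 1)
    }, numeric(1))
    for (cl in classes) {
      involving <- vapply(pairs, function(p) cl %in% p, logical(1))
      s <- max(pair_score[involving])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes[j], class = cl, score = s, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$bin <- cut(out$score, breaks = c(-Inf, bin_edges, Inf), right = FALSE,
                 labels = c("Very Low", "Low", "Moderate", "High", "Very High"))
  out$occurrence <- if (is.null(occurrence)) NA_integer_ else
    as.integer(occurrence[out$gene])
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("importance_table: %d genes x %d classes\n",
              length(unique(x$gene)), length(unique(x$class))))
  NextMethod()
}
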