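#' DEG-calling criteria
#'
#' Thresholds of the per-gene screening procedure: the interaction-coefficient
#' cutoff deciding between the interaction and additive models, the t-test
#' p-value cutoff on the group coefficient, and the fold-change cutoff.
#'
#' @param gamma_cutoff Additive model is used when |gamma| is below this
#'   (default 0.1).
#' @param p_cutoff Two-sided t-test p-value cutoff on the group offset
#'   (default 0.05, inclusive).
#' @param fc_cutoff Fold-change cutoff, ratio mean(ASD)/mean(CTR)
#'   (default 1.25, inclusive).
#' @param two_sided_fc If `TRUE` (default) down-regulation also qualifies:
#'   fold change <= 1/fc_cutoff passes. `FALSE` reproduces the strict
#'   one-sided reading (only FC >= fc_cutoff).
#' @return An object of class `deg_criteria`.
#' @export
deg_criteria <- function(gamma_cutoff = 0.1, p_cutoff = 0.05,
                         fc_cutoff = 1.25, two_sided_fc = TRUE) {
  out <- list(
    gamma_cutoff = check_number(gamma_cutoff, "gamma_cutoff", 0, strict = TRUE),
    p_cutoff = check_number(p_cutoff, "p_cutoff", 0, strict = TRUE),
    fc_cutoff = check_number(fc_cutoff, "fc_cutoff", 0, strict = TRUE),
    two_sided_fc = isTRUE(two_sided_fc)
  )
  if (out$p_cutoff > 1) stop_parameter("p_cutoff must be <= 1")
  structure(out, class = "deg_criteria")
}

check_design <- function(y, age, offset, p) {
  n <- length(y)
  if (length(age) != n || length(offset) != n) {
    stop_input("y, age and offset must have equal length")
  }
  if (n < 5L) stop_input("at least 5 samples are required")
  if (!all(is.finite(y)) || !all(is.finite(age))) {
    stop_input("y and age must be finite")
  }
  if (!all(offset %in% c(0, 1)) || length(unique(offset)) < 2L) {
    stop_input("offset must be 0/1 with both levels present")
  }
  X <- cbind(1, age, offset, age * offset)[, seq_len(p), drop = FALSE]
  if (qr(X)$rank < p) {
    sdc_abort("design matrix is rank deficient (e.g. all ages equal)",
              "sdc_degenerate_design_error")
  }
  invisible(NULL)
}

#' Fit the per-gene interaction model
#'
#' Ordinary least squares of expression on age, diagnosis offset and their
#' interaction, with an intercept:
#' `y = mu + alpha*age + beta*offset + gamma*age:offset + e`.
#' Coefficient p-values are two-sided t-tests on `n - 4` degrees of freedom.
#'
#' @param y Expression vector for one gene.
#' @param age Ages in years.
#' @param offset 0/1 diagnosis indicator (1 = ASD), both levels present.
#' @return List with `alpha`, `beta`, `gamma`, `p_beta`, `p_gamma`,
#'   `intercept` and `df`.
#' @export
fit_interaction_model <- function(y, age, offset) {
  check_design(y, age, offset, 4L)
  fit <- stats::lm(y ~ age + offset + age:offset)
  cf <- summary(fit)$coefficients
  list(alpha = cf["age", 1], beta = cf["offset", 1],
       gamma = cf["age:offset", 1],
       p_beta = cf["offset", 4], p_gamma = cf["age:offset", 4],
       intercept = cf["(Intercept)", 1], df = fit$df.residual)
}

#' Fit the per-gene additive model
#'
#' Ordinary least squares of expression on age and diagnosis offset (shared
#' age slope), with an intercept; the two-sided t-test on the group
#' coefficient has `n - 3` degrees of freedom.
#'
#' @inheritParams fit_interaction_model
#' @return List with `alpha`, `beta`, `p_beta`, `intercept` and `df`.
#' @export
fit_additive_model <- function(y, age, offset) {
  check_design(y, age, offset, 3L)
  fit <- stats::lm(y ~ age + offset)
  cf <- summary(fit)$coefficients
  list(alpha = cf["age", 1], beta = cf["offset", 1],
       p_beta = cf["offset", 4],
       intercept = cf["(Intercept)", 1], df = fit$df.residual)
}

#' Choose between the interaction and additive models
#'
#' The additive model is selected when the fitted interaction coefficient is
#' small in magnitude (|gamma| < `gamma_cutoff`), i.e. when ASD and control
#' samples can be assumed to share the same age slope; otherwise the full
#' interaction model is retained.
#'
#' @param gamma Fitted interaction coefficient (finite).
#' @param criteria A [deg_criteria()].
#' @return `"additive"` or `"interaction"`.
#' @export
select_model <- function(gamma, criteria = deg_criteria()) {
  if (!is.finite(gamma)) stop_input("gamma must be finite")
  if (abs(gamma) < criteria$gamma_cutoff) "additive" else "interaction"
}

#' Group fold change
#'
#' Ratio of group means, `mean(ASD) / mean(CTR)`.
#'
#' @inheritParams fit_interaction_model
#' @return The fold-change ratio.
#' @export
fold_change <- function(y, offset) {
  if (!any(offset == 1) || !any(offset == 0)) {
    stop_input("both groups must be non-empty")
  }
  m_ctr <- mean(y[offset == 0])
  if (m_ctr <= 0) {
    sdc_abort("control mean is <= 0; fold change undefined",
              "sdc_fold_change_error")
  }
  mean(y[offset == 1]) / m_ctr
}

fc_passes <- function(fc, criteria) {
  if (!is.finite(fc)) return(FALSE)
  fc >= criteria$fc_cutoff ||
    (criteria$two_sided_fc && fc <= 1 / criteria$fc_cutoff)
}

#' Balance a cohort by subsampling controls
#'
#' Keeps all ASD samples and randomly subsamples controls, without
#' replacement, down to the ASD count. A cohort with fewer controls than ASD
#' samples is returned unchanged with a warning.
#'
#' @param m A [cohort_matrix()].
#' @param seed Integer seed making the selection reproducible.
#' @return A [cohort_matrix()] with equal group sizes.
#' @export
balance_cohort <- function(m, seed = 1) {
  stopifnot(inherits(m, "cohort_matrix"))
  asd <- which(m$meta$group == "ASD")
  ctr <- which(m$meta$group == "CTR")
  if (length(ctr) < length(asd)) {
    warning("fewer controls than ASD samples; cohort returned unchanged")
    return(m)
  }
  if (length(ctr) == length(asd)) return(m)
  keep_ctr <- withr::with_seed(seed, sort(sample(ctr, length(asd))))
  keep <- sort(c(asd, keep_ctr))
  cohort_matrix(m$values[, keep, drop = FALSE], m$meta[keep, , drop = FALSE])
}

#' Filter a mouse DEG table
#'
#' Retains rows with `|log2fc| >= lfc_cutoff` and `pvalue <= p_cutoff`;
#' both boundaries are inclusive.
#'
#' @param tab Data frame with columns `gene`, `log2fc`, `pvalue`.
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 0.58).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @return The retained rows of `tab`.
#' @export
filter_mouse_degs <- function(tab, lfc_cutoff = 0.58, p_cutoff = 0.05) {
  miss <- setdiff(c("gene", "log2fc", "pvalue"), names(tab))
  if (length(miss)) {
    stop_schema(paste0("DEG table is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  keep <- abs(tab$log2fc) >= lfc_cutoff & tab$pvalue <= p_cutoff
  tab[keep, , drop = FALSE]
}

#' Screen a cohort for differentially expressed genes
#'
#' The central fitting function. For each candidate gene it fits the
#' age-by-diagnosis interaction model; when the fitted interaction
#' coefficient is small (|gamma| < `gamma_cutoff`) the gene is refit under
#' the additive model and the group coefficient is t-tested there, otherwise
#' the coefficient and test come from the interaction fit. A gene is called
#' a DEG when the group-coefficient p-value is at most `p_cutoff` and its
#' fold change (mean ASD over mean CTR) passes the fold-change criterion.
#'
#' @param m A [cohort_matrix()].
#' @param candidates Character vector of genes to test; default all genes in
#'   `m`. Must be a subset of `rownames(m$values)`.
#' @param criteria A [deg_criteria()].
#' @param balance If `TRUE`, [balance_cohort()] is applied first.
#' @param seed Seed for the balancing subsample.
#' @return An object of class `cohort_deg` with elements `results` (data
#'   frame: `gene`, `alpha`, `beta`, `gamma`, `model_used`, `p_beta`,
#'   `fold_change`, `is_deg`), `criteria`, `n_asd`, `n_ctr` and `balanced`.
#'   `gamma` is `NA` for genes tested under the additive model; genes whose
#'   fold change is undefined (control mean <= 0) have `fold_change = NA`
#'   and are never called DEGs.
#' @examples
#' syn <- gen_cohort(cohort_spec(n_asd = 15, n_ctr = 15, n_genes = 40,
#'                               n_true_deg = 5, seed = 3))
#' fit <- cohort_deg(syn$cohort)
#' summary(fit)
#' @export
cohort_deg <- function(m, candidates = NULL, criteria = deg_criteria(),
                       balance = FALSE, seed = 1) {
  stopifnot(inherits(m, "cohort_matrix"), inherits(criteria, "deg_criteria"))
  balanced <- FALSE
  if (balance) {
    n_before <- ncol(m$values)
    m <- balance_cohort(m, seed = seed)
    balanced <- ncol(m$values) < n_before
  }
  genes <- rownames(m$values)
  if (is.null(candidates)) candidates <- genes
  unknown <- setdiff(candidates, genes)
  if (length(unknown)) {
    stop_input(paste0("candidate gene(s) not in cohort: ",
                      paste(utils::head(unknown, 5), collapse = ", ")))
  }
  age <- m$meta$age
  offset <- as.numeric(m$meta$group == "ASD")

  res <- lapply(candidates, function(g) {
    y <- m$values[g, ]
    full <- fit_interaction_model(y, age, offset)
    model <- select_model(full$gamma, criteria)
    if (model == "additive") {
      add <- fit_additive_model(y, age, offset)
      alpha <- add$alpha; beta <- add$beta; p_beta <- add$p_beta
      gamma <- NA_real_
    } else {
      alpha <- full$alpha; beta <- full$beta; p_beta <- full$p_beta
      gamma <- full$gamma
    }
    fc <- tryCatch(fold_change(y, offset),
                   sdc_fold_change_error = function(e) NA_real_)
    data.frame(gene = g, alpha = alpha, beta = beta, gamma = gamma,
               model_used = model, p_beta = p_beta, fold_change = fc,
               is_deg = p_beta <= criteria$p_cutoff && fc_passes(fc, criteria),
               stringsAsFactors = FALSE)
  })
  results <- if (length(res)) {
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  }
  if (is.null(results)) {
    results <- data.frame(gene = character(), alpha = numeric(),
                          beta = numeric(), gamma = numeric(),
                          model_used = character(), p_beta = numeric(),
                          fold_change = numeric(), is_deg = logical(),
                          stringsAsFactors = FALSE)
  }
  structure(list(results = results, criteria = criteria,
                 n_asd = sum(offset == 1), n_ctr = sum(offset == 0),
                 balanced = balanced),
            class = "cohort_deg")
}

#' @export
print.cohort_deg <- function(x, ...) {
  cat(sprintf("cohort_deg: %d genes tested on %d ASD / %d CTR samples%s\n",
              nrow(x$results), x$n_asd, x$n_ctr,
              if (x$balanced) " (balanced)" else ""))
  cat(sprintf("  DEGs called: %d (p <= %g and fold change %s %g%s)\n",
              sum(x$results$is_deg), x$criteria$p_cutoff,
              if (x$criteria$two_sided_fc) ">=|<=" else ">=",
              x$criteria$fc_cutoff,
              if (x$criteria$two_sided_fc)
                sprintf(" or <= %.3g", 1 / x$criteria$fc_cutoff) else ""))
  invisible(x)
}

#' @export
summary.cohort_deg <- function(object, ...) {
  r <- object$results
  out <- list(
    n_tested = nrow(r),
    n_deg = sum(r$is_deg),
    model_used = table(factor(r$model_used,
                              levels = c("additive", "interaction"))),
    n_fc_undefined = sum(is.na(r$fold_change)),
    criteria = object$criteria,
    degs = r[r$is_deg, , drop = FALSE]
  )
  class(out) <- "summary.cohort_deg"
  out
}

#' @export
print.summary.cohort_deg <- function(x, ...) {
  cat(sprintf("Genes tested: %d | additive model: %d | interaction model: %d\n",
              x$n_tested, x$model_used[["additive"]],
              x$model_used[["interaction"]]))
  if (x$n_fc_undefined) {
    cat(sprintf("Fold change undefined (excluded): %d\n", x$n_fc_undefined))
  }
  cat(sprintf("DEGs called: %d\n", x$n_deg))
  if (x$n_deg > 0) {
    show <- utils::head(x$degs[order(x$degs$p_beta), ], 10)
    print(show, row.names = FALSE, digits = 4)
    if (x$n_deg > 10) cat(sprintf("... and %d more\n", x$n_deg - 10))
  }
  invisible(x)
}

#' @export
coef.cohort_deg <- function(object, ...) {
  r <- object$results
  out <- as.matrix(r[, c("alpha", "beta", "gamma")])
  rownames(out) <- r$gene
  out
}

#' @export
as.data.frame.cohort_deg <- function(x, ...) x$results

#' Volcano-style plot of a cohort screen
#'
#' @param x A `cohort_deg` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cohort_deg <- function(x, ...) {
  r <- x$results[is.finite(x$results$fold_change), ]
  graphics::plot(log2(r$fold_change), -log10(r$p_beta),
                 col = ifelse(r$is_deg, "red3", "grey40"),
                 pch = 16, cex = 0.6,
                 xlab = "log2 fold change (ASD / CTR)",
                 ylab = "-log10 p(beta)", ...)
  graphics::abline(h = -log10(x$criteria$p_cutoff), lty = 2)
  graphics::abline(v = c(-1, 1) * log2(x$criteria$fc_cutoff), lty = 2)
  invisible(x)
}
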