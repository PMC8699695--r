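test_that("noiseless linear data is fit exactly", {
  set.seed(1)
  d <- rand_design(20)
  y <- 3 + 1 * d$age + 2 * d$offset
  # summary.lm warns on exactly collinear data; the estimates remain exact
  full <- suppressWarnings(fit_interaction_model(y, d$age, d$offset))
  expect_equal(full$alpha, 1, tolerance = 1e-8)
  expect_equal(full$beta, 2, tolerance = 1e-8)
  expect_equal(full$gamma, 0, tolerance = 1e-8)
  add <- suppressWarnings(fit_additive_model(y, d$age, d$offset))
  expect_equal(add$beta, 2, tolerance = 1e-8)
  expect_equal(add$intercept, 3, tolerance = 1e-8)
  # pure interaction signal
  y2 <- d$offset * d$age
  full2 <- suppressWarnings(fit_interaction_model(y2, d$age, d$offset))
  expect_equal(full2$gamma, 1, tolerance = 1e-8)
  expect_equal(full2$beta, 0, tolerance = 1e-8)
})

test_that("both models agree with the normal-equations oracle", {
  set.seed(7)
  n <- 30
  d <- rand_design(n)
  y <- 2 + 0.1 * d$age + 0.5 * d$offset + rnorm(n)
  full <- fit_interaction_model(y, d$age, d$offset)
  oracle <- ols_oracle(y, cbind(1, d$age, d$offset, d$age * d$offset))
  expect_equal(full$beta, oracle$coef[3], tolerance = 1e-8)
  expect_equal(full$gamma, oracle$coef[4], tolerance = 1e-8)
  expect_equal(full$p_beta, oracle$p[3], tolerance = 1e-8)
  expect_equal(full$p_gamma, oracle$p[4], tolerance = 1e-8)
  add <- fit_additive_model(y, d$age, d$offset)
  oracle2 <- ols_oracle(y, cbind(1, d$age, d$offset))
  expect_equal(add$beta, oracle2$coef[3], tolerance = 1e-8)
  expect_equal(add$p_beta, oracle2$p[3], tolerance = 1e-8)
  expect_equal(add$df, oracle2$df)
})

test_that("fits are invariant to sample permutation", {
  set.seed(2)
  n <- 24
  d <- rand_design(n)
  y <- 1 + 0.05 * d$age + d$offset + rnorm(n)
  perm <- sample.int(n)
  a <- fit_interaction_model(y, d$age, d$offset)
  b <- fit_interaction_model(y[perm], d$age[perm], d$offset[perm])
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("degenerate designs raise a typed error", {
  expect_error(fit_interaction_model(rnorm(10), rep(30, 10),
                                     rep(c(0, 1), 5)),
               class = "sdc_degenerate_design_error")
  expect_error(fit_additive_model(rnorm(4), runif(4), c(0, 1, 0, 1)),
               class = "sdc_input_error")
  expect_error(fit_additive_model(rnorm(10), runif(10), rep(0, 10)),
               class = "sdc_input_error")
})

test_that("model selection is a pure threshold on |gamma|", {
  crit <- deg_criteria()
  expect_equal(select_model(0.05, crit), "additive")
  expect_equal(select_model(0.5, crit), "interaction")
  expect_equal(select_model(-0.05, crit), "additive")
  expect_equal(select_model(-0.5, crit), "interaction")
  expect_equal(select_model(0.1, crit), "interaction")  # boundary: not below
  expect_error(select_model(NaN, crit), class = "sdc_input_error")
})

test_that("fold change follows the ratio-of-means definition", {
  y <- c(rep(10, 4), rep(8, 4))
  offset <- rep(c(1, 0), each = 4)
  expect_equal(fold_change(y, offset), 1.25)
  expect_equal(fold_change(rep(3, 8), offset), 1)
  expect_error(fold_change(c(1, 1, -2, -2), c(1, 1, 0, 0)),
               class = "sdc_fold_change_error")
})

test_that("down-regulation passes only under the two-sided convention", {
  y <- c(rep(8, 5), rep(10, 5))     # FC = 0.8 = 1/1.25
  offset <- rep(c(1, 0), each = 5)
  fc <- fold_change(y, offset)
  expect_equal(fc, 0.8)
  two <- deg_criteria(two_sided_fc = TRUE)
  one <- deg_criteria(two_sided_fc = FALSE)
  pass <- function(fc, crit) fc >= crit$fc_cutoff ||
    (crit$two_sided_fc && fc <= 1 / crit$fc_cutoff)
  expect_true(pass(fc, two))
  expect_false(pass(fc, one))
})

test_that("cohort balancing keeps all cases and subsamples controls reproducibly", {
  syn <- gen_cohort(cohort_spec(n_asd = 25, n_ctr = 38, n_genes = 10,
                                n_true_deg = 0, seed = 9))
  b1 <- balance_cohort(syn$cohort, seed = 5)
  expect_equal(as.integer(table(b1$meta$group)[c("ASD", "CTR")]), c(25L, 25L))
  expect_true(all(syn$cohort$meta$sample_id[syn$cohort$meta$group == "ASD"]
                  %in% b1$meta$sample_id))
  b2 <- balance_cohort(syn$cohort, seed = 5)
  expect_identical(b1, b2)
  expect_false(identical(b1$meta$sample_id,
                         balance_cohort(syn$cohort, seed = 6)$meta$sample_id))
  expect_identical(balance_cohort(b1, seed = 1), b1)  # already balanced
  flipped <- gen_cohort(cohort_spec(n_asd = 10, n_ctr = 5, n_genes = 5,
                                    n_true_deg = 0, seed = 2))$cohort
  expect_warning(out <- balance_cohort(flipped), "unchanged")
  expect_identical(out, flipped)
})

test_that("mouse DEG filtering is boundary-inclusive", {
  tab <- data.frame(
    gene = paste0("g", 1:6),
    log2fc = c(0.58, -0.60, 0.57, 1.50, -0.30, 0.80),
    pvalue = c(0.05, 0.01, 0.01, 0.20, 0.04, 0.049))
  kept <- filter_mouse_degs(tab)
  expect_setequal(kept$gene, c("g1", "g2", "g6"))
  expect_error(filter_mouse_degs(tab[, c("gene", "log2fc")]),
               class = "sdc_schema_error")
})

test_that("cohort screening handles empty candidate sets and reports gamma only when retained", {
  syn <- gen_cohort(cohort_spec(n_asd = 12, n_ctr = 12, n_genes = 30,
                                n_true_deg = 3, gamma_effect = 0.5, seed = 8))
  fit <- cohort_deg(syn$cohort)
  r <- fit$results
  expect_true(all(is.na(r$gamma[r$model_used == "additive"])))
  expect_true(all(!is.na(r$gamma[r$model_used == "interaction"])))
  expect_true(all(r$p_beta >= 0 & r$p_beta <= 1))
  empty <- cohort_deg(syn$cohort, candidates = character(0))
  expect_equal(nrow(empty$results), 0)
  expect_error(cohort_deg(syn$cohort, candidates = "NOPE"),
               class = "sdc_input_error")
})

test_that("screening results are invariant to gene and sample ordering", {
  syn <- gen_cohort(cohort_spec(n_asd = 8, n_ctr = 8, n_genes = 12,
                                n_true_deg = 2, seed = 21))
  m <- syn$cohort
  fit1 <- cohort_deg(m)$results
  gperm <- sample(nrow(m$values))
  sperm <- sample(ncol(m$values))
  m2 <- cohort_matrix(m$values[gperm, sperm], m$meta[sperm, ])
  fit2 <- cohort_deg(m2)$results
  fit2 <- fit2[match(fit1$gene, fit2$gene), ]
  rownames(fit2) <- NULL
  expect_equal(fit1, fit2, tolerance = 1e-12)
})

test_that("beta estimates are unbiased and tighten with sample size", {
  bias <- vapply(c(20, 80, 320), function(n) {
    reps <- vapply(1:40, function(i) {
      set.seed(n + i)
      d <- rand_design(n)
      y <- 4 + 0.02 * d$age + 1 * d$offset + rnorm(n)
      fit_additive_model(y, d$age, d$offset)$beta
    }, numeric(1))
    mean(reps) - 1
  }, numeric(1))
  expect_lt(abs(bias[3]), abs(bias[1]) + 0.1)
  expect_lt(abs(bias[3]), 0.1)
})
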