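# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (normal equations, exhaustive pair enumeration) and do
# not share code with the package internals.

# Closed-form OLS with two-sided t-tests: X includes the intercept column.
ols_oracle <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  XtX_inv <- solve(t(X) %*% X)
  beta <- drop(XtX_inv %*% t(X) %*% y)
  resid <- y - drop(X %*% beta)
  s2 <- sum(resid^2) / (n - p)
  se <- sqrt(diag(XtX_inv) * s2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  list(coef = beta, se = se, p = pval, df = n - p)
}

# Exhaustive pairwise AUC: P(pos > neg) + 0.5 P(pos == neg).
auc_brute <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force multi-set tally: for each gene, count the sets containing it.
venn_brute <- function(sets) {
  genes <- unique(unlist(sets))
  k <- vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  table(factor(k, levels = seq_along(sets)))
}

# One grid step of the default log period grid, as a ratio.
grid_step <- function(pmin = 4, pmax = 32, n = 200) (pmax / pmin)^(1 / (n - 1))

expect_within_one_grid_step <- function(estimate, target) {
  expect_lte(abs(log(estimate) - log(target)), log(grid_step()) + 1e-12)
}

rand_design <- function(n) {
  list(age = stats::runif(n, 5, 40),
       offset = sample(rep(c(0, 1), length.out = n)))
}
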