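test_that("cohort generator is a pure function of its spec", {
  spec <- cohort_spec(n_asd = 6, n_ctr = 8, n_genes = 30, n_true_deg = 5,
                     seed = 11)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a, b)
  c <- gen_cohort(cohort_spec(n_asd = 6, n_ctr = 8, n_genes = 30,
                              n_true_deg = 5, seed = 12))
  expect_false(identical(a$cohort$values, c$cohort$values))
})

test_that("cohort metadata matches the requested group sizes and labels", {
  syn <- gen_cohort(cohort_spec(n_asd = 25, n_ctr = 38, n_genes = 20,
                                n_true_deg = 2, seed = 1))
  tab <- table(syn$cohort$meta$group)
  expect_equal(unname(tab[["ASD"]]), 25)
  expect_equal(unname(tab[["CTR"]]), 38)
  # ADI-R classes only on ASD samples, drawn from the five ordinal labels
  meta <- syn$cohort$meta
  expect_true(all(is.na(meta$adir_class[meta$group == "CTR"])))
  asd_cls <- meta$adir_class[meta$group == "ASD"]
  expect_false(anyNA(asd_cls))
  expect_true(all(asd_cls %in% c("low", "moderate2", "moderate1",
                                 "high2", "high1")))
  ages <- meta$age
  expect_true(all(ages >= 5 & ages <= 40))
})

test_that("noiseless plants are recovered exactly by the fitted models", {
  syn <- gen_cohort(cohort_spec(n_asd = 10, n_ctr = 10, n_genes = 5,
                                n_true_deg = 1, beta_effect = 2,
                                noise_sd = 1e-9, seed = 4))
  g <- syn$truth$gene[syn$truth$is_deg]
  m <- syn$cohort
  fit <- fit_interaction_model(m$values[g, ], m$meta$age,
                               as.numeric(m$meta$group == "ASD"))
  expect_equal(fit$beta, 2, tolerance = 1e-6)
  expect_equal(fit$gamma, 0, tolerance = 1e-6)
  null_g <- syn$truth$gene[!syn$truth$is_deg][1]
  expect_equal(syn$truth$true_beta[syn$truth$gene == null_g], 0)
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(n_true_deg = 50, n_genes = 10), class = "sdc_parameter_error")
  expect_error(cohort_spec(n_asd = 1), class = "sdc_parameter_error")
  expect_error(cohort_spec(noise_sd = 0), class = "sdc_parameter_error")
  expect_error(cohort_spec(age_range = c(10, 10)), class = "sdc_parameter_error")
})

test_that("zero light-phase rate confines all activity to the dark phase", {
  sched <- ld_schedule(12, 12)
  a <- gen_actogram(sched, days = 4, bin_minutes = 6, rate_dark = 5,
                    rate_light = 0, seed = 3)
  mid_h <- (seq_along(a$counts) - 0.5) * a$bin_minutes / 60
  light <- is_light(sched, mid_h)
  expect_true(all(a$counts[light] == 0))
  expect_gt(sum(a$counts[!light]), 0)
})

test_that("an 8:8 record has its activity autocorrelation peak at the 16 h lag", {
  a <- gen_actogram(ld_schedule(8, 8), days = 14, bin_minutes = 6,
                    rate_dark = 5, rate_light = 0.2, seed = 5)
  bins_per_h <- 60 / a$bin_minutes
  ac <- stats::acf(a$counts, lag.max = 32 * bins_per_h, plot = FALSE)$acf[-1]
  search <- seq(8 * bins_per_h, 32 * bins_per_h)  # lags from 8 h out
  peak_lag_h <- search[which.max(ac[search])] / bins_per_h
  expect_equal(peak_lag_h, 16, tolerance = 0.05)
})

test_that("daily totals agree with the Poisson expectation within 3 SD", {
  days <- 14
  a <- gen_actogram(ld_schedule(12, 12), days = days, bin_minutes = 6,
                    rate_dark = 5, rate_light = 0.2, seed = 6)
  mid_h <- (seq_along(a$counts) - 0.5) * a$bin_minutes / 60
  light <- is_light(a$schedule, mid_h)
  expected <- 5 * sum(!light) + 0.2 * sum(light)
  sd_total <- sqrt(expected)  # variance of a Poisson sum
  expect_lt(abs(sum(a$counts) - expected), 3 * sd_total)
  # conservation: the binned record holds every generated event
  expect_equal(total_daily_activity(a) * days, sum(a$counts))
})

test_that("actogram generator validates its parameters", {
  expect_error(gen_actogram(ld_schedule(12, 12), days = 0), class = "sdc_parameter_error")
  expect_error(gen_actogram(ld_schedule(12, 12), days = 2, bin_minutes = 7),
               class = "sdc_parameter_error")
  expect_error(gen_actogram(ld_schedule(12, 12), days = 2, rate_dark = 1,
                            rate_light = 2), class = "sdc_parameter_error")
})

test_that("mouse DEG tables contain the constructed number of passing rows", {
  none <- gen_mouse_deg_table(200, frac_sig = 0, seed = 1)
  expect_equal(nrow(filter_mouse_degs(none)), 0)
  tab <- gen_mouse_deg_table(1000, frac_sig = 0.1, seed = 2)
  sig <- filter_mouse_degs(tab)
  expect_equal(nrow(sig), 100)
  expect_true(all(abs(sig$log2fc) >= 0.58))
  expect_true(all(sig$pvalue <= 0.05))
  # determinism
  expect_identical(tab, gen_mouse_deg_table(1000, frac_sig = 0.1, seed = 2))
})

test_that("homolog map follows the upper-casing convention and stays injective", {
  map <- gen_homolog_map(c("Slc16a9", "Pon1", "Chac1"))
  expect_equal(unname(map["Slc16a9"]), "SLC16A9")
  expect_equal(unname(map["Pon1"]), "PON1")
  expect_equal(anyDuplicated(map), 0L)
  over <- gen_homolog_map(c("Slc16a9", "Xkr4"), overrides = c(Xkr4 = "XKR4L"))
  expect_equal(unname(over["Xkr4"]), "XKR4L")
  expect_error(gen_homolog_map(c("Pon1", "Pon1")), class = "sdc_input_error")
  # a collision produced by case-folding two distinct symbols is rejected
  expect_error(gen_homolog_map(c("Pon1", "PON1")), class = "sdc_input_error")
})
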