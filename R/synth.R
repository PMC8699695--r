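#' Specify a synthetic expression cohort
#'
#' Parameters of the generative model behind [gen_cohort()]. Expression for
#' gene g in sample s is
#' `baseline + alpha_slope * age + beta_g * offset + gamma_g * age * offset + e`,
#' where `offset` is 1 for ASD samples and 0 for controls and
#' `e ~ N(0, noise_sd^2)`. A seeded subset of `n_true_deg` genes is planted
#' with group offset `beta_effect` (and interaction slope `gamma_effect`);
#' all other genes have zero group effect.
#'
#' @param n_asd,n_ctr Number of ASD and control samples (each >= 2).
#' @param n_genes Number of genes.
#' @param n_true_deg Number of planted differentially expressed genes
#'   (<= `n_genes`).
#' @param beta_effect Group offset planted on DEG genes, in expression units.
#' @param gamma_effect Age-by-group interaction slope planted on DEG genes,
#'   in expression units per year.
#' @param alpha_slope Common age slope, expression units per year.
#' @param age_range Closed interval of sample ages in years (nondegenerate).
#' @param noise_sd Residual standard deviation, expression units (> 0).
#' @param baseline Intercept expression level for controls at age 0.
#' @param seed Integer seed; the generator is a pure function of the spec.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 25, n_ctr = 38, n_genes = 1000,
                        n_true_deg = 50, beta_effect = 1.5, gamma_effect = 0,
                        alpha_slope = 0.02, age_range = c(5, 40),
                        noise_sd = 1, baseline = 4, seed = 1) {
  spec <- list(
    n_asd = check_count(n_asd, "n_asd", min = 2),
    n_ctr = check_count(n_ctr, "n_ctr", min = 2),
    n_genes = check_count(n_genes, "n_genes", min = 1),
    n_true_deg = check_count(n_true_deg, "n_true_deg"),
    beta_effect = check_number(beta_effect, "beta_effect"),
    gamma_effect = check_number(gamma_effect, "gamma_effect"),
    alpha_slope = check_number(alpha_slope, "alpha_slope"),
    age_range = age_range,
    noise_sd = check_number(noise_sd, "noise_sd", min = 0, strict = TRUE),
    baseline = check_number(baseline, "baseline"),
    seed = check_count(seed, "seed")
  )
  if (spec$n_true_deg > spec$n_genes) {
    stop_parameter("n_true_deg must not exceed n_genes")
  }
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      !all(is.finite(age_range)) || diff(age_range) <= 0) {
    stop_parameter("age_range must be a nondegenerate finite interval")
  }
  structure(spec, class = "cohort_spec")
}

# Ordinal ADI-R severity labels used throughout, lowest to highest severity.
adir_levels <- function() c("low", "moderate2", "moderate1", "high2", "high1")

#' Generate a synthetic expression cohort with planted effects
#'
#' Draws a gene-by-sample matrix under the linear model described in
#' [cohort_spec()], together with the ground truth of which genes carry a
#' planted group effect. ASD samples additionally receive an ordinal ADI-R
#' severity class, assigned by quintile of a latent severity score (the mean
#' z-scored expression of the planted genes), so that severity is learnable
#' from the planted signal; controls get `NA`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `cohort` (a [cohort_matrix()]) and `truth`
#'   (data frame `gene`, `is_deg`, `true_beta`, `true_gamma`).
#' @examples
#' syn <- gen_cohort(cohort_spec(n_asd = 10, n_ctr = 12, n_genes = 50,
#'                               n_true_deg = 5, seed = 42))
#' head(syn$truth)
#' @export
gen_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  withr::with_seed(spec$seed, {
    n <- spec$n_asd + spec$n_ctr
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    samples <- sprintf("S%03d", seq_len(n))
    group <- c(rep("ASD", spec$n_asd), rep("CTR", spec$n_ctr))
    offset <- as.numeric(group == "ASD")
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])

    deg_idx <- sort(sample.int(spec$n_genes, spec$n_true_deg))
    beta <- numeric(spec$n_genes)
    gamma <- numeric(spec$n_genes)
    beta[deg_idx] <- spec$beta_effect
    gamma[deg_idx] <- spec$gamma_effect

    mu <- spec$baseline + spec$alpha_slope * outer(rep(1, spec$n_genes), age) +
      outer(beta, offset) + outer(gamma, rep(1, n)) * outer(rep(1, spec$n_genes),
                                                            age * offset)
    values <- mu + matrix(stats::rnorm(spec$n_genes * n, sd = spec$noise_sd),
                          spec$n_genes, n)
    dimnames(values) <- list(genes, samples)

    # Latent severity for ASD samples: planted-gene burden (z-scored mean);
    # with no planted genes severity is pure noise.
    asd <- which(offset == 1)
    if (length(deg_idx)) {
      sub <- values[deg_idx, asd, drop = FALSE]
      z <- (sub - rowMeans(sub)) / pmax(apply(sub, 1, stats::sd), .Machine$double.eps)
      severity <- colMeans(z)
    } else {
      severity <- stats::rnorm(length(asd))
    }
    lev <- adir_levels()
    bins <- cut(rank(severity, ties.method = "first"),
                breaks = length(lev), labels = lev)
    adir <- rep(NA_character_, n)
    adir[asd] <- as.character(bins)

    meta <- data.frame(sample_id = samples, group = group, age = age,
                       adir_class = adir, stringsAsFactors = FALSE)
    truth <- data.frame(gene = genes,
                        is_deg = seq_len(spec$n_genes) %in% deg_idx,
                        true_beta = beta, true_gamma = gamma,
                        stringsAsFactors = FALSE)
    list(cohort = cohort_matrix(values, meta), truth = truth)
  })
}

#' Light/dark schedule
#'
#' A rectangular LD schedule: lights on for `light_hours`, off for
#' `dark_hours`, repeating. `phase_hours` shifts the cycle so that lights-on
#' occurs `phase_hours` after the record start.
#'
#' @param light_hours,dark_hours Positive durations in hours.
#' @param phase_hours Offset of the first lights-on, hours (default 0).
#' @return An object of class `ld_schedule`.
#' @export
ld_schedule <- function(light_hours = 12, dark_hours = 12, phase_hours = 0) {
  light_hours <- check_number(light_hours, "light_hours", 0, strict = TRUE)
  dark_hours <- check_number(dark_hours, "dark_hours", 0, strict = TRUE)
  phase_hours <- check_number(phase_hours, "phase_hours")
  structure(list(light_hours = light_hours, dark_hours = dark_hours,
                 phase_hours = phase_hours,
                 cycle_hours = light_hours + dark_hours),
            class = "ld_schedule")
}

#' Is a time point in the light phase?
#'
#' @param schedule An [ld_schedule()].
#' @param time_hours Numeric vector of times, hours from record start.
#' @return Logical vector, `TRUE` where lights are on.
#' @export
is_light <- function(schedule, time_hours) {
  phase <- (time_hours - schedule$phase_hours) %% schedule$cycle_hours
  phase < schedule$light_hours
}

#' Generate an LD-entrained activity record
#'
#' Simulates a wheel-running actogram as independent Poisson counts per time
#' bin, with the rate switching between `rate_dark` and `rate_light` according
#' to the light state of the bin midpoint under `schedule`. This emulates
#' masking/entrainment (activity confined to the dark phase when
#' `rate_light` is small), not free-running circadian dynamics.
#'
#' @param schedule An [ld_schedule()].
#' @param days Number of 24-h days to simulate (> 0).
#' @param bin_minutes Bin width in minutes; must divide 60. Default 6.
#' @param rate_dark,rate_light Expected counts per bin in dark and light;
#'   `rate_dark > rate_light >= 0`.
#' @param seed Integer seed.
#' @return An [actogram()].
#' @examples
#' a <- gen_actogram(ld_schedule(12, 12), days = 3, rate_dark = 5,
#'                   rate_light = 0.2, seed = 1)
#' total_daily_activity(a)
#' @export
gen_actogram <- function(schedule, days, bin_minutes = 6, rate_dark = 5,
                         rate_light = 0.2, seed = 1) {
  if (!inherits(schedule, "ld_schedule")) stop_parameter("schedule must be an ld_schedule")
  days <- check_number(days, "days", 0, strict = TRUE)
  bin_minutes <- check_count(bin_minutes, "bin_minutes", min = 1)
  if (60 %% bin_minutes != 0) stop_parameter("bin_minutes must divide 60")
  rate_dark <- check_number(rate_dark, "rate_dark", 0)
  rate_light <- check_number(rate_light, "rate_light", 0)
  if (!(rate_dark > rate_light)) stop_parameter("rate_dark must exceed rate_light")
  n_bins <- as.integer(round(days * 24 * 60 / bin_minutes))
  if (n_bins < 1L) stop_parameter("record must contain at least one bin")
  mid_h <- ((seq_len(n_bins) - 0.5) * bin_minutes) / 60
  light <- is_light(schedule, mid_h)
  rate <- ifelse(light, rate_light, rate_dark)
  counts <- withr::with_seed(seed, stats::rpois(n_bins, rate))
  actogram(counts, bin_minutes = bin_minutes, schedule = schedule)
}

#' Generate a mouse DEG table with a known pass fraction
#'
#' Builds a `gene`, `log2fc`, `pvalue` table in which exactly
#' `round(frac_sig * n_genes)` rows satisfy the mouse DEG cutoffs
#' (|log2FC| >= 0.58 and p <= 0.05) used by [filter_mouse_degs()];
#' the remaining rows are constructed to fail at least one cutoff.
#'
#' @param n_genes Number of rows.
#' @param frac_sig Fraction of rows passing the cutoffs, in \[0, 1\].
#' @param seed Integer seed.
#' @return Data frame `gene`, `log2fc`, `pvalue`.
#' @export
gen_mouse_deg_table <- function(n_genes, frac_sig, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  frac_sig <- check_number(frac_sig, "frac_sig", 0)
  if (frac_sig > 1) stop_parameter("frac_sig must be <= 1")
  withr::with_seed(seed, {
    n_sig <- as.integer(round(frac_sig * n_genes))
    gene <- sprintf("Mgene%04d", seq_len(n_genes))
    log2fc <- numeric(n_genes)
    pvalue <- numeric(n_genes)
    sig <- seq_len(n_sig)
    if (n_sig > 0) {
      log2fc[sig] <- sample(c(-1, 1), n_sig, replace = TRUE) *
        (0.58 + stats::rexp(n_sig, rate = 2))
      pvalue[sig] <- stats::runif(n_sig, 0, 0.05)
    }
    if (n_sig < n_genes) {
      fail <- (n_sig + 1L):n_genes
      by_p <- fail[seq_len(length(fail) %/% 2)]       # large effect, weak p
      by_fc <- setdiff(fail, by_p)                    # small effect, any p
      log2fc[by_p] <- sample(c(-1, 1), length(by_p), TRUE) *
        (0.58 + stats::rexp(length(by_p), rate = 2))
      pvalue[by_p] <- stats::runif(length(by_p), 0.0501, 1)
      log2fc[by_fc] <- stats::runif(length(by_fc), -0.5799, 0.5799)
      pvalue[by_fc] <- stats::runif(length(by_fc), 0, 1)
    }
    ord <- sample.int(n_genes)
    data.frame(gene = gene[ord], log2fc = log2fc[ord], pvalue = pvalue[ord],
               stringsAsFactors = FALSE)
  })
}

#' Generate a simple interaction-network edge list
#'
#' Random simple undirected graph with exactly `n_nodes` non-isolated nodes
#' and `n_edges` distinct edges: a spanning cycle guarantees every node an
#' endpoint, and the remaining edges are drawn uniformly without replacement.
#' Requires `n_edges >= n_nodes` and at most the number of possible pairs.
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @param seed Integer seed.
#' @return Data frame with columns `from` and `to`.
#' @examples
#' gs <- graph_summary(gen_ppi_edges(82, 140, seed = 1))
#' gs$avg_degree
#' @export
gen_ppi_edges <- function(n_nodes, n_edges, seed = 1) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 3)
  n_edges <- check_count(n_edges, "n_edges", min = 1)
  if (n_edges < n_nodes || n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop_parameter("n_edges must lie in [n_nodes, choose(n_nodes, 2)]")
  }
  withr::with_seed(seed, {
    edges <- cbind(seq_len(n_nodes), c(seq_len(n_nodes)[-1], 1L))
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(edges))) {
      assign(paste(sort(edges[i, ]), collapse = "|"), TRUE, envir = seen)
    }
    while (nrow(edges) < n_edges) {
      e <- sort(sample.int(n_nodes, 2))
      k <- paste(e, collapse = "|")
      if (!exists(k, envir = seen)) {
        edges <- rbind(edges, e)
        assign(k, TRUE, envir = seen)
      }
    }
    data.frame(from = sprintf("n%03d", edges[, 1]),
               to = sprintf("n%03d", edges[, 2]),
               stringsAsFactors = FALSE)
  })
}

#' Mouse-to-human homolog symbol map
#'
#' Maps mouse gene symbols to human symbols by the upper-casing convention
#' (e.g. `Slc16a9 -> SLC16A9`), with an optional override table for orthologs
#' whose symbols differ non-trivially. The result is required to be
#' one-to-one.
#'
#' @param genes Character vector of mouse symbols, non-empty and unique.
#' @param overrides Named character vector: names are mouse symbols, values
#'   the human symbol to use instead of the default.
#' @return Named character vector mapping mouse symbol to human symbol.
#' @examples
#' gen_homolog_map(c("Slc16a9", "Pon1"))
#' @export
gen_homolog_map <- function(genes, overrides = NULL) {
  if (!is.character(genes) || length(genes) == 0 || any(!nzchar(genes))) {
    stop_input("'genes' must be a non-empty character vector of symbols")
  }
  if (anyDuplicated(genes)) {
    stop_input(paste0("duplicate mouse symbol(s): ",
                      paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  human <- toupper(genes)
  names(human) <- genes
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop_input("'overrides' must be a named character vector")
    }
    hit <- intersect(names(overrides), genes)
    human[hit] <- overrides[hit]
  }
  if (anyDuplicated(human)) {
    stop_input(paste0("homolog map is not injective; colliding human symbol(s): ",
                      paste(unique(human[duplicated(human)]), collapse = ", ")))
  }
  human
}
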