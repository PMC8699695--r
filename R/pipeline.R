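#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]. Every stochastic
#' stage has an explicit seed derived from `seed`; all thresholds default to
#' the screening defaults of [deg_criteria()].
#'
#' @param seed Master integer seed.
#' @param n_cohorts Number of synthetic human cohorts to simulate.
#' @param cohort Named list of [cohort_spec()] arguments (seed added per
#'   cohort).
#' @param mouse Named list: `frac_sig` fraction of mouse genes passing the
#'   DEG cutoffs.
#' @param criteria Named list of [deg_criteria()] arguments.
#' @param balance Balance each cohort before screening?
#' @param actogram Named list: `days`, `bin_minutes`, `rate_dark`,
#'   `rate_light`.
#' @param wavelet Named list: `period_min`, `period_max`, `n_periods`,
#'   `omega0`.
#' @param graph Named list: `n_nodes`, `n_edges` of the synthetic
#'   interaction network.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_cohorts = 2,
                       cohort = list(), mouse = list(frac_sig = 0.1),
                       criteria = list(), balance = TRUE,
                       actogram = list(days = 14, bin_minutes = 6,
                                       rate_dark = 5, rate_light = 0.2),
                       wavelet = list(period_min = 4, period_max = 32,
                                      n_periods = 200, omega0 = 6),
                       graph = list(n_nodes = 82, n_edges = 140)) {
  structure(list(seed = check_count(seed, "seed"), n_cohorts = n_cohorts,
                 cohort = cohort, mouse = mouse, criteria = criteria,
                 balance = balance, actogram = actogram, wavelet = wavelet,
                 graph = graph),
            class = "run_config")
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- unclass(config)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    sdc_abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
              "sdc_config_error")
  }
  do.call(run_config, config)
}

#' Run the full synthetic-to-summary pipeline
#'
#' Executes, in order: cohort/mouse-table/homolog-map simulation, per-cohort
#' DEG screening, cross-species overlap and multi-cohort tally, per-class
#' importance scoring, actogram simulation with wavelet period analysis
#' (a 12:12-entrained control record and an 8:8-entrained record), and the
#' formula-defined summary metrics on seeded synthetic behaviour and network
#' inputs. All intermediate tables are written under `outdir` together with
#' a `manifest.json` recording the configuration, seeds and an MD5 digest of
#' every output file, so identical configurations yield identical manifests.
#'
#' @param config A [run_config()], a plain named list of its arguments, or
#'   the path to a YAML file holding them. Unknown keys are an error.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("sdc_run_")) {
  cfg <- load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(outdir, ...)
  criteria <- do.call(deg_criteria, cfg$criteria)

  # --- simulate cohorts --------------------------------------------------
  cohorts <- list()
  for (i in seq_len(cfg$n_cohorts)) {
    args <- cfg$cohort
    args$seed <- cfg$seed + i
    syn <- gen_cohort(do.call(cohort_spec, args))
    nm <- sprintf("cohort%d", i)
    write_cohort(syn$cohort, path(paste0(nm, "_expr.tsv")),
                 path(paste0(nm, "_meta.csv")))
    utils::write.table(syn$truth, path(paste0(nm, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cohorts[[nm]] <- syn
  }
  genes <- rownames(cohorts[[1]]$cohort$values)

  # Mouse DEG table over homologs of the cohort genes (mouse symbols are the
  # lower-cased human symbols, so the upper-casing map recovers them).
  mouse_tab <- gen_mouse_deg_table(length(genes),
                                   frac_sig = cfg$mouse$frac_sig,
                                   seed = cfg$seed + 100)
  mouse_tab$gene <- tolower(genes)[match(mouse_tab$gene,
                                         sort(mouse_tab$gene))]
  write_deg_table(mouse_tab, path("mouse_degs.tsv"))
  map <- gen_homolog_map(mouse_tab$gene)
  write_homolog_map(map, path("homolog_map.tsv"))

  # --- per-cohort screening and concordance ------------------------------
  mouse_sig <- filter_mouse_degs(mouse_tab)$gene
  per_cohort_degs <- list()
  fits <- list()
  for (nm in names(cohorts)) {
    m <- cohorts[[nm]]$cohort
    candidates <- overlap_candidates(mouse_sig, map, rownames(m$values))
    fit <- cohort_deg(m, candidates = as.character(candidates),
                      criteria = criteria, balance = cfg$balance,
                      seed = cfg$seed)
    write_gene_results(fit, path(paste0(nm, "_results.tsv")))
    per_cohort_degs[[nm]] <- fit$results$gene[fit$results$is_deg]
    fits[[nm]] <- fit
  }
  vt <- venn_tally(per_cohort_degs)
  write_venn(vt, path("venn.tsv"))

  # --- importance scoring on the first cohort ----------------------------
  first <- cohorts[[1]]$cohort
  imp_genes <- unique(unlist(per_cohort_degs))
  if (length(imp_genes) < 2L) imp_genes <- utils::head(genes, 10)
  asd <- first$meta$group == "ASD"
  occurrence <- vapply(vt$membership, length, integer(1))
  imp <- importance_scores(t(first$values[imp_genes, asd, drop = FALSE]),
                           first$meta$adir_class[asd],
                           occurrence = occurrence)
  write_importance(imp, path("importance.tsv"))

  # --- rhythm ------------------------------------------------------------
  act_cfg <- cfg$actogram
  schedules <- list(ctr = ld_schedule(12, 12), sd = ld_schedule(8, 8))
  rhythm_summary <- list()
  for (nm in names(schedules)) {
    a <- gen_actogram(schedules[[nm]], days = act_cfg$days,
                      bin_minutes = act_cfg$bin_minutes,
                      rate_dark = act_cfg$rate_dark,
                      rate_light = act_cfg$rate_light,
                      seed = cfg$seed + 200 + match(nm, names(schedules)))
    write_actogram(a, path(paste0("actogram_", nm, ".csv")))
    pg <- do.call(morlet_periodogram, c(list(a), cfg$wavelet))
    utils::write.table(data.frame(period_h = pg$periods, power = pg$power),
                       path(paste0("periodogram_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rhythm_summary[[nm]] <- list(dominant_period_h = pg$dominant_period,
                                 total_daily_activity = total_daily_activity(a))
  }

  # --- summary metrics on seeded synthetic inputs ------------------------
  metrics <- withr::with_seed(cfg$seed + 300, {
    trials <- data.frame(time_novel = stats::rgamma(10, 20, 1),
                         time_familiar = stats::rgamma(10, 10, 1))
    di <- discrimination_index(trials$time_novel, trials$time_familiar)
    spines <- stats::setNames(stats::rpois(5, c(20, 30, 25, 10, 5)),
                              c("A", "B", "C", "D", "E"))
    gs <- graph_summary(gen_ppi_edges(cfg$graph$n_nodes, cfg$graph$n_edges,
                                      seed = cfg$seed + 301))
    list(mean_di = mean(di$di),
         spine_mature_fraction = unname(spine_fractions(spines)["mature"]),
         graph = list(n_nodes = gs$n_nodes, n_edges = gs$n_edges,
                      avg_degree = gs$avg_degree_display))
  })

  manifest <- list(
    package = "sdconcord",
    version = as.character(utils::packageVersion("sdconcord")),
    config = unclass(cfg),
    cohort_deg_counts = lapply(per_cohort_degs, length),
    shared_at_least_2 = unname(vt$at_least[["2"]]),
    rhythm = rhythm_summary,
    metrics = metrics,
    outputs = as.list(tools::md5sum(sort(list.files(outdir, full.names = TRUE))))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
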