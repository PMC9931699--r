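#' @title End-to-end drivers and report emission
#' @name reporting
#' @description Ties curation, the robust Bayesian model, inference and the
#'   frequentist companion together for the standard analyses — a single
#'   two-group comparison over a period (optionally JIF-normalized) and the
#'   multi-period comparison — and writes the result tables, diagnostics and
#'   a run manifest to disk.
NULL

#' Read a citation table from CSV
#'
#' Expects the canonical schema (`paper_id`, `year`, `group`, `scopus`,
#' `wos`, `gscholar`, `jif_2014` ... `jif_2021`; empty cells are missing)
#' and validates it, reporting offending rows.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated `citation_records` table.
#' @export
read_citations_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    needed <- c("paper_id", "year", "group", "scopus", "wos", "gscholar")
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols)) {
      stop("missing required columns: ",
           paste(missing_cols, collapse = ", "))
    }
    df$paper_id <- character(0)
    class(df) <- unique(c("citation_records", class(df)))
    return(df)
  }
  as_citation_records(df)
}

#' Write a citation table to CSV
#'
#' @param records A `citation_records` table.
#' @param path Output path.
#' @export
write_citations_table <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run one two-group comparison end to end
#'
#' Curates the input table (period filter, deduplication, imputation,
#' averaging, optional JIF normalization), fits the robust Bayesian model
#' with pooled-data priors, summarizes the decision quantities, runs the
#' Mann-Whitney U companion and the convergence diagnostics.
#'
#' @param records A `citation_records` table or a path to one.
#' @param group1,group2 Group labels to compare (group 1 minus group 2).
#' @param period `c(start_year, end_year)` or `NULL` for all years.
#' @param normalize_by_jif Divide citations by the average JIF?
#' @param draws,chains,warmup,seed Passed to [sample_posterior()].
#' @param prior_mode `"default"` or `"sensitivity"` pooled priors.
#' @param decision A [decision_config()].
#' @param keep_trace Keep the full posterior trace in the result?
#' @return An object of class `best_run`: `summary`
#'   ([compare_groups()] output), `frequentist` ([mwu_test()] output),
#'   `diagnostics`, `curation_log`, the settings, and optionally `trace`.
#' @export
run_comparison <- function(records,
                           group1 = "REPRODUCIBLE",
                           group2 = "NON_REPRODUCIBLE",
                           period = NULL, normalize_by_jif = FALSE,
                           draws = 100000, chains = 4, warmup = 1000,
                           seed = 1, prior_mode = "default",
                           decision = decision_config(),
                           keep_trace = TRUE) {
  if (is.character(records)) records <- read_citations_table(records)
  ccfg <- curation_config(period = period,
                          normalize_by_jif = normalize_by_jif)
  cur <- curate_citations(records, ccfg)
  gd <- lapply(c(group1, group2), function(g) {
    sel <- cur$records[cur$records$group == g, , drop = FALSE]
    if (nrow(sel) < 2) {
      stop("insufficient data: group '", g, "' has ", nrow(sel),
           " curated record(s)")
    }
    group_dataset(g, sel$analysis_value)
  })
  trace <- best_fit(gd, draws = draws, chains = chains, warmup = warmup,
                    seed = seed, prior_mode = prior_mode)
  structure(list(
    summary = compare_groups(trace, 1, 2, decision),
    frequentist = mwu_test(gd[[1]]$values, gd[[2]]$values),
    diagnostics = convergence_diagnostics(trace),
    curation_log = cur$log,
    period = period, normalize_by_jif = normalize_by_jif,
    draws = draws, chains = chains, warmup = warmup, seed = seed,
    prior_mode = prior_mode,
    trace = if (keep_trace) trace else NULL),
    class = "best_run")
}

#' @export
print.best_run <- function(x, ...) {
  if (!is.null(x$period)) {
    cat("Period ", x$period[1], "-", x$period[2],
        if (x$normalize_by_jif) " (JIF normalized)", "\n", sep = "")
  }
  print(x$summary)
  print(x$frequentist)
  cat(sprintf("  max PSRF = %.4f, min ESS = %.0f\n",
              max(x$diagnostics$psrf), min(x$diagnostics$ess)))
  invisible(x)
}

period_label <- function(p) sprintf("%d-%d", p[1], p[2])

#' Multi-period comparison with a shared-tail joint model
#'
#' Builds one analysis group per (group label, period) combination, fits a
#' single joint robust model — individual means and scales per group, one
#' shared normality parameter — and reports the credibility that the first
#' label's mean exceeds the second label's for every pair of periods: the
#' data behind a multi-period credibility heatmap.
#'
#' @inheritParams run_comparison
#' @param periods List of `c(start_year, end_year)` vectors.
#' @return A list of class `multi_period_run`: `credibility` (matrix, rows =
#'   `group1` periods, columns = `group2` periods), per-period
#'   `summaries`, `diagnostics`, and the trace.
#' @export
run_multi_period <- function(records,
                             periods = list(c(2010, 2020), c(2013, 2020),
                                            c(2014, 2020), c(2016, 2020),
                                            c(2018, 2020)),
                             group1 = "REPRODUCIBLE",
                             group2 = "NON_REPRODUCIBLE",
                             normalize_by_jif = FALSE,
                             draws = 100000, chains = 4, warmup = 1000,
                             seed = 1, prior_mode = "default",
                             decision = decision_config()) {
  if (is.character(records)) records <- read_citations_table(records)
  P <- length(periods)
  if (P < 1) stop("need at least one period")
  gd <- list()
  for (p in seq_len(P)) {
    ccfg <- curation_config(period = periods[[p]],
                            normalize_by_jif = normalize_by_jif)
    cur <- curate_citations(records, ccfg)
    for (g in c(group1, group2)) {
      sel <- cur$records[cur$records$group == g, , drop = FALSE]
      gd[[sprintf("%s %s", g, period_label(periods[[p]]))]] <-
        group_dataset(sprintf("%s %s", g, period_label(periods[[p]])),
                      sel$analysis_value)
    }
  }
  trace <- best_fit(unname(gd), draws = draws, chains = chains,
                    warmup = warmup, seed = seed, prior_mode = prior_mode)
  full <- pairwise_credibility_matrix(trace)
  lab1 <- sprintf("%s %s", group1, vapply(periods, period_label, ""))
  lab2 <- sprintf("%s %s", group2, vapply(periods, period_label, ""))
  summaries <- lapply(seq_len(P), function(p) {
    compare_groups(trace, lab1[p], lab2[p], decision)
  })
  names(summaries) <- vapply(periods, period_label, "")
  structure(list(credibility = full[lab1, lab2, drop = FALSE],
                 summaries = summaries,
                 diagnostics = convergence_diagnostics(trace),
                 periods = periods, trace = trace, seed = seed),
            class = "multi_period_run")
}

comparison_row <- function(s) {
  data.frame(group_pair = sprintf("%s versus %s", s$group1, s$group2),
             n1 = s$n1, n2 = s$n2,
             mean_diff = s$mean_diff$mean,
             hdi_low = s$mean_diff$hdi_low,
             hdi_high = s$mean_diff$hdi_high,
             credibility_above_zero = s$mean_diff$credibility_above_zero,
             effect_size = s$effect_size$mean,
             effect_hdi_low = s$effect_size$hdi_low,
             effect_hdi_high = s$effect_size$hdi_high,
             decision = s$decision)
}

frequentist_row <- function(f, s) {
  data.frame(group_pair = sprintf("%s versus %s", s$group1, s$group2),
             n1 = f$n1, n2 = f$n2, u = f$u, p_value = f$p_value,
             method = f$method)
}

#' Write a report bundle for one or more comparison runs
#'
#' Emits `frequentist_tests.csv` (one row per pair: n1, n2, U, p),
#' `bayesian_summaries.csv` (posterior mean difference, HDI, credibility,
#' effect size, decision), `diagnostics.json` (PSRF/ESS per run) and
#' `manifest.json` (seeds, settings, package version, config hash). When a
#' `multi_period_run` is included, its credibility matrix goes to
#' `credibility_matrix.csv`.
#'
#' @param runs A `best_run`, a `multi_period_run`, or a list of them;
#'   names label the rows.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(runs, outdir) {
  if (inherits(runs, c("best_run", "multi_period_run"))) runs <- list(runs)
  if (!length(runs)) stop("no results to report")
  if (is.null(names(runs))) names(runs) <- sprintf("run%d", seq_along(runs))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bayes <- list(); freq <- list(); diag <- list(); paths <- character()
  for (nm in names(runs)) {
    r <- runs[[nm]]
    if (inherits(r, "best_run")) {
      bayes[[nm]] <- cbind(run = nm, comparison_row(r$summary))
      freq[[nm]] <- cbind(run = nm, frequentist_row(r$frequentist, r$summary))
      diag[[nm]] <- r$diagnostics
    } else if (inherits(r, "multi_period_run")) {
      for (p in names(r$summaries)) {
        s <- r$summaries[[p]]
        bayes[[paste(nm, p)]] <- cbind(run = paste(nm, p),
                                       comparison_row(s))
      }
      diag[[nm]] <- r$diagnostics
      mp <- file.path(outdir, "credibility_matrix.csv")
      write.csv(r$credibility, mp, row.names = TRUE)
      paths <- c(paths, mp)
    } else {
      stop("unknown result type for '", nm, "'")
    }
  }
  bp <- file.path(outdir, "bayesian_summaries.csv")
  write.csv(do.call(rbind, bayes), bp, row.names = FALSE)
  paths <- c(paths, bp)
  if (length(freq)) {
    fp <- file.path(outdir, "frequentist_tests.csv")
    write.csv(do.call(rbind, freq), fp, row.names = FALSE)
    paths <- c(paths, fp)
  }
  dp <- file.path(outdir, "diagnostics.json")
  jsonlite::write_json(diag, dp, dataframe = "rows", digits = NA)
  paths <- c(paths, dp)
  settings <- lapply(runs, function(r) {
    r[intersect(names(r), c("period", "periods", "normalize_by_jif",
                            "draws", "chains", "warmup", "seed",
                            "prior_mode"))]
  })
  cfg_file <- tempfile()
  jsonlite::write_json(settings, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "bestcite",
    version = as.character(utils::packageVersion("bestcite")),
    seeds = lapply(runs, `[[`, "seed"),
    settings = settings,
    config_hash = unname(tools::md5sum(cfg_file)))
  unlink(cfg_file)
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized fields: `input` (CSV path), `periods` (list of two-year
#' vectors), `group1`, `group2`, `normalize_by_jif`, `prior_mode`, `draws`,
#' `chains`, `warmup`, `seed`, `hdi_mass`, `rope`, `outdir`. Missing fields
#' fall back to the function defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the analyses described by a configuration
#'
#' One [run_comparison()] per configured period (a single period) and, when
#' several periods are given, additionally the joint [run_multi_period()]
#' comparison. Writes a report bundle when `outdir` is configured.
#'
#' @param cfg A list as returned by [read_run_config()].
#' @return Named list of run objects (invisibly also written to
#'   `cfg$outdir` when set).
#' @export
run_from_config <- function(cfg) {
  records <- read_citations_table(cfg$input)
  dec <- decision_config(
    hdi_mass = if (is.null(cfg$hdi_mass)) 0.95 else cfg$hdi_mass,
    rope = if (is.null(cfg$rope)) c(-0.2, 0.2) else unlist(cfg$rope))
  defaults <- list(group1 = "REPRODUCIBLE", group2 = "NON_REPRODUCIBLE",
                   normalize_by_jif = FALSE, prior_mode = "default",
                   draws = 100000, chains = 4, warmup = 1000, seed = 1)
  for (f in names(defaults)) if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  periods <- cfg$periods
  if (is.null(periods)) periods <- list(NULL)
  if (is.matrix(periods)) periods <- asplit(periods, 1)
  runs <- list()
  for (p in periods) {
    nm <- if (is.null(p)) "all-years" else period_label(p)
    runs[[nm]] <- run_comparison(
      records, cfg$group1, cfg$group2, period = p,
      normalize_by_jif = cfg$normalize_by_jif, draws = cfg$draws,
      chains = cfg$chains, warmup = cfg$warmup, seed = cfg$seed,
      prior_mode = cfg$prior_mode, decision = dec, keep_trace = FALSE)
  }
  if (length(periods) > 1 && !any(vapply(periods, is.null, TRUE))) {
    runs[["multi-period"]] <- run_multi_period(
      records, periods, cfg$group1, cfg$group2,
      normalize_by_jif = cfg$normalize_by_jif, draws = cfg$draws,
      chains = cfg$chains, warmup = cfg$warmup, seed = cfg$seed,
      prior_mode = cfg$prior_mode, decision = dec)
  }
  if (!is.null(cfg$outdir)) write_report(runs, cfg$outdir)
  runs
}

#' Recompute the published-style result tables from a deposited dataset
#'
#' Given the deposited study table in the canonical schema, reruns the four
#' standard comparisons — full period, 2013--2020, 2013--2020 JIF
#' normalized, and the PEtab benchmark group versus the non-reproducible
#' group — and returns the frequentist (U, p) and Bayesian (mean
#' difference, HDI, credibility) result tables.
#'
#' @param records Path to the deposited CSV or a `citation_records` table.
#' @param draws,chains,warmup,seed Sampling settings (defaults are the full
#'   production settings).
#' @return List with data frames `frequentist` and `bayesian` plus the
#'   underlying runs.
#' @export
reproduce_published_tables <- function(records, draws = 100000, chains = 4,
                                       warmup = 1000, seed = 1) {
  if (is.character(records)) records <- read_citations_table(records)
  specs <- list(
    `1985-2020 Reproducible versus Non-Reproducible` =
      list(period = NULL, jif = FALSE, g = c("REPRODUCIBLE", "NON_REPRODUCIBLE")),
    `2013-2020 Reproducible versus Non-Reproducible` =
      list(period = c(2013, 2020), jif = FALSE,
           g = c("REPRODUCIBLE", "NON_REPRODUCIBLE")),
    `2013-2020 JIF normalized Reproducible versus Non-Reproducible` =
      list(period = c(2013, 2020), jif = TRUE,
           g = c("REPRODUCIBLE", "NON_REPRODUCIBLE")),
    `2013-2020 PEtab models versus Non-Reproducible` =
      list(period = c(2013, 2020), jif = FALSE,
           g = c("PETAB", "NON_REPRODUCIBLE")))
  runs <- lapply(specs, function(sp) {
    run_comparison(records, sp$g[1], sp$g[2], period = sp$period,
                   normalize_by_jif = sp$jif, draws = draws,
                   chains = chains, warmup = warmup, seed = seed,
                   keep_trace = FALSE)
  })
  freq <- do.call(rbind, lapply(names(runs), function(nm) {
    cbind(comparison = nm,
          frequentist_row(runs[[nm]]$frequentist, runs[[nm]]$summary))
  }))
  bayes <- do.call(rbind, lapply(names(runs), function(nm) {
    cbind(comparison = nm, comparison_row(runs[[nm]]$summary))
  }))
  list(frequentist = freq, bayesian = bayes, runs = runs)
}
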