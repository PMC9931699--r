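#' @title Synthetic citation studies
#' @name synthetic_data
#' @description Generates publication tables with the statistical structure
#'   the analysis assumes — heavy-tailed non-negative citation counts with a
#'   configurable group effect, three positively correlated citation sources
#'   with missingness in the restrictive databases, publication years, and
#'   per-year journal impact factors — plus a ground-truth manifest, so the
#'   whole pipeline can be exercised and calibrated without any downloads.
NULL

#' Configuration of a synthetic citation study
#'
#' Defaults emulate the post-standardization (2013--2020) two-group
#' comparison: 111 "reproducible" and 76 "non-reproducible" papers, group
#' means 13.4 and 10 citations (a difference of 3.4), a common scale of 8.5
#' and heavy tails (nu = 3), years uniform on 2013--2020, roughly 10%
#' missingness in each restrictive database, and log-normal journal impact
#' factors with median around 3.
#'
#' @param groups Data frame with columns `group` (label), `n`, `mu`,
#'   `sigma`, `nu` — one row per group.
#' @param year_range Inclusive publication-year range.
#' @param missing_scopus,missing_wos Per-record probability that the Scopus
#'   / Web of Science count is missing, in \[0, 1). Google Scholar is always
#'   present so every record stays imputable.
#' @param jif_meanlog,jif_sdlog Log-normal parameters of the per-journal
#'   impact factor level.
#' @param round_counts Emit integer citation counts (default TRUE; real
#'   databases report integers, a mild misspecification the robust t
#'   likelihood is meant to tolerate).
#' @param imputation_factor The source ratio built into the table: Scopus
#'   and Web of Science counts are generated at this fraction of the Google
#'   Scholar count, so curation's imputation rule is exercised consistently.
#' @return An object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(
    groups = data.frame(
      group = c("REPRODUCIBLE", "NON_REPRODUCIBLE"),
      n = c(111L, 76L),
      mu = c(13.4, 10),
      sigma = c(8.5, 8.5),
      nu = c(3, 3)),
    year_range = c(2013L, 2020L),
    missing_scopus = 0.1, missing_wos = 0.1,
    jif_meanlog = 1.1, jif_sdlog = 0.6,
    round_counts = TRUE,
    imputation_factor = 0.6287) {
  stopifnot(all(c("group", "n", "mu", "sigma", "nu") %in% names(groups)),
            all(groups$n >= 2), all(groups$sigma > 0), all(groups$nu > 0),
            missing_scopus >= 0, missing_scopus < 1,
            missing_wos >= 0, missing_wos < 1,
            jif_sdlog > 0, imputation_factor > 0, imputation_factor <= 1,
            year_range[1] <= year_range[2])
  structure(list(groups = groups, year_range = as.integer(year_range),
                 missing_scopus = missing_scopus, missing_wos = missing_wos,
                 jif_meanlog = jif_meanlog, jif_sdlog = jif_sdlog,
                 round_counts = isTRUE(round_counts),
                 imputation_factor = imputation_factor),
            class = "synthetic_study_config")
}

#' Draw one group's latent citation values
#'
#' `n` draws from the location-scale t(mu, sigma, nu); deterministic given
#' `seed`. Values are returned unclamped — clamping at zero happens when a
#' citation table is assembled.
#'
#' @param n Number of draws (>= 1).
#' @param mu,sigma,nu Location, scale (> 0) and shape (> 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @export
generate_group <- function(n, mu, sigma, nu, seed = NULL) {
  stopifnot(n >= 1, sigma > 0, nu > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rt_ls(n, mu, sigma, nu)
}

#' Generate a synthetic multi-source citation table
#'
#' Per paper, a latent citation level is drawn from its group's
#' location-scale t and clamped at zero; the three source counts are placed
#' around it with small multiplicative log-normal jitter such that the
#' Scopus and Web of Science counts sit at `imputation_factor` times the
#' Google Scholar count while their three-way average stays at the latent
#' level. Scopus and Web of Science are then masked independently at the
#' configured rates, per-year JIFs are drawn log-normally around a
#' per-journal level, and years are uniform over the configured range.
#'
#' @param cfg A [synthetic_study_config()].
#' @param seed Integer seed, or `NULL`.
#' @return A `citation_records` table in the canonical schema.
#' @export
generate_citation_table <- function(cfg = synthetic_study_config(),
                                    seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- cfg$imputation_factor
  gs_factor <- 3 / (1 + 2 * f)   # so mean(scopus, wos, gscholar) = latent
  sw_factor <- f * gs_factor
  rows <- lapply(seq_len(nrow(cfg$groups)), function(g) {
    gr <- cfg$groups[g, ]
    latent <- pmax(rt_ls(gr$n, gr$mu, gr$sigma, gr$nu), 0)
    jitter <- function() rlnorm(gr$n, 0, 0.05)
    scopus <- latent * sw_factor * jitter()
    wos <- latent * sw_factor * jitter()
    gscholar <- latent * gs_factor * jitter()
    if (cfg$round_counts) {
      scopus <- round(scopus); wos <- round(wos); gscholar <- round(gscholar)
    }
    scopus[runif(gr$n) < cfg$missing_scopus] <- NA_real_
    wos[runif(gr$n) < cfg$missing_wos] <- NA_real_
    jif_level <- rlnorm(gr$n, cfg$jif_meanlog, cfg$jif_sdlog)
    jifs <- sapply(JIF_YEARS_DEFAULT,
                   function(y) jif_level * rlnorm(gr$n, 0, 0.1))
    colnames(jifs) <- jif_columns(JIF_YEARS_DEFAULT)
    cbind(data.frame(
      paper_id = sprintf("%s-%04d", abbreviate(gr$group, 2), seq_len(gr$n)),
      year = sample(seq(cfg$year_range[1], cfg$year_range[2]), gr$n,
                    replace = TRUE),
      group = gr$group,
      scopus = scopus, wos = wos, gscholar = gscholar),
      as.data.frame(jifs))
  })
  as_citation_records(do.call(rbind, rows))
}

#' Generate a full synthetic study with a truth manifest
#'
#' @inheritParams generate_citation_table
#' @return A list with `records` (the citation table) and `truth`, a
#'   manifest holding the configured per-group parameters and the implied
#'   pairwise differences of means — the quantities recovery tests check
#'   against.
#' @export
generate_study <- function(cfg = synthetic_study_config(), seed = NULL) {
  records <- generate_citation_table(cfg, seed)
  g <- cfg$groups
  diffs <- list()
  if (nrow(g) >= 2) {
    for (i in seq_len(nrow(g) - 1)) {
      for (j in seq(i + 1, nrow(g))) {
        diffs[[sprintf("%s_vs_%s", g$group[i], g$group[j])]] <-
          g$mu[i] - g$mu[j]
      }
    }
  }
  truth <- list(groups = g, mean_diffs = diffs,
                year_range = cfg$year_range,
                imputation_factor = cfg$imputation_factor,
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  list(records = records, truth = truth)
}
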