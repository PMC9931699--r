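#' @title Bibliometric data curation
#' @name curation
#' @description Functions turning a raw multi-source publication table into
#'   per-group analysis vectors: imputation of citation sources missing from
#'   the more restrictive databases, averaging across sources, journal
#'   impact factor (JIF) averaging and normalization, period filtering and
#'   deduplication.
NULL

CITATION_GROUPS <- c("REPRODUCIBLE", "NON_REPRODUCIBLE", "PETAB")
JIF_YEARS_DEFAULT <- 2014:2021

#' Curation configuration
#'
#' @param imputation_factor Fraction of the Google Scholar count used to fill
#'   a missing Scopus or Web of Science count. The default 0.6287 reflects
#'   that the restrictive databases report on average 37.13% fewer citations
#'   than Google Scholar; imputing the raw Google Scholar count instead would
#'   systematically favour papers absent from those databases.
#' @param period Integer vector `c(start_year, end_year)` (both inclusive)
#'   restricting records by publication year, or `NULL` for no restriction.
#' @param jif_years Years over which per-year JIFs are averaged
#'   (default 2014--2021, matching the JIF coverage of the input schema).
#' @param normalize_by_jif If `TRUE`, analysis values are citation counts
#'   divided by the paper's average JIF; records without any JIF in
#'   `jif_years` are then dropped (and logged as excluded).
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(imputation_factor = 0.6287, period = NULL,
                            jif_years = JIF_YEARS_DEFAULT,
                            normalize_by_jif = FALSE) {
  if (!is.numeric(imputation_factor) || length(imputation_factor) != 1 ||
      is.na(imputation_factor) ||
      imputation_factor <= 0 || imputation_factor > 1) {
    stop("`imputation_factor` must be a single number in (0, 1]")
  }
  if (!is.null(period)) {
    if (length(period) != 2 || anyNA(period)) {
      stop("`period` must be c(start_year, end_year)")
    }
    if (period[1] > period[2]) stop("period start_year must be <= end_year")
  }
  structure(list(imputation_factor = imputation_factor,
                 period = if (is.null(period)) NULL else as.integer(period),
                 jif_years = as.integer(jif_years),
                 normalize_by_jif = isTRUE(normalize_by_jif)),
            class = "curation_config")
}

jif_columns <- function(years) paste0("jif_", years)

#' Validate a table of publication citation records
#'
#' Checks the canonical schema: `paper_id`, `year`, `group` (one of
#' REPRODUCIBLE, NON_REPRODUCIBLE, PETAB), the three source counts `scopus`,
#' `wos`, `gscholar` (`NA` = missing, at least one present per record, all
#' finite and non-negative) and per-year JIF columns `jif_2014` ...
#' `jif_2021` (`NA` allowed, present values must be positive).
#'
#' @param records A data frame in the canonical schema.
#' @return The validated data frame, with class `citation_records` prepended.
#' @export
as_citation_records <- function(records) {
  records <- as.data.frame(records)
  needed <- c("paper_id", "year", "group", "scopus", "wos", "gscholar")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  records$paper_id <- as.character(records$paper_id)
  records$year <- as.integer(records$year)
  records$group <- as.character(records$group)
  bad_group <- !records$group %in% CITATION_GROUPS
  if (any(bad_group)) {
    stop("unknown group label(s) in rows ",
         paste(which(bad_group), collapse = ", "),
         "; expected one of ", paste(CITATION_GROUPS, collapse = ", "))
  }
  if (anyNA(records$year)) stop("`year` must be an integer for every record")
  src <- as.matrix(records[, c("scopus", "wos", "gscholar")])
  if (any(!is.na(src) & (!is.finite(src) | src < 0))) {
    stop("citation counts must be finite and >= 0")
  }
  if (any(rowSums(!is.na(src)) == 0)) {
    stop("every record needs at least one citation source; rows ",
         paste(which(rowSums(!is.na(src)) == 0), collapse = ", "),
         " have none")
  }
  jc <- intersect(jif_columns(JIF_YEARS_DEFAULT), names(records))
  for (cl in jc) {
    v <- records[[cl]]
    if (any(!is.na(v) & (!is.finite(v) | v <= 0))) {
      stop("JIF values must be positive and finite (column ", cl, ")")
    }
  }
  class(records) <- unique(c("citation_records", class(records)))
  records
}

#' Impute citation sources missing from the restrictive databases
#'
#' A paper missing from Scopus or Web of Science gets the Google Scholar
#' count scaled by the imputation factor in its place; present counts are
#' never touched and the Google Scholar count itself is never imputed.
#' The operation is idempotent.
#'
#' @param records A `citation_records` table (or a single-row data frame).
#' @param cfg A [curation_config()].
#' @return The table with `scopus`/`wos` gaps filled.
#' @export
impute_missing_sources <- function(records, cfg = curation_config()) {
  records <- as_citation_records(records)
  need <- is.na(records$scopus) | is.na(records$wos)
  if (any(need & is.na(records$gscholar))) {
    stop("unimputable record(s): Scopus or Web of Science missing and no ",
         "Google Scholar count to impute from (rows ",
         paste(which(need & is.na(records$gscholar)), collapse = ", "), ")")
  }
  fill <- records$gscholar * cfg$imputation_factor
  records$scopus <- ifelse(is.na(records$scopus), fill, records$scopus)
  records$wos <- ifelse(is.na(records$wos), fill, records$wos)
  records
}

#' Average the three citation sources
#'
#' Arithmetic mean of the Scopus, Web of Science and Google Scholar counts.
#' All three must be present (run [impute_missing_sources()] first).
#'
#' @param records A fully imputed `citation_records` table.
#' @return Numeric vector of per-record averaged citation counts.
#' @export
average_citations <- function(records) {
  records <- as_citation_records(records)
  src <- as.matrix(records[, c("scopus", "wos", "gscholar")])
  if (anyNA(src)) {
    stop("citation sources still missing; run impute_missing_sources() first")
  }
  rowMeans(src)
}

#' Average the per-year journal impact factors
#'
#' Mean of the JIF values available within `cfg$jif_years`; a record whose
#' journal has no JIF in that range gets `NA` (and is excluded downstream
#' when JIF normalization is on).
#'
#' @inheritParams impute_missing_sources
#' @return Numeric vector of average JIFs (`NA` where no JIF is available).
#' @export
average_jif <- function(records, cfg = curation_config()) {
  records <- as_citation_records(records)
  jc <- intersect(jif_columns(cfg$jif_years), names(records))
  if (!length(jc)) return(rep(NA_real_, nrow(records)))
  jm <- as.matrix(records[, jc, drop = FALSE])
  out <- rowMeans(jm, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Normalize citation counts by the journal impact factor
#'
#' @param citations Non-negative citation counts.
#' @param jif Positive average JIFs (same length or scalar).
#' @return `citations / jif`.
#' @export
normalize_citations_by_jif <- function(citations, jif) {
  if (anyNA(jif) || any(jif <= 0)) {
    stop("JIF must be present and > 0 for normalization; ",
         "exclude records without JIF coverage instead")
  }
  citations / jif
}

#' Restrict to a publication period and collapse duplicate papers
#'
#' Keeps one record per `paper_id` (several models from the same paper count
#' once) and only records published within the configured period, inclusive
#' on both endpoints. Exact duplicates collapse to one record; duplicates
#' with conflicting fields raise a curation-conflict error. Output rows are
#' ordered by `paper_id`.
#'
#' @inheritParams impute_missing_sources
#' @return The filtered, deduplicated table.
#' @export
filter_and_deduplicate <- function(records, cfg = curation_config()) {
  records <- as_citation_records(records)
  if (!is.null(cfg$period)) {
    records <- records[records$year >= cfg$period[1] &
                         records$year <= cfg$period[2], , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(records)
  }
  cmp_cols <- setdiff(names(records), "paper_id")
  split_idx <- split(seq_len(nrow(records)), records$paper_id)
  keep <- vapply(split_idx, function(idx) {
    if (length(idx) > 1) {
      ref <- records[idx[1], cmp_cols]
      for (i in idx[-1]) {
        same <- mapply(identical,
                       lapply(ref, unname),
                       lapply(records[i, cmp_cols], unname))
        if (!all(same)) {
          stop("curation conflict: duplicate paper_id '",
               records$paper_id[idx[1]], "' with differing fields")
        }
      }
    }
    idx[1]
  }, integer(1))
  out <- records[keep[order(names(keep))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A labelled vector of analysis values for one group
#'
#' @param label Group label.
#' @param values Finite numeric analysis values (citations or JIF-normalized
#'   citations), length at least 2.
#' @return An object of class `group_dataset` with fields `label`, `values`
#'   and `n`.
#' @export
group_dataset <- function(label, values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("insufficient data for group '", label, "': need n >= 2, got ",
         length(values))
  }
  if (!all(is.finite(values))) {
    stop("group '", label, "' contains non-finite values")
  }
  structure(list(label = as.character(label), values = values,
                 n = length(values)),
            class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat("Group dataset '", x$label, "': n = ", x$n,
      ", mean = ", signif(mean(x$values), 4),
      ", sd = ", signif(sd(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' Assemble the analysis vector for one group
#'
#' Takes curated records (imputed, filtered, deduplicated), selects the
#' requested group, averages the citation sources and, when
#' `cfg$normalize_by_jif` is on, divides by the average JIF, dropping
#' records without JIF coverage.
#'
#' @param records Curated `citation_records`.
#' @param group One of `"REPRODUCIBLE"`, `"NON_REPRODUCIBLE"`, `"PETAB"`.
#' @inheritParams impute_missing_sources
#' @return A [group_dataset()].
#' @export
build_group_dataset <- function(records, group, cfg = curation_config()) {
  group <- match.arg(group, CITATION_GROUPS)
  records <- as_citation_records(records)
  sel <- records[records$group == group, , drop = FALSE]
  if (nrow(sel) < 2) {
    stop("insufficient data: group '", group, "' has ", nrow(sel),
         " curated record(s), need >= 2")
  }
  vals <- average_citations(sel)
  if (cfg$normalize_by_jif) {
    jif <- average_jif(sel, cfg)
    keep <- !is.na(jif)
    vals <- normalize_citations_by_jif(vals[keep], jif[keep])
  }
  group_dataset(group, vals)
}

#' Run the full curation pipeline
#'
#' Filter and deduplicate, impute missing sources, average citations and
#' JIFs, and report every excluded record with its reason. The returned
#' curated table carries `avg_citations`, `avg_jif` and the final
#' `analysis_value` column actually used downstream.
#'
#' @inheritParams impute_missing_sources
#' @return A list with `records` (curated table), `log` (data frame of
#'   excluded `paper_id`s and reasons) and `cfg`.
#' @export
curate_citations <- function(records, cfg = curation_config()) {
  records <- as_citation_records(records)
  log <- data.frame(paper_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(cfg$period)) {
    out_of_period <- records$year < cfg$period[1] |
      records$year > cfg$period[2]
    if (any(out_of_period)) {
      log <- rbind(log, data.frame(
        paper_id = records$paper_id[out_of_period],
        reason = sprintf("published %d, outside period %d-%d",
                         records$year[out_of_period],
                         cfg$period[1], cfg$period[2])))
    }
  }
  cur <- filter_and_deduplicate(records, cfg)
  cur <- impute_missing_sources(cur, cfg)
  cur$avg_citations <- average_citations(cur)
  cur$avg_jif <- average_jif(cur, cfg)
  if (cfg$normalize_by_jif) {
    no_jif <- is.na(cur$avg_jif)
    if (any(no_jif)) {
      log <- rbind(log, data.frame(
        paper_id = cur$paper_id[no_jif],
        reason = sprintf("no JIF available in %d-%d",
                         min(cfg$jif_years), max(cfg$jif_years))))
    }
    cur <- cur[!no_jif, , drop = FALSE]
    cur$analysis_value <- normalize_citations_by_jif(cur$avg_citations,
                                                     cur$avg_jif)
  } else {
    cur$analysis_value <- cur$avg_citations
  }
  rownames(cur) <- NULL
  list(records = cur, log = log, cfg = cfg)
}
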