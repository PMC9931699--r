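test_that("missing restrictive sources are imputed from Google Scholar", {
  rec <- make_record(gscholar = 100, wos = 50)
  out <- impute_missing_sources(rec)
  expect_equal(out$scopus, 62.87)
  expect_equal(out$wos, 50)       # present values untouched
  expect_equal(out$gscholar, 100) # never imputed

  full <- make_record(scopus = 10, wos = 20, gscholar = 30)
  expect_equal(
    as.data.frame(impute_missing_sources(full))[, c("scopus", "wos", "gscholar")],
    full[, c("scopus", "wos", "gscholar")])

  zero <- make_record(gscholar = 0)
  out0 <- impute_missing_sources(zero)
  expect_equal(out0$scopus, 0)
  expect_equal(out0$wos, 0)

  # idempotence
  twice <- impute_missing_sources(impute_missing_sources(rec))
  expect_identical(twice, impute_missing_sources(rec))

  # configurable factor
  out5 <- impute_missing_sources(rec, curation_config(imputation_factor = 0.5))
  expect_equal(out5$scopus, 50)
})

test_that("records with no imputation donor are rejected", {
  rec <- make_record(scopus = 5) # wos and gscholar missing
  expect_error(impute_missing_sources(rec), "unimputable")
})

test_that("citation averaging is the three-source mean and needs all sources", {
  expect_equal(average_citations(make_record(scopus = 10, wos = 20,
                                             gscholar = 30)), 20)
  expect_equal(average_citations(make_record(scopus = 0, wos = 0,
                                             gscholar = 0)), 0)
  expect_equal(average_citations(make_record(scopus = 100, wos = 62.87,
                                             gscholar = 62.87)),
               (100 + 62.87 + 62.87) / 3)
  expect_error(average_citations(make_record(gscholar = 5)),
               "impute_missing_sources")
})

test_that("averaging is monotone in each source count", {
  base <- make_record(scopus = 10, wos = 20, gscholar = 30)
  a0 <- average_citations(base)
  for (src in c("scopus", "wos", "gscholar")) {
    up <- base
    up[[src]] <- up[[src]] + 7
    expect_gt(average_citations(up), a0)
  }
})

test_that("JIF averaging uses available years and flags empty coverage", {
  const <- make_record(gscholar = 1,
                       jifs = as.list(setNames(rep(5, 8),
                                               as.character(2014:2021))))
  expect_equal(average_jif(const), 5)
  two <- make_record(gscholar = 1, jifs = list(`2014` = 2, `2021` = 4))
  expect_equal(average_jif(two), 3)
  expect_true(is.na(average_jif(make_record(gscholar = 1))))
  bad <- make_record(gscholar = 1, jifs = list(`2014` = -1))
  expect_error(as_citation_records(bad), "positive")
  # restricted year window
  expect_equal(average_jif(two, curation_config(jif_years = 2014:2015)), 2)
})

test_that("JIF normalization divides and rejects missing or non-positive JIF", {
  expect_equal(normalize_citations_by_jif(20, 4), 5)
  expect_equal(normalize_citations_by_jif(0, 7.3), 0)
  expect_equal(normalize_citations_by_jif(17, 2.5), 6.8)
  expect_error(normalize_citations_by_jif(10, NA), "JIF")
  expect_error(normalize_citations_by_jif(10, 0), "JIF")
})

test_that("period filter is inclusive and deduplication keeps one per paper", {
  r12 <- make_record("a", 2012L, scopus = 1, wos = 1, gscholar = 1)
  r13 <- make_record("b", 2013L, scopus = 1, wos = 1, gscholar = 1)
  r20 <- make_record("c", 2020L, scopus = 1, wos = 1, gscholar = 1)
  cfg <- curation_config(period = c(2013, 2020))
  out <- filter_and_deduplicate(make_records(r12, r13, r20), cfg)
  expect_setequal(out$paper_id, c("b", "c"))

  dup <- make_records(r13, r13)
  expect_equal(nrow(filter_and_deduplicate(dup, cfg)), 1)

  conflict <- make_records(r13,
                           make_record("b", 2013L, scopus = 2, wos = 1,
                                       gscholar = 1))
  expect_error(filter_and_deduplicate(conflict, cfg), "conflict")
})

test_that("group datasets carry curated analysis values", {
  recs <- make_records(
    make_record("a", 2015L, "REPRODUCIBLE", 10, 10, 10,
                jifs = list(`2014` = 2)),
    make_record("b", 2016L, "REPRODUCIBLE", 20, 20, 20,
                jifs = list(`2015` = 4)),
    make_record("c", 2017L, "REPRODUCIBLE", 30, 30, 30), # no JIF
    make_record("d", 2015L, "NON_REPRODUCIBLE", 5, 5, 5,
                jifs = list(`2014` = 1)),
    make_record("e", 2016L, "NON_REPRODUCIBLE", 7, 7, 7,
                jifs = list(`2014` = 1)))
  gd <- build_group_dataset(recs, "REPRODUCIBLE")
  expect_s3_class(gd, "group_dataset")
  expect_equal(gd$n, 3)
  expect_equal(sort(gd$values), c(10, 20, 30))

  gdj <- build_group_dataset(recs, "REPRODUCIBLE",
                             curation_config(normalize_by_jif = TRUE))
  expect_equal(gdj$n, 2) # the JIF-less record drops out
  expect_setequal(gdj$values, c(10 / 2, 20 / 4))

  expect_error(build_group_dataset(recs, "PETAB"), "insufficient")
})

test_that("with normalization off, curated group sizes equal unique in-period papers", {
  study <- small_study(seed = 3)
  cur <- curate_citations(study$records,
                          curation_config(period = c(2013, 2020)))
  for (g in c("REPRODUCIBLE", "NON_REPRODUCIBLE")) {
    expected <- length(unique(
      study$records$paper_id[study$records$group == g &
                               study$records$year >= 2013 &
                               study$records$year <= 2020]))
    expect_equal(sum(cur$records$group == g), expected)
  }
})

test_that("curation log records exclusions with reasons", {
  recs <- make_records(
    make_record("a", 2010L, "REPRODUCIBLE", 1, 1, 1),
    make_record("b", 2015L, "REPRODUCIBLE", 2, 2, 2),
    make_record("c", 2016L, "REPRODUCIBLE", 3, 3, 3))
  cur <- curate_citations(recs, curation_config(period = c(2013, 2020),
                                                normalize_by_jif = TRUE))
  expect_true("a" %in% cur$log$paper_id)       # out of period
  expect_true(any(grepl("period", cur$log$reason)))
  expect_true(all(c("b", "c") %in% cur$log$paper_id)) # no JIF coverage
  expect_equal(nrow(cur$records), 0)
})

test_that("curated tables round-trip through CSV unchanged", {
  study <- small_study(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_citations_table(study$records, path)
  back <- read_citations_table(path)
  cfg <- curation_config(period = c(2013, 2020))
  g_orig <- build_group_dataset(
    impute_missing_sources(filter_and_deduplicate(study$records, cfg)),
    "REPRODUCIBLE", cfg)
  g_back <- build_group_dataset(
    impute_missing_sources(filter_and_deduplicate(back, cfg)),
    "REPRODUCIBLE", cfg)
  expect_equal(g_back$values, g_orig$values)
})
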