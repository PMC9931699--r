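# small hand-built citation tables and shared fixtures

make_record <- function(paper_id = "p1", year = 2015L,
                        group = "REPRODUCIBLE",
                        scopus = NA, wos = NA, gscholar = NA,
                        jifs = NULL) {
  df <- data.frame(paper_id = paper_id, year = year, group = group,
                   scopus = as.numeric(scopus), wos = as.numeric(wos),
                   gscholar = as.numeric(gscholar))
  for (y in 2014:2021) {
    cl <- paste0("jif_", y)
    df[[cl]] <- if (!is.null(jifs) && !is.null(jifs[[as.character(y)]])) {
      jifs[[as.character(y)]]
    } else {
      NA_real_
    }
  }
  df
}

make_records <- function(...) do.call(rbind, list(...))

# a small deterministic study used by several tests
small_study <- function(seed = 11, n = c(40L, 30L)) {
  cfg <- synthetic_study_config(
    groups = data.frame(group = c("REPRODUCIBLE", "NON_REPRODUCIBLE"),
                        n = n, mu = c(15, 10), sigma = c(6, 6),
                        nu = c(4, 4)))
  generate_study(cfg, seed = seed)
}

# independent brute-force shortest-interval search used as the HDI oracle
hdi_bruteforce <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    lo <- x[i]
    hi <- x[i + k - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# rank-sum identity oracle for the U statistic: U = R2 - n2 (n2 + 1) / 2,
# where R2 is the sum of midranks of the second sample in the pooled data
u_rank_oracle <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[(length(x) + 1):(length(x) + length(y))]) -
    length(y) * (length(y) + 1) / 2
}
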