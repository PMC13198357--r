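# Shared, lazily computed simulation products: the mechanistic case series
# (30 substrates, 10 per mechanism) and its decrement-free counterpart are
# used by several test files, so they are built once per run.

.case_cache <- new.env(parent = emptyenv())

mech_cases <- function() {
  if (is.null(.case_cache$cases)) {
    .case_cache$cases <- run_mechanistic_study(n_per_mechanism = 10, seed = 1)
  }
  .case_cache$cases
}

decrement_free_cases <- function() {
  if (is.null(.case_cache$df_cases)) {
    .case_cache$df_cases <- run_mechanistic_study(
      n_per_mechanism = 4, seed = 2,
      mechanisms = c("AVNRT", "ORT"), decrement_free = TRUE
    )
  }
  .case_cache$df_cases
}

fixture_dir <- function() {
  if (is.null(.case_cache$fixtures)) {
    d <- file.path(tempdir(), "svt-fixtures")
    make_fixtures(d)
    .case_cache$fixtures <- d
  }
  .case_cache$fixtures
}

# simple event-table constructor for hand-built series
events_tbl <- function(...) {
  df <- as.data.frame(rbind(...), stringsAsFactors = FALSE)
  names(df) <- c("time_ms", "channel", "kind", "origin")[seq_len(ncol(df))]
  df$time_ms <- as.numeric(df$time_ms)
  df
}

# a clean induced-tachycardia series: one inducing stimulus train, then a
# regular tachycardia with the given V-V intervals
toy_tachycardia <- function(vv, ippi = 500, n_stim = 3, stim_cl = 400,
                            meta = list()) {
  stims <- stim_cl * (0:(n_stim - 1))
  last <- max(stims)
  v <- last + ippi + cumsum(c(0, vv))
  egm_series(dplyr::bind_rows(
    tibble::tibble(time_ms = stims, channel = "RVA", kind = "STIM",
                   origin = "PACED"),
    tibble::tibble(time_ms = v, channel = "RVA", kind = "V",
                   origin = "CONDUCTED")
  ), meta = meta)
}
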