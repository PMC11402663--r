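#' Published signal-score table shipped with the package
#'
#' The 30-drug constipation signal table transcribed from a published FAERS
#' disproportionality study, with each drug's case count, the four
#' statistics with their interval bounds, and the per-algorithm significance
#' marks
#' (`*_star` columns). Used by [replicate_from_printed()] to re-derive the
#' signal classification without access to the raw database.
#'
#' @return data.frame with columns `rank, drug, a, ror, ror_lo, ror_hi,
#'   ror_star, prr, chi2, prr_star, ebgm, eb05, mgps_star, ic, ic025,
#'   ic_star`.
#' @export
published_signal_table <- function() {
  path <- system.file("extdata", "published_signal_table.csv", package = "faersdpa",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Drug class letters shipped with the package
#'
#' A static drug -> ATC first-level letter mapping for the 30 study drugs.
#' This mapping is user-editable data, not a computed classification; two
#' letters printed in the source table (duloxetine, capecitabine) appear
#' transposed relative to ATC and are recorded here ATC-correct.
#'
#' @return named character vector drug -> class letter.
#' @export
atc_classes <- function() {
  path <- system.file("extdata", "atc_classes.csv", package = "faersdpa",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$class, df$drug)
}

#' Apply the signal criteria to published statistic rows
#'
#' Re-derives per-algorithm signal flags directly from published values —
#' no raw data needed — and returns per-algorithm counts plus the union.
#' Rows must carry `drug, ror_lo, prr, chi2, eb05, ic025` (and `a`, the
#' case count, if the `min_a` criterion should bind; rows without `a` are
#' treated as satisfying it).
#'
#' @param rows data.frame of published statistics, e.g. [published_signal_table()].
#' @param criteria a [signal_criteria()].
#' @return list with `flags` (data.frame of per-drug logical flags) and
#'   `counts` (named vector `ror, prr, mgps, bcpnn, any`).
#' @export
replicate_from_printed <- function(rows, criteria = signal_criteria()) {
  stopifnot(is.data.frame(rows))
  need <- c("drug", "ror_lo", "prr", "chi2", "eb05", "ic025")
  if (!all(need %in% names(rows))) {
    stop_faersdpa("printed rows lack column(s): ",
                  paste(setdiff(need, names(rows)), collapse = ", "))
  }
  bad <- !stats::complete.cases(rows[setdiff(need, "drug")])
  if (any(bad)) {
    stop_faersdpa("malformed printed row for drug(s): ",
                  paste(rows$drug[bad], collapse = ", "))
  }
  flags <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    row <- as.list(rows[i, ])
    if (is.null(row$a)) row$a <- Inf # count not printed: min_a satisfied
    as.data.frame(as.list(classify_signals(row, criteria)))
  }))
  flags <- cbind(drug = rows$drug, flags, stringsAsFactors = FALSE)
  counts <- c(ror = sum(flags$ror_signal), prr = sum(flags$prr_signal),
              mgps = sum(flags$mgps_signal), bcpnn = sum(flags$bcpnn_signal),
              any = sum(flags$any_signal))
  list(flags = flags, counts = counts)
}

#' Run the full signal-detection pipeline
#'
#' Orchestrates ingest, deduplication, drug ranking, disproportionality
#' with signal criteria, trend and demographic summaries, and time-to-onset
#' analysis of the flagged drugs. Optionally writes the output bundle
#' (CSV tables, a JSON manifest, and a reconciliation log) to `out_dir`.
#'
#' @param input_dir directory of FAERS-format quarterly files.
#' @param target_pt target preferred term (default "CONSTIPATION").
#' @param top_n how many drugs to rank and test (default 30).
#' @param dedup deduplicate case versions (default TRUE); FALSE enables the
#'   report-level sensitivity mode.
#' @param criteria a [signal_criteria()].
#' @param mgps_mode,bcpnn_mode,yates statistic variants, see
#'   [signal_stats()]. Defaults are the table-compatible variants
#'   (`"simplified"` EBGM, `"table_compat"` IC, uncorrected chi-squared).
#' @param classes optional drug -> class letter map for the ranking table.
#' @param synonyms optional drug-name synonym map.
#' @param out_dir optional output directory.
#' @param min_tto_n minimum retained TTO sample for a Weibull fit.
#' @return a `faers_run` bundle: `dataset, ranking, signals, tto, trend_year,
#'   trend_quarter, demographics, log` (character vector of structured log
#'   lines), invisibly written to disk when `out_dir` is given.
#' @export
run_pipeline <- function(input_dir, target_pt = "CONSTIPATION", top_n = 30,
                         dedup = TRUE, criteria = signal_criteria(),
                         mgps_mode = c("simplified", "full"),
                         bcpnn_mode = c("table_compat", "noren"),
                         yates = FALSE, classes = NULL, synonyms = NULL,
                         out_dir = NULL, min_tto_n = 3) {
  mgps_mode <- match.arg(mgps_mode)
  bcpnn_mode <- match.arg(bcpnn_mode)
  target_pt <- norm_string(target_pt)
  log <- character()
  say <- function(...) {
    line <- paste0(...)
    log <<- c(log, line)
    message(line)
  }

  raw <- read_faers_dir(input_dir)
  quarters <- attr(raw, "quarters")
  say("input_dir=", input_dir)
  say("quarters=", paste(quarters, collapse = ","))
  for (k in names(raw)) say("rows_in ", k, "=", nrow(raw[[k]]))
  missing_tables <- setdiff(c("DEMO", "DRUG", "REAC", "THER"), names(raw))
  if (length(missing_tables)) {
    warning("partial quarter set: missing table(s) ",
            paste(missing_tables, collapse = ", "), call. = FALSE)
  }

  dataset <- build_event_dataset(raw, dedup = dedup, synonyms = synonyms)
  for (k in names(dataset$drops)) {
    say("drops ", k, ": ",
        paste(names(dataset$drops[[k]]), dataset$drops[[k]], sep = "=",
              collapse = " "))
  }
  say("cases=", nrow(dataset$cases))

  event_cases <- unique(dataset$events$caseid[dataset$events$pt == target_pt])
  if (length(event_cases) == 0L) {
    stop_faersdpa("no cases report target PT '", target_pt, "'")
  }
  say("event_cases=", length(event_cases))

  counts <- count_event_by_drug(dataset, target_pt)
  ranking <- rank_top(counts, n = top_n, event_total = length(event_cases),
                      classes = classes)
  say("drugs_ranked=", nrow(ranking))

  signals <- signal_table(dataset, ranking$drug, pt = target_pt,
                          criteria = criteria, mgps_mode = mgps_mode,
                          bcpnn_mode = bcpnn_mode, yates = yates)
  say("signals_any=", sum(signals$any_signal))

  flagged <- signals$drug[signals$any_signal]
  tto <- if (length(flagged)) {
    tto_table(dataset, flagged, pt = target_pt, min_n = min_tto_n)
  } else {
    tto_table(dataset, character(0), pt = target_pt)
  }
  say("tto_drugs=", if (is.null(tto)) 0 else nrow(tto))

  trend_year <- trend_series(dataset, target_pt, "year")
  trend_quarter <- trend_series(dataset, target_pt, "quarter")
  demographics <- demographic_summary(dataset, target_pt)

  bundle <- structure(
    list(dataset = dataset, ranking = ranking, signals = signals, tto = tto,
         trend_year = trend_year, trend_quarter = trend_quarter,
         demographics = demographics, log = log,
         params = list(target_pt = target_pt, top_n = top_n, dedup = dedup,
                       mgps_mode = mgps_mode, bcpnn_mode = bcpnn_mode,
                       yates = yates)),
    class = "faers_run"
  )
  if (!is.null(out_dir)) write_run_bundle(bundle, out_dir)
  bundle
}

#' @export
print.faers_run <- function(x, ...) {
  cat("FAERS signal-detection run: target", x$params$target_pt, "\n")
  cat("  cases:", nrow(x$dataset$cases),
      " ranked drugs:", nrow(x$ranking),
      " any-signal:", sum(x$signals$any_signal), "\n")
  invisible(x)
}

#' Write a pipeline bundle to disk
#'
#' Emits `ranking.csv`, `signal_table.csv`, `tto_table.csv`,
#' `trend_year.csv`, `trend_quarter.csv`, `demographics.csv`, a
#' full-precision `manifest.json`, and `run.log`.
#'
#' @param bundle a `faers_run` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "faers_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(bundle$ranking, "ranking.csv")
  wr(bundle$signals, "signal_table.csv")
  wr(bundle$tto, "tto_table.csv")
  wr(bundle$trend_year, "trend_year.csv")
  wr(bundle$trend_quarter, "trend_quarter.csv")
  wr(bundle$demographics, "demographics.csv")
  manifest <- list(
    params = bundle$params,
    n_cases = nrow(bundle$dataset$cases),
    n_event_cases = sum(bundle$demographics$count[
      bundle$demographics$category == "total"]),
    drops = bundle$dataset$drops,
    signals = bundle$signals,
    counts = list(any_signal = sum(bundle$signals$any_signal),
                  ror = sum(bundle$signals$ror_signal),
                  prr = sum(bundle$signals$prr_signal),
                  mgps = sum(bundle$signals$mgps_signal),
                  bcpnn = sum(bundle$signals$bcpnn_signal))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
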