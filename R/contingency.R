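#' Count target-event cases per primary-suspect drug
#'
#' For each drug, counts the number of deduplicated cases that both name the
#' drug as primary suspect and report the target preferred term. A case
#' contributes at most once per drug; a case with several PS drugs
#' contributes once to each of them.
#'
#' @param dataset a [build_event_dataset()] result.
#' @param pt target MedDRA preferred term (normalized internally).
#' @return named integer vector: drug name -> case count `a`. Empty if no
#'   case reports the PT.
#' @export
count_event_by_drug <- function(dataset, pt = "CONSTIPATION") {
  stopifnot(inherits(dataset, "faers_dataset"))
  pt <- norm_string(pt)
  event_cases <- unique(dataset$events$caseid[dataset$events$pt == pt])
  m <- dataset$drug_mentions
  m <- m[m$caseid %in% event_cases, , drop = FALSE]
  if (nrow(m) == 0L) return(stats::setNames(integer(0), character(0)))
  pairs <- unique(m[c("caseid", "drugname")])
  tab <- table(pairs$drugname)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  sort(counts, decreasing = TRUE)
}

#' Rank drugs by event frequency
#'
#' Orders drugs by descending event count `a`, breaking ties by drug name
#' ascending, and attaches the percentage of the event total (rounded
#' half-up to 2 decimals for display). Optionally attaches a drug class
#' letter from a static mapping.
#'
#' @param counts named vector from [count_event_by_drug()].
#' @param n number of top drugs to keep (all if fewer exist).
#' @param event_total denominator for the percentage (total target-event
#'   cases or reports).
#' @param classes optional named character vector drug -> class letter (e.g.
#'   an ATC first-level letter).
#' @return data.frame `rank, drug, frequency, percentage, class`.
#' @export
rank_top <- function(counts, n = 30, event_total, classes = NULL) {
  stopifnot(n >= 1, event_total > 0)
  if (length(counts) == 0L) {
    return(data.frame(rank = integer(), drug = character(),
                      frequency = integer(), percentage = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  }
  ord <- order(-as.numeric(counts), names(counts))
  top <- utils::head(ord, n)
  drug <- names(counts)[top]
  data.frame(
    rank = seq_along(top),
    drug = drug,
    frequency = as.integer(counts[top]),
    percentage = round_half_up(100 * as.numeric(counts[top]) / event_total, 2),
    class = if (is.null(classes)) NA_character_ else unname(classes[drug]),
    stringsAsFactors = FALSE
  )
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Cells: `a` = cases with the drug (as primary suspect) and the event,
#' `b` = cases with the drug without the event, `c` = event cases without
#' the drug, `d` = cases with neither, `N = a+b+c+d` = all cases.
#'
#' @param dataset a [build_event_dataset()] result.
#' @param drug normalized drug name.
#' @param pt target preferred term.
#' @return a `faers_ctab` object (named list `a,b,c,d,N` plus `drug`, `pt`).
#' @export
build_table <- function(dataset, drug, pt = "CONSTIPATION") {
  stopifnot(inherits(dataset, "faers_dataset"))
  drug <- normalize_drug_name(drug)
  pt <- norm_string(pt)
  all_cases <- dataset$cases$caseid
  event_cases <- unique(dataset$events$caseid[dataset$events$pt == pt])
  drug_cases <- unique(
    dataset$drug_mentions$caseid[dataset$drug_mentions$drugname == drug]
  )
  a <- sum(drug_cases %in% event_cases)
  b <- length(drug_cases) - a
  c_ <- length(event_cases) - a
  d <- length(all_cases) - a - b - c_
  contingency_table(a, b, c_, d, drug = drug, pt = pt)
}

#' Construct a 2x2 contingency table from counts
#'
#' @param a,b,c,d non-negative cell counts (drug+event, drug only, event
#'   only, neither).
#' @param drug,pt optional labels.
#' @return a `faers_ctab` object.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              pt = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop_faersdpa("contingency cells must be non-negative counts")
  }
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         d = as.numeric(d), N = as.numeric(a + b + c + d),
         drug = drug, pt = pt),
    class = "faers_ctab"
  )
}

#' @export
print.faers_ctab <- function(x, ...) {
  cat("2x2 contingency table",
      if (!is.na(x$drug)) paste0("[", x$drug, " x ", x$pt, "]"), "\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  print(m)
  cat("N =", format(x$N, big.mark = ","), "\n")
  invisible(x)
}

#' Reconstruct a 2x2 table from published margins and the ROR
#'
#' Published disproportionality tables usually print `a`, the database total
#' `N`, the event margin `a+c`, and the ROR, but not `b` and `d`. Given
#' those, the drug-only cell is determined:
#' `b = a (N - a - c) / (ROR * c + a)`, with `d = N - a - b - c`.
#'
#' @param a drug-and-event count.
#' @param n_total database total `N`.
#' @param event_total event margin `a + c`.
#' @param ror the published reporting odds ratio.
#' @param round_counts round `b` to the nearest integer (counts; default
#'   `TRUE`).
#' @param drug,pt optional labels carried on the table.
#' @return a `faers_ctab` object.
#' @export
reconstruct_table_from_ror <- function(a, n_total, event_total, ror,
                                       round_counts = TRUE,
                                       drug = NA_character_,
                                       pt = NA_character_) {
  stopifnot(a > 0, event_total > a, n_total > event_total, ror > 0)
  c_ <- event_total - a
  b <- a * (n_total - a - c_) / (ror * c_ + a)
  if (round_counts) b <- round(b)
  contingency_table(a, b, c_, n_total - a - b - c_, drug = drug, pt = pt)
}

#' Period trend of event reporting
#'
#' Tabulates, per calendar period, the number of target-event cases, the
#' number of all-ADE cases, and the event percentage. Periods are taken from
#' each retained case's quarter tag; with `granularity = "year"` quarters are
#' collapsed to years. Every period between the first and last observed is
#' included, with zero counts where empty. With `scope = "per_drug"` the
#' tabulation is restricted to cases naming `drug` as primary suspect, so the
#' percentage is the share of that drug's ADE cases reporting the event.
#'
#' @param dataset a [build_event_dataset()] result.
#' @param pt target preferred term.
#' @param granularity `"year"` or `"quarter"`.
#' @param scope `"all"` or `"per_drug"`.
#' @param drug drug name, required when `scope = "per_drug"`.
#' @return data.frame `period, event_count, total_count, percentage`
#'   (percentage half-up, 2 decimals; `NA` when the denominator is 0).
#' @export
trend_series <- function(dataset, pt = "CONSTIPATION",
                         granularity = c("year", "quarter"),
                         scope = c("all", "per_drug"), drug = NULL) {
  stopifnot(inherits(dataset, "faers_dataset"))
  granularity <- match.arg(granularity)
  scope <- match.arg(scope)
  pt <- norm_string(pt)

  cases <- dataset$cases
  if (scope == "per_drug") {
    if (is.null(drug)) stop_faersdpa("scope='per_drug' requires a drug name")
    drug <- normalize_drug_name(drug)
    ids <- unique(
      dataset$drug_mentions$caseid[dataset$drug_mentions$drugname == drug]
    )
    cases <- cases[cases$caseid %in% ids, , drop = FALSE]
  }
  event_ids <- unique(dataset$events$caseid[dataset$events$pt == pt])

  per <- cases$quarter
  if (granularity == "year") per <- substr(per, 1, 4)
  ok <- !is.na(per)
  per <- per[ok]
  is_event <- cases$caseid[ok] %in% event_ids

  if (length(per) == 0L) {
    return(data.frame(period = character(), event_count = integer(),
                      total_count = integer(), percentage = numeric(),
                      stringsAsFactors = FALSE))
  }
  levels <- if (granularity == "year") {
    as.character(seq(min(as.integer(per)), max(as.integer(per))))
  } else {
    yrs <- as.integer(substr(per, 1, 4))
    qs <- as.integer(substr(per, 6, 6))
    all_idx <- seq(min(4 * yrs + qs), max(4 * yrs + qs))
    sprintf("%04dQ%d", (all_idx - 1) %/% 4, (all_idx - 1) %% 4 + 1)
  }
  total <- table(factor(per, levels = levels))
  events <- table(factor(per[is_event], levels = levels))
  out <- data.frame(
    period = levels,
    event_count = as.integer(events),
    total_count = as.integer(total),
    stringsAsFactors = FALSE
  )
  out$percentage <- ifelse(
    out$total_count > 0,
    round_half_up(100 * out$event_count / out$total_count, 2),
    NA_real_
  )
  out
}

# age bands as published demographic tables stratify them
AGE_BAND_LEVELS <- c("<18", "18-39", "40-64", ">=65", "unknown")

age_band <- function(age_years) {
  out <- rep("unknown", length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "<18"
  out[!is.na(age_years) & age_years >= 18 & age_years < 40] <- "18-39"
  out[!is.na(age_years) & age_years >= 40 & age_years < 65] <- "40-64"
  out[!is.na(age_years) & age_years >= 65] <- ">=65"
  factor(out, levels = AGE_BAND_LEVELS)
}

#' Demographic summary of target-event cases
#'
#' Counts and percentages (half-up, 1 decimal) of deduplicated target-event
#' cases by age band, sex, and the top reporting countries.
#'
#' @param dataset a [build_event_dataset()] result.
#' @param pt target preferred term.
#' @param top_countries how many countries to list individually.
#' @return data.frame `category, level, count, percentage`.
#' @export
demographic_summary <- function(dataset, pt = "CONSTIPATION",
                                top_countries = 5) {
  stopifnot(inherits(dataset, "faers_dataset"))
  pt <- norm_string(pt)
  ids <- unique(dataset$events$caseid[dataset$events$pt == pt])
  cases <- dataset$cases[dataset$cases$caseid %in% ids, , drop = FALSE]
  n <- nrow(cases)
  if (n == 0L) stop_faersdpa("no cases report PT '", pt, "'")

  row_block <- function(category, counts) {
    data.frame(category = category, level = names(counts),
               count = as.integer(counts),
               percentage = round_half_up(100 * as.integer(counts) / n, 1),
               stringsAsFactors = FALSE)
  }
  age <- table(age_band(cases$age_years))
  sex <- table(factor(cases$sex, levels = c("M", "F", "unknown")))
  ctry <- sort(table(cases$country), decreasing = TRUE)
  top <- utils::head(ctry, top_countries)

  rbind(
    data.frame(category = "total", level = "total", count = n,
               percentage = 100, stringsAsFactors = FALSE),
    row_block("age", age),
    row_block("sex", sex),
    row_block("country", top)
  )
}
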