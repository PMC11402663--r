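#' @name faers-io
#' @title Reading FAERS quarterly ASCII extracts
#'
#' @description
#' FAERS quarterly data are published as `$`-delimited ASCII tables with a
#' single header line: DEMO (demographics and administrative data), DRUG
#' (reported medications with role codes), REAC (MedDRA preferred terms),
#' THER (therapy start/end dates), plus INDI/OUTC/RPSR which are parsed but
#' not used downstream. Reports are keyed by `primaryid` (one row per report
#' version) and `caseid` (the underlying patient case). Legacy extracts
#' (before 2012Q4) use `ISR`/`CASE` keys; these are mapped automatically.
NULL

FAERS_TABLE_KINDS <- c("DEMO", "DRUG", "REAC", "THER", "INDI", "OUTC", "RPSR")

# Legacy (ISR-era) header aliases -> modern names.
FAERS_COLUMN_ALIASES <- c(
  isr = "primaryid",
  case = "caseid",
  gndr_cod = "sex",
  drug_seq_no = "drug_seq"
)

#' Read one FAERS-format ASCII table
#'
#' Parses a `$`-delimited FAERS table file. All columns are kept as character
#' strings; unknown columns are preserved untouched. Lines whose field count
#' does not match the header are counted as malformed and dropped with a
#' warning (embedded delimiters cannot be recovered from this dialect).
#'
#' @param path path to the text file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"INDI"`,
#'   `"OUTC"`, `"RPSR"`.
#' @return a `data.frame` of character columns with lower-case names
#'   (legacy `ISR`/`CASE` headers are renamed to `primaryid`/`caseid`).
#'   Attributes: `table_kind`, and `n_malformed` (count of dropped lines).
#' @export
read_faers_table <- function(path, table_kind) {
  table_kind <- match.arg(toupper(table_kind), FAERS_TABLE_KINDS)
  if (!file.exists(path)) {
    stop_faersdpa("FAERS ", table_kind, " file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_faersdpa("FAERS file is empty: ", path)
  }
  # a sentinel preserves trailing empty fields (strsplit drops them)
  split <- strsplit(paste0(lines, "$\x01"), "$", fixed = TRUE)
  split <- lapply(split, function(f) f[-length(f)])

  header <- tolower(trimws(split[[1]]))
  alias <- FAERS_COLUMN_ALIASES[header]
  header[!is.na(alias)] <- alias[!is.na(alias)]
  if (!"primaryid" %in% header) {
    stop_faersdpa(
      "FAERS ", table_kind, " header lacks a primaryid/ISR column: ", path
    )
  }

  body <- split[-1]
  nfield <- lengths(body)
  ok <- nfield == length(header)
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    warning(
      sprintf(
        "%s: %d malformed line(s) (field count != %d) dropped",
        basename(path), n_malformed, length(header)
      ),
      call. = FALSE
    )
  }
  body <- body[ok]
  out <- as.data.frame(
    do.call(rbind, c(body, list(character(length(header))))),
    stringsAsFactors = FALSE
  )[seq_along(body), , drop = FALSE]
  if (length(body) == 0L) out <- out[0, , drop = FALSE]
  names(out) <- header
  rownames(out) <- NULL
  attr(out, "table_kind") <- table_kind
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Read all FAERS tables found in a directory
#'
#' Scans `dir` for files named like `DEMO20Q1.txt`, `DRUG20Q1.txt`, ...
#' (case-insensitive), reads every quarter found, and row-binds each table
#' kind across quarters with a `src_quarter` column ("YYYYQn") recording the
#' source file's quarter.
#'
#' @param dir directory containing FAERS quarterly files.
#' @param tables table kinds to load (default DEMO/DRUG/REAC/THER).
#' @return a named list of data.frames (one per table kind present), plus
#'   attribute `quarters` listing the quarters found.
#' @export
read_faers_dir <- function(dir, tables = c("DEMO", "DRUG", "REAC", "THER")) {
  if (!dir.exists(dir)) stop_faersdpa("input directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.(txt|TXT)$", full.names = TRUE)
  rx <- "^(DEMO|DRUG|REAC|THER|INDI|OUTC|RPSR)([0-9]{2})Q([1-4])\\.txt$"
  m <- regexec(rx, basename(files), ignore.case = TRUE)
  hits <- regmatches(basename(files), m)
  keep <- lengths(hits) == 4L
  files <- files[keep]
  hits <- hits[keep]
  if (length(files) == 0L) {
    stop_faersdpa("no FAERS-format files (e.g. DEMO20Q1.txt) in ", dir)
  }
  kind <- toupper(vapply(hits, `[`, "", 2L))
  yy <- as.integer(vapply(hits, `[`, "", 3L))
  qq <- vapply(hits, `[`, "", 4L)
  quarter <- sprintf("%04dQ%s", ifelse(yy >= 50, 1900 + yy, 2000 + yy), qq)

  out <- list()
  for (k in intersect(tables, unique(kind))) {
    idx <- which(kind == k)
    idx <- idx[order(quarter[idx])]
    parts <- lapply(idx, function(i) {
      df <- read_faers_table(files[i], k)
      df$src_quarter <- quarter[i]
      df
    })
    cols <- unique(unlist(lapply(parts, names)))
    parts <- lapply(parts, function(df) {
      missing <- setdiff(cols, names(df))
      for (mc in missing) df[[mc]] <- NA_character_
      df[cols]
    })
    out[[k]] <- do.call(rbind, parts)
    rownames(out[[k]]) <- NULL
  }
  attr(out, "quarters") <- sort(unique(quarter))
  out
}

#' Parse FAERS partial-precision dates
#'
#' FAERS date fields (`EVENT_DT`, `START_DT`, `FDA_DT`) are digit strings of
#' 4 (year), 6 (year-month) or 8 (full day) digits, and are frequently blank.
#' Precision is derived solely from digit count; an 8-digit string that is
#' not a real calendar date (e.g. month 13) is flagged invalid rather than
#' raising an error.
#'
#' @param text character vector of raw date strings.
#' @return a data.frame with columns `text`, `precision` (one of `"day"`,
#'   `"month"`, `"year"`, `"missing"`, `"invalid"`) and `date` (a `Date`,
#'   non-`NA` only at day precision).
#' @export
#' @examples
#' parse_faers_date(c("20200104", "202001", "2020", "", "20201340"))
parse_faers_date <- function(text) {
  text <- trimws(as.character(text))
  text[is.na(text)] <- ""
  n <- nchar(text)
  digits <- grepl("^[0-9]*$", text)
  precision <- rep("invalid", length(text))
  precision[n == 0L] <- "missing"
  precision[digits & n == 4L] <- "year"
  precision[digits & n == 6L] <- "month"
  precision[digits & n == 8L] <- "day"
  # month-precision sanity: month must be 01..12
  mo <- suppressWarnings(as.integer(substr(text, 5, 6)))
  bad_month <- precision %in% c("month", "day") & (is.na(mo) | mo < 1 | mo > 12)
  precision[bad_month] <- "invalid"

  date <- rep(as.Date(NA), length(text))
  isday <- precision == "day"
  if (any(isday)) {
    d <- as.Date(text[isday], format = "%Y%m%d")
    bad <- is.na(d)
    date[isday] <- d
    if (any(bad)) precision[isday][bad] <- "invalid"
  }
  data.frame(text = text, precision = precision, date = date,
             stringsAsFactors = FALSE)
}

#' Normalize a reported drug name
#'
#' Trims, upper-cases and collapses internal whitespace; optionally applies a
#' user-supplied synonym map (exact match after case-folding) so brand names
#' and salt variants can be folded onto one preferred name.
#'
#' @param raw character vector of reported names.
#' @param synonyms optional named character vector: `c(REVLIMID =
#'   "LENALIDOMIDE", ...)`. Keys are matched after normalization.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_drug_name("  Lenalidomide ")
#' normalize_drug_name("REVLIMID", synonyms = c(REVLIMID = "LENALIDOMIDE"))
normalize_drug_name <- function(raw, synonyms = NULL) {
  x <- norm_string(raw)
  if (!is.null(synonyms)) {
    keys <- norm_string(names(synonyms))
    vals <- norm_string(unname(synonyms))
    hit <- match(x, keys)
    x[!is.na(hit)] <- vals[hit[!is.na(hit)]]
  }
  x
}

#' Deduplicate FAERS case versions
#'
#' FAERS cases are reported repeatedly: one `caseid` accrues several report
#' versions (`primaryid`s). Following the community convention, the retained
#' version is the one with the latest `fda_dt`; ties are broken by the
#' greatest `primaryid` (compared numerically when both sides parse as
#' integers, lexicographically otherwise). Records with a missing `caseid`
#' are kept as their own singleton cases keyed by `primaryid` and counted in
#' a warning. Output rows are sorted by `caseid`, so the result is
#' deterministic and the operation idempotent.
#'
#' @param demo a DEMO data.frame with at least `primaryid`, `caseid`,
#'   `fda_dt` columns.
#' @return the subset of `demo` rows retained (one per case), sorted by
#'   `caseid`, with attribute `n_removed`.
#' @export
dedup_cases <- function(demo) {
  stopifnot(is.data.frame(demo), all(c("primaryid", "caseid") %in% names(demo)))
  if (nrow(demo) == 0L) return(demo)
  caseid <- trimws(as.character(demo$caseid))
  missing_case <- is.na(caseid) | caseid == ""
  if (any(missing_case)) {
    warning(sum(missing_case),
            " record(s) lack a caseid; treated as singleton cases",
            call. = FALSE)
    caseid[missing_case] <- paste0("PID:", demo$primaryid[missing_case])
  }
  fda <- suppressWarnings(as.numeric(demo$fda_dt))
  fda[is.na(fda)] <- -Inf
  pid_chr <- as.character(demo$primaryid)
  pid_num <- suppressWarnings(as.numeric(pid_chr))

  groups <- split(seq_len(nrow(demo)), caseid) # sorted by caseid
  keep <- vapply(groups, function(ii) {
    if (length(ii) == 1L) return(ii)
    ii <- ii[fda[ii] == max(fda[ii])]
    if (length(ii) == 1L) return(ii)
    pn <- pid_num[ii]
    if (!anyNA(pn)) ii[which.max(pn)] else ii[which.max(xtfrm(pid_chr[ii]))]
  }, integer(1L))
  keep <- unname(keep)
  out <- demo[keep, , drop = FALSE]
  out$caseid <- caseid[keep]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(demo) - nrow(out)
  out
}

# AGE_COD unit -> factor converting to years.
AGE_UNIT_FACTORS <- c(
  DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365.25, HR = 1 / 8766
)

# Convert AGE + AGE_COD to years; unparseable or negative -> NA.
age_to_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  u <- unname(AGE_UNIT_FACTORS[norm_string(age_cod)])
  u[is.na(u) & (is.na(age_cod) | trimws(age_cod) == "")] <- 1
  out <- a * u
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

normalize_sex <- function(sex) {
  s <- norm_string(sex)
  out <- rep("unknown", length(s))
  out[s == "M"] <- "M"
  out[s == "F"] <- "F"
  out
}

#' Assemble the joined event dataset
#'
#' Takes the raw tables from [read_faers_dir()] and produces the analysis
#' dataset: deduplicated cases with demographics, per-case primary-suspect
#' (PS) drug mentions with therapy start dates, and per-case reaction
#' preferred terms. Drugs with secondary-suspect, concomitant or interacting
#' roles are excluded. Records whose `primaryid` does not match a retained
#' case version are dropped as orphans/superseded; all drop counts are
#' reported so that input rows reconcile exactly with retained rows.
#'
#' @param raw list with `DEMO`, `DRUG`, `REAC` (and optionally `THER`)
#'   data.frames, as returned by [read_faers_dir()].
#' @param dedup logical; deduplicate case versions (default `TRUE`). With
#'   `FALSE` every report version is kept as its own "case" (report-level
#'   sensitivity mode).
#' @param synonyms optional drug-name synonym map, see
#'   [normalize_drug_name()].
#' @return an object of class `faers_dataset`: a list with data.frames
#'   `cases` (caseid, primaryid, fda_dt, event_dt, age_years, sex, country,
#'   quarter), `drug_mentions` (caseid, drug_seq, drugname, start_dt),
#'   `events` (caseid, pt), and `drops`, a named list of drop counts per
#'   table.
#' @export
build_event_dataset <- function(raw, dedup = TRUE, synonyms = NULL) {
  stopifnot(is.list(raw), !is.null(raw$DEMO))
  demo <- raw$DEMO
  need <- c("primaryid", "caseid", "fda_dt")
  if (!all(need %in% names(demo))) {
    stop_faersdpa("DEMO lacks required columns: ",
                  paste(setdiff(need, names(demo)), collapse = ", "))
  }
  n_demo_in <- nrow(demo)
  if (dedup) {
    demo <- dedup_cases(demo)
    n_superseded <- attr(demo, "n_removed")
  } else {
    demo$caseid <- as.character(demo$primaryid)
    n_superseded <- 0L
  }

  fda <- parse_faers_date(demo$fda_dt)
  quarter <- quarter_tag(fda$text)
  if ("src_quarter" %in% names(demo)) {
    quarter[is.na(quarter)] <- demo$src_quarter[is.na(quarter)]
  }
  cases <- data.frame(
    caseid = as.character(demo$caseid),
    primaryid = as.character(demo$primaryid),
    fda_dt = fda$text,
    event_dt = if ("event_dt" %in% names(demo)) {
      as.character(demo$event_dt)
    } else NA_character_,
    age_years = if (all(c("age", "age_cod") %in% names(demo))) {
      age_to_years(demo$age, demo$age_cod)
    } else NA_real_,
    sex = if ("sex" %in% names(demo)) normalize_sex(demo$sex) else "unknown",
    country = if ("reporter_country" %in% names(demo)) {
      norm_string(demo$reporter_country)
    } else if ("occr_country" %in% names(demo)) {
      norm_string(demo$occr_country)
    } else NA_character_,
    quarter = quarter,
    stringsAsFactors = FALSE
  )
  pid_to_case <- stats::setNames(cases$caseid, cases$primaryid)

  drops <- list(DEMO = c(retained = nrow(cases), superseded = n_superseded))

  # DRUG: keep PS mentions of retained versions
  drug <- raw$DRUG
  mentions <- data.frame(caseid = character(), drug_seq = character(),
                         drugname = character(), start_dt = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(drug) && nrow(drug) > 0L) {
    role <- norm_string(drug$role_cod %||% rep("", nrow(drug)))
    is_ps <- role == "PS"
    known <- as.character(drug$primaryid) %in% names(pid_to_case)
    keep <- is_ps & known
    drops$DRUG <- c(retained = sum(keep),
                    non_primary_suspect = sum(!is_ps),
                    orphan_or_superseded = sum(is_ps & !known))
    d <- drug[keep, , drop = FALSE]
    mentions <- data.frame(
      caseid = unname(pid_to_case[as.character(d$primaryid)]),
      drug_seq = as.character(d$drug_seq %||% rep(NA_character_, nrow(d))),
      drugname = normalize_drug_name(d$drugname, synonyms),
      start_dt = NA_character_,
      stringsAsFactors = FALSE
    )
    # one mention per (case, drug): repeated listings of a drug do not
    # inflate counts; the earliest drug_seq representative is kept
    ord <- order(mentions$caseid, mentions$drugname,
                 suppressWarnings(as.numeric(mentions$drug_seq)))
    mentions <- mentions[ord, , drop = FALSE]
    dupd <- duplicated(mentions[c("caseid", "drugname")])
    seq_map <- mentions # all rows, for THER joining before collapse
    mentions <- mentions[!dupd, , drop = FALSE]
  } else {
    drops$DRUG <- c(retained = 0L, non_primary_suspect = 0L,
                    orphan_or_superseded = 0L)
    seq_map <- mentions
  }

  # THER: attach earliest day-precision start date to matching PS mention
  ther <- raw$THER
  if (!is.null(ther) && nrow(ther) > 0L && nrow(seq_map) > 0L) {
    known <- as.character(ther$primaryid) %in% names(pid_to_case)
    drops$THER <- c(retained = sum(known),
                    orphan_or_superseded = sum(!known))
    t2 <- ther[known, , drop = FALSE]
    tc <- unname(pid_to_case[as.character(t2$primaryid)])
    tkey <- paste(tc, as.character(t2$dsg_drug_seq %||% NA), sep = "\r")
    sd <- parse_faers_date(t2$start_dt %||% rep("", nrow(t2)))
    dayok <- sd$precision == "day"
    # earliest day-precision start per (case, drug_seq)
    starts <- tapply(sd$text[dayok], tkey[dayok], min)
    skey <- paste(seq_map$caseid, seq_map$drug_seq, sep = "\r")
    seq_map$start_dt <- unname(starts[skey])
    # collapse to (case, drug): earliest available start date
    agg_key <- paste(seq_map$caseid, seq_map$drugname, sep = "\r")
    first_start <- tapply(seq_map$start_dt, agg_key, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) min(v) else NA_character_
    })
    mkey <- paste(mentions$caseid, mentions$drugname, sep = "\r")
    mentions$start_dt <- unname(first_start[mkey])
  } else {
    drops$THER <- c(retained = 0L, orphan_or_superseded = 0L)
  }

  # REAC: PTs of retained versions, unique per (case, pt)
  reac <- raw$REAC
  events <- data.frame(caseid = character(), pt = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(reac) && nrow(reac) > 0L) {
    known <- as.character(reac$primaryid) %in% names(pid_to_case)
    drops$REAC <- c(retained = sum(known),
                    orphan_or_superseded = sum(!known))
    r <- reac[known, , drop = FALSE]
    events <- data.frame(
      caseid = unname(pid_to_case[as.character(r$primaryid)]),
      pt = norm_string(r$pt),
      stringsAsFactors = FALSE
    )
    events <- unique(events)
    events <- events[order(events$caseid, events$pt), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    drops$REAC <- c(retained = 0L, orphan_or_superseded = 0L)
  }

  rownames(mentions) <- NULL
  structure(
    list(cases = cases, drug_mentions = mentions, events = events,
         drops = drops, n_demo_in = n_demo_in),
    class = "faers_dataset"
  )
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat("FAERS event dataset\n")
  cat("  cases:        ", nrow(x$cases), "\n")
  cat("  PS mentions:  ", nrow(x$drug_mentions), "\n")
  cat("  reaction PTs: ", nrow(x$events), "\n")
  inv <- x$drops
  if (length(inv)) {
    for (k in names(inv)) {
      cat("  ", k, ": ", paste(names(inv[[k]]), inv[[k]], sep = "=",
                               collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a data.frame in FAERS ASCII dialect
#'
#' Emits the `$`-delimited, header-first dialect the readers consume.
#' `NA` values are written as empty fields.
#'
#' @param df data.frame of character-coercible columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(df, path) {
  mat <- vapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  }, character(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)
  lines <- c(
    paste(names(df), collapse = "$"),
    if (nrow(df)) apply(mat, 1L, paste, collapse = "$")
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
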