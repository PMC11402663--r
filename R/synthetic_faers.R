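#' @name synthetic-faers
#' @title Synthetic FAERS-format data with known ground truth
#'
#' @description
#' The generator emits FAERS-dialect quarterly files (DEMO/DRUG/REAC/THER)
#' with controlled statistical structure, so that every pipeline stage —
#' parsing, deduplication, 2x2 counting, disproportionality, and
#' time-to-onset — can be validated against a ground-truth ledger without
#' downloading the real database.
#'
#' Each synthetic report gets one primary-suspect drug drawn from configured
#' marginal shares; the target event occurs with probability
#' `min(1, background_event_rate * rrr_target(drug))`, so a drug's true
#' relative reporting rate is (approximately, for small rates) its
#' `rrr_target`. Event onsets are Weibull-distributed per drug and converted
#' into `START_DT`/`EVENT_DT` pairs; duplicate case versions, date
#' corruption, concomitant-role drug rows, and demographic distributions
#' emulate the messiness the real extracts exhibit.
NULL

default_synthetic_drugs <- function() {
  data.frame(
    name = c("SEVELAMER CARBONATE", "PATIROMER", "ORLISTAT", "LENALIDOMIDE",
             "OXYCODONE", "PREGABALIN", "METFORMIN", "LISINOPRIL",
             "ATORVASTATIN", "OMEPRAZOLE"),
    share = c(0.02, 0.03, 0.05, 0.10, 0.10, 0.10, 0.15, 0.15, 0.15, 0.15),
    rrr_target = c(80, 23, 11, 3.8, 1.1, 0.9, 1, 1, 1, 1),
    weibull_alpha = c(31.6, 74.7, 9.2, 110.3, 174.7, 60, 60, 60, 60, 60),
    weibull_beta = c(0.59, 0.55, 0.55, 0.60, 0.46, 0.58, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

DEFAULT_DECOY_PTS <- c("NAUSEA", "HEADACHE", "DIARRHOEA", "FATIGUE", "RASH",
                       "DIZZINESS", "VOMITING", "PRURITUS")

#' Configuration for the synthetic FAERS generator
#'
#' Defaults emulate the structure of a constipation signal study: a 0.34\%
#' background target-event rate (the share of constipation among all FAERS
#' ADEs), drugs spanning strong (RRR ~80), moderate, null and
#' slightly-protective association, early-failure Weibull onsets (shape
#' 0.46-0.6, scales from days to months), ~5\% duplicated case versions and
#' a few percent of corrupted dates.
#'
#' @param seed integer RNG seed; generation is byte-deterministic given it.
#' @param n_reports number of synthetic cases (before duplication).
#' @param quarters character vector of "YYYYQn" tags to spread reports over.
#' @param drugs data.frame with columns `name`, `share` (marginal report
#'   shares, summing to 1), `rrr_target` (event-association multiplier),
#'   `weibull_alpha` (onset scale, days), `weibull_beta` (onset shape).
#' @param background_event_rate probability of the target PT absent any drug
#'   effect.
#' @param duplicate_case_rate probability a case gets a second report
#'   version (later `fda_dt`, fresh `primaryid`, same `caseid`).
#' @param date_corruption named probabilities for `missing`, `partial`,
#'   `event_before_start` date corruption of event reports.
#' @param demographics named list of categorical distributions: `sex`
#'   (M/F/UNK), `age_band` (the age-band levels above), `country`.
#' @param concomitant_rate probability a report carries an extra
#'   concomitant-role drug row (must be ignored by the pipeline).
#' @param multi_drug_rate probability a report carries a second
#'   primary-suspect drug (exercises per-drug case counting).
#' @param decoy_pts preferred-term pool for non-target reactions.
#' @param target_pt the target event term.
#' @return a `synthetic_config` list, validated.
#' @export
synthetic_config <- function(seed = 1,
                             n_reports = 50000,
                             quarters = c(sprintf("2020Q%d", 1:4),
                                          sprintf("2021Q%d", 1:4)),
                             drugs = default_synthetic_drugs(),
                             background_event_rate = 0.0034,
                             duplicate_case_rate = 0.05,
                             date_corruption = c(missing = 0.02,
                                                 partial = 0.02,
                                                 event_before_start = 0.01),
                             demographics = list(
                               sex = c(M = 0.333, F = 0.566, UNK = 0.101),
                               age_band = c("<18" = 0.018, "18-39" = 0.061,
                                            "40-64" = 0.248, ">=65" = 0.281,
                                            unknown = 0.392),
                               country = c(US = 0.712, CA = 0.057, GB = 0.039,
                                           JP = 0.024, DE = 0.022,
                                           OTHER = 0.146)
                             ),
                             concomitant_rate = 0.3,
                             multi_drug_rate = 0,
                             decoy_pts = DEFAULT_DECOY_PTS,
                             target_pt = "CONSTIPATION") {
  stopifnot(
    n_reports >= 1,
    all(grepl("^[0-9]{4}Q[1-4]$", quarters)),
    is.data.frame(drugs),
    all(c("name", "share", "rrr_target", "weibull_alpha",
          "weibull_beta") %in% names(drugs)),
    all(drugs$share >= 0 & drugs$share <= 1),
    abs(sum(drugs$share) - 1) < 1e-8,
    all(drugs$rrr_target > 0),
    all(drugs$weibull_alpha > 0), all(drugs$weibull_beta > 0),
    background_event_rate >= 0, background_event_rate <= 1,
    duplicate_case_rate >= 0, duplicate_case_rate <= 1,
    all(date_corruption >= 0), sum(date_corruption) <= 1,
    multi_drug_rate >= 0, multi_drug_rate <= 1
  )
  stopifnot(all(c("missing", "partial", "event_before_start") %in%
                  names(date_corruption)))
  drugs$name <- normalize_drug_name(drugs$name)
  exp_a <- n_reports * drugs$share *
    pmin(1, background_event_rate * drugs$rrr_target)
  low <- exp_a < 1
  if (any(low)) {
    warning("expected target-event count < 1 for drug(s): ",
            paste(drugs$name[low], collapse = ", "), call. = FALSE)
  }
  structure(
    list(seed = seed, n_reports = n_reports, quarters = quarters,
         drugs = drugs, background_event_rate = background_event_rate,
         duplicate_case_rate = duplicate_case_rate,
         date_corruption = date_corruption, demographics = demographics,
         concomitant_rate = concomitant_rate,
         multi_drug_rate = multi_drug_rate,
         decoy_pts = norm_string(decoy_pts),
         target_pt = norm_string(target_pt)),
    class = "synthetic_config"
  )
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate synthetic FAERS quarterly files
#'
#' Writes `DEMOyyQq.txt`, `DRUGyyQq.txt`, `REACyyQq.txt`, `THERyyQq.txt`
#' for every configured quarter into `dir`, plus `ledger.json` recording
#' the ground truth: the realized 2x2 cells per drug (over deduplicated
#' cases, before date corruption), the true Weibull onset parameters, and
#' the corruption/duplication counts. Identical configurations (including
#' the seed) produce byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return the ground-truth ledger (class `faers_ledger`), invisibly; also
#'   written as JSON.
#' @export
generate_faers <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- config$drugs
  k <- nrow(drugs)

  caseid_num <- 10000000 + seq_len(n)
  quarter <- sample(config$quarters, n, replace = TRUE)
  d1 <- sample.int(k, n, replace = TRUE, prob = drugs$share)
  d2 <- rep(NA_integer_, n)
  if (config$multi_drug_rate > 0) {
    has2 <- stats::runif(n) < config$multi_drug_rate
    d2[has2] <- sample.int(k, sum(has2), replace = TRUE, prob = drugs$share)
    d2[!is.na(d2) & d2 == d1] <- NA_integer_
  }
  p_event <- pmin(1, config$background_event_rate * drugs$rrr_target[d1])
  # with a second PS drug the event fires if either drug triggers it
  if (any(!is.na(d2))) {
    p2 <- pmin(1, config$background_event_rate * drugs$rrr_target[d2])
    p2[is.na(p2)] <- 0
    p_event <- 1 - (1 - p_event) * (1 - p2)
  }
  event <- stats::runif(n) < p_event

  # dates: report received (fda) within the quarter; event precedes it by a
  # short reporting delay; therapy start precedes the event by the onset
  qstart <- quarter_start(quarter)
  qdays <- quarter_days(quarter)
  fda <- qstart + floor(stats::runif(n) * qdays)
  delay <- floor(stats::rexp(n, rate = 1 / 20))
  event_date <- fda - delay
  onset <- stats::rweibull(n, shape = drugs$weibull_beta[d1],
                           scale = drugs$weibull_alpha[d1])
  tto_days <- round(onset)
  start_date <- event_date - tto_days

  # demographics
  sex <- sample_cat(n, config$demographics$sex)
  band <- sample_cat(n, config$demographics$age_band)
  age <- rep(NA_real_, n)
  age[band == "<18"] <- floor(stats::runif(sum(band == "<18"), 0, 18))
  age[band == "18-39"] <- floor(stats::runif(sum(band == "18-39"), 18, 40))
  age[band == "40-64"] <- floor(stats::runif(sum(band == "40-64"), 40, 65))
  age[band == ">=65"] <- floor(stats::runif(sum(band == ">=65"), 65, 95))
  country <- sample_cat(n, config$demographics$country)

  # reactions: target PT for event reports (some also carry a decoy term),
  # one decoy PT otherwise
  decoy <- sample(config$decoy_pts, n, replace = TRUE)
  extra_decoy <- event & stats::runif(n) < 0.3

  # date corruption of event reports' TTO-relevant dates
  corr <- rep("none", n)
  u <- stats::runif(n)
  dc <- config$date_corruption
  corr[event & u < dc[["missing"]]] <- "missing"
  corr[event & u >= dc[["missing"]] &
         u < dc[["missing"]] + dc[["partial"]]] <- "partial"
  corr[event & u >= dc[["missing"]] + dc[["partial"]] &
         u < sum(dc)] <- "event_before_start"

  start_txt <- date8(start_date)
  event_txt <- date8(event_date)
  which_date <- stats::runif(n) < 0.5 # corrupt start vs event date
  i <- corr == "missing"
  start_txt[i & which_date] <- ""
  event_txt[i & !which_date] <- ""
  i <- corr == "partial"
  start_txt[i & which_date] <- substr(start_txt[i & which_date], 1, 6)
  event_txt[i & !which_date] <- substr(event_txt[i & !which_date], 1, 6)
  i <- corr == "event_before_start"
  event_txt[i] <- date8(start_date[i] - (1 + floor(stats::runif(sum(i)) * 30)))

  # duplicate case versions
  dup <- stats::runif(n) < config$duplicate_case_rate
  fda_dup <- fda + 1 + floor(stats::runif(n) * 90)

  demo_row <- function(version, idx, fda_txt) {
    data.frame(
      primaryid = as.character(caseid_num[idx] * 10 + version),
      caseid = as.character(caseid_num[idx]),
      event_dt = event_txt[idx],
      fda_dt = fda_txt,
      age = ifelse(is.na(age[idx]), "", as.character(age[idx])),
      age_cod = ifelse(is.na(age[idx]), "", "YR"),
      sex = sex[idx],
      reporter_country = country[idx],
      quarter = quarter[idx],
      stringsAsFactors = FALSE
    )
  }
  demo <- rbind(demo_row(1L, seq_len(n), date8(fda)),
                demo_row(2L, which(dup), date8(fda_dup[dup])))

  drug_rows <- function(version, idx, seqno, names_, role) {
    data.frame(
      primaryid = as.character(caseid_num[idx] * 10 + version),
      caseid = as.character(caseid_num[idx]),
      drug_seq = as.character(seqno),
      role_cod = role,
      drugname = names_,
      quarter = quarter[idx],
      stringsAsFactors = FALSE
    )
  }
  conc <- stats::runif(n) < config$concomitant_rate
  conc_name <- sample(c("ASPIRIN", "PARACETAMOL", "IBUPROFEN"), n,
                      replace = TRUE)
  build_drug <- function(version, idx) {
    out <- drug_rows(version, idx, 1L, drugs$name[d1[idx]], "PS")
    i2 <- idx[!is.na(d2[idx])]
    if (length(i2)) {
      out <- rbind(out, drug_rows(version, i2, 2L, drugs$name[d2[i2]], "PS"))
    }
    ic <- idx[conc[idx]]
    if (length(ic)) {
      out <- rbind(out, drug_rows(version, ic, 9L, conc_name[ic], "C"))
    }
    out
  }
  drug_tab <- rbind(build_drug(1L, seq_len(n)), build_drug(2L, which(dup)))

  reac_rows <- function(version, idx, pts) {
    data.frame(
      primaryid = as.character(caseid_num[idx] * 10 + version),
      caseid = as.character(caseid_num[idx]),
      pt = pts,
      quarter = quarter[idx],
      stringsAsFactors = FALSE
    )
  }
  build_reac <- function(version, idx) {
    rbind(
      reac_rows(version, idx[event[idx]],
                rep(config$target_pt, sum(event[idx]))),
      reac_rows(version, idx[!event[idx]], decoy[idx[!event[idx]]]),
      reac_rows(version, idx[extra_decoy[idx]], decoy[idx[extra_decoy[idx]]])
    )
  }
  reac_tab <- rbind(build_reac(1L, seq_len(n)), build_reac(2L, which(dup)))

  ther_rows <- function(version, idx) {
    data.frame(
      primaryid = as.character(caseid_num[idx] * 10 + version),
      caseid = as.character(caseid_num[idx]),
      dsg_drug_seq = "1",
      start_dt = start_txt[idx],
      end_dt = "",
      quarter = quarter[idx],
      stringsAsFactors = FALSE
    )
  }
  ther_tab <- rbind(ther_rows(1L, seq_len(n)), ther_rows(2L, which(dup)))

  # write per-quarter files
  for (q in config$quarters) {
    yy <- substr(q, 3, 4)
    qq <- substr(q, 5, 6)
    emit <- function(tab, kind) {
      sub <- tab[tab$quarter == q, setdiff(names(tab), "quarter"),
                 drop = FALSE]
      sub <- sub[order(as.numeric(sub$primaryid)), , drop = FALSE]
      write_faers_table(sub, file.path(dir, sprintf("%s%s%s.txt", kind, yy,
                                                    qq)))
    }
    emit(demo, "DEMO")
    emit(drug_tab, "DRUG")
    emit(reac_tab, "REAC")
    emit(ther_tab, "THER")
  }

  # ground truth over deduplicated cases (duplication does not change truth)
  # implied_rrr is the generative expectation of the RRR *statistic*: the
  # drug's event rate over the share-weighted database event rate (the
  # rrr_target multiplies the background rate, not the database average)
  p_e <- pmin(1, config$background_event_rate * drugs$rrr_target)
  implied <- p_e / sum(drugs$share * p_e)
  in_drug <- function(j) d1 == j | (!is.na(d2) & d2 == j)
  truth <- do.call(rbind, lapply(seq_len(k), function(j) {
    m <- in_drug(j)
    data.frame(
      drug = drugs$name[j],
      a = sum(m & event), b = sum(m & !event),
      c = sum(!m & event), d = sum(!m & !event),
      rrr_target = drugs$rrr_target[j],
      implied_rrr = implied[j],
      weibull_alpha = drugs$weibull_alpha[j],
      weibull_beta = drugs$weibull_beta[j],
      stringsAsFactors = FALSE
    )
  }))
  ledger <- structure(
    list(
      n_reports = n,
      n_cases = n,
      n_duplicates = sum(dup),
      n_event_cases = sum(event),
      target_pt = config$target_pt,
      truth = truth,
      corruption_counts = c(table(factor(corr, levels = c(
        "none", "missing", "partial", "event_before_start")))),
      tto_true = data.frame(drug = drugs$name[d1],
                            days = tto_days, event = event,
                            corrupted = corr != "none",
                            stringsAsFactors = FALSE),
      seed = config$seed
    ),
    class = "faers_ledger"
  )
  ledger_out <- ledger
  ledger_out$tto_true <- NULL # keep the JSON compact
  jsonlite::write_json(unclass(ledger_out), file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ledger)
}

#' @export
print.faers_ledger <- function(x, ...) {
  cat("Synthetic FAERS ground-truth ledger (seed ", x$seed, ")\n", sep = "")
  cat("  cases:", x$n_cases, " duplicates:", x$n_duplicates,
      " target-event cases:", x$n_event_cases, "\n")
  print(x$truth[c("drug", "a", "b", "c", "d", "rrr_target")])
  invisible(x)
}

#' Check pipeline recovery against the ground-truth ledger
#'
#' Rebuilds each listed drug's 2x2 table from the pipeline's event dataset
#' and compares it with the ledger truth (exact equality is expected when no
#' date corruption was configured, since corruption only affects TTO dates).
#' Optionally compares Weibull fits against the true onset parameters.
#'
#' @param dataset a [build_event_dataset()] result from the generated files.
#' @param ledger the [generate_faers()] ledger.
#' @param check_weibull also fit TTO Weibull per drug and check whether the
#'   true shape lies inside the fitted 95\% CI.
#' @return list with data.frames `tables` (per-drug estimated vs true cells
#'   and an `exact` flag) and, if requested, `weibull` (`beta_true`,
#'   `beta_hat`, CI, `covered`).
#' @export
ledger_check <- function(dataset, ledger, check_weibull = FALSE) {
  stopifnot(inherits(dataset, "faers_dataset"),
            inherits(ledger, "faers_ledger"))
  pt <- ledger$target_pt
  tabs <- lapply(ledger$truth$drug, function(dr) build_table(dataset, dr, pt))
  est <- do.call(rbind, lapply(tabs, function(t) {
    data.frame(a_est = t$a, b_est = t$b, c_est = t$c, d_est = t$d)
  }))
  tables <- cbind(ledger$truth[c("drug", "a", "b", "c", "d")], est)
  tables$exact <- tables$a == tables$a_est & tables$b == tables$b_est &
    tables$c == tables$c_est & tables$d == tables$d_est
  out <- list(tables = tables)
  if (check_weibull) {
    out$weibull <- do.call(rbind, lapply(seq_len(nrow(ledger$truth)),
                                         function(i) {
      dr <- ledger$truth$drug[i]
      fit <- tryCatch(weibull_fit(tto_sample(dataset, dr, pt)),
                      error = function(e) NULL)
      data.frame(
        drug = dr,
        beta_true = ledger$truth$weibull_beta[i],
        beta_hat = if (is.null(fit)) NA_real_ else fit$beta,
        beta_lo = if (is.null(fit)) NA_real_ else fit$beta_lo,
        beta_hi = if (is.null(fit)) NA_real_ else fit$beta_hi,
        covered = if (is.null(fit)) NA else
          ledger$truth$weibull_beta[i] >= fit$beta_lo &
          ledger$truth$weibull_beta[i] <= fit$beta_hi,
        stringsAsFactors = FALSE
      )
    }))
  }
  out
}
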