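#' @name disproportionality
#' @title Disproportionality statistics on 2x2 report tables
#'
#' @description
#' All four statistics compare the observed drug-and-event cell `a` of a
#' [contingency_table()] to its expectation under independent reporting:
#'
#' * ROR, the reporting odds ratio `(a d)/(b c)` with a Woolf (log-normal)
#'   95\% confidence interval;
#' * PRR, the proportional reporting ratio `[a/(a+b)]/[c/(c+d)]` with the
#'   (uncorrected) Pearson chi-squared statistic of the table;
#' * RRR, the relative reporting ratio `a N / ((a+b)(a+c))` — the
#'   observed/expected ratio that MGPS shrinks and whose log2 is the
#'   information component;
#' * EBGM/EB05 (see [ebgm_estimate()]) and the BCPNN IC (see [bcpnn_ic()]).
#'
#' Tables with zero cells make some statistics undefined; those return `NA`
#' together with a `reason` rather than silently applying a continuity
#' correction (an explicit Yates option exists for the chi-squared).
NULL

undefined_stat <- function(fields, reason) {
  out <- as.list(stats::setNames(rep(NA_real_, length(fields)), fields))
  out$reason <- reason
  out
}

#' Reporting odds ratio with Woolf 95\% CI
#'
#' @param t a `faers_ctab`.
#' @param conf_z normal quantile for the interval (1.96 for 95\%).
#' @return list `ror, lo, hi, reason` (`reason` is `NA` unless undefined).
#' @export
ror_estimate <- function(t, conf_z = 1.96) {
  stopifnot(inherits(t, "faers_ctab"))
  if (min(t$a, t$b, t$c, t$d) <= 0) {
    return(undefined_stat(c("ror", "lo", "hi"), "zero cell"))
  }
  log_ror <- log(t$a) + log(t$d) - log(t$b) - log(t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  list(ror = exp(log_ror), lo = exp(log_ror - conf_z * se),
       hi = exp(log_ror + conf_z * se), reason = NA_character_)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' The chi-squared is the uncorrected Pearson statistic of the 2x2 table,
#' computed from observed and expected cell counts. `yates = TRUE` applies
#' the continuity correction.
#'
#' @param t a `faers_ctab`.
#' @param yates apply Yates continuity correction to the chi-squared.
#' @return list `prr, chi2, reason`.
#' @export
prr_estimate <- function(t, yates = FALSE) {
  stopifnot(inherits(t, "faers_ctab"))
  if (t$a + t$b <= 0 || t$c + t$d <= 0 || t$c <= 0) {
    return(undefined_stat(c("prr", "chi2"), "zero margin"))
  }
  prr <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  o <- c(t$a, t$b, t$c, t$d)
  e <- c((t$a + t$b) * (t$a + t$c), (t$a + t$b) * (t$b + t$d),
         (t$c + t$d) * (t$a + t$c), (t$c + t$d) * (t$b + t$d)) / t$N
  if (any(e == 0)) {
    return(undefined_stat(c("prr", "chi2"), "zero margin"))
  }
  dev <- abs(o - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  list(prr = prr, chi2 = sum(dev^2 / e), reason = NA_character_)
}

#' Relative reporting ratio (observed/expected)
#'
#' @param t a `faers_ctab`.
#' @return list `rrr, reason`.
#' @export
rrr_estimate <- function(t) {
  stopifnot(inherits(t, "faers_ctab"))
  if (t$a + t$b <= 0 || t$a + t$c <= 0 || t$a <= 0) {
    return(undefined_stat("rrr", "zero margin or zero a"))
  }
  log_rrr <- log(t$a) + log(t$N) - log(t$a + t$b) - log(t$a + t$c)
  list(rrr = exp(log_rrr), reason = NA_character_)
}

#' BCPNN information component
#'
#' Two variants are provided. `"noren"` (the default for new analyses) is the
#' credible-interval form in common modern use:
#' `IC = log2((a + 0.5) / (E + 0.5))` with `E = (a+b)(a+c)/N`, and
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2.4 (a+0.5)^{-1}`.
#' `"table_compat"` reproduces published tables in which
#' `IC = log2(RRR)` and `IC025 = IC - 1.67` (a constant-width lower bound).
#'
#' @param t a `faers_ctab`.
#' @param mode `"noren"` or `"table_compat"`.
#' @return list `ic, ic025, reason`.
#' @export
bcpnn_ic <- function(t, mode = c("noren", "table_compat")) {
  stopifnot(inherits(t, "faers_ctab"))
  mode <- match.arg(mode)
  if (t$a + t$b <= 0 || t$a + t$c <= 0) {
    return(undefined_stat(c("ic", "ic025"), "zero margin"))
  }
  if (mode == "noren") {
    e <- (t$a + t$b) * (t$a + t$c) / t$N
    ic <- log2((t$a + 0.5) / (e + 0.5))
    ic025 <- ic - 3.3 * (t$a + 0.5)^(-0.5) - 2.4 * (t$a + 0.5)^(-1)
  } else {
    rrr <- rrr_estimate(t)
    if (is.na(rrr$rrr)) return(undefined_stat(c("ic", "ic025"), rrr$reason))
    ic <- log2(rrr$rrr)
    ic025 <- ic - 1.67
  }
  list(ic = ic, ic025 = ic025, reason = NA_character_)
}

#' Signal criteria for the four algorithms
#'
#' The community-standard thresholds: ROR signals when the lower 95\% CI
#' bound exceeds 1 with at least `min_a` cases; PRR when `PRR >= 2` and
#' `chi2 >= 4` with at least `min_a` cases; MGPS when `EB05 > 2`; BCPNN when
#' `IC025 > 0`. An undefined statistic never signals.
#'
#' @param min_a minimum drug-and-event count for ROR/PRR (default 3).
#' @param ror_lo_gt,prr_ge,chi2_ge,eb05_gt,ic025_gt thresholds.
#' @return a `signal_criteria` list.
#' @export
signal_criteria <- function(min_a = 3, ror_lo_gt = 1, prr_ge = 2, chi2_ge = 4,
                            eb05_gt = 2, ic025_gt = 0) {
  stopifnot(min_a >= 1, ror_lo_gt > 0, prr_ge > 0, chi2_ge > 0, eb05_gt > 0)
  structure(list(min_a = min_a, ror_lo_gt = ror_lo_gt, prr_ge = prr_ge,
                 chi2_ge = chi2_ge, eb05_gt = eb05_gt, ic025_gt = ic025_gt),
            class = "signal_criteria")
}

flag_true <- function(x, thr, strict = TRUE) {
  !is.na(x) & if (strict) x > thr else x >= thr
}

#' Apply the signal criteria to one row of statistics
#'
#' @param row a list or one-row data.frame with fields `a`, `ror_lo`, `prr`,
#'   `chi2`, `eb05`, `ic025` (missing/`NA` entries simply never signal).
#' @param criteria a [signal_criteria()] object.
#' @return logical vector `ror_signal, prr_signal, mgps_signal,
#'   bcpnn_signal, any_signal`.
#' @export
classify_signals <- function(row, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  g <- function(f) {
    v <- row[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  a_ok <- !is.na(g("a")) && g("a") >= criteria$min_a
  ror_signal <- a_ok && flag_true(g("ror_lo"), criteria$ror_lo_gt)
  prr_signal <- a_ok &&
    flag_true(g("prr"), criteria$prr_ge, strict = FALSE) &&
    flag_true(g("chi2"), criteria$chi2_ge, strict = FALSE)
  mgps_signal <- isTRUE(flag_true(g("eb05"), criteria$eb05_gt))
  bcpnn_signal <- isTRUE(flag_true(g("ic025"), criteria$ic025_gt))
  c(ror_signal = isTRUE(ror_signal), prr_signal = isTRUE(prr_signal),
    mgps_signal = mgps_signal, bcpnn_signal = bcpnn_signal,
    any_signal = isTRUE(ror_signal) || isTRUE(prr_signal) ||
      mgps_signal || bcpnn_signal)
}

#' All four statistics and signal flags for one table
#'
#' @param t a `faers_ctab`.
#' @param criteria a [signal_criteria()] object.
#' @param mgps_mode `"simplified"` or `"full"`, see [ebgm_estimate()].
#' @param bcpnn_mode `"table_compat"` or `"noren"`, see [bcpnn_ic()].
#' @param prior fitted [mgps_fit_prior()] result (required for
#'   `mgps_mode = "full"`).
#' @param yates apply Yates correction to the chi-squared.
#' @return one-row data.frame with the SignalRow fields: `drug, a, ror,
#'   ror_lo, ror_hi, prr, chi2, rrr, ebgm, eb05, ic, ic025` and the five
#'   flags.
#' @export
signal_stats <- function(t, criteria = signal_criteria(),
                         mgps_mode = c("simplified", "full"),
                         bcpnn_mode = c("table_compat", "noren"),
                         prior = NULL, yates = FALSE) {
  stopifnot(inherits(t, "faers_ctab"))
  mgps_mode <- match.arg(mgps_mode)
  bcpnn_mode <- match.arg(bcpnn_mode)
  ror <- ror_estimate(t)
  prr <- prr_estimate(t, yates = yates)
  rrr <- rrr_estimate(t)
  eb <- ebgm_estimate(t, prior = prior, mode = mgps_mode)
  ic <- bcpnn_ic(t, mode = bcpnn_mode)
  row <- data.frame(
    drug = t$drug, a = t$a,
    ror = ror$ror, ror_lo = ror$lo, ror_hi = ror$hi,
    prr = prr$prr, chi2 = prr$chi2, rrr = rrr$rrr,
    ebgm = eb$ebgm, eb05 = eb$eb05, ic = ic$ic, ic025 = ic$ic025,
    stringsAsFactors = FALSE
  )
  flags <- classify_signals(row, criteria)
  cbind(row, as.data.frame(as.list(flags)))
}

#' Signal table over many drugs
#'
#' Builds the 2x2 table for each drug and stacks [signal_stats()] rows.
#' With `mgps_mode = "full"` a shared MGPS prior is fitted across the
#' supplied drugs' cells first (see [mgps_fit_prior()]).
#'
#' @param dataset a [build_event_dataset()] result.
#' @param drugs character vector of normalized drug names.
#' @param pt target preferred term.
#' @inheritParams signal_stats
#' @return data.frame, one row per drug.
#' @export
signal_table <- function(dataset, drugs, pt = "CONSTIPATION",
                         criteria = signal_criteria(),
                         mgps_mode = c("simplified", "full"),
                         bcpnn_mode = c("table_compat", "noren"),
                         yates = FALSE) {
  mgps_mode <- match.arg(mgps_mode)
  bcpnn_mode <- match.arg(bcpnn_mode)
  tabs <- lapply(drugs, function(dr) build_table(dataset, dr, pt))
  prior <- NULL
  if (mgps_mode == "full") {
    a <- vapply(tabs, function(t) t$a, 0)
    e <- vapply(tabs, function(t) (t$a + t$b) * (t$a + t$c) / t$N, 0)
    keep <- e > 0
    prior <- mgps_fit_prior(a[keep], e[keep])
  }
  rows <- lapply(tabs, signal_stats, criteria = criteria,
                 mgps_mode = mgps_mode, bcpnn_mode = bcpnn_mode,
                 prior = prior, yates = yates)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
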