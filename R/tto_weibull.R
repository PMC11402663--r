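#' @name tto-weibull
#' @title Time-to-onset analysis with the Weibull shape-parameter test
#'
#' @description
#' Time-to-onset (TTO) is the number of days between the start of drug
#' therapy (`START_DT`) and the onset of the adverse event (`EVENT_DT`).
#' Pairs where the event precedes the start, either date is missing, or a
#' date has only month/year precision are excluded, each under a named
#' reason so accounting reconciles. Same-day onsets are retained as 0.5 day
#' for the likelihood (a zero breaks the Weibull log-likelihood) and as 0 in
#' descriptive summaries.
#'
#' The shape-parameter (failure type) test fits a two-parameter Weibull by
#' maximum likelihood: shape `beta < 1` with its whole CI below 1 indicates
#' a hazard decreasing with time on drug ("early failure"); a CI above 1
#' indicates wear-out; a CI covering 1 is consistent with a constant hazard
#' ("random failure").
NULL

TTO_EXCLUSION_REASONS <- c("event_before_start", "missing_date",
                           "partial_precision", "invalid_date")

#' Compute time-to-onset for date pairs
#'
#' Vectorized over report rows. Returns the TTO in days where computable and
#' an exclusion reason otherwise; exclusions are values, never errors.
#'
#' @param event_dt,start_dt character vectors of raw FAERS date strings.
#' @return data.frame `days` (numeric; 0.5 for same-day onset, `NA` when
#'   excluded) and `reason` (`NA` when retained, else one of
#'   `event_before_start`, `missing_date`, `partial_precision`,
#'   `invalid_date`).
#' @export
#' @examples
#' compute_tto("20200104", "20200101") # 3 days
#' compute_tto("20191231", "20200101") # excluded: event_before_start
#' compute_tto("202001", "20200101")   # excluded: partial_precision
compute_tto <- function(event_dt, start_dt) {
  n <- max(length(event_dt), length(start_dt))
  ev <- parse_faers_date(rep_len(as.character(event_dt), n))
  st <- parse_faers_date(rep_len(as.character(start_dt), n))
  reason <- rep(NA_character_, n)
  pick <- function(cur, cond, val) ifelse(is.na(cur) & cond, val, cur)
  reason <- pick(reason, ev$precision == "missing" | st$precision == "missing",
                 "missing_date")
  reason <- pick(reason, ev$precision == "invalid" | st$precision == "invalid",
                 "invalid_date")
  reason <- pick(reason,
                 ev$precision %in% c("month", "year") |
                   st$precision %in% c("month", "year"),
                 "partial_precision")
  days <- rep(NA_real_, n)
  ok <- is.na(reason)
  d <- as.numeric(ev$date[ok] - st$date[ok])
  neg <- d < 0
  reason[ok][neg] <- "event_before_start"
  d[neg] <- NA_real_
  d[!is.na(d) & d == 0] <- 0.5
  days[ok] <- d
  data.frame(days = days, reason = reason, stringsAsFactors = FALSE)
}

#' Extract the TTO sample for one drug
#'
#' Candidate pairs are the deduplicated cases that report the target event
#' and name the drug as primary suspect; each contributes its case
#' `EVENT_DT` and the earliest day-precision therapy start attached to the
#' drug mention.
#'
#' @param dataset a [build_event_dataset()] result.
#' @param drug normalized drug name.
#' @param pt target preferred term.
#' @return a `tto_sample` object: list with `drug`, `values` (retained TTO
#'   days), and `n_excluded_by_reason` (named counts; retained + excluded =
#'   candidate pairs).
#' @export
tto_sample <- function(dataset, drug, pt = "CONSTIPATION") {
  stopifnot(inherits(dataset, "faers_dataset"))
  drug <- normalize_drug_name(drug)
  pt <- norm_string(pt)
  event_cases <- unique(dataset$events$caseid[dataset$events$pt == pt])
  m <- dataset$drug_mentions
  m <- m[m$drugname == drug & m$caseid %in% event_cases, , drop = FALSE]
  ev <- dataset$cases$event_dt[match(m$caseid, dataset$cases$caseid)]
  tto <- compute_tto(ev, m$start_dt)
  excl <- table(factor(tto$reason, levels = TTO_EXCLUSION_REASONS))
  structure(
    list(drug = drug,
         values = tto$days[!is.na(tto$days)],
         n_excluded_by_reason = stats::setNames(as.integer(excl),
                                                TTO_EXCLUSION_REASONS),
         n_candidates = nrow(m)),
    class = "tto_sample"
  )
}

#' @export
print.tto_sample <- function(x, ...) {
  cat("TTO sample for", x$drug, "-", length(x$values), "retained of",
      x$n_candidates, "candidate pairs\n")
  excl <- x$n_excluded_by_reason
  excl <- excl[excl > 0]
  if (length(excl)) {
    cat("  excluded:", paste(names(excl), excl, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Median and quartiles of a TTO sample
#'
#' Quartiles use linear interpolation between order statistics (R's default
#' quantile type 7). Same-day onsets (stored as 0.5 for fitting) enter the
#' descriptive summary as 0 days.
#'
#' @param sample a `tto_sample` or a numeric vector of days.
#' @return list `n, median, q1, q3`.
#' @export
tto_summary <- function(sample) {
  values <- if (inherits(sample, "tto_sample")) sample$values else sample
  if (length(values) < 1L) stop_faersdpa("empty TTO sample")
  v <- ifelse(values == 0.5, 0, values)
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
}

# log-likelihood pieces for theta = (log alpha, log beta)
weibull_ll <- function(theta, x) {
  la <- theta[1]; lb <- theta[2]
  b <- exp(lb)
  t_ <- log(x) - la
  z <- exp(b * t_)
  n <- length(x)
  ll <- n * lb + (b - 1) * sum(log(x)) - n * b * la - sum(z)
  g <- c(b * (sum(z) - n),
         n + b * sum(t_) - b * sum(z * t_))
  h11 <- -b^2 * sum(z)
  h12 <- b * (sum(z) - n) + b^2 * sum(z * t_)
  h22 <- b * sum(t_) - b * sum(z * t_) - b^2 * sum(z * t_^2)
  list(ll = ll, grad = g, hess = matrix(c(h11, h12, h12, h22), 2, 2))
}

#' Two-parameter Weibull maximum-likelihood fit
#'
#' Newton iterations on the log-parameterization `(log alpha, log beta)`
#' (scale alpha in days, shape beta), stopping when the step norm falls
#' below `1e-10`. 95\% confidence intervals are Wald intervals from the
#' observed information on the log scale, back-transformed (so bounds are
#' always positive); a percentile bootstrap is available for small samples.
#'
#' @param sample a `tto_sample` or numeric vector of positive days.
#' @param ci `"wald"` or `"bootstrap"`.
#' @param boot_n bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param conf_z normal quantile for the Wald interval.
#' @return a `weibull_fit` object: `alpha, alpha_lo, alpha_hi, beta,
#'   beta_lo, beta_hi, n, loglik, iterations`.
#' @export
weibull_fit <- function(sample, ci = c("wald", "bootstrap"), boot_n = 1000,
                        seed = 1, conf_z = 1.96) {
  ci <- match.arg(ci)
  x <- if (inherits(sample, "tto_sample")) sample$values else sample
  x <- as.numeric(x)
  if (length(x) < 3L) {
    stop_faersdpa("Weibull fit needs at least 3 observations")
  }
  if (any(x <= 0)) stop_faersdpa("Weibull fit requires positive values")
  if (stats::sd(log(x)) == 0) {
    stop_faersdpa("all values identical: Weibull shape is unbounded")
  }
  theta <- weibull_mle(x)
  info <- weibull_ll(theta$par, x)
  if (ci == "wald") {
    vc <- solve(-info$hess)
    se <- sqrt(pmax(diag(vc), 0))
    lo <- exp(theta$par - conf_z * se)
    hi <- exp(theta$par + conf_z * se)
  } else {
    est <- local({
      set.seed(seed)
      replicate(boot_n, {
        xi <- x[sample.int(length(x), replace = TRUE)]
        if (stats::sd(log(xi)) == 0) c(NA_real_, NA_real_)
        else weibull_mle(xi)$par
      })
    })
    qs <- apply(est, 1L, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    lo <- exp(qs[1, ]); hi <- exp(qs[2, ])
  }
  structure(
    list(alpha = exp(theta$par[1]), alpha_lo = lo[1], alpha_hi = hi[1],
         beta = exp(theta$par[2]), beta_lo = lo[2], beta_hi = hi[2],
         n = length(x), loglik = info$ll, iterations = theta$iterations,
         ci_method = ci),
    class = "weibull_fit"
  )
}

# Newton on (log alpha, log beta); Gumbel moment start.
weibull_mle <- function(x, tol = 1e-10, maxit = 200) {
  lx <- log(x)
  b0 <- min(max(1.2826 / stats::sd(lx), 1e-3), 1e3)
  theta <- c(mean(lx) + 0.5772 / b0, log(b0))
  for (it in seq_len(maxit)) {
    d <- weibull_ll(theta, x)
    step <- tryCatch(solve(d$hess, d$grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop_faersdpa("Weibull fit did not converge: singular Hessian at ",
                    "iteration ", it)
    }
    # damped Newton: halve until the likelihood does not decrease
    lam <- 1
    repeat {
      cand <- theta - lam * step
      if (weibull_ll(cand, x)$ll >= d$ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    theta <- cand
    if (sqrt(sum((lam * step)^2)) < tol) {
      return(list(par = theta, iterations = it))
    }
  }
  stop_faersdpa("Weibull fit did not converge in ", maxit, " iterations; ",
                "final step ", sqrt(sum(step^2)))
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull MLE (n=%d): scale alpha = %.4g (%.4g, %.4g) days, ",
              x$n, x$alpha, x$alpha_lo, x$alpha_hi))
  cat(sprintf("shape beta = %.4g (%.4g, %.4g)\n",
              x$beta, x$beta_lo, x$beta_hi))
  cat("failure type:", classify_failure(x$beta, x$beta_lo, x$beta_hi), "\n")
  invisible(x)
}

#' Classify the hazard (failure) type from the Weibull shape CI
#'
#' @param beta fitted shape.
#' @param beta_lo,beta_hi 95\% CI bounds.
#' @return `"early"` (CI entirely below 1: decreasing hazard), `"wear-out"`
#'   (entirely above 1), `"random"` (CI covers 1), or `"indeterminate"`.
#' @export
classify_failure <- function(beta, beta_lo, beta_hi) {
  if (any(!is.finite(c(beta, beta_lo, beta_hi)))) return("indeterminate")
  if (beta_hi < 1) return("early")
  if (beta_lo > 1) return("wear-out")
  if (beta_lo <= 1 && beta_hi >= 1) return("random")
  "indeterminate"
}

#' TTO table over many drugs
#'
#' One row per drug: retained n, median and quartiles, Weibull scale/shape
#' with CIs, and the failure type. Drugs whose retained sample is too small
#' or degenerate for the fit get `NA` fit columns and failure type
#' `"indeterminate"`.
#'
#' @param dataset a [build_event_dataset()] result.
#' @param drugs character vector of drug names.
#' @param pt target preferred term.
#' @param min_n minimum retained sample size to attempt the fit.
#' @return data.frame mirroring a published TTO table.
#' @export
tto_table <- function(dataset, drugs, pt = "CONSTIPATION", min_n = 3) {
  rows <- lapply(drugs, function(dr) {
    s <- tto_sample(dataset, dr, pt)
    base <- data.frame(drug = dr, n = length(s$values),
                       median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                       alpha = NA_real_, alpha_lo = NA_real_,
                       alpha_hi = NA_real_, beta = NA_real_,
                       beta_lo = NA_real_, beta_hi = NA_real_,
                       failure_type = "indeterminate",
                       stringsAsFactors = FALSE)
    if (length(s$values) >= 1L) {
      q <- tto_summary(s)
      base$median <- q$median; base$q1 <- q$q1; base$q3 <- q$q3
    }
    if (length(s$values) >= min_n) {
      fit <- tryCatch(weibull_fit(s), error = function(e) NULL)
      if (!is.null(fit)) {
        base$alpha <- fit$alpha
        base$alpha_lo <- fit$alpha_lo; base$alpha_hi <- fit$alpha_hi
        base$beta <- fit$beta
        base$beta_lo <- fit$beta_lo; base$beta_hi <- fit$beta_hi
        base$failure_type <- classify_failure(fit$beta, fit$beta_lo,
                                              fit$beta_hi)
      }
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
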