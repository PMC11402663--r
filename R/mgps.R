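#' @name mgps
#' @title Multi-item gamma Poisson shrinker (MGPS)
#'
#' @description
#' MGPS models the observed drug-event count `a` as Poisson with mean
#' `lambda * E`, where `E = (a+b)(a+c)/N` is the count expected under
#' independent reporting and `lambda` has a two-component gamma mixture
#' prior. Marginally, `a` then follows a mixture of negative binomials, and
#' the five hyperparameters (two gamma shape/rate pairs and the mixture
#' weight) are estimated by maximizing the summed marginal log-likelihood
#' over all drug-event cells. The posterior for each cell is again a gamma
#' mixture; EBGM is the posterior geometric mean `2^{E[log2 lambda]}` and
#' EB05 the posterior 5th percentile.
#'
#' A `"simplified"` mode is also provided in [ebgm_estimate()] for
#' reproducing published tables in which EBGM equals the unshrunk
#' relative reporting ratio and EB05 is a log-normal lower bound
#' `exp(ln RRR - 1.64 sqrt(1/a + 1/b + 1/c + 1/d))`.
NULL

# Mixture negative-binomial log-density of counts a given expectations E.
mgps_marginal_loglik <- function(theta, a, E) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m)))
}

# Deterministic base starts (first is the classical DuMouchel init),
# optionally followed by seeded jitters around it.
mgps_starts <- function(n_random = 5, seed = 1) {
  base <- list(
    c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, w = 1 / 3),
    c(alpha1 = 1, beta1 = 1, alpha2 = 2, beta2 = 2, w = 0.5),
    c(alpha1 = 0.5, beta1 = 0.5, alpha2 = 5, beta2 = 1, w = 0.2)
  )
  to_theta <- function(p) c(log(p[1:4]), stats::qlogis(p[5]))
  starts <- lapply(base, to_theta)
  if (n_random > 0) {
    rng <- local({
      set.seed(seed)
      matrix(stats::rnorm(5 * n_random, sd = 0.7), ncol = 5)
    })
    for (i in seq_len(n_random)) {
      starts[[length(starts) + 1L]] <- starts[[1L]] + rng[i, ]
    }
  }
  starts
}

#' Fit the MGPS gamma-mixture prior
#'
#' Maximizes the negative-binomial mixture marginal likelihood of the
#' observed cell counts given their expected counts, over the five
#' hyperparameters, using multiple deterministic and seeded starting points.
#'
#' @param a integer vector of observed drug-event counts (one per cell).
#' @param E positive vector of expected counts `(a+b)(a+c)/N`.
#' @param n_random_starts extra jittered starts beyond the three fixed ones.
#' @param seed seed for the jittered starts (fit is deterministic given it).
#' @return an object of class `mgps_prior`: `alpha1, beta1, alpha2, beta2, w`
#'   plus `loglik`, `converged`, and `n_cells`.
#' @export
mgps_fit_prior <- function(a, E, n_random_starts = 5, seed = 1) {
  a <- as.numeric(a)
  E <- as.numeric(E)
  stopifnot(length(a) == length(E))
  keep <- is.finite(a) & is.finite(E) & E > 0 & a >= 0
  a <- a[keep]; E <- E[keep]
  if (length(a) < 2L) {
    stop_faersdpa("MGPS prior fit needs at least 2 cells with positive ",
                  "expected counts (got ", length(a), ")")
  }
  neg <- function(theta) {
    # extreme trial parameters can overflow dnbinom; treat as -Inf loglik
    ll <- suppressWarnings(mgps_marginal_loglik(theta, a, E))
    if (!is.finite(ll)) 1e12 else -ll
  }
  best <- NULL
  any_converged <- FALSE
  for (s in mgps_starts(n_random_starts, seed)) {
    fit <- tryCatch(
      stats::optim(s, neg, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop_faersdpa("MGPS prior fit failed from every start")
  th <- best$par
  prior <- structure(
    list(alpha1 = exp(th[[1]]), beta1 = exp(th[[2]]),
         alpha2 = exp(th[[3]]), beta2 = exp(th[[4]]),
         w = stats::plogis(th[[5]]),
         loglik = -best$value, converged = any_converged,
         n_cells = length(a)),
    class = "mgps_prior"
  )
  if (!any_converged) {
    cond <- structure(
      class = c("mgps_convergence_error", "error", "condition"),
      list(message = "MGPS prior fit did not converge from any start",
           call = sys.call(-1), prior = prior)
    )
    stop(cond)
  }
  prior
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior (", x$n_cells, " cells)\n", sep = "")
  cat(sprintf("  component 1: Gamma(shape=%.4g, rate=%.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Gamma(shape=%.4g, rate=%.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$w))
  cat(sprintf("  marginal log-likelihood %.3f, converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

# Posterior mixture weight of component 1 given (a, E).
mgps_posterior_q <- function(prior, a, E) {
  l1 <- log(prior$w) +
    stats::dnbinom(a, size = prior$alpha1,
                   prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- log(1 - prior$w) +
    stats::dnbinom(a, size = prior$alpha2,
                   prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- max(l1, l2)
  exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
}

# Posterior 5th percentile of the gamma mixture by monotone root-finding.
mgps_posterior_quantile <- function(prior, a, E, p = 0.05, tol = 1e-8) {
  q <- mgps_posterior_q(prior, a, E)
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  cdf <- function(x) {
    q * stats::pgamma(x, s1, rate = r1) +
      (1 - q) * stats::pgamma(x, s2, rate = r2) - p
  }
  lo <- min(stats::qgamma(p, s1, rate = r1), stats::qgamma(p, s2, rate = r2))
  hi <- max(stats::qgamma(p, s1, rate = r1), stats::qgamma(p, s2, rate = r2))
  if (lo == hi) return(lo)
  stats::uniroot(cdf, lower = lo, upper = hi, tol = tol,
                 extendInt = "upX")$root
}

#' EBGM and EB05 for one table
#'
#' `mode = "full"` uses the fitted gamma-mixture posterior:
#' `EBGM = exp(E[ln lambda | a])` and EB05 the posterior 5th percentile
#' (root-found on the mixture CDF to 1e-8). `mode = "simplified"`
#' reproduces published tables where no Bayesian shrinkage was applied:
#' `EBGM = RRR` and `EB05 = exp(ln RRR - 1.64 sqrt(1/a+1/b+1/c+1/d))`.
#'
#' @param t a `faers_ctab`.
#' @param prior an [mgps_fit_prior()] result (required for `"full"`).
#' @param mode `"simplified"` or `"full"`.
#' @return list `ebgm, eb05, reason`.
#' @export
ebgm_estimate <- function(t, prior = NULL, mode = c("simplified", "full")) {
  stopifnot(inherits(t, "faers_ctab"))
  mode <- match.arg(mode)
  if (mode == "simplified") {
    if (min(t$a, t$b, t$c, t$d) <= 0) {
      return(undefined_stat(c("ebgm", "eb05"), "zero cell"))
    }
    log_rrr <- log(t$a) + log(t$N) - log(t$a + t$b) - log(t$a + t$c)
    se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
    return(list(ebgm = exp(log_rrr), eb05 = exp(log_rrr - 1.64 * se),
                reason = NA_character_))
  }
  if (is.null(prior) || !inherits(prior, "mgps_prior")) {
    stop_faersdpa("mode='full' requires a fitted mgps_prior")
  }
  e <- (t$a + t$b) * (t$a + t$c) / t$N
  if (e <= 0) return(undefined_stat(c("ebgm", "eb05"), "zero margin"))
  q <- mgps_posterior_q(prior, t$a, e)
  mean_log <- q * (digamma(prior$alpha1 + t$a) - log(prior$beta1 + e)) +
    (1 - q) * (digamma(prior$alpha2 + t$a) - log(prior$beta2 + e))
  list(ebgm = exp(mean_log),
       eb05 = mgps_posterior_quantile(prior, t$a, e, p = 0.05),
       reason = NA_character_)
}
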