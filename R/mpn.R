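# Maximum-likelihood most-probable-number (MPN) estimation from
# presence/absence dilution-series bioassays. Under the Poisson
# propagule model a pot receiving diluted soil of volume v at dilution d
# from a source of density lambda is colonized with probability
# 1 - exp(-lambda * d * v); the log-likelihood over all levels is
# maximized in lambda.

#' Build a dilution-series object
#'
#' @param dilution dilution factors (e.g. `2^c(-1,-3,-5,-7)`), strictly
#'   decreasing.
#' @param volume_ml assay soil volume per pot (mL); a required input,
#'   never defaulted.
#' @param n_tested plants tested per level.
#' @param n_positive plants colonized per level.
#' @return data.frame of class `amf_dilution_series`.
#' @export
dilution_series <- function(dilution, volume_ml, n_tested, n_positive) {
  d <- data.frame(dilution = as.numeric(dilution),
                  volume_ml = as.numeric(volume_ml),
                  n_tested = as.integer(n_tested),
                  n_positive = as.integer(n_positive))
  if (any(d$n_positive < 0) || any(d$n_positive > d$n_tested))
    stop("n_positive must lie in [0, n_tested]", call. = FALSE)
  if (is.unsorted(rev(d$dilution), strictly = TRUE) &&
      is.unsorted(d$dilution, strictly = TRUE))
    stop("dilution factors must be strictly monotone", call. = FALSE)
  if (any(d$dilution <= 0) || any(d$volume_ml <= 0))
    stop("dilutions and volumes must be positive", call. = FALSE)
  class(d) <- c("amf_dilution_series", "data.frame")
  d
}

mpn_loglik <- function(lambda, d) {
  mu <- lambda * d$dilution * d$volume_ml
  p1 <- ifelse(mu > 0, log1p(-exp(-mu)), -Inf)
  sum(d$n_positive * p1) - sum((d$n_tested - d$n_positive) * mu)
}

#' Maximum-likelihood MPN estimate from one dilution series
#'
#' Maximizes the Poisson presence/absence likelihood over the propagule
#' density `lambda` by bounded one-dimensional optimization on the log
#' scale, with a profile-likelihood 95% confidence interval. All-negative
#' series return a zero estimate with a one-sided upper bound;
#' all-positive series are flagged and only a lower bound is reported.
#'
#' @param series an `amf_dilution_series` (or data.frame with columns
#'   `dilution`, `volume_ml`, `n_tested`, `n_positive`).
#' @param bracket search bracket for lambda (propagules/mL).
#' @param conf_level confidence level of the profile interval.
#' @param bulk_density optional soil bulk density (g/mL); when given the
#'   result also carries `density_per_g = density / bulk_density`
#'   (propagules per gram of soil).
#' @return an object of class `amf_mpn`: list with `density`
#'   (propagules/mL), `loglik`, `ci` (lower, upper), `boundary`
#'   (`"none"`, `"all_negative"`, or `"all_positive"`), and optionally
#'   `density_per_g`.
#' @export
#' @examples
#' s <- dilution_series(1, 1, 10, 5)
#' mpn_estimate(s)$density  # -log(0.5)
mpn_estimate <- function(series, bracket = c(1e-8, 1e4),
                         conf_level = 0.95, bulk_density = NULL) {
  d <- as.data.frame(series)
  stopifnot(all(c("dilution", "volume_ml", "n_tested", "n_positive") %in%
                  names(d)))
  finish <- function(obj) {
    if (!is.null(bulk_density))
      obj$density_per_g <- obj$density / bulk_density
    structure(obj, class = "amf_mpn")
  }
  crit <- stats::qchisq(conf_level, df = 1) / 2
  if (all(d$n_positive == 0L)) {
    # likelihood is maximized at lambda = 0; upper bound where the
    # log-likelihood drops by the chi-square criterion
    ll0 <- 0
    up <- stats::uniroot(function(l) mpn_loglik(l, d) - (ll0 - crit),
                         interval = bracket)$root
    return(finish(list(density = 0, loglik = ll0, ci = c(0, up),
                       boundary = "all_negative")))
  }
  if (all(d$n_positive == d$n_tested)) {
    # likelihood increases without bound in lambda; report the lower
    # confidence bound only
    ll_sup <- 0
    lo <- stats::uniroot(function(l) mpn_loglik(l, d) - (ll_sup - crit),
                         interval = bracket)$root
    return(finish(list(density = Inf, loglik = ll_sup,
                       ci = c(lo, Inf), boundary = "all_positive")))
  }
  opt <- stats::optimize(function(lg) mpn_loglik(exp(lg), d),
                         interval = log(bracket), maximum = TRUE,
                         tol = 1e-10)
  lam <- exp(opt$maximum)
  ll <- opt$objective
  prof <- function(l) mpn_loglik(l, d) - (ll - crit)
  lo <- if (prof(bracket[1]) < 0)
    stats::uniroot(prof, interval = c(bracket[1], lam))$root
  else bracket[1]
  up <- if (prof(bracket[2]) < 0)
    stats::uniroot(prof, interval = c(lam, bracket[2]))$root
  else bracket[2]
  finish(list(density = lam, loglik = ll, ci = c(lo, up),
              boundary = "none"))
}

#' @export
print.amf_mpn <- function(x, ...) {
  cat(sprintf("MPN estimate: %.4g propagules/mL (95%% CI %.4g-%.4g)%s\n",
              x$density, x$ci[1], x$ci[2],
              if (x$boundary != "none") paste0(" [", x$boundary, "]")
              else ""))
  invisible(x)
}

#' Per-trial MPN means from replicated dilution series
#'
#' Estimates the propagule density of every trial x block series and
#' summarizes each trial by the arithmetic mean and standard error of
#' its block-level estimates.
#'
#' @param tables data.frame with columns `trial`, `block`, `dilution`,
#'   `volume_ml`, `n_tested`, `n_positive` (as produced by
#'   [make_dilution_series()]).
#' @param ... passed to [mpn_estimate()].
#' @return list with `estimates` (one row per trial x block) and
#'   `summary` (per trial: `mean`, `se`, `n`).
#' @export
mpn_batch <- function(tables, ...) {
  stopifnot(all(c("trial", "block", "dilution", "volume_ml", "n_tested",
                  "n_positive") %in% names(tables)))
  key <- interaction(tables$trial, tables$block, drop = TRUE)
  est <- do.call(rbind, lapply(split(tables, key), function(d) {
    e <- mpn_estimate(d, ...)
    data.frame(trial = d$trial[1], block = d$block[1],
               density = e$density, boundary = e$boundary,
               stringsAsFactors = FALSE)
  }))
  rownames(est) <- NULL
  finite <- est[is.finite(est$density), ]
  smry <- do.call(rbind, lapply(split(finite, finite$trial), function(d) {
    n <- nrow(d)
    data.frame(trial = d$trial[1], mean = mean(d$density),
               se = if (n > 1) stats::sd(d$density) / sqrt(n) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL
  list(estimates = est, summary = smry)
}
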