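#' Sample excess kurtosis
#'
#' Moment-based excess kurtosis `m4/m2^2 - 3` with the `(1 - 1/n)^2`
#' small-sample convention (the default, "type 3" estimator of the e1071
#' package, which this wraps). Values well above 0 indicate a heavy tail;
#' a half-normal law has excess kurtosis ~0.87, a two-point symmetric law
#' -2.
#'
#' @param x Numeric sample of at least 4 values with positive variance.
#' @return A single number.
#' @export
excess_kurtosis <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate sample: zero variance", call. = FALSE)
  e1071::kurtosis(x, type = 3)
}

new_dist_fit <- function(model, params, loglik, k, n, x_min = NA_real_,
                         family = model) {
  out <- list(model = model, family = family, params = params,
              loglik = loglik, k = k, aic = 2 * k - 2 * loglik, n = n,
              x_min = x_min)
  class(out) <- "dist_fit"
  out
}

#' Maximum-likelihood lognormal fit
#'
#' Closed-form MLE: `meanlog` is the mean of the logs and `sdlog` the
#' root-mean-square deviation of the logs (divisor `n`).
#'
#' @param x Positive numeric sample.
#' @return A `dist_fit` object (model, parameters, log-likelihood, AIC).
#' @examples
#' fit_lognormal(c(1, exp(1), exp(2)))
#' @export
fit_lognormal <- function(x) {
  x <- as.numeric(x)
  if (any(x <= 0)) stop("lognormal support requires all x > 0", call. = FALSE)
  lx <- log(x)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2))
  if (sdlog == 0) stop("degenerate sample: zero variance of logs", call. = FALSE)
  ll <- sum(stats::dlnorm(x, meanlog, sdlog, log = TRUE))
  new_dist_fit("lognormal", list(meanlog = meanlog, sdlog = sdlog), ll, 2,
               length(x))
}

#' Maximum-likelihood exponential fit
#'
#' MLE rate is the reciprocal of the sample mean; support is `x >= 0`
#' (integer jump data, with minimum 1, sits inside this support — the
#' rate is 1/mean either way).
#'
#' @param x Nonnegative numeric sample with positive mean.
#' @return A `dist_fit` object.
#' @export
fit_exponential <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("exponential support requires all x >= 0", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("degenerate sample: zero mean", call. = FALSE)
  rate <- 1 / m
  ll <- length(x) * log(rate) - rate * sum(x)
  new_dist_fit("exponential", list(rate = rate), ll, 1, length(x))
}

#' Maximum-likelihood half-normal fit with location fixed at 1
#'
#' Density `2 phi((x - 1) / sigma) / sigma` on `x >= 1`; the MLE is
#' `sigma = sqrt(mean((x - 1)^2))`. Location 1 matches jump data, whose
#' smallest possible value is one state.
#'
#' @param x Numeric sample with all values `>= 1` and not all equal to 1.
#' @return A `dist_fit` object.
#' @export
fit_halfnormal_loc1 <- function(x) {
  x <- as.numeric(x)
  if (any(x < 1)) stop("half-normal support requires all x >= 1", call. = FALSE)
  sigma <- sqrt(mean((x - 1)^2))
  if (sigma == 0) stop("degenerate sample: all values equal 1", call. = FALSE)
  ll <- sum(log(2) - log(sigma) + stats::dnorm((x - 1) / sigma, log = TRUE))
  new_dist_fit("halfnormal", list(sigma = sigma), ll, 1, length(x))
}

# Hurwitz zeta over the integers >= x_min: zeta(a) - sum_{k < x_min} k^-a.
# pracma::zeta evaluates the Riemann zeta to machine precision.
hurwitz_zeta <- function(a, x_min = 1) {
  z <- pracma::zeta(a)
  if (x_min > 1) z <- z - sum((seq_len(x_min - 1))^(-a))
  z
}

#' Maximum-likelihood discrete power-law (zeta) fit
#'
#' Fits `P(X = x) = x^-alpha / zeta(alpha, x_min)` on the integers
#' `x >= x_min` by one-dimensional numerical maximisation of the zeta
#' likelihood over `alpha > 1`.
#'
#' @param x Integer-valued sample with all values `>= x_min`.
#' @param x_min Lower bound of the power-law support (default 1).
#' @return A `dist_fit` object with parameters `alpha` and `x_min`.
#' @export
fit_powerlaw_discrete <- function(x, x_min = 1) {
  x <- as.numeric(x)
  if (any(x != round(x))) stop("discrete power law requires integer values",
                               call. = FALSE)
  if (x_min > max(x)) stop("invalid support: x_min exceeds max(x)",
                           call. = FALSE)
  if (any(x < x_min)) stop("all values must be >= x_min", call. = FALSE)
  n <- length(x)
  slx <- sum(log(x))
  negll <- function(a) n * log(hurwitz_zeta(a, x_min)) + a * slx
  opt <- stats::optimize(negll, interval = c(1 + 1e-8, 50), tol = 1e-9)
  if (!is.finite(opt$objective)) stop("power-law fit failed to converge",
                                      call. = FALSE)
  new_dist_fit("powerlaw", list(alpha = opt$minimum, x_min = x_min),
               -opt$objective, 1, n, x_min, family = "zeta")
}

#' Maximum-likelihood continuous power-law (Pareto) fit
#'
#' Fits the continuous power-law density `f(x) = (alpha - 1) x_min^(alpha
#' - 1) x^-alpha` on `x >= x_min` by the closed-form Hill/Pareto MLE
#' `alpha = 1 + n / sum(log(x / x_min))`. This is the estimator the
#' lognormal-vs-power-law comparison uses by default: applied to
#' integer-valued data it mirrors the continuous lognormal, exponential
#' and half-normal likelihoods (no continuity correction anywhere), so
#' the four AIC values are directly comparable. The discrete zeta
#' alternative is [fit_powerlaw_discrete()].
#'
#' @param x Sample with all values `>= x_min` and not all equal to
#'   `x_min`.
#' @param x_min Lower bound of the power-law support (default 1).
#' @return A `dist_fit` object with parameters `alpha` and `x_min`.
#' @export
fit_powerlaw_continuous <- function(x, x_min = 1) {
  x <- as.numeric(x)
  if (x_min > max(x)) stop("invalid support: x_min exceeds max(x)",
                           call. = FALSE)
  if (any(x < x_min)) stop("all values must be >= x_min", call. = FALSE)
  slx <- sum(log(x / x_min))
  if (slx == 0) stop("degenerate sample: all values equal x_min",
                     call. = FALSE)
  n <- length(x)
  alpha <- 1 + n / slx
  ll <- n * log(alpha - 1) + n * (alpha - 1) * log(x_min) - alpha * sum(log(x))
  new_dist_fit("powerlaw", list(alpha = alpha, x_min = x_min), ll, 1, n,
               x_min, family = "pareto")
}

#' Fit and rank all candidate distributions by AIC
#'
#' Fits the lognormal, exponential, half-normal (location 1) and
#' power-law models to the same sample and ranks them by AIC (ascending;
#' ties broken by alphabetical model name). Models whose fit fails (e.g.
#' degenerate samples) are dropped from the ranking with a warning.
#'
#' @param x Numeric sample; all values must be `>= 1` (the strictest
#'   support among the candidates).
#' @param x_min Lower bound passed to the power-law fit.
#' @param powerlaw `"continuous"` (default) uses the Pareto likelihood of
#'   [fit_powerlaw_continuous()], keeping all four candidates on
#'   continuous densities; `"discrete"` uses the zeta likelihood of
#'   [fit_powerlaw_discrete()].
#' @return Object of class `model_comparison`: list with `fits` (named
#'   list of `dist_fit`) and `table` (tibble `model`, `loglik`, `k`,
#'   `aic`, sorted ascending by AIC).
#' @examples
#' set.seed(1)
#' x <- round(rlnorm(500, 2, 1)) + 1
#' compare_models_aic(x)$table
#' @export
compare_models_aic <- function(x, x_min = 1,
                               powerlaw = c("continuous", "discrete")) {
  powerlaw <- match.arg(powerlaw)
  pl_fitter <- if (powerlaw == "continuous") {
    function(z) fit_powerlaw_continuous(z, x_min)
  } else {
    function(z) fit_powerlaw_discrete(z, x_min)
  }
  fitters <- list(
    lognormal = fit_lognormal,
    exponential = fit_exponential,
    halfnormal = fit_halfnormal_loc1,
    powerlaw = pl_fitter
  )
  fits <- list()
  for (m in names(fitters)) {
    f <- tryCatch(fitters[[m]](x), error = function(e) {
      warning(sprintf("%s fit failed: %s", m, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[m]] <- f
  }
  tab <- tibble::tibble(
    model = names(fits),
    loglik = purrr::map_dbl(fits, "loglik"),
    k = purrr::map_int(fits, "k"),
    aic = purrr::map_dbl(fits, "aic")
  )
  tab <- dplyr::arrange(tab, .data$aic, .data$model)
  out <- list(fits = fits, table = tab, n = length(x), x_min = x_min,
              data = as.numeric(x))
  class(out) <- "model_comparison"
  out
}

#' Bootstrap model-preference counts
#'
#' Resamples the data with replacement `B` times; on each replicate all
#' candidate models are refit and the AIC winner recorded. Replicates on
#' which every fit fails are skipped (and counted).
#'
#' @param x Numeric sample (all values `>= 1`).
#' @param B Number of bootstrap replicates (default 1000).
#' @param x_min Lower bound for the power-law candidate.
#' @param powerlaw Power-law likelihood, as in [compare_models_aic()].
#' @return List with `counts` (named integer vector of wins per model),
#'   `B`, and `skipped`.
#' @export
bootstrap_model_preference <- function(x, B = 1000, x_min = 1,
                                       powerlaw = c("continuous",
                                                    "discrete")) {
  powerlaw <- match.arg(powerlaw)
  if (B < 1) stop("`B` must be at least 1", call. = FALSE)
  models <- c("exponential", "halfnormal", "lognormal", "powerlaw")
  counts <- stats::setNames(integer(length(models)), models)
  skipped <- 0L
  for (b in seq_len(B)) {
    xb <- sample(x, length(x), replace = TRUE)
    cmp <- suppressWarnings(compare_models_aic(xb, x_min, powerlaw))
    if (nrow(cmp$table) == 0) {
      skipped <- skipped + 1L
      next
    }
    w <- cmp$table$model[1]
    counts[w] <- counts[w] + 1L
  }
  list(counts = counts, B = B, skipped = skipped)
}

#' Empirical CDF and CCDF table
#'
#' Tabulates, at each distinct sample value, the fraction of observations
#' `<= v` (CDF) and `> v` (CCDF). The two always sum to 1; the CCDF at the
#' sample maximum is 0 and should be dropped before plotting on a log
#' scale.
#'
#' @param x Nonempty numeric sample.
#' @return Tibble with columns `value`, `cdf`, `ccdf`.
#' @export
empirical_cdf_ccdf <- function(x) {
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  v <- sort(unique(as.numeric(x)))
  cdf <- stats::ecdf(x)(v)
  tibble::tibble(value = v, cdf = cdf, ccdf = 1 - cdf)
}

# Theoretical CDF of a fitted candidate model, used by the plotting layer.
dist_fit_cdf <- function(fit, q) {
  p <- fit$params
  switch(fit$model,
    lognormal = stats::plnorm(q, p$meanlog, p$sdlog),
    exponential = stats::pexp(q, p$rate),
    halfnormal = ifelse(q < 1, 0, 2 * stats::pnorm((q - 1) / p$sigma) - 1),
    powerlaw = if (identical(fit$family, "pareto")) {
      ifelse(q < p$x_min, 0, 1 - (q / p$x_min)^(1 - p$alpha))
    } else {
      xm <- p$x_min
      vapply(q, function(qi) {
        if (qi < xm) return(0)
        ks <- xm:floor(qi)
        sum(ks^(-p$alpha)) / hurwitz_zeta(p$alpha, xm)
      }, numeric(1))
    },
    stop("unknown model", call. = FALSE)
  )
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("<dist_fit: %s>\n", x$model))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  cat(sprintf("  loglik = %.2f, AIC = %.2f, n = %d\n", x$loglik, x$aic, x$n))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison: %d models, n = %d>\n", nrow(x$table), x$n))
  print(x$table)
  invisible(x)
}

#' Tidy a fitted distribution
#'
#' @param x A `dist_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term` and `estimate`.
#' @method tidy dist_fit
#' @export
tidy.dist_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = as.numeric(unlist(x$params)))
}

#' One-row model summary of a fitted distribution
#'
#' @param x A `dist_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `model`, `loglik`, `df` (parameter count),
#'   `AIC`, and `nobs`.
#' @method glance dist_fit
#' @export
glance.dist_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik, df = x$k, AIC = x$aic,
                 nobs = x$n)
}

#' Tidy a model comparison
#'
#' @param x A `model_comparison` object.
#' @param ... Unused.
#' @return The AIC-ranked table with per-model parameter estimates nested
#'   in a list column.
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  dplyr::mutate(x$table,
                parameters = purrr::map(x$fits[.data$model], tidy))
}
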