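test_that("excess kurtosis matches known laws", {
  # two-point symmetric law has excess kurtosis -2
  expect_equal(excess_kurtosis(rep(c(-1, 1), 5000)), -2, tolerance = 1e-3)
  set.seed(2)
  expect_lt(abs(excess_kurtosis(rnorm(1e5))), 0.1)
  # half-normal shifted to 1: ~0.87
  set.seed(3)
  expect_equal(excess_kurtosis(1 + abs(rnorm(1e5))), 0.87, tolerance = 0.1)
  expect_error(excess_kurtosis(rep(2, 10)), "zero variance")
  expect_error(excess_kurtosis(c(1, 2, 3)), "at least 4")
})

test_that("closed-form MLEs are exact on analytic samples", {
  ln <- fit_lognormal(c(1, exp(1), exp(2)))
  expect_equal(ln$params$meanlog, 1)
  expect_equal(ln$params$sdlog, sqrt(2 / 3))
  expect_error(fit_lognormal(c(1, -1)), "x > 0")

  ex <- fit_exponential(c(1, 2, 3))
  expect_equal(ex$params$rate, 0.5)
  expect_error(fit_exponential(c(0, 0)), "zero mean")

  hn <- fit_halfnormal_loc1(c(1, 2, 3))
  expect_equal(hn$params$sigma, sqrt(5 / 3))
  expect_error(fit_halfnormal_loc1(c(0.5, 2)), "x >= 1")
  expect_error(fit_halfnormal_loc1(c(1, 1, 1)), "degenerate")

  pc <- fit_powerlaw_continuous(c(2, 4, 8))
  expect_equal(pc$params$alpha, 1 + 3 / sum(log(c(2, 4, 8))))
  expect_error(fit_powerlaw_discrete(c(5, 6, 7), x_min = 10), "x_min")
})

test_that("log-likelihoods match direct density sums and the AIC identity", {
  set.seed(5)
  x <- round(rlnorm(200, 1.5, 1)) + 1
  ln <- fit_lognormal(x)
  expect_equal(ln$loglik,
               sum(dlnorm(x, ln$params$meanlog, ln$params$sdlog, log = TRUE)),
               tolerance = 1e-8)
  ex <- fit_exponential(x)
  expect_equal(ex$loglik, sum(dexp(x, ex$params$rate, log = TRUE)),
               tolerance = 1e-8)
  hn <- fit_halfnormal_loc1(x)
  expect_equal(hn$loglik,
               sum(log(2 / hn$params$sigma *
                         dnorm((x - 1) / hn$params$sigma) / dnorm(0) *
                         dnorm(0))),
               tolerance = 1e-8)
  pd <- fit_powerlaw_discrete(x)
  a <- pd$params$alpha
  expect_equal(pd$loglik, sum(-a * log(x)) - length(x) * log(pracma::zeta(a)),
               tolerance = 1e-6)
  for (f in list(ln, ex, hn, pd)) {
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
  }
})

test_that("every MLE is a local likelihood optimum", {
  set.seed(8)
  x <- round(rlnorm(300, 2, 1)) + 1
  perturb_worse <- function(fit, loglik_fun) {
    base <- do.call(loglik_fun, fit$params)
    for (d in c(0.99, 1.01)) {
      p <- fit$params
      p[[1]] <- p[[1]] * d
      expect_lte(do.call(loglik_fun, p), base + 1e-9)
    }
  }
  perturb_worse(fit_lognormal(x), function(meanlog, sdlog) {
    sum(dlnorm(x, meanlog, sdlog, log = TRUE))
  })
  perturb_worse(fit_exponential(x), function(rate) {
    sum(dexp(x, rate, log = TRUE))
  })
  perturb_worse(fit_halfnormal_loc1(x), function(sigma) {
    sum(log(2) - log(sigma) + dnorm((x - 1) / sigma, log = TRUE))
  })
  perturb_worse(fit_powerlaw_discrete(x), function(alpha, x_min) {
    sum(-alpha * log(x)) - length(x) * log(pracma::zeta(alpha))
  })
})

test_that("fits recover generating parameters on synthetic draws", {
  set.seed(10)
  # lognormal
  x <- rlnorm(10000, 2, 1)
  ln <- fit_lognormal(x)
  expect_equal(ln$params$meanlog, 2, tolerance = 2 * 1 / sqrt(10000) * 2)
  expect_equal(ln$params$sdlog, 1, tolerance = 0.03)
  # exponential
  ex <- fit_exponential(rexp(10000, 0.4))
  expect_equal(ex$params$rate, 0.4, tolerance = 0.02)
  # half-normal at location 1
  hn <- fit_halfnormal_loc1(1 + abs(rnorm(10000, 0, 3)))
  expect_equal(hn$params$sigma, 3, tolerance = 0.1)
  # discrete power law: inverse-pmf sampling from the zeta law
  alpha <- 2.5
  support <- 1:100000
  pmf <- support^(-alpha) / pracma::zeta(alpha)
  z <- sample(support, 50000, replace = TRUE, prob = pmf)
  pd <- fit_powerlaw_discrete(z)
  expect_gte(pd$params$alpha, 2.45)
  expect_lte(pd$params$alpha, 2.55)
  # continuous power law: inverse-CDF Pareto draws
  u <- runif(20000)
  y <- u^(-1 / 1.5)  # alpha = 2.5, x_min = 1
  pc <- fit_powerlaw_continuous(y)
  expect_equal(pc$params$alpha, 2.5, tolerance = 0.05)
})

test_that("lognormal MLE agrees with fitdistrplus", {
  skip_if_not_installed("fitdistrplus")
  set.seed(12)
  x <- round(rlnorm(500, 2, 1.2)) + 1
  ref <- fitdistrplus::fitdist(x, "lnorm")
  ln <- fit_lognormal(x)
  expect_equal(ln$params$meanlog, unname(ref$estimate["meanlog"]),
               tolerance = 1e-3)
  expect_equal(ln$params$sdlog, unname(ref$estimate["sdlog"]),
               tolerance = 1e-3)
  expect_equal(ln$aic, ref$aic, tolerance = 1e-4)
})

test_that("model comparison ranks by AIC and self-selects on synthetic data", {
  set.seed(15)
  x <- pmax(round(rlnorm(10000, 2, 1)), 1)
  cmp <- compare_models_aic(x)
  expect_equal(cmp$table$model[1], "lognormal")
  expect_equal(cmp$table$aic, sort(cmp$table$aic))
  expect_setequal(cmp$table$model,
                  c("lognormal", "exponential", "halfnormal", "powerlaw"))
  # tidy/glance methods expose the ranking
  td <- tidy(cmp)
  expect_equal(nrow(td), 4)
  expect_s3_class(glance(cmp$fits$lognormal), "tbl_df")
})

test_that("bootstrap preference is conservative, reproducible and counted", {
  set.seed(16)
  x <- pmax(round(rlnorm(400, 2, 1)), 1)
  set.seed(1)
  bp <- bootstrap_model_preference(x, B = 25)
  expect_equal(sum(bp$counts) + bp$skipped, 25)
  set.seed(1)
  bp2 <- bootstrap_model_preference(x, B = 25)
  expect_identical(bp$counts, bp2$counts)
  set.seed(2)
  b1 <- bootstrap_model_preference(x, B = 1)
  expect_equal(sum(b1$counts), 1)
  expect_equal(unname(b1$counts["lognormal"]), 1L)
})

test_that("CDF/CCDF tables are complementary and monotone", {
  tab <- empirical_cdf_ccdf(c(1, 1, 2))
  expect_equal(tab$value, c(1, 2))
  expect_equal(tab$cdf, c(2 / 3, 1))
  expect_equal(tab$ccdf, c(1 / 3, 0))
  set.seed(18)
  tab2 <- empirical_cdf_ccdf(rpois(200, 10))
  expect_true(all(diff(tab2$cdf) >= 0))
  expect_true(all(diff(tab2$ccdf) <= 0))
  expect_equal(tab2$cdf + tab2$ccdf, rep(1, nrow(tab2)))
})
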