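test_that("exponential MLE equals its closed form", {
  set.seed(31)
  ipd <- data.frame(time = rexp(400, 0.12), event = rbinom(400, 1, 0.7))
  f <- fit_mle(ipd, "exponential")
  expect_equal(unname(f$dist$params[["rate"]]),
               sum(ipd$event) / sum(ipd$time), tolerance = 1e-8)
  expect_equal(f$k, 1L)
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)
  expect_equal(f$bic, log(nrow(ipd)) - 2 * f$loglik)
})

test_that("log-logistic parameters are recovered within 2% at n = 10,000", {
  tt <- sample_event_times(tis_os(), 10000, seed = 42)
  f <- fit_mle(data.frame(time = tt, event = 1), "loglogistic")
  expect_equal(unname(f$dist$params[["scale"]]), 16.50756, tolerance = 0.02)
  expect_equal(unname(f$dist$params[["shape"]]), 1.70402, tolerance = 0.02)
  expect_true(f$converged)
})

test_that("fitted optimum dominates the generating parameters in likelihood", {
  set.seed(9)
  for (nm in c("exponential", "weibull", "loglogistic", "lognormal", "gamma")) {
    truth <- family_cases()[[nm]]
    tt <- sample_event_times(truth, 800)
    cens <- pmin(tt, 60)
    ipd <- data.frame(time = cens, event = as.integer(tt <= 60))
    f <- suppressWarnings(fit_mle(ipd, nm))
    ll_truth <- sum(ifelse(ipd$event == 1,
                           density_at(truth, ipd$time, log = TRUE),
                           log(survival_at(truth, ipd$time))))
    expect_gte(f$loglik + 1e-6, ll_truth)
  }
})

test_that("censored log-logistic fit agrees with an independent fitter", {
  skip_if_not_installed("flexsurv")
  skip_if_not_installed("survival")
  spec <- trial_sim_spec(seed = 5)
  ipd <- generate_ipd(spec)
  sub <- ipd[ipd$arm == "tislelizumab" & ipd$endpoint == "os", c("time", "event")]
  ours <- fit_mle(sub, "loglogistic")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                               data = sub, dist = "llogis")
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(ours$dist$params[["scale"]]),
               unname(ref$res["scale", "est"]), tolerance = 1e-4)
  expect_equal(unname(ours$dist$params[["shape"]]),
               unname(ref$res["shape", "est"]), tolerance = 1e-4)
  # covariance of (log scale, log shape) vs the reference (log shape, log scale)
  expect_equal(unname(diag(ours$vcov_log)),
               unname(diag(vcov(ref))[c("scale", "shape")]), tolerance = 1e-3)
})

test_that("model selection: log-logistic wins AIC on log-logistic data, majority of seeds", {
  wins <- 0L
  for (s in 1:3) {
    tt <- sample_event_times(tis_os(), 2000, seed = 100 + s)
    tab <- cmd_fit(data.frame(time = tt, event = 1))
    if (tab$family[1] == "loglogistic") wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("rank_models orders by AIC with BIC/name tie-breaks and reports dAIC", {
  mk <- function(fam, ll, k, n = 100) {
    psmcea:::new_fit_result(family_cases()[[fam]], ll, n, as.integer(k),
                            NULL, TRUE)
  }
  one <- rank_models(list(mk("weibull", -50, 2)))
  expect_equal(one$delta_aic, 0)
  # equal loglik: fewer parameters first
  two <- rank_models(list(mk("generalized_gamma", -50, 3), mk("exponential", -50, 1)))
  expect_equal(two$family, c("exponential", "generalized_gamma"))
  expect_equal(two$delta_aic, c(0, 4))
  # independent arithmetic: AIC recomputed from stored logliks
  fits <- lapply(c("weibull", "loglogistic", "gamma"), function(f) {
    tt <- sample_event_times(tis_os(), 500, seed = 7)
    suppressWarnings(fit_mle(data.frame(time = tt, event = 1), f))
  })
  tab <- rank_models(fits)
  expect_equal(tab$aic, 2 * tab$k - 2 * tab$loglik)
  expect_true(all(diff(tab$aic) >= 0))
  expect_error(rank_models(list(mk("weibull", -50, 2, n = 100),
                                mk("gamma", -50, 2, n = 99))),
               "same data")
})

test_that("degenerate IPD is rejected", {
  expect_error(fit_mle(data.frame(time = c(1, 2), event = c(0, 0)), "weibull"),
               "at least 2 events")
  expect_error(fit_mle(data.frame(time = c(-1, 2), event = c(1, 1)), "weibull"),
               "> 0")
  expect_error(fit_mle(data.frame(x = 1), "weibull"), "columns")
})

test_that("IPD round-trips through CSV", {
  ipd <- data.frame(time = c(1.5, 2.25, 8), event = c(1L, 0L, 1L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_ipd(ipd, p)
  expect_equal(read_ipd(p), ipd)
})
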