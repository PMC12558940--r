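test_that("gamma moment matching: closed form, Monte-Carlo mean, degenerate limit", {
  expect_equal(moment_match_gamma(4, 2), c(shape = 4, rate = 1))
  set.seed(5)
  g <- moment_match_gamma(2467, 251.74)
  x <- rgamma(1e5, g[["shape"]], rate = g[["rate"]])
  expect_lt(abs(mean(x) - 2467), 3 * 251.74 / sqrt(1e5))
  expect_equal(sd(x), 251.74, tolerance = 0.02)
  g0 <- moment_match_gamma(10, 1e-5)
  expect_lt(sqrt(g0[["shape"]]) / g0[["rate"]] * g0[["rate"]] / g0[["rate"]], 1)
  x0 <- rgamma(1e4, g0[["shape"]], rate = g0[["rate"]])
  expect_lt(sd(x0), 1e-4)
  expect_error(moment_match_gamma(-1, 1), "> 0")
  expect_error(moment_match_gamma(1, 0), "> 0")
})

test_that("beta moment matching: symmetry, mean recovery, support errors", {
  b <- moment_match_beta(0.5, 0.1)
  expect_equal(b[["a"]], b[["b"]])
  se <- se_from_range(0.724, 0.884)
  b2 <- moment_match_beta(0.804, se)
  set.seed(6)
  x <- rbeta(1e5, b2[["a"]], b2[["b"]])
  expect_lt(abs(mean(x) - 0.804), 3 * se / sqrt(1e5))
  expect_error(moment_match_beta(0.5, 0.5), "too large")
  expect_error(moment_match_beta(1.2, 0.1), "\\(0, 1\\)")
})

test_that("tornado: unread and degenerate parameters have zero spread", {
  inp <- base_inputs()  # cisplatin partner: carboplatin price is never read
  tor <- owsa(inp, "psm")
  expect_equal(tor$spread[tor$parameter == "cost_carboplatin"], 0)
  # low = high = base for every parameter -> all spreads zero
  inp2 <- inp
  inp2$parameter_table$low <- inp2$parameter_table$base
  inp2$parameter_table$high <- inp2$parameter_table$base
  tor2 <- owsa(inp2, "psm")
  expect_equal(tor2$spread, rep(0, nrow(tor2)))
})

test_that("tornado entries re-evaluate the ICER at the range bounds", {
  inp <- base_inputs()
  tor <- owsa(inp, "markov", include_structural = TRUE)
  # independent re-evaluation for one parameter
  row <- tor[tor$parameter == "cost_bsc", ]
  lo <- evaluate_cea(inp, "markov", overrides = c(cost_bsc = 1973.65))
  hi <- evaluate_cea(inp, "markov", overrides = c(cost_bsc = 2960.47))
  expect_equal(row$icer_low, lo$incremental$icer)
  expect_equal(row$icer_high, hi$incremental$icer)
  expect_equal(row$spread, abs(row$icer_high - row$icer_low))
  # discount rate varied over 0-8% brackets the base-case ICER
  dr <- tor[tor$parameter == "discount_rate", ]
  base_icer <- attr(tor, "base_icer")
  expect_lt(min(dr$icer_low, dr$icer_high), base_icer)
  expect_gt(max(dr$icer_low, dr$icer_high), base_icer)
  # sorted by spread descending
  expect_true(all(diff(tor$spread) <= 0))
})

test_that("PSA is reproducible from its seed and degenerates to the base case", {
  inp <- base_inputs()
  inp$conventions$psa_survival <- FALSE
  a <- run_psa(inp, "psm", n_iter = 25, seed = 33)
  b <- run_psa(inp, "psm", n_iter = 25, seed = 33)
  expect_identical(a$draws, b$draws)
  expect_identical(a$sampled, b$sampled)
  # all-fixed parameters: the single draw equals the base-case deltas exactly
  inp2 <- inp
  inp2$parameter_table$psa_family <- "fixed"
  d <- run_psa(inp2, "psm", n_iter = 1, seed = 1)
  base <- evaluate_cea(inp2, "psm")$incremental
  expect_equal(d$draws$delta_cost, base$delta_cost)
  expect_equal(d$draws$delta_qaly, base$delta_qaly)
})

test_that("PSA with survival-parameter sampling is seed-stable end to end", {
  inp <- base_inputs()
  a <- run_psa(inp, "psm", n_iter = 8, seed = 99)
  b <- run_psa(inp, "psm", n_iter = 8, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_true(all(is.finite(a$draws$delta_cost)))
  expect_true(all(is.finite(a$draws$delta_qaly)))
})

test_that("sampled values stay inside their distribution supports", {
  inp <- base_inputs()
  inp$conventions$psa_survival <- FALSE
  psa <- run_psa(inp, "psm", n_iter = 200, seed = 12)
  pt <- inp$parameter_table
  beta_cols <- pt$name[pt$psa_family == "beta"]
  expect_true(all(psa$sampled[, beta_cols] >= 0 & psa$sampled[, beta_cols] <= 1))
  gamma_cols <- pt$name[pt$psa_family == "gamma"]
  expect_true(all(psa$sampled[, gamma_cols] > 0))
  fixed_cols <- pt$name[pt$psa_family == "fixed"]
  expect_equal(unname(psa$sampled[1, fixed_cols]),
               pt$base[match(fixed_cols, pt$name)])
})

test_that("acceptability: enumeration oracle and edge cases", {
  draws <- data.frame(delta_cost = c(-5, 10, 120, 50),
                      delta_qaly = c(0.1, 0.1, 0.001, -0.2))
  # wtp = 100: NMB = 15, 0, -119.9, -70 -> exactly one positive
  acc <- acceptability(draws, wtp = 100)
  expect_equal(acc$probability, 1 / 4)
  expect_true(acc$ci_low <= 0.25 && 0.25 <= acc$ci_high)
  dominant <- data.frame(delta_cost = rep(-1, 5), delta_qaly = rep(0.1, 5))
  expect_equal(acceptability(dominant, 0)$probability, 1)
  costly <- data.frame(delta_cost = rep(10, 5), delta_qaly = rep(0.1, 5))
  expect_equal(acceptability(costly, 0)$probability, 0)
})

test_that("CEAC of identical draws is a step at the draw's own ICER", {
  draws <- data.frame(delta_cost = rep(100, 10), delta_qaly = rep(0.001, 10))
  curve <- ceac(draws, wtp_grid = c(50000, 150000))
  expect_equal(curve$prob_ce, c(0, 1))
  expect_equal(ceac_crossing(curve, 0.5), 100000)
  expect_error(ceac(draws, c(2, 1)), "ascending")
})

test_that("CEAC is monotone when all draws gain QALYs, and the 50% crossing tracks the median ICER", {
  set.seed(8)
  draws <- data.frame(delta_cost = rnorm(400, 40000, 8000),
                      delta_qaly = runif(400, 0.1, 0.3))
  grid <- seq(0, 500000, by = 1000)
  curve <- ceac(draws, grid)
  expect_true(all(diff(curve$prob_ce) >= 0))
  med <- median(draws$delta_cost / draws$delta_qaly)
  expect_equal(ceac_crossing(curve, 0.5), med, tolerance = 1000 / med + 0.01)
  flat <- ceac(draws, c(1, 2))  # far below every draw ICER
  out <- ceac_crossing(flat, 0.5)
  expect_true(is.na(out))
})

test_that("survival_vcov returns positive-definite 2x2 covariances for all four curves", {
  inp <- base_inputs()
  vc <- survival_vcov(inp, seed = 3)
  for (arm in c("placebo", "tislelizumab")) {
    for (ep in c("os", "pfs")) {
      m <- vc[[arm]][[ep]]
      expect_equal(dim(m), c(2, 2))
      expect_true(all(eigen(m)$values > 0))
      expect_lt(sqrt(m[1, 1]), 0.2)  # log-scale SE plausible at n ~ 228
    }
  }
})
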