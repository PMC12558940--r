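flat_pfs_trace <- function(n = 6) {
  cohort_trace(times = (0:n) * 21 / (365.25 / 12),
               pfs = rep(1, n + 1), pd = rep(0, n + 1), dead = rep(0, n + 1),
               pd_entrants = rep(0, n + 1))
}

test_that("discount factor: cycle 0, one-year identity, r = 0", {
  s <- model_settings()
  expect_equal(discount_factor(0, s), 1.0)
  # k * cycle_length = 365 days -> one year of discounting
  s365 <- model_settings(cycle_length_days = 365 / 5)
  expect_equal(discount_factor(5, s365), 1 / 1.05, tolerance = 1e-12)
  expect_equal(discount_factor(0:50, s, rate = 0), rep(1, 51))
})

test_that("induction-cycle drug cost is the hand sum of the per-cycle prices", {
  inp <- base_inputs()
  tr <- flat_pfs_trace()
  v <- discount_factor(1:6, inp$settings)
  # default platinum partner: cisplatin
  co <- cost_trace(tr, inp$arms[[2]], inp)
  drug_cis <- 2507.06 + 1630.56 + 102.81
  expect_equal(co$per_cycle[1:4] - 600.58 * v[1:4], drug_cis * v[1:4],
               tolerance = 1e-10)
  # carboplatin switch
  inp2 <- inp
  inp2$conventions <- default_conventions(platinum = "carboplatin")
  co2 <- cost_trace(tr, inp2$arms[[2]], inp2)
  expect_equal(co2$per_cycle[1] - 600.58 * v[1], (2507.06 + 1630.56 + 521.03) * v[1],
               tolerance = 1e-10)
  # maintenance from cycle 5: study drug only (plus follow-up)
  expect_equal(co$per_cycle[5:6], (2507.06 + 600.58) * v[5:6], tolerance = 1e-10)
  # placebo arm pays no maintenance drug
  cop <- cost_trace(tr, inp$arms[[1]], inp)
  expect_equal(cop$per_cycle[5:6], 600.58 * v[5:6], tolerance = 1e-10)
})

test_that("one-off adverse-event cost equals the incidence-weighted hand sum", {
  inp <- base_inputs()
  co <- cost_trace(flat_pfs_trace(), inp$arms[[2]], inp)
  hand <- 0.5595 * 607.45 + 0.2379 * 3361.50 + 0.1938 * 7603.00 + 0.1630 * 3665.90
  expect_equal(unname(co$breakdown[["ae"]]), hand, tolerance = 1e-10)
  cop <- cost_trace(flat_pfs_trace(), inp$arms[[1]], inp)
  handp <- 0.5459 * 607.45 + 0.2751 * 3361.50 + 0.2533 * 7603.00 + 0.1659 * 3665.90
  expect_equal(unname(cop$breakdown[["ae"]]), handp, tolerance = 1e-10)
})

test_that("no PD occupancy means no BSC and no subsequent-therapy cost", {
  inp <- base_inputs()
  same <- list(os = tis_os(), pfs = tis_os())
  out <- evaluate_arm(inp, "tislelizumab", "psm", surv = same)
  expect_equal(unname(out$cost_breakdown[["bsc"]]), 0)
  expect_equal(unname(out$cost_breakdown[["subsequent_tx"]]), 0)
})

test_that("total cost is additive over the breakdown", {
  inp <- base_inputs()
  for (arm in c("placebo", "tislelizumab")) {
    out <- evaluate_arm(inp, arm, "psm")
    expect_equal(out$total_cost, sum(out$cost_breakdown),
                 tolerance = 1e-6)
  }
})

test_that("QALYs equal life-years in the utility-identity limit", {
  inp <- base_inputs()
  ov <- c(utility_pfs = 1, utility_pd = 1,
          disutility_neutropenia = 0, disutility_wbc_decreased = 0,
          disutility_thrombocytopenia = 0, disutility_anemia = 0)
  vals <- psmcea:::param_values(inp, ov)
  out <- evaluate_arm(inp, "tislelizumab", "psm", values = vals)
  expect_equal(out$qaly, out$ly, tolerance = 1e-12)
})

test_that("QALYs respect the utility bound and utilities are validated", {
  inp <- base_inputs()
  out <- evaluate_arm(inp, "tislelizumab", "psm")
  expect_lte(out$qaly, out$ly * 0.804)
  expect_gte(out$qaly, 0)
  vals <- psmcea:::param_values(inp, c(utility_pfs = 1.3))
  expect_error(evaluate_arm(inp, "tislelizumab", "psm", values = vals),
               "\\[0, 1\\]")
})

test_that("dead-from-cycle-1 cohort accrues only the entry-cycle QALY terms", {
  inp <- base_inputs()
  n <- 6
  tr <- cohort_trace(times = (0:n) * 21 / (365.25 / 12),
                     pfs = c(1, rep(0, n)), pd = rep(0, n + 1),
                     dead = c(0, rep(1, n)), pd_entrants = rep(0, n + 1))
  qa <- qaly_trace(tr, inp$arms[[1]], inp)
  # end-of-cycle membership: no occupancy survives to any cycle end
  expect_equal(unname(qa$breakdown[["pfs"]] + qa$breakdown[["pd"]]), 0)
  expect_equal(qa$total, unname(qa$breakdown[["ae_decrement"]]))
})

test_that("incremental: ratios, dominance flags and hand-computed NMB", {
  mk <- function(cost, qaly) {
    structure(list(total_cost = cost, qaly = qaly, ly = qaly),
              class = "econ_outcome")
  }
  r <- incremental(mk(1000, 1.0), mk(1100, 1.5), wtp = 268074)
  expect_equal(r$icer, 200)
  expect_equal(r$dominance, "none")
  r2 <- incremental(mk(1000, 1.0), mk(999, 1.1), wtp = 100)
  expect_equal(r2$dominance, "dominant")
  expect_true(is.na(r2$icer))
  r3 <- incremental(mk(1000, 1.0), mk(1200, 0.9), wtp = 100)
  expect_equal(r3$dominance, "dominated")
  r4 <- incremental(mk(1000, 1.0), mk(1500, 1.0), wtp = 100)
  expect_equal(r4$dominance, "undefined")
  expect_equal(r4$nmb, -500)
  r5 <- incremental(mk(0, 0), mk(41654.95, 0.2), wtp = 268074)
  expect_equal(r5$nmb, 268074 * 0.2 - 41654.95)
})

test_that("the ICER is invariant to a common scaling of both deltas", {
  mk <- function(cost, qaly) {
    structure(list(total_cost = cost, qaly = qaly, ly = qaly),
              class = "econ_outcome")
  }
  base <- incremental(mk(0, 0), mk(40000, 0.2))
  scaled <- incremental(mk(0, 0), mk(40000 * 3.7, 0.2 * 3.7))
  expect_equal(base$icer, scaled$icer)
})

test_that("raising the PFS utility raises both arms' QALYs and lowers the ICER", {
  inp <- base_inputs()
  lo <- evaluate_cea(inp, "psm", overrides = c(utility_pfs = 0.724))
  hi <- evaluate_cea(inp, "psm", overrides = c(utility_pfs = 0.884))
  expect_gt(hi$comparator$qaly, lo$comparator$qaly)
  expect_gt(hi$intervention$qaly, lo$intervention$qaly)
  expect_lt(hi$incremental$icer, lo$incremental$icer)
})

test_that("switching discounting off equals a zero discount rate", {
  inp <- base_inputs()
  off <- evaluate_cea(inp, "psm", overrides = c(discount_rate = 0))
  tr <- off$intervention$trace
  expect_equal(off$intervention$ly,
               life_years(tr, inp$settings, discounted = FALSE),
               tolerance = 1e-12)
})
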