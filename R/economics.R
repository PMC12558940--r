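#' Per-cycle discount factor
#'
#' Discrete discounting at cycle boundaries:
#' `(1 + r)^(-k * cycle_length_days / 365)`.
#'
#' @param k Cycle index (vectorised, `k >= 0`).
#' @param settings A [model_settings()].
#' @param rate Annual rate; defaults to the settings' rate.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(k, settings = model_settings(),
                            rate = settings$discount_annual) {
  stopifnot(all(k >= 0))
  (1 + rate)^(-(k * settings$cycle_length_days / 365))
}

# platinum unit cost per cycle under the configured partner
platinum_cost <- function(values, conv) {
  switch(conv$platinum,
    cisplatin   = values[["cost_cisplatin"]],
    carboplatin = values[["cost_carboplatin"]],
    mix         = conv$mix_cisplatin * values[["cost_cisplatin"]] +
                  (1 - conv$mix_cisplatin) * values[["cost_carboplatin"]])
}

#' Discounted cost accrual over a cohort trace
#'
#' Costs for cycle k (k = 1..N) are charged on state membership at the
#' cycle start (`cost_timing = "start"`, the default: drugs are dispensed on
#' day 1 of each cycle) or cycle end, and discounted with
#' [discount_factor()]. Components: induction regimen (study drug +
#' etoposide + platinum, cycles 1..4, charged per protocol to patients
#' alive at the cycle start under the default `induction_costing =
#' "alive"`); maintenance study drug while progression-free from cycle 5;
#' routine follow-up; best supportive care in PD; a one-off subsequent
#' platinum-etoposide course (`proportion * n_sub_cycles * unit costs`)
#' charged to new PD entrants; and one-off adverse-event costs
#' (`sum incidence * unit cost`) at model entry.
#'
#' @param trace A [cohort_trace()].
#' @param arm An arm specification from `inputs$arms`.
#' @param inputs A `model_inputs` object.
#' @param values Optional named parameter vector (defaults to base case);
#'   used by the sensitivity analyses to substitute sampled values.
#' @return List with `per_cycle` (discounted CNY per cycle 1..N), `total`,
#'   and `breakdown` (induction_drugs, maintenance_drug, subsequent_tx,
#'   bsc, followup, ae).
#' @export
cost_trace <- function(trace, arm, inputs, values = param_values(inputs)) {
  conv <- inputs$conventions
  r <- values[["discount_rate"]]
  n <- nrow(trace) - 1
  k <- seq_len(n)
  v <- discount_factor(k, inputs$settings, rate = r)

  occ <- function(col) occupancy_weights(trace[[col]],
    if (conv$cost_timing == "start") "start" else "none")
  pfs_c <- occ("pfs"); pd_c <- occ("pd")
  alive_c <- pfs_c + pd_c
  ent <- trace$pd_entrants[-1]

  plat <- platinum_cost(values, conv)
  chemo <- values[["cost_etoposide"]] + plat
  maint <- if (is.null(arm$maintenance_cost_param)) 0 else
    values[[arm$maintenance_cost_param]]
  ind <- k <= arm$induction_cycles
  ind_occ <- if (conv$induction_costing == "alive") alive_c else pfs_c
  fu_occ <- if (conv$followup_states == "alive") alive_c else pfs_c

  induction <- ifelse(ind, ind_occ * (maint + chemo), 0) * v
  maintenance <- ifelse(ind, 0, pfs_c * maint) * v
  followup <- fu_occ * values[["cost_followup"]] * v
  bsc <- pd_c * values[["cost_bsc"]] * v
  subp <- values[[arm$subsequent_param]]
  subsequent <- ent * subp * conv$n_sub_cycles * chemo * v
  ae <- sum(values[arm$ae$incidence_param] * values[arm$ae$cost_param])

  per_cycle <- induction + maintenance + followup + bsc + subsequent
  breakdown <- c(induction_drugs = sum(induction),
                 maintenance_drug = sum(maintenance),
                 subsequent_tx = sum(subsequent),
                 bsc = sum(bsc), followup = sum(followup), ae = ae)
  list(per_cycle = per_cycle, total = sum(per_cycle) + ae,
       breakdown = breakdown)
}

#' Discounted QALY accrual over a cohort trace
#'
#' Each cycle contributes
#' `(pfs * u_pfs + pd * u_pd) * cycle_length/365 * discount`, with state
#' membership at cycle end (`half_cycle = "none"`) or the half-cycle-
#' corrected average (`"standard"`). A one-off adverse-event decrement
#' `sum(incidence * disutility) * ae_duration_cycles * cycle_length/365`
#' is subtracted at model entry.
#'
#' @inheritParams cost_trace
#' @return List with `per_cycle` (discounted QALYs per cycle 1..N),
#'   `total`, and `breakdown` (pfs, pd, ae_decrement).
#' @export
qaly_trace <- function(trace, arm, inputs, values = param_values(inputs)) {
  conv <- inputs$conventions
  u_pfs <- values[["utility_pfs"]]
  u_pd <- values[["utility_pd"]]
  if (u_pfs < 0 || u_pfs > 1 || u_pd < 0 || u_pd > 1) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  r <- values[["discount_rate"]]
  n <- nrow(trace) - 1
  v <- discount_factor(seq_len(n), inputs$settings, rate = r)
  dt <- inputs$settings$cycle_length_days / 365
  pfs_o <- occupancy_weights(trace$pfs, conv$half_cycle)
  pd_o <- occupancy_weights(trace$pd, conv$half_cycle)
  q_pfs <- pfs_o * u_pfs * dt * v
  q_pd <- pd_o * u_pd * dt * v
  dec <- sum(values[arm$ae$incidence_param] * values[arm$ae$disutility_param]) *
    conv$ae_duration_cycles * dt
  list(per_cycle = q_pfs + q_pd,
       total = sum(q_pfs) + sum(q_pd) - dec,
       breakdown = c(pfs = sum(q_pfs), pd = sum(q_pd), ae_decrement = -dec))
}

#' Evaluate one arm: trace plus discounted costs, LYs and QALYs
#'
#' @inheritParams cost_trace
#' @param engine `"psm"` or `"markov"`.
#' @param surv Optional list `list(os = , pfs = )` of [surv_dist()] objects
#'   overriding the curves implied by `values` (used when the PSA samples
#'   survival parameters).
#' @return An `econ_outcome` list: `arm`, `total_cost`, `ly`, `qaly`,
#'   `cost_breakdown`, `qaly_breakdown`, `trace`.
#' @export
evaluate_arm <- function(inputs, arm, engine = c("psm", "markov"),
                         values = param_values(inputs), surv = NULL) {
  engine <- match.arg(engine)
  if (is.character(arm)) {
    idx <- match(arm, vapply(inputs$arms, `[[`, character(1), "name"))
    if (is.na(idx)) stop("unknown arm: ", arm, call. = FALSE)
    arm <- inputs$arms[[idx]]
  }
  if (is.null(surv)) {
    surv <- list(os = arm_surv_dist(arm, "os", values),
                 pfs = arm_surv_dist(arm, "pfs", values))
  }
  trace <- build_trace(surv$os, surv$pfs, inputs$settings, engine)
  co <- cost_trace(trace, arm, inputs, values)
  qa <- qaly_trace(trace, arm, inputs, values)
  r <- values[["discount_rate"]]
  n <- nrow(trace) - 1
  v <- discount_factor(seq_len(n), inputs$settings, rate = r)
  alive <- occupancy_weights(trace$pfs + trace$pd, inputs$conventions$half_cycle)
  ly <- sum(alive * v) * inputs$settings$cycle_length_days / 365
  structure(list(arm = arm$name, engine = engine,
                 total_cost = co$total, ly = ly, qaly = qa$total,
                 cost_breakdown = co$breakdown, qaly_breakdown = qa$breakdown,
                 trace = trace),
            class = "econ_outcome")
}

#' @export
print.econ_outcome <- function(x, ...) {
  cat(sprintf("<econ_outcome> %s (%s): cost CNY %.2f, %.4f LYs, %.4f QALYs\n",
              x$arm, x$engine, x$total_cost, x$ly, x$qaly))
  invisible(x)
}

#' Incremental cost-effectiveness comparison
#'
#' @param comparator,intervention `econ_outcome` objects from
#'   [evaluate_arm()] under the same settings.
#' @param wtp Willingness-to-pay threshold (CNY/QALY).
#' @return An `icer_result` list: `delta_cost`, `delta_qaly`, `delta_ly`,
#'   `icer` (`NA` with a `dominance` flag when the signs make the ratio
#'   meaningless), `dominance` (`"none"`, `"dominant"`, `"dominated"`,
#'   `"undefined"`), `nmb` (`wtp * delta_qaly - delta_cost`), `wtp`.
#' @export
incremental <- function(comparator, intervention, wtp = 268074) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$qaly - comparator$qaly
  dl <- intervention$ly - comparator$ly
  dominance <- "none"
  icer <- NA_real_
  if (dq == 0) {
    dominance <- "undefined"
  } else if (dc < 0 && dq > 0) {
    dominance <- "dominant"
  } else if (dc > 0 && dq < 0) {
    dominance <- "dominated"
  } else {
    icer <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
                 icer = icer, dominance = dominance,
                 nmb = wtp * dq - dc, wtp = wtp),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> dCost = %.2f, dQALY = %.4f -> %s (NMB at %g: %.2f)\n",
              x$delta_cost, x$delta_qaly,
              if (x$dominance == "none") sprintf("ICER %.2f", x$icer)
              else x$dominance, x$wtp, x$nmb))
  invisible(x)
}

#' Evaluate both arms and the incremental comparison
#'
#' The central base-case evaluation: builds both arms' traces under the
#' chosen engine, accrues discounted costs and QALYs, and compares the
#' intervention (second arm) with the comparator (first arm).
#'
#' @inheritParams evaluate_arm
#' @param overrides Named vector of parameter overrides.
#' @param surv Optional list `list(comparator =, intervention =)`, each
#'   `list(os =, pfs =)`, overriding the survival curves.
#' @return List with `comparator`, `intervention` (econ outcomes) and
#'   `incremental` (an `icer_result`).
#' @export
evaluate_cea <- function(inputs, engine = c("psm", "markov"),
                         overrides = NULL, surv = NULL) {
  engine <- match.arg(engine)
  values <- param_values(inputs, overrides)
  comp <- evaluate_arm(inputs, inputs$arms[[1]], engine, values,
                       surv = surv$comparator)
  intv <- evaluate_arm(inputs, inputs$arms[[2]], engine, values,
                       surv = surv$intervention)
  list(comparator = comp, intervention = intv,
       incremental = incremental(comp, intv, inputs$settings$wtp))
}
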