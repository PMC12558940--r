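#' Cohort trace constructor
#'
#' Per-cycle occupancy of the three mutually exclusive health states
#' (progression-free, progressed disease, dead) plus the probability mass
#' newly entering PD each cycle. Row `k` holds occupancy at cycle-end time
#' `t_k = k * cycle_length` (months); row 0 is the model start `(1, 0, 0)`.
#'
#' @param times Numeric vector of cycle-end times (months).
#' @param pfs,pd,dead State occupancy per cycle; must sum to 1.
#' @param pd_entrants Probability mass newly entering PD per cycle.
#' @return A `cohort_trace` data frame with columns
#'   `cycle, time_months, pfs, pd, dead, pd_entrants`.
#' @export
cohort_trace <- function(times, pfs, pd, dead, pd_entrants) {
  tr <- data.frame(cycle = seq_along(times) - 1L, time_months = times,
                   pfs = pfs, pd = pd, dead = dead, pd_entrants = pd_entrants)
  class(tr) <- c("cohort_trace", "data.frame")
  validate_trace(tr)
  tr
}

validate_trace <- function(tr, tol = 1e-12) {
  with(tr, {
    if (max(abs(pfs + pd + dead - 1)) > tol) {
      stop("trace occupancy does not sum to 1", call. = FALSE)
    }
    if (any(pfs < -tol | pd < -tol | dead < -tol)) {
      stop("negative state occupancy", call. = FALSE)
    }
    if (any(diff(dead) < -tol)) stop("dead occupancy must be non-decreasing",
                                     call. = FALSE)
  })
  if (abs(tr$pfs[1] - 1) > tol || abs(tr$pd[1]) > tol || abs(tr$dead[1]) > tol) {
    stop("trace must start at (pfs, pd, dead) = (1, 0, 0)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a partitioned-survival cohort trace
#'
#' State occupancy is read directly off the two survival curves at each
#' cycle-end time: the progression-free share is `S_PFS(t)`, the dead share
#' is `1 - S_OS(t)`, and the progressed-disease share is the difference
#' `S_OS(t) - S_PFS(t)`. If the extrapolated PFS curve crosses above the OS
#' curve the PD share is clamped to zero with a warning naming the first
#' crossing time.
#'
#' New PD entrants in cycle k are the net PD increase plus the PD deaths
#' replaced during the cycle, with deaths attributed to PD in proportion to
#' its share of the alive states at the cycle start:
#' `max(0, pd_k - pd_{k-1} + (dead_k - dead_{k-1}) * pd_{k-1} / (pd_{k-1} + pfs_{k-1}))`.
#'
#' @param os,pfs [surv_dist()] objects for overall and progression-free
#'   survival.
#' @param settings A [model_settings()].
#' @return A [cohort_trace()] with `n_cycles(settings) + 1` rows.
#' @examples
#' os <- surv_dist("loglogistic", scale = 16.50756, shape = 1.70402)
#' pfs <- surv_dist("loglogistic", scale = 5.6371, shape = 1.81906)
#' tr <- build_psm_trace(os, pfs, model_settings())
#' head(tr)
#' @export
build_psm_trace <- function(os, pfs, settings = model_settings()) {
  stopifnot(inherits(os, "surv_dist"), inherits(pfs, "surv_dist"))
  validate_settings(settings)
  times <- cycle_times(settings)
  s_os <- survival_at(os, times)
  s_pfs <- survival_at(pfs, times)
  cross <- s_pfs > s_os + 1e-12
  if (any(cross)) {
    warning(sprintf(
      "PFS curve exceeds OS curve from t = %.3f months; PD clamped to 0",
      times[which(cross)[1]]), call. = FALSE)
  }
  pd <- pmax(0, s_os - s_pfs)
  pfs_occ <- pmin(s_pfs, s_os)  # consistent with the clamp
  dead <- 1 - pfs_occ - pd
  pd_prev <- c(0, pd[-length(pd)])
  pfs_prev <- c(1, pfs_occ[-length(pfs_occ)])
  dead_prev <- c(0, dead[-length(dead)])
  alive_prev <- pd_prev + pfs_prev
  ent <- pmax(0, pd - pd_prev +
                (dead - dead_prev) * ifelse(alive_prev > 0, pd_prev / alive_prev, 0))
  ent[1] <- 0
  cohort_trace(times, pfs_occ, pd, dead, ent)
}

cycle_times <- function(settings) {
  (0:n_cycles(settings)) * settings$cycle_length_days / DAYS_PER_MONTH
}

#' Discounted life-years of a cohort trace
#'
#' Sums alive occupancy over cycles 1..N, each cycle contributing
#' `alive * cycle_length/365 years * (1 + r)^(-k * cycle_length/365)`.
#' Occupancy is taken at cycle end (`half_cycle = "none"`) or as the
#' cycle-start/cycle-end average (`half_cycle = "standard"`). With
#' `discounted = FALSE` (or `r = 0`) no discounting is applied.
#'
#' @param trace A [cohort_trace()].
#' @param settings A [model_settings()].
#' @param discounted Apply the annual discount rate?
#' @param half_cycle Occupancy rule, `"none"` or `"standard"`.
#' @return Life-years (scalar).
#' @export
life_years <- function(trace, settings = model_settings(), discounted = TRUE,
                       half_cycle = c("none", "standard")) {
  half_cycle <- match.arg(half_cycle)
  alive <- trace$pfs + trace$pd
  occ <- occupancy_weights(alive, half_cycle)
  v <- discount_factor(seq_along(occ), settings,
                       rate = if (discounted) settings$discount_annual else 0)
  sum(occ * v) * settings$cycle_length_days / 365
}

# per-cycle occupancy for cycles 1..N under the chosen membership rule
occupancy_weights <- function(x, rule) {
  n <- length(x)
  switch(rule,
    none = x[-1],
    start = x[-n],
    standard = 0.5 * (x[-1] + x[-n]))
}

#' Export a cohort trace to CSV
#'
#' @param trace A [cohort_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
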