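#' Derive per-cycle transition probabilities from marginal survival curves
#'
#' The Markov engine needs conditional per-cycle transition probabilities;
#' the trial evidence is two marginal curves. For cycle k (spanning
#' `t_k` to `t_{k+1}`):
#' \itemize{
#'   \item conditional death probability
#'     `q_d(k) = 1 - S_OS(t_{k+1}) / S_OS(t_k)`,
#'   \item conditional PFS-exit probability
#'     `q_e(k) = 1 - S_PFS(t_{k+1}) / S_PFS(t_k)`,
#'   \item `p_pfs_dead = min(q_d, q_e)`, `p_pfs_pd = max(0, q_e - q_d)`,
#'     `p_pd_dead = q_d`.
#' }
#' Both alive states share the marginal OS conditional hazard (no
#' state-specific mortality is reported), which makes the Markov dead series
#' reproduce `1 - S_OS` exactly and the two engines agree on occupancy.
#' Once `S_OS(t_k)` underflows to zero, death is pinned absorbing.
#'
#' @inheritParams build_psm_trace
#' @return A `transition_schedule` data frame with columns
#'   `cycle, p_pfs_pd, p_pfs_dead, p_pd_dead`, one row per cycle 0..N-1
#'   (row k governs the transition from `t_k` to `t_{k+1}`).
#' @export
derive_transitions <- function(os, pfs, settings = model_settings()) {
  stopifnot(inherits(os, "surv_dist"), inherits(pfs, "surv_dist"))
  validate_settings(settings)
  times <- cycle_times(settings)
  s_os <- survival_at(os, times)
  s_pfs <- survival_at(pfs, times)
  n <- length(times) - 1
  i <- seq_len(n)
  q_d <- ifelse(s_os[i] > 0, 1 - s_os[i + 1] / s_os[i], 1)
  q_e <- ifelse(s_pfs[i] > 0, 1 - s_pfs[i + 1] / s_pfs[i], 1)
  q_d <- pmin(pmax(q_d, 0), 1)
  q_e <- pmin(pmax(q_e, 0), 1)
  sched <- data.frame(cycle = i - 1L,
                      p_pfs_pd = pmax(0, q_e - q_d),
                      p_pfs_dead = pmin(q_d, q_e),
                      p_pd_dead = q_d)
  class(sched) <- c("transition_schedule", "data.frame")
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched) {
  with(sched, {
    if (any(p_pfs_pd < 0 | p_pfs_dead < 0 | p_pd_dead < 0) ||
        any(p_pfs_pd > 1 | p_pfs_dead > 1 | p_pd_dead > 1)) {
      stop("transition probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (any(p_pfs_pd + p_pfs_dead > 1 + 1e-12)) {
      stop("PFS row transition probabilities sum above 1", call. = FALSE)
    }
  })
  invisible(TRUE)
}

#' Iterate a Markov cohort trace from a transition schedule
#'
#' Advances the cohort `(pfs, pd, dead)` from `(1, 0, 0)` through the
#' per-cycle transition matrices; death is absorbing. PD entrants in cycle
#' k are `pfs_{k-1} * p_pfs_pd(k-1)`.
#'
#' @param schedule A `transition_schedule` from [derive_transitions()].
#' @param settings A [model_settings()] whose cycle count matches the
#'   schedule length.
#' @return A [cohort_trace()] with `nrow(schedule) + 1` rows.
#' @export
build_markov_trace <- function(schedule, settings = model_settings()) {
  validate_schedule(schedule)
  n <- nrow(schedule)
  pfs <- pd <- dead <- ent <- numeric(n + 1)
  pfs[1] <- 1
  for (k in seq_len(n)) {
    p_pd <- schedule$p_pfs_pd[k]
    p_fd <- schedule$p_pfs_dead[k]
    p_dd <- schedule$p_pd_dead[k]
    ent[k + 1] <- pfs[k] * p_pd
    pfs[k + 1] <- pfs[k] * (1 - p_pd - p_fd)
    pd[k + 1] <- pd[k] * (1 - p_dd) + ent[k + 1]
    dead[k + 1] <- dead[k] + pfs[k] * p_fd + pd[k] * p_dd
  }
  times <- (0:n) * settings$cycle_length_days / DAYS_PER_MONTH
  cohort_trace(times, pfs, pd, dead, ent)
}

#' Export a transition schedule to CSV
#'
#' @param schedule A `transition_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' Build the cohort trace for one arm under either engine
#'
#' @param os,pfs [surv_dist()] curves.
#' @param settings A [model_settings()].
#' @param engine `"psm"` (partitioned survival) or `"markov"`.
#' @return A [cohort_trace()].
#' @export
build_trace <- function(os, pfs, settings = model_settings(),
                        engine = c("psm", "markov")) {
  engine <- match.arg(engine)
  if (engine == "psm") {
    build_psm_trace(os, pfs, settings)
  } else {
    build_markov_trace(derive_transitions(os, pfs, settings), settings)
  }
}
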