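#' Specification for a synthetic trial dataset
#'
#' Describes a two-arm trial whose OS and PFS event times follow the
#' log-logistic laws of the packaged base case, so the fitting stage can be
#' exercised without the original Kaplan-Meier figures. Defaults mirror the
#' trial scale: 457 patients randomised 1:1 (228/229), administrative
#' censoring at 40 months of follow-up, and a light random loss to
#' follow-up of 0.005 events/month. The data are synthetic stand-ins for
#' the reconstructed curves, not patient records.
#'
#' @param n_per_arm Integer vector of length 2 (comparator, intervention).
#' @param curves Nested list `[[arm]][[endpoint]]` of [surv_dist()]
#'   objects; defaults to the packaged base-case curves of `inputs`.
#' @param admin_censor_time Administrative censoring time (months).
#' @param random_censor_rate Exponential loss-to-follow-up rate
#'   (events/month, >= 0).
#' @param copula_rho Gaussian-copula correlation linking each subject's
#'   PFS and OS uniforms (marginals are unaffected).
#' @param seed Integer seed.
#' @param inputs `model_inputs` supplying the default curves.
#' @return A `trial_sim_spec` list.
#' @export
trial_sim_spec <- function(n_per_arm = c(229L, 228L), curves = NULL,
                           admin_censor_time = 40, random_censor_rate = 0.005,
                           copula_rho = 0.5, seed = 1L,
                           inputs = default_inputs()) {
  if (is.null(curves)) {
    vals <- param_values(inputs)
    curves <- lapply(inputs$arms, function(a) {
      list(os = arm_surv_dist(a, "os", vals),
           pfs = arm_surv_dist(a, "pfs", vals))
    })
    names(curves) <- vapply(inputs$arms, `[[`, character(1), "name")
  }
  stopifnot(length(n_per_arm) == length(curves), all(n_per_arm >= 2),
            admin_censor_time > 0, random_censor_rate >= 0,
            copula_rho > -1, copula_rho < 1)
  structure(list(n_per_arm = as.integer(n_per_arm), curves = curves,
                 admin_censor_time = admin_censor_time,
                 random_censor_rate = random_censor_rate,
                 copula_rho = copula_rho, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

#' Sample event times by inverse-CDF
#'
#' Draws `T = surv_quantile(dist, U)` with `U ~ Uniform(0, 1)`;
#' reproducible from `seed`.
#'
#' @param dist A [surv_dist()].
#' @param n Number of draws.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return Numeric vector of event times (months).
#' @export
sample_event_times <- function(dist, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  surv_quantile(dist, stats::runif(n))
}

#' Generate synthetic individual patient data
#'
#' For each subject, correlated uniforms (Gaussian copula, `copula_rho`)
#' drive the inverse-CDF draws of the OS and PFS event times; PFS times are
#' capped at the subject's OS time (progression cannot follow death). The
#' observed time is the minimum of the event time, an exponential random
#' censoring time and the administrative censoring time, with the event
#' indicator set accordingly.
#'
#' @param spec A [trial_sim_spec()].
#' @return Data frame `arm, endpoint, time, event`, one row per subject and
#'   endpoint; `time` in months, `event` 1 = event, 0 = censored.
#' @export
generate_ipd <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  set.seed(spec$seed)
  rho <- spec$copula_rho
  out <- list()
  for (j in seq_along(spec$curves)) {
    arm_nm <- names(spec$curves)[j]
    n <- spec$n_per_arm[j]
    z_os <- stats::rnorm(n)
    z_pfs <- rho * z_os + sqrt(1 - rho^2) * stats::rnorm(n)
    t_os <- surv_quantile(spec$curves[[j]]$os, stats::pnorm(z_os))
    t_pfs <- pmin(surv_quantile(spec$curves[[j]]$pfs, stats::pnorm(z_pfs)), t_os)
    cens <- if (spec$random_censor_rate > 0) {
      stats::rexp(n, spec$random_censor_rate)
    } else {
      rep(Inf, n)
    }
    cens <- pmin(cens, spec$admin_censor_time)
    for (ep in c("os", "pfs")) {
      t_ev <- if (ep == "os") t_os else t_pfs
      obs <- pmin(t_ev, cens)
      out[[length(out) + 1]] <- data.frame(
        arm = arm_nm, endpoint = ep,
        time = pmax(obs, .Machine$double.eps),
        event = as.integer(t_ev <= cens), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
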