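# shared fixtures, built in code

base_inputs <- function() default_inputs()

# the four packaged base-case curves
tis_os <- function() surv_dist("loglogistic", scale = 16.50756, shape = 1.70402)
tis_pfs <- function() surv_dist("loglogistic", scale = 5.6371, shape = 1.81906)
plc_os <- function() surv_dist("loglogistic", scale = 14.9796, shape = 1.9698)
plc_pfs <- function() surv_dist("loglogistic", scale = 4.94181, shape = 2.51144)

# one representative parameter set per family, used in property loops
family_cases <- function() {
  list(
    exponential = surv_dist("exponential", rate = 0.08),
    weibull = surv_dist("weibull", shape = 1.4, scale = 14),
    gompertz = surv_dist("gompertz", shape = 0.05, rate = 0.04),
    gamma = surv_dist("gamma", shape = 1.8, rate = 0.12),
    generalized_gamma = surv_dist("generalized_gamma", mu = 2.4, sigma = 0.8, Q = 0.6),
    loglogistic = surv_dist("loglogistic", scale = 16.50756, shape = 1.70402),
    lognormal = surv_dist("lognormal", meanlog = 2.4, sdlog = 0.9))
}

# short-horizon settings for cheap engine tests
short_settings <- function() model_settings(horizon_years = 2)

# closed-form log-logistic survivor function, written out independently
ll_surv <- function(t, alpha, beta) 1 / (1 + (t / alpha)^beta)
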