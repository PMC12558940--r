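#' Parametric survival distributions
#'
#' Constructor for the parametric survival laws used to extrapolate the
#' trial overall-survival (OS) and progression-free-survival (PFS) curves.
#' Seven families are supported: `exponential`, `weibull`, `gompertz`,
#' `gamma`, `generalized_gamma`, `loglogistic` and `lognormal`.
#'
#' Time is measured in months throughout. Parameterisations:
#' \describe{
#'   \item{exponential}{`rate` (events/month); `S(t) = exp(-rate * t)`.}
#'   \item{weibull}{`shape`, `scale` as in [stats::pweibull()].}
#'   \item{gompertz}{`shape` (1/month, may be negative), `rate` (> 0) as in
#'     [flexsurv::pgompertz()]. A negative shape implies a survival plateau
#'     `S(Inf) > 0`; allowed with a warning.}
#'   \item{gamma}{`shape`, `rate` as in [stats::pgamma()].}
#'   \item{generalized_gamma}{`mu`, `sigma` (> 0), `Q` as in
#'     [flexsurv::pgengamma()] (Prentice parameterisation).}
#'   \item{loglogistic}{`scale` (alpha, months; equals the median) and
#'     `shape` (beta, dimensionless): `S(t) = 1 / (1 + (t/scale)^shape)`.
#'     This is the parameterisation in which the published scale/shape pairs
#'     for the trial arms are stated.}
#'   \item{lognormal}{`meanlog`, `sdlog` as in [stats::plnorm()].}
#' }
#'
#' @param family Character, one of the seven family names above.
#' @param ... Named numeric parameters for the family (see Details).
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("loglogistic", scale = 16.50756, shape = 1.70402)
#' survival_at(d, 12)
#' @export
surv_dist <- function(family, ...) {
  family <- match.arg(family, surv_families())
  params <- c(...)
  need <- surv_param_names(family)
  if (!setequal(names(params), need)) {
    stop(sprintf("family '%s' needs parameters: %s (got: %s)",
                 family, paste(need, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  }
  params <- params[need]
  check_surv_params(family, params)
  structure(list(family = family, params = params), class = "surv_dist")
}

#' @export
print.surv_dist <- function(x, ...) {
  cat(sprintf("<surv_dist> %s(%s)\n", x$family,
              paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}

#' Supported survival families
#' @return Character vector of family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gompertz", "gamma",
    "generalized_gamma", "loglogistic", "lognormal")
}

surv_param_names <- function(family) {
  switch(family,
    exponential       = "rate",
    weibull           = c("shape", "scale"),
    gompertz          = c("shape", "rate"),
    gamma             = c("shape", "rate"),
    generalized_gamma = c("mu", "sigma", "Q"),
    loglogistic       = c("scale", "shape"),
    lognormal         = c("meanlog", "sdlog"))
}

# which parameters must be strictly positive (optimised on the log scale)
surv_positive_params <- function(family) {
  switch(family,
    exponential       = "rate",
    weibull           = c("shape", "scale"),
    gompertz          = "rate",       # shape may be negative
    gamma             = c("shape", "rate"),
    generalized_gamma = "sigma",      # mu, Q unrestricted
    loglogistic       = c("scale", "shape"),
    lognormal         = "sdlog")      # meanlog unrestricted
}

check_surv_params <- function(family, params) {
  if (any(!is.finite(params))) stop("non-finite survival parameter", call. = FALSE)
  pos <- surv_positive_params(family)
  bad <- params[pos] <= 0
  if (any(bad)) {
    stop(sprintf("parameter(s) %s of %s must be > 0",
                 paste(pos[bad], collapse = ", "), family), call. = FALSE)
  }
  if (family == "gompertz" && params[["shape"]] < 0) {
    warning(sprintf(
      "Gompertz shape %g < 0: survival plateaus at S(Inf) = %g > 0",
      params[["shape"]], exp(params[["rate"]] / params[["shape"]])),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Survival function S(t)
#'
#' @param dist A [surv_dist()].
#' @param t Time(s) in months, `t >= 0` (vectorised).
#' @return Survival probabilities in `[0, 1]`, with `S(0) = 1`.
#' @export
survival_at <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- dist$params
  switch(dist$family,
    exponential       = exp(-p[["rate"]] * t),
    weibull           = stats::pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    gompertz          = flexsurv::pgompertz(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    gamma             = stats::pgamma(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]], lower.tail = FALSE),
    loglogistic       = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal         = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE))
}

#' Density f(t)
#'
#' @inheritParams survival_at
#' @param log Return the log density?
#' @return Density values (or log densities).
#' @export
density_at <- function(dist, t, log = FALSE) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- dist$params
  switch(dist$family,
    exponential       = stats::dexp(t, p[["rate"]], log = log),
    weibull           = stats::dweibull(t, p[["shape"]], p[["scale"]], log = log),
    gompertz          = flexsurv::dgompertz(t, p[["shape"]], p[["rate"]], log = log),
    gamma             = stats::dgamma(t, p[["shape"]], p[["rate"]], log = log),
    generalized_gamma = flexsurv::dgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]], log = log),
    loglogistic       = dllogis_sc(t, p[["scale"]], p[["shape"]], log = log),
    lognormal         = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]], log = log))
}

# log-logistic density in the (scale alpha, shape beta) parameterisation
dllogis_sc <- function(t, scale, shape, log = FALSE) {
  lx <- log(shape) - log(scale) + (shape - 1) * (log(t) - log(scale)) -
    2 * log1p((t / scale)^shape)
  lx[t == 0] <- if (shape == 1) log(1 / scale) else if (shape < 1) Inf else -Inf
  if (log) lx else exp(lx)
}

#' Survival quantile (inverse of the survivor function's complement)
#'
#' Returns the time `t` with `P(T <= t) = p`, i.e. `S(t) = 1 - p`.
#'
#' @inheritParams survival_at
#' @param p Probability in (0, 1) (vectorised).
#' @return Time(s) in months.
#' @export
surv_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  q <- dist$params
  switch(dist$family,
    exponential       = stats::qexp(p, q[["rate"]]),
    weibull           = stats::qweibull(p, q[["shape"]], q[["scale"]]),
    gompertz          = flexsurv::qgompertz(p, q[["shape"]], q[["rate"]]),
    gamma             = stats::qgamma(p, q[["shape"]], q[["rate"]]),
    generalized_gamma = flexsurv::qgengamma(p, q[["mu"]], q[["sigma"]], q[["Q"]]),
    loglogistic       = q[["scale"]] * (p / (1 - p))^(1 / q[["shape"]]),
    lognormal         = stats::qlnorm(p, q[["meanlog"]], q[["sdlog"]]))
}

# days per month used to convert cycle lengths to the month time scale
DAYS_PER_MONTH <- 365.25 / 12
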