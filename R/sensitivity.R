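#' Standard error reconstructed from a sensitivity range
#'
#' Published ranges (highest/lowest bid price, otherwise +/-20% for costs
#' and +/-10% for utilities and probabilities) are read as approximate 95%
#' intervals: `se = (high - low) / (2 * 1.96)`.
#'
#' @param low,high Range bounds.
#' @return Standard error (0 when `low == high`).
#' @export
se_from_range <- function(low, high) (high - low) / (2 * 1.96)

#' Moment-matched gamma parameters
#'
#' @param mean,se Target mean and standard error, both > 0.
#' @return Named vector `c(shape, rate)` with `shape = mean^2/se^2`,
#'   `rate = mean/se^2`.
#' @export
moment_match_gamma <- function(mean, se) {
  if (mean <= 0 || se <= 0) stop("mean and se must be > 0", call. = FALSE)
  c(shape = mean^2 / se^2, rate = mean / se^2)
}

#' Moment-matched beta parameters
#'
#' @param mean Target mean in (0, 1).
#' @param se Target standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @return Named vector `c(a, b)`.
#' @export
moment_match_beta <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)", call. = FALSE)
  if (se <= 0) stop("se must be > 0", call. = FALSE)
  if (se^2 >= mean * (1 - mean)) {
    stop("se too large for a beta distribution with this mean", call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

sample_parameter <- function(n, family, base, low, high) {
  se <- se_from_range(low, high)
  if (family == "fixed" || se == 0) return(rep(base, n))
  if (family == "gamma") {
    g <- moment_match_gamma(base, se)
    stats::rgamma(n, shape = g[["shape"]], rate = g[["rate"]])
  } else {
    b <- moment_match_beta(base, se)
    stats::rbeta(n, b[["a"]], b[["b"]])
  }
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the ICER with each parameter at its low and high bound, all
#' others held at base. By default the tornado covers the sampled
#' (gamma/beta) parameters; `include_structural = TRUE` adds the
#' fixed-in-PSA methodological parameters with a published range (the
#' discount rate), which the package otherwise reports as a scenario
#' range. An engine failure at an extreme is flagged on the entry, not
#' dropped.
#'
#' @param inputs A `model_inputs` object.
#' @param engine `"psm"` or `"markov"`.
#' @param include_structural Also vary fixed-family parameters with
#'   `low < high`?
#' @return A `tornado` data frame `parameter, icer_low, icer_high, spread,
#'   flagged`, sorted by spread descending (ties by name), with the
#'   base-case ICER in `attr(, "base_icer")`.
#' @export
owsa <- function(inputs, engine = c("psm", "markov"),
                 include_structural = FALSE) {
  engine <- match.arg(engine)
  base <- evaluate_cea(inputs, engine)$incremental$icer
  pt <- inputs$parameter_table
  vary <- pt$psa_family %in% c("gamma", "beta")
  if (include_structural) vary <- vary | (pt$psa_family == "fixed" & pt$low < pt$high)
  rows <- lapply(which(vary), function(i) {
    icer_at <- function(val) {
      tryCatch(evaluate_cea(inputs, engine,
                            overrides = stats::setNames(val, pt$name[i])
                            )$incremental$icer,
               error = function(e) NA_real_)
    }
    lo <- icer_at(pt$low[i]); hi <- icer_at(pt$high[i])
    data.frame(parameter = pt$name[i], icer_low = lo, icer_high = hi,
               spread = abs(hi - lo), flagged = is.na(lo) || is.na(hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spread[out$flagged] <- NA_real_
  out <- out[order(-out$spread, out$parameter, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  attr(out, "base_icer") <- base
  attr(out, "engine") <- engine
  out
}

#' Covariance of the fitted survival parameters from synthetic IPD
#'
#' The published inputs give the log-logistic (scale, shape) point
#' estimates but no uncertainty. This helper reconstructs individual
#' patient data at the trial's sample size from those curves (see
#' [generate_ipd()]), refits the log-logistic by maximum likelihood, and
#' returns each curve's 2x2 covariance of `(log scale, log shape)` for the
#' PSA's multivariate-normal sampling. The means used in sampling remain
#' the published point estimates.
#'
#' @param inputs A `model_inputs` object.
#' @param seed Integer seed for the IPD reconstruction.
#' @return Nested list `[[arm]][[endpoint]]` of 2x2 covariance matrices.
#' @export
survival_vcov <- function(inputs, seed = 1L) {
  spec <- trial_sim_spec(inputs = inputs, seed = seed)
  ipd <- generate_ipd(spec)
  out <- list()
  for (a in inputs$arms) {
    out[[a$name]] <- list()
    for (ep in c("os", "pfs")) {
      sub <- ipd[ipd$arm == a$name & ipd$endpoint == ep, c("time", "event")]
      fit <- fit_mle(sub, "loglogistic")
      vc <- fit$vcov_log
      if (is.null(vc)) stop("could not obtain survival parameter covariance",
                            call. = FALSE)
      out[[a$name]][[ep]] <- vc
    }
  }
  out
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Samples every non-fixed input parameter independently from its
#' moment-matched distribution (gamma for costs, beta for probabilities
#' and utilities, standard errors from [se_from_range()]); when
#' `psa_survival` is enabled the four log-logistic (scale, shape) pairs
#' are additionally drawn from a multivariate normal on the log scale,
#' centred on the published estimates with covariance from
#' [survival_vcov()]. Each draw runs both arms through the chosen engine
#' and records the incremental cost and QALYs. Fully reproducible from
#' `seed`.
#'
#' @param inputs A `model_inputs` object.
#' @param engine `"psm"` or `"markov"`.
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param seed Integer seed (required).
#' @param surv_vcov Optional precomputed [survival_vcov()] result; computed
#'   (seeded from `seed`) when `NULL` and `psa_survival` is enabled.
#' @return A `psa_result` list: `draws` (data frame `draw, delta_cost,
#'   delta_qaly`), `sampled` (audit matrix of sampled parameter values),
#'   `engine`, `wtp`, `seed`.
#' @export
run_psa <- function(inputs, engine = c("psm", "markov"), n_iter = 1000,
                    seed, surv_vcov = NULL) {
  engine <- match.arg(engine)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_iter >= 1)
  conv <- inputs$conventions
  if (conv$psa_survival && is.null(surv_vcov)) {
    surv_vcov <- survival_vcov(inputs, seed = seed + 1L)
  }
  set.seed(seed)
  pt <- inputs$parameter_table
  sampled <- vapply(seq_len(nrow(pt)), function(i) {
    sample_parameter(n_iter, pt$psa_family[i], pt$base[i], pt$low[i], pt$high[i])
  }, numeric(n_iter))
  if (n_iter == 1) sampled <- matrix(sampled, nrow = 1)
  colnames(sampled) <- pt$name

  surv_draws <- NULL
  if (conv$psa_survival) {
    base_vals <- param_values(inputs)
    surv_draws <- list()
    for (a in inputs$arms) {
      surv_draws[[a$name]] <- list()
      for (ep in c("os", "pfs")) {
        mu <- log(c(base_vals[[a[[ep]]$scale_param]],
                    base_vals[[a[[ep]]$shape_param]]))
        vc <- surv_vcov[[a$name]][[ep]]
        z <- matrix(stats::rnorm(2 * n_iter), n_iter, 2) %*% chol(vc)
        surv_draws[[a$name]][[ep]] <-
          exp(sweep(z, 2, mu, "+"))  # columns: scale, shape
      }
    }
  }

  dc <- dq <- numeric(n_iter)
  comp_name <- inputs$arms[[1]]$name
  intv_name <- inputs$arms[[2]]$name
  for (i in seq_len(n_iter)) {
    ov <- sampled[i, ]
    surv <- NULL
    if (!is.null(surv_draws)) {
      mk <- function(arm_nm, ep) {
        p <- unname(surv_draws[[arm_nm]][[ep]][i, ])
        surv_dist("loglogistic", scale = p[1], shape = p[2])
      }
      surv <- list(
        comparator = list(os = mk(comp_name, "os"), pfs = mk(comp_name, "pfs")),
        intervention = list(os = mk(intv_name, "os"), pfs = mk(intv_name, "pfs")))
    }
    res <- suppressWarnings(evaluate_cea(inputs, engine, overrides = ov, surv = surv))
    dc[i] <- res$incremental$delta_cost
    dq[i] <- res$incremental$delta_qaly
  }
  structure(list(
    draws = data.frame(draw = seq_len(n_iter), delta_cost = dc, delta_qaly = dq),
    sampled = sampled, engine = engine,
    wtp = inputs$settings$wtp, seed = seed),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  acc <- acceptability(x, x$wtp)
  cat(sprintf("<psa_result> %s engine, %d draws (seed %d): P(CE at WTP %g) = %.1f%%\n",
              x$engine, nrow(x$draws), x$seed, x$wtp, 100 * acc$probability))
  invisible(x)
}

psa_draws <- function(x) {
  if (inherits(x, "psa_result")) x$draws else x
}

#' Probability of cost-effectiveness at a willingness-to-pay threshold
#'
#' Fraction of PSA draws with positive net monetary benefit
#' `wtp * dQALY - dCost > 0`, with a Wilson 95% binomial interval.
#'
#' @param draws A `psa_result` or a data frame with `delta_cost`,
#'   `delta_qaly`.
#' @param wtp Willingness-to-pay threshold (CNY/QALY).
#' @return List `probability`, `ci_low`, `ci_high`, `n`.
#' @export
acceptability <- function(draws, wtp) {
  d <- psa_draws(draws)
  if (nrow(d) == 0) stop("no draws", call. = FALSE)
  x <- sum(wtp * d$delta_qaly - d$delta_cost > 0)
  n <- nrow(d)
  p <- x / n
  z <- stats::qnorm(0.975)
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(probability = p, ci_low = max(0, centre - half),
       ci_high = min(1, centre + half), n = n)
}

#' Cost-effectiveness acceptability curve
#'
#' @param draws A `psa_result` or draw data frame.
#' @param wtp_grid Strictly ascending WTP grid (CNY/QALY).
#' @return A `ceac_curve` data frame `wtp, prob_ce`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (any(diff(wtp_grid) <= 0)) stop("wtp_grid must be strictly ascending",
                                     call. = FALSE)
  d <- psa_draws(draws)
  prob <- vapply(wtp_grid, function(w) mean(w * d$delta_qaly - d$delta_cost > 0),
                 numeric(1))
  out <- data.frame(wtp = wtp_grid, prob_ce = prob)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' WTP at which the acceptability curve first crosses a level
#'
#' Linear interpolation of the first upward crossing; `NA` (with a
#' message attribute) when the level is never reached.
#'
#' @param curve A [ceac()] result.
#' @param level Probability in (0, 1).
#' @return WTP value (CNY/QALY), or `NA` if the curve never reaches
#'   `level`.
#' @export
ceac_crossing <- function(curve, level = 0.5) {
  stopifnot(level > 0, level < 1)
  p <- curve$prob_ce
  w <- curve$wtp
  if (p[1] >= level) return(w[1])
  idx <- which(p[-1] >= level & p[-length(p)] < level)
  if (length(idx) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "level never reached on the grid"
    return(out)
  }
  i <- idx[1]
  w[i] + (level - p[i]) * (w[i + 1] - w[i]) / (p[i + 1] - p[i])
}

#' Export sensitivity-analysis artifacts to CSV
#'
#' `write_tornado()` writes `parameter,icer_low,icer_high,spread`;
#' `write_ce_plane()` writes `draw,delta_cost,delta_qaly`;
#' `write_ceac()` writes `wtp,prob_ce`.
#'
#' @param x The respective object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("parameter", "icer_low", "icer_high",
                                        "spread")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado
#' @export
write_ce_plane <- function(x, path) {
  utils::write.csv(psa_draws(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado
#' @export
write_ceac <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
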