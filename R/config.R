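#' Model settings
#'
#' Structural settings of the cohort engines: a 21-day cycle, a 10-year
#' horizon, 5% annual discounting of both costs and health outcomes, and the
#' Chinese willingness-to-pay threshold of three times 2023 per-capita GDP
#' (CNY 268,074 per QALY).
#'
#' @param cycle_length_days Cycle length in days (> 0).
#' @param horizon_years Time horizon in years (> 0).
#' @param discount_annual Annual discount rate, in `[0, 1]`.
#' @param wtp Willingness-to-pay threshold, CNY per QALY (> 0).
#' @return A `model_settings` list; `n_cycles(settings)` gives the cycle count.
#' @export
model_settings <- function(cycle_length_days = 21, horizon_years = 10,
                           discount_annual = 0.05, wtp = 268074) {
  s <- list(cycle_length_days = cycle_length_days,
            horizon_years = horizon_years,
            discount_annual = discount_annual, wtp = wtp)
  validate_settings(s)
  structure(s, class = "model_settings")
}

validate_settings <- function(s) {
  stopifnot(s$cycle_length_days > 0, s$horizon_years > 0,
            s$discount_annual >= 0, s$discount_annual <= 1, s$wtp > 0)
  if (n_cycles(s) < 1) stop("horizon shorter than one cycle", call. = FALSE)
  invisible(TRUE)
}

#' @rdname model_settings
#' @param settings A `model_settings` object.
#' @export
n_cycles <- function(settings) {
  as.integer(floor(settings$horizon_years * 365 / settings$cycle_length_days))
}

#' One model input parameter
#'
#' A named scalar with its base-case value, one-way sensitivity range and
#' the distribution family used to sample it in probabilistic sensitivity
#' analysis (`gamma` for costs, `beta` for probabilities and utilities,
#' `fixed` for parameters never perturbed).
#'
#' @param name Identifier.
#' @param base,low,high Base-case value and range, `low <= base <= high`.
#' @param psa_family One of `"gamma"`, `"beta"`, `"fixed"`.
#' @return A one-row data frame.
#' @export
parameter_entry <- function(name, base, low = base, high = base,
                            psa_family = c("fixed", "gamma", "beta")) {
  psa_family <- match.arg(psa_family)
  if (!(low <= base && base <= high)) {
    stop(sprintf("parameter '%s': need low <= base <= high (got %g, %g, %g)",
                 name, low, base, high), call. = FALSE)
  }
  if (psa_family == "beta" && (low < 0 || high > 1)) {
    stop(sprintf("parameter '%s': beta-distributed values must lie in [0, 1]",
                 name), call. = FALSE)
  }
  data.frame(name = name, base = base, low = low, high = high,
             psa_family = psa_family, stringsAsFactors = FALSE)
}

ae_names <- function() c("neutropenia", "wbc_decreased", "thrombocytopenia", "anemia")

#' Packaged base-case input set
#'
#' Builds the full published base-case input set: the fitted log-logistic
#' OS/PFS scale/shape pairs per arm, per-cycle drug and care costs (CNY),
#' grade >= 3 adverse-event unit costs, incidences and disutilities,
#' subsequent-chemotherapy proportions (55% tislelizumab / 67% placebo),
#' health-state utilities (PFS 0.804, PD 0.321) and the 5% discount rate,
#' together with the package's documented accrual conventions.
#'
#' @param settings A [model_settings()].
#' @return A validated `model_inputs` object.
#' @examples
#' inp <- default_inputs()
#' resolve_parameter(inp, "utility_pfs")
#' @export
default_inputs <- function(settings = model_settings()) {
  pt <- rbind(
    parameter_entry("surv_tislelizumab_os_scale", 16.50756),
    parameter_entry("surv_tislelizumab_os_shape", 1.70402),
    parameter_entry("surv_tislelizumab_pfs_scale", 5.6371),
    parameter_entry("surv_tislelizumab_pfs_shape", 1.81906),
    parameter_entry("surv_placebo_os_scale", 14.9796),
    parameter_entry("surv_placebo_os_shape", 1.9698),
    parameter_entry("surv_placebo_pfs_scale", 4.94181),
    parameter_entry("surv_placebo_pfs_shape", 2.51144),
    parameter_entry("cost_tislelizumab", 2507.06, 2507.06, 2755.00, "gamma"),
    parameter_entry("cost_cisplatin", 102.81, 82.22, 641.13, "gamma"),
    parameter_entry("cost_carboplatin", 521.03, 132.30, 1420.00, "gamma"),
    parameter_entry("cost_etoposide", 1630.56, 40.20, 3250.16, "gamma"),
    parameter_entry("cost_bsc", 2467.00, 1973.65, 2960.47, "gamma"),
    parameter_entry("cost_followup", 600.58, 480.46, 720.70, "gamma"),
    parameter_entry("cost_ae_neutropenia", 607.45, 485.92, 728.91, "gamma"),
    parameter_entry("cost_ae_wbc_decreased", 3361.50, 2689.19, 4033.79, "gamma"),
    parameter_entry("cost_ae_thrombocytopenia", 7603.00, 6082.42, 9123.64, "gamma"),
    parameter_entry("cost_ae_anemia", 3665.90, 2932.73, 4399.07, "gamma"),
    parameter_entry("risk_tislelizumab_neutropenia", 0.5595, 0.504, 0.615, "beta"),
    parameter_entry("risk_tislelizumab_wbc_decreased", 0.2379, 0.214, 0.262, "beta"),
    parameter_entry("risk_tislelizumab_thrombocytopenia", 0.1938, 0.174, 0.213, "beta"),
    parameter_entry("risk_tislelizumab_anemia", 0.1630, 0.147, 0.179, "beta"),
    parameter_entry("risk_placebo_neutropenia", 0.5459, 0.491, 0.600, "beta"),
    parameter_entry("risk_placebo_wbc_decreased", 0.2751, 0.248, 0.303, "beta"),
    parameter_entry("risk_placebo_thrombocytopenia", 0.2533, 0.228, 0.279, "beta"),
    parameter_entry("risk_placebo_anemia", 0.1659, 0.149, 0.182, "beta"),
    parameter_entry("sub_prop_tislelizumab", 0.55, 0.495, 0.605, "beta"),
    parameter_entry("sub_prop_placebo", 0.67, 0.603, 0.737, "beta"),
    parameter_entry("utility_pfs", 0.804, 0.724, 0.884, "beta"),
    parameter_entry("utility_pd", 0.321, 0.289, 0.353, "beta"),
    parameter_entry("disutility_neutropenia", 0.200, 0.180, 0.220, "beta"),
    parameter_entry("disutility_wbc_decreased", 0.200, 0.180, 0.220, "beta"),
    parameter_entry("disutility_thrombocytopenia", 0.190, 0.171, 0.209, "beta"),
    parameter_entry("disutility_anemia", 0.078, 0.070, 0.086, "beta"),
    parameter_entry("discount_rate", settings$discount_annual, 0, 0.08, "fixed")
  )
  arms <- list(
    arm_spec("placebo", maintenance_cost_param = NULL,
             subsequent_param = "sub_prop_placebo"),
    arm_spec("tislelizumab", maintenance_cost_param = "cost_tislelizumab",
             subsequent_param = "sub_prop_tislelizumab")
  )
  new_model_inputs(settings, default_conventions(), arms, pt)
}

arm_spec <- function(name, maintenance_cost_param, subsequent_param,
                     induction_cycles = 4L) {
  list(name = name,
       os  = list(scale_param = sprintf("surv_%s_os_scale", name),
                  shape_param = sprintf("surv_%s_os_shape", name)),
       pfs = list(scale_param = sprintf("surv_%s_pfs_scale", name),
                  shape_param = sprintf("surv_%s_pfs_shape", name)),
       induction_cycles = as.integer(induction_cycles),
       maintenance_cost_param = maintenance_cost_param,
       subsequent_param = subsequent_param,
       ae = data.frame(
         ae = ae_names(),
         incidence_param  = sprintf("risk_%s_%s", name, ae_names()),
         cost_param       = sprintf("cost_ae_%s", ae_names()),
         disutility_param = sprintf("disutility_%s", ae_names()),
         stringsAsFactors = FALSE))
}

#' Accrual conventions
#'
#' The documented switches behind the engines' cost and outcome accrual.
#' The shipped defaults are the package's calibrated base case (see the
#' methods vignette for the rationale behind each):
#' \describe{
#'   \item{platinum}{First-line and subsequent-line platinum partner:
#'     `"cisplatin"` (default), `"carboplatin"`, or `"mix"` (costed as
#'     `mix_cisplatin` cisplatin + remainder carboplatin).}
#'   \item{n_sub_cycles}{Cycles of subsequent platinum-etoposide charged as a
#'     one-off course at progression (default 6).}
#'   \item{ae_duration_cycles}{Duration, in cycles, of the one-off
#'     adverse-event disutility at model entry (default 1).}
#'   \item{half_cycle}{Outcome (LY/QALY) occupancy rule: `"none"` =
#'     end-of-cycle membership, `"standard"` = half-cycle-corrected
#'     (trapezoid) membership.}
#'   \item{cost_timing}{Cost occupancy rule: `"start"` = state at cycle
#'     start (drugs are dispensed on day 1 of each cycle), `"end"`.}
#'   \item{induction_costing}{Induction chemotherapy charged to `"alive"`
#'     (per-protocol: every patient alive at the cycle start receives the
#'     scheduled induction cycle) or `"pfs"` (progression-free only).}
#'   \item{followup_states}{Routine follow-up cost accrued in `"alive"`
#'     states (default) or `"pfs"` only.}
#'   \item{psa_survival}{Sample the log-logistic (scale, shape) pairs in the
#'     PSA from a multivariate normal on the log scale (default `TRUE`)?}
#' }
#'
#' @param platinum,mix_cisplatin,n_sub_cycles,ae_duration_cycles,half_cycle,cost_timing,induction_costing,followup_states,psa_survival See Details.
#' @return A named list of conventions.
#' @export
default_conventions <- function(platinum = c("cisplatin", "carboplatin", "mix"),
                                mix_cisplatin = 0.5,
                                n_sub_cycles = 6,
                                ae_duration_cycles = 1,
                                half_cycle = c("none", "standard"),
                                cost_timing = c("start", "end"),
                                induction_costing = c("alive", "pfs"),
                                followup_states = c("alive", "pfs"),
                                psa_survival = TRUE) {
  conv <- list(platinum = match.arg(platinum),
               mix_cisplatin = mix_cisplatin,
               n_sub_cycles = n_sub_cycles,
               ae_duration_cycles = ae_duration_cycles,
               half_cycle = match.arg(half_cycle),
               cost_timing = match.arg(cost_timing),
               induction_costing = match.arg(induction_costing),
               followup_states = match.arg(followup_states),
               psa_survival = isTRUE(psa_survival))
  stopifnot(conv$mix_cisplatin >= 0, conv$mix_cisplatin <= 1,
            conv$n_sub_cycles >= 0, conv$ae_duration_cycles >= 0)
  conv
}

new_model_inputs <- function(settings, conventions, arms, parameter_table) {
  x <- structure(list(settings = settings, conventions = conventions,
                      arms = arms, parameter_table = parameter_table),
                 class = "model_inputs")
  validate_inputs(x)
  x
}

validate_inputs <- function(x) {
  validate_settings(x$settings)
  if (length(x$arms) != 2) stop("exactly two arms required", call. = FALSE)
  if (anyDuplicated(x$parameter_table$name)) {
    stop("duplicate parameter names", call. = FALSE)
  }
  # re-check every row's invariants
  for (i in seq_len(nrow(x$parameter_table))) {
    r <- x$parameter_table[i, ]
    parameter_entry(r$name, r$base, r$low, r$high, r$psa_family)
  }
  # every referenced parameter resolves
  refs <- unlist(lapply(x$arms, function(a) c(
    a$os$scale_param, a$os$shape_param, a$pfs$scale_param, a$pfs$shape_param,
    a$maintenance_cost_param, a$subsequent_param,
    a$ae$incidence_param, a$ae$cost_param, a$ae$disutility_param)))
  refs <- c(refs, "cost_etoposide", "cost_cisplatin", "cost_carboplatin",
            "cost_bsc", "cost_followup", "utility_pfs", "utility_pd",
            "discount_rate")
  missing <- setdiff(refs, x$parameter_table$name)
  if (length(missing)) {
    stop("unresolved parameter reference(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (a in x$arms) {
    if (a$induction_cycles < 0) stop("induction_cycles must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.model_inputs <- function(x, ...) {
  cat(sprintf("<model_inputs> arms: %s vs %s; %d parameters; %d-day cycles over %g years\n",
              x$arms[[2]]$name, x$arms[[1]]$name, nrow(x$parameter_table),
              x$settings$cycle_length_days, x$settings$horizon_years))
  invisible(x)
}

#' Resolve a model parameter
#'
#' Every scalar the engines consume is read through this accessor, so that
#' one-way and probabilistic sensitivity analyses can substitute values
#' uniformly.
#'
#' @param inputs A `model_inputs` object.
#' @param name Parameter identifier.
#' @param override Optional replacement value; returned as-is when given.
#' @return The override if provided, else the base-case value.
#' @export
resolve_parameter <- function(inputs, name, override = NULL) {
  i <- match(name, inputs$parameter_table$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  if (!is.null(override)) return(override)
  inputs$parameter_table$base[i]
}

# named base-value vector with overrides substituted
param_values <- function(inputs, overrides = NULL) {
  v <- stats::setNames(inputs$parameter_table$base, inputs$parameter_table$name)
  if (!is.null(overrides) && length(overrides)) {
    bad <- setdiff(names(overrides), names(v))
    if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    v[names(overrides)] <- overrides
  }
  v
}

# survival distribution of one arm/endpoint under a parameter vector
arm_surv_dist <- function(arm, endpoint, values) {
  ep <- arm[[endpoint]]
  surv_dist("loglogistic",
            scale = values[[ep$scale_param]],
            shape = values[[ep$shape_param]])
}

#' Load model inputs from a YAML or JSON config file
#'
#' The schema mirrors [default_inputs()]: top-level keys `settings`,
#' `conventions`, `arms` (comparator first) and `parameters` (the flat
#' named table of base/low/high/psa entries). Unknown keys are rejected;
#' omitted `settings` and `conventions` fields take the documented
#' defaults. The packaged default config is at
#' `system.file("extdata", "rationale312.yaml", package = "psmcea")`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated `model_inputs` object.
#' @export
load_inputs <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("settings", "conventions", "arms", "parameters")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  st <- raw$settings
  if (is.null(st)) st <- list()
  unknown <- setdiff(names(st), c("cycle_length_days", "horizon_years",
                                  "discount_annual", "wtp"))
  if (length(unknown)) {
    stop("unknown settings key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  settings <- do.call(model_settings, st)
  cv <- raw$conventions
  if (is.null(cv)) cv <- list()
  unknown <- setdiff(names(cv), names(formals(default_conventions)))
  if (length(unknown)) {
    stop("unknown conventions key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  conventions <- do.call(default_conventions, cv)
  if (is.null(raw$parameters)) stop("missing required field: parameters", call. = FALSE)
  pt <- do.call(rbind, lapply(names(raw$parameters), function(nm) {
    p <- raw$parameters[[nm]]
    for (f in c("base")) {
      if (is.null(p[[f]])) stop(sprintf("parameter '%s': missing required field '%s'",
                                        nm, f), call. = FALSE)
    }
    unknown <- setdiff(names(p), c("base", "low", "high", "psa"))
    if (length(unknown)) {
      stop(sprintf("parameter '%s': unknown field(s) %s", nm,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    parameter_entry(nm, p$base,
                    low = if (is.null(p$low)) p$base else p$low,
                    high = if (is.null(p$high)) p$base else p$high,
                    psa_family = if (is.null(p$psa)) "fixed" else p$psa)
  }))
  if (is.null(raw$arms)) stop("missing required field: arms", call. = FALSE)
  if (length(raw$arms) != 2) stop("exactly two arms required (comparator first)",
                                  call. = FALSE)
  arms <- lapply(raw$arms, function(a) {
    for (f in c("name", "subsequent_param")) {
      if (is.null(a[[f]])) stop("arm missing required field: ", f, call. = FALSE)
    }
    unknown <- setdiff(names(a), c("name", "induction_cycles",
                                   "maintenance_cost_param", "subsequent_param"))
    if (length(unknown)) {
      stop(sprintf("arm '%s': unknown field(s) %s", a$name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    arm_spec(a$name,
             maintenance_cost_param = a$maintenance_cost_param,
             subsequent_param = a$subsequent_param,
             induction_cycles = if (is.null(a$induction_cycles)) 4L
                                else a$induction_cycles)
  })
  new_model_inputs(settings, conventions, arms, pt)
}

#' Write model inputs to a YAML config file
#'
#' Inverse of [load_inputs()]: a written file reloads to a structure equal
#' field-by-field to the original.
#'
#' @param inputs A `model_inputs` object.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_inputs <- function(inputs, path) {
  pt <- inputs$parameter_table
  params <- lapply(seq_len(nrow(pt)), function(i) {
    list(base = pt$base[i], low = pt$low[i], high = pt$high[i],
         psa = pt$psa_family[i])
  })
  names(params) <- pt$name
  obj <- list(
    settings = unclass(inputs$settings),
    conventions = inputs$conventions,
    arms = lapply(inputs$arms, function(a) {
      out <- list(name = a$name, induction_cycles = a$induction_cycles,
                  subsequent_param = a$subsequent_param)
      if (!is.null(a$maintenance_cost_param)) {
        out$maintenance_cost_param <- a$maintenance_cost_param
      }
      out
    }),
    parameters = params)
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}
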