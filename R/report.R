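#' Run the base-case analysis and assemble a reproducible report
#'
#' Evaluates the packaged (or supplied) inputs through one or both cohort
#' engines and collects per-arm discounted costs, life-years and QALYs
#' plus the incremental comparison, along with the config hash, any
#' engine warnings and the paths of artifacts written.
#'
#' @param inputs A `model_inputs` object (default: packaged base case).
#' @param engine `"psm"`, `"markov"` or `"both"`.
#' @param out_dir Optional directory; when given, per-arm traces and the
#'   results table are written there as CSV/JSON.
#' @return A `run_report` list: `config_hash`, `engine`, per-engine
#'   `results` (each with `comparator`, `intervention`, `incremental`),
#'   `table` (a Table-2-style data frame), `warnings`, `artifacts`.
#' @examples
#' rep <- cmd_run(engine = "both")
#' rep$table
#' @export
cmd_run <- function(inputs = default_inputs(), engine = c("both", "psm", "markov"),
                    out_dir = NULL) {
  engine <- match.arg(engine)
  engines <- if (engine == "both") c("psm", "markov") else engine
  warns <- character()
  results <- list()
  for (eng in engines) {
    res <- withCallingHandlers(
      evaluate_cea(inputs, eng),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    results[[eng]] <- res
  }
  tab <- do.call(rbind, lapply(names(results), function(eng) {
    r <- results[[eng]]
    data.frame(
      model = eng,
      group = c(r$intervention$arm, r$comparator$arm),
      total_cost = c(r$intervention$total_cost, r$comparator$total_cost),
      ly = c(r$intervention$ly, r$comparator$ly),
      qaly = c(r$intervention$qaly, r$comparator$qaly),
      icer = c(r$incremental$icer, NA_real_),
      stringsAsFactors = FALSE)
  }))
  artifacts <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (eng in names(results)) {
      for (side in c("comparator", "intervention")) {
        p <- file.path(out_dir, sprintf("trace_%s_%s.csv", eng,
                                        results[[eng]][[side]]$arm))
        write_trace(results[[eng]][[side]]$trace, p)
        artifacts <- c(artifacts, p)
      }
    }
    p <- file.path(out_dir, "results.json")
    jsonlite::write_json(report_json(results, tab), p, auto_unbox = TRUE,
                         digits = NA)
    artifacts <- c(artifacts, p)
    pt <- file.path(out_dir, "results_table.csv")
    utils::write.csv(tab, pt, row.names = FALSE)
    artifacts <- c(artifacts, pt)
  }
  structure(list(config_hash = config_hash(inputs), engine = engine,
                 results = results, table = tab, warnings = unique(warns),
                 artifacts = artifacts),
            class = "run_report")
}

report_json <- function(results, tab) {
  list(
    table = tab,
    detail = lapply(results, function(r) list(
      comparator = econ_json(r$comparator),
      intervention = econ_json(r$intervention),
      incremental = unclass(r$incremental))))
}

econ_json <- function(x) {
  list(arm = x$arm, total_cost = x$total_cost, ly = x$ly, qaly = x$qaly,
       cost_breakdown = as.list(x$cost_breakdown),
       qaly_breakdown = as.list(x$qaly_breakdown))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> config %s\n", x$config_hash))
  tab <- x$table
  tab$total_cost <- sprintf("%.2f", tab$total_cost)
  tab$ly <- sprintf("%.2f", tab$ly)
  tab$qaly <- sprintf("%.2f", tab$qaly)
  tab$icer <- ifelse(is.na(tab$icer), "-", sprintf("%.2f", tab$icer))
  print(tab, row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Stable hash of a model-inputs object
#'
#' Serialises the inputs canonically (JSON, fixed digit count) and hashes
#' the bytes, so reruns of the same config are identifiable in logs.
#'
#' @param inputs A `model_inputs` object.
#' @return Hex string.
#' @export
config_hash <- function(inputs) {
  js <- jsonlite::toJSON(list(settings = unclass(inputs$settings),
                              conventions = inputs$conventions,
                              arms = inputs$arms,
                              parameters = inputs$parameter_table),
                         auto_unbox = TRUE, digits = 12)
  # 31-ary polynomial hash mod 2^31-1 over the serialised bytes;
  # dependency-free and stable across platforms
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' One-way sensitivity analysis with artifacts
#'
#' @inheritParams cmd_run
#' @param engine `"psm"` or `"markov"`.
#' @param include_structural Passed to [owsa()].
#' @return The [owsa()] tornado, with CSV written when `out_dir` is given.
#' @export
cmd_owsa <- function(inputs = default_inputs(), engine = c("psm", "markov"),
                     out_dir = NULL, include_structural = FALSE) {
  engine <- match.arg(engine)
  tor <- owsa(inputs, engine, include_structural = include_structural)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tornado(tor, file.path(out_dir, sprintf("tornado_%s.csv", engine)))
  }
  tor
}

#' Probabilistic sensitivity analysis with artifacts
#'
#' Runs [run_psa()] and, when `out_dir` is given, writes the CE-plane and
#' CEAC CSVs plus a JSON summary logging the seed and config hash, so a
#' rerun with the same seed reproduces byte-identical artifacts.
#'
#' @inheritParams run_psa
#' @param out_dir Optional output directory.
#' @param wtp_grid WTP grid for the CEAC (default 0 to 500k in 2.5k steps).
#' @return The `psa_result`, with `ceac` and `summary` attached.
#' @export
cmd_psa <- function(inputs = default_inputs(), engine = c("psm", "markov"),
                    n_iter = 1000, seed = 1L, out_dir = NULL,
                    wtp_grid = seq(0, 500000, by = 2500)) {
  engine <- match.arg(engine)
  psa <- run_psa(inputs, engine, n_iter = n_iter, seed = seed)
  curve <- ceac(psa, wtp_grid)
  acc <- acceptability(psa, inputs$settings$wtp)
  psa$ceac <- curve
  psa$summary <- list(wtp = inputs$settings$wtp,
                      acceptability = acc,
                      ceac_50 = ceac_crossing(curve, 0.5),
                      config_hash = config_hash(inputs), seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ce_plane(psa, file.path(out_dir, sprintf("ce_plane_%s.csv", engine)))
    write_ceac(curve, file.path(out_dir, sprintf("ceac_%s.csv", engine)))
    jsonlite::write_json(psa$summary,
                         file.path(out_dir, sprintf("psa_summary_%s.json", engine)),
                         auto_unbox = TRUE, digits = NA)
  }
  psa
}

#' Fit all (or selected) candidate families to an IPD table
#'
#' @param ipd Data frame with `time`, `event` (see [read_ipd()]).
#' @param families Character vector of families (default all seven).
#' @param out_path Optional JSON report path.
#' @return The [rank_models()] table, with the fit list in
#'   `attr(, "fits")`.
#' @export
cmd_fit <- function(ipd, families = surv_families(), out_path = NULL) {
  fits <- lapply(families, function(f) {
    tryCatch(suppressWarnings(fit_mle(ipd, f)), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("no family could be fitted", call. = FALSE)
  tab <- rank_models(fits)
  if (!is.null(out_path)) write_fit_report(fits, out_path)
  attr(tab, "fits") <- fits
  tab
}
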