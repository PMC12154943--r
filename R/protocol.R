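#' Read a protocol configuration
#'
#' Protocols are JSON with a `mode` key (`simulate`, `dose_rate`,
#' `dose_response`, `fit` or `reproduce`) plus mode-specific fields:
#' `scheme` (path to a scheme config, or `{builder, params}`), `doses_uM`,
#' exactly one of `t_end_s` / `tDR_s` / `tDR_h` where the mode requires a
#' time (hours are converted to seconds on load), `figure` for `reproduce`,
#' `data_csv`, `free` and `fixed` for `fit`, and optional tolerance overrides
#' `rtol` / `atol`.
#'
#' @param path JSON file path.
#' @return A validated protocol list (class `kin_protocol`).
#' @export
read_protocol <- function(path) {
  if (!file.exists(path))
    stop("protocol file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse protocol '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  validate_protocol(obj)
}

validate_protocol <- function(obj) {
  if (is.null(obj$mode))
    stop("protocol: missing required key 'mode'", call. = FALSE)
  mode <- match.arg(obj$mode, c("simulate", "dose_rate", "dose_response",
                                "fit", "reproduce"))
  obj$mode <- mode
  times <- intersect(c("t_end_s", "tDR_s", "tDR_h"), names(obj))
  if (mode %in% c("simulate", "dose_rate", "dose_response")) {
    if (length(times) != 1)
      stop("protocol: mode '", mode, "' requires exactly one of ",
           "t_end_s / tDR_s / tDR_h (found ", length(times), ")",
           call. = FALSE)
    obj$t_s <- if (times == "tDR_h") obj[[times]] * 3600 else obj[[times]]
    if (!is.numeric(obj$t_s) || obj$t_s <= 0)
      stop("protocol: time must be a positive number", call. = FALSE)
  }
  if (mode == "reproduce" && is.null(obj$figure))
    stop("protocol: mode 'reproduce' requires 'figure'", call. = FALSE)
  if (mode == "fit" && is.null(obj$data_csv))
    stop("protocol: mode 'fit' requires 'data_csv'", call. = FALSE)
  structure(obj, class = "kin_protocol")
}

resolve_scheme <- function(spec) {
  if (is.null(spec))
    stop("protocol: missing 'scheme'", call. = FALSE)
  if (is.character(spec)) return(read_scheme(spec))
  if (!is.null(spec$builder))
    return(do.call(build_scheme, c(list(name = spec$builder),
                                   as.list(spec$params))))
  stop("protocol: 'scheme' must be a file path or {builder, params}",
       call. = FALSE)
}

#' Run a protocol
#'
#' Executes a validated protocol and writes its artifacts: canonical CSV
#' tables plus a machine-readable JSON summary embedding the fully resolved
#' parameter set, package version and config hash. Outputs are deterministic:
#' identical protocols produce byte-identical tables. Progress is logged to
#' stderr as timestamped stage lines.
#'
#' @param protocol A protocol list, a `kin_protocol`, or a JSON file path.
#' @param out_dir Output directory (created if needed); defaults to
#'   `protocol$out_dir` or the working directory.
#' @return Invisibly, the list of result tables.
#' @export
run_protocol <- function(protocol, out_dir = NULL) {
  if (is.character(protocol)) protocol <- read_protocol(protocol)
  if (!inherits(protocol, "kin_protocol"))
    protocol <- validate_protocol(protocol)
  out_dir <- out_dir %||% protocol$out_dir %||% "."
  log_stage <- function(stage, msg)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] ", msg)
  rtol <- protocol$rtol %||% 1e-8
  atol <- protocol$atol %||% 1e-12
  mode <- protocol$mode
  log_stage("start", paste("mode", mode))
  tables <- switch(mode,
    simulate = {
      scheme <- resolve_scheme(protocol$scheme)
      tc <- simulate_scheme(scheme, t_end = protocol$t_s, rtol = rtol,
                            atol = atol)
      tbl <- dplyr::rename(tibble::as_tibble(tc), time_s = "time")
      list(timecourse = tbl)
    },
    dose_rate = {
      prm <- as.list(protocol$scheme$params)
      dr <- dose_rate(kon = prm$kon, koff = prm$koff, kinact = prm$kinact,
                      pr = prm$pr, E0 = prm$E0 %||% 1e-3,
                      doses = protocol$doses_uM, t_end = protocol$t_s,
                      rtol = rtol, atol = atol)
      list(kobs = dr$data, estimates = glance(dr))
    },
    dose_response = {
      prm <- as.list(protocol$scheme$params)
      dr <- dose_response(kon = prm$kon, koffapp = prm$koffapp,
                          kinactapp = prm$kinactapp, E0 = prm$E0,
                          t_dr = protocol$t_s, doses = protocol$doses_uM,
                          rtol = rtol, atol = atol)
      hf <- fit_hill(dr$data, amplitude = dr$amplitude,
                     ec50 = dr$ec50_analytic)
      list(curve = tidy_dose_response(dr),
           estimates = dplyr::mutate(glance(dr), n_fit = hf$n))
    },
    fit = {
      if (!file.exists(protocol$data_csv))
        stop("fit data file not found: ", protocol$data_csv, call. = FALSE)
      raw <- readr::read_csv(protocol$data_csv, show_col_types = FALSE)
      names(raw) <- sub("^dose_uM$", "dose", names(raw))
      names(raw) <- sub("^time_s$", "time", names(raw))
      names(raw) <- sub("^CO$", "co", names(raw))
      gf <- global_fit(raw, free = protocol$free %||% c("Kd", "pr", "kinact"),
                       fixed = as.list(protocol$fixed),
                       rtol = rtol, atol = atol)
      list(estimates = tidy(gf), fitted = gf$fitted)
    },
    reproduce = {
      log_stage("reproduce", protocol$figure)
      return(invisible(reproduce_figure(protocol$figure, out_dir = out_dir)))
    })
  stem <- protocol$stem %||% mode
  write_report(tables, stem, out_dir,
               params = unclass(protocol)[setdiff(names(protocol),
                                                  c("mode", "out_dir"))],
               extra = list(mode = mode))
  log_stage("done", paste("artifacts in", out_dir))
  invisible(tables)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `covkin` executable script:
#' `covkin simulate|dose-rate|dose-response|fit|reproduce --config <json>`
#' with optional per-flag overrides `--out-dir`, `--figure`, `--scheme`,
#' `--t-end` (seconds) and `--seed`. Returns the process exit status.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: covkin <simulate|dose-rate|dose-response|fit|reproduce>",
    "[--config <json>] [--out-dir <dir>] [--figure <figN>]",
    "[--scheme <json>] [--t-end <s>] [--seed <int>]")
  status <- tryCatch({
    if (!length(args)) stop(usage, call. = FALSE)
    mode <- gsub("-", "_", args[1])
    flags <- list()
    i <- 2
    while (i <= length(args)) {
      if (!startsWith(args[i], "--"))
        stop("unexpected argument '", args[i], "'\n", usage, call. = FALSE)
      key <- gsub("-", "_", substring(args[i], 3))
      if (i + 1 > length(args))
        stop("flag --", key, " needs a value", call. = FALSE)
      flags[[key]] <- args[i + 1]
      i <- i + 2
    }
    protocol <- if (!is.null(flags$config))
      unclass(read_protocol(flags$config)) else list()
    protocol$mode <- mode
    if (!is.null(flags$figure)) protocol$figure <- flags$figure
    if (!is.null(flags$scheme)) protocol$scheme <- flags$scheme
    if (!is.null(flags$t_end)) protocol$t_end_s <- as.numeric(flags$t_end)
    if (!is.null(flags$out_dir)) protocol$out_dir <- flags$out_dir
    if (!is.null(flags$seed)) set.seed(as.integer(flags$seed))
    run_protocol(validate_protocol(protocol))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
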