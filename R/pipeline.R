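#' Pipeline configuration
#'
#' Validated, JSON-serializable configuration for [run_pipeline()].  Unknown
#' keys and out-of-range overrides are rejected outright (fail-fast).
#'
#' @param overrides named list of [model_params()] overrides (checked against
#'   the parameter invariants).
#' @param t_max,tol solver settings.
#' @param experiment `"1"`, `"2"` or `"all"`.
#' @param detect list with `grid_n` and `margin` for the detection stage.
#' @param out_dir output directory.
#' @param base_seed integer; seeds the synthetic module only (the forward
#'   model is deterministic).
#' @param variant `"fixed_quota"` or `"droop"`.
#' @param n_points gradient resolution.
#' @return An object of class `ter_config`.
#' @export
pipeline_config <- function(overrides = list(), t_max = 3000, tol = 1e-6,
                            experiment = c("1", "2", "all"),
                            detect = list(grid_n = 201, margin = 2),
                            out_dir = "ter_out", base_seed = 1L,
                            variant = c("fixed_quota", "droop"),
                            n_points = 100) {
  experiment <- match.arg(as.character(experiment), c("1", "2", "all"))
  variant <- match.arg(variant)
  allowed <- names(formals(model_params))
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown) > 0)
    stop("pipeline_config: unknown parameter override(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(model_params, overrides)  # range-check now, fail fast
  dflt <- list(grid_n = 201, margin = 2)
  unknown <- setdiff(names(detect), names(dflt))
  if (length(unknown) > 0)
    stop("pipeline_config: unknown detect setting(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  detect <- utils::modifyList(dflt, detect)
  cfg <- list(overrides = overrides, t_max = t_max, tol = tol,
              experiment = experiment, detect = detect, out_dir = out_dir,
              base_seed = as.integer(base_seed), variant = variant,
              n_points = n_points)
  class(cfg) <- "ter_config"
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' @param cfg a [pipeline_config()].
#' @param file path of the JSON file.
#' @return `file` (write) or the reloaded `ter_config` (read).
#' @export
write_config <- function(cfg, file) {
  jsonlite::write_json(unclass(cfg), file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  raw$overrides <- as.list(raw$overrides)
  raw$detect <- as.list(raw$detect)
  do.call(pipeline_config, raw[setdiff(names(raw), character(0))])
}

# polynomial rolling hash of the serialized config, for the log
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(txt)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

estimate_report <- function(est) {
  rep <- list(x_ter = if (is.finite(est$x_ter)) est$x_ter else NULL,
       y_ter = if (is.finite(est$y_ter)) est$y_ter else NULL,
       shape = est$shape,
       scores = as.list(est$scores),
       delta_best = est$delta_best,
       slope_below = if (is.finite(est$slope_below)) est$slope_below else NULL,
       slope_above = if (is.finite(est$slope_above)) est$slope_above else NULL,
       mech_switch_x = if (is.finite(est$mech_switch_x)) est$mech_switch_x
                       else NULL,
       n_points_used = est$n)
  rep[!vapply(rep, is.null, logical(1))]  # absent quantities are omitted
}

#' Run the full pipeline: experiments, detection, reports
#'
#' Validates the light calibration, runs the selected model experiment(s),
#' writes one curve CSV (plus units sidecar) and one threshold JSON report
#' per scenario, and a summary table across scenarios.  Reruns with the same
#' configuration reproduce identical CSVs (the forward model has no
#' stochastic elements).  Partial outputs are removed if any stage fails.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-scenario log lines.
#' @return Invisibly, a list with `summary` (data frame) and `out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "ter_config"))
  params <- do.call(model_params, cfg$overrides)
  if (cfg$variant == "droop") params <- droop_params(params)
  calibrate_light(params, t_max = cfg$t_max, tol = cfg$tol)

  scens <- list()
  if (cfg$experiment %in% c("1", "all"))
    scens <- c(scens, build_experiment1(params, n_points = cfg$n_points))
  if (cfg$experiment %in% c("2", "all"))
    scens <- c(scens, build_experiment2(params, n_points = cfg$n_points))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  t0 <- proc.time()[["elapsed"]]
  log_lines <- c(sprintf("config_hash=%s r_version=%s terlake=%s",
                         config_hash(cfg), getRversion(),
                         as.character(utils::packageVersion("terlake"))))
  summary_rows <- list()
  ok <- FALSE
  on.exit(if (!ok) unlink(made), add = TRUE)

  for (s in scens) {
    cv <- run_gradient(s, t_max = cfg$t_max, tol = cfg$tol,
                       variant = cfg$variant)
    est <- detect_ter(cv, margin = cfg$detect$margin,
                      grid_n = cfg$detect$grid_n,
                      t_max = cfg$t_max, tol = cfg$tol)
    csv <- file.path(cfg$out_dir, paste0(s$id, ".csv"))
    write_curve(cv, csv)
    rep_file <- file.path(cfg$out_dir, paste0(s$id, "_ter.json"))
    jsonlite::write_json(estimate_report(est), rep_file, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    made <- c(made, csv, paste0(csv, ".meta.json"), rep_file)
    census <- table(factor(cv$limiter, levels = c("N", "P", "light")))
    line <- sprintf(
      "scenario=%s converged=%d/%d limiters=N:%d,P:%d,light:%d shape=%s x_ter=%s",
      s$id, sum(cv$converged), nrow(cv), census[["N"]], census[["P"]],
      census[["light"]], est$shape,
      if (is.finite(est$x_ter)) sprintf("%.4g", est$x_ter) else "absent")
    if (!quiet) message(line)
    log_lines <- c(log_lines, line)
    summary_rows[[s$id]] <- data.frame(
      scenario_id = s$id, param_name = s$param_name,
      param_value = s$param_value, shape = est$shape,
      x_ter = est$x_ter, y_ter = est$y_ter,
      slope_below = est$slope_below, slope_above = est$slope_above,
      mech_switch_x = est$mech_switch_x, stringsAsFactors = FALSE)
  }

  summary_df <- do.call(rbind, summary_rows)
  rownames(summary_df) <- NULL
  sfile <- file.path(cfg$out_dir, "summary.csv")
  utils::write.csv(summary_df, sfile, row.names = FALSE)
  cfile <- file.path(cfg$out_dir, "config.json")
  write_config(cfg, cfile)
  log_lines <- c(log_lines, sprintf("wall_time_s=%.1f",
                                    proc.time()[["elapsed"]] - t0))
  lfile <- file.path(cfg$out_dir, "run.log")
  writeLines(log_lines, lfile)
  made <- c(made, sfile, cfile, lfile)
  ok <- TRUE
  invisible(list(summary = summary_df, out_dir = cfg$out_dir))
}

#' Detect a threshold in a response-curve file
#'
#' Reads a CSV with user-named x and y columns, runs [detect_ter()], and
#' writes a JSON report.  A "no threshold" outcome is a success; a malformed
#' file or missing column is an error raised before any output is written.
#'
#' @param file CSV path.
#' @param x_col,y_col column names of the ratio and response.
#' @param out path of the JSON report to write (optional).
#' @param margin,grid_n detection settings.
#' @return The `ter_estimate`, invisibly.
#' @export
detect_file <- function(file, x_col = "molar_NP", y_col = "gpp", out = NULL,
                        margin = 2, grid_n = 201) {
  if (!file.exists(file)) stop("detect_file: no such file: ", file,
                               call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(c(x_col, y_col), names(df))
  if (length(miss) > 0)
    stop("detect_file: missing column(s) ", paste(miss, collapse = ", "),
         "; file has: ", paste(names(df), collapse = ", "), call. = FALSE)
  if (nrow(df) < 10)
    stop("insufficient data: detect_file needs >= 10 rows", call. = FALSE)
  if (!is.numeric(df[[x_col]]) || !is.numeric(df[[y_col]]))
    stop("detect_file: columns ", x_col, "/", y_col, " must be numeric",
         call. = FALSE)
  est <- detect_ter(df, x_col = x_col, y_col = y_col, margin = margin,
                    grid_n = grid_n, attach_switch = FALSE)
  if (!is.null(out))
    jsonlite::write_json(estimate_report(est), out, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  invisible(est)
}

#' Generate synthetic curves from a spec file
#'
#' Reads a JSON array of [curve_spec()] field lists, writes one CSV per curve
#' plus a ground-truth JSON sidecar.
#'
#' @param spec_file JSON path.
#' @param out_dir output directory.
#' @param seed base seed added to each spec's own seed.
#' @return Invisibly, the paths written.
#' @export
synth_from_file <- function(spec_file, out_dir, seed = 1L) {
  specs <- jsonlite::read_json(spec_file, simplifyVector = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- as.integer(seed) + if (is.null(sp$seed)) i else sp$seed
    g <- gen_curve(do.call(curve_spec, sp))
    base <- file.path(out_dir, sprintf("synth_%02d_%s", i, g$truth$shape))
    utils::write.csv(g$curve, paste0(base, ".csv"), row.names = FALSE)
    jsonlite::write_json(g$truth, paste0(base, "_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- c(paths, paste0(base, ".csv"), paste0(base, "_truth.json"))
  }
  invisible(paths)
}
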