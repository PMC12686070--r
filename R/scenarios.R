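#' Define a supply-gradient scenario
#'
#' A scenario sweeps one nutrient input over a log-spaced gradient while
#' holding the other fixed, producing one GPP-versus-supply-N:P response
#' curve.
#'
#' @param id scenario label.
#' @param params a [model_params()] object.
#' @param swept which input varies: `"N_in"` or `"P_in"`.
#' @param sweep_lo,sweep_hi gradient endpoints, mg m^-3.
#' @param fixed_value the non-swept input, mg m^-3.
#' @param n_points gradient resolution (>= 20).
#' @param param_name,param_value bookkeeping for perturbation experiments
#'   (which parameter, if any, was varied from baseline).
#' @return An object of class `ter_scenario`.
#' @export
scenario <- function(id, params, swept = c("N_in", "P_in"),
                     sweep_lo, sweep_hi, fixed_value, n_points = 100,
                     param_name = "baseline", param_value = NA_real_) {
  swept <- match.arg(swept)
  if (!is.numeric(sweep_lo) || !is.numeric(sweep_hi) || sweep_lo <= 0 ||
      sweep_hi <= sweep_lo)
    stop("invalid scenario: need 0 < sweep_lo < sweep_hi", call. = FALSE)
  if (fixed_value <= 0) stop("invalid scenario: fixed_value must be positive",
                             call. = FALSE)
  if (n_points < 20) stop("invalid scenario: n_points must be >= 20",
                          call. = FALSE)
  structure(list(id = id, params = params, swept = swept,
                 sweep_lo = sweep_lo, sweep_hi = sweep_hi,
                 fixed_value = fixed_value, n_points = n_points,
                 spacing = "log", param_name = param_name,
                 param_value = param_value),
            class = "ter_scenario")
}

#' The four supply scenarios of the first model experiment
#'
#' High/low N sweeps (P fixed) and high/low P sweeps (N fixed); the "high"
#' member of each pair is the "low" member with both inputs scaled tenfold,
#' so each pair covers the same molar N:P interval at different absolute
#' concentrations.
#'
#' @param params baseline [model_params()] shared by all four scenarios.
#' @param n_points gradient resolution per scenario.
#' @return Named list of four `ter_scenario` objects
#'   (`high_N`, `low_N`, `high_P`, `low_P`).
#' @export
build_experiment1 <- function(params = model_params(), n_points = 100) {
  list(
    high_N = scenario("high_N", params, "N_in", 700, 14000, 300, n_points),
    low_N  = scenario("low_N",  params, "N_in", 70,   1400,  30,  n_points),
    high_P = scenario("high_P", params, "P_in", 150,  2000,  7000, n_points),
    low_P  = scenario("low_P",  params, "P_in", 15,   200,   700,  n_points)
  )
}

#' The twelve perturbation scenarios of the second model experiment
#'
#' Each scenario is the low-P sweep with exactly one parameter replaced:
#' dilution rate `a` in \{0.1, 0.6, 0.7\} d^-1, depth `z_max` in \{1, 2.5, 5\}
#' m, P half-saturation `m_P` in \{0.7, 1.5, 3\} mg P m^-3, or P quota `c_P`
#' in \{0.005, 0.015, 0.025\} mg P per mg C.
#'
#' @param params baseline [model_params()].
#' @param n_points gradient resolution per scenario.
#' @return Named list of twelve `ter_scenario` objects with ids like
#'   `"lowP_a_0.6"`.
#' @export
build_experiment2 <- function(params = model_params(), n_points = 100) {
  grid <- list(a = c(0.1, 0.6, 0.7), z_max = c(1, 2.5, 5),
               m_P = c(0.7, 1.5, 3), c_P = c(0.005, 0.015, 0.025))
  out <- list()
  for (pn in names(grid)) {
    for (v in grid[[pn]]) {
      p <- params
      p[[pn]] <- v
      p <- suppressWarnings(validate_params(p))  # a = 0.7 may wash out: allowed
      class(p) <- class(params)
      id <- sprintf("lowP_%s_%g", pn, v)
      out[[id]] <- scenario(id, p, "P_in", 15, 200, 700, n_points,
                            param_name = pn, param_value = v)
    }
  }
  out
}

#' Run a supply-gradient sweep
#'
#' Solves [solve_steady_state()] at each of `n_points` log-spaced values of
#' the swept input and assembles the response curve, sorted by molar supply
#' N:P.  Non-converged points are flagged, never dropped; more than 10%
#' non-converged is a hard error.
#'
#' @param s a [scenario()] object.
#' @param t_max,tol solver settings, see [solve_steady_state()].
#' @param variant model variant passed to the solver (`"droop"` requires
#'   `s$params` built by [droop_params()]).
#' @return A `ter_curve`: data frame with one row per gradient point and
#'   columns `scenario_id`, `param_name`, `param_value`, `N_in`, `P_in`,
#'   `molar_NP`, `A_star`, `N_star`, `P_star`, `mu`, `f_N`, `f_P`, `f_I`,
#'   `limiter`, `gpp`, `converged`; the scenario is attached as an attribute.
#' @export
run_gradient <- function(s, t_max = 3000, tol = 1e-6,
                         variant = c("fixed_quota", "droop")) {
  variant <- match.arg(variant)
  stopifnot(inherits(s, "ter_scenario"))
  vals <- 10^seq(log10(s$sweep_lo), log10(s$sweep_hi), length.out = s$n_points)
  rows <- lapply(vals, function(v) {
    sup <- if (s$swept == "N_in") supply(v, s$fixed_value)
           else supply(s$fixed_value, v)
    ss <- withCallingHandlers(
      solve_steady_state(s$params, sup, t_max = t_max, tol = tol,
                         variant = variant),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    data.frame(scenario_id = s$id, param_name = s$param_name,
               param_value = s$param_value, N_in = sup$N_in, P_in = sup$P_in,
               molar_NP = supply_molar_ratio(sup$N_in, sup$P_in),
               A_star = ss$state[["A"]], N_star = ss$state[["N"]],
               P_star = ss$state[["P"]], mu = ss$mu, f_N = ss$f_N,
               f_P = ss$f_P, f_I = ss$f_I, limiter = ss$limiter,
               gpp = ss$gpp, converged = ss$converged,
               stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$molar_NP), ]
  rownames(curve) <- NULL
  n_bad <- sum(!curve$converged)
  if (n_bad > 0.1 * nrow(curve))
    stop(sprintf(paste("run_gradient: %d/%d points failed to converge;",
                       "try a larger t_max"), n_bad, nrow(curve)),
         call. = FALSE)
  structure(curve, scenario = s, class = c("ter_curve", "data.frame"))
}

#' Check that the light environment separates the supply regimes
#'
#' Asserts the qualitative regime split of the first experiment: (i) the low-N
#' and low-P scenarios are nutrient-limited at every converged point, and
#' (ii) the high-N and high-P scenarios are light-limited (self-shading) over
#' at least 90% of points.  Raises a calibration error naming the violating
#' scenario and condition otherwise.
#'
#' @param params candidate [model_params()].
#' @param scenarios the four experiment-1 scenarios (rebuilt from `params`
#'   when omitted).
#' @param t_max,tol solver settings.
#' @return `params`, invisibly, when both conditions hold.
#' @export
calibrate_light <- function(params, scenarios = build_experiment1(params),
                            t_max = 3000, tol = 1e-6) {
  curves <- lapply(scenarios, run_gradient, t_max = t_max, tol = tol)
  for (nm in c("low_N", "low_P")) {
    cv <- curves[[nm]]
    ok <- cv$converged & cv$A_star >= .WASHOUT_A & cv$limiter %in% c("N", "P")
    bad <- which(cv$converged & !ok)
    if (length(bad) > 0)
      stop(sprintf(paste("light calibration failed: condition (i), scenario",
                         "%s, point %d (molar N:P %.3g) has limiter '%s'",
                         "or washout"),
                   nm, bad[1], cv$molar_NP[bad[1]], cv$limiter[bad[1]]),
           call. = FALSE)
  }
  for (nm in c("high_N", "high_P")) {
    cv <- curves[[nm]]
    frac <- mean(cv$limiter[cv$converged] == "light")
    if (is.na(frac) || frac < 0.9)
      stop(sprintf(paste("light calibration failed: condition (ii), scenario",
                         "%s is light-limited at only %.0f%% of points"),
                   nm, 100 * frac), call. = FALSE)
  }
  invisible(params)
}

#' Write / read a response-curve CSV
#'
#' Plain comma-separated UTF-8 with a header row; a JSON sidecar
#' (`<file>.meta.json`) documents the units of every column.
#'
#' @param curve a `ter_curve` (or compatible data frame).
#' @param file path of the CSV to write.
#' @return `file`, invisibly.
#' @export
write_curve <- function(curve, file) {
  utils::write.csv(as.data.frame(curve), file, row.names = FALSE)
  meta <- list(
    columns = list(
      scenario_id = "label", param_name = "varied parameter or 'baseline'",
      param_value = "value of varied parameter",
      N_in = "mg N m-3", P_in = "mg P m-3",
      molar_NP = "dimensionless molar N:P",
      A_star = "mg C m-3", N_star = "mg N m-3", P_star = "mg P m-3",
      mu = "d-1", f_N = "fraction", f_P = "fraction", f_I = "fraction",
      limiter = "one of N, P, light", gpp = "mg O2 L-1 d-1",
      converged = "logical"))
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_curve
#' @export
read_curve <- function(file) {
  cv <- utils::read.csv(file, stringsAsFactors = FALSE)
  structure(cv, class = c("ter_curve", "data.frame"))
}
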