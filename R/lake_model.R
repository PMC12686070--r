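#' Monod (saturating) limitation term
#'
#' @param conc non-negative concentration.
#' @param halfsat positive half-saturation constant, same units as `conc`.
#' @return `conc / (halfsat + conc)`, a fraction in \[0, 1).
#' @examples
#' monod(1.5, 1.5)  # 0.5
#' @export
monod <- function(conc, halfsat) {
  if (any(!is.finite(halfsat)) || any(halfsat <= 0))
    stop("invalid parameter: halfsat must be strictly positive", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("invalid parameter: conc must be non-negative", call. = FALSE)
  conc / (halfsat + conc)
}

#' Depth-averaged light limitation with algal self-shading
#'
#' Light declines with depth as `I(z) = I_in * exp(-k z)` where the
#' attenuation `k = k_bg + k_A * A` includes self-shading by the algae
#' themselves.  Averaging the saturating response `I/(h_I + I)` over the mixed
#' layer gives the closed form
#' `f_I = ln((h_I + I_in)/(h_I + I(z_max))) / (k * z_max)`.
#'
#' @param A algal biomass, mg C m^-3 (vectorised).
#' @param params a [model_params()] object.
#' @return Fraction in (0, 1\], strictly decreasing in `A`.
#' @export
light_limitation <- function(A, params) {
  if (any(!is.finite(A)) || any(A < 0))
    stop("invalid parameter: A must be non-negative", call. = FALSE)
  k <- params$k_bg + params$k_A * A
  kz <- k * params$z_max
  I_z <- params$I_in * exp(-kz)
  log((params$h_I + params$I_in) / (params$h_I + I_z)) / kz
}

#' Limitation factors and limiter identity at a model state
#'
#' Computes the three dimensionless limitation factors (Monod in N, Monod in
#' P, depth-averaged light) and the identity of the Liebig-minimum limiter.
#' Ties are broken by the fixed order N < P < light so the limiter label is
#' deterministic (the growth rate itself is unaffected by tie-breaking).
#'
#' @param state named list or vector with elements `A`, `N`, `P`.
#' @param params a [model_params()] object.
#' @return List with `f_N`, `f_P`, `f_I` and `limiter` (one of `"N"`, `"P"`,
#'   `"light"`).
#' @export
growth_factors <- function(state, params) {
  st <- as.list(state)
  f_N <- monod(st$N, params$m_N)
  f_P <- monod(st$P, params$m_P)
  f_I <- light_limitation(st$A, params)
  f <- c(N = f_N, P = f_P, light = f_I)
  list(f_N = f_N, f_P = f_P, f_I = f_I,
       limiter = names(f)[which.min(f)])  # which.min takes the first on ties
}

#' Time derivatives of the lake model
#'
#' The fixed-quota core: algae grow at `mu = mu_max * min(f_N, f_P, f_I)` and
#' are washed out at the dilution rate; each dissolved nutrient is supplied
#' and flushed by dilution and consumed in strict proportion (quota) to carbon
#' production.
#'
#' @param state named list or vector with `A`, `N`, `P` (mg m^-3).
#' @param params a [model_params()] object.
#' @param supply a [supply()] object.
#' @return Named numeric vector `(dA, dN, dP)` in mg m^-3 d^-1.
#' @export
lake_rhs <- function(state, params, supply) {
  st <- as.list(state)
  gf <- growth_factors(st, params)
  mu <- params$mu_max * min(gf$f_N, gf$f_P, gf$f_I)
  d <- c(dA = (mu - params$a) * st$A,
         dN = params$a * (supply$N_in - st$N) - params$c_N * mu * st$A,
         dP = params$a * (supply$P_in - st$P) - params$c_P * mu * st$A)
  if (any(!is.finite(d)))
    stop("numerical failure in lake_rhs: non-finite derivative in ",
         paste(names(d)[!is.finite(d)], collapse = ", "), call. = FALSE)
  d
}

#' Droop-variant time derivatives
#'
#' Flexible-stoichiometry core: growth depends on internal cell quotas
#' (`mu = mu_inf * min_X(1 - Qmin_X/Q_X) * f_I`), uptake is Monod in the
#' external concentration, and quotas are diluted by growth.  Quotas below
#' subsistence are clipped (with a warning) before evaluating growth.
#'
#' @param state named list or vector with `A`, `N`, `P`, `Q_N`, `Q_P`.
#' @param params a [droop_params()] object.
#' @param supply a [supply()] object.
#' @return Named numeric vector `(dA, dN, dP, dQ_N, dQ_P)`.
#' @export
droop_rhs <- function(state, params, supply) {
  if (!inherits(params, "ter_droop_params"))
    stop("droop_rhs requires droop_params()", call. = FALSE)
  st <- as.list(state)
  if (st$Q_N < params$Qmin_N || st$Q_P < params$Qmin_P) {
    warning("quota below subsistence clipped in droop_rhs", call. = FALSE)
    st$Q_N <- max(st$Q_N, params$Qmin_N)
    st$Q_P <- max(st$Q_P, params$Qmin_P)
  }
  f_I <- light_limitation(st$A, params)
  g <- min(1 - params$Qmin_N / st$Q_N, 1 - params$Qmin_P / st$Q_P)
  mu <- params$mu_inf * g * f_I
  v_N <- params$vmax_N * monod(st$N, params$m_N)
  v_P <- params$vmax_P * monod(st$P, params$m_P)
  d <- c(dA = (mu - params$a) * st$A,
         dN = params$a * (supply$N_in - st$N) - v_N * st$A,
         dP = params$a * (supply$P_in - st$P) - v_P * st$A,
         dQ_N = v_N - mu * st$Q_N,
         dQ_P = v_P - mu * st$Q_P)
  if (any(!is.finite(d)))
    stop("numerical failure in droop_rhs: non-finite derivative in ",
         paste(names(d)[!is.finite(d)], collapse = ", "), call. = FALSE)
  d
}

#' GPP from a steady state
#'
#' Gross primary production is the gross carbon fixation `mu * A` converted
#' to oxygen units by `o2_per_c` and to per-litre by 1/1000; no respiration is
#' subtracted (the model carries no explicit respiration term).
#'
#' @param ss a `ter_steady_state` from [solve_steady_state()].
#' @param params a [model_params()] object.
#' @return GPP in mg O2 L^-1 d^-1 (zero for washout states).
#' @export
gpp_from_state <- function(ss, params) {
  if (isTRUE(ss$washout)) return(0)
  ss$mu * ss$state[["A"]] * params$o2_per_c / 1000
}

.WASHOUT_A <- 1e-3  # mg C m^-3: biomass below this is treated as washed out

pars_vector <- function(params, supply) {
  base <- c(params$mu_max, params$a, params$z_max, params$m_N, params$m_P,
            params$c_N, params$c_P, params$I_in, params$h_I, params$k_bg,
            params$k_A, supply$N_in, supply$P_in)
  if (inherits(params, "ter_droop_params"))
    base <- c(base, params$mu_inf, params$Qmin_N, params$Qmin_P,
              params$vmax_N, params$vmax_P)
  base
}

#' Integrate the lake model to steady state
#'
#' Integrates from the reproducible initial state (A = 1 mg C m^-3, dissolved
#' nutrients at their supply concentrations) with an adaptive linearly
#' implicit (Rosenbrock) stepper until the relative rate of change
#' `max_i |dx_i/dt| / (|x_i| + 1e-6)` falls below `tol`, or `t_max` is
#' reached.  For the Droop variant the initial quotas are twice subsistence.
#'
#' @param params a [model_params()] or [droop_params()] object.
#' @param supply a [supply()] object.
#' @param t_max maximum integration time, days (>= 500).
#' @param tol relative-rate convergence tolerance, in (0, 1e-3].
#' @param variant `"fixed_quota"` or `"droop"` (the latter requires
#'   [droop_params()]).
#' @return An object of class `ter_steady_state`: list with `state` (named
#'   A/N/P vector, plus quotas for Droop), `f_N`, `f_P`, `f_I`, `limiter`,
#'   `mu`, `gpp`, `converged`, `washout`, `t_end`.
#' @examples
#' ss <- solve_steady_state(model_params(), supply(700, 30))
#' ss$mu  # ~0.1: growth balances dilution
#' @export
solve_steady_state <- function(params, supply, t_max = 3000, tol = 1e-6,
                               variant = c("fixed_quota", "droop")) {
  variant <- match.arg(variant)
  if (!is.numeric(t_max) || t_max < 500)
    stop("invalid parameter: t_max must be >= 500 days", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0 || tol > 1e-3)
    stop("invalid parameter: tol must be in (0, 1e-3]", call. = FALSE)
  if (variant == "droop" && !inherits(params, "ter_droop_params"))
    stop("variant 'droop' requires droop_params()", call. = FALSE)

  if (variant == "droop") {
    y0 <- c(1, supply$N_in, supply$P_in, 2 * params$Qmin_N, 2 * params$Qmin_P)
  } else {
    y0 <- c(1, supply$N_in, supply$P_in)
  }
  res <- .ode_steady_cpp(y0, pars_vector(params, supply),
                         as.integer(variant == "droop"), t_max, tol,
                         1e-8, 1e-10)
  if (!res$converged)
    warning("steady-state solver did not converge by t_max = ", t_max,
            " d (rate ", signif(res$rate, 3), ")", call. = FALSE)

  st <- res$state
  names(st) <- if (variant == "droop") c("A", "N", "P", "Q_N", "Q_P")
               else c("A", "N", "P")
  washout <- st[["A"]] < .WASHOUT_A
  if (variant == "droop") {
    f_I <- light_limitation(st[["A"]], params)
    gq <- min(1 - params$Qmin_N / max(st[["Q_N"]], params$Qmin_N),
              1 - params$Qmin_P / max(st[["Q_P"]], params$Qmin_P))
    mu <- params$mu_inf * gq * f_I
    gf <- growth_factors(st[c("A", "N", "P")], params)
    f_N <- gf$f_N; f_P <- gf$f_P
    limiter <- gf$limiter
  } else {
    gf <- growth_factors(st, params)
    f_N <- gf$f_N; f_P <- gf$f_P; f_I <- gf$f_I
    limiter <- gf$limiter
    mu <- params$mu_max * min(f_N, f_P, f_I)
  }
  out <- list(state = st, f_N = f_N, f_P = f_P, f_I = f_I, limiter = limiter,
              mu = mu, converged = res$converged, washout = washout,
              t_end = res$t_end, rate = res$rate, variant = variant)
  out$gpp <- if (washout) 0 else mu * st[["A"]] * params$o2_per_c / 1000
  class(out) <- "ter_steady_state"
  out
}

#' @export
print.ter_steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s)%s%s\n", x$variant,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$washout) " [washout]" else ""))
  cat("  state:", paste(sprintf("%s = %.4g", names(x$state), x$state),
                        collapse = ", "), "\n")
  cat(sprintf("  mu = %.5f d-1, limiter = %s (f_N %.3f, f_P %.3f, f_I %.3f)\n",
              x$mu, x$limiter, x$f_N, x$f_P, x$f_I))
  cat(sprintf("  GPP = %.4f mg O2 L-1 d-1\n", x$gpp))
  invisible(x)
}
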