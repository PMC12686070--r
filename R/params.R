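#' Lake model parameters
#'
#' Constructs the full parameter set of the lake chemostat model: algal
#' physiology (maximum growth rate, half-saturation constants, fixed element
#' quotas), physical setting (dilution rate, mixed-layer depth), the light
#' environment (incident irradiance, half-saturation irradiance, background
#' and algal-specific attenuation), and the O2-per-C conversion used to
#' express gross primary production.
#'
#' Defaults place the model in a mesotrophic-lake regime in which the low
#' supply scenarios are nutrient-limited throughout and the high supply
#' scenarios are capped by self-shading (see [calibrate_light()]).  The quota
#' pair `c_N`/`c_P` is chosen so the molar consumption N:P ratio equals the
#' Redfield proportion of 16 (see [consumption_np()]).
#'
#' @param mu_max maximum specific algal growth rate, d^-1.
#' @param a dilution rate (inverse water residence time), d^-1.
#' @param z_max maximum (mixed-layer) depth, m.
#' @param m_N,m_P half-saturation constants for N and P limitation of growth,
#'   mg N m^-3 and mg P m^-3.
#' @param c_N,c_P fixed algal quotas, mg N and mg P per mg C.
#' @param I_in incident surface irradiance, umol photons m^-2 s^-1.
#' @param h_I half-saturation irradiance for growth, same units as `I_in`.
#' @param k_bg background light attenuation, m^-1.
#' @param k_A algal specific light attenuation, m^2 per mg C.
#' @param o2_per_c O2 produced per C fixed (photosynthetic quotient 1 gives
#'   32/12), mg O2 per mg C.
#' @return An object of class `ter_params` (a named list).
#' @examples
#' p <- model_params()
#' consumption_np(p)  # ~16, molar
#' @export
model_params <- function(mu_max = 1.0, a = 0.1, z_max = 2.5,
                         m_N = 10.8, m_P = 1.5,
                         c_N = 0.1084, c_P = 0.015,
                         I_in = 300, h_I = 120,
                         k_bg = 0.2, k_A = 0.00073,
                         o2_per_c = 32 / 12) {
  p <- list(mu_max = mu_max, a = a, z_max = z_max, m_N = m_N, m_P = m_P,
            c_N = c_N, c_P = c_P, I_in = I_in, h_I = h_I, k_bg = k_bg,
            k_A = k_A, o2_per_c = o2_per_c)
  validate_params(p)
  class(p) <- "ter_params"
  p
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("invalid parameter: all fields must be finite numeric scalars (",
         paste(names(p)[!num], collapse = ", "), ")", call. = FALSE)
  pos <- vapply(p, function(x) x > 0, logical(1))
  if (!all(pos))
    stop("invalid parameter: all fields must be strictly positive (",
         paste(names(p)[!pos], collapse = ", "), ")", call. = FALSE)
  if (p$a >= p$mu_max)
    warning("a >= mu_max: algae cannot persist (washout) in any scenario",
            call. = FALSE)
  invisible(p)
}

# atomic masses used for all mass <-> molar N:P conversions
.MASS_N <- 14.007
.MASS_P <- 30.974

#' Molar consumption N:P ratio implied by the algal quotas
#'
#' The fixed quotas `c_N` and `c_P` (mass per mg C) set the ratio in which the
#' algae consume the two nutrients; expressed in moles this is the supply
#' ratio at which limitation switches between N and P (16 with the default
#' Redfield-proportioned quotas).
#'
#' @param params a [model_params()] object.
#' @return Dimensionless molar N:P ratio `(c_N/14.007)/(c_P/30.974)`.
#' @export
consumption_np <- function(params) {
  (params$c_N / .MASS_N) / (params$c_P / .MASS_P)
}

#' @export
print.ter_params <- function(x, ...) {
  cat("Lake model parameters (fixed-quota):\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  cat(sprintf("  molar consumption N:P = %.3f\n", consumption_np(x)))
  invisible(x)
}

#' Nutrient supply (inflow concentrations)
#'
#' @param N_in nitrogen input concentration, mg N m^-3.
#' @param P_in phosphorus input concentration, mg P m^-3.
#' @return An object of class `ter_supply`.
#' @export
supply <- function(N_in, P_in) {
  if (!is.numeric(N_in) || !is.numeric(P_in) || length(N_in) != 1 ||
      length(P_in) != 1 || !is.finite(N_in) || !is.finite(P_in) ||
      N_in <= 0 || P_in <= 0)
    stop("invalid parameter: N_in and P_in must be strictly positive scalars",
         call. = FALSE)
  structure(list(N_in = N_in, P_in = P_in), class = "ter_supply")
}

#' Molar N:P ratio of a nutrient supply
#'
#' Converts mass concentrations (mg m^-3) to moles using atomic masses 14.007
#' (N) and 30.974 (P) and returns their ratio.
#'
#' @param N_in nitrogen input, mg N m^-3 (or a `ter_supply` object).
#' @param P_in phosphorus input, mg P m^-3.
#' @return Dimensionless molar N:P.
#' @examples
#' supply_molar_ratio(700, 30)  # ~51.6
#' @export
supply_molar_ratio <- function(N_in, P_in) {
  if (inherits(N_in, "ter_supply")) {
    P_in <- N_in$P_in
    N_in <- N_in$N_in
  }
  if (any(!is.finite(N_in)) || any(!is.finite(P_in)) ||
      any(N_in <= 0) || any(P_in <= 0))
    stop("invalid parameter: inputs to supply_molar_ratio must be positive",
         call. = FALSE)
  (N_in / .MASS_N) / (P_in / .MASS_P)
}

#' Droop (flexible-quota) variant parameters
#'
#' Extends the fixed-quota parameter set with the quantities of the Droop
#' formulation: growth approaches `mu_inf` as cell quotas rise above the
#' subsistence quotas `Qmin_N`/`Qmin_P`, and uptake saturates in the external
#' concentration with maxima `vmax_N`/`vmax_P` (half-saturations are shared
#' with the fixed model's `m_N`/`m_P`).  Growth is
#' `mu_inf * min_X(1 - Qmin_X/Q_X) * f_I`.
#'
#' @param params a [model_params()] object supplying the shared fields.
#' @param mu_inf growth rate at infinite quota, d^-1.
#' @param Qmin_N,Qmin_P subsistence quotas, mg per mg C.
#' @param vmax_N,vmax_P maximum uptake rates, mg per mg C per d.
#' @return An object of class `ter_droop_params`.
#' @export
droop_params <- function(params = model_params(), mu_inf = 2.0,
                         Qmin_N = params$c_N / 2, Qmin_P = params$c_P / 2,
                         vmax_N = 10 * params$c_N, vmax_P = 10 * params$c_P) {
  extra <- list(mu_inf = mu_inf, Qmin_N = Qmin_N, Qmin_P = Qmin_P,
                vmax_N = vmax_N, vmax_P = vmax_P)
  bad <- vapply(extra, function(x) !is.numeric(x) || length(x) != 1 ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    stop("invalid parameter: ", paste(names(extra)[bad], collapse = ", "),
         call. = FALSE)
  p <- c(unclass(params), extra)
  class(p) <- c("ter_droop_params", "ter_params")
  p
}
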