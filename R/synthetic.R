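#' Specify a synthetic response curve
#'
#' Defines a noisy response curve of known shape over a molar N:P range, used
#' to validate the detection stage without running the lake model.  Shapes
#' are defined on the log10 ratio axis `t = log10(x)` (except `saturating`,
#' a shifted Michaelis-Menten in the natural ratio):
#' \describe{
#'   \item{flat}{`y0`}
#'   \item{linear}{`b0 + b1 * t`}
#'   \item{hinge}{`b0 + b1 * t + (b2 - b1) * max(0, t - psi)`, `psi` in log10
#'     units; slopes `b1` below and `b2` above}
#'   \item{logistic}{`lower + (upper - lower)/(1 + exp(-s (t - m)))`,
#'     threshold at `10^m`}
#'   \item{saturating}{`ymax * x / (K + x)`, no threshold}
#' }
#'
#' @param shape one of `"flat"`, `"linear"`, `"saturating"`, `"logistic"`,
#'   `"hinge"`.
#' @param x_lo,x_hi molar N:P range (log-spaced sampling).
#' @param n_points number of samples.
#' @param noise_sigma Gaussian observation noise s.d., response units.
#' @param seed integer seed making the curve reproducible.
#' @param ... shape parameters overriding the defaults
#'   (`y0`, `b0`, `b1`, `b2`, `psi`, `lower`, `upper`, `m`, `s`, `ymax`, `K`).
#' @return An object of class `ter_curve_spec`.
#' @export
curve_spec <- function(shape = c("hinge", "logistic", "flat", "linear",
                                 "saturating"),
                       x_lo = 2, x_hi = 120, n_points = 40,
                       noise_sigma = 0, seed = 1L, ...) {
  shape <- match.arg(shape)
  if (!(x_lo > 0 && x_hi > x_lo))
    stop("invalid spec: need 0 < x_lo < x_hi", call. = FALSE)
  if (noise_sigma < 0) stop("invalid spec: noise_sigma must be >= 0",
                            call. = FALSE)
  defaults <- switch(shape,
    flat = list(y0 = 1),
    linear = list(b0 = 0, b1 = 1),
    hinge = list(b0 = 0, b1 = 2, b2 = 0, psi = log10(16)),
    logistic = list(lower = 0, upper = 1, m = log10(16), s = 6),
    saturating = list(ymax = 1, K = 16))
  pars <- utils::modifyList(defaults, list(...))
  if (!all(vapply(pars, is.finite, logical(1))))
    stop("invalid spec: all shape parameters must be finite", call. = FALSE)
  structure(list(shape = shape, pars = pars, x_lo = x_lo, x_hi = x_hi,
                 n_points = n_points, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "ter_curve_spec")
}

curve_shape_fun <- function(spec) {
  p <- spec$pars
  switch(spec$shape,
    flat = function(t) rep(p$y0, length(t)),
    linear = function(t) p$b0 + p$b1 * t,
    hinge = function(t) p$b0 + p$b1 * t + (p$b2 - p$b1) * pmax(0, t - p$psi),
    logistic = function(t) p$lower +
      (p$upper - p$lower) / (1 + exp(-p$s * (t - p$m))),
    saturating = function(t) p$ymax * 10^t / (p$K + 10^t))
}

#' Generate a synthetic response curve with known ground truth
#'
#' Samples the spec's shape at log-spaced ratios, adds seeded Gaussian noise,
#' and returns the data together with the true threshold location and slopes
#' so detection error can be measured exactly.
#'
#' @param spec a [curve_spec()].
#' @return List with `curve` (data frame with columns `x`, `y`) and `truth`
#'   (list with `shape`, `x_ter`, `slope_below`, `slope_above`).
#' @examples
#' g <- gen_curve(curve_spec("hinge", noise_sigma = 0.02, seed = 7))
#' g$truth$x_ter  # 16
#' @export
gen_curve <- function(spec) {
  stopifnot(inherits(spec, "ter_curve_spec"))
  x <- 10^seq(log10(spec$x_lo), log10(spec$x_hi), length.out = spec$n_points)
  t <- log10(x)
  y <- curve_shape_fun(spec)(t)
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(spec$seed)
    y <- y + stats::rnorm(length(y), 0, spec$noise_sigma)
  }
  truth <- list(shape = spec$shape,
                x_ter = switch(spec$shape, hinge = 10^spec$pars$psi,
                               logistic = 10^spec$pars$m, NA_real_),
                slope_below = switch(spec$shape, hinge = spec$pars$b1,
                                     linear = spec$pars$b1, NA_real_),
                slope_above = switch(spec$shape, hinge = spec$pars$b2,
                                     NA_real_))
  list(curve = data.frame(x = x, y = y), truth = truth)
}

#' Threshold-recovery experiment over seeded replicates
#'
#' For each curve spec, generates `n_reps` replicate noisy curves (seeds
#' derived deterministically from `base_seed`), runs [detect_ter()] on each,
#' and summarizes shape-classification accuracy and the error of the
#' recovered threshold location and slopes.
#'
#' @param specs list of [curve_spec()] objects.
#' @param n_reps replicates per spec (>= 20).
#' @param base_seed integer governing all replicate seeds.
#' @param margin model-selection margin passed to [detect_ter()].
#' @return Data frame with one row per spec: `shape_true`, `noise_sigma`,
#'   `n_points`, `accuracy` (fraction classified as the true shape),
#'   `threshold_rate` (fraction with any threshold detected),
#'   `median_rel_err`, `iqr_rel_err` (relative x_ter error, threshold shapes
#'   only), `median_slope_err`.
#' @export
recovery_experiment <- function(specs, n_reps = 50, base_seed = 1L,
                                margin = 2) {
  if (inherits(specs, "ter_curve_spec")) specs <- list(specs)
  if (n_reps < 20) stop("invalid parameter: n_reps must be >= 20",
                        call. = FALSE)
  base_seed <- as.integer(base_seed)
  rows <- lapply(seq_along(specs), function(si) {
    spec <- specs[[si]]
    res <- lapply(seq_len(n_reps), function(i) {
      sp <- spec
      sp$seed <- (base_seed %% 9973L) * 100000L + si * 1000L + i
      g <- gen_curve(sp)
      est <- detect_ter(g$curve, x_col = "x", y_col = "y", margin = margin,
                        attach_switch = FALSE)
      rel <- if (is.finite(g$truth$x_ter) && is.finite(est$x_ter))
        abs(est$x_ter - g$truth$x_ter) / g$truth$x_ter else NA_real_
      serr <- if (is.finite(g$truth$slope_below) &&
                  is.finite(est$slope_below))
        abs(est$slope_below - g$truth$slope_below) else NA_real_
      list(shape = est$shape, thr = is.finite(est$x_ter), rel = rel,
           serr = serr)
    })
    shp <- vapply(res, `[[`, character(1), "shape")
    rel <- vapply(res, `[[`, numeric(1), "rel")
    serr <- vapply(res, `[[`, numeric(1), "serr")
    data.frame(shape_true = spec$shape, noise_sigma = spec$noise_sigma,
               n_points = spec$n_points,
               accuracy = mean(shp == spec$shape),
               threshold_rate = mean(vapply(res, `[[`, logical(1), "thr")),
               median_rel_err = stats::median(rel, na.rm = TRUE),
               iqr_rel_err = stats::IQR(rel, na.rm = TRUE),
               median_slope_err = stats::median(serr, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
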