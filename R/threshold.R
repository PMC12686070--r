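#' Continuous two-segment (hinge) fit with profiled breakpoint
#'
#' Fits `y = b0 + b1 * x + b2 * max(0, x - psi)` by profiling the breakpoint
#' `psi` over `grid_n` candidates inside `window` (by default the central 90%
#' of the x-range: boundary breakpoints are unidentifiable) and refining the
#' best candidate by golden-section search.  At each candidate the remaining
#' coefficients are solved by ordinary least squares.
#'
#' @param x abscissa values, strictly increasing (any axis: the breakpoint is
#'   returned on the same axis).
#' @param y response values, same length, >= 8 finite points.
#' @param window length-2 numeric, admissible breakpoint interval.
#' @param grid_n number of profile candidates (default 201).
#' @return List with `psi`, `intercept`, `slope1` (below), `slope2` (above),
#'   `rss`, `degenerate` (collinear input), `boundary` (optimum pinned at the
#'   window edge), `grid_step` and `fitted`.
#' @examples
#' x <- seq(0, 2, length.out = 40)
#' f <- fit_hinge(x, 1 + 2 * x - 2 * pmax(0, x - 1.2))
#' f$psi  # 1.2
#' @export
fit_hinge <- function(x, y, window = NULL, grid_n = 201) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 8)
    stop("insufficient data: fit_hinge needs >= 8 finite points",
         call. = FALSE)
  if (any(diff(x) <= 0))
    stop("invalid parameter: x must be strictly increasing", call. = FALSE)
  rng <- range(x)
  if (is.null(window))
    window <- c(rng[1] + 0.05 * diff(rng), rng[2] - 0.05 * diff(rng))
  grid <- seq(window[1], window[2], length.out = grid_n)
  step <- diff(window) / (grid_n - 1)

  prof_rss <- function(psi) {
    X <- cbind(1, x, pmax(0, x - psi))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  rss_grid <- vapply(grid, prof_rss, numeric(1))
  i <- which.min(rss_grid)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(prof_rss, c(lo, hi), tol = .Machine$double.eps^0.5)
  psi <- if (opt$objective < rss_grid[i]) opt$minimum else grid[i]

  X <- cbind(1, x, pmax(0, x - psi))
  f <- stats::lm.fit(X, y)
  b <- f$coefficients
  rss <- sum(f$residuals^2)
  line_rss <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  scale2 <- sum((y - mean(y))^2)
  list(psi = psi, intercept = unname(b[1]), slope1 = unname(b[2]),
       slope2 = unname(b[2] + b[3]), rss = rss,
       degenerate = line_rss <= max(1e-12 * scale2, 1e-20),
       boundary = min(psi - window[1], window[2] - psi) < 0.5 * step,
       grid_step = step, window = window,
       fitted = unname(X %*% b)[, 1])
}

# least-squares 4-parameter logistic on t with the midpoint box-constrained
# to [mlo, mhi] via a logit transform; several (steepness, midpoint) starts
fit_logistic4 <- function(t, y, mlo, mhi) {
  pred <- function(L, U, m, s) L + (U - L) / (1 + exp(-s * (t - m)))
  obj <- function(p) {
    m <- mlo + (mhi - mlo) * stats::plogis(p[3])
    r <- y - pred(p[1], p[2], m, p[4])
    sum(r^2)
  }
  dirn <- sign(stats::cov(t, y)); if (dirn == 0) dirn <- 1
  drange <- diff(range(t))
  best <- NULL
  for (s0 in c(2, 6, 20, 60) * dirn / drange) {
    for (q in c(0.35, 0.65)) {
      m0 <- stats::quantile(t, q, names = FALSE)
      z0 <- stats::qlogis(min(max((m0 - mlo) / (mhi - mlo), 0.02), 0.98))
      o <- try(stats::optim(c(min(y), max(y), z0, s0), obj,
                            control = list(maxit = 3000, reltol = 1e-12)),
               silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  if (is.null(best)) return(NULL)
  best <- stats::optim(best$par, obj,
                       control = list(maxit = 6000, reltol = 1e-14))
  p <- best$par
  m <- mlo + (mhi - mlo) * stats::plogis(p[3])
  step <- (mhi - mlo) / 200
  list(lower = p[1], upper = p[2], midpoint = m, steepness = p[4],
       rss = best$value, boundary = min(m - mlo, mhi - m) < 0.5 * step,
       fitted = pred(p[1], p[2], m, p[4]))
}

# least-squares shifted Michaelis-Menten saturating fit on the natural axis
fit_saturating <- function(x, y) {
  pred <- function(y0, ym, lK) y0 + (ym - y0) * x / (exp(lK) + x)
  obj <- function(p) sum((y - pred(p[1], p[2], p[3]))^2)
  best <- NULL
  for (K0 in stats::quantile(x, c(0.15, 0.5, 0.85), names = FALSE)) {
    o <- try(stats::optim(c(y[1], y[length(y)], log(K0)), obj,
                          control = list(maxit = 3000, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) return(NULL)
  best <- stats::optim(best$par, obj,
                       control = list(maxit = 6000, reltol = 1e-14))
  p <- best$par
  list(y0 = p[1], ymax = p[2], K = exp(p[3]), rss = best$value,
       fitted = pred(p[1], p[2], p[3]))
}

# small-sample corrected information criterion; k counts shape parameters
# plus the residual variance
aicc <- function(rss, n, k) {
  rss <- max(rss, 1e-20)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Classify the shape of a response curve
#'
#' Competes five response families — flat, linear (in log10 ratio),
#' saturating (shifted Michaelis-Menten in the natural ratio), 4-parameter
#' logistic (in log10 ratio) and breakpoint/hinge — by least squares and
#' ranks them with a small-sample corrected information criterion.  The
#' hinge family is profiled on three abscissa parameterizations (log10 x, x
#' and 1/x, because Liebig response limbs are linear in the swept nutrient
#' concentration, i.e. in the ratio or its inverse); the best of the three
#' represents the family.  Hinge breakpoints and logistic midpoints are
#' confined to the central 90% of the log10 range; fits whose optimum pins at
#' that window's edge are boundary-unidentifiable and excluded from model
#' selection.  The minimum-criterion model wins only with a margin of
#' `margin` over every simpler candidate; otherwise the simplest candidate
#' within `margin` of the minimum is preferred.
#'
#' @param x ratio values (natural scale, strictly positive, increasing).
#' @param y response values (>= 10 points).
#' @param margin information-criterion units required to prefer a more
#'   complex model (default 2).
#' @param grid_n hinge profile resolution.
#' @param flat_tol relative response variation below which the curve is
#'   declared flat without fitting: deterministic model curves carry
#'   structured solver error of order the convergence tolerance, which an
#'   information criterion would otherwise happily "detect" (default 1e-4,
#'   two orders above the solver tolerance and far below any real response).
#' @return List with `shape`, `scores` (criterion per candidate), the
#'   post-exclusion `delta_best` margin, `x_ter` (NA when the winning shape
#'   carries no threshold), `y_ter`, and the per-family `fits`.
#' @export
classify_response <- function(x, y, margin = 2, grid_n = 201,
                              flat_tol = 1e-4) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10)
    stop("insufficient data: classify_response needs >= 10 points",
         call. = FALSE)
  if (any(x <= 0)) stop("invalid parameter: ratios must be positive",
                        call. = FALSE)
  o <- order(x); x <- x[o]; y <- y[o]
  t <- log10(x)
  n <- length(y)
  if (diff(range(y)) <= flat_tol * max(abs(y), .Machine$double.xmin)) {
    scores <- c(flat = aicc(sum((y - mean(y))^2), n, 2), linear = NA_real_,
                saturating = NA_real_, hinge = NA_real_, logistic = NA_real_)
    return(list(shape = "flat", scores = scores, delta_best = Inf,
                x_ter = NA_real_, y_ter = NA_real_,
                fits = list(flat = list(mean = mean(y),
                                        rss = sum((y - mean(y))^2),
                                        fitted = rep(mean(y), n))),
                n = n, flat_guard = TRUE))
  }
  rng <- range(t)
  tlo <- rng[1] + 0.05 * diff(rng); thi <- rng[2] - 0.05 * diff(rng)

  fits <- list()
  fits$flat <- list(mean = mean(y), rss = sum((y - mean(y))^2),
                    fitted = rep(mean(y), n))
  fl <- stats::lm.fit(cbind(1, t), y)
  fits$linear <- list(coef = fl$coefficients, rss = sum(fl$residuals^2),
                      fitted = y - fl$residuals)
  fits$saturating <- tryCatch(fit_saturating(x, y), error = function(e) NULL)

  hcand <- list(
    log = try(fit_hinge(t, y, window = c(tlo, thi), grid_n = grid_n),
              silent = TRUE),
    nat = try(fit_hinge(x, y, window = c(10^tlo, 10^thi), grid_n = grid_n),
              silent = TRUE),
    inv = try({
      u <- rev(1 / x)
      h <- fit_hinge(u, rev(y), window = c(10^-thi, 10^-tlo), grid_n = grid_n)
      h$fitted <- rev(h$fitted)
      h
    }, silent = TRUE))
  hcand <- hcand[!vapply(hcand, inherits, logical(1), "try-error")]
  if (length(hcand) > 0) {
    hb <- which.min(vapply(hcand, `[[`, numeric(1), "rss"))
    fits$hinge <- hcand[[hb]]
    fits$hinge$axis <- names(hcand)[hb]
    fits$hinge$x_ter <- switch(fits$hinge$axis, log = 10^fits$hinge$psi,
                               nat = fits$hinge$psi, inv = 1 / fits$hinge$psi)
  }
  fits$logistic <- tryCatch(fit_logistic4(t, y, tlo, thi),
                            error = function(e) NULL)
  if (!is.null(fits$logistic)) fits$logistic$x_ter <- 10^fits$logistic$midpoint

  shapes <- c("flat", "linear", "saturating", "hinge", "logistic")
  kpar <- c(flat = 2, linear = 3, saturating = 4, hinge = 5, logistic = 5)
  scores <- vapply(shapes, function(s) {
    f <- fits[[s]]
    if (is.null(f)) {
      message("classify_response: ", s, " fit failed to converge; scored Inf")
      return(Inf)
    }
    aicc(f$rss, n, kpar[[s]])
  }, numeric(1))

  eligible <- scores
  for (s in c("hinge", "logistic"))
    if (!is.null(fits[[s]]) && isTRUE(fits[[s]]$boundary)) eligible[s] <- Inf
  fin <- eligible[is.finite(eligible)]
  if (length(fin) == 0) stop("classify_response: all candidate fits failed",
                             call. = FALSE)
  within <- names(fin)[fin <= min(fin) + margin]
  shape <- within[which.min(kpar[within])]
  delta_best <- if (length(fin) > 1) diff(sort(fin)[1:2]) else Inf

  thr <- shape %in% c("hinge", "logistic")
  x_ter <- if (thr) fits[[shape]]$x_ter else NA_real_
  y_ter <- NA_real_
  if (thr) {
    f <- fits[[shape]]
    y_ter <- if (shape == "hinge") {
      g <- switch(f$axis, log = log10(x_ter), nat = x_ter, inv = 1 / x_ter)
      f$intercept + f$slope1 * g   # at the knot both segments agree
    } else {
      (f$lower + f$upper) / 2      # symmetric 4PL: inflection = midpoint
    }
  }
  list(shape = shape, scores = scores, delta_best = delta_best,
       x_ter = x_ter, y_ter = y_ter, fits = fits, n = n)
}

#' Locate and characterize the threshold elemental ratio on a response curve
#'
#' Runs [classify_response()] on the converged points of a response curve.
#' When the winning shape carries a threshold (hinge or logistic), the TER is
#' reported as x (the molar supply N:P at the breakpoint, or the logistic
#' inflection abscissa) and y (the fitted response there), together with
#' least-squares data slopes below and above the threshold.  When the winning
#' shape is flat, linear or saturating the estimate is returned with `x_ter`
#' absent (`NA`) — that outcome is not an error.  For model curves carrying a
#' scenario attribute the mechanistic N-to-P limitation switch point is
#' attached (see [mechanistic_switch()]).
#'
#' @param curve a `ter_curve` from [run_gradient()], or any data frame; by
#'   default columns `molar_NP`/`gpp` are used, else `x`/`y`.
#' @param x_col,y_col column names overriding the defaults.
#' @param margin,grid_n,flat_tol see [classify_response()].
#' @param attach_switch compute `mech_switch_x` when a scenario is attached.
#' @param t_max,tol solver settings for the mechanistic switch.
#' @return An object of class `ter_estimate`: `x_ter`, `y_ter`, `shape`,
#'   `scores`, `delta_best`, `slope_below`, `slope_above`, `mech_switch_x`,
#'   plus fit diagnostics.
#' @export
detect_ter <- function(curve, x_col = NULL, y_col = NULL, margin = 2,
                       grid_n = 201, flat_tol = 1e-4, attach_switch = TRUE,
                       t_max = 3000, tol = 1e-6) {
  df <- as.data.frame(curve)
  if (is.null(x_col)) x_col <- if ("molar_NP" %in% names(df)) "molar_NP" else "x"
  if (is.null(y_col)) y_col <- if ("gpp" %in% names(df)) "gpp" else "y"
  miss <- setdiff(c(x_col, y_col), names(df))
  if (length(miss) > 0)
    stop("detect_ter: missing column(s) ", paste(miss, collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "), call. = FALSE)
  if ("converged" %in% names(df)) df <- df[df$converged, ]
  x <- df[[x_col]]; y <- df[[y_col]]
  if (sum(is.finite(x) & is.finite(y)) < 10)
    stop("insufficient data: detect_ter needs >= 10 converged points",
         call. = FALSE)

  cl <- classify_response(x, y, margin = margin, grid_n = grid_n,
                          flat_tol = flat_tol)
  sl <- c(slope_below = NA_real_, slope_above = NA_real_)
  if (is.finite(cl$x_ter))
    sl <- side_slopes(x, y, cl$x_ter)

  mech <- NA_real_
  scen <- attr(curve, "scenario")
  if (attach_switch && inherits(scen, "ter_scenario"))
    mech <- mechanistic_switch(scen, t_max = t_max, tol = tol)

  est <- list(x_ter = cl$x_ter, y_ter = cl$y_ter, shape = cl$shape,
              scores = cl$scores, delta_best = cl$delta_best,
              slope_below = unname(sl[1]), slope_above = unname(sl[2]),
              mech_switch_x = mech, n = cl$n, fits = cl$fits,
              x_col = x_col, y_col = y_col)
  class(est) <- "ter_estimate"
  est
}

# least-squares slope of y on log10(x) on each side of the threshold;
# a side with fewer than 4 points is reported NA
side_slopes <- function(x, y, x_ter) {
  t <- log10(x)
  out <- c(NA_real_, NA_real_)
  lower <- t <= log10(x_ter); upper <- !lower
  if (sum(lower) >= 4)
    out[1] <- stats::lm.fit(cbind(1, t[lower]), y[lower])$coefficients[2]
  if (sum(upper) >= 4)
    out[2] <- stats::lm.fit(cbind(1, t[upper]), y[upper])$coefficients[2]
  out
}

#' Sensitivity slopes below and above a threshold
#'
#' Least-squares slopes of the response against log10(molar N:P) on each side
#' of the detected threshold, each side requiring at least 4 points (a
#' thinner side is reported `NA`).
#'
#' @param est a `ter_estimate` with `x_ter` present.
#' @param curve the curve the estimate was computed from.
#' @return Named numeric vector `(slope_below, slope_above)`, response units
#'   per unit log10(N:P).
#' @export
sensitivity_slopes <- function(est, curve) {
  if (!is.finite(est$x_ter))
    stop("sensitivity_slopes: estimate has no threshold (x_ter absent)",
         call. = FALSE)
  df <- as.data.frame(curve)
  if ("converged" %in% names(df)) df <- df[df$converged, ]
  sl <- side_slopes(df[[est$x_col]], df[[est$y_col]], est$x_ter)
  c(slope_below = sl[1], slope_above = sl[2])
}

#' Supply ratio at which steady-state limitation switches between N and P
#'
#' Bisects the swept input of a scenario for the point where the steady-state
#' Monod factors satisfy `f_N = f_P` (light is excluded from the comparison:
#' the nutrient-order switch exists even when light masks the GPP response).
#'
#' @param s a [scenario()] object.
#' @param t_max,tol solver settings.
#' @param max_iter bisection iteration cap.
#' @return Molar supply N:P at the crossing, or `NA` if `f_N - f_P` does not
#'   change sign over the sweep.
#' @export
mechanistic_switch <- function(s, t_max = 3000, tol = 1e-6, max_iter = 60) {
  stopifnot(inherits(s, "ter_scenario"))
  gap <- function(v) {
    sup <- if (s$swept == "N_in") supply(v, s$fixed_value)
           else supply(s$fixed_value, v)
    ss <- suppressWarnings(solve_steady_state(s$params, sup, t_max = t_max,
                                              tol = tol))
    ss$f_N - ss$f_P
  }
  probe <- 10^seq(log10(s$sweep_lo), log10(s$sweep_hi), length.out = 9)
  gv <- vapply(probe, gap, numeric(1))
  sw <- which(diff(sign(gv)) != 0)
  if (length(sw) == 0) return(NA_real_)
  lo <- log10(probe[sw[1]]); hi <- log10(probe[sw[1] + 1])
  glo <- gv[sw[1]]
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    gm <- gap(10^mid)
    if (!is.finite(gm))
      stop("numerical failure in mechanistic_switch bisection", call. = FALSE)
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    if (hi - lo < 1e-10) break
  }
  v <- 10^((lo + hi) / 2)
  if (s$swept == "N_in") supply_molar_ratio(v, s$fixed_value)
  else supply_molar_ratio(s$fixed_value, v)
}

#' @export
print.ter_estimate <- function(x, ...) {
  cat("TER estimate:\n")
  cat(sprintf("  shape      = %s (margin %.2f over runner-up)\n",
              x$shape, x$delta_best))
  if (is.finite(x$x_ter)) {
    cat(sprintf("  x_ter      = %.4g (molar N:P)\n", x$x_ter))
    cat(sprintf("  y_ter      = %.4g\n", x$y_ter))
    cat(sprintf("  slopes     = %.4g (below) / %.4g (above) per log10 unit\n",
                x$slope_below, x$slope_above))
  } else {
    cat("  x_ter      = absent (no threshold-bearing shape selected)\n")
  }
  if (is.finite(x$mech_switch_x))
    cat(sprintf("  mechanistic N/P switch at molar N:P = %.4g\n",
                x$mech_switch_x))
  cat("  scores:", paste(sprintf("%s %.1f", names(x$scores), x$scores),
                         collapse = ", "), "\n")
  invisible(x)
}
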