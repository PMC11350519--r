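#' Forward model for spatially resolved diffuse reflectance
#'
#' R(rho) = (C1 / rho^m) * exp(-mu_eff * rho): the exponential-regime
#' approximation of the diffusion solution for a semi-infinite medium, with a
#' power-law prefactor whose exponent m depends on the detection range and
#' the optical properties (values of 0.5, 1 and 2 are all in use; m = 1 suits
#' the 2-10 mm range analyzed here). Used as a noiseless fixture generator
#' and as the fitting model.
#'
#' @param rho radial distances (mm), > 0.
#' @param C1 amplitude, > 0.
#' @param m power-law exponent.
#' @param mu_eff effective attenuation coefficient (mm^-1), >= 0.
#' @return reflectance values.
#' @examples
#' model_reflectance(2, C1 = 1, m = 1, mu_eff = 0.5)  # 0.18394
#' @export
model_reflectance <- function(rho, C1, m, mu_eff) {
  stopifnot(all(rho > 0), C1 > 0, mu_eff >= 0)
  (C1 / rho^m) * exp(-mu_eff * rho)
}

#' Log-transform a reflectance profile
#'
#' Computes y = ln(R * rho^m), the representation in which the
#' multiple-scattering region of a diffuse-reflectance profile is
#' approximately linear with slope -mu_eff. Bins with non-positive or
#' non-finite reflectance are masked (not zero-filled), so far-field empty
#' bins never enter downstream fits. Uncertainties propagate to first order
#' as y_se = R_se / R.
#'
#' @param profile a `dr_profile` (from [simulate_dr()], [read_profile_csv()]
#'   or [emulate_measurement()]).
#' @param m power-law exponent, default 1.
#' @return An object of class `log_profile`: list with `rho`, `y`, `y_se`,
#'   `m`, and logical `valid` mask.
#' @export
to_log_profile <- function(profile, m = 1) {
  stopifnot(inherits(profile, "dr_profile"), is.numeric(m), length(m) == 1L)
  valid <- is.finite(profile$R) & profile$R > 0
  if (!any(valid)) stop("profile has no bins with positive reflectance")
  y <- rep(NA_real_, length(profile$rho))
  y_se <- rep(NA_real_, length(profile$rho))
  y[valid] <- log(profile$R[valid] * profile$rho[valid]^m)
  y_se[valid] <- profile$R_se[valid] / profile$R[valid]
  structure(list(rho = profile$rho, y = y, y_se = y_se, m = m, valid = valid),
            class = "log_profile")
}

#' Construct a log-profile directly from vectors
#'
#' Mainly for constructed test fixtures and externally computed profiles.
#'
#' @param rho strictly increasing radii (mm).
#' @param y ln(R * rho^m) values (`NA` marks masked bins).
#' @param y_se optional uncertainties (default 0).
#' @param m exponent the values were computed with.
#' @return a `log_profile`.
#' @export
log_profile <- function(rho, y, y_se = NULL, m = 1) {
  stopifnot(is.numeric(rho), is.numeric(y), length(rho) == length(y),
            all(diff(rho) > 0))
  if (is.null(y_se)) y_se <- rep(0, length(y))
  stopifnot(length(y_se) == length(y))
  structure(list(rho = rho, y = y, y_se = y_se, m = m,
                 valid = is.finite(y)),
            class = "log_profile")
}

#' @export
as.data.frame.log_profile <- function(x, ...) {
  data.frame(rho_mm = x$rho, y = x$y, y_se = x$y_se)
}

#' Global slope of a log-reflectance profile
#'
#' Least-squares line fitted to y = ln(R * rho^m) over a radial range. When
#' every selected bin carries a positive uncertainty the fit is weighted by
#' 1 / y_se^2, otherwise it is unweighted. The returned `slope` is the raw
#' regression slope; its negative estimates mu_eff.
#'
#' @param logp a `log_profile`.
#' @param rho_range numeric length-2 interval (mm), inclusive.
#' @return list with `slope`, `intercept`, `slope_se`, `r_squared`, `n`,
#'   `rho_range`.
#' @export
fit_global_slope <- function(logp, rho_range) {
  stopifnot(inherits(logp, "log_profile"),
            is.numeric(rho_range), length(rho_range) == 2L,
            rho_range[2] > rho_range[1])
  sel <- logp$valid & logp$rho >= rho_range[1] & logp$rho <= rho_range[2]
  if (sum(sel) < 3) stop("need at least 3 valid bins in rho_range")
  rho <- logp$rho[sel]; y <- logp$y[sel]; se <- logp$y_se[sel]
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(y))
  # closed-form weighted least squares (quiet on exactly collinear input)
  W <- sum(w)
  xb <- sum(w * rho) / W; yb <- sum(w * y) / W
  sxx <- sum(w * (rho - xb)^2)
  slope <- sum(w * (rho - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * rho
  rss <- sum(w * res^2)
  tss <- sum(w * (y - yb)^2)
  n <- length(rho)
  list(slope = slope,
       intercept = intercept,
       slope_se = sqrt(max(rss, 0) / (n - 2) / sxx),
       r_squared = if (tss > 0) 1 - rss / tss else 1,
       n = n,
       rho_range = rho_range)
}

#' Moving-window local slopes of a log-reflectance profile
#'
#' Unweighted least-squares slope over a symmetric window of
#' 2 * window + 1 consecutive bins, centered at each bin whose full window
#' lies inside the valid mask. The symmetric design makes the estimator
#' exact for straight lines and first-order unbiased under curvature (the
#' local slope of a quadratic equals its derivative at the window center).
#'
#' @param logp a `log_profile`.
#' @param window half-width in bins, >= 2. Default 2 (a 5-point, 1 mm window
#'   at 0.2 mm spacing): wide enough to suppress Monte Carlo bin noise,
#'   narrow enough to localize a slope change to about one bin.
#' @return An object of class `slope_series`: list with `rho` (window
#'   centers), `slope`, `slope_se`, `window`.
#' @export
local_slopes <- function(logp, window = 2) {
  stopifnot(inherits(logp, "log_profile"),
            is.numeric(window), length(window) == 1L, window >= 2)
  window <- as.integer(window)
  n <- length(logp$rho)
  span <- 2L * window + 1L
  centers <- numeric(0); slopes <- numeric(0); ses <- numeric(0)
  if (n >= span) {
    for (i in seq.int(window + 1L, n - window)) {
      idx <- (i - window):(i + window)
      if (!all(logp$valid[idx])) next
      x <- logp$rho[idx]; y <- logp$y[idx]
      xc <- x - mean(x)
      sxx <- sum(xc^2)
      b <- sum(xc * y) / sxx
      res <- y - mean(y) - b * xc
      sigma2 <- sum(res^2) / (span - 2L)
      centers <- c(centers, logp$rho[i])
      slopes <- c(slopes, b)
      ses <- c(ses, sqrt(sigma2 / sxx))
    }
  }
  structure(list(rho = centers, slope = slopes, slope_se = ses,
                 window = window),
            class = "slope_series")
}

#' @export
as.data.frame.slope_series <- function(x, ...) {
  data.frame(rho_mm = x$rho, slope = x$slope, slope_se = x$slope_se)
}
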