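#' Square root of the bottom-to-top absorption ratio
#'
#' The predictor of the crossover-point relation: for fixed scattering and
#' top-layer thickness, theory predicts Cp proportional to
#' T * (1 + sqrt(mu_a2 / mu_a1)).
#'
#' @param mu_a2 bottom-layer absorption coefficient (mm^-1), >= 0.
#' @param mu_a1 top-layer absorption coefficient (mm^-1), > 0.
#' @return sqrt(mu_a2 / mu_a1), dimensionless.
#' @export
sqrt_ratio <- function(mu_a2, mu_a1) {
  if (any(mu_a1 <= 0)) stop("mu_a1 must be > 0")
  if (any(mu_a2 < 0)) stop("mu_a2 must be >= 0")
  sqrt(mu_a2 / mu_a1)
}

#' Fit the linear crossover-point relation
#'
#' Ordinary least squares of Cp against x = sqrt(mu_a2 / mu_a1) across a
#' grid of bilayer configurations. Points with externally studentized
#' residuals above 2.5 in the initial all-point fit are flagged as outliers
#' (at most `max_outliers`, largest first); the reported slope, intercept and
#' R^2 come from the refit without the flagged points, which stay listed in
#' `points`. The rule is applied once, not iterated. Points may also be
#' excluded manually by label.
#'
#' @param points data frame with columns `x`, `cp` and optionally `label`.
#' @param outlier_rule `"studentized"` (default) or `"none"`.
#' @param max_outliers cap on auto-flagged points, default 2.
#' @param exclude character labels to exclude manually (always flagged).
#' @return An object of class `relation_fit`: list with `slope` (mm per unit
#'   x), `intercept` (mm), `r_squared`, `slope_se`, `intercept_se`,
#'   `points` (input plus `outlier` flag), `n_used`.
#' @export
fit_cp_relation <- function(points, outlier_rule = c("studentized", "none"),
                            max_outliers = 2, exclude = character()) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(is.data.frame(points), all(c("x", "cp") %in% names(points)))
  if (is.null(points$label)) points$label <- paste0("p", seq_len(nrow(points)))
  pts <- points[is.finite(points$x) & is.finite(points$cp), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 points with finite x and cp")

  outlier <- pts$label %in% exclude
  if (outlier_rule == "studentized" && nrow(pts) >= 4) {
    fit0 <- stats::lm(cp ~ x, data = pts)
    rs <- suppressWarnings(abs(stats::rstudent(fit0)))
    # non-finite studentized residuals: a zero raw residual means an exact
    # fit (no outlier); a nonzero one means the case-deleted fit is perfect,
    # i.e. an unambiguous outlier
    bad <- !is.finite(rs)
    rs[bad] <- ifelse(abs(stats::residuals(fit0)[bad]) >
                        1e-8 * max(abs(pts$cp), 1), Inf, 0)
    cand <- which(rs > 2.5 & !outlier)
    if (length(cand) > max_outliers) {
      cand <- cand[order(rs[cand], decreasing = TRUE)][seq_len(max_outliers)]
    }
    outlier[cand] <- TRUE
  }
  keep <- !outlier
  if (sum(keep) < 3) stop("fewer than 3 non-outlier points remain")
  if (length(unique(pts$x[keep])) < 2) stop("degenerate fit: all x equal")

  fit <- stats::lm(cp ~ x, data = pts[keep, , drop = FALSE])
  sm <- suppressWarnings(summary(fit))  # quiet on exactly collinear input
  pts$outlier <- outlier
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         slope_se = unname(sm$coefficients[2, 2]),
         intercept_se = unname(sm$coefficients[1, 2]),
         points = pts, n_used = sum(keep)),
    class = "relation_fit")
}

#' @export
print.relation_fit <- function(x, ...) {
  cat(sprintf(
    "<relation_fit> Cp = %.3f * sqrt(mu_a2/mu_a1) + %.3f mm  (R^2 = %.4f, n = %d%s)\n",
    x$slope, x$intercept, x$r_squared, x$n_used,
    if (any(x$points$outlier)) sprintf(", %d outlier(s) excluded",
                                       sum(x$points$outlier)) else ""))
  invisible(x)
}

#' @export
plot.relation_fit <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$x, pts$cp,
                 pch = ifelse(pts$outlier, 4, 19),
                 xlab = expression(sqrt(mu["a,2"] / mu["a,1"])),
                 ylab = "crossover point (mm)", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("Cp = %.2f x + %.2f  (R2 = %.3f)",
                                    x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Consistency of a fitted relation with the random-walk prediction
#'
#' Theory gives Cp proportional to T * (1 + sqrt(mu_a2/mu_a1)): equal
#' pre-factors on the constant and the square-root term, both scaling with
#' the top-layer thickness T. This report decomposes a fitted line
#' a*x + b as a*(x + 1) + (b - a): `slope_over_T` = a / T and
#' `decomposition_residual` = b - a, the additive offset attributable to the
#' extraction method rather than to the layered-transport physics.
#'
#' @param fit a [fit_cp_relation()] result.
#' @param T top-layer thickness (mm).
#' @param tol relative tolerance for declaring slope and intercept equal
#'   (default 0.25).
#' @return list with `slope_over_T`, `decomposition_residual`,
#'   `prefactors_equal`.
#' @export
theory_consistency <- function(fit, T, tol = 0.25) {
  stopifnot(inherits(fit, "relation_fit"), T > 0)
  list(slope_over_T = fit$slope / T,
       decomposition_residual = fit$intercept - fit$slope,
       prefactors_equal =
         abs(fit$intercept - fit$slope) <= tol * abs(fit$slope))
}
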