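#' Local polynomial fit at one evaluation point
#'
#' Weighted least squares of `y` on powers of `x - x0` up to `degree`, with
#' Epanechnikov kernel weights `0.75 * (1 - u^2)` for `|u| < 1`,
#' `u = (x - x0)/bandwidth`, optionally multiplied by observation weights.
#' Returns the local intercept (the smoothed value at `x0`) and the standard
#' error of the linear smoother under homoskedastic errors with variance
#' `sigma2`.
#'
#' @param x,y data points.
#' @param x0 evaluation point.
#' @param degree polynomial degree.
#' @param bandwidth kernel half-width, in units of `x` (> 0).
#' @param obs_weights optional non-negative observation weights.
#' @param sigma2 error variance used for the SE (default 1; rescale later).
#' @return list `fit` (smoothed value), `se_unit` (SE for `sigma2 = 1`),
#'   `n_eff` (points with positive kernel weight); `fit` is `NA` if the local
#'   system is singular.
#' @export
local_poly_point <- function(x, y, x0, degree, bandwidth, obs_weights = NULL,
                             sigma2 = 1) {
  if (bandwidth <= 0) stop_ae("bandwidth must be > 0")
  u <- (x - x0) / bandwidth
  k <- ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0)
  if (!is.null(obs_weights)) k <- k * obs_weights
  sel <- k > 0
  if (sum(sel) < degree + 1L)
    return(list(fit = NA_real_, se_unit = NA_real_, n_eff = sum(sel)))
  P <- outer(x[sel] - x0, 0:degree, `^`)
  W <- k[sel]
  A <- crossprod(P * W, P)
  b_rhs <- crossprod(P * W, y[sel])
  sol <- try(solve(A, cbind(b_rhs, t(P * W))), silent = TRUE)
  if (inherits(sol, "try-error"))
    return(list(fit = NA_real_, se_unit = NA_real_, n_eff = sum(sel)))
  beta <- sol[, 1L]
  l <- sol[1L, -1L]                      # smoother weights at x0
  list(fit = beta[1L], se_unit = sqrt(sigma2 * sum(l^2)), n_eff = sum(sel))
}

#' Smoothed mortality trend curves by wealth quintile
#'
#' Local polynomial smoothing (default degree 6, Epanechnikov kernel) of the
#' annual country-level mortality rates in each wealth quintile, with
#' pointwise 95\% bands from the linear-smoother variance. The error variance
#' per quintile is estimated from the residuals of the smooth at the observed
#' points. When no bandwidth is given it is chosen by leave-one-year-out
#' cross-validation over `bandwidth_grid`.
#'
#' @param cells `StratumYearCell` table from [mortality_cells()].
#' @param degree local polynomial degree (default 6).
#' @param bandwidth kernel half-width in years; `NULL` for cross-validated.
#' @param grid years at which to evaluate (default: each observed year).
#' @param obs_weights `"none"` or `"exposure"` (weight country-year points by
#'   cell child-years).
#' @param bandwidth_grid candidate bandwidths for cross-validation.
#' @param level confidence level of the bands.
#' @return data frame of class `"aid_trends"`: `quintile`, `year`, `fit`,
#'   `se`, `lower`, `upper`; the bandwidth used per quintile is in
#'   `attr(, "bandwidth")`. Quintiles with fewer than `degree + 2` distinct
#'   years are skipped with a warning.
#' @export
smoothed_trends <- function(cells, degree = 6L, bandwidth = NULL,
                            grid = NULL,
                            obs_weights = c("none", "exposure"),
                            bandwidth_grid = c(4, 6, 8, 10, 12, 16, 20),
                            level = 0.95) {
  obs_weights <- match.arg(obs_weights)
  if (!is.null(bandwidth) && bandwidth <= 0) stop_ae("bandwidth must be > 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  bws <- c()
  for (q in sort(unique(cells$quintile))) {
    d <- cells[cells$quintile == q, , drop = FALSE]
    x <- d$year
    y <- d$mortality_rate
    w <- if (obs_weights == "exposure") d$child_years else NULL
    if (length(unique(x)) < degree + 2L) {
      warning("quintile ", q, " skipped: fewer than degree + 2 distinct years")
      next
    }
    bw <- bandwidth %||% cv_bandwidth(x, y, degree, bandwidth_grid, w)
    bws[as.character(q)] <- bw
    gx <- grid %||% sort(unique(x))

    # residual variance of the smooth at the observed points
    fit_at <- vapply(x, function(x0)
      local_poly_point(x, y, x0, degree, bw, w)$fit, numeric(1))
    ok <- is.finite(fit_at)
    dfree <- max(1, sum(ok) - (degree + 1L))
    s2 <- sum((y[ok] - fit_at[ok])^2) / dfree

    res <- lapply(gx, function(x0) local_poly_point(x, y, x0, degree, bw, w,
                                                    sigma2 = s2))
    fit <- vapply(res, `[[`, numeric(1), "fit")
    se <- vapply(res, `[[`, numeric(1), "se_unit")
    out[[length(out) + 1L]] <- data.frame(
      quintile = q, year = gx, fit = fit, se = se,
      lower = fit - z * se, upper = fit + z * se
    )
  }
  res <- do.call(rbind, out)
  attr(res, "bandwidth") <- bws
  attr(res, "degree") <- degree
  class(res) <- c("aid_trends", class(res))
  res
}

# leave-one-year-out cross-validation of the kernel bandwidth
cv_bandwidth <- function(x, y, degree, bandwidth_grid, obs_weights = NULL) {
  yrs <- unique(x)
  err <- vapply(bandwidth_grid, function(bw) {
    e <- 0
    for (yr in yrs) {
      tr <- x != yr
      te <- !tr
      f <- local_poly_point(x[tr], y[tr], yr, degree, bw,
                            obs_weights[tr])$fit
      if (!is.finite(f)) return(Inf)
      e <- e + sum((y[te] - f)^2)
    }
    e
  }, numeric(1))
  if (all(!is.finite(err)))
    stop_ae("no candidate bandwidth supports a degree-", degree, " local fit")
  bandwidth_grid[which.min(err)]
}

#' @export
plot.aid_trends <- function(x, ...) {
  qs <- sort(unique(x$quintile))
  cols <- grDevices::hcl.colors(max(qs), "Zissou 1")
  plot(range(x$year), range(c(x$lower, x$upper), na.rm = TRUE), type = "n",
       xlab = "Year", ylab = "Under-5 deaths per 1,000 child-years", ...)
  for (q in qs) {
    d <- x[x$quintile == q, ]
    graphics::polygon(c(d$year, rev(d$year)), c(d$lower, rev(d$upper)),
                      col = grDevices::adjustcolor(cols[q], 0.15), border = NA)
    graphics::lines(d$year, d$fit, col = cols[q], lwd = 2)
  }
  graphics::legend("topright", legend = paste0("q", qs, c(" (wealthiest)",
                                                          "", "", "",
                                                          " (poorest)")[qs]),
                   col = cols[qs], lwd = 2, bty = "n")
  invisible(x)
}
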