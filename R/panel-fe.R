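#' Specification of the two-way fixed-effects mortality model
#'
#' Describes one regression of cell-level under-5 mortality on wealth
#' quintile, lagged health aid, their interactions and covariates, with
#' country and year fixed effects and country-clustered standard errors:
#' \deqn{M_{ctq} = \beta_q + \gamma A_{c,t-lag} + \delta_q A_{c,t-lag}
#'   + \theta E_{cq} + \phi G_{ct} + \psi U_{ct} + \alpha_c + \tau_t + \epsilon_{ctq}}
#' with the wealthiest quintile (q = 1) as the reference stratum, so
#' \eqn{\delta_q} measures how much more a dollar of aid is associated with
#' mortality change in quintile q than among the wealthiest.
#'
#' @param outcome `"rate"` (deaths per 1,000 child-years) or `"log_rate"`
#'   (natural log; zero-rate cells are dropped and coefficients read as
#'   semi-elasticities).
#' @param aid `"total"` or `"malaria"` aid per capita.
#' @param lag aid lag in years, 0..3 (default 1).
#' @param ldv include the cell's previous-year outcome as a regressor
#'   (dynamic-panel robustness check; plain OLS).
#' @param covariates include median maternal education, government health
#'   spending and urbanization.
#' @param exposure_weights weight observations by cell child-years
#'   (off by default; the baseline model is unweighted).
#' @return object of class `"fe_spec"`.
#' @export
fe_spec <- function(outcome = c("rate", "log_rate"),
                    aid = c("total", "malaria"),
                    lag = 1L,
                    ldv = FALSE,
                    covariates = TRUE,
                    exposure_weights = FALSE) {
  outcome <- match.arg(outcome)
  aid <- match.arg(aid)
  lag <- as.integer(lag)
  if (lag < 0L || lag > 3L) stop_ae("aid lag must be in 0..3")
  structure(list(outcome = outcome, aid = aid, lag = lag, ldv = ldv,
                 covariates = covariates,
                 exposure_weights = exposure_weights),
            class = "fe_spec")
}

#' @export
print.fe_spec <- function(x, ...) {
  cat(sprintf(
    "Two-way FE spec: outcome = %s, %s aid lagged %d year(s)%s%s\n",
    x$outcome, x$aid, x$lag,
    if (x$ldv) ", lagged dependent variable" else "",
    if (x$exposure_weights) ", exposure-weighted" else ""))
  invisible(x)
}

#' Build the regression design from mortality cells and the country panel
#'
#' One row per cell surviving the spec's filters: rows lose their lagged aid
#' value if the panel does not cover `year - lag` (dropped with a message),
#' zero-rate cells are dropped under the log outcome, and the
#' lagged-dependent-variable variant drops rows without a previous-year cell.
#' Columns: intercept, quintile dummies q2..q5, lagged aid, the four
#' aid-by-quintile interactions, covariates, and explicit country and year
#' dummies (first level absorbed by the intercept).
#'
#' @param cells `StratumYearCell` table from [mortality_cells()].
#' @param panel country-year table with `total_aid_pc`, `malaria_aid_pc`,
#'   `govt_health_pc`, `urban_share`.
#' @param spec an [fe_spec()].
#' @return list with `X` (design matrix), `y`, `cluster` (country id per
#'   row), `weights` (or NULL), `cells` (the retained rows).
#' @export
build_design <- function(cells, panel, spec = fe_spec()) {
  stopifnot(inherits(spec, "fe_spec"))
  aid_col <- if (spec$aid == "total") "total_aid_pc" else "malaria_aid_pc"
  pk <- paste(panel$country, panel$year, sep = ":")
  aid_lag <- panel[[aid_col]][match(paste(cells$country, cells$year - spec$lag,
                                          sep = ":"), pk)]
  govt <- panel$govt_health_pc[match(paste(cells$country, cells$year,
                                           sep = ":"), pk)]
  urban <- panel$urban_share[match(paste(cells$country, cells$year,
                                         sep = ":"), pk)]

  keep <- !is.na(aid_lag)
  if (any(!keep))
    message(sum(!keep), " cell(s) dropped: lagged aid not covered by the panel")

  y <- cells$mortality_rate
  if (spec$outcome == "log_rate") {
    zero <- cells$mortality_rate <= 0
    if (all(zero[keep])) stop_ae("all retained cells have zero mortality rate")
    keep <- keep & !zero
    y <- suppressWarnings(log(cells$mortality_rate))
  }

  ldv <- NULL
  if (spec$ldv) {
    ck <- paste(cells$country, cells$quintile, cells$year, sep = ":")
    prev <- match(paste(cells$country, cells$quintile, cells$year - 1L,
                        sep = ":"), ck)
    ldv <- y[prev]
    # previous-year outcome must itself be usable on the model scale
    ldv[!is.na(prev) & !is.finite(ldv)] <- NA
    keep <- keep & !is.na(ldv)
  }

  d <- cells[keep, , drop = FALSE]
  aid_lag <- aid_lag[keep]; govt <- govt[keep]; urban <- urban[keep]
  y <- y[keep]
  if (!is.null(ldv)) ldv <- ldv[keep]
  if (nrow(d) == 0L) stop_ae("no cells left after design filters")

  qf <- factor(d$quintile)        # reference: lowest label present (wealthiest)
  Q <- stats::model.matrix(~qf)[, -1L, drop = FALSE]
  colnames(Q) <- paste0("q", levels(qf)[-1L])
  inter <- Q * aid_lag
  colnames(inter) <- paste0("aid:q", levels(qf)[-1L])

  X <- cbind(`(Intercept)` = 1, Q, aid = aid_lag, inter)
  if (spec$covariates)
    X <- cbind(X, edu = d$median_mother_education, govt = govt, urban = urban)
  if (spec$ldv) X <- cbind(X, ldv = ldv)

  cf <- factor(d$country)
  if (nlevels(cf) > 1L) {
    CD <- stats::model.matrix(~cf)[, -1L, drop = FALSE]
    colnames(CD) <- paste0("country_", levels(cf)[-1L])
    X <- cbind(X, CD)
  }
  yf <- factor(d$year)
  if (nlevels(yf) > 1L) {
    YD <- stats::model.matrix(~yf)[, -1L, drop = FALSE]
    colnames(YD) <- paste0("year_", levels(yf)[-1L])
    X <- cbind(X, YD)
  }

  list(X = X, y = y, cluster = d$country,
       weights = if (spec$exposure_weights) d$child_years else NULL,
       cells = d)
}

#' Cluster-robust (sandwich) covariance for an OLS fit
#'
#' \deqn{V = a\,(X'X)^{-1}\Big(\sum_c X_c' \hat e_c \hat e_c' X_c\Big)(X'X)^{-1}}
#' with the small-sample factor
#' \eqn{a = G/(G-1)\cdot(N-1)/(N-K)} (the convention of Stata's clustered
#' within regressions); inference uses a t distribution with G - 1 degrees of
#' freedom. With every observation its own cluster this reduces exactly to
#' the HC1 heteroskedasticity-robust estimator.
#'
#' @param X design matrix (N x K, full rank).
#' @param resid OLS residuals.
#' @param cluster cluster id per row.
#' @param weights optional observation weights (WLS); the meat uses
#'   `w_i x_i e_i` scores.
#' @return K x K covariance matrix with attribute `"G"` (cluster count).
#' @export
vcov_cluster <- function(X, resid, cluster, weights = NULL) {
  N <- nrow(X)
  K <- ncol(X)
  G <- length(unique(cluster))
  if (G < 2L) stop_ae("clustered variance undefined with a single cluster")
  w <- weights %||% rep(1, N)
  bread <- solve(crossprod(X * w, X))
  scores <- X * (w * resid)
  S <- rowsum(scores, cluster)
  meat <- crossprod(S)
  a <- (G / (G - 1)) * ((N - 1) / (N - K))
  V <- a * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  attr(V, "G") <- G
  V
}

#' Fit the two-way fixed-effects interaction model
#'
#' The core estimator: OLS on the dummy-inclusive design from
#' [build_design()], with country-clustered robust standard errors
#' ([vcov_cluster()]) and p-values from a t distribution with G - 1 degrees
#' of freedom (G = number of country clusters). Fixed effects are absorbed by
#' explicit dummies; at panel scale (tens of countries, ~20 years) this is
#' numerically identical to the within (demeaning) estimator.
#'
#' @param cells `StratumYearCell` table from [mortality_cells()].
#' @param panel country-year aid/covariate table.
#' @param spec an [fe_spec()].
#' @return object of class `"fe_fit"`: coefficients, clustered `vcov`,
#'   `se`, `p_value`, `n_obs`, `n_clusters`, `r_squared` (overall R^2 of the
#'   dummy regression), `spec`, plus the fitted design for diagnostics.
#' @examples
#' cfg <- sim_config(n_countries = 6, households_per_survey = 80, seed = 3)
#' dat <- simulate_survey_data(cfg)
#' widx <- wealth_index(dat$households)
#' scored <- predict(widx, dat$households)
#' cells <- mortality_cells(dat$births, dat$households, scored)
#' fit <- fe_mortality(cells, dat$panel)
#' summary(fit)
#' @export
fe_mortality <- function(cells, panel, spec = fe_spec()) {
  design <- build_design(cells, panel, spec)
  fit_within(design, spec = spec)
}

#' Fit the within estimator on a prepared design
#'
#' Lower-level entry point taking the output of [build_design()] directly.
#'
#' @param design list with `X`, `y`, `cluster` and optionally `weights`
#'   (as returned by [build_design()]).
#' @param spec the [fe_spec()] recorded in the result (optional).
#' @return an `"fe_fit"` object; see [fe_mortality()].
#' @export
fit_within <- function(design, spec = NULL) {
  X <- design$X
  y <- design$y
  w <- design$weights
  qr_ <- qr(if (is.null(w)) X else X * sqrt(w))
  if (qr_$rank < ncol(X)) {
    dropped <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    stop_ae("design is rank deficient; collinear column(s): ",
            paste(dropped, collapse = ", "))
  }
  fit <- if (is.null(w)) stats::lm.fit(X, y) else stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  res <- y - drop(X %*% beta)
  V <- vcov_cluster(X, res, design$cluster, weights = w)
  G <- attr(V, "G")
  attr(V, "G") <- NULL
  se <- sqrt(diag(V))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = G - 1)

  ybar <- if (is.null(w)) mean(y) else sum(w * y) / sum(w)
  ssr <- if (is.null(w)) sum(res^2) else sum(w * res^2)
  sst <- if (is.null(w)) sum((y - ybar)^2) else sum(w * (y - ybar)^2)

  structure(list(
    coefficients = beta,
    vcov = V,
    se = se,
    t_value = tval,
    p_value = p,
    n_obs = length(y),
    n_clusters = G,
    df_inference = G - 1,
    r_squared = 1 - ssr / sst,
    residuals = res,
    fitted_values = drop(X %*% beta),
    spec = spec,
    design = design
  ), class = "fe_fit")
}

#' @export
coef.fe_fit <- function(object, ...) object$coefficients

#' @export
vcov.fe_fit <- function(object, ...) object$vcov

#' @export
nobs.fe_fit <- function(object, ...) object$n_obs

#' @export
residuals.fe_fit <- function(object, ...) object$residuals

#' @export
fitted.fe_fit <- function(object, ...) object$fitted_values

#' @export
confint.fe_fit <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object)
  if (missing(parm)) parm <- names(cf)
  q <- stats::qt(1 - (1 - level) / 2, df = object$df_inference)
  out <- cbind(cf[parm] - q * object$se[parm], cf[parm] + q * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
predict.fe_fit <- function(object, newdesign = NULL, ...) {
  if (is.null(newdesign)) return(object$fitted_values)
  drop(newdesign$X %*% coef(object))
}

#' @export
print.fe_fit <- function(x, ...) {
  if (!is.null(x$spec)) print(x$spec)
  main <- fe_terms(x)
  cat(sprintf("n = %d cells, %d country clusters, R^2 = %.3f\n",
              x$n_obs, x$n_clusters, x$r_squared))
  cat("Aid x quintile interactions (reference: q1, wealthiest):\n")
  print(round(main[grepl("^aid", rownames(main)), , drop = FALSE], 4))
  invisible(x)
}

#' @export
summary.fe_fit <- function(object, ...) {
  tab <- fe_terms(object, all = TRUE)
  structure(list(fit = object, table = tab), class = "summary.fe_fit")
}

#' @export
print.summary.fe_fit <- function(x, ...) {
  f <- x$fit
  if (!is.null(f$spec)) print(f$spec)
  cat(sprintf("n = %d cells, %d country clusters (t inference with %d df), R^2 = %.3f\n\n",
              f$n_obs, f$n_clusters, f$df_inference, f$r_squared))
  stats::printCoefmat(x$table, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nCountry and year fixed-effect dummies omitted from the display.\n")
  invisible(x)
}

fe_terms <- function(fit, all = FALSE) {
  keep <- !grepl("^(country_|year_)", names(fit$coefficients))
  if (!all) keep <- keep & names(fit$coefficients) != "(Intercept)"
  cbind(Estimate = fit$coefficients[keep],
        `Std. Error` = fit$se[keep],
        `t value` = fit$t_value[keep],
        `Pr(>|t|)` = fit$p_value[keep])
}

#' Aid-by-quintile interaction estimates of a fit
#'
#' Convenience accessor for the four interaction coefficients
#' (`aid:q2`..`aid:q5`), their clustered SEs and p-values. In the log model,
#' 100 times the estimate reads as the percent mortality difference per aid
#' dollar relative to the wealthiest quintile; `exp(estimate) - 1` is also
#' reported for the exact reading.
#'
#' @param fit an `"fe_fit"`.
#' @return data frame with `term`, `estimate`, `se`, `p_value`,
#'   `pct_per_dollar` (100 * estimate) and `pct_exact`
#'   (100 * (exp(estimate) - 1)); the percent columns are only meaningful
#'   for the log outcome.
#' @export
interaction_estimates <- function(fit) {
  nm <- paste0("aid:q", 2:5)
  data.frame(
    term = nm,
    estimate = unname(coef(fit)[nm]),
    se = unname(fit$se[nm]),
    p_value = unname(fit$p_value[nm]),
    pct_per_dollar = unname(100 * coef(fit)[nm]),
    pct_exact = unname(100 * (exp(coef(fit)[nm]) - 1)),
    stringsAsFactors = FALSE
  )
}

#' Robustness sweep over model variants
#'
#' Fits every combination of aid lag, outcome transform, aid series and the
#' lagged-dependent-variable flag, collecting the aid-by-quintile interaction
#' estimates. Failing fits are recorded and skipped.
#'
#' @param cells `StratumYearCell` table.
#' @param panel country-year table.
#' @param lags integer vector of aid lags.
#' @param outcomes outcome transforms to sweep.
#' @param aids aid series to sweep.
#' @param ldv logical vector of LDV settings.
#' @param covariates passed through to [fe_spec()].
#' @return list with `table` (one row per variant and interaction term:
#'   estimates, SEs, p-values, n_obs) and `fits` (named list of `"fe_fit"`
#'   or `try-error`).
#' @export
variant_sweep <- function(cells, panel, lags = 0:3,
                          outcomes = c("rate", "log_rate"),
                          aids = "total", ldv = FALSE,
                          covariates = TRUE) {
  grid <- expand.grid(lag = lags, outcome = outcomes, aid = aids, ldv = ldv,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  names(fits) <- apply(grid, 1L, function(g)
    sprintf("%s_%s_lag%s%s", g[["aid"]], g[["outcome"]], g[["lag"]],
            if (as.logical(g[["ldv"]])) "_ldv" else ""))
  for (i in seq_len(nrow(grid))) {
    sp <- fe_spec(outcome = grid$outcome[i], aid = grid$aid[i],
                  lag = grid$lag[i], ldv = grid$ldv[i],
                  covariates = covariates)
    f <- try(fe_mortality(cells, panel, sp), silent = TRUE)
    fits[[i]] <- f
    if (!inherits(f, "try-error")) {
      ie <- interaction_estimates(f)
      rows[[i]] <- cbind(variant = names(fits)[i], grid[i, , drop = FALSE],
                         ie, n_obs = f$n_obs, row.names = NULL)
    }
  }
  list(table = do.call(rbind, rows), fits = fits)
}
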