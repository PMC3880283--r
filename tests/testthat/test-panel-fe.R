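test_that("design rows follow the lag and filter arithmetic", {
  cells <- make_toy_cells(countries = 2L, years = 2001:2003)
  panel <- make_toy_panel(countries = 2L, years = 2001:2003)  # no 2000
  d <- suppressMessages(build_design(cells, panel, fe_spec(lag = 1L)))
  # first year lost to the lag: 2 countries x 2 years x 5 quintiles
  expect_equal(nrow(d$X), 20L)
  expect_equal(sort(unique(d$cells$year)), c(2002L, 2003L))

  # lag 0 with full coverage keeps all 30 rows
  d0 <- build_design(cells, panel, fe_spec(lag = 0L))
  expect_equal(nrow(d0$X), 30L)
})

test_that("the log specification drops exactly the zero-rate cells", {
  # 3,199 cells of which 89 have zero rate -> n_obs 3,110
  set.seed(1)
  n <- 3199L
  cells <- data.frame(
    country = rep(1:7, length.out = n),
    year = rep(2001:2012, length.out = n),
    quintile = rep(1:5, length.out = n),
    child_years = 100,
    n_children = 50L
  )
  cells$median_mother_education <- 4 + ((cells$country * cells$quintile) %% 3)
  cells$deaths <- rpois(n, 3) + 1
  cells$deaths[sample.int(n, 89L)] <- 0
  cells$mortality_rate <- 1000 * cells$deaths / cells$child_years
  panel <- make_toy_panel(countries = 7L, years = 1998:2012)
  fit_lin <- fe_mortality(cells, panel, fe_spec("rate"))
  fit_log <- fe_mortality(cells, panel, fe_spec("log_rate"))
  expect_equal(fit_lin$n_obs, 3199L)
  expect_equal(fit_log$n_obs, 3110L)
})

test_that("the LDV variant drops exactly the rows without a prior-year cell", {
  cells <- make_toy_cells(countries = 3L, years = 2001:2005)
  panel <- make_toy_panel(countries = 3L, years = 1998:2005)
  base <- build_design(cells, panel, fe_spec(lag = 1L))
  ldv <- build_design(cells, panel, fe_spec(lag = 1L, ldv = TRUE))
  have_prev <- with(base$cells, paste(country, quintile, year - 1L) %in%
                      paste(cells$country, cells$quintile, cells$year))
  expect_equal(nrow(ldv$X), sum(have_prev))
  expect_true("ldv" %in% colnames(ldv$X))
})

test_that("coefficients equal the normal-equations solution to 1e-10", {
  # 12-row panel: 2 countries x 2 years x 3 quintiles, built by hand
  g <- expand.grid(country = 1:2, year = 2001:2002, quintile = 1:3)
  # the estimator regresses on aid lagged one year
  aid <- c(1, 2)[g$country] + c(0.5, 1.1)[g$country] * (g$year - 1 - 2001)
  set.seed(9)
  y <- 10 + 2 * (g$quintile - 1) - 0.4 * aid * (g$quintile == 3) +
    rnorm(12, sd = 0.3)
  cells <- data.frame(g, deaths = 1, child_years = 1, mortality_rate = y,
                      median_mother_education = 3 + g$country,
                      n_children = 10L)
  panel <- data.frame(country = rep(1:2, each = 3),
                      year = rep(2000:2002, 2))
  panel$total_aid_pc <- c(1, 2)[panel$country] +
    c(0.5, 1.1)[panel$country] * (panel$year - 2001)
  panel$malaria_aid_pc <- 0.5
  panel$govt_health_pc <- 10
  panel$urban_share <- 20
  spec <- fe_spec(lag = 1L, covariates = FALSE)
  fit <- fe_mortality(cells, panel, spec)

  # independent oracle: hand-built dummy design, solve() on X'X b = X'y
  qd <- outer(g$quintile, 2:3, `==`) * 1
  Xo <- cbind(1, qd, aid, qd * aid, g$country == 2, g$year == 2002)
  beta_o <- solve(t(Xo) %*% Xo, t(Xo) %*% y)
  expect_equal(unname(coef(fit)), unname(drop(beta_o)), tolerance = 1e-10)
})

test_that("clustered SEs reduce to HC1 when every row is its own cluster", {
  skip_if_not_installed("sandwich")
  set.seed(4)
  n <- 60L
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n)
  fit <- fit_within(list(X = X, y = y, cluster = seq_len(n), weights = NULL))
  lmfit <- lm(y ~ x1 + x2, data = data.frame(y = y, x1 = X[, 2], x2 = X[, 3]))
  Vhc1 <- sandwich::vcovHC(lmfit, type = "HC1")
  expect_equal(unname(fit$vcov), unname(Vhc1), tolerance = 1e-10)

  # and the clustered case agrees with the sandwich/meatCL implementation
  cl <- rep(1:6, each = 10)
  fitc <- fit_within(list(X = X, y = y, cluster = cl, weights = NULL))
  Vcl <- sandwich::vcovCL(lmfit, cluster = cl, type = "HC1",
                          cadjust = TRUE)
  expect_equal(unname(fitc$vcov), unname(Vcl), tolerance = 1e-10)
})

test_that("dummy absorption equals explicit demeaning (within estimator)", {
  cells <- make_toy_cells(countries = 4L, years = 2001:2006)
  panel <- make_toy_panel(countries = 4L, years = 1998:2006)
  d <- build_design(cells, panel, fe_spec())
  fit <- fit_within(d)
  # residualize outcome and non-FE columns on the FE dummies, then OLS
  fe_cols <- grepl("^(country_|year_|\\(Intercept\\))", colnames(d$X))
  Fe <- d$X[, fe_cols, drop = FALSE]
  M <- diag(nrow(Fe)) - Fe %*% solve(crossprod(Fe)) %*% t(Fe)
  Xw <- M %*% d$X[, !fe_cols, drop = FALSE]
  yw <- drop(M %*% d$y)
  bw <- solve(crossprod(Xw), crossprod(Xw, yw))
  expect_equal(unname(coef(fit)[!fe_cols]), unname(drop(bw)), tolerance = 1e-8)

  # Frisch-Waugh for the interaction block alone
  int_cols <- grepl("^aid:q", colnames(d$X))
  Mo <- diag(nrow(d$X)) -
    d$X[, !int_cols] %*% solve(crossprod(d$X[, !int_cols])) %*%
    t(d$X[, !int_cols])
  Xi <- Mo %*% d$X[, int_cols]
  bi <- solve(crossprod(Xi), crossprod(Xi, drop(Mo %*% d$y)))
  expect_equal(unname(coef(fit)[int_cols]), unname(drop(bi)), tolerance = 1e-8)
})

test_that("rank deficiency and single clusters raise errors", {
  cells <- make_toy_cells(countries = 2L, years = 2001:2003)
  cells$median_mother_education <- 1        # constant -> collinear
  panel <- make_toy_panel(countries = 2L, years = 1998:2003)
  expect_error(fe_mortality(cells, panel, fe_spec()), "collinear")

  set.seed(8)
  X1 <- cbind(1, rnorm(10))
  expect_error(
    fit_within(list(X = X1, y = rnorm(10), cluster = rep(1L, 10),
                    weights = NULL)),
    "single cluster")
})

test_that("the estimator recovers a known interaction from noise-free cells", {
  # deterministic cell rates built directly from the linear model
  g <- expand.grid(country = 1:6, year = 2001:2010, quintile = 1:5)
  panel <- make_toy_panel(countries = 6L, years = 2000:2010, seed = 2)
  aid <- panel$total_aid_pc[match(paste(g$country, g$year - 1),
                                  paste(panel$country, panel$year))]
  truth <- c(0, 0.1, -0.2, -0.5, -0.6)
  rate <- 20 + 3 * g$quintile + (0.3 + truth[g$quintile]) * aid
  cells <- data.frame(g, deaths = rate, child_years = 1000,
                      mortality_rate = rate,
                      median_mother_education = 8 - g$quintile + 0.3 * g$country +
                        0.2 * ((g$country * g$quintile) %% 3),
                      n_children = 100L)
  fit <- fe_mortality(cells, panel, fe_spec())
  expect_equal(unname(coef(fit)[paste0("aid:q", 2:5)]), truth[2:5],
               tolerance = 1e-8)
  expect_equal(unname(coef(fit)["aid"]), 0.3, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("identity and log fits agree in sign on monotone noise-free data", {
  g <- expand.grid(country = 1:6, year = 2001:2010, quintile = 1:5)
  panel <- make_toy_panel(countries = 6L, years = 2000:2010, seed = 3)
  aid <- panel$total_aid_pc[match(paste(g$country, g$year - 1),
                                  paste(panel$country, panel$year))]
  rate <- (10 + 5 * g$quintile) * exp(-0.01 * (g$quintile - 1) * aid)
  cells <- data.frame(g, deaths = rate, child_years = 1000,
                      mortality_rate = rate,
                      median_mother_education = 8 - g$quintile + 0.3 * g$country +
                        0.2 * ((g$country * g$quintile) %% 3),
                      n_children = 100L)
  f_lin <- fe_mortality(cells, panel, fe_spec("rate"))
  f_log <- fe_mortality(cells, panel, fe_spec("log_rate"))
  s_lin <- sign(coef(f_lin)[paste0("aid:q", 2:5)])
  s_log <- sign(coef(f_log)[paste0("aid:q", 2:5)])
  expect_equal(unname(s_lin), unname(s_log))
  expect_true(all(s_log == -1))
})

test_that("variant sweep runs all variants and LDV is null on white noise", {
  cells <- make_toy_cells(countries = 4L, years = 2001:2008, seed = 12)
  panel <- make_toy_panel(countries = 4L, years = 1997:2008)
  sw <- variant_sweep(cells, panel, lags = 0:3,
                      outcomes = c("rate", "log_rate"))
  expect_equal(length(sw$fits), 8L)
  expect_equal(nrow(sw$table), 8L * 4L)
  expect_true(all(c("estimate", "se", "p_value", "n_obs") %in%
                    names(sw$table)))

  # white-noise outcome: the lagged-dependent-variable coefficient is ~0
  set.seed(30)
  cells$mortality_rate <- 20 + rnorm(nrow(cells))
  cells$deaths <- cells$mortality_rate * cells$child_years / 1000
  f <- fe_mortality(cells, panel, fe_spec(ldv = TRUE, covariates = FALSE))
  expect_lt(abs(coef(f)["ldv"]), 3 * f$se["ldv"] + 0.2)
})

test_that("the aid lag is best identified at the generating lag", {
  # aid with strong year-to-year noise so lags are distinguishable;
  # the generator applies aid at lag 1
  reps <- 20L
  D5 <- matrix(NA_real_, reps, 4L)     # columns: lag 0..3
  for (r in seq_len(reps)) {
    cfg <- sim_config(
      n_countries = 8L, households_per_survey = 250L, seed = 7000L + r,
      aid_params = list(
        total = list(level_range = c(6, 10), slope_range = c(0, 0.2),
                     noise_sd = 3),
        malaria = list(level_range = c(0, 0.3), slope_range = c(0.05, 0.3),
                       noise_sd = 0.2),
        ramp_start = 2000L
      ))
    dat <- simulate_survey_data(cfg)
    scored <- data.frame(household_id = dat$truth$household_id,
                         quintile = dat$truth$latent_quintile)
    cells <- mortality_cells(dat$births, dat$households, scored)
    D5[r, ] <- vapply(0:3, function(l) {
      f <- try(fe_mortality(cells, dat$panel, fe_spec(lag = l)),
               silent = TRUE)
      if (inherits(f, "try-error")) return(NA_real_)
      coef(f)[["aid:q5"]]
    }, numeric(1))
  }
  # in expectation the generating lag carries the largest interaction
  mean_d5 <- colMeans(D5, na.rm = TRUE)
  expect_equal(which.max(abs(mean_d5)), 2L)   # lag 1 (column 2)
})
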