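# Independent oracles and fixture builders used across the test files.
# Oracles deliberately use brute-force code paths (month enumeration,
# explicit double-loop moments, solve() on normal equations) distinct from
# the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# month-by-month enumeration of a child's window-clipped exposure and death
exposure_oracle <- function(birth_month, interview_month,
                            age_at_death = NA, window = 120L) {
  exposure <- integer(0)
  death_year <- NA_integer_
  for (m in seq.int(interview_month - window, interview_month - 1L)) {
    age <- m - birth_month
    if (age < 0L || age >= 60L) next
    if (!is.na(age_at_death)) {
      if (age == age_at_death) death_year <- cmc_year(m)
      if (age >= age_at_death) next     # death month itself: no exposure
    }
    exposure <- c(exposure, m)
  }
  counts <- table(cmc_year(exposure))
  list(exposure = stats::setNames(as.numeric(counts), names(counts)),
       death_year = death_year)
}

# explicit double-loop weighted covariance of standardized columns
weighted_cov_oracle <- function(X, w) {
  p <- ncol(X)
  mu <- sds <- numeric(p)
  for (j in seq_len(p)) {
    mu[j] <- sum(w * X[, j]) / sum(w)
    sds[j] <- sqrt(sum(w * (X[, j] - mu[j])^2) / sum(w))
  }
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  C <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(p))
    C[j, k] <- sum(w * Z[, j] * Z[, k]) / sum(w)
  C
}

# small deterministic panel of mortality cells with known structure
make_toy_cells <- function(countries = 2L, years = 2001:2003,
                           quintiles = 1:5, base = 20, seed = 42) {
  set.seed(seed)
  g <- expand.grid(country = seq_len(countries), year = years,
                   quintile = quintiles)
  g$child_years <- 50 + 10 * g$quintile
  g$mortality_rate <- base + 5 * g$quintile + rnorm(nrow(g), sd = 2)
  g$deaths <- g$mortality_rate * g$child_years / 1000
  # education varies by country and quintile but is NOT additively separable
  # in them (otherwise it would be absorbed by the dummies)
  g$median_mother_education <- 9 - 1.5 * g$quintile + 0.5 * g$country +
    0.3 * ((g$country * g$quintile) %% 3)
  g$n_children <- 100L
  g
}

make_toy_panel <- function(countries = 2L, years = 1998:2003, seed = 43) {
  set.seed(seed)
  g <- expand.grid(country = seq_len(countries), year = years)
  g$total_aid_pc <- 1 + 0.5 * g$country + 0.3 * (g$year - min(years)) +
    rnorm(nrow(g), sd = 0.3)
  g$malaria_aid_pc <- 0.3 * g$total_aid_pc
  # covariates must not be additively separable in country and year, or they
  # would be absorbed exactly by the two-way dummies
  g$govt_health_pc <- 10 + g$country + 0.2 * (g$year - min(years)) +
    0.3 * ((g$country * (g$year - min(years))) %% 3)
  g$urban_share <- 30 + 2 * g$country + 0.5 * (g$year - min(years)) +
    0.4 * ((g$country + 2 * (g$year - min(years))) %% 4)
  g
}

# quick small-scale generator configuration for tests
test_config <- function(...) {
  args <- utils::modifyList(
    list(n_countries = 5L, households_per_survey = 120L, seed = 99L),
    list(...))
  do.call(sim_config, args)
}
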