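#' Generate the synthetic country-year aid and covariate panel
#'
#' One row per country and calendar year of the configured range, with total
#' and malaria health aid per capita (constant USD), government health
#' spending per capita, and the urban population share. Each aid series is
#' `max(0, level_c + slope_c * max(0, year - ramp_start) + noise)`: flat
#' through the 1990s, then country-specific linear growth, mimicking the
#' post-2000 scale-up of development assistance for health.
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns `country`, `year`, `total_aid_pc`,
#'   `malaria_aid_pc`, `govt_health_pc`, `urban_share`.
#' @export
sim_country_panel <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  nc <- config$n_countries
  yrs <- config$years
  ny <- length(yrs)
  ap <- config$aid_params
  ramp <- pmax(0, yrs - ap$ramp_start)

  series <- function(level_range, slope_range, noise_sd, x = ramp) {
    level <- stats::runif(nc, level_range[1L], level_range[2L])
    slope <- stats::runif(nc, slope_range[1L], slope_range[2L])
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(nc * ny, sd = noise_sd), nc, ny) else 0
    m <- outer(level, rep(1, ny)) + outer(slope, x) + noise
    m[m < 0] <- 0                    # aid and spending are non-negative
    m
  }

  total <- series(ap$total$level_range, ap$total$slope_range, ap$total$noise_sd)
  malaria <- series(ap$malaria$level_range, ap$malaria$slope_range,
                    ap$malaria$noise_sd)
  govt <- series(config$govt_params$level_range,
                 config$govt_params$trend_range,
                 config$govt_params$noise_sd, x = yrs - min(yrs))
  urban <- series(config$urban_params$level_range,
                  config$urban_params$trend_range,
                  config$urban_params$noise_sd, x = yrs - min(yrs))
  urban[urban > 100] <- 100

  data.frame(
    country = rep(seq_len(nc), each = ny),
    year = rep(yrs, times = nc),
    total_aid_pc = as.vector(t(total)),
    malaria_aid_pc = as.vector(t(malaria)),
    govt_health_pc = as.vector(t(govt)),
    urban_share = as.vector(t(urban))
  )
}

#' Generate synthetic surveyed households
#'
#' Draws `households_per_survey` households for every survey wave in every
#' country. Each household has a latent wealth score `N(0, latent_wealth_sd)`;
#' each binary asset is owned with probability
#' `plogis(intercept + slope * latent_wealth)` and rooms-per-person is
#' log-normal with a wealth slope, so ownership of every asset is
#' stochastically non-decreasing in wealth. Survey weights are i.i.d. around 1
#' (no cluster design); the population-share weight is the survey country's
#' simulated population share, used later to weight the pooled wealth index.
#'
#' @param config a [sim_config()] object.
#' @return `HouseholdRecord` data frame: `household_id`, `survey_id`,
#'   `country`, `survey_year`, `interview_month` (CMC), `survey_weight`,
#'   `population_share_weight`, the ten binary asset columns,
#'   `rooms_per_person`, `mother_edu_years`, and the generator-internal
#'   `latent_wealth` (withheld from analysis input by [simulate_survey_data()]).
#' @export
sim_households <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  nc <- config$n_countries
  waves <- config$survey_years
  hps <- config$households_per_survey

  # country population shares (for the pooled-index weighting)
  pop <- stats::rlnorm(nc, meanlog = 0, sdlog = 0.5)
  pop_share <- pop / mean(pop)
  # country-level schooling multiplier (keeps E_cq varying across countries)
  edu_mult <- stats::rlnorm(nc, meanlog = 0, sdlog = config$edu_country_sdlog)

  grid <- expand.grid(wave = seq_along(waves), country = seq_len(nc))
  n_surveys <- nrow(grid)
  n <- n_surveys * hps

  country <- rep(grid$country, each = hps)
  survey_year <- rep(waves[grid$wave], each = hps)
  survey_id <- rep(sprintf("C%02dY%d", grid$country, waves[grid$wave]),
                   each = hps)
  z <- stats::rnorm(n, 0, config$latent_wealth_sd)

  al <- config$asset_loadings
  assets <- matrix(0L, n, nrow(al),
                   dimnames = list(NULL, al$asset))
  for (j in seq_len(nrow(al))) {
    p <- stats::plogis(al$intercept[j] + al$slope[j] * z)
    assets[, j] <- as.integer(stats::runif(n) < p)
  }
  rooms <- exp(config$rooms_meanlog + config$rooms_slope * z +
                 stats::rnorm(n, 0, config$rooms_sdlog))
  q <- latent_quintile(z, config$latent_wealth_sd)
  edu <- stats::rpois(n, lambda = config$edu_median[q] * edu_mult[country])

  out <- data.frame(
    household_id = sprintf("%s-H%05d", survey_id, rep(seq_len(hps), n_surveys)),
    survey_id = survey_id,
    country = country,
    survey_year = survey_year,
    interview_month = cmc(survey_year, 6L),
    survey_weight = stats::rlnorm(n, meanlog = -config$survey_weight_sdlog^2 / 2,
                                  sdlog = config$survey_weight_sdlog),
    population_share_weight = pop_share[country],
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(assets))
  out$rooms_per_person <- rooms
  out$mother_edu_years <- edu
  out$latent_wealth <- z
  out
}

#' Simulate complete birth histories with an aid-dependent death hazard
#'
#' For each household, a Poisson number of births (mean set by the
#' latent-wealth quintile; poorer households have more births) is placed
#' uniformly over the 120 months preceding the interview. Each child's
#' survival is then simulated month by month from age 0 to 59: in each lived
#' month a Bernoulli draw fires with the monthly hazard determined by the
#' household's latent-wealth quintile, the country's lagged aid, and the
#' covariates (see [sim_config()] for the hazard model). Simulation stops at
#' death, at age 60 months, or at the interview month, whichever comes first.
#'
#' @param households output of [sim_households()] (must carry `latent_wealth`).
#' @param panel output of [sim_country_panel()]; must cover the year before
#'   every lived calendar month (the hazard uses aid lagged one year).
#' @param config the same [sim_config()] object.
#' @return `BirthRecord` data frame: `child_id`, `household_id`,
#'   `mother_edu_years`, `birth_month` (CMC), `died` (0/1),
#'   `age_at_death_months` (NA when alive).
#' @export
sim_birth_histories <- function(households, panel, config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  win <- config$window_months

  q_hh <- latent_quintile(households$latent_wealth, config$latent_wealth_sd)
  n_births <- stats::rpois(nrow(households), config$fertility_mean[q_hh])
  idx <- rep(seq_len(nrow(households)), n_births)
  n <- length(idx)

  birth_month <- households$interview_month[idx] - win +
    as.integer(floor(stats::runif(n) * win))      # uniform over the window
  interview <- households$interview_month[idx]
  country <- households$country[idx]
  quintile <- q_hh[idx]
  edu <- households$mother_edu_years[idx]

  # lagged-aid lookup matrix: country x year
  yrs <- sort(unique(panel$year))
  aid_col <- if (config$effect_aid == "total") "total_aid_pc" else "malaria_aid_pc"
  lookup <- function(col) {
    m <- matrix(NA_real_, max(panel$country), length(yrs))
    m[cbind(panel$country, match(panel$year, yrs))] <- panel[[col]]
    m
  }
  aid_m <- lookup(aid_col)
  govt_m <- lookup("govt_health_pc")
  urban_m <- lookup("urban_share")
  # precompute the (country, year, quintile) part of the monthly hazard;
  # lag years must exist in the panel for every lived calendar month
  lived_years <- range(cmc_year(c(birth_month, interview - 1L)))
  need <- (lived_years[1L] - 1L):lived_years[2L]
  if (!all(need %in% yrs))
    stop_ae("panel does not cover calendar year(s) ",
            paste(setdiff(need, yrs), collapse = ", "),
            " required by the birth histories (including the lag year)")

  ce <- config$covariate_effects
  ny <- length(yrs)
  nc <- max(panel$country)
  # H[c, y, q]: hazard component excluding the child's education term
  aid_lag_m <- cbind(NA_real_, aid_m[, -ny, drop = FALSE])  # aid at year - 1
  H <- array(NA_real_, c(nc, ny, 5L))
  for (q in 1:5) {
    if (config$effect_type == "linear") {
      H[, , q] <- config$baseline_hazard[q] +
        ((config$gamma + config$delta[q]) * aid_lag_m +
           ce[2L] * govt_m + ce[3L] * urban_m) / 12000
    } else {
      H[, , q] <- config$baseline_hazard[q] *
        exp((config$gamma + config$delta[q]) * aid_lag_m +
              ce[2L] * govt_m + ce[3L] * urban_m)
    }
  }
  # per-child education contribution
  edu_term <- if (config$effect_type == "linear")
    ce[1L] * edu / 12000 else exp(ce[1L] * edu)

  base_idx <- country + (quintile - 1L) * (nc * ny)   # flat index less year
  alive <- rep(TRUE, n)
  died <- rep(FALSE, n)
  age_death <- rep(NA_integer_, n)

  for (a in 0:59) {
    m <- birth_month + a
    at_risk <- which(alive & (m < interview))
    if (!length(at_risk)) break
    yi <- cmc_year(m[at_risk]) - yrs[1L] + 1L
    h <- H[base_idx[at_risk] + (yi - 1L) * nc]
    h <- if (config$effect_type == "linear")
      h + edu_term[at_risk] else h * edu_term[at_risk]
    if (anyNA(h) || any(h > 1)) {
      bad <- at_risk[which(is.na(h) | h > 1)[1L]]
      stop_ae(sprintf(
        "monthly hazard missing or > 1 for country %d, year %d, quintile %d",
        country[bad], cmc_year(birth_month[bad] + a), quintile[bad]))
    }
    fire <- stats::runif(length(at_risk)) < h    # h < 0 never fires
    who <- at_risk[fire]
    alive[who] <- FALSE
    died[who] <- TRUE
    age_death[who] <- a
  }

  data.frame(
    child_id = sprintf("%s-B%02d", households$household_id[idx],
                       sequence(n_births)),
    household_id = households$household_id[idx],
    mother_edu_years = edu,
    birth_month = birth_month,
    died = as.integer(died),
    age_at_death_months = age_death,
    stringsAsFactors = FALSE
  )
}

#' Run the whole generator
#'
#' Convenience wrapper producing the three analysis tables from one
#' configuration. The generator-internal `latent_wealth` column is dropped
#' from the household table it returns (the analysis must recover wealth from
#' assets), but is kept in the `truth` component for validation.
#'
#' @param config a [sim_config()] object.
#' @return list with components `households` (analysis columns only),
#'   `births`, `panel`, and `truth` (data frame `household_id`,
#'   `latent_wealth`, `latent_quintile`).
#' @export
simulate_survey_data <- function(config) {
  panel <- sim_country_panel(config)
  hh <- sim_households(config)
  births <- sim_birth_histories(hh, panel, config)
  truth <- data.frame(household_id = hh$household_id,
                      latent_wealth = hh$latent_wealth,
                      latent_quintile = latent_quintile(hh$latent_wealth,
                                                        config$latent_wealth_sd),
                      stringsAsFactors = FALSE)
  hh$latent_wealth <- NULL
  list(households = hh, births = births, panel = panel, truth = truth)
}

#' Write generated tables as delimited text
#'
#' Writes `households.tsv`, `births.tsv` and `country_panel.tsv` (UTF-8,
#' tab-separated, with headers) plus an echo of the generating configuration
#' (`config.yaml`) into `dir`.
#'
#' @param data list as returned by [simulate_survey_data()].
#' @param dir output directory (created if needed).
#' @param config the generating [sim_config()], echoed as YAML.
#' @return `dir`, invisibly.
#' @export
write_survey_data <- function(data, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  wr(data$households, "households.tsv")
  wr(data$births, "births.tsv")
  wr(data$panel, "country_panel.tsv")
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$asset_loadings <- as.list(cfg$asset_loadings)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read generated tables back from a directory
#'
#' @param dir directory written by [write_survey_data()].
#' @return list with `households`, `births`, `panel`.
#' @export
read_survey_data <- function(dir) {
  rd <- function(f)
    utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  list(households = rd("households.tsv"),
       births = rd("births.tsv"),
       panel = rd("country_panel.tsv"))
}
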