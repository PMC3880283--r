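test_that("child exposure handles the canonical cases", {
  iv <- cmc(2010, 6)

  # born 24 months before interview, alive: 24 months, no death
  r <- child_exposure(iv - 24L, iv)
  expect_equal(sum(r$exposure), 24)
  expect_true(is.na(r$death_year))
  # months split across calendar years by month arithmetic
  o <- exposure_oracle(iv - 24L, iv)
  expect_equal(r$exposure, o$exposure)

  # died at age 6 months within one calendar year: 6 months, 1 death
  b <- cmc(2008, 2)
  r2 <- child_exposure(b, iv, age_at_death_months = 6L)
  expect_equal(unname(r2$exposure), 6)
  expect_equal(names(r2$exposure), "2008")
  expect_equal(r2$death_year, 2008L)

  # born 130 months before interview, died at 4 months: fully pre-window
  r3 <- child_exposure(iv - 130L, iv, age_at_death_months = 4L)
  expect_equal(sum(r3$exposure), 0)
  expect_true(is.na(r3$death_year))

  expect_error(child_exposure(iv + 1L, iv), "after interview")
  expect_error(child_exposure(iv - 10L, iv, age_at_death_months = 60L),
               "under-5")
})

test_that("exposure matches the month-enumeration oracle across cases", {
  iv <- cmc(2011, 3)
  set.seed(77)
  for (i in 1:200) {
    b <- iv - sample.int(140L, 1)
    age <- if (runif(1) < 0.4) sample(0:59, 1) else NA
    r <- child_exposure(b, iv, age_at_death_months = age)
    o <- exposure_oracle(b, iv, age_at_death = age)
    expect_equal(sum(r$exposure), sum(o$exposure))
    if (length(o$exposure)) expect_equal(r$exposure, o$exposure)
    expect_equal(r$death_year, o$death_year)
  }
})

test_that("cell aggregation scales with weights and matches a hand tally", {
  iv <- cmc(2010, 1)
  hh <- data.frame(household_id = "h1", country = 1L, quintile = 3L,
                   interview_month = iv, survey_weight = 2)
  # one child, 12 exposure months then death at age 12 (born February, so
  # the death year also carries exposure and no cell is exposure-free)
  births <- data.frame(child_id = "c1", household_id = "h1",
                       mother_edu_years = 5L, birth_month = cmc(2008, 2),
                       died = 1L, age_at_death_months = 12L)
  cells <- mortality_cells(births, hh)
  expect_equal(sum(cells$child_years), 2)        # 12 months x weight 2
  expect_equal(sum(cells$deaths), 2)
  expect_equal(1000 * sum(cells$deaths) / sum(cells$child_years), 1000)

  # 20-record fixture against a per-child oracle tally
  set.seed(11)
  hh20 <- data.frame(
    household_id = paste0("h", 1:10),
    country = rep(1:2, each = 5),
    quintile = rep(c(1L, 3L, 5L, 2L, 4L), 2),
    interview_month = iv,
    survey_weight = runif(10, 0.5, 2)
  )
  b20 <- data.frame(
    child_id = paste0("c", 1:20),
    household_id = rep(hh20$household_id, 2),
    mother_edu_years = rep(c(2L, 8L), 10),
    birth_month = iv - sample.int(130L, 20),
    died = rep(c(1L, 0L), c(8, 12)),
    age_at_death_months = c(sample(0:59, 8), rep(NA, 12))
  )
  cells20 <- mortality_cells(b20, hh20)
  # oracle: accumulate each child's exposure and death into cells by hand
  acc <- list()
  for (i in 1:20) {
    j <- match(b20$household_id[i], hh20$household_id)
    o <- exposure_oracle(b20$birth_month[i], iv, b20$age_at_death_months[i])
    w <- hh20$survey_weight[j]
    for (y in names(o$exposure)) {
      k <- paste(hh20$country[j], y, hh20$quintile[j])
      acc[[k]] <- (acc[[k]] %||% c(0, 0)) + c(o$exposure[[y]] * w / 12, 0)
    }
    if (!is.na(o$death_year)) {
      k <- paste(hh20$country[j], o$death_year, hh20$quintile[j])
      acc[[k]] <- (acc[[k]] %||% c(0, 0)) + c(0, w)
    }
  }
  for (r in seq_len(nrow(cells20))) {
    k <- paste(cells20$country[r], cells20$year[r], cells20$quintile[r])
    expect_equal(cells20$child_years[r], acc[[k]][1], tolerance = 1e-12)
    expect_equal(cells20$deaths[r], acc[[k]][2], tolerance = 1e-12)
  }
  # conservation: totals match the oracle totals
  expect_equal(sum(cells20$child_years),
               sum(vapply(acc, `[`, numeric(1), 1)), tolerance = 1e-12)
})

test_that("rates are invariant to rescaling all survey weights", {
  cfg <- test_config()
  dat <- simulate_survey_data(cfg)
  scored <- data.frame(household_id = dat$truth$household_id,
                       quintile = dat$truth$latent_quintile)
  c1 <- mortality_cells(dat$births, dat$households, scored)
  hh2 <- dat$households
  hh2$survey_weight <- hh2$survey_weight * 7.3
  c2 <- mortality_cells(dat$births, hh2, scored)
  expect_equal(c1$mortality_rate, c2$mortality_rate, tolerance = 1e-12)
  expect_equal(c2$deaths, 7.3 * c1$deaths, tolerance = 1e-12)
})

test_that("a shorter recall window only removes early years", {
  cfg <- test_config()
  dat <- simulate_survey_data(cfg)
  scored <- data.frame(household_id = dat$truth$household_id,
                       quintile = dat$truth$latent_quintile)
  full <- mortality_cells(dat$births, dat$households, scored,
                          window_months = 120L)
  short <- mortality_cells(dat$births, dat$households, scored,
                           window_months = 60L)
  # years fully covered by both windows agree cell by cell
  iv_years <- unique(cmc_year(dat$households$interview_month))
  common <- intersect(full$year, short$year)
  safe <- common[common >= max(iv_years) - 3]   # well inside both windows
  for (y in safe) {
    a <- full[full$year == y, ]
    b <- short[short$year == y, ]
    key <- paste(a$country, a$quintile)
    m <- match(paste(b$country, b$quintile), key)
    expect_equal(b$deaths, a$deaths[m], tolerance = 1e-12)
  }
})

test_that("orphan births and invalid death ages are caught", {
  iv <- cmc(2010, 1)
  hh <- data.frame(household_id = "h1", country = 1L, quintile = 1L,
                   interview_month = iv, survey_weight = 1)
  b <- data.frame(child_id = "c", household_id = "zzz",
                  mother_edu_years = 1L, birth_month = iv - 10L,
                  died = 0L, age_at_death_months = NA_integer_)
  expect_error(mortality_cells(b, hh), "no household match")
  b2 <- data.frame(child_id = c("c", "c2"), household_id = "h1",
                   mother_edu_years = 1L, birth_month = iv - 70L,
                   died = c(1L, 0L), age_at_death_months = c(65L, NA))
  expect_error(mortality_cells(b2, hh), ">= 60 months")
  expect_message(out <- mortality_cells(b2, hh, on_invalid = "drop"),
                 "dropped")
  expect_true(all(out$n_children == 1L))  # only the valid record remains
})

test_that("period summaries reproduce the published decline arithmetic", {
  # the reference-table rates, fed through the decline arithmetic
  dec_poor <- rate_decline(36.9, 23.0)
  expect_equal(round(dec_poor$abs_decline, 1), 13.9)
  expect_equal(round(dec_poor$pct_decline, 1), 37.7)
  dec_rich <- rate_decline(7.9, 7.1)
  expect_equal(round(dec_rich$abs_decline, 1), 0.8)
  expect_equal(round(dec_rich$pct_decline, 1), 10.1)
  expect_equal(rate_decline(5, 5)$pct_decline, 0)
  expect_true(is.na(rate_decline(0, 3)$pct_decline))

  # exposure weighting: the period rate is total deaths / total child-years
  cells <- data.frame(country = 1L, year = c(1995L, 1996L, 2006L),
                      quintile = 5L, deaths = c(10, 40, 12),
                      child_years = c(1000, 2000, 1500))
  cells$mortality_rate <- 1000 * cells$deaths / cells$child_years
  s <- period_summary(cells, 1993:2000, 2005:2012)
  expect_equal(s$rate_a[5], 1000 * 50 / 3000)    # not mean(10, 20)
  expect_equal(s$rate_b[5], 8)
  expect_error(period_summary(cells, 1980:1985, 2005:2012), "no cell years")
})
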