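#' Exposure months and death year for a single birth record
#'
#' Computes, for one child, the number of full months lived while under age
#' five and inside the recall window preceding the interview, bucketed by
#' calendar year, plus the calendar year of death (if any death falls inside
#' the window).
#'
#' Conventions (month-granular, matching complete-birth-history data):
#' exposure months are calendar months `m` with
#' `birth_month <= m < min(birth_month + 60, death_month, interview_month)`
#' and `m >= interview_month - window_months`; the interview month itself
#' contributes nothing (only full months lived count) and the death month
#' contributes no exposure (death at month start). The death event is counted
#' in the year of `death_month = birth_month + age_at_death_months` only when
#' that month lies inside the window, before the interview, and the child was
#' under 60 months old.
#'
#' @param birth_month birth month (CMC).
#' @param interview_month interview month (CMC).
#' @param age_at_death_months age at death in months, or `NA` if alive.
#' @param window_months recall window length (default 120 = 10 years).
#' @return list with `exposure` (named numeric vector: months of exposure per
#'   calendar year) and `death_year` (integer or `NA`).
#' @export
child_exposure <- function(birth_month, interview_month,
                           age_at_death_months = NA,
                           window_months = 120L) {
  if (birth_month > interview_month)
    stop_ae("birth_month after interview_month")
  died <- !is.na(age_at_death_months)
  if (died && age_at_death_months >= 60L)
    stop_ae("age_at_death_months >= 60 violates the under-5 definition")
  death_month <- if (died) birth_month + age_at_death_months else Inf
  win_start <- interview_month - window_months
  m0 <- max(birth_month, win_start)
  m1 <- min(birth_month + 60L, death_month, interview_month)
  exposure <- numeric(0)
  if (m1 > m0) {
    months <- seq.int(m0, m1 - 1L)
    exposure <- vapply(split(months, cmc_year(months)), length, numeric(1))
  }
  death_year <- NA_integer_
  if (died && death_month >= win_start && death_month < interview_month)
    death_year <- cmc_year(death_month)
  list(exposure = exposure, death_year = death_year)
}

#' Aggregate birth histories into country-year-quintile mortality cells
#'
#' Converts birth records into survey-weighted deaths, child-years of
#' exposure, and under-5 mortality rates per (country, calendar year, wealth
#' quintile) cell over the recall window preceding each survey, using the
#' month conventions of [child_exposure()]. Overlapping surveys from one
#' country are pooled (weighted union of children), preserving the
#' deaths/exposure definition of the rate. The maternal-education covariate
#' is the survey-weighted median years of education per (country, quintile),
#' held constant over that stratum's years.
#'
#' @param births `BirthRecord` data frame (`household_id`,
#'   `mother_edu_years`, `birth_month`, `died`, `age_at_death_months`).
#' @param households household table carrying `household_id`, `country`,
#'   `interview_month` and `survey_weight`.
#' @param scored quintile assignment (`household_id`, `quintile`), e.g. from
#'   [predict.wealth_index()].
#' @param window_months recall window (default 120).
#' @param on_invalid what to do with records whose age at death is >= 60
#'   months: `"error"` (default) or `"drop"` (excluded with a message).
#' @return `StratumYearCell` data frame: `country`, `year`, `quintile`,
#'   `deaths` (weighted), `child_years` (weighted),
#'   `mortality_rate` (deaths per 1,000 child-years),
#'   `median_mother_education`, `n_children` (unweighted contributors).
#'   Cells with zero exposure are omitted.
#' @export
mortality_cells <- function(births, households, scored = NULL,
                            window_months = 120L,
                            on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  hh <- households
  if (!is.null(scored)) {
    m <- match(hh$household_id, scored$household_id)
    hh$quintile <- scored$quintile[m]
    hh <- hh[!is.na(hh$quintile), , drop = FALSE]
  }
  if (!"quintile" %in% names(hh))
    stop_ae("no quintile assignment: pass `scored` or a quintile column")

  m <- match(births$household_id, hh$household_id)
  if (anyNA(m)) {
    orphans <- unique(births$household_id[is.na(m)])
    if (!is.null(scored) && all(orphans %in% households$household_id)) {
      # households dropped at scoring (incomplete assets): drop their births
      births <- births[!is.na(m), , drop = FALSE]
      m <- m[!is.na(m)]
    } else {
      stop_ae("birth records with no household match: ",
              paste(utils::head(orphans, 5L), collapse = ", "),
              if (length(orphans) > 5L) ", ...")
    }
  }
  died <- births$died == 1L & !is.na(births$age_at_death_months)
  bad <- died & births$age_at_death_months >= 60L
  if (any(bad)) {
    if (on_invalid == "error")
      stop_ae(sum(bad), " record(s) with age at death >= 60 months")
    message(sum(bad), " record(s) with age at death >= 60 months dropped")
    births <- births[!bad, , drop = FALSE]
    m <- m[!bad]
    died <- died[!bad]
  }

  country <- hh$country[m]
  quintile <- hh$quintile[m]
  interview <- hh$interview_month[m]
  w <- hh$survey_weight[m]
  birth_month <- births$birth_month
  if (any(birth_month > interview))
    stop_ae("birth month after interview month")

  death_month <- ifelse(died, birth_month + births$age_at_death_months, NA)
  win_start <- interview - window_months
  m0 <- pmax(birth_month, win_start)
  m1 <- pmin(birth_month + 60L, interview)
  m1 <- ifelse(died & death_month < m1, death_month, m1)

  # split each child's exposure months [m0, m1) by calendar year; cells are
  # accumulated under an integer (country, year, quintile) key
  n <- length(m0)
  has_exp <- m1 > m0
  start_year <- cmc_year(pmin(m0, m1))
  keys <- vals <- vector("list", 7L)
  for (k in 0:5) {
    ystart <- cmc(start_year + k, 1L)
    mo <- pmax(0L, pmin(m1, ystart + 12L) - pmax(m0, ystart))
    sel <- which(has_exp & mo > 0L)
    if (!length(sel)) next
    keys[[k + 1L]] <- (country[sel] * 100000 + (start_year[sel] + k)) * 10 +
      quintile[sel]
    vals[[k + 1L]] <- cbind(mw = mo[sel] * w[sel], child = 1, d = 0)
  }
  if (all(vapply(keys, is.null, logical(1)))) stop_ae("no exposure in any cell")

  # death events inside the window, before interview
  dsel <- which(died & death_month >= win_start & death_month < interview)
  if (length(dsel)) {
    keys[[7L]] <- (country[dsel] * 100000 + cmc_year(death_month[dsel])) *
      10 + quintile[dsel]
    vals[[7L]] <- cbind(mw = 0, child = 0, d = w[dsel])
  }

  key <- unlist(keys, use.names = FALSE)
  agg <- rowsum(do.call(rbind, vals), key)
  kk <- as.numeric(rownames(agg))
  cells <- data.frame(
    country = as.integer(kk %/% 1000000),
    year = as.integer((kk %/% 10) %% 100000),
    quintile = as.integer(kk %% 10),
    deaths = agg[, "d"],
    child_years = agg[, "mw"] / 12,
    n_children = as.integer(agg[, "child"])
  )
  cells <- cells[cells$child_years > 0, , drop = FALSE]
  cells$mortality_rate <- 1000 * cells$deaths / cells$child_years

  # E_cq: weighted median maternal education per (country, quintile)
  ek <- interaction(country, quintile, drop = TRUE)
  emed <- vapply(split(seq_len(n), ek), function(i)
    weighted_median(births$mother_edu_years[i], w[i]), numeric(1))
  cells$median_mother_education <-
    emed[match(paste(cells$country, cells$quintile, sep = "."), names(emed))]

  cells <- cells[order(cells$country, cells$year, cells$quintile), ,
                 drop = FALSE]
  rownames(cells) <- NULL
  cells[, c("country", "year", "quintile", "deaths", "child_years",
            "mortality_rate", "median_mother_education", "n_children")]
}

#' Period mortality summary by wealth quintile
#'
#' Exposure-weighted period rates (total deaths over total child-years within
#' each period, not an average of annual rates) per quintile, with the
#' absolute and percent decline between the two periods.
#'
#' @param cells `StratumYearCell` table from [mortality_cells()].
#' @param period_a,period_b calendar-year vectors of the earlier and later
#'   period.
#' @return data frame per quintile: `rate_a`, `rate_b`, `exposure_a`,
#'   `exposure_b` (child-years, thousands), `abs_decline`, `pct_decline`
#'   (`NA` when `rate_a` is 0 and `rate_b` > 0).
#' @export
period_summary <- function(cells, period_a, period_b) {
  if (!any(cells$year %in% period_a) || !any(cells$year %in% period_b))
    stop_ae("a summary period contains no cell years")
  one <- function(period) {
    sel <- cells$year %in% period
    d <- tapply(cells$deaths[sel], cells$quintile[sel], sum)
    cy <- tapply(cells$child_years[sel], cells$quintile[sel], sum)
    qs <- as.integer(names(d))
    full_d <- full_cy <- rep(NA_real_, 5L)
    full_d[qs] <- d
    full_cy[qs] <- cy
    list(rate = 1000 * full_d / full_cy, cy = full_cy)
  }
  a <- one(period_a)
  b <- one(period_b)
  out <- data.frame(
    quintile = 1:5,
    rate_a = a$rate, rate_b = b$rate,
    exposure_a = a$cy / 1000, exposure_b = b$cy / 1000
  )
  dec <- rate_decline(out$rate_a, out$rate_b)
  out$abs_decline <- dec$abs_decline
  out$pct_decline <- dec$pct_decline
  out
}

#' Absolute and percent decline between two rates
#'
#' @param rate_a,rate_b earlier and later period rates.
#' @return list with `abs_decline` (`rate_a - rate_b`) and `pct_decline`
#'   (`100 * (rate_a - rate_b) / rate_a`; `NA` when `rate_a` is 0 and
#'   `rate_b` is not).
#' @export
rate_decline <- function(rate_a, rate_b) {
  abs_decline <- rate_a - rate_b
  pct_decline <- ifelse(rate_a == 0,
                        ifelse(rate_b == 0, 0, NA_real_),
                        100 * abs_decline / rate_a)
  list(abs_decline = abs_decline, pct_decline = pct_decline)
}
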