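#' Fit the pooled absolute wealth index
#'
#' Builds a single cross-country household wealth score as the first
#' principal component of standardized asset/service indicators, pooled over
#' all surveys so that scores are comparable in absolute terms across
#' countries and years. The construction mirrors standard DHS practice
#' (Rutstein-style PCA on the correlation scale) with two additions used for
#' pooled multi-survey data:
#' \itemize{
#'   \item every moment (means, SDs, covariances, quantiles) is weighted,
#'     by default with each survey's share of its national population, so
#'     uniquely large surveys do not dominate the index;
#'   \item year effects: weighted per-survey-year means of each standardized
#'     variable are removed before the eigen-decomposition, absorbing common
#'     shifts in asset ownership over the survey period.
#' }
#' Loadings are sign-normalized so the score increases with wealth (the
#' electricity loading, or failing that the first positive-able loading, is
#' positive). Quintile cutpoints are the weighted 20/40/60/80 percentiles of
#' the fitted scores.
#'
#' @param households data frame of household records; must contain the
#'   variables in `vars` and, when `year_effects = TRUE`, the `year_var`
#'   column.
#' @param weights positive household weights; defaults to the
#'   `population_share_weight` column, or uniform weights if absent.
#' @param vars character vector of index variables (binary assets plus
#'   continuous rooms-per-person, all standardized and treated alike).
#' @param year_effects logical; remove weighted per-year means of each
#'   standardized variable before the decomposition.
#' @param year_var name of the survey-year column.
#' @return An object of class `"wealth_index"` with components
#'   `vars`, `asset_means`, `asset_sds`, `year_effects` (matrix year x
#'   variable, or NULL), `loadings`, `explained_variance_share`,
#'   `quintile_cutpoints` (ascending weighted 20/40/60/80 percentiles).
#' @examples
#' cfg <- sim_config(n_countries = 3, households_per_survey = 150, seed = 7)
#' hh <- sim_households(cfg)
#' m <- wealth_index(hh)
#' summary(m)
#' @export
wealth_index <- function(households,
                         weights = NULL,
                         vars = wealth_index_vars(),
                         year_effects = TRUE,
                         year_var = "survey_year") {
  missing_vars <- setdiff(vars, names(households))
  if (length(missing_vars))
    stop_ae("household table lacks index variable(s): ",
            paste(missing_vars, collapse = ", "))
  if (nrow(households) < 2L)
    stop_ae("need at least 2 households to fit the wealth index")
  if (nrow(households) < length(vars))
    stop_ae("fewer households than index variables")
  w <- weights %||% households$population_share_weight %||%
    rep(1, nrow(households))
  if (any(w <= 0) || anyNA(w)) stop_ae("weights must be positive")

  X <- as.matrix(households[, vars, drop = FALSE])
  if (anyNA(X)) stop_ae("missing values in index variables; complete cases only")

  mu <- apply(X, 2L, wtd_mean, w = w)
  sd_ <- apply(X, 2L, wtd_sd, w = w)
  zero_var <- sd_ <= 0
  if (any(zero_var))
    stop_ae("zero weighted variance in index variable(s): ",
            paste(vars[zero_var], collapse = ", "))
  Z <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")

  ye <- NULL
  if (isTRUE(year_effects)) {
    if (!year_var %in% names(households))
      stop_ae("year_effects = TRUE but no '", year_var, "' column")
    yr <- as.integer(households[[year_var]])
    yl <- sort(unique(yr))
    ye <- matrix(0, length(yl), length(vars),
                 dimnames = list(as.character(yl), vars))
    for (i in seq_along(yl)) {
      sel <- yr == yl[i]
      ye[i, ] <- apply(Z[sel, , drop = FALSE], 2L, wtd_mean, w = w[sel])
    }
    Z <- Z - ye[match(yr, yl), , drop = FALSE]
  }

  # weighted covariance of the standardized (correlation-scale) variables
  C <- crossprod(Z * w, Z) / sum(w)
  eg <- eigen(C, symmetric = TRUE)
  loadings <- eg$vectors[, 1L]
  names(loadings) <- vars
  evs <- eg$values[1L] / sum(pmax(eg$values, 0))

  # sign normalization: score must increase with wealth
  anchor <- if ("electricity" %in% vars) "electricity" else
    vars[which.max(abs(loadings))]
  if (loadings[anchor] < 0) loadings <- -loadings

  score <- drop(Z %*% loadings)
  cuts <- weighted_quantile(score, w, probs = c(0.2, 0.4, 0.6, 0.8))
  if (is.unsorted(cuts, strictly = FALSE))
    stop_ae("quintile cutpoints are not ascending")

  structure(list(
    vars = vars,
    asset_means = mu,
    asset_sds = sd_,
    year_effects = ye,
    loadings = loadings,
    explained_variance_share = evs,
    quintile_cutpoints = cuts,
    n = nrow(households)
  ), class = "wealth_index")
}

#' Default wealth-index variable set
#'
#' The ten binary asset/service indicators plus continuous rooms-per-person
#' used by the pooled index.
#' @return character vector of column names.
#' @export
wealth_index_vars <- function() {
  c("water_improved", "sanitation_improved", "floor_finished", "electricity",
    "radio", "television", "phone", "refrigerator", "motorcycle", "car",
    "rooms_per_person")
}

#' @export
print.wealth_index <- function(x, ...) {
  cat(sprintf("Pooled wealth index (weighted PC1, %d households)\n", x$n))
  cat(sprintf("  explained variance share: %.3f\n", x$explained_variance_share))
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
summary.wealth_index <- function(object, ...) {
  print(object)
  cat("  quintile cutpoints (ascending; scores above the last are q1 = wealthiest):\n  ")
  cat(paste(format(object$quintile_cutpoints, digits = 4), collapse = ", "), "\n")
  if (!is.null(object$year_effects)) {
    cat(sprintf("  year effects removed for %d survey years\n",
                nrow(object$year_effects)))
  }
  invisible(object)
}

#' Score households and assign wealth quintiles
#'
#' Applies a fitted [wealth_index()] to (possibly unseen) households:
#' standardizes each index variable with the stored weighted means/SDs,
#' removes the stored year effect for the household's survey year (unseen
#' years get no adjustment), takes the loading-weighted sum as the wealth
#' score, and assigns quintiles from the stored cutpoints. Quintile 1 is the
#' wealthiest (highest scores), 5 the poorest; a score exactly at a cutpoint
#' is assigned to the poorer quintile.
#'
#' Households with a missing value in any index variable are excluded, with
#' a message giving the count (analyses use complete-information households
#' only).
#'
#' @param object fitted `"wealth_index"`.
#' @param newdata household data frame.
#' @param year_var survey-year column name (used for year effects).
#' @param ... unused.
#' @return data frame `household_id`, `wealth_score`, `quintile`.
#' @export
predict.wealth_index <- function(object, newdata, year_var = "survey_year",
                                 ...) {
  missing_vars <- setdiff(object$vars, names(newdata))
  if (length(missing_vars))
    stop_ae("newdata lacks index variable(s): ",
            paste(missing_vars, collapse = ", "))
  X <- as.matrix(newdata[, object$vars, drop = FALSE])
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    message(sum(!keep), " household(s) excluded for incomplete asset information")
    X <- X[keep, , drop = FALSE]
    newdata <- newdata[keep, , drop = FALSE]
  }
  Z <- sweep(sweep(X, 2L, object$asset_means), 2L, object$asset_sds, "/")
  if (!is.null(object$year_effects) && year_var %in% names(newdata)) {
    yl <- as.integer(rownames(object$year_effects))
    m <- match(as.integer(newdata[[year_var]]), yl)
    adj <- object$year_effects[ifelse(is.na(m), 1L, m), , drop = FALSE]
    adj[is.na(m), ] <- 0
    Z <- Z - adj
  }
  score <- drop(Z %*% object$loadings)
  # scores <= cut[1] are the poorest fifth; ties go to the poorer quintile
  quintile <- 5L - findInterval(score, object$quintile_cutpoints,
                                left.open = TRUE)
  data.frame(
    household_id = newdata$household_id %||% seq_len(nrow(newdata)),
    wealth_score = score,
    quintile = as.integer(quintile),
    stringsAsFactors = FALSE
  )
}

#' Weighted asset-ownership shares by wealth quintile
#'
#' Survey-weighted ownership share (percent) of each binary asset per
#' assigned quintile, plus mean rooms-per-person, in the layout of a
#' sample-description table (columns poorest .. wealthiest).
#'
#' @param scored data frame from [predict.wealth_index()].
#' @param households household table; joined 1:1 on `household_id`.
#' @param weights optional weight column name in `households` (default
#'   `survey_weight`; uniform if absent).
#' @param assets binary asset columns to tabulate.
#' @return data frame with one row per asset (shares in percent) plus a
#'   `rooms_per_person` row (means), columns `q1` (wealthiest) .. `q5`
#'   (poorest).
#' @export
tabulate_assets_by_quintile <- function(scored, households,
                                        weights = "survey_weight",
                                        assets = setdiff(wealth_index_vars(),
                                                         "rooms_per_person")) {
  m <- match(scored$household_id, households$household_id)
  if (anyNA(m)) stop_ae("scored households missing from household table")
  hh <- households[m, , drop = FALSE]
  w <- if (weights %in% names(hh)) hh[[weights]] else rep(1, nrow(hh))
  q <- scored$quintile
  one <- function(v, f = wtd_mean) {
    vapply(1:5, function(k) f(v[q == k], w[q == k]), numeric(1))
  }
  rows <- lapply(assets, function(a) 100 * one(hh[[a]]))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("q", 1:5)
  out <- rbind(out, one(hh$rooms_per_person))
  out$variable <- c(assets, "rooms_per_person")
  out[, c("variable", paste0("q", 1:5))]
}

#' Serialize and reload a fitted wealth index
#'
#' Plain-text key-value serialization (loadings, means, SDs, year effects,
#' cutpoints) allowing exact reload of a fitted model.
#'
#' @param model fitted `"wealth_index"`.
#' @param path file path.
#' @return `write_wealth_index()` returns `path` invisibly;
#'   `read_wealth_index()` returns the reloaded `"wealth_index"` object.
#' @export
write_wealth_index <- function(model, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = "\t")
  lines <- c(
    paste0("vars\t", paste(model$vars, collapse = "\t")),
    paste0("asset_means\t", num(model$asset_means)),
    paste0("asset_sds\t", num(model$asset_sds)),
    paste0("loadings\t", num(model$loadings)),
    paste0("explained_variance_share\t", num(model$explained_variance_share)),
    paste0("quintile_cutpoints\t", num(model$quintile_cutpoints)),
    paste0("n\t", model$n)
  )
  if (!is.null(model$year_effects)) {
    lines <- c(lines, vapply(rownames(model$year_effects), function(y)
      paste0("year_effect_", y, "\t", num(model$year_effects[y, ])),
      character(1)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_wealth_index
#' @export
read_wealth_index <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  kv <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(kv, `[[`, character(1), 1L)
  val <- lapply(kv, function(x) x[-1L])
  get_num <- function(k) as.numeric(val[[match(k, key)]])
  vars <- val[[match("vars", key)]]
  ye_keys <- grep("^year_effect_", key, value = TRUE)
  ye <- NULL
  if (length(ye_keys)) {
    ye <- do.call(rbind, lapply(ye_keys, get_num))
    rownames(ye) <- sub("^year_effect_", "", ye_keys)
    colnames(ye) <- vars
  }
  structure(list(
    vars = vars,
    asset_means = stats::setNames(get_num("asset_means"), vars),
    asset_sds = stats::setNames(get_num("asset_sds"), vars),
    year_effects = ye,
    loadings = stats::setNames(get_num("loadings"), vars),
    explained_variance_share = get_num("explained_variance_share"),
    quintile_cutpoints = get_num("quintile_cutpoints"),
    n = as.integer(get_num("n"))
  ), class = "wealth_index")
}
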