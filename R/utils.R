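#' Century-month-code helpers
#'
#' Calendar months are encoded throughout the package as integer months since
#' January 1900 (the DHS "century month code", CMC): January 1900 is 1, so
#' `cmc = (year - 1900) * 12 + month_of_year`.
#'
#' @param year calendar year (integer vector).
#' @param month month of year, 1..12.
#' @param cmc century month code (integer vector).
#' @return `cmc()` returns the integer code; `cmc_year()` and `cmc_month()`
#'   decompose it.
#' @examples
#' cmc(1900, 1)      # 1
#' cmc_year(cmc(2003, 7))
#' @export
cmc <- function(year, month = 1L) {
  (as.integer(year) - 1900L) * 12L + as.integer(month)
}

#' @rdname cmc
#' @export
cmc_year <- function(cmc) 1900L + (as.integer(cmc) - 1L) %/% 12L

#' @rdname cmc
#' @export
cmc_month <- function(cmc) (as.integer(cmc) - 1L) %% 12L + 1L

#' Weighted quantiles of the step-function CDF
#'
#' Returns, for each probability `p`, the smallest observed value `x` whose
#' weighted cumulative share is at least `p`. This step-CDF definition keeps
#' quintile assignment deterministic under ties.
#'
#' @param x numeric vector.
#' @param w positive weights, recycled to `length(x)`.
#' @param probs probabilities in (0, 1).
#' @return numeric vector, one quantile per probability.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs) {
  stopifnot(length(x) > 0L, all(w > 0), all(probs > 0 & probs < 1))
  w <- rep_len(w, length(x))
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Weighted median
#'
#' Weighted median using the step-CDF convention; at an exact 50/50 split the
#' lower of the two middle values is returned.
#'
#' @inheritParams weighted_quantile
#' @return scalar median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  if (length(x) == 0L) return(NA_real_)
  w <- rep_len(w, length(x))
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  x[which(cw >= 0.5 - 1e-12)[1L]]
}

# weighted mean/SD with population (sum-of-weights) divisor, used by the
# wealth index so that integer weights behave exactly like row replication
wtd_mean <- function(x, w) sum(w * x) / sum(w)
wtd_sd <- function(x, w) {
  m <- wtd_mean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ae <- function(...) stop(..., call. = FALSE)
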