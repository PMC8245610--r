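# Age-axis interval schemes and hazard/survival composition.

#' Build an interval scheme over the age axis
#'
#' Partitions `[min_age, max_age)` into contiguous half-open intervals
#' `[b_{k-1}, b_k)` of equal width. The last interval may overshoot
#' `max_age` so that the whole range is covered. Both hazard models predict
#' one conditional event probability per interval of a scheme; widths of 1,
#' 3 and 5 years correspond to 1-, 3- and 5-year-ahead prediction.
#'
#' @param width Interval width in years (positive; typically 1, 3 or 5).
#' @param min_age Left edge of the first interval (years). Defaults to 5,
#'   the minimum enrolment age of the cohort design this package targets.
#' @param max_age Upper end of the age range to cover (years).
#' @return An object of class `"interval_scheme"` with elements `width`,
#'   `min_age`, `max_age`, `boundaries` (length K+1) and `n_intervals`.
#' @export
#' @examples
#' interval_scheme(5, 5, 25)  # [5,10) [10,15) [15,20) [20,25)
interval_scheme <- function(width, min_age = 5, max_age = 40) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("'width' must be a single positive number", call. = FALSE)
  if (max_age <= min_age)
    stop("'max_age' must exceed 'min_age'", call. = FALSE)
  k <- ceiling((max_age - min_age) / width - 1e-9)
  structure(list(
    width = width, min_age = min_age, max_age = max_age,
    boundaries = min_age + width * (0:k),
    n_intervals = k
  ), class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat(sprintf("<interval_scheme> %d intervals of width %g over [%g, %g)\n",
              x$n_intervals, x$width, x$min_age, max(x$boundaries)))
  invisible(x)
}

# 1-based index of the half-open interval containing `age`; an age on a
# boundary belongs to the interval starting there. NA outside the scheme.
interval_index_of <- function(scheme, age) {
  k <- floor((age - scheme$min_age) / scheme$width + 1e-9) + 1
  k[age < scheme$min_age | k > scheme$n_intervals] <- NA_integer_
  as.integer(k)
}

interval_start <- function(scheme, k) scheme$boundaries[k]
interval_end   <- function(scheme, k) scheme$boundaries[k + 1L]
interval_mid   <- function(scheme, k) (scheme$boundaries[k] + scheme$boundaries[k + 1L]) / 2

#' Compose a discrete survival curve from conditional hazards
#'
#' Given the conditional probabilities `h_k` of the event occurring in
#' interval k (given survival to its start), the probability of remaining
#' event-free through interval k is the product-limit
#' `S(k) = prod_{j <= k} (1 - h_j)`.
#'
#' @param hazards Numeric vector of conditional hazards, each in \[0, 1\].
#' @return Numeric vector of the same length: survival through each interval.
#'   Non-increasing, bounded in \[0, 1\].
#' @export
#' @examples
#' survival_from_hazards(c(0.1, 0.2))  # 0.90 0.72
survival_from_hazards <- function(hazards) {
  if (length(hazards) == 0) return(numeric(0))
  if (any(!is.finite(hazards)) || any(hazards < 0 | hazards > 1))
    stop("hazards must lie in [0, 1]", call. = FALSE)
  cumprod(1 - hazards)
}

# Evaluate a step survival curve at an arbitrary age: the product over
# intervals fully completed by `age` (right-continuous in the boundaries).
# Used for fixed-age quantities such as the Brier score's S(t) = P(T > t).
survival_at_age <- function(scheme, survival, age) {
  done <- sum(scheme$boundaries[-1] <= age + 1e-9)
  if (done == 0) 1 else survival[min(done, length(survival))]
}

# Survival through the interval containing `age`: the discrete analogue of
# S(t) used when ranking subjects at an event time — within-interval
# ordering is not resolvable, so the interval's own hazard is included.
survival_through_interval <- function(scheme, survival, age) {
  k <- sum(scheme$boundaries[-length(scheme$boundaries)] <= age + 1e-9)
  survival[min(max(k, 1), length(survival))]
}
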