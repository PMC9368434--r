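#' Shelf-life specification
#'
#' Parameters of the first-order shelf-life question: starting from a
#' measured initial index value `a0`, how long until the index reaches the
#' quality limit `a_limit`? For peroxide value the conventional limit is
#' 10 meq O2/kg oil, taken as the onset of detectable rancidity of the fat
#' phase. `a0` is the measured day-zero value of the formulation — it is
#' deliberately an explicit input, not inferred from a regression intercept.
#'
#' @param a0 Initial index value (meq O2/kg), 0 < a0 < a_limit.
#' @param a_limit Quality limit (meq O2/kg), default 10.
#' @param age_at_test_months Product age when the storage trial started
#'   (months), added to the predicted days to express total shelf-life.
#'   Default 5.
#' @param days_per_month Divisor for day-to-month conversion, default 30.
#' @return Object of class `"shelf_life_spec"`.
#' @examples
#' shelf_life_spec(9e-4)
#' @export
shelf_life_spec <- function(a0, a_limit = 10, age_at_test_months = 5,
                            days_per_month = 30) {
  if (!is.finite(a0) || a0 <= 0) stop("'a0' must be positive")
  if (!is.finite(a_limit) || a_limit <= a0)
    stop("'a_limit' must exceed 'a0'")
  if (!is.finite(age_at_test_months) || age_at_test_months < 0)
    stop("'age_at_test_months' must be >= 0")
  if (!is.finite(days_per_month) || days_per_month <= 0)
    stop("'days_per_month' must be positive")
  structure(list(a0 = a0, a_limit = a_limit,
                 age_at_test_months = age_at_test_months,
                 days_per_month = days_per_month),
            class = "shelf_life_spec")
}

#' Days for a first-order index to reach the quality limit
#'
#' Under first-order growth `A(t) = a0 * exp(k t)`, the time to reach the
#' limit is `t = (ln a_limit - ln a0) / k`.
#'
#' @param spec A [shelf_life_spec()].
#' @param k First-order rate constant (1/day), > 0.
#' @return Predicted days to the limit.
#' @examples
#' shelf_life_days(shelf_life_spec(9e-4), 0.1569)  # 59.4 days
#' @export
shelf_life_days <- function(spec, k) {
  stopifnot(inherits(spec, "shelf_life_spec"))
  if (any(!is.finite(k)) || any(k <= 0))
    stop("'k' must be positive (a non-degrading product has no finite ",
         "first-order shelf-life)")
  (log(spec$a_limit) - log(spec$a0)) / k
}

#' Total shelf-life in months including pre-trial age
#'
#' `age_at_test_months + days / days_per_month`: the product was already
#' some months old when the storage trial began, so the consumer-facing
#' shelf-life adds that age to the predicted remaining days.
#'
#' @param days Predicted days to the quality limit, >= 0.
#' @param spec A [shelf_life_spec()].
#' @return Total shelf-life, months.
#' @examples
#' total_shelf_life_months(60, shelf_life_spec(9e-4))  # 7
#' @export
total_shelf_life_months <- function(days, spec) {
  stopifnot(inherits(spec, "shelf_life_spec"))
  if (any(!is.finite(days)) || any(days < 0))
    stop("'days' must be non-negative")
  spec$age_at_test_months + days / spec$days_per_month
}
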