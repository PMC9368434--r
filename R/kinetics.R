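#' Construct an oxidation time series
#'
#' One sample x storage-temperature time course of an oxidation index
#' (typically the peroxide value, meq O2/kg oil) sampled over days of
#' storage. This is the unit of data the kinetic fitting operates on.
#'
#' @param days Sampling times in days, strictly increasing, >= 0, length >= 3.
#' @param values Index values at those times, finite. Zero/first/second-order
#'   fitting on the log or reciprocal scale additionally requires positivity,
#'   checked at fit time.
#' @param sample_id Formulation label.
#' @param temperature Storage temperature (K); metadata here, used by the
#'   Arrhenius stage.
#' @param rel_humidity Relative humidity (\%), metadata only.
#'
#' @return Object of class `"oxidation_series"`.
#' @examples
#' oxidation_series(c(0, 1, 3, 5), 9e-4 * exp(0.14 * c(0, 1, 3, 5)),
#'                  sample_id = "A", temperature = 288.15)
#' @export
oxidation_series <- function(days, values, sample_id = "sample",
                             temperature = NA_real_,
                             rel_humidity = NA_real_) {
  if (length(days) != length(values))
    stop("'days' and 'values' must have the same length")
  if (length(days) < 3L)
    stop("an oxidation series needs at least 3 time points")
  if (any(!is.finite(days)) || any(!is.finite(values)))
    stop("'days' and 'values' must be finite")
  if (any(days < 0)) stop("'days' must be non-negative")
  if (any(diff(days) <= 0)) stop("'days' must be strictly increasing")
  structure(list(sample_id = as.character(sample_id),
                 temperature = temperature,
                 rel_humidity = rel_humidity,
                 days = as.numeric(days),
                 values = as.numeric(values)),
            class = "oxidation_series")
}

# linearising transform for reaction order n: A (n=0), ln A (n=1), 1/A (n=2)
.order_transform <- function(series, order) {
  if (order %in% c(1L, 2L) && any(series$values <= 0)) {
    bad <- series$days[series$values <= 0]
    stop(sprintf(
      "order-%d fitting needs positive index values; non-positive value at day %s",
      order, paste(bad, collapse = ", ")))
  }
  switch(as.character(order),
         "0" = series$values,
         "1" = log(series$values),
         "2" = 1 / series$values,
         stop("'order' must be 0, 1 or 2"))
}

#' Fit a linearised kinetic model of fixed reaction order
#'
#' Fits `dA/dt = k * A^n` for n = 0, 1 or 2 by ordinary least squares on the
#' linearising scale: A vs t (order 0), ln A vs t (order 1), 1/A vs t
#' (order 2). The goodness of fit is the R-squared of that transformed-scale
#' regression (equivalently the squared Pearson correlation of the
#' transformed values with time).
#'
#' For order 2 on a growing index, 1/A decreases, so the reported rate
#' constant is `|slope|` with the signed slope retained in `$slope`.
#'
#' @param series An [oxidation_series()].
#' @param order Reaction order: 0, 1 or 2.
#'
#' @return Object of class `"kinetic_fit"`: `order`, `k` (index/day, 1/day,
#'   or 1/(index day)), `intercept` (transformed scale), `slope` (signed),
#'   `r_squared`, `n_points`, plus the series metadata.
#' @examples
#' d <- c(0, 1, 3, 5, 8, 12, 16, 20, 31)
#' s <- oxidation_series(d, 9e-4 * exp(0.1445 * d))
#' fit_order(s, 1)  # recovers k = 0.1445 exactly
#' @export
fit_order <- function(series, order) {
  stopifnot(inherits(series, "oxidation_series"))
  order <- as.integer(order)
  y <- .order_transform(series, order)
  x <- series$days
  fit <- lm(y ~ x)
  cf <- coef(fit)
  slope <- unname(cf[2L])
  r2 <- .ols_r2(x, y)
  structure(list(order = order,
                 k = if (order == 2L) abs(slope) else slope,
                 slope = slope,
                 intercept = unname(cf[1L]),
                 r_squared = r2,
                 n_points = length(x),
                 sample_id = series$sample_id,
                 temperature = series$temperature),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  unit <- c("index/day", "1/day", "1/(index day)")[x$order + 1L]
  cat(sprintf("Order-%d kinetic fit (%s, T = %s K): k = %.4g %s, R^2 = %.4f, n = %d\n",
              x$order, x$sample_id,
              format(x$temperature), x$k, unit, x$r_squared, x$n_points))
  invisible(x)
}

#' Select the best-fitting reaction order by R-squared
#'
#' Fits the zero-, first- and second-order linearised models and returns the
#' fit with the highest transformed-scale R-squared, the procedure used
#' throughout the food-stability kinetics literature. Orders whose transform
#' is infeasible for the data (log or reciprocal of non-positive values) are
#' excluded and recorded. Near-ties (difference < 1e-9) are broken toward
#' the lower order, favouring parsimony.
#'
#' Comparing R-squared across different response transforms is statistically
#' informal (the residual scales differ); it is retained here deliberately
#' because it is the field's standard model-screening procedure.
#'
#' @param series An [oxidation_series()].
#' @return Object of class `"order_selection"`: `best` (a `"kinetic_fit"`),
#'   `fits` (list of feasible fits, named "0","1","2"), `excluded`
#'   (infeasible orders).
#' @examples
#' d <- c(0, 1, 3, 5, 8, 12, 16, 20, 31)
#' s <- oxidation_series(d, 9e-4 * exp(0.1445 * d))
#' select_order(s)$best$order  # 1
#' @export
select_order <- function(series) {
  stopifnot(inherits(series, "oxidation_series"))
  feasible <- 0:2
  if (any(series$values <= 0)) feasible <- 0L
  fits <- lapply(feasible, function(n) fit_order(series, n))
  names(fits) <- as.character(feasible)
  if (!length(fits)) stop("no feasible reaction order for this series")
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  best <- fits[[which(r2 > max(r2) - 1e-9)[1L]]]  # fits ordered by ascending n
  structure(list(best = best, fits = fits,
                 excluded = setdiff(0:2, feasible)),
            class = "order_selection")
}

#' @export
print.order_selection <- function(x, ...) {
  r2 <- vapply(x$fits, `[[`, numeric(1), "r_squared")
  cat("Reaction-order selection (", x$best$sample_id, "):\n", sep = "")
  for (nm in names(x$fits))
    cat(sprintf("  order %s: R^2 = %.4f%s\n", nm, r2[[nm]],
                if (x$best$order == as.integer(nm)) "  <- selected" else ""))
  if (length(x$excluded))
    cat("  excluded (infeasible transform): order",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Read a tidy oxidation-index CSV
#'
#' Expects one row per sample x temperature x day with columns `sample_id`,
#' `temperature_K`, `day` and the index column (default `pv`). This is the
#' schema written by [generate_trial()] and consumed by [aslt()] and
#' [run_analysis()].
#'
#' @param path CSV file path.
#' @param index Name of the index column that must be present.
#' @return data.frame.
#' @export
read_oxidation_csv <- function(path, index = "pv") {
  if (!file.exists(path)) stop("input file not found: ", path)
  dat <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "temperature_K", "day", index)
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop("input '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(dat)) stop("input '", path, "' contains no data rows")
  bad <- which(!is.finite(dat[[index]]) | !is.finite(dat$day))
  if (length(bad))
    stop("non-numeric or missing values in '", path, "' at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  dat
}
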