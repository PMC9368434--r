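#' Fit an accelerated shelf-life testing model
#'
#' The full ASLT analysis on a tidy storage-trial dataset: for every
#' formulation, (i) fit zero-, first- and second-order linearised kinetic
#' models at each storage temperature and select the reaction order by
#' R-squared, (ii) fit the Arrhenius law to the per-temperature rate
#' constants of the consensus order, (iii) derive the activation energy,
#' Q10 and rate constants at the market temperatures, (iv) predict the
#' shelf-life as the time for the index to reach its quality limit, and
#' (v) compute Eyring-type activation thermodynamics (dG, dH, dS) at each
#' storage temperature.
#'
#' The consensus reaction order per formulation is the order selected at
#' the largest number of temperatures (ties toward the lower order), unless
#' `order` fixes it. Shelf-life uses the first-order closed form and is
#' reported as `NA` for formulations whose consensus order is not 1.
#'
#' @param data data.frame with columns `sample_id`, `temperature_K`, `day`
#'   and the index column (see `index`), e.g. from [read_oxidation_csv()]
#'   or [generate_trial()].
#' @param index Name of the index column. Default `"pv"` (peroxide value,
#'   meq O2/kg oil).
#' @param a0 Initial index value(s) for shelf-life: a single number, or a
#'   named vector/list by sample. Default: the mean observed day-0 value per
#'   sample. Deliberately never taken from regression intercepts.
#' @param a_limit Quality limit for shelf-life (same unit as the index),
#'   default 10 (meq O2/kg for PV).
#' @param order Fix the reaction order (0, 1 or 2) instead of selecting it.
#' @param constants A [physical_constants()] object.
#' @param kelvin_mode `"exact"` (default) or `"integer"`; see
#'   [effective_kelvin()].
#' @param market_temperatures Temperatures (K) at which to report predicted
#'   rate constants and shelf-life. Default c(293.15, 298.15).
#' @param q10_temperatures The Q10 comparison pair (K),
#'   default c(303.15, 313.15).
#' @param age_at_test_months,days_per_month Passed to [shelf_life_spec()].
#' @param time_unit Time unit for k in the Eyring formula, see
#'   [gibbs_free_energy()].
#'
#' @return Object of class `"aslt"` with components
#'   `orders` (R-squared by order and temperature), `rates`
#'   (per-temperature kinetic fits at the consensus order), `arrhenius`
#'   (per-sample Arrhenius parameters, Ea, market-temperature k, Q10),
#'   `shelf` (days and total months per sample x market temperature),
#'   `thermo` (per-sample `"thermo_summary"` objects and a tidy table),
#'   `failures` (samples that could not be fitted, with messages),
#'   `settings`, `data` and `call`. Methods: [print.aslt()],
#'   [summary.aslt()], [coef.aslt()], [predict.aslt()], [plot.aslt()],
#'   [residuals.aslt()].
#'
#' @examples
#' trial <- generate_trial(trial_design(noise_sigma = 0, seed = 1))
#' fit <- aslt(trial)
#' fit
#' coef(fit)
#' predict(fit, temperature = 293.15)
#' @export
aslt <- function(data, index = "pv", a0 = NULL, a_limit = 10, order = NULL,
                 constants = physical_constants(),
                 kelvin_mode = c("exact", "integer"),
                 market_temperatures = c(293.15, 298.15),
                 q10_temperatures = c(303.15, 313.15),
                 age_at_test_months = 5, days_per_month = 30,
                 time_unit = c("day", "second")) {
  kelvin_mode <- match.arg(kelvin_mode)
  time_unit <- match.arg(time_unit)
  constants <- .check_constants(constants)
  need <- c("sample_id", "temperature_K", "day", index)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("'data' lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(data)) stop("'data' contains no rows")
  if (!is.null(order) && !order %in% 0:2) stop("'order' must be 0, 1 or 2")

  samples <- unique(data$sample_id)
  orders_rows <- list(); rates_rows <- list(); arr_rows <- list()
  shelf_rows <- list(); thermo_objs <- list(); thermo_rows <- list()
  failures <- list()

  for (s in samples) {
    res <- tryCatch(
      .aslt_one(data[data$sample_id == s, , drop = FALSE], s, index, a0,
                a_limit, fixed_order = order, constants, kelvin_mode,
                market_temperatures,
                q10_temperatures, age_at_test_months, days_per_month,
                time_unit),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[s]] <- conditionMessage(res)
      next
    }
    orders_rows[[s]] <- res$orders
    rates_rows[[s]] <- res$rates
    arr_rows[[s]] <- res$arrhenius
    shelf_rows[[s]] <- res$shelf
    thermo_objs[[s]] <- res$thermo
    thermo_rows[[s]] <- cbind(sample_id = s, res$thermo$records)
  }
  if (!length(arr_rows))
    stop("no sample could be fitted",
         if (length(failures)) paste0(": ",
           paste(sprintf("%s (%s)", names(failures), unlist(failures)),
                 collapse = "; ")))

  structure(list(orders = do.call(rbind, c(orders_rows,
                                           make.row.names = FALSE)),
                 rates = do.call(rbind, c(rates_rows,
                                          make.row.names = FALSE)),
                 arrhenius = do.call(rbind, c(arr_rows,
                                              make.row.names = FALSE)),
                 shelf = do.call(rbind, c(shelf_rows,
                                          make.row.names = FALSE)),
                 thermo = thermo_objs,
                 thermo_table = do.call(rbind, c(thermo_rows,
                                                 make.row.names = FALSE)),
                 failures = failures,
                 settings = list(index = index, a_limit = a_limit,
                                 kelvin_mode = kelvin_mode,
                                 constants = constants,
                                 market_temperatures = market_temperatures,
                                 q10_temperatures = q10_temperatures,
                                 age_at_test_months = age_at_test_months,
                                 days_per_month = days_per_month,
                                 time_unit = time_unit,
                                 fixed_order = order),
                 data = data,
                 call = match.call()),
            class = "aslt")
}

# one formulation: kinetics at each temperature -> consensus order ->
# Arrhenius -> Q10 / shelf-life / thermodynamics
.aslt_one <- function(dat, sample, index, a0, a_limit, fixed_order, constants,
                      kelvin_mode, market_temperatures, q10_temperatures,
                      age_at_test_months, days_per_month, time_unit) {
  temps <- sort(unique(dat$temperature_K))
  series <- lapply(temps, function(temp) {
    rows <- dat[dat$temperature_K == temp, , drop = FALSE]
    rows <- rows[order(rows$day), , drop = FALSE]
    oxidation_series(rows$day, rows[[index]], sample_id = sample,
                     temperature = temp)
  })

  selections <- lapply(series, select_order)
  orders_tab <- data.frame(
    sample_id = sample, temperature_K = temps,
    r2_order0 = vapply(selections, function(x)
      if ("0" %in% names(x$fits)) x$fits[["0"]]$r_squared else NA_real_,
      numeric(1)),
    r2_order1 = vapply(selections, function(x)
      if ("1" %in% names(x$fits)) x$fits[["1"]]$r_squared else NA_real_,
      numeric(1)),
    r2_order2 = vapply(selections, function(x)
      if ("2" %in% names(x$fits)) x$fits[["2"]]$r_squared else NA_real_,
      numeric(1)),
    best_order = vapply(selections, function(x) x$best$order, integer(1)),
    stringsAsFactors = FALSE)

  if (is.null(fixed_order)) {
    tab <- table(factor(orders_tab$best_order, levels = 0:2))
    consensus <- as.integer(names(tab)[which.max(tab)])  # ties -> lower order
  } else consensus <- as.integer(fixed_order)

  fits <- lapply(series, fit_order, order = consensus)
  rates_tab <- data.frame(
    sample_id = sample, temperature_K = temps, order = consensus,
    k = vapply(fits, `[[`, numeric(1), "k"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    n_points = vapply(fits, `[[`, numeric(1), "n_points"),
    stringsAsFactors = FALSE)

  arr <- fit_arrhenius(temps, rates_tab$k, constants, kelvin_mode)
  k_market <- predict_k(arr, market_temperatures)
  q10_val <- q10(arr$ea, q10_temperatures[1], q10_temperatures[2],
                 constants, kelvin_mode)

  a0_s <- .resolve_a0(a0, sample, dat, index)
  if (consensus == 1L && is.finite(a0_s) && a0_s < a_limit) {
    sl_spec <- shelf_life_spec(a0_s, a_limit, age_at_test_months,
                               days_per_month)
    days <- shelf_life_days(sl_spec, k_market)
    months <- total_shelf_life_months(days, sl_spec)
  } else {
    days <- rep(NA_real_, length(market_temperatures))
    months <- days
  }
  shelf_tab <- data.frame(sample_id = sample,
                          temperature_K = market_temperatures,
                          k = k_market, a0 = a0_s, days = days,
                          total_months = months, stringsAsFactors = FALSE)

  arr_tab <- data.frame(sample_id = sample, order = consensus,
                        slope = arr$slope, intercept = arr$intercept,
                        ea_kJ_mol = arr$ea / 1000,
                        r_squared = arr$r_squared, q10 = q10_val,
                        stringsAsFactors = FALSE)
  for (i in seq_along(market_temperatures))
    arr_tab[[sprintf("k_%g", market_temperatures[i])]] <- k_market[i]

  thermo <- thermo_table(temps, rates_tab$k, arr$ea, constants,
                         kelvin_mode, time_unit)

  list(orders = orders_tab, rates = rates_tab, arrhenius = arr_tab,
       shelf = shelf_tab, thermo = thermo)
}

.resolve_a0 <- function(a0, sample, dat, index) {
  if (is.null(a0)) {
    day0 <- dat[[index]][dat$day == min(dat$day)]
    return(mean(day0))
  }
  if (length(a0) == 1L && is.null(names(a0))) return(as.numeric(a0))
  if (!sample %in% names(a0))
    stop("no 'a0' supplied for sample ", sample)
  as.numeric(a0[[sample]])
}

#' @export
print.aslt <- function(x, ...) {
  cat("Accelerated shelf-life model (", nrow(x$arrhenius), " formulation(s), ",
      length(unique(x$rates$temperature_K)), " storage temperatures)\n",
      sep = "")
  cat("  index:", x$settings$index,
      "| kelvin_mode:", x$settings$kelvin_mode,
      "| quality limit:", x$settings$a_limit, "\n")
  tab <- x$arrhenius[c("sample_id", "order", "ea_kJ_mol", "q10", "r_squared")]
  tab[-(1:2)] <- round(tab[-(1:2)], 4)
  print(tab, row.names = FALSE)
  if (length(x$failures))
    cat("  failed samples:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Summarise an ASLT model
#'
#' @param object An `"aslt"` fit.
#' @param ... Unused.
#' @return Object of class `"summary.aslt"` bundling the order-selection,
#'   rate, Arrhenius, shelf-life and thermodynamic tables.
#' @export
summary.aslt <- function(object, ...) {
  structure(list(orders = object$orders, rates = object$rates,
                 arrhenius = object$arrhenius, shelf = object$shelf,
                 thermo_table = object$thermo_table,
                 thermo = object$thermo,
                 settings = object$settings, failures = object$failures),
            class = "summary.aslt")
}

#' @export
print.summary.aslt <- function(x, digits = 4, ...) {
  rnd <- function(df) { df[] <- lapply(df, function(col)
    if (is.numeric(col)) round(col, digits) else col); df }
  cat("== Reaction-order selection (R^2 by order) ==\n")
  print(rnd(x$orders), row.names = FALSE)
  cat("\n== Per-temperature kinetic fits ==\n")
  print(rnd(x$rates), row.names = FALSE)
  cat("\n== Arrhenius / Q10 / market-temperature rate constants ==\n")
  print(rnd(x$arrhenius), row.names = FALSE)
  cat("\n== Shelf-life predictions ==\n")
  print(rnd(x$shelf), row.names = FALSE)
  cat("\n== Activation thermodynamics ==\n")
  print(rnd(x$thermo_table), row.names = FALSE)
  ds <- data.frame(sample_id = names(x$thermo),
                   mean_delta_s = round(vapply(x$thermo, `[[`, numeric(1),
                                               "mean_delta_s"), digits),
                   sd_delta_s = round(vapply(x$thermo, `[[`, numeric(1),
                                             "sd_delta_s"), digits))
  print(ds, row.names = FALSE)
  invisible(x)
}

#' @export
coef.aslt <- function(object, ...) {
  m <- as.matrix(object$arrhenius[c("slope", "intercept", "ea_kJ_mol")])
  rownames(m) <- object$arrhenius$sample_id
  cbind(m, k0 = exp(m[, "intercept"]))
}

#' Predict rate constants or shelf-life at new temperatures
#'
#' @param object An `"aslt"` fit.
#' @param temperature Temperature(s) in K.
#' @param type `"rate"` (k in 1/day), `"shelf_life_days"` or
#'   `"shelf_life_months"` (first-order formulations only).
#' @param ... Unused.
#' @return data.frame with one row per sample x temperature.
#' @export
predict.aslt <- function(object, temperature,
                         type = c("rate", "shelf_life_days",
                                  "shelf_life_months"), ...) {
  type <- match.arg(type)
  st <- object$settings
  out <- lapply(seq_len(nrow(object$arrhenius)), function(i) {
    row <- object$arrhenius[i, ]
    fit <- arrhenius_line(row$slope, row$intercept, st$constants,
                          st$kelvin_mode)
    k <- predict_k(fit, temperature)
    val <- k
    if (type != "rate") {
      a0_s <- object$shelf$a0[match(row$sample_id, object$shelf$sample_id)]
      if (row$order == 1L && is.finite(a0_s) && a0_s < st$a_limit) {
        sp <- shelf_life_spec(a0_s, st$a_limit, st$age_at_test_months,
                              st$days_per_month)
        val <- shelf_life_days(sp, k)
        if (type == "shelf_life_months")
          val <- total_shelf_life_months(val, sp)
      } else val <- rep(NA_real_, length(k))
    }
    data.frame(sample_id = row$sample_id, temperature_K = temperature,
               value = val, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  names(res)[names(res) == "value"] <- switch(type, rate = "k",
                                              shelf_life_days = "days",
                                              shelf_life_months = "months")
  res
}

#' Residuals of the Arrhenius stage
#'
#' Per sample x storage temperature residuals of ln k around the fitted
#' Arrhenius line.
#'
#' @param object An `"aslt"` fit.
#' @param ... Unused.
#' @return data.frame: `sample_id`, `temperature_K`, `residual` (ln k scale).
#' @export
residuals.aslt <- function(object, ...) {
  st <- object$settings
  do.call(rbind, lapply(seq_len(nrow(object$arrhenius)), function(i) {
    row <- object$arrhenius[i, ]
    rk <- object$rates[object$rates$sample_id == row$sample_id, ]
    t_eff <- effective_kelvin(rk$temperature_K, st$kelvin_mode)
    data.frame(sample_id = row$sample_id,
               temperature_K = rk$temperature_K,
               residual = log(rk$k) - (row$intercept + row$slope / t_eff),
               stringsAsFactors = FALSE)
  }))
}

#' Diagnostic plots for an ASLT model
#'
#' `which = "arrhenius"` draws ln k against 1/T with the fitted lines, one
#' colour per formulation; `which = "kinetics"` draws the linearised index
#' (log scale for order 1) against storage day for every temperature of one
#' sample, with the fitted lines.
#'
#' @param x An `"aslt"` fit.
#' @param which `"arrhenius"` or `"kinetics"`.
#' @param sample Sample to show for `which = "kinetics"` (default: first).
#' @param ... Passed to the underlying plot call.
#' @return Invisibly, `x`.
#' @export
plot.aslt <- function(x, which = c("arrhenius", "kinetics"),
                      sample = NULL, ...) {
  which <- match.arg(which)
  st <- x$settings
  if (which == "arrhenius") {
    inv_t <- 1 / effective_kelvin(x$rates$temperature_K, st$kelvin_mode)
    plot(inv_t, log(x$rates$k), pch = 19,
         col = factor(x$rates$sample_id),
         xlab = "1/T (1/K)", ylab = "ln k", main = "Arrhenius plot", ...)
    for (i in seq_len(nrow(x$arrhenius)))
      abline(x$arrhenius$intercept[i], x$arrhenius$slope[i],
             col = i, lty = 2)
    legend("topright", legend = x$arrhenius$sample_id,
           col = seq_len(nrow(x$arrhenius)), pch = 19, cex = 0.8)
  } else {
    if (is.null(sample)) sample <- x$arrhenius$sample_id[1L]
    dat <- x$data[x$data$sample_id == sample, ]
    ord <- x$arrhenius$order[x$arrhenius$sample_id == sample]
    y <- switch(as.character(ord), "0" = dat[[st$index]],
                "1" = log(dat[[st$index]]), "2" = 1 / dat[[st$index]])
    plot(dat$day, y, pch = 19, col = factor(dat$temperature_K),
         xlab = "storage day",
         ylab = c("index", "ln index", "1/index")[ord + 1L],
         main = paste0(sample, " (order ", ord, ")"), ...)
    rk <- x$rates[x$rates$sample_id == sample, ]
    for (i in seq_len(nrow(rk))) {
      sl <- if (ord == 2L) -rk$k[i] else rk$k[i]
      abline(rk$intercept[i], sl, col = i, lty = 2)
    }
    legend("topleft", legend = paste(rk$temperature_K, "K"),
           col = seq_len(nrow(rk)), pch = 19, cex = 0.8)
  }
  invisible(x)
}
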