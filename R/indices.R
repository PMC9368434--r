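#' Fit a hydroperoxide calibration curve
#'
#' Ordinary least-squares line through blank-corrected absorbances at 510 nm
#' versus hydroperoxide standard concentrations (typically a cumene
#' hydroperoxide series, 0-0.4 mM). The fitted line is used by
#' [peroxide_value()] to back-calculate hydroperoxide concentrations in
#' sample extracts.
#'
#' @param concentrations Standard concentrations (mM), at least 3 distinct
#'   non-negative values.
#' @param absorbances Blank-corrected absorbance at 510 nm, one per standard.
#'
#' @return An object of class `"calibration_curve"`: list with
#'   `concentrations`, `absorbances`, `slope` (A510 per mM), `intercept`
#'   and `r_squared`.
#'
#' @examples
#' fit_calibration(c(0, 0.2, 0.4), c(0, 0.5, 1.0))
#' @export
fit_calibration <- function(concentrations, absorbances) {
  if (length(concentrations) != length(absorbances))
    stop("'concentrations' and 'absorbances' must have the same length")
  if (length(concentrations) < 3L)
    stop("a calibration curve needs at least 3 points")
  if (any(!is.finite(concentrations)) || any(!is.finite(absorbances)))
    stop("calibration points must be finite")
  if (any(concentrations < 0))
    stop("standard concentrations must be non-negative")
  if (length(unique(concentrations)) < 3L)
    stop("at least 3 distinct concentrations are required (zero variance ",
         "or repeated-standard designs cannot identify a line)")
  ord <- order(concentrations)
  concentrations <- concentrations[ord]
  absorbances <- absorbances[ord]
  fit <- lm(absorbances ~ concentrations)
  cf <- coef(fit)
  structure(list(concentrations = concentrations,
                 absorbances = absorbances,
                 slope = unname(cf[2L]),
                 intercept = unname(cf[1L]),
                 r_squared = .ols_r2(concentrations, absorbances)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Hydroperoxide calibration curve (", length(x$concentrations),
      " standards)\n", sep = "")
  cat(sprintf("  A510 = %.5g x conc(mM) + %.5g,  R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Peroxide value from a spectrophotometric hydroperoxide assay
#'
#' Converts a ferric-thiocyanate absorbance reading (A510) into a peroxide
#' value in milliequivalents of active oxygen per kg of oil, using a fitted
#' hydroperoxide calibration curve and an explicit dimensional chain:
#' the back-calculated concentration (mM) refers to the assayed aliquot of
#' the solvent extract; the amount in the aliquot is scaled to the whole
#' extract by `extract_volume / aliquot_volume`, and 1 umol hydroperoxide is
#' taken as 1 ueq active oxygen. The oil mass is `sample_mass * fat_fraction`.
#'
#' @param absorbance_sample,absorbance_blank Absorbance at 510 nm of the
#'   sample and reagent blank. A sample reading below the blank triggers a
#'   warning (expected only for essentially unoxidised samples).
#' @param curve A `"calibration_curve"` from [fit_calibration()]; its slope
#'   must be positive.
#' @param sample_mass Mass of product extracted (g).
#' @param extract_volume Total volume of extraction solvent (mL).
#'   Default 1.5 mL.
#' @param aliquot_volume Volume of extract carried into the assay (mL).
#'   Default 0.2 mL.
#' @param fat_fraction Fat content of the product (g fat per g sample),
#'   in (0, 1]. Default 1 (pure oil).
#'
#' @return Peroxide value, meq O2 per kg oil. A back-calculated negative
#'   concentration (blank exceeding a weak sample) is clamped to zero with
#'   a warning.
#'
#' @examples
#' cal <- fit_calibration(c(0, 0.2, 0.4), c(0, 0.5, 1.0))
#' peroxide_value(0.25, 0, cal, sample_mass = 0.3, fat_fraction = 0.36)
#' @export
peroxide_value <- function(absorbance_sample, absorbance_blank, curve,
                           sample_mass, extract_volume = 1.5,
                           aliquot_volume = 0.2, fat_fraction = 1) {
  if (!inherits(curve, "calibration_curve"))
    stop("'curve' must be a calibration_curve from fit_calibration()")
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("calibration slope must be positive")
  if (!is.finite(sample_mass) || sample_mass <= 0)
    stop("'sample_mass' must be positive")
  if (!is.finite(extract_volume) || extract_volume <= 0 ||
      !is.finite(aliquot_volume) || aliquot_volume <= 0)
    stop("extract and aliquot volumes must be positive")
  if (!is.finite(fat_fraction) || fat_fraction <= 0 || fat_fraction > 1)
    stop("'fat_fraction' must be in (0, 1]")
  if (absorbance_sample < absorbance_blank)
    warning("sample absorbance below blank; concentration will be clamped to 0")
  conc <- (absorbance_sample - absorbance_blank - curve$intercept) / curve$slope
  if (conc < 0) {
    # warn only for genuinely negative concentrations, not rounding dust
    if (conc < -1e-10 && absorbance_sample >= absorbance_blank)
      warning("negative back-calculated concentration clamped to 0")
    conc <- 0
  }
  # mM x mL = umol; aliquot amount scaled to whole extract; 1 umol == 1 ueq O2
  ueq_total <- conc * aliquot_volume * (extract_volume / aliquot_volume)
  meq_total <- ueq_total * 1e-3
  kg_oil <- sample_mass * fat_fraction * 1e-3
  meq_total / kg_oil
}

#' Para-anisidine value
#'
#' Index of secondary oxidation products (aldehydes) from the absorbance at
#' 350 nm of a fat extract before and after reaction with para-anisidine.
#' The default follows the AOCS Cd 18-90 convention,
#' `25 * (1.2 * A_after - A_before) / m`, which is non-negative for any
#' sample whose absorbance increases on reaction. `mode = "verbatim"`
#' instead evaluates `25 * 1.2 * (A_before - A_after) / m`, a form that
#' appears in some published method sections but yields negative values for
#' oxidising samples; it is provided for auditability only and the mode used
#' is recorded as an attribute of the result.
#'
#' @param a_before Absorbance of the extract before reaction.
#' @param a_after Absorbance after reaction with the p-anisidine reagent.
#' @param mass Sample mass (g), > 0.
#' @param mode `"aocs"` (default) or `"verbatim"`.
#'
#' @return The p-anisidine value (unitless), with attribute `"mode"`.
#' @examples
#' p_anisidine_value(0.1, 0.2, 1)                     # 3.5
#' p_anisidine_value(0.1, 0.2, 1, mode = "verbatim")  # -3.0
#' @export
p_anisidine_value <- function(a_before, a_after, mass,
                              mode = c("aocs", "verbatim")) {
  mode <- match.arg(mode)
  if (!is.finite(mass) || mass <= 0) stop("'mass' must be positive")
  if (any(!is.finite(c(a_before, a_after))) || a_before < 0 || a_after < 0)
    stop("absorbances must be finite and non-negative")
  val <- if (mode == "aocs") 25 * (1.2 * a_after - a_before) / mass
         else 25 * 1.2 * (a_before - a_after) / mass
  attr(val, "mode") <- mode
  val
}

#' TOTOX combined oxidation index
#'
#' `TOTOX = 2 * PV + p-AnV`, weighting primary (hydroperoxide) against
#' secondary (aldehyde) oxidation products.
#'
#' @param pv Peroxide value (meq O2/kg oil).
#' @param p_anv Para-anisidine value.
#' @return TOTOX value (unitless scale).
#' @examples totox(1.5, 3)  # 6
#' @export
totox <- function(pv, p_anv) {
  if (any(!is.finite(pv)) || any(!is.finite(p_anv)))
    stop("'pv' and 'p_anv' must be finite")
  2 * pv + p_anv
}

#' Moisture content by oven drying
#'
#' Percent mass lost on drying to constant weight:
#' `100 * (fresh - dried) / fresh`.
#'
#' @param fresh_weight Fresh sample weight (g), > 0.
#' @param dried_weight Weight after drying (g), in (0, fresh_weight].
#' @return Moisture, percent of fresh weight.
#' @examples moisture_fraction(5, 4.9)  # 2
#' @export
moisture_fraction <- function(fresh_weight, dried_weight) {
  if (!is.finite(fresh_weight) || fresh_weight <= 0)
    stop("'fresh_weight' must be positive")
  if (!is.finite(dried_weight) || dried_weight <= 0)
    stop("'dried_weight' must be positive (a fully volatilised sample ",
         "indicates an assay failure, not 100% moisture)")
  if (dried_weight > fresh_weight)
    stop("'dried_weight' cannot exceed 'fresh_weight'")
  100 * (fresh_weight - dried_weight) / fresh_weight
}

#' Compute oxidation indices from a table of raw assays
#'
#' Turns a tidy table of raw spectrophotometric assays (one row per assay,
#' as read with `read.csv`) into an index table with one row per
#' sample x temperature x day carrying `pv`, `p_anv` and, where both are
#' present, `totox`. Peroxide assays (`assay_type == "pv"`) need columns
#' `absorbance_sample`, `absorbance_blank`, `sample_mass` and optionally
#' `extract_volume`, `aliquot_volume`, `fat_fraction`; anisidine assays
#' (`assay_type == "panv"`) need `a_before`, `a_after`, `mass`.
#'
#' @param assays data.frame with columns `sample_id`, `temperature_K`,
#'   `day`, `assay_type` plus the per-assay fields above.
#' @param curve Calibration curve for the peroxide assays.
#' @param anisidine_mode Passed to [p_anisidine_value()].
#' @return data.frame: `sample_id`, `temperature_K`, `day`, `pv`, `p_anv`,
#'   `totox`.
#' @export
indices_from_assays <- function(assays, curve,
                                anisidine_mode = c("aocs", "verbatim")) {
  anisidine_mode <- match.arg(anisidine_mode)
  need <- c("sample_id", "temperature_K", "day", "assay_type")
  missing_cols <- setdiff(need, names(assays))
  if (length(missing_cols))
    stop("assay table lacks column(s): ", paste(missing_cols, collapse = ", "))
  key <- c("sample_id", "temperature_K", "day")
  pv_rows <- assays[assays$assay_type == "pv", , drop = FALSE]
  an_rows <- assays[assays$assay_type == "panv", , drop = FALSE]
  pv_tab <- NULL
  if (nrow(pv_rows)) {
    ev <- if ("extract_volume" %in% names(pv_rows)) pv_rows$extract_volume else 1.5
    av <- if ("aliquot_volume" %in% names(pv_rows)) pv_rows$aliquot_volume else 0.2
    ff <- if ("fat_fraction" %in% names(pv_rows)) pv_rows$fat_fraction else 1
    ev <- rep_len(ev, nrow(pv_rows)); av <- rep_len(av, nrow(pv_rows))
    ff <- rep_len(ff, nrow(pv_rows))
    pv_tab <- cbind(pv_rows[key],
                    pv = vapply(seq_len(nrow(pv_rows)), function(i)
                      peroxide_value(pv_rows$absorbance_sample[i],
                                     pv_rows$absorbance_blank[i], curve,
                                     pv_rows$sample_mass[i], ev[i], av[i],
                                     ff[i]), numeric(1)))
  }
  an_tab <- NULL
  if (nrow(an_rows)) {
    an_tab <- cbind(an_rows[key],
                    p_anv = vapply(seq_len(nrow(an_rows)), function(i)
                      as.numeric(p_anisidine_value(an_rows$a_before[i],
                                                   an_rows$a_after[i],
                                                   an_rows$mass[i],
                                                   anisidine_mode)),
                      numeric(1)))
  }
  out <- if (is.null(pv_tab)) an_tab
         else if (is.null(an_tab)) pv_tab
         else merge(pv_tab, an_tab, by = key, all = TRUE)
  if (is.null(out)) stop("no recognised assay rows ('pv' or 'panv')")
  if (!"pv" %in% names(out)) out$pv <- NA_real_
  if (!"p_anv" %in% names(out)) out$p_anv <- NA_real_
  out$totox <- ifelse(is.finite(out$pv) & is.finite(out$p_anv),
                      2 * out$pv + out$p_anv, NA_real_)
  attr(out, "anisidine_mode") <- anisidine_mode
  out[order(out$sample_id, out$temperature_K, out$day), , drop = FALSE]
}
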