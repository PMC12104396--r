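# Fluorescent-standard calibration and assay-window QC.

#' Standard stock and working-solution arithmetic
#'
#' The kit's fluorescent standard (0.1 umol) is reconstituted in DMSO to a
#' 100 uM stock, then diluted into reaction buffer to the working standard
#' used for the plate's calibration column.
#'
#' @param standard_nmol Amount of fluorescent standard reconstituted (nmol).
#' @param reconstitution_ml Reconstitution volume (mL).
#' @param aliquot_ul Stock aliquot taken into buffer (uL).
#' @param final_ul Final working-solution volume (uL).
#' @return List with `stock_uM` and `working_nM`.
#' @examples
#' prepare_standard_stocks()  # 100 uM stock, 500 nM working standard
#' @export
prepare_standard_stocks <- function(standard_nmol = 100,
                                    reconstitution_ml = 1,
                                    aliquot_ul = 5, final_ul = 1000) {
  if (any(c(standard_nmol, reconstitution_ml, aliquot_ul, final_ul) <= 0)) {
    stop("amounts and volumes must be > 0", call. = FALSE)
  }
  if (aliquot_ul > final_ul) {
    stop("aliquot volume cannot exceed final volume", call. = FALSE)
  }
  stock_uM <- standard_nmol / reconstitution_ml / 1000 * 1000  # nmol/mL = uM
  working_nM <- stock_uM * 1000 * aliquot_ul / final_ul
  list(stock_uM = stock_uM, working_nM = working_nM)
}

#' Fit a linear fluorescent-standard curve
#'
#' Ordinary least-squares line through the serial-dilution standard wells,
#' RFU as a function of fluorophore concentration (nM). Blank wells enter as
#' concentration-0 points, so the intercept is the background estimate.
#'
#' @param conc_nM Standard concentrations (nM), blanks at 0.
#' @param rfu Measured fluorescence.
#' @return Object of class `standard_curve`: `slope` (RFU/nM), `intercept`
#'   (RFU), `r_squared`, `n_points`, `points` (aggregated means per level).
#' @export
fit_standard_curve <- function(conc_nM, rfu) {
  if (length(conc_nM) != length(rfu)) {
    stop("conc_nM and rfu must have equal length", call. = FALSE)
  }
  ok <- is.finite(conc_nM) & is.finite(rfu)
  conc_nM <- conc_nM[ok]; rfu <- rfu[ok]
  if (length(unique(conc_nM)) < 3) {
    stop("standard curve needs >= 3 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(rfu ~ conc_nM)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((rfu - mean(rfu))^2)
  pts <- stats::aggregate(list(mean_rfu = rfu), list(conc_nM = conc_nM), mean)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = length(rfu),
                 points = pts[order(-pts$conc_nM), ]),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Fluorescent standard curve: RFU = %.4g + %.4g * [nM]  (R^2 = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Convert fluorescence to fluorophore concentration via a standard curve
#'
#' @param curve A `standard_curve`.
#' @param rfu Fluorescence value(s).
#' @return Concentration in nM.
#' @export
rfu_to_nM <- function(curve, rfu) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("standard curve slope is not positive; cannot invert", call. = FALSE)
  }
  (rfu - curve$intercept) / curve$slope
}

#' Fit the standard curve from a plate's calibration column
#'
#' Pulls `role = "standard"` wells (nM) and `role = "blank"` wells
#' (concentration 0) from a plate readout and fits [fit_standard_curve()].
#'
#' @param wells A `well_table` for one plate.
#' @return A `standard_curve`.
#' @export
plate_standard_curve <- function(wells) {
  std <- wells[wells$role == "standard", , drop = FALSE]
  blk <- wells[wells$role == "blank", , drop = FALSE]
  if (nrow(std) == 0) stop("no standard wells on plate", call. = FALSE)
  if (any(std$conc_unit != "nM")) {
    std$conc_value <- to_uM(std$conc_value, std$conc_unit) * 1000
  }
  fit_standard_curve(c(std$conc_value, rep(0, nrow(blk))),
                     c(std$rfu, blk$rfu))
}

#' Assay-window quality control
#'
#' Screening QC for the mix-and-read format: reports the signal window
#' between the solvent control (A) and positive-inhibitor control (B), the
#' background fraction, and a Z'-style window statistic when control SDs are
#' available. Flags, never errors: degenerate plates are reported, and the
#' decision to proceed is the caller's.
#'
#' @param a_rfu Solvent-control mean RFU.
#' @param b_rfu Positive-control mean RFU.
#' @param blank_rfu Blank (buffer-only) mean RFU; optional.
#' @param a_sd,b_sd Control SDs; optional, enable the Z' statistic.
#' @return List with `window`, `background_fraction`, `z_prime` (NA without
#'   SDs), and `status` in `"ok"`, `"degenerate"`, `"inverted"`.
#' @export
assay_window_qc <- function(a_rfu, b_rfu, blank_rfu = NA_real_,
                            a_sd = NA_real_, b_sd = NA_real_) {
  window <- a_rfu - b_rfu
  status <- if (window == 0) "degenerate" else if (window < 0) "inverted" else "ok"
  zp <- if (is.finite(a_sd) && is.finite(b_sd) && window != 0) {
    1 - 3 * (a_sd + b_sd) / abs(window)
  } else NA_real_
  bg <- if (is.finite(blank_rfu) && a_rfu > 0) blank_rfu / a_rfu else NA_real_
  list(window = window, background_fraction = bg, z_prime = zp,
       status = status)
}
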