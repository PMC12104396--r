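# In-vitro-to-in-vivo extrapolation: unbound corrections, Cheng-Prusoff
# inhibition constants, and the basic static-model DDI risk call.

#' Unbound IC50
#'
#' Corrects a total IC50 for nonspecific binding in the incubation:
#' IC50,u = IC50 / fu,inc. The default fu,inc of 0.02 is the regulatory
#' assumption for highly protein-bound drugs.
#'
#' @param ic50 Total IC50 (uM), > 0.
#' @param fu_inc Fraction unbound in the incubation system, in (0, 1].
#' @return Unbound IC50 (uM).
#' @examples
#' unbound_ic50(1.41)  # 70.5
#' @export
unbound_ic50 <- function(ic50, fu_inc = 0.02) {
  if (any(!is.finite(ic50) | ic50 <= 0)) stop("ic50 must be > 0",
                                              call. = FALSE)
  if (any(!is.finite(fu_inc) | fu_inc <= 0 | fu_inc > 1)) {
    stop("fu_inc must be in (0, 1]", call. = FALSE)
  }
  ic50 / fu_inc
}

#' Cheng-Prusoff unbound inhibition constant
#'
#' For competitive inhibition, Ki,u = IC50,u / (1 + S/Km), where S is the
#' substrate concentration in the assay and Km its Michaelis constant.
#'
#' @param ic50_u Unbound IC50 (uM), > 0.
#' @param s Substrate concentration (uM), >= 0.
#' @param km Michaelis constant (uM), > 0.
#' @return Ki,u (uM).
#' @examples
#' ki_u_cheng_prusoff(331, s = 10, km = 10)  # 165.5
#' @export
ki_u_cheng_prusoff <- function(ic50_u, s, km) {
  if (any(!is.finite(ic50_u) | ic50_u <= 0)) stop("ic50_u must be > 0",
                                                  call. = FALSE)
  if (any(!is.finite(s) | s < 0)) stop("s must be >= 0", call. = FALSE)
  if (any(!is.finite(km) | km <= 0)) stop("km must be > 0", call. = FALSE)
  ic50_u / (1 + s / km)
}

#' Regulatory half-IC50 convention for Ki,u
#'
#' The convention Ki,u = IC50,u / 2 used in regulatory screening when
#' substrate-specific kinetics are not resolved. Algebraically it equals the
#' Cheng-Prusoff value at S = Km.
#'
#' @param ic50_u Unbound IC50 (uM), > 0.
#' @return Ki,u (uM).
#' @examples
#' ki_u_regulatory(70.5)  # 35.25
#' @export
ki_u_regulatory <- function(ic50_u) {
  if (any(!is.finite(ic50_u) | ic50_u <= 0)) stop("ic50_u must be > 0",
                                                  call. = FALSE)
  ic50_u / 2
}

#' Unbound peak plasma concentration
#'
#' Cmax,u = Cmax x fu, in ug/mL, with the micromolar equivalent computed from
#' the compound's molecular weight.
#'
#' @param profile A `compound_profile` (one or more rows).
#' @return data.frame with `name`, `cmax_u_ug_per_ml`, `cmax_u_uM`.
#' @export
unbound_cmax <- function(profile) {
  stopifnot(inherits(profile, "compound_profile") || all(
    c("name", "molecular_weight", "cmax_ug_per_ml", "fu_plasma") %in%
      names(profile)))
  ug <- profile$cmax_ug_per_ml * profile$fu_plasma
  data.frame(name = profile$name,
             cmax_u_ug_per_ml = ug,
             cmax_u_uM = mass_conc_to_molar(ug, profile$molecular_weight),
             stringsAsFactors = FALSE)
}

#' Basic static-model interaction ratio and risk flag
#'
#' Computes the Cmax,u/Ki,u ratio and flags the compound as a potential in
#' vivo CYP2C19 inhibitor when the ratio meets or exceeds the regulatory
#' cutoff (default 0.02, inclusive). Both quantities must be in uM;
#' mixed-unit inputs are converted upstream, never divided raw.
#'
#' @param cmax_u_uM Unbound Cmax (uM), >= 0.
#' @param ki_u_uM Unbound inhibition constant (uM), > 0.
#' @param threshold Decision cutoff (default 0.02).
#' @return data.frame with `ratio`, `threshold`, `risk_flag`
#'   (`"potential_inhibitor"` or `"risk_excluded"`).
#' @examples
#' ddi_ratio_and_flag(0.0324, 35.25)
#' @export
ddi_ratio_and_flag <- function(cmax_u_uM, ki_u_uM, threshold = 0.02) {
  if (any(!is.finite(ki_u_uM) | ki_u_uM <= 0)) {
    stop("ki_u_uM must be > 0", call. = FALSE)
  }
  if (any(!is.finite(cmax_u_uM) | cmax_u_uM < 0)) {
    stop("cmax_u_uM must be >= 0", call. = FALSE)
  }
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  ratio <- cmax_u_uM / ki_u_uM
  data.frame(ratio = ratio, threshold = threshold,
             risk_flag = ifelse(ratio >= threshold, "potential_inhibitor",
                                "risk_excluded"),
             stringsAsFactors = FALSE)
}

#' Full DDI assessment for a set of compounds
#'
#' Chains the unbound corrections: IC50 -> IC50,u (via fu,inc) -> Ki,u (via
#' the chosen convention) -> Cmax,u (via fu and molecular weight) -> ratio
#' and risk flag.
#'
#' @param profiles A `compound_profile` data.frame (one row per compound).
#' @param ic50_uM Named numeric vector of total IC50s (uM); names must match
#'   `profiles$name`.
#' @param ki_convention `"regulatory_half"` (Ki,u = IC50,u/2, the default) or
#'   `"cheng_prusoff"` (requires `s` and `km`).
#' @param s,km Substrate concentration and Michaelis constant (uM) for the
#'   Cheng-Prusoff convention.
#' @param threshold Ratio cutoff, default 0.02 (inclusive).
#' @return data.frame of class `ddi_assessment`: `compound`, `ic50_uM`,
#'   `ic50_u_uM`, `ki_u_uM`, `cmax_u_ug_per_ml`, `cmax_u_uM`, `ratio`,
#'   `threshold`, `risk_flag`.
#' @export
ddi_assess <- function(profiles, ic50_uM,
                       ki_convention = c("regulatory_half", "cheng_prusoff"),
                       s = NULL, km = NULL, threshold = 0.02) {
  ki_convention <- match.arg(ki_convention)
  if (is.null(names(ic50_uM))) {
    stop("ic50_uM must be a named vector", call. = FALSE)
  }
  prof <- profiles[match(names(ic50_uM), profiles$name), , drop = FALSE]
  if (anyNA(prof$name)) {
    stop("no profile for compound(s): ",
         paste(setdiff(names(ic50_uM), profiles$name), collapse = ", "),
         call. = FALSE)
  }
  ic50_u <- unbound_ic50(ic50_uM, prof$fu_incubation)
  ki_u <- if (ki_convention == "regulatory_half") {
    ki_u_regulatory(ic50_u)
  } else {
    if (is.null(s) || is.null(km)) {
      stop("cheng_prusoff convention requires s and km", call. = FALSE)
    }
    ki_u_cheng_prusoff(ic50_u, s, km)
  }
  cu <- unbound_cmax(prof)
  rf <- ddi_ratio_and_flag(cu$cmax_u_uM, ki_u, threshold)
  out <- data.frame(compound = prof$name,
                    ic50_uM = unname(ic50_uM),
                    ic50_u_uM = unname(ic50_u),
                    ki_u_uM = unname(ki_u),
                    cmax_u_ug_per_ml = cu$cmax_u_ug_per_ml,
                    cmax_u_uM = cu$cmax_u_uM,
                    ratio = rf$ratio,
                    threshold = rf$threshold,
                    risk_flag = rf$risk_flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ddi_assessment", class(out))
  out
}

#' @export
print.ddi_assessment <- function(x, digits = 3, ...) {
  cat("CYP2C19 DDI assessment (basic static model, cutoff ",
      format(x$threshold[1]), ")\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Rank compounds by inhibitory potency
#'
#' Orders an assessment (or fit) table by ascending IC50, most potent first.
#' Exact IC50 ties are broken alphabetically and flagged.
#'
#' @param x data.frame with columns `compound` and `ic50_uM`.
#' @return The table reordered, with `rank` and logical `tie` columns.
#' @export
rank_by_potency <- function(x) {
  if (!nrow(x)) stop("empty table", call. = FALSE)
  if (anyNA(x$ic50_uM)) stop("all IC50 values must be present", call. = FALSE)
  ord <- order(x$ic50_uM, x$compound)
  out <- x[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tie <- duplicated(out$ic50_uM) | duplicated(out$ic50_uM, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
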