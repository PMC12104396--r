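#' @keywords internal
"_PACKAGE"

# Valid well roles on an inhibition plate.
WELL_ROLES <- c("test", "solvent_control", "positive_control", "standard", "blank")

#' Parse and normalise a 96-well coordinate
#'
#' Accepts coordinates like `"a1"`, `"H12"` and returns the canonical
#' uppercase form together with the row letter and column number. Rows run
#' A-H and columns 1-12 (standard 96-well geometry).
#'
#' @param well Character vector of well labels.
#' @return A data.frame with columns `well`, `row`, `column`.
#' @examples
#' parse_well(c("a1", "H12"))
#' @export
parse_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-H])([0-9]{1,2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("invalid well coordinate(s): ", paste(well[bad], collapse = ", "),
         " (expected A1-H12)", call. = FALSE)
  }
  row <- vapply(m, `[`, character(1), 2L)
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  if (any(col < 1L | col > 12L)) {
    stop("well column out of range 1-12: ", paste(well[col < 1L | col > 12L],
         collapse = ", "), call. = FALSE)
  }
  data.frame(well = paste0(row, col), row = row, column = col,
             stringsAsFactors = FALSE)
}

#' Construct a table of well measurements
#'
#' A plate readout is a long-form data.frame with one row per well read:
#' `plate_id`, `well`, `role`, `compound`, `conc_value`, `conc_unit`, `rfu`.
#' This constructor normalises well labels and validates the role-specific
#' invariants (blanks at zero concentration, test wells with a compound and a
#' positive concentration, finite non-negative fluorescence).
#'
#' @param plate_id Plate identifier (recycled).
#' @param well Well coordinates (A1-H12).
#' @param role One of `"test"`, `"solvent_control"`, `"positive_control"`,
#'   `"standard"`, `"blank"`.
#' @param compound Compound name; empty string for non-test wells.
#' @param conc_value Non-negative concentration value.
#' @param conc_unit Concentration unit, one of `"uM"`, `"nM"`, `"ug/mL"`.
#' @param rfu Endpoint relative fluorescence units (finite, >= 0).
#' @return A validated data.frame of class `well_table`.
#' @export
well_table <- function(plate_id, well, role, compound = "", conc_value = 0,
                       conc_unit = "uM", rfu) {
  w <- parse_well(well)
  df <- data.frame(plate_id = as.character(plate_id), well = w$well,
                   role = as.character(role),
                   compound = as.character(compound),
                   conc_value = as.numeric(conc_value),
                   conc_unit = as.character(conc_unit),
                   rfu = as.numeric(rfu), stringsAsFactors = FALSE)
  validate_well_table(df)
}

#' Validate a plate readout table
#'
#' @param df A data.frame with the long-form plate columns.
#' @return The table, invisibly classed as `well_table`, or an error
#'   describing the first violated invariant.
#' @export
validate_well_table <- function(df) {
  need <- c("plate_id", "well", "role", "compound", "conc_value",
            "conc_unit", "rfu")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$well <- parse_well(df$well)$well
  bad_role <- !df$role %in% WELL_ROLES
  if (any(bad_role)) stop("unknown role(s): ",
                          paste(unique(df$role[bad_role]), collapse = ", "),
                          call. = FALSE)
  if (any(!is.finite(df$rfu) | df$rfu < 0)) {
    stop("rfu must be finite and >= 0", call. = FALSE)
  }
  if (any(df$conc_value < 0)) stop("concentration must be >= 0", call. = FALSE)
  blk <- df$role == "blank"
  if (any(df$conc_value[blk] != 0)) {
    stop("blank wells must have concentration 0", call. = FALSE)
  }
  tst <- df$role == "test"
  if (any(tst & (is.na(df$compound) | df$compound == ""))) {
    stop("test wells must name a compound", call. = FALSE)
  }
  if (any(tst & df$conc_value <= 0)) {
    stop("test wells must have concentration > 0", call. = FALSE)
  }
  dup <- duplicated(df[c("plate_id", "well")])
  if (any(dup)) {
    stop("duplicate well assignment(s): ",
         paste(unique(paste(df$plate_id[dup], df$well[dup])), collapse = ", "),
         call. = FALSE)
  }
  class(df) <- unique(c("well_table", class(df)))
  df
}

#' Percent inhibition from endpoint fluorescence
#'
#' Quantifies inhibition of the fluorogenic reaction relative to the assay
#' window defined by the solvent control (uninhibited reaction, `a_rfu`) and
#' the positive-inhibitor control (fully inhibited reaction, `b_rfu`):
#'
#' \deqn{\%I = \left(1 - \frac{X - B}{A - B}\right) \times 100}
#'
#' Values below 0 or above 100 are preserved by default because the
#' dose-response fit needs unclipped responses; set `clip = TRUE` only for
#' display.
#'
#' @param x_rfu Test-well fluorescence.
#' @param a_rfu Solvent-control fluorescence (no inhibitor).
#' @param b_rfu Positive-inhibitor-control fluorescence (full inhibition).
#' @param clip Clip the result into \[0, 100\] for reporting (default FALSE).
#' @return Percent inhibition (numeric, vectorised over `x_rfu`).
#' @examples
#' percent_inhibition(550, 1000, 100)  # 50
#' @export
percent_inhibition <- function(x_rfu, a_rfu, b_rfu, clip = FALSE) {
  if (!all(is.finite(x_rfu), is.finite(a_rfu), is.finite(b_rfu))) {
    stop("fluorescence inputs must be finite", call. = FALSE)
  }
  if (any(a_rfu == b_rfu)) {
    stop("degenerate controls: solvent and positive control RFU are equal ",
         "(assay window is zero)", call. = FALSE)
  }
  pct <- (1 - (x_rfu - b_rfu) / (a_rfu - b_rfu)) * 100
  if (clip) pct <- pmin(pmax(pct, 0), 100)
  pct
}

#' Convert a mass concentration to molarity
#'
#' @param conc_ug_per_ml Concentration in micrograms per millilitre.
#' @param molecular_weight Molecular weight in g/mol.
#' @return Concentration in micromolar (uM).
#' @examples
#' mass_conc_to_molar(0.0112, 345.42)  # omeprazole unbound Cmax, ~0.0324 uM
#' @export
mass_conc_to_molar <- function(conc_ug_per_ml, molecular_weight) {
  if (any(!is.finite(molecular_weight) | molecular_weight <= 0)) {
    stop("molecular_weight must be > 0", call. = FALSE)
  }
  conc_ug_per_ml * 1000 / molecular_weight
}

#' @rdname mass_conc_to_molar
#' @param conc_uM Concentration in micromolar.
#' @export
molar_to_mass_conc <- function(conc_uM, molecular_weight) {
  if (any(!is.finite(molecular_weight) | molecular_weight <= 0)) {
    stop("molecular_weight must be > 0", call. = FALSE)
  }
  conc_uM * molecular_weight / 1000
}

#' Build a descending serial-dilution series
#'
#' Geometric dilution series as laid out on the plate: the top concentration
#' followed by `n - 1` successive `fold`-fold dilutions.
#'
#' @param top Top (highest) concentration, > 0.
#' @param fold Dilution factor between consecutive points, > 1 (default 2,
#'   the two-fold series used on the assay plates).
#' @param n Number of points, >= 2.
#' @param unit Concentration unit label carried with the series.
#' @return An object of class `dilution_series`: list with `concentrations`
#'   (descending), `top`, `fold`, `n`, `unit`.
#' @examples
#' build_dilution_series(500, 2, 7, unit = "nM")
#' build_dilution_series(6.4, 2, 4, unit = "ug/mL")  # the 0.8-6.4 ug/mL preset
#' @export
build_dilution_series <- function(top, fold = 2, n = 8, unit = "uM") {
  if (!is.finite(top) || top <= 0) stop("top concentration must be > 0",
                                        call. = FALSE)
  if (!is.finite(fold) || fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2", call. = FALSE)
  conc <- top / fold^(seq_len(n) - 1)
  structure(list(concentrations = conc, top = top, fold = fold,
                 n = as.integer(n), unit = unit),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("%d-point %g-fold dilution series (%s): %s\n", x$n, x$fold,
              x$unit, paste(signif(x$concentrations, 6), collapse = ", ")))
  invisible(x)
}

#' Aggregate plate controls
#'
#' Averages replicate control wells at the RFU level, yielding the solvent
#' control mean `a_rfu` and positive-inhibitor mean `b_rfu` used by
#' [percent_inhibition()], with per-role SDs for QC. Replicates are averaged
#' before the inhibition formula, matching its single-X form.
#'
#' @param wells A `well_table` (or compatible data.frame) for one plate.
#' @return List with `a_rfu`, `b_rfu`, `a_sd`, `b_sd`, `n_solvent`,
#'   `n_positive`, and `blank_rfu` (mean of blanks, `NA` if none).
#' @export
aggregate_controls <- function(wells) {
  a <- wells$rfu[wells$role == "solvent_control"]
  b <- wells$rfu[wells$role == "positive_control"]
  if (length(a) == 0) stop("no solvent_control wells on plate", call. = FALSE)
  if (length(b) == 0) stop("no positive_control wells on plate", call. = FALSE)
  blk <- wells$rfu[wells$role == "blank"]
  list(a_rfu = mean(a), b_rfu = mean(b),
       a_sd = if (length(a) > 1) stats::sd(a) else NA_real_,
       b_sd = if (length(b) > 1) stats::sd(b) else NA_real_,
       n_solvent = length(a), n_positive = length(b),
       blank_rfu = if (length(blk)) mean(blk) else NA_real_)
}

#' Per-well percent inhibition for the test compounds on a plate
#'
#' Aggregates each plate's controls and applies the inhibition formula to
#' every test well, converting mass-unit concentrations to micromolar with
#' the supplied molecular weights.
#'
#' @param wells A `well_table`, possibly spanning several plates (controls
#'   are aggregated per plate).
#' @param molecular_weights Optional named vector (g/mol) used to convert
#'   `ug/mL` test concentrations to uM; required only when such wells exist.
#' @return data.frame with `plate_id`, `compound`, `concentration_uM`,
#'   `replicate`, `inhibition`.
#' @export
plate_inhibition <- function(wells, molecular_weights = NULL) {
  wells <- validate_well_table(as.data.frame(wells))
  out <- lapply(split(wells, wells$plate_id), function(p) {
    ctl <- aggregate_controls(p)
    tw <- p[p$role == "test", , drop = FALSE]
    if (!nrow(tw)) return(NULL)
    conc <- to_uM(tw$conc_value, tw$conc_unit, tw$compound, molecular_weights)
    inh <- percent_inhibition(tw$rfu, ctl$a_rfu, ctl$b_rfu)
    d <- data.frame(plate_id = tw$plate_id, compound = tw$compound,
                    concentration_uM = conc, inhibition = inh,
                    stringsAsFactors = FALSE)
    # replicate index within compound x concentration, in well order
    d <- d[order(d$compound, -d$concentration_uM), , drop = FALSE]
    d$replicate <- stats::ave(seq_len(nrow(d)),
                              d$compound, d$concentration_uM,
                              FUN = seq_along)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Convert heterogeneous concentration units to uM.
to_uM <- function(value, unit, compound = NULL, molecular_weights = NULL) {
  out <- numeric(length(value))
  for (u in unique(unit)) {
    i <- unit == u
    out[i] <- switch(u,
      "uM" = value[i],
      "nM" = value[i] / 1000,
      "ug/mL" = {
        if (is.null(molecular_weights)) {
          stop("molecular weights required to convert ug/mL to uM",
               call. = FALSE)
        }
        mw <- molecular_weights[compound[i]]
        if (anyNA(mw)) stop("missing molecular weight for: ",
                            paste(unique(compound[i][is.na(mw)]),
                                  collapse = ", "), call. = FALSE)
        mass_conc_to_molar(value[i], mw)
      },
      stop("unknown concentration unit: ", u, call. = FALSE))
  }
  out
}

#' Read / write long-form plate readout CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `plate_id,well,role,compound,conc_value,conc_unit,rfu`, one row per well
#' read. Reading validates the table; writing round-trips losslessly.
#'
#' @param path File path.
#' @return `read_plate_csv` returns a validated `well_table`.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(plate_id = "character",
                                       well = "character",
                                       role = "character",
                                       compound = "character",
                                       conc_value = "numeric",
                                       conc_unit = "character",
                                       rfu = "numeric"))
  df$compound[is.na(df$compound)] <- ""
  validate_well_table(df)
}

#' @rdname read_plate_csv
#' @param wells A `well_table` to write.
#' @export
write_plate_csv <- function(wells, path) {
  utils::write.csv(as.data.frame(wells)[c("plate_id", "well", "role",
                                          "compound", "conc_value",
                                          "conc_unit", "rfu")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compound profile: per-drug constants for the unbound-parameter chain
#'
#' @param name Compound name.
#' @param molecular_weight g/mol, > 0.
#' @param cmax_total Literature peak total plasma concentration, ug/mL.
#' @param fu_plasma Fraction unbound in plasma, default 0.01 (the regulatory
#'   floor for highly protein-bound drugs).
#' @param fu_incubation Fraction unbound in the incubation system, default
#'   0.02 (regulatory assumption for highly bound drugs).
#' @return A one-row data.frame of class `compound_profile`.
#' @export
compound_profile <- function(name, molecular_weight, cmax_total,
                             fu_plasma = 0.01, fu_incubation = 0.02) {
  if (any(molecular_weight <= 0)) stop("molecular_weight must be > 0",
                                       call. = FALSE)
  if (any(fu_plasma <= 0 | fu_plasma > 1)) {
    stop("fu_plasma must be in (0, 1]", call. = FALSE)
  }
  if (any(fu_incubation <= 0 | fu_incubation > 1)) {
    stop("fu_incubation must be in (0, 1]", call. = FALSE)
  }
  if (any(!is.na(cmax_total) & cmax_total < 0)) {
    stop("cmax_total must be >= 0", call. = FALSE)
  }
  df <- data.frame(name = name, molecular_weight = molecular_weight,
                   cmax_ug_per_ml = cmax_total, fu_plasma = fu_plasma,
                   fu_incubation = fu_incubation, stringsAsFactors = FALSE)
  class(df) <- c("compound_profile", class(df))
  df
}

#' Read a compound constants CSV
#'
#' Format: `name,molecular_weight,cmax_ug_per_ml,fu_plasma,fu_incubation`.
#'
#' @param path File path; defaults to the packaged proton-pump-inhibitor
#'   constants table (see [ppi_constants()]).
#' @return A `compound_profile` data.frame.
#' @export
read_compounds_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  compound_profile(df$name, df$molecular_weight, df$cmax_ug_per_ml,
                   df$fu_plasma, df$fu_incubation)
}

#' Packaged constants for the five proton pump inhibitors
#'
#' Molecular weights and peak plasma concentrations for omeprazole,
#' lansoprazole, pantoprazole, rabeprazole and ilaprazole (plus ticlopidine,
#' the positive-control inhibitor, with no Cmax). Total Cmax values are
#' back-derived from published unbound Cmax at fu = 0.01; ilaprazole's has no
#' primary citation and is carried on the same back-derived basis.
#'
#' @return A `compound_profile` data.frame with six rows.
#' @export
ppi_constants <- function() {
  read_compounds_csv(system.file("extdata", "ppi_compounds.csv",
                                 package = "cyp2c19ddi", mustWork = TRUE))
}

#' Published in vitro summary values for the five proton pump inhibitors
#'
#' Per-drug literature IC50 (mean and spread, uM) against CYP2C19 and the
#' literature Cmax,u/Ki,u ratio, used as replay inputs when raw plate data is
#' unavailable. The literature ratio column is known not to equal
#' Cmax,u/Ki,u computed from the same source's own unbound values; it is
#' carried verbatim for replay-mode threshold calls only (see the package
#' vignette).
#'
#' @return data.frame with `name`, `ic50_uM`, `ic50_sd_uM`, `ratio_printed`.
#' @export
ppi_reported <- function() {
  utils::read.csv(system.file("extdata", "ppi_reported_ic50.csv",
                              package = "cyp2c19ddi", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Default assay conditions metadata
#'
#' Carried as metadata for reporting; the simulator models only the reaction
#' kinetics, not liquid handling.
#'
#' @param premix_volume_ul Master pre-mix volume per well (uL).
#' @param substrate_mix_volume_ul Substrate/NADP+ mixture volume (uL).
#' @param preincubation_minutes Inhibitor/enzyme preincubation at 37C.
#' @param reaction_minutes Reaction time after substrate addition.
#' @param total_incubation_minutes Total incubation as listed on the assay
#'   setup sheet (preincubation + reaction).
#' @param stop_reagent Stop solution description.
#' @param excitation_nm,emission_nm Filter wavelengths.
#' @return List of class `assay_conditions` (endpoint mode fixed).
#' @export
assay_conditions <- function(premix_volume_ul = 50,
                             substrate_mix_volume_ul = 10,
                             preincubation_minutes = 20,
                             reaction_minutes = 10,
                             total_incubation_minutes = 30,
                             stop_reagent = "50 uL 0.5 M Tris buffer",
                             excitation_nm = 415, emission_nm = 460) {
  vols <- c(premix_volume_ul, substrate_mix_volume_ul,
            preincubation_minutes, reaction_minutes,
            total_incubation_minutes, excitation_nm, emission_nm)
  if (any(vols <= 0)) stop("volumes, times and wavelengths must be > 0",
                           call. = FALSE)
  structure(list(premix_volume_ul = premix_volume_ul,
                 substrate_mix_volume_ul = substrate_mix_volume_ul,
                 preincubation_minutes = preincubation_minutes,
                 reaction_minutes = reaction_minutes,
                 total_incubation_minutes = total_incubation_minutes,
                 stop_reagent = stop_reagent,
                 excitation_nm = excitation_nm, emission_nm = emission_nm,
                 mode = "endpoint"),
            class = "assay_conditions")
}
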