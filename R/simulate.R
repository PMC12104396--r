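# Kinetic simulator for fluorometric CYP2C19 inhibition plates. Stands in
# for the wet assay: competitive Michaelis-Menten inhibition, linear product
# accumulation over the endpoint reaction window, fluorescence gain plus
# background, and multiplicative (CV-scaled) plate-reader noise.

#' Kinetic and optical parameters of the simulated assay
#'
#' Defaults give an uninhibited signal of ~1050 RFU (background 50 + 1000
#' product-derived RFU) with substrate well below Km, matching the
#' low-substrate regime the screening assay is run in.
#'
#' @param vmax Maximal velocity, product nM/min.
#' @param km Michaelis constant of the fluorogenic substrate, uM.
#' @param s Substrate concentration in the reaction, uM. `low_substrate`
#'   requires s <= km (the assay is run at substrate well below Km).
#' @param reaction_minutes Endpoint reaction time (linear accumulation).
#' @param fluorescence_gain RFU per nM product.
#' @param background_rfu Plate/buffer background fluorescence.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (0 disables noise).
#' @param residual_activity Fractional activity remaining at full positive
#'   control inhibition (default 0: ticlopidine treated as a complete
#'   inhibitor).
#' @param low_substrate Enforce s <= km.
#' @return List of class `kinetic_params`.
#' @export
kinetic_params <- function(vmax = 1100, km = 10, s = 1, reaction_minutes = 10,
                           fluorescence_gain = 1, background_rfu = 50,
                           noise_cv = 0.05, residual_activity = 0,
                           low_substrate = TRUE) {
  if (any(c(vmax, km, reaction_minutes, fluorescence_gain,
            background_rfu) <= 0) || s < 0) {
    stop("kinetic parameters must be positive (s >= 0)", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (residual_activity < 0 || residual_activity >= 1) {
    stop("residual_activity must be in [0, 1)", call. = FALSE)
  }
  if (low_substrate && s > km) {
    stop("s must be <= km when low_substrate = TRUE (low-substrate assay)",
         call. = FALSE)
  }
  structure(list(vmax = vmax, km = km, s = s,
                 reaction_minutes = reaction_minutes,
                 fluorescence_gain = fluorescence_gain,
                 background_rfu = background_rfu, noise_cv = noise_cv,
                 residual_activity = residual_activity,
                 low_substrate = low_substrate),
            class = "kinetic_params")
}

#' Product formed under competitive inhibition
#'
#' Competitive Michaelis-Menten rate
#' \deqn{v = \frac{V_{max} S}{K_m (1 + I/K_i) + S}}
#' integrated linearly over the reaction window (no substrate depletion):
#' product = v x reaction_minutes, in nM.
#'
#' @param i Inhibitor concentration (uM), >= 0.
#' @param ki Inhibition constant (uM), > 0.
#' @param params A [kinetic_params()] object.
#' @return Product concentration (nM).
#' @export
simulate_rate <- function(i, ki, params = kinetic_params()) {
  if (any(i < 0)) stop("inhibitor concentration must be >= 0", call. = FALSE)
  if (any(ki <= 0)) stop("ki must be > 0", call. = FALSE)
  v <- params$vmax * params$s / (params$km * (1 + i / ki) + params$s)
  v * params$reaction_minutes
}

#' IC50 implied by a Ki under the simulator's kinetics
#'
#' For competitive inhibition the half-inhibitory concentration is
#' IC50 = Ki (1 + S/Km) — the Cheng-Prusoff relation read forwards.
#'
#' @param ki Inhibition constant (uM).
#' @param params A [kinetic_params()] object.
#' @return IC50 (uM).
#' @export
ic50_from_ki <- function(ki, params = kinetic_params()) {
  ki * (1 + params$s / params$km)
}

#' @rdname ic50_from_ki
#' @param ic50 Observed IC50 (uM).
#' @export
ki_from_ic50 <- function(ic50, params = kinetic_params()) {
  ic50 / (1 + params$s / params$km)
}

# Standards column layout: two-fold series from the working standard in rows
# A-G of columns 1-2, blanks in H1/H2.
standards_layout <- function(working_nM = 500) {
  ser <- build_dilution_series(working_nM, 2, 7, unit = "nM")
  rows <- LETTERS[1:7]
  data.frame(well = c(paste0(rows, 1), paste0(rows, 2), "H1", "H2"),
             role = c(rep("standard", 14), "blank", "blank"),
             conc_nM = c(rep(ser$concentrations, 2), 0, 0),
             stringsAsFactors = FALSE)
}

#' Simulate complete fluorometric inhibition plates with known ground truth
#'
#' Lays out up to four compounds per 96-well plate: a fluorescent-standard
#' calibration column pair (columns 1-2: two-fold series from 500 nM in rows
#' A-G, buffer blanks in H), each compound in a duplicate column pair (8-point
#' dilution series down the rows), solvent controls (column 11, rows A-D) and
#' ticlopidine positive controls (column 12, rows A-D). Additional plates are
#' opened as needed; each plate carries its own standards and controls.
#'
#' Well fluorescence is `background + gain x product`, the product from
#' [simulate_rate()], the whole multiplied by `(1 + e)` with
#' `e ~ Normal(0, noise_cv)` drawn independently per well in row-major well
#' order (plate, row, column) so a seed fixes the entire table.
#'
#' @param compounds Named numeric vector of true Ki values (uM), or a
#'   data.frame with columns `name` and `ki_true`.
#' @param series A [build_dilution_series()] in uM for the test compounds
#'   (default 8-point two-fold from 50 uM).
#' @param replicates Wells per concentration, 1 or 2 (default 2, the assay's
#'   duplicate design).
#' @param params A [kinetic_params()] object.
#' @param seed Integer seed (required: the simulation contract is
#'   deterministic given the seed).
#' @return Object of class `simulated_plate`: `wells` (a `well_table`),
#'   `truth` (data.frame `name`, `ki_true`, `ic50_true`), `params`, `seed`.
#' @examples
#' sp <- simulate_plate(c(omeprazole = 1.282), seed = 1)
#' head(sp$wells)
#' @export
simulate_plate <- function(compounds,
                           series = build_dilution_series(50, 2, 8),
                           replicates = 2, params = kinetic_params(),
                           seed) {
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  if (is.data.frame(compounds)) {
    ki <- stats::setNames(compounds$ki_true, compounds$name)
  } else {
    ki <- compounds
  }
  if (is.null(names(ki)) || any(names(ki) == "")) {
    stop("compounds must be named", call. = FALSE)
  }
  if (any(ki <= 0)) stop("ki_true must be > 0 for every compound",
                         call. = FALSE)
  if (!replicates %in% 1:2) stop("replicates must be 1 or 2", call. = FALSE)
  if (series$n > 8) stop("at most 8 concentrations fit down a plate column",
                         call. = FALSE)

  per_plate <- 4L
  n_plate <- ceiling(length(ki) / per_plate)
  std <- standards_layout()
  rows8 <- LETTERS[1:8]

  wells <- list()
  for (p in seq_len(n_plate)) {
    pid <- sprintf("plate%02d", p)
    idx <- ((p - 1) * per_plate + 1):min(p * per_plate, length(ki))
    w <- data.frame(plate_id = pid, well = std$well, role = std$role,
                    compound = "", conc_value = std$conc_nM,
                    conc_unit = "nM", stringsAsFactors = FALSE)
    for (k in seq_along(idx)) {
      nm <- names(ki)[idx[k]]
      cols <- 2 * k + seq_len(replicates)
      for (cc in cols) {
        w <- rbind(w, data.frame(
          plate_id = pid,
          well = paste0(rows8[seq_len(series$n)], cc),
          role = "test", compound = nm,
          conc_value = series$concentrations,
          conc_unit = series$unit, stringsAsFactors = FALSE))
      }
    }
    w <- rbind(w,
      data.frame(plate_id = pid, well = paste0(LETTERS[1:4], 11),
                 role = "solvent_control", compound = "", conc_value = 0,
                 conc_unit = "uM", stringsAsFactors = FALSE),
      data.frame(plate_id = pid, well = paste0(LETTERS[1:4], 12),
                 role = "positive_control", compound = "ticlopidine",
                 conc_value = 0, conc_unit = "uM", stringsAsFactors = FALSE))
    wells[[p]] <- w
  }
  wells <- do.call(rbind, wells)

  # deterministic row-major order: plate, row letter, column number
  pw <- parse_well(wells$well)
  ord <- order(wells$plate_id, pw$row, pw$column)
  wells <- wells[ord, , drop = FALSE]

  g <- params$fluorescence_gain
  bg <- params$background_rfu
  prod0 <- simulate_rate(0, 1, params)  # ki irrelevant at i = 0
  mean_rfu <- numeric(nrow(wells))
  for (r in seq_len(nrow(wells))) {
    mean_rfu[r] <- switch(wells$role[r],
      standard = bg + g * wells$conc_value[r],
      blank = bg,
      solvent_control = bg + g * prod0,
      positive_control = bg + g * prod0 * params$residual_activity,
      test = {
        conc_uM <- to_uM(wells$conc_value[r], wells$conc_unit[r])
        bg + g * simulate_rate(conc_uM, ki[[wells$compound[r]]], params)
      })
  }
  eps <- with_seed(seed, stats::rnorm(nrow(wells), 0, params$noise_cv))
  if (params$noise_cv == 0) eps <- numeric(nrow(wells))
  wells$rfu <- pmax(mean_rfu * (1 + eps), 0)
  rownames(wells) <- NULL
  wells <- validate_well_table(wells)

  truth <- data.frame(name = names(ki), ki_true = unname(ki),
                      ic50_true = ic50_from_ki(unname(ki), params),
                      stringsAsFactors = FALSE)
  structure(list(wells = wells, truth = truth, params = params, seed = seed),
            class = "simulated_plate")
}

#' @export
print.simulated_plate <- function(x, ...) {
  cat(sprintf(
    "Simulated inhibition plate set: %d wells, %d compound(s), seed %d\n",
    nrow(x$wells), nrow(x$truth), x$seed))
  print(x$truth, row.names = FALSE)
  invisible(x)
}

#' Write a simulated plate's ground-truth sidecar JSON
#'
#' @param sp A `simulated_plate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(sp, path) {
  truth <- stats::setNames(
    lapply(seq_len(nrow(sp$truth)), function(i) {
      list(ki_true = sp$truth$ki_true[i], ic50_true = sp$truth$ic50_true[i])
    }), sp$truth$name)
  jsonlite::write_json(list(truth = truth,
                            params = unclass(sp$params),
                            seed = sp$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the canonical test fixture plates
#'
#' Generates three small plates used by the test suite and examples: a clean
#' plate (no noise), a noisy plate (CV 5%), and a degenerate plate whose
#' control wells have been dropped. Byte-identical across re-runs with the
#' same seed.
#'
#' @param out_dir Writable directory (created if absent).
#' @param seed Integer seed for the noisy plate.
#' @return Named character vector of the files written.
#' @export
make_fixture_suite <- function(out_dir, seed = 101) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- c(omeprazole = ki_from_ic50(1.41), ilaprazole = ki_from_ic50(6.62))
  clean <- simulate_plate(cmp, params = kinetic_params(noise_cv = 0),
                          seed = seed)
  noisy <- simulate_plate(cmp, params = kinetic_params(noise_cv = 0.05),
                          seed = seed)
  degen <- clean$wells[!clean$wells$role %in%
                         c("solvent_control", "positive_control"), ]
  paths <- c(clean = file.path(out_dir, "clean_plate.csv"),
             noisy = file.path(out_dir, "noisy_plate.csv"),
             degenerate = file.path(out_dir, "degenerate_plate.csv"),
             clean_truth = file.path(out_dir, "clean_plate_truth.json"),
             noisy_truth = file.path(out_dir, "noisy_plate_truth.json"))
  write_plate_csv(clean$wells, paths["clean"])
  write_plate_csv(noisy$wells, paths["noisy"])
  write_plate_csv(degen, paths["degenerate"])
  write_truth_json(clean, paths["clean_truth"])
  write_truth_json(noisy, paths["noisy_truth"])
  paths
}
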