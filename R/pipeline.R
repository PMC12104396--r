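# Pipeline orchestration: configuration, end-to-end analyze/report runs, and
# provenance. These functions back the command-line entry point in
# inst/scripts/cyp2c19-pipeline.R.

#' Pipeline configuration
#'
#' Collects the regulatory assumptions and run options used across the
#' pipeline. Unknown arguments are rejected rather than ignored.
#'
#' @param fu_incubation Fraction unbound in the incubation (default 0.02).
#' @param fu_plasma Fraction unbound in plasma (default 0.01).
#' @param ki_convention `"regulatory_half"` or `"cheng_prusoff"`.
#' @param s,km Substrate concentration and Km (uM), required only for the
#'   Cheng-Prusoff convention.
#' @param ddi_threshold Cmax,u/Ki,u decision cutoff (default 0.02).
#' @param free_asymptotes Fit 4PL asymptotes freely (default FALSE).
#' @param n_boot Bootstrap resamples for IC50 SDs (0 disables).
#' @param noise_cv Simulator noise CV.
#' @param top_conc_uM,fold,n_points,replicates Simulator dilution design.
#' @param seed Integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fu_incubation = 0.02, fu_plasma = 0.01,
                            ki_convention = "regulatory_half",
                            s = NULL, km = NULL, ddi_threshold = 0.02,
                            free_asymptotes = FALSE, n_boot = 0,
                            noise_cv = 0.05, top_conc_uM = 50, fold = 2,
                            n_points = 8, replicates = 2, seed = 1) {
  if (!is.numeric(fu_incubation) || fu_incubation <= 0 || fu_incubation > 1) {
    stop("fu_incubation must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(fu_plasma) || fu_plasma <= 0 || fu_plasma > 1) {
    stop("fu_plasma must be in (0, 1]", call. = FALSE)
  }
  if (!ki_convention %in% c("regulatory_half", "cheng_prusoff")) {
    stop("ki_convention must be 'regulatory_half' or 'cheng_prusoff'",
         call. = FALSE)
  }
  if (!is.numeric(ddi_threshold) || ddi_threshold <= 0) {
    stop("ddi_threshold must be > 0", call. = FALSE)
  }
  cfg <- list(fu_incubation = fu_incubation, fu_plasma = fu_plasma,
              ki_convention = ki_convention, s = s, km = km,
              ddi_threshold = ddi_threshold,
              free_asymptotes = isTRUE(free_asymptotes),
              n_boot = as.integer(n_boot), noise_cv = noise_cv,
              top_conc_uM = top_conc_uM, fold = fold,
              n_points = as.integer(n_points),
              replicates = as.integer(replicates), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error so that typos fail loudly rather than silently reverting a
#' regulatory assumption to its default.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

# FNV-1a 32-bit hash of a string; used only for provenance fingerprints.
# h is carried as a double, so the xor works on 16-bit halves to stay inside
# R's integer range.
fnv1a <- function(x) {
  xor32 <- function(a, b) {
    lo <- bitwXor(a %% 65536, b %% 65536)
    hi <- bitwXor(a %/% 65536, b %/% 65536)
    hi * 65536 + lo
  }
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Provenance block for a pipeline run
#'
#' @param config A `pipeline_config`.
#' @return List with the package version, the seed, and an FNV-1a fingerprint
#'   of the configuration — enough to reproduce deterministic stages
#'   bit-for-bit.
#' @export
provenance <- function(config) {
  list(package = "cyp2c19ddi",
       version = as.character(utils::packageVersion("cyp2c19ddi")),
       seed = config$seed,
       config_hash = fnv1a(paste(deparse(unclass(config)), collapse = "")))
}

#' Simulate a plate set and write it to disk
#'
#' Wraps [simulate_plate()]: simulates the five proton pump inhibitors (or a
#' caller-supplied set) at the configured dilution design and noise level,
#' writing the long-form plate CSV and the ground-truth sidecar JSON.
#'
#' @param config A `pipeline_config`.
#' @param out_plate,out_truth Output paths.
#' @param compounds Named vector of true Ki values (uM); default: Ki values
#'   whose implied IC50s equal the five PPIs' published IC50s under the
#'   simulator's kinetics.
#' @return Invisibly, the `simulated_plate` with a `provenance` attribute.
#' @export
run_simulate <- function(config = pipeline_config(),
                         out_plate = "plate.csv",
                         out_truth = "plate_truth.json",
                         compounds = NULL) {
  params <- kinetic_params(noise_cv = config$noise_cv)
  if (is.null(compounds)) {
    rep_tab <- ppi_reported()
    compounds <- stats::setNames(ki_from_ic50(rep_tab$ic50_uM, params),
                                 rep_tab$name)
  }
  sp <- simulate_plate(compounds,
                       series = build_dilution_series(config$top_conc_uM,
                                                      config$fold,
                                                      config$n_points),
                       replicates = config$replicates, params = params,
                       seed = config$seed)
  write_plate_csv(sp$wells, out_plate)
  write_truth_json(sp, out_truth)
  attr(sp, "provenance") <- provenance(config)
  invisible(sp)
}

#' Analyze a plate readout end to end
#'
#' Reads the plate and compound tables, computes per-well percent inhibition
#' against each plate's controls, fits one inhibition curve per compound
#' (with optional bootstrap SDs), and chains the unbound-parameter DDI
#' assessment. In replay mode (`replay_ic50` supplied) fitting is skipped and
#' the assessment is computed directly from the given total IC50s — the mode
#' used to audit published summary tables when raw plate data is unavailable.
#'
#' @param plate Path to a plate CSV or a `well_table` (ignored in replay
#'   mode).
#' @param compounds Path to a compound constants CSV or a `compound_profile`
#'   data.frame; default, the packaged PPI constants.
#' @param config A `pipeline_config`. Its `fu_incubation` / `fu_plasma`
#'   override the per-compound table values so a single assumption set
#'   governs the run.
#' @param replay_ic50 Optional named vector (or data.frame `name`,`ic50_uM`)
#'   of total IC50s (uM) to assess without fitting.
#' @param out_fits,out_assessment,out_json Optional output paths (CSV, CSV,
#'   JSON).
#' @return List of class `pipeline_result`: `fits` (data.frame or NULL in
#'   replay mode), `assessment` (a `ddi_assessment`), `qc` (per-plate assay
#'   window QC), `provenance`.
#' @export
run_analyze <- function(plate = NULL, compounds = NULL,
                        config = pipeline_config(), replay_ic50 = NULL,
                        out_fits = NULL, out_assessment = NULL,
                        out_json = NULL) {
  if (is.null(compounds)) {
    profiles <- ppi_constants()
  } else if (is.character(compounds)) {
    profiles <- read_compounds_csv(compounds)
  } else {
    profiles <- compounds
  }
  # one assumption set per run: config overrides the per-compound fu columns
  profiles$fu_incubation <- config$fu_incubation
  profiles$fu_plasma <- config$fu_plasma

  fits_tab <- NULL
  qc <- NULL
  if (is.null(replay_ic50)) {
    if (is.null(plate)) stop("plate input required unless replaying IC50s",
                             call. = FALSE)
    wells <- if (is.character(plate)) read_plate_csv(plate) else
      validate_well_table(as.data.frame(plate))
    mw <- stats::setNames(profiles$molecular_weight, profiles$name)
    qc <- lapply(split(wells, wells$plate_id), function(p) {
      ctl <- aggregate_controls(p)
      assay_window_qc(ctl$a_rfu, ctl$b_rfu, ctl$blank_rfu, ctl$a_sd, ctl$b_sd)
    })
    fits <- fit_plate_ic50(wells, molecular_weights = mw,
                           n_boot = config$n_boot, seed = config$seed,
                           free_asymptotes = config$free_asymptotes)
    fits_tab <- ic50_fit_table(fits)
    conv <- fits_tab[fits_tab$converged, , drop = FALSE]
    if (!nrow(conv)) stop("no compound produced a converged fit",
                          call. = FALSE)
    ic50 <- stats::setNames(conv$ic50_uM, conv$compound)
  } else {
    if (is.data.frame(replay_ic50)) {
      ic50 <- stats::setNames(replay_ic50$ic50_uM, replay_ic50$name)
    } else {
      ic50 <- replay_ic50
    }
  }
  assessment <- ddi_assess(profiles[profiles$name %in% names(ic50), ,
                                    drop = FALSE],
                           ic50[order(names(ic50))],
                           ki_convention = config$ki_convention,
                           s = config$s, km = config$km,
                           threshold = config$ddi_threshold)
  res <- structure(list(fits = fits_tab, assessment = assessment, qc = qc,
                        provenance = provenance(config)),
                   class = "pipeline_result")
  if (!is.null(out_fits) && !is.null(fits_tab)) {
    utils::write.csv(fits_tab, out_fits, row.names = FALSE)
  }
  if (!is.null(out_assessment)) {
    utils::write.csv(as.data.frame(assessment), out_assessment,
                     row.names = FALSE)
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(list(fits = fits_tab,
                              assessment = as.data.frame(assessment),
                              provenance = res$provenance),
                         out_json, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("cyp2c19ddi pipeline result (version %s, seed %s, config %s)\n",
              x$provenance$version, x$provenance$seed,
              x$provenance$config_hash))
  if (!is.null(x$fits)) {
    cat("\nDose-response fits:\n")
    print(x$fits, row.names = FALSE)
  }
  cat("\n")
  print(x$assessment)
  invisible(x)
}

#' Human-readable potency and risk report
#'
#' Renders a markdown report from a DDI assessment: compounds ranked by
#' potency (ascending IC50), risk flags at the configured cutoff, and — when
#' a published ratio column is supplied — a discrepancy note comparing
#' computed with published ratios.
#'
#' @param assessment A `ddi_assessment` (or path to an assessment CSV).
#' @param printed_ratios Optional named vector of published Cmax,u/Ki,u
#'   ratios for the same compounds.
#' @return Character vector of markdown lines (also printed).
#' @export
run_report <- function(assessment, printed_ratios = NULL) {
  if (is.character(assessment)) {
    assessment <- utils::read.csv(assessment, stringsAsFactors = FALSE)
  }
  if (!nrow(assessment)) stop("empty assessment table", call. = FALSE)
  rk <- rank_by_potency(assessment)
  lines <- c("# CYP2C19 inhibition risk report", "",
             sprintf("Basic static model, Cmax,u/Ki,u cutoff %s (inclusive).",
                     format(rk$threshold[1])), "",
             "| rank | compound | IC50 (uM) | Ki,u (uM) | Cmax,u (uM) | ratio | call |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(rk))) {
    lines <- c(lines, sprintf(
      "| %d | %s%s | %.3g | %.4g | %.3g | %.3g | %s |",
      rk$rank[i], rk$compound[i], if (rk$tie[i]) " (tie)" else "",
      rk$ic50_uM[i], rk$ki_u_uM[i], rk$cmax_u_uM[i], rk$ratio[i],
      rk$risk_flag[i]))
  }
  lines <- c(lines, "",
             sprintf("Potency ranking: %s.",
                     paste(rk$compound, collapse = " > ")))
  flagged <- rk$compound[rk$risk_flag == "potential_inhibitor"]
  lines <- c(lines, "",
             if (length(flagged)) {
               sprintf("Potential in vivo CYP2C19 inhibitor(s): %s.",
                       paste(flagged, collapse = ", "))
             } else {
               "No compound met the inhibition-risk cutoff."
             })
  if (!is.null(printed_ratios)) {
    pr <- printed_ratios[rk$compound]
    lines <- c(lines, "", "## Published vs computed ratios", "",
               "Computed ratios use Cmax,u/Ki,u in uM/uM as defined in the",
               "methods; published ratio columns are not always internally",
               "consistent with their own unbound values.", "",
               "| compound | computed | published | relative difference |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(rk))) {
      lines <- c(lines, sprintf(
        "| %s | %.3g | %.3g | %.2gx |", rk$compound[i], rk$ratio[i], pr[i],
        pr[i] / rk$ratio[i]))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
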