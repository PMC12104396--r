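# Four-parameter-logistic concentration-response modelling and IC50
# estimation. This replaces the point-and-click nonlinear regression step of
# a typical screening workflow with a scripted, reproducible fitter.

# 4PL evaluated against log10 concentration for conditioning.
fourpl <- function(conc, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(ic50) - log10(conc))))
}

#' Fit a four-parameter logistic inhibition curve and estimate the IC50
#'
#' Least-squares fit of
#' \deqn{\%I(c) = bottom + \frac{top - bottom}{1 + (IC_{50}/c)^{hill}}}
#' to percent-inhibition responses. By default the asymptotes are fixed at
#' `bottom = 0`, `top = 100` because responses are normalised to the solvent
#' and positive-inhibitor controls; `free_asymptotes = TRUE` refits them as
#' free parameters for QC. Fitting is performed against log10(concentration),
#' with a multi-start search over five IC50 initial values spanning the
#' tested range; ties are broken by lowest SSE, then lowest Hill slope.
#' Non-convergence (including an IC50 estimate escaping to the search-box
#' boundary, as happens with flat responses) is flagged, never silently
#' interpolated.
#'
#' @param concentration Concentrations, > 0, in `conc_unit`. At least 4
#'   distinct values are required.
#' @param inhibition Percent inhibition (unclipped), same length.
#' @param replicate Optional replicate identifier per point (used by the
#'   bootstrap's case resampling); defaults to within-concentration index.
#' @param conc_unit Unit label carried through to the IC50 (default `"uM"`).
#' @param free_asymptotes Fit bottom and top as free parameters.
#' @param hill_bounds Permitted Hill-slope range (default `c(0.1, 10)`).
#' @param n_starts Number of IC50 multi-start values (default 5).
#' @return An object of class `ic50_fit` with components `coefficients`
#'   (`bottom`, `top`, `hill`, `ic50`), `ic50_sd` (NA until
#'   [bootstrap_ic50_sd()] is run), `sse`, `sigma`, `converged`, `n_points`
#'   (distinct concentrations), `data`, `conc_unit`.
#' @examples
#' conc <- 50 / 2^(0:7)
#' fit <- fit_ic50(conc, 100 * conc / (conc + 2))
#' coef(fit)["ic50"]  # 2
#' @export
fit_ic50 <- function(concentration, inhibition, replicate = NULL,
                     conc_unit = "uM", free_asymptotes = FALSE,
                     hill_bounds = c(0.1, 10), n_starts = 5) {
  if (length(concentration) != length(inhibition)) {
    stop("concentration and inhibition must have equal length", call. = FALSE)
  }
  if (any(!is.finite(concentration) | concentration <= 0)) {
    stop("concentrations must be finite and > 0 ",
         "(zero-concentration controls are handled upstream)", call. = FALSE)
  }
  if (any(!is.finite(inhibition))) {
    stop("inhibition responses must be finite", call. = FALSE)
  }
  if (length(unique(concentration)) < 4) {
    stop("need >= 4 distinct concentrations to fit a 4PL", call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(concentration), concentration,
                            FUN = seq_along)
  }
  dat <- data.frame(concentration = concentration, inhibition = inhibition,
                    replicate = replicate)
  eng <- fit_4pl_engine(dat$concentration, dat$inhibition,
                        free_asymptotes = free_asymptotes,
                        hill_bounds = hill_bounds, n_starts = n_starts)
  n_par <- if (free_asymptotes) 4L else 2L
  dfree <- max(nrow(dat) - n_par, 1L)
  structure(list(coefficients = eng$coefficients,
                 ic50_sd = NA_real_,
                 sse = eng$sse,
                 sigma = sqrt(eng$sse / dfree),
                 converged = eng$converged,
                 n_points = length(unique(dat$concentration)),
                 n_obs = nrow(dat),
                 data = dat,
                 conc_unit = conc_unit,
                 free_asymptotes = free_asymptotes,
                 hill_bounds = hill_bounds,
                 n_starts = n_starts,
                 call = match.call()),
            class = "ic50_fit")
}

# Multi-start bounded least squares on (log10 IC50, hill [, bottom, top]).
fit_4pl_engine <- function(conc, resp, free_asymptotes, hill_bounds,
                           n_starts) {
  lx <- log10(conc)
  box <- c(min(lx) - 3, max(lx) + 3)
  sse_fn <- function(par) {
    b <- if (free_asymptotes) par[3] else 0
    t <- if (free_asymptotes) par[4] else 100
    pred <- b + (t - b) / (1 + 10^(par[2] * (par[1] - lx)))
    sum((resp - pred)^2)
  }
  starts <- seq(min(lx), max(lx), length.out = n_starts)
  lower <- c(box[1], hill_bounds[1])
  upper <- c(box[2], hill_bounds[2])
  if (free_asymptotes) {
    lower <- c(lower, -100, 50)
    upper <- c(upper, 50, 200)
  }
  best <- NULL
  best_clean <- NULL  # best run that terminated with a clean convergence code
  for (s in starts) {
    par0 <- c(s, 1)
    if (free_asymptotes) par0 <- c(par0, 0, 100)
    opt <- tryCatch(
      stats::optim(par0, sse_fn, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1e3, pgtol = 1e-12, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-12 ||
        (abs(opt$value - best$value) <= 1e-12 && opt$par[2] < best$par[2])) {
      best <- opt
    }
    if (opt$convergence == 0 &&
        (is.null(best_clean) || opt$value < best_clean$value)) {
      best_clean <- opt
    }
  }
  if (is.null(best)) {
    stop("4PL optimisation failed from every start", call. = FALSE)
  }
  at_edge <- min(abs(best$par[1] - box)) < 1e-6
  coefs <- c(bottom = if (free_asymptotes) best$par[3] else 0,
             top = if (free_asymptotes) best$par[4] else 100,
             hill = best$par[2],
             ic50 = 10^best$par[1])
  # converged when some clean run reached (essentially) the same optimum and
  # the IC50 did not escape to the search-box boundary (flat responses do)
  clean_ok <- !is.null(best_clean) &&
    best_clean$value <= best$value * (1 + 1e-4) + 1e-8
  converged <- clean_ok && !at_edge &&
    (!free_asymptotes || coefs["bottom"] < coefs["top"])
  list(coefficients = coefs, sse = best$value, converged = converged)
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic inhibition fit\n")
  cat(sprintf("  IC50: %s %s%s\n", format(signif(x$coefficients["ic50"], digits)),
              x$conc_unit,
              if (is.finite(x$ic50_sd))
                sprintf(" (bootstrap SD %s)", format(signif(x$ic50_sd, digits)))
              else ""))
  cat(sprintf("  Hill: %s   bottom: %s   top: %s\n",
              format(signif(x$coefficients["hill"], digits)),
              format(signif(x$coefficients["bottom"], digits)),
              format(signif(x$coefficients["top"], digits))))
  cat(sprintf("  %d obs at %d concentrations; SSE = %s; converged: %s\n",
              x$n_obs, x$n_points, format(signif(x$sse, digits)),
              x$converged))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) object$coefficients

#' @export
summary.ic50_fit <- function(object, ...) {
  structure(list(fit = object,
                 residual_sd = object$sigma,
                 residuals = stats::residuals(object)),
            class = "summary.ic50_fit")
}

#' @export
print.summary.ic50_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  residual SD: %s   residual range: [%s, %s]\n",
              format(signif(x$residual_sd, digits)),
              format(signif(min(x$residuals), digits)),
              format(signif(max(x$residuals), digits))))
  invisible(x)
}

#' Predict percent inhibition from a fitted curve
#'
#' @param object An `ic50_fit`.
#' @param concentration Concentrations (> 0) at which to evaluate the curve;
#'   defaults to the fitted data's concentrations.
#' @param ... Unused.
#' @return Percent inhibition.
#' @export
predict.ic50_fit <- function(object, concentration = NULL, ...) {
  if (is.null(concentration)) concentration <- object$data$concentration
  if (any(concentration <= 0)) {
    stop("concentration must be > 0", call. = FALSE)
  }
  cf <- object$coefficients
  unname(fourpl(concentration, cf["bottom"], cf["top"], cf["hill"],
                cf["ic50"]))
}

#' Evaluate a fitted inhibition curve at given concentrations
#'
#' Convenience wrapper around [predict.ic50_fit()] that refuses to
#' extrapolate from a non-converged fit.
#'
#' @param fit An `ic50_fit`.
#' @param concentration Concentration(s), > 0, in the fit's unit.
#' @return Percent inhibition.
#' @export
predict_inhibition <- function(fit, concentration) {
  stopifnot(inherits(fit, "ic50_fit"))
  if (!fit$converged) {
    stop("fit did not converge; predictions are not meaningful",
         call. = FALSE)
  }
  predict(fit, concentration)
}

#' @export
fitted.ic50_fit <- function(object, ...) predict(object)

#' @export
residuals.ic50_fit <- function(object, ...) {
  object$data$inhibition - predict(object)
}

#' Simulate response vectors from a fitted inhibition curve
#'
#' Draws Gaussian noise with the fit's residual SD around the fitted curve at
#' the observed design points — a parametric-bootstrap companion to the
#' case-resampling [bootstrap_ic50_sd()].
#'
#' @param object An `ic50_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return data.frame with one column per simulation.
#' @export
simulate.ic50_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- predict(object)
  runner <- function() {
    as.data.frame(replicate(nsim, stats::rnorm(length(mu), mu, object$sigma),
                            simplify = FALSE),
                  col.names = paste0("sim_", seq_len(nsim)))
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' Plot a fitted inhibition curve
#'
#' Mean +/- SD percent inhibition per concentration on a log axis, with the
#' fitted 4PL overlaid and the IC50 marked.
#'
#' @param x An `ic50_fit`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ic50_fit <- function(x, main = "CYP2C19 inhibition", ...) {
  d <- x$data
  agg <- stats::aggregate(inhibition ~ concentration, d,
                          function(v) c(m = mean(v), s = stats::sd(v)))
  conc <- agg$concentration
  m <- agg$inhibition[, "m"]
  s <- agg$inhibition[, "s"]
  ylim <- range(c(m - s, m + s, 0, 100), na.rm = TRUE)
  graphics::plot(conc, m, log = "x", ylim = ylim,
                 xlab = sprintf("concentration (%s)", x$conc_unit),
                 ylab = "% inhibition", main = main, pch = 19, ...)
  ok <- is.finite(s) & s > 0
  if (any(ok)) {
    graphics::arrows(conc[ok], (m - s)[ok], conc[ok], (m + s)[ok],
                     angle = 90, code = 3, length = 0.04)
  }
  grid <- 10^seq(log10(min(conc)), log10(max(conc)), length.out = 200)
  graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  if (x$converged) {
    graphics::abline(v = x$coefficients["ic50"], lty = 3, col = "grey40")
  }
  invisible(x)
}

#' Bootstrap standard deviation of the IC50
#'
#' Case-resamples the fitted data by replicate well (each
#' concentration-replicate observation is one resampling unit), refits the
#' 4PL on every resample, and reports the SD of the IC50 estimates.
#' Deterministic for a given seed; the global RNG state is restored.
#'
#' @param object A converged `ic50_fit`.
#' @param n_boot Number of bootstrap resamples, >= 100.
#' @param seed Integer seed.
#' @return Object of class `ic50_boot`: `sd` (same unit as the fit's IC50),
#'   `n_boot`, `n_failed` (resamples with < 4 distinct concentrations or a
#'   non-converged refit), `fraction_failed`, `estimates`.
#' @export
bootstrap_ic50_sd <- function(object, n_boot = 500, seed = 1) {
  stopifnot(inherits(object, "ic50_fit"))
  if (!object$converged) {
    stop("cannot bootstrap a non-converged fit", call. = FALSE)
  }
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  d <- object$data
  est <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(d), nrow(d), replace = TRUE)
      db <- d[idx, ]
      if (length(unique(db$concentration)) < 4) return(NA_real_)
      f <- tryCatch(
        fit_ic50(db$concentration, db$inhibition, db$replicate,
                 conc_unit = object$conc_unit,
                 free_asymptotes = object$free_asymptotes,
                 hill_bounds = object$hill_bounds,
                 n_starts = object$n_starts),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) return(NA_real_)
      unname(f$coefficients["ic50"])
    }, numeric(1))
  })
  structure(list(sd = stats::sd(est, na.rm = TRUE),
                 n_boot = n_boot,
                 n_failed = sum(is.na(est)),
                 fraction_failed = mean(is.na(est)),
                 estimates = est,
                 seed = seed),
            class = "ic50_boot")
}

#' @export
print.ic50_boot <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap IC50 SD: %s  (%d resamples, %.1f%% failed)\n",
              format(signif(x$sd, digits)), x$n_boot,
              100 * x$fraction_failed))
  invisible(x)
}

#' Plate-level bootstrap standard deviation of the IC50
#'
#' Unlike [bootstrap_ic50_sd()], which resamples only the derived
#' dose-response points, this bootstrap resamples the plate's raw wells:
#' control wells within role and test wells within concentration, recomputing
#' percent inhibition against the resampled controls before every refit. The
#' control-well resampling propagates the plate-level error component that
#' all inhibition points share through their common normalisation — the
#' component a points-only bootstrap cannot see — so this SD is the one
#' comparable to the spread of IC50 estimates across independently run
#' plates.
#'
#' @param wells A `well_table` containing the compound's plate.
#' @param compound Compound name to bootstrap.
#' @param molecular_weights Named vector for ug/mL to uM conversion, if
#'   needed.
#' @param n_boot Number of resamples, >= 100.
#' @param seed Integer seed (RNG state restored afterwards).
#' @param ... Passed to [fit_ic50()].
#' @return An `ic50_boot` object (see [bootstrap_ic50_sd()]).
#' @export
plate_bootstrap_ic50_sd <- function(wells, compound, molecular_weights = NULL,
                                    n_boot = 500, seed = 1, ...) {
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  wells <- validate_well_table(as.data.frame(wells))
  tw <- wells[wells$role == "test" & wells$compound == compound, ,
              drop = FALSE]
  if (!nrow(tw)) stop("no test wells for compound: ", compound,
                      call. = FALSE)
  pid <- unique(tw$plate_id)
  if (length(pid) > 1) stop("compound spans multiple plates", call. = FALSE)
  on_plate <- wells$plate_id == pid
  a <- wells$rfu[on_plate & wells$role == "solvent_control"]
  b <- wells$rfu[on_plate & wells$role == "positive_control"]
  if (!length(a) || !length(b)) {
    stop("plate lacks solvent or positive control wells", call. = FALSE)
  }
  conc <- to_uM(tw$conc_value, tw$conc_unit, tw$compound, molecular_weights)
  groups <- split(seq_len(nrow(tw)), conc)
  est <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ab <- mean(sample(a, length(a), replace = TRUE))
      bb <- mean(sample(b, length(b), replace = TRUE))
      if (ab == bb) return(NA_real_)
      idx <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      f <- tryCatch(
        fit_ic50(conc[idx], percent_inhibition(tw$rfu[idx], ab, bb), ...),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) return(NA_real_)
      unname(f$coefficients["ic50"])
    }, numeric(1))
  })
  structure(list(sd = stats::sd(est, na.rm = TRUE),
                 n_boot = n_boot,
                 n_failed = sum(is.na(est)),
                 fraction_failed = mean(is.na(est)),
                 estimates = est,
                 seed = seed),
            class = "ic50_boot")
}

#' Fit inhibition curves for every test compound on a plate
#'
#' Runs [plate_inhibition()] and fits one [fit_ic50()] per compound, with an
#' optional bootstrap SD.
#'
#' @param wells A `well_table`.
#' @param molecular_weights Named vector for ug/mL to uM conversion, if
#'   needed.
#' @param n_boot Plate-level bootstrap resamples per compound (see
#'   [plate_bootstrap_ic50_sd()]); 0 skips the bootstrap.
#' @param seed Seed for the bootstrap.
#' @param ... Passed to [fit_ic50()].
#' @return Named list of `ic50_fit` objects (with `ic50_sd` filled in when
#'   bootstrapped).
#' @export
fit_plate_ic50 <- function(wells, molecular_weights = NULL, n_boot = 0,
                           seed = 1, ...) {
  inh <- plate_inhibition(wells, molecular_weights)
  fits <- lapply(split(inh, inh$compound), function(d) {
    f <- fit_ic50(d$concentration_uM, d$inhibition, d$replicate, ...)
    if (n_boot > 0 && f$converged) {
      f$ic50_sd <- plate_bootstrap_ic50_sd(wells, d$compound[1],
                                           molecular_weights,
                                           n_boot = n_boot, seed = seed,
                                           ...)$sd
    }
    f
  })
  fits[order(names(fits))]
}

#' Tabulate a list of inhibition fits
#'
#' @param fits Named list of `ic50_fit` objects (as from [fit_plate_ic50()]).
#' @return data.frame with one row per compound: `compound`, `bottom`, `top`,
#'   `hill`, `ic50_uM`, `ic50_sd_uM`, `sse`, `converged`.
#' @export
ic50_fit_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cf <- f$coefficients
    data.frame(compound = nm, bottom = unname(cf["bottom"]),
               top = unname(cf["top"]), hill = unname(cf["hill"]),
               ic50_uM = unname(cf["ic50"]), ic50_sd_uM = f$ic50_sd,
               sse = f$sse, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
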