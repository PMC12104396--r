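test_that("noiseless hill-1 data is recovered essentially exactly", {
  pts <- exact_4pl_points(ic50 = 2)
  fit <- fit_ic50(pts$concentration, pts$inhibition)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["ic50"]), 2, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["hill"]), 1, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-6)
})

test_that("steeper and shallower exact curves are also recovered", {
  conc <- rep(50 / 2^(0:7), each = 2)
  for (h in c(0.6, 1.7)) {
    inh <- 100 / (1 + (3 / conc)^h)
    fit <- fit_ic50(conc, inh)
    expect_equal(unname(coef(fit)["ic50"]), 3, tolerance = 1e-5)
    expect_equal(unname(coef(fit)["hill"]), h, tolerance = 1e-4)
  }
})

test_that("flat responses are flagged, not interpolated", {
  fit <- fit_ic50(50 / 2^(0:7), rep(0, 8))
  expect_false(fit$converged)
  expect_error(predict_inhibition(fit, 1), "converge")
})

test_that("too few distinct concentrations is an error", {
  expect_error(fit_ic50(c(1, 2, 4), c(10, 30, 60)), ">= 4")
  expect_error(fit_ic50(rep(c(1, 2, 4, 8), 2), rep(1, 8) * NA), "finite")
})

test_that("fit agrees with an independent nonlinear least-squares route", {
  set.seed(11)
  conc <- rep(50 / 2^(0:7), each = 2)
  inh <- 100 * conc / (conc + 2.4) + rnorm(16, 0, 3)
  fit <- fit_ic50(conc, inh)
  ref <- minpack.lm::nlsLM(inh ~ 100 / (1 + (ic50 / conc)^hill),
                           start = list(ic50 = 1, hill = 1),
                           lower = c(1e-6, 0.1), upper = c(1e6, 10))
  expect_equal(unname(coef(fit)["ic50"]), unname(coef(ref)["ic50"]),
               tolerance = 1e-4)
  expect_equal(fit$sse, sum(residuals(ref)^2), tolerance = 1e-6)
})

test_that("fit is invariant to point order and rescales with units", {
  set.seed(5)
  conc <- rep(50 / 2^(0:7), each = 2)
  inh <- 100 * conc / (conc + 1.8) + rnorm(16, 0, 2)
  fit <- fit_ic50(conc, inh)
  perm <- sample(length(conc))
  expect_equal(unname(coef(fit_ic50(conc[perm], inh[perm]))["ic50"]),
               unname(coef(fit)["ic50"]), tolerance = 1e-6)
  # uniform unit rescaling rescales the IC50 by the same factor
  fit10 <- fit_ic50(conc * 10, inh)
  expect_equal(unname(coef(fit10)["ic50"]),
               10 * unname(coef(fit)["ic50"]), tolerance = 1e-8)
})

test_that("predictions satisfy the 4PL identities", {
  pts <- exact_4pl_points(ic50 = 2)
  fit <- fit_ic50(pts$concentration, pts$inhibition)
  cf <- coef(fit)
  expect_equal(predict_inhibition(fit, cf["ic50"]),
               unname((cf["bottom"] + cf["top"]) / 2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(predict_inhibition(fit, 1e9), 100, tolerance = 1e-3)
  expect_equal(predict_inhibition(fit, 1e-9), 0, tolerance = 1e-3)
  # closed form: hill 1, ic50 2, c = 6 -> 100 * 6 / 8
  expect_equal(predict_inhibition(fit, 6), 75, tolerance = 1e-4)
  expect_error(predict_inhibition(fit, -1), "> 0")
})

test_that("free-asymptote QC mode recovers shifted asymptotes", {
  conc <- rep(50 / 2^(0:7), each = 2)
  inh <- 5 + (92 - 5) / (1 + (2 / conc)^1)
  fit <- fit_ic50(conc, inh, free_asymptotes = TRUE)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[c("bottom", "top", "ic50")]), c(5, 92, 2),
               tolerance = 1e-3)
})

test_that("bootstrap SD is deterministic given a seed and ~0 without noise", {
  sp <- simulate_plate(c(drugx = ki_from_ic50(2)), seed = 2)
  inh <- plate_inhibition(sp$wells)
  fit <- fit_ic50(inh$concentration_uM, inh$inhibition, inh$replicate)
  b1 <- bootstrap_ic50_sd(fit, n_boot = 150, seed = 7)
  b2 <- bootstrap_ic50_sd(fit, n_boot = 150, seed = 7)
  expect_identical(b1$estimates, b2$estimates)
  expect_gt(b1$sd, 0)
  # noiseless data: every resample refits the same exact curve
  pts <- exact_4pl_points(ic50 = 2)
  fit0 <- fit_ic50(pts$concentration, pts$inhibition)
  b0 <- bootstrap_ic50_sd(fit0, n_boot = 100, seed = 1)
  expect_lt(b0$sd, 1e-4)
  expect_error(bootstrap_ic50_sd(fit0, n_boot = 50, seed = 1), ">= 100")
  # RNG state of the session is untouched
  set.seed(123); before <- .Random.seed
  invisible(bootstrap_ic50_sd(fit, n_boot = 100, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("plate-level bootstrap sees control noise the point bootstrap misses", {
  sp <- simulate_plate(c(drugx = ki_from_ic50(2)), seed = 8)
  inh <- plate_inhibition(sp$wells)
  fit <- fit_ic50(inh$concentration_uM, inh$inhibition, inh$replicate)
  pb1 <- plate_bootstrap_ic50_sd(sp$wells, "drugx", n_boot = 150, seed = 3)
  pb2 <- plate_bootstrap_ic50_sd(sp$wells, "drugx", n_boot = 150, seed = 3)
  expect_identical(pb1$estimates, pb2$estimates)
  # resampled controls add the shared normalisation component
  pt <- bootstrap_ic50_sd(fit, n_boot = 150, seed = 3)
  expect_gt(pb1$sd, pt$sd)
  expect_error(plate_bootstrap_ic50_sd(sp$wells, "nosuch", n_boot = 150),
               "no test wells")
})

test_that("model methods expose residuals, summary and simulation", {
  set.seed(9)
  conc <- rep(50 / 2^(0:7), each = 2)
  inh <- 100 * conc / (conc + 2) + rnorm(16, 0, 2)
  fit <- fit_ic50(conc, inh)
  expect_equal(residuals(fit), inh - fitted(fit))
  expect_equal(length(fitted(fit)), 16)
  s <- summary(fit)
  expect_s3_class(s, "summary.ic50_fit")
  expect_equal(s$residual_sd, sqrt(fit$sse / 14))
  sims <- simulate(fit, nsim = 3, seed = 4)
  expect_equal(dim(sims), c(16, 3))
  expect_identical(simulate(fit, nsim = 3, seed = 4), sims)
  expect_output(print(fit), "IC50")
})

test_that("per-plate fitting returns one converged fit per compound", {
  sp <- simulate_plate(c(aaa = ki_from_ic50(1.5), bbb = ki_from_ic50(5)),
                       seed = 4)
  fits <- fit_plate_ic50(sp$wells, n_boot = 100, seed = 4)
  expect_named(fits, c("aaa", "bbb"))
  tab <- ic50_fit_table(fits)
  expect_true(all(tab$converged))
  expect_true(all(is.finite(tab$ic50_sd_uM)))
  expect_equal(tab$ic50_uM, sp$truth$ic50_true, tolerance = 0.15)
})
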