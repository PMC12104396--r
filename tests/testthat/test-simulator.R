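test_that("competitive-inhibition kinetics obey the closed-form anchors", {
  p <- kinetic_params(noise_cv = 0)
  v0 <- p$vmax * p$s / (p$km + p$s) * p$reaction_minutes
  expect_equal(simulate_rate(0, 5, p), v0)
  expect_lt(simulate_rate(1e9, 5, p), 1e-3 * v0)
  # the half-inhibition point sits at ki * (1 + s/km)
  ic50 <- ic50_from_ki(5, p)
  expect_equal(simulate_rate(ic50, 5, p), v0 / 2)
  expect_equal(ki_from_ic50(ic50_from_ki(3.7, p), p), 3.7)
  expect_error(simulate_rate(-1, 5, p), ">= 0")
  expect_error(kinetic_params(s = 20, km = 10), "low_substrate")
})

test_that("the simulation is deterministic given a seed", {
  s1 <- simulate_plate(c(a = 1, b = 4), seed = 99)
  s2 <- simulate_plate(c(a = 1, b = 4), seed = 99)
  expect_identical(s1$wells, s2$wells)
  s3 <- simulate_plate(c(a = 1, b = 4), seed = 100)
  expect_false(identical(s1$wells$rfu, s3$wells$rfu))
})

test_that("plates carry duplicates, controls, standards and valid layout", {
  sp <- simulate_plate(c(a = 1, b = 2, c = 3, d = 4, e = 5), seed = 1)
  w <- sp$wells
  expect_s3_class(validate_well_table(as.data.frame(w)), "well_table")
  expect_equal(length(unique(w$plate_id)), 2)  # 4 compounds/plate + overflow
  counts <- table(w$compound[w$role == "test"], w$conc_value[w$role == "test"])
  expect_true(all(counts == 2))  # duplicate wells at every concentration
  for (pid in unique(w$plate_id)) {
    p <- w[w$plate_id == pid, ]
    expect_gt(sum(p$role == "solvent_control"), 0)
    expect_gt(sum(p$role == "positive_control"), 0)
    expect_equal(sum(p$role == "standard"), 14)
    expect_equal(sum(p$role == "blank"), 2)
  }
  expect_equal(sp$truth$ic50_true,
               sp$truth$ki_true * (1 + sp$params$s / sp$params$km))
})

test_that("noiseless inhibition is exactly the hill-1 curve through ic50_true", {
  sp <- simulate_plate(c(drugx = ki_from_ic50(2)),
                       params = kinetic_params(noise_cv = 0), seed = 1)
  inh <- plate_inhibition(sp$wells)
  i <- inh$concentration_uM
  expect_equal(inh$inhibition, 100 * i / (i + 2), tolerance = 1e-10)
  # a well dosed exactly at ic50_true reads 50% inhibition
  p <- kinetic_params(noise_cv = 0)
  ctl_a <- p$background_rfu + p$fluorescence_gain * simulate_rate(0, 1, p)
  ctl_b <- p$background_rfu
  x <- p$background_rfu +
    p$fluorescence_gain * simulate_rate(2, ki_from_ic50(2), p)
  expect_equal(percent_inhibition(x, ctl_a, ctl_b), 50)
})

test_that("fitting noiseless simulator output recovers the ground truth", {
  for (ic50_true in c(0.5, 6.62)) {
    sp <- simulate_plate(c(x = ki_from_ic50(ic50_true)),
                         params = kinetic_params(noise_cv = 0), seed = 1)
    inh <- plate_inhibition(sp$wells)
    fit <- fit_ic50(inh$concentration_uM, inh$inhibition, inh$replicate)
    expect_lt(abs(coef(fit)["ic50"] / ic50_true - 1), 1e-3)
  }
})

test_that("mean simulated fluorescence converges to background + gain x product", {
  p <- kinetic_params(noise_cv = 0.05)
  expected <- p$background_rfu + p$fluorescence_gain * simulate_rate(0, 1, p)
  m <- vapply(1:300, function(s) {
    sp <- simulate_plate(c(x = 2), seed = s)
    mean(sp$wells$rfu[sp$wells$role == "solvent_control"])
  }, numeric(1))
  # SE of the grand mean ~ expected * cv / sqrt(300 * 4) ~ 0.14%
  expect_equal(mean(m), expected, tolerance = 0.01)
})

test_that("fixture suite is reproducible and triggers the degenerate path", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixture_suite(d1, seed = 101)
  f2 <- make_fixture_suite(d2, seed = 101)
  expect_true(all(file.exists(f1)))
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
  clean <- read_plate_csv(f1["clean"])
  expect_s3_class(clean, "well_table")
  degen <- read_plate_csv(f1["degenerate"])
  expect_error(aggregate_controls(degen), "solvent_control")
  truth <- jsonlite::read_json(f1[["clean_truth"]])
  expect_equal(truth$truth$omeprazole$ic50_true, 1.41, tolerance = 1e-9)
})
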