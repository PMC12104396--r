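test_that("percent inhibition hits its control-defined anchor points", {
  a <- 1000; b <- 100
  expect_equal(percent_inhibition(a, a, b), 0)
  expect_equal(percent_inhibition(b, a, b), 100)
  expect_equal(percent_inhibition((a + b) / 2, a, b), 50)
  # unclipped by default, clipped on request
  expect_gt(percent_inhibition(50, a, b), 100)
  expect_lt(percent_inhibition(1100, a, b), 0)
  expect_equal(percent_inhibition(c(50, 1100), a, b, clip = TRUE), c(100, 0))
})

test_that("percent inhibition is affine in the test signal", {
  set.seed(42)
  for (i in 1:50) {
    ab <- sort(runif(2, 0, 2000), decreasing = TRUE)
    a <- ab[1]; b <- ab[2]
    x1 <- runif(1, 0, 2000); x2 <- runif(1, 0, 2000)
    alpha <- runif(1)
    expect_equal(
      percent_inhibition(alpha * x1 + (1 - alpha) * x2, a, b),
      alpha * percent_inhibition(x1, a, b) +
        (1 - alpha) * percent_inhibition(x2, a, b))
    expect_equal(percent_inhibition(a, a, b), 0)
    expect_equal(percent_inhibition(b, a, b), 100)
  }
})

test_that("a zero assay window is a hard error", {
  expect_error(percent_inhibition(500, 300, 300), "degenerate")
  expect_error(percent_inhibition(Inf, 1000, 100), "finite")
})

test_that("mass/molar conversion matches published unbound Cmax values", {
  expect_equal(mass_conc_to_molar(0.0112, 345.42), 0.0324, tolerance = 2e-3)
  expect_equal(mass_conc_to_molar(0.0045, 366.44), 0.0123, tolerance = 2e-3)
  expect_equal(mass_conc_to_molar(0, 500), 0)
  expect_error(mass_conc_to_molar(1, 0), "molecular_weight")
})

test_that("mass <-> molar conversion round-trips to machine precision", {
  set.seed(7)
  x <- runif(20, 1e-4, 100)
  mw <- runif(20, 100, 900)
  expect_equal(molar_to_mass_conc(mass_conc_to_molar(x, mw), mw), x)
  expect_equal(mass_conc_to_molar(molar_to_mass_conc(x, mw), mw), x)
})

test_that("dilution series follows the plate's geometric layout", {
  s <- build_dilution_series(500, 2, 7, unit = "nM")
  expect_equal(s$concentrations,
               c(500, 250, 125, 62.5, 31.25, 15.625, 7.8125))
  expect_equal(build_dilution_series(6.4, 2, 4, unit = "ug/mL")$concentrations,
               c(6.4, 3.2, 1.6, 0.8))
  expect_equal(build_dilution_series(9, 3, 2)$concentrations, c(9, 3))
  # consecutive ratio equals the fold exactly
  s2 <- build_dilution_series(17.3, 2.5, 8)
  expect_equal(s2$concentrations[-8] / s2$concentrations[-1], rep(2.5, 7))
  expect_true(all(diff(s2$concentrations) < 0))
  expect_error(build_dilution_series(10, 1, 4), "fold")
  expect_error(build_dilution_series(10, 2, 1), "n must")
})

test_that("controls are averaged at the RFU level with QC SDs", {
  p <- tiny_plate()
  ctl <- aggregate_controls(p)
  expect_equal(ctl$a_rfu, 1005)
  expect_equal(ctl$b_rfu, 105)
  expect_equal(ctl$a_sd, sd(c(1000, 1010)))
  expect_equal(ctl$blank_rfu, 50)
  # single well per role: value passes through, SD flagged undefined
  one <- p[p$well %in% c("A11", "A12"), ]
  ctl1 <- aggregate_controls(one)
  expect_equal(ctl1$a_rfu, 1000)
  expect_true(is.na(ctl1$a_sd))
  expect_error(aggregate_controls(p[p$role != "positive_control", ]),
               "positive_control")
})

test_that("well parsing normalises case and rejects off-plate coordinates", {
  expect_equal(parse_well(c("a1", "h12", "C07"))$well, c("A1", "H12", "C7"))
  expect_error(parse_well("I3"), "invalid")
  expect_error(parse_well("A13"), "invalid|range")
})

test_that("well-table invariants are enforced", {
  expect_error(well_table("p", "A1", "blank", conc_value = 5, rfu = 10),
               "blank")
  expect_error(well_table("p", "A1", "test", compound = "", conc_value = 1,
                          rfu = 10), "compound")
  expect_error(well_table("p", "A1", "test", compound = "x", conc_value = 0,
                          rfu = 10), "concentration")
  expect_error(well_table("p", "A1", "standard", conc_value = 1, rfu = -3),
               "rfu")
  expect_error(validate_well_table(rbind(tiny_plate(), tiny_plate()[1, ])),
               "duplicate")
})

test_that("plate CSV round-trips losslessly", {
  p <- tiny_plate()
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(p, f)
  back <- read_plate_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(p))
})

test_that("plate inhibition converts units and indexes replicates", {
  p <- tiny_plate()
  inh <- plate_inhibition(p)
  expect_equal(nrow(inh), 8)
  expect_equal(sort(unique(inh$replicate)), 1:2)
  # spot-check one well against the formula
  expect_equal(inh$inhibition[inh$concentration_uM == 8][1],
               percent_inhibition(300, 1005, 105))
  # ug/mL wells need a molecular weight
  p2 <- p
  p2$conc_unit[p2$role == "test"] <- "ug/mL"
  expect_error(plate_inhibition(p2), "molecular weight")
  inh2 <- plate_inhibition(p2, molecular_weights = c(drugx = 400))
  expect_equal(sort(unique(inh2$concentration_uM)),
               sort(mass_conc_to_molar(c(8, 4, 2, 1), 400)))
})

test_that("packaged PPI constants reproduce the published unbound Cmax", {
  prof <- ppi_constants()
  expect_setequal(tab2$name, setdiff(prof$name, "ticlopidine"))
  prof <- prof[match(tab2$name, prof$name), ]
  expect_equal(prof$cmax_ug_per_ml * prof$fu_plasma, tab2$cmax_u_ug_per_ml)
  rep_tab <- ppi_reported()
  expect_equal(rep_tab$ic50_uM[match(tab2$name, rep_tab$name)], tab2$ic50_uM)
})
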