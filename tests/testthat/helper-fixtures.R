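# Shared fixtures: the published five-PPI summary table (frozen from the
# packaged constants) and small hand-built plates.

tab2 <- data.frame(
  name = c("omeprazole", "lansoprazole", "pantoprazole", "rabeprazole",
           "ilaprazole"),
  ic50_uM = c(1.41, 1.65, 3.52, 6.43, 6.62),
  ic50_u_uM = c(70.5, 82.5, 176, 321.5, 331),
  ki_u_uM = c(35.25, 41.25, 88, 160.75, 165.5),
  cmax_u_ug_per_ml = c(0.0112, 0.0115, 0.025, 0.0062, 0.0045),
  cmax_u_uM = c(0.0324, 0.0311, 0.0652, 0.0173, 0.0123),
  ratio_printed = c(0.0288, 0.00332, 0.00124, 0.000635, 0.00224),
  stringsAsFactors = FALSE)

potency_order <- c("omeprazole", "lansoprazole", "pantoprazole",
                   "rabeprazole", "ilaprazole")

# minimal valid plate: 2 solvent + 2 positive controls, one compound in
# duplicate at 4 concentrations, blanks
tiny_plate <- function(a = c(1000, 1010), b = c(100, 110)) {
  conc <- c(8, 4, 2, 1)
  rfu <- rep(c(300, 500, 700, 850), each = 2)  # arbitrary monotone signal
  well_table(
    plate_id = "p1",
    well = c("A11", "B11", "A12", "B12", "H1",
             paste0(rep(LETTERS[1:4], each = 2), rep(3:4, 4))),
    role = c("solvent_control", "solvent_control", "positive_control",
             "positive_control", "blank", rep("test", 8)),
    compound = c(rep("", 5), rep("drugx", 8)),
    conc_value = c(rep(0, 5), rep(conc, each = 2)),
    conc_unit = "uM",
    rfu = c(a, b, 50, rfu))
}

# exact hill = 1 responses, duplicated
exact_4pl_points <- function(ic50 = 2, n = 8, top_conc = 50, reps = 2) {
  conc <- rep(top_conc / 2^(0:(n - 1)), each = reps)
  list(concentration = conc, inhibition = 100 * conc / (conc + ic50))
}
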