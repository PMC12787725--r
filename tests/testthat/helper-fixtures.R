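# Printed single-metal pollution and ecological index values for the
# contaminated soil (registry order Cu, Cr, Zn, Cd, Pb, As).
printed_pi <- function() {
  c(Cu = 0.65, Cr = 0.32, Zn = 1.96, Cd = 3.35, Pb = 4.66, As = 5.92)
}

printed_ei <- function() {
  c(Cu = 3.26, Cr = 0.65, Zn = 1.96, Cd = 100.43, Pb = 23.30, As = 59.24)
}

# Published per-cell hazard quotients and carcinogenic risks for the six
# metals, four pathways and two populations; CR is NA where no slope factor
# exists (Cu, Zn entirely; Pb dermal). Used to check the aggregation margins.
table3_cells <- function() {
  pw <- c("food", "ing", "inh", "der")
  row <- function(population, metal, hq, cr) {
    tibble::tibble(population = population, metal = metal, pathway = pw,
                   hq = hq, cr = cr)
  }
  none <- rep(NA_real_, 4)
  dplyr::bind_rows(
    row("adult", "Cu", c(7.72e-1, 5.21e-4, 3.05e-14, 3.46e-5), none),
    row("child", "Cu", c(1.61, 3.19e-3, 3.55e-14, 1.19e-4), none),
    row("adult", "Cr", c(11.63, 7.43e-3, 4.59e-10, 1.48e-4),
        c(1.74e-2, 1.11e-5, 5.51e-13, 8.90e-6)),
    row("child", "Cr", c(24.38, 4.55e-2, 5.33e-10, 5.10e-4),
        c(3.66e-2, 6.82e-5, 6.41e-13, 3.06e-5)),
    row("adult", "Zn", c(1.01, 5.23e-4, 3.08e-13, 5.22e-5), none),
    row("child", "Zn", c(2.12, 3.20e-3, 3.58e-13, 1.79e-4), none),
    row("adult", "Cd", c(1.93, 6.42e-4, 3.78e-13, 1.28e-3),
        c(1.18e-2, 3.92e-6, 2.38e-15, 7.81e-8)),
    row("child", "Cd", c(4.05, 3.93e-3, 4.39e-13, 4.40e-3),
        c(2.47e-2, 2.40e-5, 2.77e-15, 2.69e-7)),
    row("adult", "Pb", c(5.38, 5.96e-2, 3.48e-11, 7.92e-3),
        c(1.60e-4, 1.77e-6, 5.15e-15, NA)),
    row("child", "Pb", c(11.27, 3.65e-1, 4.05e-11, 2.72e-2),
        c(3.35e-4, 1.09e-5, 5.99e-15, NA)),
    row("adult", "As", c(28.23, 1.58e-1, 2.26e-10, 2.30e-1),
        c(1.27e-2, 7.10e-5, 4.20e-13, 1.04e-4)),
    row("child", "As", c(59.18, 9.66e-1, 2.63e-10, 7.92e-1),
        c(2.66e-2, 4.35e-4, 4.89e-13, 3.56e-4))
  )
}

# tiny concentration CSV written on the fly
write_soil_csv <- function(path, concentrations = c(Cu = 65.18, Cr = 69.75,
                                                    Zn = 490.87, Cd = 2.01,
                                                    Pb = 652.34, As = 148.11),
                           group = "contaminated") {
  tbl <- tibble::tibble(sample_id = "S01", group = group,
                        metal = names(concentrations),
                        concentration = unname(concentrations))
  readr::write_csv(tbl, path)
  path
}
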