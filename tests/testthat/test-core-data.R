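test_that("soil CSV loading validates schema, values and metals", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_soil_csv(path)
  tbl <- read_concentration_table(path, "soil")
  expect_equal(nrow(tbl), 6)
  expect_true(all(tbl$group == "contaminated"))
  expect_true(all(tbl$tissue == "soil"))
  expect_equal(tbl$concentration[tbl$metal == "Pb"], 652.34)

  # header-only file is a valid empty table
  writeLines("sample_id,group,metal,concentration", path)
  expect_equal(nrow(read_concentration_table(path, "soil")), 0)

  # missing column named in the error
  writeLines(c("sample_id,metal,concentration", "S01,Cu,1.0"), path)
  expect_error(read_concentration_table(path, "soil"), "group")

  # negative concentration rejected with its row index
  writeLines(c("sample_id,group,metal,concentration",
               "S01,contaminated,Cu,1.0",
               "S02,contaminated,Cu,-1.0"), path)
  expect_error(read_concentration_table(path, "soil"), "negative.*2")

  # unknown metal rejected
  writeLines(c("sample_id,group,metal,concentration",
               "S01,contaminated,Hg,1.0"), path)
  expect_error(read_concentration_table(path, "soil"), "Hg")
})

test_that("concentration tables round-trip through CSV bit-identically", {
  d <- generate_dataset(generator_config(seed = 11))
  for (kind in c("soil", "tissue")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_concentration_table(d[[kind]], path)
    back <- read_concentration_table(path, kind)
    expect_identical(back$concentration, d[[kind]]$concentration)
    expect_identical(back[c("sample_id", "stage", "tissue", "metal", "group")],
                     d[[kind]][c("sample_id", "stage", "tissue", "metal",
                                 "group")])
  }
})

test_that("tissue tables reject grain at tillering and duplicate keys", {
  row <- tibble::tibble(sample_id = "S01", stage = "tillering",
                        tissue = "grain", metal = "Cd", concentration = 0.1,
                        group = "contaminated")
  expect_error(validate_concentration_table(row, "tissue"), "tillering")
  dup <- tibble::tibble(sample_id = "S01", stage = "maturity",
                        tissue = "grain", metal = c("Cd", "Cd"),
                        concentration = c(0.1, 0.2), group = "contaminated")
  expect_error(validate_concentration_table(dup, "tissue"), "duplicate")
})

test_that("parameter-set validation reports every gap and notes CR exclusions", {
  exposure <- list(adult = exposure_parameters("adult"),
                   child = exposure_parameters("child"))
  ref <- toxicology_references()
  full <- validate_parameter_sets(gb15618_screening("paddy", 6.15),
                                  toxic_response_factors(), exposure, ref)
  expect_equal(nrow(full[full$severity == "missing", ]), 0)
  # absent slope factors are exclusions, not blockers: Pb dermal among them
  excl <- full[full$severity == "excluded", ]
  expect_true(any(excl$metal == "Pb" & grepl("der", excl$parameter)))

  # a screening value dropped for Cd is reported as missing
  std5 <- structure(unclass(gb15618_screening("paddy", 6.15))[-4],
                    class = "screening_standards")
  rep <- validate_parameter_sets(std5, toxic_response_factors(), exposure, ref)
  expect_true(any(rep$metal == "Cd" &
                    rep$parameter == "screening standard" &
                    rep$severity == "missing"))
})

test_that("exposure parameter sets enforce positivity and averaging times", {
  expect_error(exposure_parameters("adult", BW = -1), "BW")
  expect_error(exposure_parameters("adult", ABS = 2), "ABS")
  expect_error(exposure_parameters("adult", AT_nc = 100), "ED x 365")
  expect_error(exposure_parameters("adult", bogus = 1), "bogus")
  p <- exposure_parameters("child", BW = 16)
  expect_equal(p$BW, 16)
  expect_equal(p$population, "child")
})

test_that("screening constructors carry provenance and reject gaps", {
  std <- gb15618_screening("paddy", ph = 6.15)
  expect_match(attr(std, "provenance"), "GB 15618-2018")
  expect_match(attr(std, "provenance"), "5.5<pH<=6.5")
  expect_error(screening_standards(c(Cu = 100)), "missing")
  expect_error(screening_standards(stats::setNames(c(-1, 1, 1, 1, 1, 1),
                                                   hm_metals())),
               "positive")
  expect_match(attr(screening_backcalc(), "provenance"), "synthetic")
})
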