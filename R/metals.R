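#' Metals assessed by the pipeline
#'
#' The six heavy metals covered by the assessment, in their fixed registry
#' order. This order is also the tie-break order wherever factor values are
#' ranked.
#'
#' @return Character vector `c("Cu", "Cr", "Zn", "Cd", "Pb", "As")`.
#' @export
#' @examples
#' hm_metals()
hm_metals <- function() {
  c("Cu", "Cr", "Zn", "Cd", "Pb", "As")
}

#' Growth stages and tissues recognised by the pipeline
#'
#' @return Character vectors of the rice growth stages (`hm_stages()`) and
#'   plant tissues plus soil (`hm_tissues()`).
#' @export
hm_stages <- function() c("tillering", "heading", "maturity")

#' @rdname hm_stages
#' @export
hm_tissues <- function() c("soil", "root", "stem", "leaf", "grain")

#' Validate metal symbols
#'
#' @param x character vector of candidate metal symbols.
#' @return `x`, unchanged, if every element is a registered metal.
#' @export
as_metal <- function(x) {
  bad <- setdiff(unique(x), hm_metals())
  if (length(bad) > 0) {
    stop("unknown metal symbol(s): ", paste(bad, collapse = ", "),
         "; registered metals are ", paste(hm_metals(), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Hakanson toxic response factors
#'
#' Dimensionless toxicity weights used by the potential ecological risk index
#' (EI = T_i x PI). Defaults are the standard Hakanson factors for the six
#' assessed metals.
#'
#' @param values optional named numeric vector overriding the defaults; names
#'   must be registered metals and values strictly positive.
#' @return Named numeric vector over all six metals, class
#'   `"toxic_response_factors"`.
#' @export
#' @examples
#' toxic_response_factors()
toxic_response_factors <- function(values = NULL) {
  defaults <- c(Cu = 5, Cr = 2, Zn = 1, Cd = 30, Pb = 5, As = 10)
  if (!is.null(values)) {
    as_metal(names(values))
    if (any(!is.finite(values) | values <= 0)) {
      stop("toxic response factors must be strictly positive", call. = FALSE)
    }
    defaults[names(values)] <- values
  }
  structure(defaults[hm_metals()], class = "toxic_response_factors")
}

#' Soil screening standards
#'
#' A set of regulatory screening values S_i (mg/kg dry weight) against which
#' soil concentrations are indexed (PI = C_i / S_i). No default is assumed:
#' the screening set in force depends on land use and soil pH band, so it is
#' always explicit and is echoed in every report.
#'
#' @param values named numeric vector, mg/kg, one strictly positive entry per
#'   assessed metal.
#' @param provenance free-text note naming the standard and pH band.
#' @return A `screening_standards` object (named numeric with a `provenance`
#'   attribute).
#' @seealso [gb15618_screening()] for packaged GB 15618-2018 sets,
#'   [screening_backcalc()] for the synthetic reconstructed set.
#' @export
screening_standards <- function(values, provenance = "user supplied") {
  as_metal(names(values))
  missing <- setdiff(hm_metals(), names(values))
  if (length(missing) > 0) {
    stop("screening standard missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values) | values <= 0)) {
    stop("screening standards must be strictly positive", call. = FALSE)
  }
  structure(values[hm_metals()], provenance = provenance,
            class = "screening_standards")
}

#' GB 15618-2018 risk screening values
#'
#' Packaged screening sets from the Chinese agricultural-land soil quality
#' standard GB 15618-2018, keyed by land use (paddy field vs other farmland)
#' and soil pH band. Values are mg/kg dry weight.
#'
#' @param land_use `"paddy"` or `"other"`.
#' @param ph soil pH used to select the band: <=5.5, (5.5, 6.5], (6.5, 7.5],
#'   >7.5.
#' @return A [screening_standards()] set with provenance recorded.
#' @export
#' @examples
#' gb15618_screening("paddy", ph = 6.15)
gb15618_screening <- function(land_use = c("paddy", "other"), ph) {
  land_use <- match.arg(land_use)
  stopifnot(is.numeric(ph), length(ph) == 1, is.finite(ph))
  band <- if (ph <= 5.5) 1L else if (ph <= 6.5) 2L else if (ph <= 7.5) 3L else 4L
  tabs <- list(
    paddy = rbind(
      Cu = c(150, 150, 200, 200),
      Cr = c(250, 250, 300, 350),
      Zn = c(200, 200, 250, 300),
      Cd = c(0.3, 0.4, 0.6, 0.8),
      Pb = c(80, 100, 140, 240),
      As = c(30, 30, 25, 20)
    ),
    other = rbind(
      Cu = c(50, 50, 100, 100),
      Cr = c(150, 150, 200, 250),
      Zn = c(200, 200, 250, 300),
      Cd = c(0.3, 0.3, 0.3, 0.6),
      Pb = c(70, 90, 120, 170),
      As = c(40, 40, 30, 25)
    )
  )
  vals <- tabs[[land_use]][, band]
  band_label <- c("pH<=5.5", "5.5<pH<=6.5", "6.5<pH<=7.5", "pH>7.5")[band]
  screening_standards(
    vals,
    provenance = sprintf("GB 15618-2018 risk screening values, %s land, %s",
                         land_use, band_label)
  )
}

#' Synthetic screening set reconstructed from index ratios
#'
#' A screening set back-calculated so that the packaged contaminated-soil
#' concentration means divided by these values reproduce a reference set of
#' single-metal pollution indices. It is a synthetic reconstruction, not a
#' regulatory standard (the Cr entry matches no GB 15618-2018 band); it exists
#' so that end-to-end synthetic runs exercise a realistic PI ordering.
#'
#' @return A [screening_standards()] set flagged as synthetic in its
#'   provenance.
#' @export
screening_backcalc <- function() {
  screening_standards(
    c(Cu = 100, Cr = 218, Zn = 250, Cd = 0.6, Pb = 140, As = 25),
    provenance = "synthetic: back-calculated from reference PI ratios, not a regulatory standard"
  )
}

#' Exposure parameter sets
#'
#' Population-specific constants of the average-daily-intake model. Defaults
#' follow widely used Chinese/US-EPA exposure handbook values; all are
#' overridable. Units: `IR` rice intake kg/day, `IngR` soil ingestion mg/day,
#' `InhR` inhalation m^3/day, `EF` exposure frequency days/year, `ED` exposure
#' duration years, `BW` body weight kg, `AT_nc`/`AT_ca` averaging time days
#' for non-carcinogenic (ED x 365) and carcinogenic (70 y lifetime) effects,
#' `SA` exposed skin cm^2, `AF` soil adherence mg/cm^2/day, `ABS` dermal
#' absorption fraction, `PEF` particle emission factor m^3/kg.
#'
#' @param population `"adult"` or `"child"`.
#' @param ... named overrides of any parameter listed above.
#' @return A named list of parameters, class `"exposure_parameters"`.
#' @export
#' @examples
#' exposure_parameters("adult")
#' exposure_parameters("child", BW = 16)
exposure_parameters <- function(population = c("adult", "child"), ...) {
  population <- match.arg(population)
  p <- switch(population,
    adult = list(IR = 0.3, IngR = 100, InhR = 14.5, EF = 350, ED = 24,
                 BW = 60, AT_nc = 24 * 365, AT_ca = 70 * 365,
                 SA = 5700, AF = 0.07, ABS = 0.001, PEF = 1.36e9),
    child = list(IR = 0.2, IngR = 200, InhR = 7.5, EF = 350, ED = 6,
                 BW = 15, AT_nc = 6 * 365, AT_ca = 70 * 365,
                 SA = 2800, AF = 0.2, ABS = 0.001, PEF = 1.36e9)
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad) > 0) {
      stop("unknown exposure parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(overrides)] <- overrides
  }
  p$population <- population
  validate_exposure_parameters(p)
  structure(p, class = "exposure_parameters")
}

validate_exposure_parameters <- function(p) {
  num <- c("IR", "IngR", "InhR", "EF", "ED", "BW", "AT_nc", "AT_ca",
           "SA", "AF", "ABS", "PEF")
  for (nm in num) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("exposure parameter ", nm, " must be strictly positive",
           call. = FALSE)
    }
  }
  if (any(p$ABS > 1)) stop("ABS must lie in (0, 1]", call. = FALSE)
  if (any(p$AT_nc < p$ED * 365) || any(p$AT_ca < p$ED * 365)) {
    stop("averaging times must be at least ED x 365 days", call. = FALSE)
  }
  invisible(p)
}

#' Toxicological reference values (RfD and slope factors)
#'
#' Reference doses RfD (mg/kg/day) for the hazard quotient and carcinogenic
#' slope factors SF ((mg/kg/day)^-1) for the carcinogenic risk, per metal and
#' exposure pathway (`food`, `ing`, `inh`, `der`). The food pathway shares the
#' oral values. Defaults are standard US EPA IRIS / RAIS values commonly used
#' in soil heavy-metal assessments; slope factors are absent (`NA`) where no
#' value is established (Cu and Zn throughout; Pb dermal), and absent cells
#' are excluded from carcinogenic sums rather than treated as zero.
#'
#' @param rfd,sf optional tibbles with columns `metal`, `pathway`, `value`
#'   overriding individual default entries.
#' @return A tibble with columns `metal`, `pathway`, `rfd`, `sf`, class
#'   `"toxicology_references"` prepended.
#' @export
#' @examples
#' toxicology_references()
toxicology_references <- function(rfd = NULL, sf = NULL) {
  oral_rfd <- c(Cu = 4e-2, Cr = 3e-3, Zn = 3e-1, Cd = 1e-3, Pb = 3.5e-3,
                As = 3e-4)
  inh_rfd  <- c(Cu = 4.02e-2, Cr = 2.86e-5, Zn = 3e-1, Cd = 1e-3,
                Pb = 3.52e-3, As = 3.01e-4)
  der_rfd  <- c(Cu = 1.2e-2, Cr = 6e-5, Zn = 6e-2, Cd = 1e-5, Pb = 5.25e-4,
                As = 1.23e-4)
  oral_sf  <- c(Cu = NA, Cr = 0.5, Zn = NA, Cd = 6.1, Pb = 8.5e-3, As = 1.5)
  inh_sf   <- c(Cu = NA, Cr = 42, Zn = NA, Cd = 6.3, Pb = 4.2e-2, As = 15.1)
  der_sf   <- c(Cu = NA, Cr = 20, Zn = NA, Cd = 6.1, Pb = NA, As = 3.66)

  tab <- tibble::tibble(
    metal = rep(hm_metals(), times = 4),
    pathway = rep(c("food", "ing", "inh", "der"), each = 6),
    rfd = c(oral_rfd, oral_rfd, inh_rfd, der_rfd),
    sf = c(oral_sf, oral_sf, inh_sf, der_sf)
  )
  patch <- function(tab, repl, col) {
    if (is.null(repl)) return(tab)
    stopifnot(all(c("metal", "pathway", "value") %in% names(repl)))
    as_metal(repl$metal)
    for (i in seq_len(nrow(repl))) {
      sel <- tab$metal == repl$metal[i] & tab$pathway == repl$pathway[i]
      if (!any(sel)) stop("unknown (metal, pathway): ", repl$metal[i], ", ",
                          repl$pathway[i], call. = FALSE)
      tab[[col]][sel] <- repl$value[i]
    }
    tab
  }
  tab <- patch(tab, rfd, "rfd")
  tab <- patch(tab, sf, "sf")
  if (any(!is.finite(tab$rfd) | tab$rfd <= 0)) {
    stop("every (metal, pathway) must have a strictly positive RfD",
         call. = FALSE)
  }
  if (any(!is.na(tab$sf) & tab$sf <= 0)) {
    stop("slope factors must be strictly positive where present",
         call. = FALSE)
  }
  class(tab) <- c("toxicology_references", class(tab))
  tab
}

#' Read a concentration table from CSV
#'
#' Reads and validates a soil or plant-tissue heavy-metal concentration table.
#' Soil files need columns `sample_id`, `group`, `metal`, `concentration`;
#' tissue files additionally need `stage` and `tissue`. Concentrations are
#' mg/kg dry weight and must be non-negative; metals outside the registry and
#' duplicate keys are rejected.
#'
#' @param path path to a CSV file (RFC 4180, UTF-8, "." decimal).
#' @param kind `"soil"` or `"tissue"`.
#' @return A validated tibble. Soil tables carry `stage = NA` and
#'   `tissue = "soil"` so both kinds share one layout.
#' @export
read_concentration_table <- function(path, kind = c("soil", "tissue")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("sample_id", "group", "metal", "concentration")
  if (kind == "tissue") needed <- c(needed, "stage", "tissue")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  if (kind == "soil") {
    raw$stage <- NA_character_
    raw$tissue <- "soil"
  }
  conc <- suppressWarnings(as.numeric(raw$concentration))
  bad <- which(is.na(conc) & !is.na(raw$concentration) | is.na(raw$concentration))
  if (length(bad) > 0) {
    stop("validation error: non-numeric concentration at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  neg <- which(conc < 0)
  if (length(neg) > 0) {
    stop("validation error: negative concentration at row(s) ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::tibble(
    sample_id = raw$sample_id,
    stage = raw$stage,
    tissue = raw$tissue,
    metal = raw$metal,
    concentration = conc,
    group = raw$group
  )
  validate_concentration_table(tbl, kind)
}

#' @rdname read_concentration_table
#' @param tbl a concentration tibble as returned by
#'   [read_concentration_table()] or the synthetic generator.
#' @export
write_concentration_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

validate_concentration_table <- function(tbl, kind = c("soil", "tissue")) {
  kind <- match.arg(kind)
  if (nrow(tbl) == 0) return(tbl)
  as_metal(tbl$metal)
  if (any(!tbl$group %in% c("contaminated", "control"))) {
    stop("group must be 'contaminated' or 'control'", call. = FALSE)
  }
  if (kind == "tissue") {
    if (any(!tbl$stage %in% hm_stages())) {
      stop("stage must be one of ", paste(hm_stages(), collapse = ", "),
           call. = FALSE)
    }
    if (any(!tbl$tissue %in% setdiff(hm_tissues(), "soil"))) {
      stop("tissue must be one of root, stem, leaf, grain", call. = FALSE)
    }
    if (any(tbl$tissue == "grain" & tbl$stage == "tillering")) {
      stop("grain records are not defined at tillering", call. = FALSE)
    }
  }
  key <- paste(tbl$sample_id, tbl$stage, tbl$tissue, tbl$metal, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, stage, tissue, metal) records", call. = FALSE)
  }
  if (any(tbl$concentration < 0)) {
    stop("validation error: negative concentration", call. = FALSE)
  }
  tbl
}

#' Check that parameter sets cover the requested metals
#'
#' Report-only completeness check run before the pipeline: lists every
#' missing (metal, parameter) pair across the screening standards, toxic
#' response factors, exposure parameters and RfD/SF tables. Absent slope
#' factors are noted as carcinogenic-risk exclusions, not errors, since the
#' model drops those cells from the sums.
#'
#' @param std a [screening_standards()] set (or `NULL` to flag all metals).
#' @param tox a [toxic_response_factors()] set.
#' @param exposure a list of [exposure_parameters()] sets.
#' @param ref a [toxicology_references()] table.
#' @param metals metals the pipeline will assess.
#' @return A tibble with columns `metal`, `parameter`, `severity`
#'   (`"missing"` blocks the run, `"excluded"` is informational). Zero
#'   blocking rows means the pipeline can run end-to-end.
#' @export
validate_parameter_sets <- function(std, tox, exposure, ref,
                                    metals = hm_metals()) {
  as_metal(metals)
  report <- tibble::tibble(metal = character(), parameter = character(),
                           severity = character())
  add <- function(report, metal, parameter, severity) {
    dplyr::bind_rows(report, tibble::tibble(metal = metal,
                                            parameter = parameter,
                                            severity = severity))
  }
  std_have <- if (is.null(std)) character() else names(std)
  for (m in setdiff(metals, std_have)) {
    report <- add(report, m, "screening standard", "missing")
  }
  tox_have <- if (is.null(tox)) character() else names(tox)
  for (m in setdiff(metals, tox_have)) {
    report <- add(report, m, "toxic response factor", "missing")
  }
  if (is.null(exposure) || length(exposure) == 0) {
    report <- add(report, NA_character_, "exposure parameters", "missing")
  } else {
    for (p in exposure) validate_exposure_parameters(p)
  }
  if (is.null(ref)) {
    for (m in metals) report <- add(report, m, "RfD table", "missing")
  } else {
    for (m in metals) {
      for (pw in c("food", "ing", "inh", "der")) {
        row <- ref[ref$metal == m & ref$pathway == pw, ]
        if (nrow(row) == 0 || is.na(row$rfd)) {
          report <- add(report, m, paste0("RfD (", pw, ")"), "missing")
        } else if (is.na(row$sf)) {
          report <- add(report, m, paste0("SF (", pw, ") - CR cell excluded"),
                        "excluded")
        }
      }
    }
  }
  report
}
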