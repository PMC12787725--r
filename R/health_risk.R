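#' Average daily intake through rice consumption
#'
#' ADI_food = C_rice x IR x EF x ED / (BW x AT), mg per kg body weight per
#' day. The averaging time is `AT_nc` for non-carcinogenic and `AT_ca`
#' (lifetime) for carcinogenic assessment.
#'
#' @param c_rice metal concentration in rice grain, mg/kg, >= 0.
#' @param p an [exposure_parameters()] set (vector-valued components are
#'   allowed, e.g. Monte Carlo draws).
#' @param averaging `"nc"` (non-carcinogenic) or `"ca"` (carcinogenic).
#' @return ADI in mg/kg/day.
#' @export
#' @examples
#' adi_food(0.5, exposure_parameters("adult"))
adi_food <- function(c_rice, p, averaging = c("nc", "ca")) {
  averaging <- match.arg(averaging)
  if (any(c_rice < 0)) stop("rice concentration must be >= 0", call. = FALSE)
  at <- if (averaging == "nc") p$AT_nc else p$AT_ca
  c_rice * p$IR * p$EF * p$ED / (p$BW * at)
}

#' Average daily intake from soil exposure
#'
#' The three direct soil pathways, mg per kg body weight per day:
#' \describe{
#'   \item{ing}{C_soil x IngR x EF x ED / (BW x AT) x 1e-6}
#'   \item{inh}{C_soil x InhR x EF x ED / (PEF x BW x AT) x 1e-6}
#'   \item{der}{C_soil x SA x AF x ABS x EF x ED / (BW x AT) x 1e-6}
#' }
#' The 1e-6 factor converts mg of soil to kg and applies only to these soil
#' pathways, not to rice consumption.
#'
#' @param c_soil metal concentration in soil, mg/kg, >= 0.
#' @param p an [exposure_parameters()] set.
#' @param pathway `"ing"`, `"inh"` or `"der"` (for food use [adi_food()]).
#' @param averaging `"nc"` or `"ca"`.
#' @return ADI in mg/kg/day.
#' @export
adi_soil <- function(c_soil, p, pathway = c("ing", "inh", "der"),
                     averaging = c("nc", "ca")) {
  if (identical(pathway, "food")) {
    stop("pathway 'food' is computed by adi_food()", call. = FALSE)
  }
  pathway <- match.arg(pathway)
  averaging <- match.arg(averaging)
  if (any(c_soil < 0)) stop("soil concentration must be >= 0", call. = FALSE)
  at <- if (averaging == "nc") p$AT_nc else p$AT_ca
  base <- c_soil * p$EF * p$ED / (p$BW * at) * 1e-6
  switch(pathway,
    ing = base * p$IngR,
    inh = base * p$InhR / p$PEF,
    der = base * p$SA * p$AF * p$ABS
  )
}

#' Hazard quotient
#'
#' HQ = ADI / RfD: the non-carcinogenic dose relative to the reference dose
#' for that metal and pathway. HQ > 1 flags possible non-carcinogenic
#' effects.
#'
#' @param adi average daily intake, mg/kg/day.
#' @param rfd reference dose, mg/kg/day, > 0.
#' @return Dimensionless HQ.
#' @export
hazard_quotient <- function(adi, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    stop("RfD must be > 0", call. = FALSE)
  }
  adi / rfd
}

#' Carcinogenic risk
#'
#' CR = ADI x SF, the incremental lifetime cancer probability. Where no slope
#' factor is established the cell is absent (`NA`) and is excluded from the
#' total-risk sums rather than counted as zero.
#'
#' @param adi average daily intake, mg/kg/day, >= 0.
#' @param sf slope factor, (mg/kg/day)^-1, or `NA` when absent.
#' @return CR, or `NA` where `sf` is absent.
#' @export
carcinogenic_risk <- function(adi, sf) {
  if (any(adi < 0, na.rm = TRUE)) stop("ADI must be >= 0", call. = FALSE)
  ifelse(is.na(sf), NA_real_, adi * sf)
}

#' Build the per-cell risk table
#'
#' Computes ADI, HQ and CR for every (population, metal, pathway) cell from
#' grain and soil concentrations. Non-carcinogenic doses use `AT_nc`,
#' carcinogenic doses `AT_ca`.
#'
#' @param c_rice named numeric vector of grain concentrations per metal,
#'   mg/kg.
#' @param c_soil named numeric vector of soil concentrations per metal,
#'   mg/kg.
#' @param exposure named list of [exposure_parameters()] sets, one per
#'   population.
#' @param ref a [toxicology_references()] table.
#' @param metals metals to assess (default: those present in both inputs).
#' @return Tibble of cells: `population`, `metal`, `pathway`, `adi_nc`,
#'   `adi_ca`, `hq`, `cr`.
#' @export
risk_cells <- function(c_rice, c_soil,
                       exposure = list(adult = exposure_parameters("adult"),
                                       child = exposure_parameters("child")),
                       ref = toxicology_references(),
                       metals = NULL) {
  if (is.null(metals)) {
    metals <- intersect(hm_metals(), intersect(names(c_rice), names(c_soil)))
  }
  as_metal(metals)
  miss <- setdiff(metals, names(c_rice))
  if (length(miss) > 0) stop("no grain concentration for ",
                             paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(metals, names(c_soil))
  if (length(miss) > 0) stop("no soil concentration for ",
                             paste(miss, collapse = ", "), call. = FALSE)

  grid <- tidyr::expand_grid(population = names(exposure), metal = metals,
                             pathway = c("food", "ing", "inh", "der"))
  cell <- function(population, metal, pathway) {
    p <- exposure[[population]]
    if (pathway == "food") {
      adi_nc <- adi_food(c_rice[[metal]], p, "nc")
      adi_ca <- adi_food(c_rice[[metal]], p, "ca")
    } else {
      adi_nc <- adi_soil(c_soil[[metal]], p, pathway, "nc")
      adi_ca <- adi_soil(c_soil[[metal]], p, pathway, "ca")
    }
    row <- ref[ref$metal == metal & ref$pathway == pathway, ]
    tibble::tibble(population = population, metal = metal, pathway = pathway,
                   adi_nc = adi_nc, adi_ca = adi_ca,
                   hq = hazard_quotient(adi_nc, row$rfd),
                   cr = carcinogenic_risk(adi_ca, row$sf))
  }
  dplyr::bind_rows(Map(cell, grid$population, grid$metal, grid$pathway))
}

#' Aggregate a risk table to its margins
#'
#' Sums hazard quotients to per-metal totals and the hazard index
#' HI = sum(HQ), and carcinogenic risks to per-metal totals and the total
#' carcinogenic risk TCR = sum(CR). Sums are exact over the provided values;
#' absent CR cells (no slope factor) are skipped, and a metal with no CR cell
#' at all carries an absent total rather than zero.
#'
#' @param cells a [risk_cells()] tibble (columns `population`, `metal`,
#'   `pathway`, `hq`, `cr`; any extra columns are carried through).
#' @return A list of class `"risk_table"`: `cells`, `metal_totals`
#'   (`hq_total`, `cr_total` per population and metal), `pathway_totals`
#'   (column sums per population and pathway) and `grand` (`hi`, `tcr` per
#'   population, with threshold class labels).
#' @export
aggregate_risk <- function(cells) {
  stopifnot(all(c("population", "metal", "pathway", "hq", "cr") %in%
                  names(cells)))
  sum_or_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  # fix summation order (registry metals, food/ing/inh/der) so totals are
  # reproducible regardless of input row order
  cells <- dplyr::arrange(
    cells,
    .data$population,
    factor(.data$metal, levels = hm_metals()),
    factor(.data$pathway, levels = c("food", "ing", "inh", "der")))
  metal_totals <- cells |>
    dplyr::group_by(.data$population, .data$metal) |>
    dplyr::summarise(hq_total = sum(.data$hq),
                     cr_total = sum_or_na(.data$cr), .groups = "drop") |>
    dplyr::arrange(.data$population,
                   factor(.data$metal, levels = hm_metals()))
  pathway_totals <- cells |>
    dplyr::group_by(.data$population, .data$pathway) |>
    dplyr::summarise(hq_total = sum(.data$hq),
                     cr_total = sum_or_na(.data$cr), .groups = "drop") |>
    dplyr::arrange(.data$population,
                   factor(.data$pathway,
                          levels = c("food", "ing", "inh", "der")))
  grand <- metal_totals |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(hi = sum(.data$hq_total),
                     tcr = sum_or_na(.data$cr_total), .groups = "drop")
  grand$hi_class <- classify_risk(grand$hi, "HQ_HI")
  grand$tcr_class <- NA_character_
  ok <- !is.na(grand$tcr)
  grand$tcr_class[ok] <- classify_risk(grand$tcr[ok], "CR_TCR")
  structure(list(cells = cells, metal_totals = metal_totals,
                 pathway_totals = pathway_totals, grand = grand),
            class = "risk_table")
}

#' Classify a hazard or carcinogenic risk value
#'
#' Threshold comparisons are strict: HQ/HI above 1 indicates possible
#' non-carcinogenic effects (exactly 1 is assigned to the no-risk side);
#' CR/TCR above 1e-4 is unacceptable, within [1e-6, 1e-4] acceptable, below
#' 1e-6 no obvious risk.
#'
#' @param value risk value(s), >= 0.
#' @param kind `"HQ_HI"` or `"CR_TCR"`.
#' @return Character label(s).
#' @export
classify_risk <- function(value, kind = c("HQ_HI", "CR_TCR")) {
  kind <- match.arg(kind)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("risk value must be >= 0", call. = FALSE)
  }
  if (kind == "HQ_HI") {
    ifelse(value > 1, "risk", "no potential risk")
  } else {
    ifelse(value > 1e-4, "unacceptable",
           ifelse(value >= 1e-6, "acceptable", "no obvious risk"))
  }
}

#' @export
print.risk_table <- function(x, ...) {
  cat("Human health risk assessment\n\n")
  print(as.data.frame(risk_table_wide(x)), row.names = FALSE)
  g <- x$grand
  for (i in seq_len(nrow(g))) {
    cat(sprintf("%s: HI = %.3g (%s); TCR = %.3g (%s)\n", g$population[i],
                g$hi[i], g$hi_class[i], g$tcr[i], g$tcr_class[i]))
  }
  invisible(x)
}

#' Risk table in wide per-pathway layout
#'
#' One row per metal and population with HQ and CR columns per pathway plus
#' the marginal totals; the last rows carry the HI/TCR margins. Mirrors the
#' conventional published layout of soil health-risk tables.
#'
#' @param rt an [aggregate_risk()] result.
#' @return A tibble.
#' @export
risk_table_wide <- function(rt) {
  wide <- function(col) {
    tidyr::pivot_wider(rt$cells[, c("population", "metal", "pathway", col)],
                       names_from = "pathway", values_from = dplyr::all_of(col),
                       names_prefix = paste0(toupper(col), "_"))
  }
  out <- dplyr::left_join(wide("hq"), wide("cr"),
                          by = c("population", "metal"))
  out <- dplyr::left_join(out,
                          rt$metal_totals |>
                            dplyr::rename(HQ_total = "hq_total",
                                          CR_total = "cr_total"),
                          by = c("population", "metal"))
  margins <- dplyr::left_join(
    tidyr::pivot_wider(rt$pathway_totals[, c("population", "pathway",
                                             "hq_total")],
                       names_from = "pathway", values_from = "hq_total",
                       names_prefix = "HQ_"),
    tidyr::pivot_wider(rt$pathway_totals[, c("population", "pathway",
                                             "cr_total")],
                       names_from = "pathway", values_from = "cr_total",
                       names_prefix = "CR_"),
    by = "population")
  margins$metal <- "HI/TCR"
  margins <- dplyr::left_join(margins,
                              rt$grand |>
                                dplyr::select(population = "population",
                                              HQ_total = "hi",
                                              CR_total = "tcr"),
                              by = "population")
  ord <- c("population", "metal", "HQ_food", "HQ_ing", "HQ_inh", "HQ_der",
           "HQ_total", "CR_food", "CR_ing", "CR_inh", "CR_der", "CR_total")
  dplyr::bind_rows(out[, ord], margins[, ord])
}

#' Write a risk table as CSV
#'
#' @param rt an [aggregate_risk()] result.
#' @param path output CSV path. Values are written in full precision;
#'   formatted (3-significant-figure scientific) rendering is left to report
#'   consumers.
#' @export
write_risk_table <- function(rt, path) {
  readr::write_csv(risk_table_wide(rt), path, na = "")
  invisible(path)
}
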