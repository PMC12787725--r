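#' Single-metal pollution index
#'
#' PI = C_i / S_i: the soil concentration of a metal divided by its
#' regulatory screening value, both mg/kg dry weight.
#'
#' @param ci soil concentration(s), mg/kg, >= 0.
#' @param si screening standard(s), mg/kg, > 0.
#' @return Dimensionless PI at full precision.
#' @export
#' @examples
#' pollution_index(652.34, 140)
pollution_index <- function(ci, si) {
  if (any(!is.finite(si)) || any(si <= 0)) {
    stop("screening standard must be > 0", call. = FALSE)
  }
  if (any(!is.finite(ci)) || any(ci < 0)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  ci / si
}

#' Nemerow composite pollution index
#'
#' NIPI = sqrt((mean(PI)^2 + max(PI)^2) / 2), a composite that up-weights the
#' single worst metal. Algebraically PI_max / sqrt(2) <= NIPI <= PI_max.
#'
#' @param pis numeric vector of single-metal PI values, length >= 1, all
#'   >= 0.
#' @return The composite index.
#' @export
#' @examples
#' nemerow_index(c(5.92, 4.66, 3.35, 1.96, 0.65, 0.32))
nemerow_index <- function(pis) {
  if (length(pis) == 0) stop("NIPI undefined for an empty PI vector",
                             call. = FALSE)
  if (any(!is.finite(pis)) || any(pis < 0)) {
    stop("PI values must be finite and >= 0", call. = FALSE)
  }
  sqrt((mean(pis)^2 + max(pis)^2) / 2)
}

#' Hakanson single-metal ecological risk index
#'
#' EI = T_i x PI: the pollution index weighted by the metal's toxic response
#' factor.
#'
#' @param pi single-metal pollution index, >= 0.
#' @param ti toxic response factor, > 0.
#' @return Dimensionless EI.
#' @export
#' @examples
#' ecological_index(4.66, 5) # Pb
ecological_index <- function(pi, ti) {
  if (any(!is.finite(ti)) || any(ti <= 0)) {
    stop("toxic response factor must be > 0", call. = FALSE)
  }
  if (any(!is.finite(pi)) || any(pi < 0)) {
    stop("PI must be >= 0", call. = FALSE)
  }
  ti * pi
}

#' Hakanson integrated potential ecological risk index
#'
#' RI = sum of the single-metal EI values.
#'
#' @param eis numeric vector of EI values, length >= 1, all >= 0.
#' @return The integrated index.
#' @export
risk_index <- function(eis) {
  if (length(eis) == 0) stop("RI undefined for an empty EI vector",
                             call. = FALSE)
  if (any(!is.finite(eis)) || any(eis < 0)) {
    stop("EI values must be finite and >= 0", call. = FALSE)
  }
  sum(eis)
}

#' Default classification bands for the pollution and risk indices
#'
#' Conventional Nemerow / Hakanson class boundaries. Every band is half-open,
#' `[lower, upper)`, so each value falls in exactly one class. The tables are
#' config-overridable: pass a modified copy to [classify_index()] or
#' [assess_soil()].
#'
#' @return Named list of tibbles (`PI`, `NIPI`, `EI`, `RI`), each with
#'   columns `lower`, `upper`, `label`.
#' @export
default_index_bands <- function() {
  band <- function(lower, upper, label) {
    tibble::tibble(lower = lower, upper = upper, label = label)
  }
  list(
    PI = band(c(0, 1, 2, 3), c(1, 2, 3, Inf),
              c("unpolluted", "low", "moderate", "high")),
    NIPI = band(c(0, 0.7, 1, 2, 3), c(0.7, 1, 2, 3, Inf),
                c("safe", "warning", "light", "moderate", "high")),
    EI = band(c(0, 40, 80, 160, 320), c(40, 80, 160, 320, Inf),
              c("low", "moderate", "considerable", "high", "very high")),
    RI = band(c(0, 150, 300, 600), c(150, 300, 600, Inf),
              c("low", "moderate", "considerable", "very high"))
  )
}

#' Classify an index value
#'
#' Maps an index value to its class label using half-open `[lower, upper)`
#' bands: a value equal to a boundary falls in the class above it (PI exactly
#' 1 is "low", EI exactly 40 is "moderate"). Published band tables rarely
#' state which side a boundary belongs to; the half-open convention is
#' applied uniformly and documented here.
#'
#' @param value index value, >= 0.
#' @param scheme one of `"PI"`, `"NIPI"`, `"EI"`, `"RI"`.
#' @param bands band list as from [default_index_bands()].
#' @return Character class label.
#' @export
#' @examples
#' classify_index(100.43, "EI")
classify_index <- function(value, scheme, bands = default_index_bands()) {
  if (!scheme %in% names(bands)) {
    stop("unknown classification scheme: ", scheme, call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("index value must be >= 0", call. = FALSE)
  }
  tab <- bands[[scheme]]
  vapply(value, function(v) {
    hit <- which(v >= tab$lower & v < tab$upper)
    tab$label[hit[1]]
  }, character(1))
}

#' Soil pollution and ecological risk assessment
#'
#' Runs the full index chain on a soil concentration table: per-metal PI and
#' EI with class labels, the Nemerow composite NIPI and the integrated
#' ecological risk RI. Concentrations are averaged over replicate samples per
#' metal before indexing. The screening set used is echoed in the result so
#' reports always state the standard in force.
#'
#' @param soil soil concentration tibble.
#' @param std a [screening_standards()] set.
#' @param tox a [toxic_response_factors()] set.
#' @param bands classification bands, default [default_index_bands()].
#' @param group exposure group to assess, default `"contaminated"`.
#' @return A list of class `"index_result"`: `per_metal` tibble (`metal`,
#'   `concentration`, `si`, `pi`, `pi_class`, `ti`, `ei`, `ei_class`),
#'   composites `nipi`, `nipi_class`, `ri`, `ri_class`, and
#'   `screening_provenance`.
#' @export
assess_soil <- function(soil, std, tox = toxic_response_factors(),
                        bands = default_index_bands(),
                        group = "contaminated") {
  soil <- soil[soil$group == group, ]
  if (nrow(soil) == 0) stop("no soil records for group ", group, call. = FALSE)
  rep <- validate_parameter_sets(std, tox, exposure = NULL, ref = NULL,
                                 metals = unique(soil$metal))
  rep <- rep[rep$severity == "missing" &
               rep$parameter %in% c("screening standard",
                                    "toxic response factor"), ]
  if (nrow(rep) > 0) {
    stop("cannot assess: missing ", paste(rep$parameter, "for", rep$metal,
                                          collapse = "; "), call. = FALSE)
  }
  per <- soil |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(concentration = mean(.data$concentration),
                     .groups = "drop")
  per$metal <- factor(per$metal, levels = hm_metals())
  per <- dplyr::arrange(per, .data$metal)
  per$metal <- as.character(per$metal)
  per$si <- unclass(std)[per$metal]
  per$pi <- pollution_index(per$concentration, per$si)
  per$pi_class <- classify_index(per$pi, "PI", bands)
  per$ti <- unclass(tox)[per$metal]
  per$ei <- ecological_index(per$pi, per$ti)
  per$ei_class <- classify_index(per$ei, "EI", bands)

  nipi <- nemerow_index(per$pi)
  ri <- risk_index(per$ei)
  structure(list(
    per_metal = per,
    nipi = nipi, nipi_class = classify_index(nipi, "NIPI", bands),
    ri = ri, ri_class = classify_index(ri, "RI", bands),
    screening_provenance = attr(std, "provenance")
  ), class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat("Soil pollution / ecological risk assessment\n")
  cat("Screening standards:", x$screening_provenance, "\n\n")
  per <- x$per_metal
  per$pi <- round(per$pi, 2)
  per$ei <- round(per$ei, 2)
  print(as.data.frame(per), row.names = FALSE)
  cat(sprintf("\nNIPI = %.2f (%s); RI = %.2f (%s)\n",
              x$nipi, x$nipi_class, x$ri, x$ri_class))
  invisible(x)
}

#' Write an index assessment as CSV
#'
#' @param result an [assess_soil()] result.
#' @param path output CSV path; composites are appended as extra rows with
#'   `metal` set to `NIPI` / `RI`.
#' @export
write_index_result <- function(result, path) {
  per <- result$per_metal
  comp <- tibble::tibble(
    metal = c("NIPI", "RI"), concentration = NA, si = NA,
    pi = c(result$nipi, NA), pi_class = c(result$nipi_class, NA),
    ti = NA, ei = c(NA, result$ri), ei_class = c(NA, result$ri_class)
  )
  readr::write_csv(dplyr::bind_rows(per, comp), path, na = "")
  invisible(path)
}
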