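#' Percent change of a treated mean relative to control
#'
#' 100 x (treated - control) / control. Negative values are inhibition (a
#' growth endpoint suppressed by metal stress), positive values stimulation
#' (e.g. induced antioxidant enzyme activity or amino-acid exudation).
#'
#' @param treated_mean treated-group mean, in the endpoint's units.
#' @param control_mean control-group mean, same units, > 0.
#' @return Percent change (units cancel).
#' @export
#' @examples
#' percent_change(68.6, 100) # 31.4% inhibition
percent_change <- function(treated_mean, control_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    stop("control mean must be > 0", call. = FALSE)
  }
  100 * (treated_mean - control_mean) / control_mean
}

#' Endpoint labels used by the packaged generator
#'
#' Controlled vocabulary for the phytotoxicity endpoints: growth traits,
#' oxidative-stress markers (MDA and the antioxidant enzymes SOD, POD, CAT)
#' and rhizosphere amino acids. Free-text labels are also accepted
#' throughout.
#'
#' @return Character vector of endpoint labels.
#' @export
phytotox_endpoints <- function() {
  c("plant_height", "root_length", "aboveground_dry_weight",
    "root_dry_weight", "tiller_number", "panicle_emergence",
    "MDA", "SOD", "POD", "CAT",
    "Tau", "Ser", "Glu", "Gly", "Lys")
}

#' Percent-change summary of phytotoxicity endpoints
#'
#' For each (endpoint, stage, tissue) with matched contaminated and control
#' groups, reports the percent change of the treated mean relative to the
#' control mean, together with a replicate-level SD (the SD of per-replicate
#' percent changes against the control mean) and a direction label. No
#' significance testing is performed; the SDs let external tools test.
#'
#' @param table tibble with columns `endpoint`, `stage`, `tissue` (may be
#'   `NA` for whole-plant traits), `group` (`contaminated`/`control`),
#'   `value` (> 0, one row per replicate).
#' @return Tibble: `endpoint`, `stage`, `tissue`, `n_treated`, `n_control`,
#'   `control_mean`, `treated_mean`, `pct_change`, `pct_sd`, `direction`.
#' @export
endpoint_summary <- function(table) {
  stopifnot(all(c("endpoint", "stage", "group", "value") %in% names(table)))
  if (!"tissue" %in% names(table)) table$tissue <- NA_character_
  if (any(!table$group %in% c("contaminated", "control"))) {
    stop("group must be 'contaminated' or 'control'", call. = FALSE)
  }
  groups <- table |>
    dplyr::group_by(.data$endpoint, .data$stage, .data$tissue) |>
    dplyr::group_split()
  one <- function(g) {
    tr <- g$value[g$group == "contaminated"]
    ct <- g$value[g$group == "control"]
    if (length(ct) == 0) {
      stop("missing control group for endpoint '", g$endpoint[1], "' at ",
           g$stage[1], call. = FALSE)
    }
    if (length(tr) == 0) {
      stop("missing contaminated group for endpoint '", g$endpoint[1],
           "' at ", g$stage[1], call. = FALSE)
    }
    cm <- mean(ct)
    pct_i <- percent_change(tr, cm)
    pct <- mean(pct_i)
    tibble::tibble(
      endpoint = g$endpoint[1], stage = g$stage[1], tissue = g$tissue[1],
      n_treated = length(tr), n_control = length(ct),
      control_mean = cm, treated_mean = mean(tr),
      pct_change = pct,
      pct_sd = if (length(tr) > 1) stats::sd(pct_i) else NA_real_,
      direction = if (pct < 0) "inhibition" else if (pct > 0) "stimulation"
                  else "none")
  }
  dplyr::bind_rows(lapply(groups, one))
}
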