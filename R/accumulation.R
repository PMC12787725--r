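#' Concentration ratio
#'
#' Elementary ratio underlying every bioconcentration (BF) and translocation
#' (TF) factor: the concentration of a metal in a downstream compartment
#' divided by its concentration in the upstream compartment, both mg/kg dry
#' weight, so the result is dimensionless.
#'
#' @param numerator downstream concentration(s), mg/kg DW, >= 0.
#' @param denominator upstream concentration(s), mg/kg DW, > 0.
#' @return `numerator / denominator` at full precision.
#' @export
#' @examples
#' compute_ratio(3.9195, 2.01) # root Cd over soil Cd
compute_ratio <- function(numerator, denominator) {
  if (any(!is.finite(denominator)) || any(denominator <= 0)) {
    stop("ratio undefined: upstream concentration must be > 0", call. = FALSE)
  }
  if (any(!is.finite(numerator)) || any(numerator < 0)) {
    stop("numerator concentration must be >= 0", call. = FALSE)
  }
  numerator / denominator
}

# (kind, numerator tissue, denominator tissue) registry for the four factors
transfer_kinds <- function() {
  tibble::tibble(
    kind = c("BF_root_soil", "TF_stem_root", "TF_leaf_stem", "TF_grain_stem"),
    num = c("root", "stem", "leaf", "grain"),
    den = c("soil", "root", "stem", "stem")
  )
}

#' Bioconcentration and translocation factor table
#'
#' Computes, for every metal and growth stage present in the inputs, the four
#' soil-plant transfer factors: BF root/soil, TF stem/root, TF leaf/stem and
#' TF grain/stem. Ratios are formed per replicate sample (each sample's
#' tissue concentration over that same sample's upstream concentration) and
#' then aggregated to mean and SD across replicates; the ratio of group means
#' is deliberately not used. Factors whose numerator tissue is absent at a
#' stage (grain before heading) are reported as absent with a reason, never
#' as zero.
#'
#' @param tissue tissue concentration tibble (columns `sample_id`, `stage`,
#'   `tissue`, `metal`, `concentration`, `group`).
#' @param soil soil concentration tibble (one record per sample and metal).
#' @param group which exposure group to evaluate (default `"contaminated"`).
#' @return A tibble with columns `metal`, `stage`, `kind`, `mean`, `sd`, `n`,
#'   `absent`, `reason`, ordered by the metal registry.
#' @export
transfer_factors <- function(tissue, soil, group = "contaminated") {
  tissue <- tissue[tissue$group == group, ]
  soil <- soil[soil$group == group, ]
  if (nrow(soil) == 0) stop("no soil records for group ", group, call. = FALSE)
  if (anyDuplicated(paste(soil$sample_id, soil$metal))) {
    stop("soil table must hold one concentration per (sample, metal)",
         call. = FALSE)
  }
  kinds <- transfer_kinds()
  stages <- intersect(hm_stages(), unique(tissue$stage))
  metals <- intersect(hm_metals(), unique(tissue$metal))

  grid <- tidyr::expand_grid(metal = metals, stage = stages,
                             kind = kinds$kind)
  grid <- dplyr::left_join(grid, kinds, by = "kind")

  one_factor <- function(metal, stage, kind, num, den) {
    num_tab <- tissue[tissue$metal == metal & tissue$stage == stage &
                        tissue$tissue == num, ]
    if (den == "soil") {
      den_tab <- soil[soil$metal == metal, c("sample_id", "concentration")]
    } else {
      den_tab <- tissue[tissue$metal == metal & tissue$stage == stage &
                          tissue$tissue == den, c("sample_id", "concentration")]
    }
    if (nrow(num_tab) == 0) {
      return(tibble::tibble(metal = metal, stage = stage, kind = kind,
                            mean = NA_real_, sd = NA_real_, n = 0L,
                            absent = TRUE,
                            reason = paste0("no ", num, " records at ", stage)))
    }
    if (nrow(den_tab) == 0) {
      return(tibble::tibble(metal = metal, stage = stage, kind = kind,
                            mean = NA_real_, sd = NA_real_, n = 0L,
                            absent = TRUE,
                            reason = paste0("no ", den, " records at ", stage)))
    }
    paired <- dplyr::inner_join(num_tab[, c("sample_id", "concentration")],
                                den_tab, by = "sample_id",
                                suffix = c("_num", "_den"))
    if (nrow(paired) == 0) {
      return(tibble::tibble(metal = metal, stage = stage, kind = kind,
                            mean = NA_real_, sd = NA_real_, n = 0L,
                            absent = TRUE,
                            reason = "no samples with both compartments"))
    }
    r <- compute_ratio(paired$concentration_num, paired$concentration_den)
    tibble::tibble(metal = metal, stage = stage, kind = kind,
                   mean = mean(r),
                   sd = if (length(r) > 1) stats::sd(r) else NA_real_,
                   n = length(r), absent = FALSE, reason = NA_character_)
  }

  out <- dplyr::bind_rows(Map(one_factor, grid$metal, grid$stage, grid$kind,
                              grid$num, grid$den))
  out$metal <- factor(out$metal, levels = hm_metals())
  out$stage <- factor(out$stage, levels = hm_stages())
  out <- dplyr::arrange(out, .data$metal, .data$stage, .data$kind)
  out$metal <- as.character(out$metal)
  out$stage <- as.character(out$stage)
  out
}

#' Rank metals by a transfer factor
#'
#' Orders the six metals by descending factor value for one (kind, stage)
#' combination, the comparison used to describe which metals rice enriches or
#' translocates most strongly. Ties are broken by the fixed metal registry
#' order and flagged.
#'
#' @param table a [transfer_factors()] tibble.
#' @param kind one of `"BF_root_soil"`, `"TF_stem_root"`, `"TF_leaf_stem"`,
#'   `"TF_grain_stem"`.
#' @param stage growth stage.
#' @return A list with `order` (metal symbols, descending value), `values`
#'   (named numeric in that order) and `ties` (logical).
#' @export
rank_metals <- function(table, kind, stage) {
  stopifnot(kind %in% transfer_kinds()$kind, stage %in% hm_stages())
  sub <- table[table$kind == kind & table$stage == stage & !table$absent, ]
  missing <- setdiff(hm_metals(), sub$metal)
  if (length(missing) > 0) {
    stop("rank_metals: missing factor value for ",
         paste(missing, collapse = ", "), " (", kind, ", ", stage, ")",
         call. = FALSE)
  }
  v <- stats::setNames(sub$mean, sub$metal)[hm_metals()]
  ord <- order(-v)  # stable: registry order breaks ties
  list(order = names(v)[ord], values = v[ord],
       ties = anyDuplicated(v) > 0)
}

#' Write a transfer-factor table as CSV
#'
#' Wide layout with one row per metal and stage and one `mean +/- sd` style
#' pair of columns per factor kind.
#'
#' @param table a [transfer_factors()] tibble.
#' @param path output CSV path.
#' @export
write_transfer_factors <- function(table, path) {
  wide <- tidyr::pivot_wider(
    table[, c("metal", "stage", "kind", "mean", "sd")],
    names_from = "kind", values_from = c("mean", "sd"),
    names_glue = "{kind}_{.value}"
  )
  readr::write_csv(wide, path, na = "")
  invisible(path)
}
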