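#' Configuration for the synthetic soil-rice dataset generator
#'
#' Defines the forward model the generator samples from. Defaults emulate a
#' pot study on paddy soil collected near a long-exploited Pb-Zn mining
#' area: contaminated and control soil concentration means, stage- and
#' tissue-resolved transfer factors for the forward soil-to-grain chain, and
#' percent-change effects for growth, oxidative-stress and amino-acid
#' endpoints. Concentrations are lognormal (non-negative, right-skewed, the
#' standard choice for environmental concentration data); tissue noise is
#' multiplicative lognormal around the deterministic transfer chain.
#'
#' @param soil_means named vector, contaminated-soil means mg/kg DW.
#' @param control_soil_means named vector, control-soil means mg/kg DW.
#' @param soil_cv coefficient of variation of soil concentrations (default
#'   0.05, the order of the replicate scatter in the emulated study).
#' @param true_factors tibble (`metal`, `stage`, `kind`, `value`) of the
#'   generating transfer factors; default [default_true_factors()].
#' @param tissue_noise_sd lognormal sigma of the multiplicative tissue noise
#'   (default 0.1).
#' @param n_replicates replicate pots per group (default 4).
#' @param endpoint_effects tibble (`endpoint`, `tissue`, `stage`, `effect`)
#'   of percent changes vs control; default [default_endpoint_effects()].
#' @param endpoint_control_means named vector of control means per endpoint,
#'   in endpoint units; defaults are field-plausible magnitudes (the
#'   emulated study prints only percent changes).
#' @param endpoint_noise_sd lognormal sigma of endpoint replicate noise
#'   (default 0.05).
#' @param seed integer seed making the generated dataset reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    soil_means = c(Cu = 65.18, Cr = 69.75, Zn = 490.87, Cd = 2.01,
                   Pb = 652.34, As = 148.11),
    control_soil_means = c(Cu = 23.98, Cr = 38.46, Zn = 123.94, Cd = 0.27,
                           Pb = 31.92, As = 13.08),
    soil_cv = 0.05,
    true_factors = default_true_factors(),
    tissue_noise_sd = 0.1,
    n_replicates = 4,
    endpoint_effects = default_endpoint_effects(),
    endpoint_control_means = c(
      plant_height = 90, root_length = 20, aboveground_dry_weight = 15,
      root_dry_weight = 5, tiller_number = 12, panicle_emergence = 10,
      MDA = 10, Glu = 50),
    endpoint_noise_sd = 0.05,
    seed = 1L) {
  as_metal(names(soil_means)); as_metal(names(control_soil_means))
  stopifnot(all(soil_means > 0), all(control_soil_means > 0),
            soil_cv >= 0, tissue_noise_sd >= 0, n_replicates >= 1,
            endpoint_noise_sd >= 0,
            all(endpoint_control_means > 0))
  if (any(true_factors$kind == "TF_grain_stem" &
            true_factors$stage == "tillering")) {
    stop("grain factors are not defined at tillering", call. = FALSE)
  }
  miss <- setdiff(unique(endpoint_effects$endpoint),
                  names(endpoint_control_means))
  if (length(miss) > 0) {
    stop("no control mean for endpoint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    soil_means = soil_means, control_soil_means = control_soil_means,
    soil_cv = soil_cv, true_factors = true_factors,
    tissue_noise_sd = tissue_noise_sd,
    n_replicates = as.integer(n_replicates),
    endpoint_effects = endpoint_effects,
    endpoint_control_means = endpoint_control_means,
    endpoint_noise_sd = endpoint_noise_sd,
    seed = as.integer(seed)), class = "generator_config")
}

#' Default generating transfer factors
#'
#' Stage- and metal-resolved bioconcentration and translocation factors used
#' as the truth of the forward model: Cd enrichment in roots rising from
#' 0.79 at tillering to 1.95 at maturity, weak Pb stem transfer, strong Cr
#' leaf transfer, and no grain compartment before heading.
#'
#' @return Tibble with columns `metal`, `stage`, `kind`, `value`.
#' @export
default_true_factors <- function() {
  # value order per metal: BF_root_soil, TF_stem_root, TF_leaf_stem at
  # tillering/heading/maturity, then TF_grain_stem at heading/maturity
  vals <- list(
    Cu = c(0.38, 0.27, 1.34, 0.49, 0.28, 0.84, 0.60, 0.16, 0.81, 0.66, 0.91),
    Cr = c(0.53, 0.41, 0.95, 0.46, 0.52, 1.28, 0.35, 0.53, 1.35, 0.51, 0.50),
    Zn = c(0.44, 0.36, 1.20, 0.33, 0.43, 0.97, 0.52, 0.36, 1.14, 0.80, 0.61),
    Cd = c(0.79, 0.47, 0.65, 1.04, 0.35, 0.44, 1.95, 0.17, 0.61, 0.52, 0.55),
    Pb = c(0.44, 0.04, 1.31, 0.46, 0.06, 0.90, 0.75, 0.05, 0.51, 0.13, 0.14),
    As = c(0.45, 0.33, 1.09, 0.42, 0.36, 0.87, 0.32, 0.38, 1.07, 0.09, 0.09)
  )
  frame <- tibble::tibble(
    stage = c(rep(c("tillering", "heading", "maturity"), each = 3),
              "heading", "maturity"),
    kind = c(rep(c("BF_root_soil", "TF_stem_root", "TF_leaf_stem"), 3),
             "TF_grain_stem", "TF_grain_stem")
  )
  dplyr::bind_rows(lapply(hm_metals(), function(m) {
    dplyr::mutate(frame, metal = m, value = vals[[m]])
  }))[, c("metal", "stage", "kind", "value")]
}

#' Default generating phytotoxicity effects
#'
#' Percent changes of the contaminated group relative to control used as the
#' generator's truth: growth traits inhibited at all three stages,
#' lipid-peroxidation marker MDA elevated most strongly in stems at heading,
#' and glutamate exudation rising steeply through the season.
#'
#' @return Tibble with columns `endpoint`, `tissue`, `stage`, `effect`
#'   (percent).
#' @export
default_endpoint_effects <- function() {
  stages <- hm_stages()
  growth <- function(endpoint, eff) {
    tibble::tibble(endpoint = endpoint, tissue = NA_character_,
                   stage = stages, effect = eff)
  }
  dplyr::bind_rows(
    growth("plant_height", c(-31.4, -28.8, -27.8)),
    growth("root_length", c(-31.7, -29.4, -21.6)),
    growth("aboveground_dry_weight", c(-44.7, -27.1, -33.5)),
    growth("root_dry_weight", c(-28.4, -46.4, -60.6)),
    growth("tiller_number", c(-31.7, -33.2, -50.0)),
    growth("panicle_emergence", c(-29.2, -34.3, -42.0)),
    tibble::tibble(endpoint = "MDA", tissue = "root", stage = stages,
                   effect = c(11.0, 28.9, 18.0)),
    tibble::tibble(endpoint = "MDA", tissue = "stem", stage = stages,
                   effect = c(81.2, 116.6, 30.4)),
    tibble::tibble(endpoint = "MDA", tissue = "leaf", stage = stages,
                   effect = c(16.8, 26.4, 6.3)),
    growth("Glu", c(65.4, 155.9, 211.8))
  )
}

# lognormal with arithmetic mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

mult_noise <- function(n, sd) {
  if (sd == 0) rep(1, n) else exp(stats::rnorm(n, 0, sd))
}

#' Generate a synthetic soil-rice dataset
#'
#' Samples a complete dataset from the forward model described by a
#' [generator_config()]: replicate soil concentrations per group, plant
#' tissue concentrations obtained by chaining the true transfer factors
#' (root from soil, stem from root, leaf from stem, grain from stem, with
#' multiplicative lognormal noise at each step and no grain at tillering),
#' and phytotoxicity endpoints as control mean x (1 + effect/100) x noise.
#' The returned truth record stores every generating value so estimator
#' recovery can be tested.
#'
#' @param config a [generator_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return List with tibbles `soil`, `tissue`, `endpoints` and the list
#'   `truth`.
#' @export
#' @examples
#' d <- generate_dataset(generator_config(seed = 42))
#' head(d$soil)
generate_dataset <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  nrep <- config$n_replicates
  groups <- list(contaminated = config$soil_means,
                 control = config$control_soil_means)

  soil <- list(); tissue <- list()
  for (grp in names(groups)) {
    means <- groups[[grp]]
    ids <- sprintf("%s%02d", if (grp == "contaminated") "S" else "C",
                   seq_len(nrep))
    for (m in names(means)) {
      c_soil <- rlnorm_mean_cv(nrep, means[[m]], config$soil_cv)
      soil[[paste(grp, m)]] <- tibble::tibble(
        sample_id = ids, stage = NA_character_, tissue = "soil", metal = m,
        concentration = c_soil, group = grp)
      for (st in hm_stages()) {
        tf <- config$true_factors[config$true_factors$metal == m &
                                    config$true_factors$stage == st, ]
        fac <- stats::setNames(tf$value, tf$kind)
        c_root <- c_soil * fac[["BF_root_soil"]] *
          mult_noise(nrep, config$tissue_noise_sd)
        c_stem <- c_root * fac[["TF_stem_root"]] *
          mult_noise(nrep, config$tissue_noise_sd)
        c_leaf <- c_stem * fac[["TF_leaf_stem"]] *
          mult_noise(nrep, config$tissue_noise_sd)
        rows <- tibble::tibble(
          sample_id = rep(ids, 3),
          stage = st,
          tissue = rep(c("root", "stem", "leaf"), each = nrep),
          metal = m,
          concentration = c(c_root, c_stem, c_leaf),
          group = grp)
        if ("TF_grain_stem" %in% names(fac)) {
          c_grain <- c_stem * fac[["TF_grain_stem"]] *
            mult_noise(nrep, config$tissue_noise_sd)
          rows <- dplyr::bind_rows(rows, tibble::tibble(
            sample_id = ids, stage = st, tissue = "grain", metal = m,
            concentration = c_grain, group = grp))
        }
        tissue[[paste(grp, m, st)]] <- rows
      }
    }
  }
  soil <- dplyr::bind_rows(soil)
  tissue <- dplyr::bind_rows(tissue)

  eff <- config$endpoint_effects
  endpoints <- dplyr::bind_rows(lapply(seq_len(nrow(eff)), function(i) {
    cm <- config$endpoint_control_means[[eff$endpoint[i]]]
    tm <- cm * (1 + eff$effect[i] / 100)
    tibble::tibble(
      endpoint = eff$endpoint[i], stage = eff$stage[i],
      tissue = eff$tissue[i],
      group = rep(c("contaminated", "control"), each = nrep),
      replicate = rep(seq_len(nrep), 2),
      value = c(tm * mult_noise(nrep, config$endpoint_noise_sd),
                cm * mult_noise(nrep, config$endpoint_noise_sd)))
  }))

  list(
    soil = validate_concentration_table(soil, "soil"),
    tissue = validate_concentration_table(tissue, "tissue"),
    endpoints = endpoints,
    truth = list(
      soil_means = config$soil_means,
      control_soil_means = config$control_soil_means,
      soil_cv = config$soil_cv,
      factors = config$true_factors,
      endpoint_effects = config$endpoint_effects,
      endpoint_control_means = config$endpoint_control_means,
      tissue_noise_sd = config$tissue_noise_sd,
      n_replicates = nrep,
      seed = config$seed)
  )
}
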