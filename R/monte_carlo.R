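#' Distribution specification for Monte Carlo inputs
#'
#' A named univariate distribution with optional truncation bounds, used to
#' describe the uncertainty of a health-risk input (a concentration, intake
#' rate, body weight or exposure duration). Families:
#' \describe{
#'   \item{point}{degenerate at `value`}
#'   \item{normal}{`mean`, `sd > 0`}
#'   \item{lognormal}{`meanlog`, `sdlog > 0` (parameters on the log scale)}
#'   \item{uniform}{`min < max`}
#'   \item{triangular}{`min <= mode <= max`, `min < max`}
#' }
#' Truncation is applied by rejection, so draws follow the conditional
#' distribution inside `[lower, upper]`.
#'
#' @param family distribution family name.
#' @param ... family parameters (see above).
#' @param lower,upper optional truncation bounds; for physical quantities
#'   `lower` must be >= 0.
#' @return A `dist_spec` object.
#' @export
#' @examples
#' dist_spec("lognormal", meanlog = log(650), sdlog = 0.05, lower = 0)
dist_spec <- function(family = c("point", "normal", "lognormal", "uniform",
                                 "triangular"),
                      ..., lower = NULL, upper = NULL) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    point = "value", normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"), uniform = c("min", "max"),
    triangular = c("min", "mode", "max"))
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    stop(family, " distribution needs parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  params <- params[need]
  ok <- switch(family,
    point = TRUE,
    normal = params$sd > 0,
    lognormal = params$sdlog > 0,
    uniform = params$min < params$max,
    triangular = params$min < params$max && params$mode >= params$min &&
      params$mode <= params$max)
  if (!isTRUE(ok)) stop("invalid parameters for ", family, " distribution",
                        call. = FALSE)
  if (!is.null(lower) && !is.null(upper) && lower >= upper) {
    stop("empty truncation interval", call. = FALSE)
  }
  structure(list(family = family, params = params, lower = lower,
                 upper = upper), class = "dist_spec")
}

r_untruncated <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, n),
    normal = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    uniform = stats::runif(n, p$min, p$max),
    triangular = {
      # inverse-CDF sampling of the triangular distribution
      u <- stats::runif(n)
      fc <- (p$mode - p$min) / (p$max - p$min)
      ifelse(u < fc,
             p$min + sqrt(u * (p$max - p$min) * (p$mode - p$min)),
             p$max - sqrt((1 - u) * (p$max - p$min) * (p$max - p$mode)))
    })
}

#' Draw from a distribution specification
#'
#' Reproducible sampling with truncation by rejection. Rejection batches
#' continue until `n` accepted draws exist; if the empirical acceptance rate
#' falls below 1e-4 the truncation interval is deemed to exclude essentially
#' all mass and an error is raised.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws, >= 1.
#' @param seed optional integer seed; when given, the draw is a pure function
#'   of `(spec, n, seed)`.
#' @return Numeric vector of length `n`, all values inside the truncation
#'   bounds.
#' @export
sample_dist <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lo <- if (is.null(spec$lower)) -Inf else spec$lower
  hi <- if (is.null(spec$upper)) Inf else spec$upper
  if (spec$family == "point") {
    v <- spec$params$value
    if (v < lo || v > hi) {
      stop("point mass lies outside the truncation bounds", call. = FALSE)
    }
    return(rep(v, n))
  }
  out <- numeric(0)
  tried <- 0
  while (length(out) < n) {
    draw <- r_untruncated(spec, max(n, 1000L))
    tried <- tried + length(draw)
    out <- c(out, draw[draw >= lo & draw <= hi])
    if (length(out) / tried < 1e-4 && tried >= 1e6) {
      stop("truncation bounds exclude essentially all probability mass",
           call. = FALSE)
    }
  }
  out[seq_len(n)]
}

# Resolve a dotted path like "c_soil.Pb" or "exposure.adult.BW" inside the
# fixed configuration, returning accessor/assign closures.
resolve_path <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (p in parts) {
    if (is.null(node[[p]])) return(NULL)
    node <- node[[p]]
  }
  parts
}

assign_path <- function(config, parts, value) {
  if (length(parts) == 1) {
    config[[parts]] <- value
    return(config)
  }
  config[[parts[1]]] <- assign_path(config[[parts[1]]], parts[-1], value)
  config
}

#' Monte Carlo propagation of uncertainty through the health-risk model
#'
#' Replaces selected health-risk inputs by random draws and pushes each
#' iteration through the same average-daily-intake, hazard-quotient and
#' carcinogenic-risk operations as the deterministic pipeline, yielding
#' exceedance probabilities and percentiles per endpoint. Parameters are
#' sampled independently. Endpoints are the per-metal pathway-summed HQ and
#' CR, the hazard index HI and the total carcinogenic risk TCR, for every
#' population; exceedance thresholds are HQ/HI > 1 and CR/TCR > 1e-4.
#'
#' @param dist_config named list of [dist_spec()] objects; names are dotted
#'   paths into the fixed configuration, e.g. `"c_soil.Pb"`,
#'   `"c_rice.Cd"`, `"exposure.adult.BW"`.
#' @param fixed_config list with elements `c_rice` (named vector), `c_soil`
#'   (named vector), `exposure` (named list of [exposure_parameters()]),
#'   `ref` (a [toxicology_references()] table); every model parameter must be
#'   covered by `fixed_config`, with `dist_config` overriding.
#' @param n number of iterations (default 10000).
#' @param seed integer seed; mandatory so results are reproducible.
#' @param keep_draws if `TRUE`, per-iteration endpoint values are returned
#'   for audit.
#' @return A list of class `"mc_result"`: `n_iter`, `seed`, `summary` tibble
#'   (`population`, `endpoint`, `metal`, `exceedance`, `mean`, `p5`, `p50`,
#'   `p95`) and optionally `draws`.
#' @export
simulate_risk <- function(dist_config, fixed_config, n = 10000, seed,
                          keep_draws = FALSE) {
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  stopifnot(n >= 1)
  for (el in c("c_rice", "c_soil", "exposure", "ref")) {
    if (is.null(fixed_config[[el]])) {
      stop("fixed configuration is missing '", el, "'", call. = FALSE)
    }
  }
  metals <- intersect(hm_metals(),
                      intersect(names(fixed_config$c_rice),
                                names(fixed_config$c_soil)))
  if (length(metals) == 0) stop("no metals covered by both c_rice and c_soil",
                                call. = FALSE)
  for (nm in names(dist_config)) {
    if (!inherits(dist_config[[nm]], "dist_spec")) {
      stop("dist_config entry '", nm, "' is not a dist_spec", call. = FALSE)
    }
    if (is.null(resolve_path(fixed_config, nm))) {
      stop("distribution given for unknown parameter '", nm, "'",
           call. = FALSE)
    }
  }

  set.seed(seed)
  # expand every parameter to an n-vector: draws for dist_config entries,
  # replicated constants otherwise, then reuse the deterministic operations
  cfg <- fixed_config
  cfg$c_rice <- lapply(as.list(fixed_config$c_rice[metals]), rep, n)
  cfg$c_soil <- lapply(as.list(fixed_config$c_soil[metals]), rep, n)
  cfg$exposure <- lapply(fixed_config$exposure, function(p) {
    p2 <- unclass(p)
    scalars <- setdiff(names(p2), "population")
    p2[scalars] <- lapply(p2[scalars], rep, n)
    p2
  })
  for (nm in names(dist_config)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg <- assign_path(cfg, parts, sample_dist(dist_config[[nm]], n))
  }

  ref <- fixed_config$ref
  pop_summaries <- list()
  draws <- list()
  for (pop in names(cfg$exposure)) {
    p <- cfg$exposure[[pop]]
    hq_total <- matrix(0, n, length(metals), dimnames = list(NULL, metals))
    cr_total <- matrix(NA_real_, n, length(metals),
                       dimnames = list(NULL, metals))
    for (m in metals) {
      hq_cols <- matrix(NA_real_, n, 4)
      cr_cols <- NULL
      pw_all <- c("food", "ing", "inh", "der")
      for (j in seq_along(pw_all)) {
        pw <- pw_all[j]
        row <- ref[ref$metal == m & ref$pathway == pw, ]
        adi_nc <- if (pw == "food") adi_food(cfg$c_rice[[m]], p, "nc")
                  else adi_soil(cfg$c_soil[[m]], p, pw, "nc")
        hq_cols[, j] <- hazard_quotient(adi_nc, row$rfd)
        if (!is.na(row$sf)) {
          adi_ca <- if (pw == "food") adi_food(cfg$c_rice[[m]], p, "ca")
                    else adi_soil(cfg$c_soil[[m]], p, pw, "ca")
          cr_cols <- cbind(cr_cols, carcinogenic_risk(adi_ca, row$sf))
        }
      }
      # rowSums shares sum()'s extended-precision accumulation, so the
      # degenerate (all-point) simulation matches aggregate_risk exactly
      hq_total[, m] <- rowSums(hq_cols)
      if (!is.null(cr_cols)) cr_total[, m] <- rowSums(cr_cols)
    }
    hi <- rowSums(hq_total)
    has_cr <- colnames(cr_total)[!is.na(cr_total[1, ])]
    tcr <- if (length(has_cr) > 0) {
      rowSums(cr_total[, has_cr, drop = FALSE])
    } else rep(NA_real_, n)

    summarise_endpoint <- function(x, threshold) {
      q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
      tibble::tibble(exceedance = mean(x > threshold), mean = mean(x),
                     p5 = q[1], p50 = q[2], p95 = q[3])
    }
    rows <- list()
    for (m in metals) {
      rows[[paste0("HQ_", m)]] <- dplyr::mutate(
        summarise_endpoint(hq_total[, m], 1),
        endpoint = "HQ", metal = m)
      if (!is.na(cr_total[1, m])) {
        rows[[paste0("CR_", m)]] <- dplyr::mutate(
          summarise_endpoint(cr_total[, m], 1e-4),
          endpoint = "CR", metal = m)
      }
    }
    rows[["HI"]] <- dplyr::mutate(summarise_endpoint(hi, 1),
                                  endpoint = "HI", metal = NA_character_)
    if (!all(is.na(tcr))) {
      rows[["TCR"]] <- dplyr::mutate(summarise_endpoint(tcr, 1e-4),
                                     endpoint = "TCR", metal = NA_character_)
    }
    s <- dplyr::bind_rows(rows)
    s$population <- pop
    pop_summaries[[pop]] <- s
    if (keep_draws) {
      draws[[pop]] <- list(hq = hq_total, cr = cr_total, hi = hi, tcr = tcr)
    }
  }
  summary <- dplyr::bind_rows(pop_summaries)[, c("population", "endpoint",
                                                 "metal", "exceedance",
                                                 "mean", "p5", "p50", "p95")]
  out <- list(n_iter = as.integer(n), seed = as.integer(seed),
              summary = summary)
  if (keep_draws) out$draws <- draws
  structure(out, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo health-risk simulation: %d iterations, seed %d\n\n",
              x$n_iter, x$seed))
  s <- x$summary
  s$exceedance <- sprintf("%.1f%%", 100 * s$exceedance)
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' Write a Monte Carlo summary as CSV
#'
#' @param result an [simulate_risk()] result.
#' @param path output CSV path.
#' @export
write_mc_result <- function(result, path) {
  readr::write_csv(result$summary, path, na = "")
  invisible(path)
}
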