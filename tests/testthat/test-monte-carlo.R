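fixed_fixture <- function(c_rice = c(Cd = 0.2, Pb = 0.4),
                          c_soil = c(Cd = 2.01, Pb = 652.34)) {
  list(c_rice = c_rice, c_soil = c_soil,
       exposure = list(adult = exposure_parameters("adult")),
       ref = toxicology_references())
}

test_that("distribution sampling is reproducible and respects truncation", {
  expect_equal(sample_dist(dist_spec("point", value = 3), 5), rep(3, 5))
  u <- sample_dist(dist_spec("uniform", min = 0, max = 1), 1e4, seed = 9)
  expect_lt(abs(mean(u) - 0.5), 0.02)  # CLT bound
  tn <- sample_dist(dist_spec("normal", mean = 0, sd = 1, lower = 0), 1000,
                    seed = 4)
  expect_true(all(tn >= 0))
  tr <- sample_dist(dist_spec("triangular", min = 1, mode = 2, max = 4),
                    1e4, seed = 2)
  expect_true(all(tr >= 1 & tr <= 4))
  expect_lt(abs(mean(tr) - 7 / 3), 0.05)  # (min+mode+max)/3
  # same seed, same draws; different seed, different draws
  spec <- dist_spec("lognormal", meanlog = 0, sdlog = 1)
  expect_identical(sample_dist(spec, 100, seed = 7),
                   sample_dist(spec, 100, seed = 7))
  expect_false(identical(sample_dist(spec, 100, seed = 7),
                         sample_dist(spec, 100, seed = 8)))
  expect_error(dist_spec("normal", mean = 0, sd = -1), "invalid")
  expect_error(dist_spec("uniform", min = 1, max = 0), "invalid")
  expect_error(dist_spec("normal", mean = 0, sd = 1, lower = 2, upper = 1),
               "empty")
  expect_error(sample_dist(dist_spec("normal", mean = 0, sd = 1,
                                     lower = 100), 10, seed = 1),
               "mass")
})

test_that("point distributions reduce to the deterministic pipeline", {
  fixed <- fixed_fixture()
  dists <- list(
    "c_rice.Cd" = dist_spec("point", value = fixed$c_rice[["Cd"]]),
    "c_soil.Pb" = dist_spec("point", value = fixed$c_soil[["Pb"]]),
    "exposure.adult.BW" = dist_spec("point",
                                    value = fixed$exposure$adult$BW))
  mc <- simulate_risk(dists, fixed, n = 50, seed = 1)
  det <- aggregate_risk(risk_cells(fixed$c_rice, fixed$c_soil,
                                   fixed$exposure, fixed$ref))
  s <- mc$summary
  for (m in c("Cd", "Pb")) {
    mt <- det$metal_totals
    expect_identical(s$mean[s$endpoint == "HQ" & s$metal == m],
                     mt$hq_total[mt$metal == m])
    expect_identical(s$mean[s$endpoint == "CR" & s$metal == m],
                     mt$cr_total[mt$metal == m])
  }
  expect_identical(s$mean[s$endpoint == "HI"], det$grand$hi)
  expect_identical(s$mean[s$endpoint == "TCR"], det$grand$tcr)
  # degenerate exceedance is exactly 0 or 1
  expect_equal(s$exceedance[s$endpoint == "HI"],
               as.numeric(det$grand$hi > 1))
  expect_true(all(s$p5 <= s$p50 & s$p50 <= s$p95))
})

test_that("lognormal exceedance matches the closed-form tail probability", {
  # single metal, HQ linear in soil concentration with rice intake zero, so
  # P(HQ > 1) = P(C > 1/k) with C lognormal -- the analytic oracle
  fixed <- fixed_fixture(c_rice = c(Cd = 0), c_soil = c(Cd = 2.01))
  det <- aggregate_risk(risk_cells(c(Cd = 0), c(Cd = 1), fixed$exposure,
                                   fixed$ref))
  k <- det$metal_totals$hq_total  # HQ per unit soil concentration
  meanlog <- log(1 / k)           # median at the threshold-equivalent level
  sdlog <- 0.8
  n <- 1e4
  mc <- simulate_risk(list("c_soil.Cd" = dist_spec("lognormal",
                                                   meanlog = meanlog + 1,
                                                   sdlog = sdlog)),
                      fixed, n = n, seed = 12)
  p_true <- 1 - stats::plnorm(1 / k, meanlog + 1, sdlog)
  p_hat <- mc$summary$exceedance[mc$summary$endpoint == "HQ" &
                                   mc$summary$metal == "Cd"]
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("simulation is seed-deterministic and monotone in location", {
  fixed <- fixed_fixture()
  dists <- list("c_soil.Pb" = dist_spec("lognormal", meanlog = log(650),
                                        sdlog = 0.3))
  a <- simulate_risk(dists, fixed, n = 500, seed = 42)
  b <- simulate_risk(dists, fixed, n = 500, seed = 42)
  expect_identical(a, b)
  # shifting the concentration distribution upward cannot lower exceedance
  up <- simulate_risk(list("c_soil.Pb" = dist_spec("lognormal",
                                                   meanlog = log(6500),
                                                   sdlog = 0.3)),
                      fixed, n = 500, seed = 42)
  joined <- merge(a$summary, up$summary,
                  by = c("population", "endpoint", "metal"))
  expect_true(all(joined$exceedance.y >= joined$exceedance.x))
})

test_that("misconfigured simulations fail with the parameter named", {
  fixed <- fixed_fixture()
  expect_error(simulate_risk(list("exposure.adult.XYZ" =
                                    dist_spec("point", value = 1)),
                             fixed, n = 10, seed = 1), "XYZ")
  expect_error(simulate_risk(list(), fixed[-1], n = 10, seed = 1), "c_rice")
  expect_error(simulate_risk(list(), fixed, n = 10), "seed")
})
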