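test_that("scenario templates have the documented structure", {
  d <- default_design()
  s1 <- build_scenario(1, d)
  expect_length(s1$params, 1)
  expect_length(s1$constraints, 0)
  expect_length(s1$breaks, 0)

  s2 <- build_scenario(2, d)
  expect_setequal(s2$params, c("N_anc", paste0("N", 1:5)))
  expect_length(s2$breaks, 5)
  # drop at each round, recovery until the next round
  cons <- vapply(s2$constraints, paste, character(1), collapse = " ")
  expect_true(all(c("N2 <= N1", "N5 <= N4", "N2 <= N3", "N3 <= N4",
                    "N_anc <= N1") %in% cons))

  s3 <- build_scenario(3, d)
  cons3 <- vapply(s3$constraints, paste, character(1), collapse = " ")
  expect_true(all(c("N1 <= N_anc", "N2 <= N1", "N3 <= N2", "N4 <= N3",
                    "N5 <= N4") %in% cons3))

  # scenario 6 carries a mid-interval change point ~3 months after round 1
  s6 <- build_scenario(6, d)
  split_gen <- calendar_to_generations(as.Date("2009-06-14") + 91, s6$clock)
  expect_true(any(abs(s6$breaks - split_gen) < 1e-9))
  expect_setequal(s6$params,
                  c("N_anc", "N1", "N2", "N3", "N4a", "N4b", "N5"))

  # missing inputs are rejected with clear errors
  d_norain <- default_design(rainfall = NULL)
  expect_error(build_scenario(4, d_norain), "rainfall")
  d_nospray <- sampling_design(d$dates, d$sizes, d$n_loci)
  expect_error(build_scenario(2, d_nospray), "spray")
})

test_that("every accepted draw satisfies its scenario constraints", {
  d <- default_design()
  set.seed(42)
  for (sid in 1:6) {
    spec <- build_scenario(sid, d)
    par <- draw_scenario_params(spec, 500)
    expect_true(all(check_constraints(spec, par)),
                label = paste("scenario", sid, "constraints total"))
    expect_true(all(par >= 10 & par <= 1e5))
  }
  # scenario 3 at larger n: monotone chain holds on every draw
  p3 <- draw_scenario_params(build_scenario(3, d), 10000)
  expect_true(all(p3[, "N5"] <= p3[, "N4"] & p3[, "N4"] <= p3[, "N3"] &
                    p3[, "N3"] <= p3[, "N2"] & p3[, "N2"] <= p3[, "N1"] &
                    p3[, "N1"] <= p3[, "N_anc"]))
})

test_that("rank constraints make interval Ne concordant with rainfall", {
  d <- default_design()
  rain_ranks <- rank(interval_rainfall_means(d))
  set.seed(7)
  p4 <- draw_scenario_params(build_scenario(4, d), 200)
  ivl <- p4[, paste0("N", 1:5), drop = FALSE]
  expect_true(all(apply(ivl, 1, function(v) all(rank(v) == rain_ranks))))
  p5 <- draw_scenario_params(build_scenario(5, d), 200)
  ivl5 <- p5[, paste0("N", 1:5), drop = FALSE]
  expect_true(all(apply(ivl5, 1, function(v) all(rank(-v) == rain_ranks))))
})

test_that("point-mass priors return the point mass", {
  d <- default_design()
  spec <- build_scenario(1, d, ne_bounds = c(500, 500))
  set.seed(1)
  p <- draw_scenario_params(spec, 10)
  expect_equal(unname(p[, 1]), rep(500, 10))
})

test_that("log-uniform draws have the right support and median", {
  d <- default_design()
  spec <- build_scenario(1, d)  # unconstrained single parameter
  set.seed(99)
  p <- draw_scenario_params(spec, 20000)[, 1]
  expect_true(all(p >= 10 & p <= 1e5))
  # median of log10(Ne) ~ Uniform(1, 5): midpoint 3, SE of sample median
  # ~ 1.2533 * sd / sqrt(n)
  se_med <- 1.2533 * sqrt((5 - 1)^2 / 12) / sqrt(20000)
  expect_lt(abs(median(log10(p)) - 3), 3 * se_med)
})

test_that("an impossible constraint set aborts with a diagnostic", {
  d <- default_design()
  spec <- build_scenario(3, d)
  # constrain to a measure-near-zero region via degenerate bounds plus an
  # extra impossible constraint
  spec$constraints <- c(spec$constraints,
                        list(c("N_anc", "<=", "N5"), c("N5", "<=", "N_anc")))
  spec$ne_bounds <- c(10, 1e5)
  set.seed(3)
  expect_error(draw_scenario_params(spec, 10), "acceptance rate")
})

test_that("realized trajectories map parameters onto the right epochs", {
  d <- default_design()
  spec <- build_scenario(2, d)
  par <- c(N_anc = 1200, N1 = 5692, N2 = 428, N3 = 1782, N4 = 12060,
           N5 = 4204)
  tr <- realize_trajectory(spec, par)
  cl <- spec$clock
  # a date inside each interval must see that interval's Ne
  probe <- as.Date(c("2009-04-20", "2009-06-20", "2009-08-01",
                     "2009-10-10", "2010-01-15"))
  expect_equal(trajectory_at(tr, calendar_to_generations(probe, cl)),
               unname(par[paste0("N", 1:5)]))
  # before the first sample: ancestral size
  expect_equal(trajectory_at(tr, 25), 1200)
})

test_that("scenario specs round-trip through YAML configs", {
  d <- default_design()
  spec <- build_scenario(4, d, ne_bounds = c(20, 2e4), anchor = "spray")
  f <- tempfile(fileext = ".yaml")
  scenario_to_yaml(spec, f)
  back <- scenario_from_yaml(f)
  expect_equal(back$scenario_id, spec$scenario_id)
  expect_equal(back$ne_bounds, spec$ne_bounds)
  expect_equal(back$anchor, spec$anchor)
  expect_equal(back$breaks, spec$breaks)
  expect_equal(back$rank_target, spec$rank_target)
  expect_equal(back$clock$gpy, spec$clock$gpy)
  unlink(f)
})

test_that("run configs validate keys and values", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_per_scenario: 5000", "seed: 7"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$n_per_scenario, 5000)
  expect_equal(cfg$retention_fraction, 0.01)
  writeLines(c("n_per_scenario: 5000", "bogus_key: 1"), f)
  expect_error(read_run_config(f), "unknown configuration key")
  writeLines("retention_fraction: 1.5", f)
  expect_error(read_run_config(f))
  unlink(f)
  pr <- run_provenance(cfg, 7)
  expect_match(pr$config_hash, "^[0-9a-f]{8}$")
})
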