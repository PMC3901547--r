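# small shared fixtures: a cheap design so reference tables are fast
abc_design <- function()
  sampling_design(c("2009-03-25", "2009-07-07", "2009-11-10"),
                  c(12, 12, 12), n_loci = 4,
                  spray_dates = as.Date(c("2008-10-01", "2009-06-14")))

abc_specs <- function(d = abc_design()) {
  sp <- list(scenario_1 = build_scenario(1, d),
             scenario_3 = build_scenario(3, d))
  sp
}

test_that("reference tables have the right shape and are seed-deterministic", {
  specs <- abc_specs()
  set.seed(40)
  tab <- simulate_reference_table(specs, 150)
  expect_equal(nrow(tab$stats), 300)
  expect_equal(as.vector(table(tab$model)), c(150, 150))
  expect_equal(ncol(tab$stats), 4 * 3 + 4 * 2)
  expect_true(all(is.finite(tab$stats)))
  # scenario 1 rows carry no N_anc draws; scenario 3 rows do
  expect_true(all(is.na(tab$params$N_anc[tab$model == "scenario_1"])))
  expect_true(all(!is.na(tab$params$N_anc[tab$model == "scenario_3"])))
  set.seed(40)
  tab2 <- simulate_reference_table(specs, 150)
  expect_identical(tab$stats, tab2$stats)
  expect_identical(tab$params, tab2$params)
})

test_that("retention keeps the nearest rows under robust normalization", {
  specs <- abc_specs()
  set.seed(41)
  tab <- simulate_reference_table(specs, 200)
  obs <- tab$stats[17, ]  # an observed vector equal to a simulated row
  ret <- retain_nearest(tab, obs, fraction = 0.05)
  expect_equal(length(ret$index), ceiling(0.05 * 400))
  expect_equal(ret$index[1], 17)
  expect_equal(ret$distance[1], 0)
  expect_true(!is.unsorted(ret$distance))
  # rescaling any stat column leaves the retained set unchanged
  tab_sc <- tab
  tab_sc$stats[, 3] <- tab_sc$stats[, 3] * 7
  obs_sc <- obs; obs_sc[3] <- obs_sc[3] * 7
  ret_sc <- retain_nearest(tab_sc, obs_sc, fraction = 0.05)
  expect_equal(ret_sc$index, ret$index)
  # column scale factors equal an independent recomputation
  expect_equal(unname(ret$scale),
               unname(apply(tab$stats, 2, stats::mad)),
               tolerance = 1e-12)
  # a zero-variance column is excluded with a warning
  tab_z <- tab
  tab_z$stats[, 5] <- 1
  obs_z <- obs; obs_z[5] <- 1
  expect_warning(retain_nearest(tab_z, obs_z, 0.05), "zero-spread")
})

test_that("posterior probabilities behave at their fixed points", {
  specs <- abc_specs()
  set.seed(42)
  tab <- simulate_reference_table(specs, 150)
  obs <- stat_vector(simulate_dataset(
    epoch_trajectory(numeric(0), 300), abc_design()))
  ret <- retain_nearest(tab, obs, 0.05)
  sp <- scenario_posteriors(ret)
  expect_equal(sum(sp$logistic), 1, tolerance = 1e-9)
  expect_equal(sum(sp$rejection), 1, tolerance = 1e-9)
  # the rejection estimator equals retained proportions exactly
  expect_equal(unname(sp$rejection),
               as.vector(table(ret$model)) / length(ret$index))
  # all retained rows from one scenario -> probability 1 for it
  ret1 <- ret
  keep <- ret1$model == "scenario_1"
  expect_true(any(keep))
  ret1$model <- ret1$model[keep]
  ret1$distance <- ret1$distance[keep]
  ret1$params <- ret1$params[keep, , drop = FALSE]
  ret1$stats_centered <- ret1$stats_centered[keep, , drop = FALSE]
  sp1 <- scenario_posteriors(ret1)
  expect_equal(unname(sp1$logistic["scenario_1"]), 1)
})

test_that("posteriors are equivariant under relabeling the scenarios", {
  specs <- abc_specs()
  set.seed(43)
  tab <- simulate_reference_table(specs, 150)
  obs <- stat_vector(simulate_dataset(
    epoch_trajectory(numeric(0), 300), abc_design()))
  sp <- scenario_posteriors(retain_nearest(tab, obs, 0.05))
  # swap labels
  tab_sw <- tab
  tab_sw$model <- factor(ifelse(tab_sw$model == "scenario_1", "scenario_3",
                                "scenario_1"),
                         levels = c("scenario_1", "scenario_3"))
  sp_sw <- scenario_posteriors(retain_nearest(tab_sw, obs, 0.05))
  expect_equal(unname(sp_sw$rejection["scenario_3"]),
               unname(sp$rejection["scenario_1"]), tolerance = 1e-12)
  expect_equal(unname(sp_sw$logistic["scenario_3"]),
               unname(sp$logistic["scenario_1"]), tolerance = 1e-6)
})

test_that("identically specified models split the posterior evenly", {
  d <- abc_design()
  specs <- list(a = build_scenario(1, d), b = build_scenario(1, d))
  set.seed(44)
  tab <- simulate_reference_table(specs, 400)
  obs <- stat_vector(simulate_dataset(
    epoch_trajectory(numeric(0), 300), d))
  sp <- scenario_posteriors(retain_nearest(tab, obs, 0.05))
  m <- length(sp$n_retained)
  se <- sqrt(0.25 / sp$n_retained)
  expect_lt(abs(sp$rejection["a"] - 0.5), 3 * se)
})

test_that("a larger table cannot worsen the counting estimator's precision", {
  d <- abc_design()
  specs <- list(a = build_scenario(1, d), b = build_scenario(1, d))
  set.seed(45)
  tab_small <- simulate_reference_table(specs, 500)
  set.seed(45)
  tab_big <- simulate_reference_table(specs, 5000)
  obs <- stat_vector(simulate_dataset(epoch_trajectory(numeric(0), 300), d))
  sp_s <- scenario_posteriors(retain_nearest(tab_small, obs, 0.01))
  sp_b <- scenario_posteriors(retain_nearest(tab_big, obs, 0.01))
  se <- function(sp) {
    p <- sp$rejection[1]
    sqrt(p * (1 - p) / sp$n_retained)
  }
  expect_lte(se(sp_b), se(sp_s) + 1e-12)
})

test_that("parameter posteriors summarize retained draws correctly", {
  # degenerate: all retained values equal
  pp <- parameter_posterior(rep(3, 100))
  expect_equal(pp$median, 3)
  expect_equal(pp$ci_quantile, c(3, 3))
  expect_equal(pp$ci_density, c(3, 3))
  # uniform draws: median ~ 0.5, interval ~ [0.025, 0.975]
  set.seed(46)
  u <- runif(10000)
  pp <- parameter_posterior(u)
  expect_lt(abs(pp$median - 0.5), 0.015)
  expect_lt(abs(pp$ci_quantile[1] - 0.025), 0.01)
  expect_lt(abs(pp$ci_quantile[2] - 0.975), 0.01)
  expect_true(pp$ci_quantile[1] <= pp$median &&
                pp$median <= pp$ci_quantile[2])
  expect_error(parameter_posterior(runif(10)), "too few")
})

test_that("sensitivity analysis removes each category and keeps a baseline", {
  specs <- abc_specs()
  set.seed(47)
  tab <- simulate_reference_table(specs, 200)
  obs <- stat_vector(simulate_dataset(
    epoch_trajectory(numeric(0), 300), abc_design()))
  sens <- sensitivity_drop_stats(tab, obs, fraction = 0.05)
  cats <- unique(stat_categories(colnames(tab$stats)))
  expect_equal(nrow(sens), length(cats) + 1)
  expect_equal(sens$removed[1], "none")
  # baseline row equals a direct call
  sp <- scenario_posteriors(retain_nearest(tab, obs, 0.05))
  expect_equal(sens$scenario_1[1], unname(sp$logistic["scenario_1"]),
               tolerance = 1e-6)
  # probabilities are proper in every row
  expect_true(all(abs(sens$scenario_1 + sens$scenario_3 - 1) < 1e-6))
})

test_that("a single candidate clock gets posterior one", {
  d <- abc_design()
  set.seed(48)
  obs <- stat_vector(simulate_dataset(epoch_trajectory(numeric(0), 300), d))
  res <- compare_generation_clocks(obs, scenario_id = 3, design = d,
                                   clocks = 18, n_per_clock = 100)
  expect_equal(unname(res$logistic), 1)
})
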