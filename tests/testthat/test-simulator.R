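# Forward-time founder-haplotype simulator: determinism, degenerate cases,
# background fidelity, recombination-model agreement, ABC behaviour.

sim_map_single <- function(theta_mb = 2) {
  # one marker at `theta_mb` Mb from the mutation (theta = theta_mb / 100)
  marker_map(data.frame(name = "M1", position_mb = 100 + theta_mb),
             mutation_position_mb = 100)
}

sim_bg_single <- function(p_founder = 0.3) {
  list(M1 = c("150" = p_founder, "152" = 1 - p_founder))
}

founder1 <- function() structure(c(M1 = 150L), class = "haplotype")

test_that("identical config and seed give bit-identical results", {
  cfg <- sim_config(sim_map_single(), founder1(), sim_bg_single(),
                    g = 20, r = 0.2, n_disease = 30, n_control = 40)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$table$records, b$table$records)
  expect_identical(a$lineage_trajectory, b$lineage_trajectory)
  c <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$table$records, c$table$records))
})

test_that("the lineage starts from a single founder chromosome", {
  cfg <- sim_config(sim_map_single(), founder1(), sim_bg_single(),
                    g = 15, r = 0.3, n_disease = 10, n_control = 5)
  sim <- simulate_cohort(cfg, seed = 3)
  expect_equal(sim$lineage_trajectory[1], 1L)
  expect_gte(sim$lineage_trajectory[length(sim$lineage_trajectory)], 10L)
  expect_true(all(sim$table$records$group[1:10] == "disease"))
})

test_that("zero recombination preserves the founder haplotype everywhere", {
  map <- marker_map(data.frame(name = "M0", position_mb = 100),
                    mutation_position_mb = 100)  # theta = 0
  cfg <- sim_config(map, structure(c(M0 = 150L), class = "haplotype"),
                    list(M0 = c("150" = 0.3, "152" = 0.7)),
                    g = 25, r = 0.3, n_disease = 40, n_control = 500)
  sim <- simulate_cohort(cfg, seed = 11)
  dis <- sim$table$records[sim$table$records$group == "disease", "M0"]
  expect_true(all(dis == 150L))
  at <- association_table(sim$table,
                          structure(c(M0 = 150L), class = "haplotype"),
                          n_boot = 0)
  expect_equal(at$delta, 1)
})

test_that("age zero yields copies of the founder chromosome", {
  cfg <- sim_config(sim_map_single(), founder1(), sim_bg_single(),
                    g = 0, n_disease = 12, n_control = 4)
  sim <- simulate_cohort(cfg, seed = 5)
  dis <- sim$table$records[sim$table$records$group == "disease", "M1"]
  expect_identical(dis, rep(150L, 12))
  expect_identical(sim$lineage_trajectory, 1L)
})

test_that("control chromosomes reproduce the background spectrum", {
  bg <- list(M1 = c("150" = 0.25, "152" = 0.6, "154" = 0.15))
  cfg <- sim_config(sim_map_single(), founder1(), bg,
                    g = 0, n_disease = 1, n_control = 4000)
  sim <- simulate_cohort(cfg, seed = 8)
  ctl <- sim$table$records[sim$table$records$group == "control", "M1"]
  for (al in names(bg$M1)) {
    p <- bg$M1[[al]]
    se <- sqrt(p * (1 - p) / 4000)
    expect_lt(abs(mean(ctl == as.integer(al)) - p), 4 * se)
  }
})

test_that("an unsustainable lineage errors after the restart budget", {
  cfg <- sim_config(sim_map_single(), founder1(), sim_bg_single(),
                    g = 40, r = 0.001, n_disease = 50, n_control = 1,
                    max_restarts = 50)
  expect_error(simulate_cohort(cfg, seed = 1), "attempts")
})

test_that("haldane_map and per_marker_independent agree on single-marker retention", {
  ret <- function(model, seeds) {
    cfg <- sim_config(sim_map_single(5), founder1(),
                      sim_bg_single(0), g = 10, r = 0.6,
                      n_disease = 200, n_control = 1, recomb_model = model)
    vapply(seeds, function(s) {
      core <- simulate_cohort(cfg, s)
      mean(core$table$records$M1[core$table$records$group == "disease"] == 150L)
    }, numeric(1))
  }
  r1 <- ret("per_marker_independent", 1:30)
  r2 <- ret("haldane_map", 101:130)
  expected <- (1 - 0.05)^10
  se1 <- sd(r1) / sqrt(30); se2 <- sd(r2) / sqrt(30)
  expect_lt(abs(mean(r1) - expected), 3 * se1 + 1e-3)
  expect_lt(abs(mean(r2) - expected), 3 * se2 + 1e-3)
  expect_lt(abs(mean(r1) - mean(r2)), 3 * sqrt(se1^2 + se2^2) + 1e-3)
})

test_that("haldane_map replaces whole flank segments coherently", {
  # two markers on the same arm: a crossover proximal to both replaces both
  map <- marker_map(data.frame(name = c("N1", "N2"),
                               position_mb = c(105, 130)),
                    mutation_position_mb = 100)
  founder <- structure(c(N1 = 10L, N2 = 10L), class = "haplotype")
  bg <- list(N1 = c("10" = 0, "12" = 1), N2 = c("10" = 0, "12" = 1))
  cfg <- sim_config(map, founder, bg, g = 5, r = 1.5, n_disease = 400,
                    n_control = 1, recomb_model = "haldane_map",
                    pop_cap = 400)
  sim <- simulate_cohort(cfg, seed = 21)
  d <- sim$table$records[sim$table$records$group == "disease", c("N1", "N2")]
  # monotone erosion along the arm: distal marker replaced at least as often
  expect_gte(mean(d$N2 != 10L), mean(d$N1 != 10L))
  # marginal replacement over 5 meioses is near 1 - (1 - theta)^5
  expect_lt(abs(mean(d$N1 != 10L) - (1 - 0.95^5)), 0.12)
})

test_that("stepwise slippage moves alleles by one repeat unit", {
  map <- sim_map_single()
  cfg <- sim_config(map, founder1(), sim_bg_single(0),
                    g = 3, r = 2, n_disease = 300, n_control = 1,
                    slippage_rate = 0.5, pop_cap = 300)
  sim <- simulate_cohort(cfg, seed = 13)
  d <- sim$table$records$M1[sim$table$records$group == "disease"]
  expect_true(all(abs(d - 150L) <= 6L))
  expect_true(all((d - 150L) %% 2 == 0))
  expect_gt(mean(d != 150L), 0.2)
})

test_that("recovery experiment summarises bias, RMSE and exclusions", {
  cfg <- sim_config(sim_map_single(1), founder1(), sim_bg_single(0.3),
                    g = 30, r = 0.2, n_disease = 100, n_control = 200,
                    pop_cap = 500)
  rec <- recovery_experiment(cfg, n_reps = 30, estimator = "moment", seed = 42)
  expect_length(rec$estimates, 30)
  expect_equal(rec$n_excluded, sum(is.na(rec$estimates)))
  expect_lt(abs(rec$median - 30) / 30, 0.5)
  expect_true(rec$interval[1] <= rec$median && rec$median <= rec$interval[2])
  # reproducible under the same master seed
  rec2 <- recovery_experiment(cfg, n_reps = 30, estimator = "moment", seed = 42)
  expect_identical(rec$estimates, rec2$estimates)
})

test_that("larger disease samples reduce the RMSE of the age estimate", {
  rmse_at <- function(n) {
    cfg <- sim_config(sim_map_single(1), founder1(), sim_bg_single(0.3),
                      g = 30, r = 0.25, n_disease = n, n_control = 300,
                      pop_cap = 2000)
    recovery_experiment(cfg, n_reps = 60, estimator = "moment", seed = 7)$rmse
  }
  r <- vapply(c(50, 100, 200), rmse_at, numeric(1))
  expect_lt(r[3], r[1])            # monotone end to end
  expect_lt(r[2], r[1] * 1.15)     # intermediate within MC noise
})

test_that("ABC posterior behaves at the degenerate extremes", {
  cfg <- sim_config(sim_map_single(2), founder1(), sim_bg_single(0.3),
                    g = 20, r = 0.25, n_disease = 24, n_control = 60,
                    pop_cap = 200)
  obs <- simulate_cohort(cfg, seed = 77)$table

  # infinite tolerance accepts everything: uniform posterior
  post <- abc_posterior(obs, cfg, g_grid = c(10, 20, 30), n_sims_per_g = 20,
                        tolerance = Inf, seed = 1)
  expect_equal(post$weights, rep(1 / 3, 3))

  # a single-point grid concentrates all mass
  post1 <- abc_posterior(obs, cfg, g_grid = 20, n_sims_per_g = 20,
                         tolerance = Inf, seed = 2)
  expect_equal(post1$weights, 1)
  expect_equal(post1$credible_interval, c(20, 20))

  # zero tolerance with few sims: no acceptances -> informative error
  expect_error(abc_posterior(obs, cfg, g_grid = c(10, 30), n_sims_per_g = 3,
                             tolerance = 0, seed = 3), "tolerance")
})
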