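subset_ce_for_test <- function(ds, level) {
  keep <- ds$covariates$subgroup == level
  ce_dataset(tx = ds$tx[keep], cost = ds$cost[keep], effect = ds$effect[keep],
             allow_negative_cost = TRUE)
}

make_fit_stub <- function(b, p2) {
  structure(list(coefficients = c(`(Intercept)` = 0, tx = b),
                 p_two_sided = c(`(Intercept)` = 1, tx = p2)),
            class = "nb_linear_fit")
}

test_that("one-sided conversion keyed on the INB sign", {
  expect_equal(prob_ce_parametric(make_fit_stub(898, 0.9080)), 0.546)
  expect_equal(prob_ce_parametric(make_fit_stub(-898, 0.9080)), 0.454)
  expect_equal(prob_ce_parametric(make_fit_stub(1, 1e-12)), 1, tolerance = 1e-10)
  expect_equal(prob_ce_parametric(make_fit_stub(0, 1)), 0.5)
})

test_that("parametric CEAC endpoints follow the cost and effect fits", {
  d <- random_ds(60, seed = 8)
  inc <- incremental_summary(d)
  grid <- c(0, 1e5, 1e12)
  ceac <- ceac_parametric(d, grid)
  expect_true(all(ceac$prob_ce >= 0 & ceac$prob_ce <= 1))
  # wtp = 0: one-sided probability that the treatment saves money
  p0 <- if (-inc$delta_cost > 0) 1 - inc$p_cost / 2 else inc$p_cost / 2
  expect_equal(ceac$prob_ce[1], p0)
  # huge wtp: approaches the one-sided probability the effect is positive
  pe <- if (inc$delta_effect > 0) 1 - inc$p_effect / 2 else inc$p_effect / 2
  expect_equal(ceac$prob_ce[3], pe, tolerance = 1e-4)
})

test_that("parametric CEAC equals one half at the point-estimate ICER", {
  d <- generate_ce_trial(bvn_config(n_per_arm = 200, seed = 3))
  inc <- incremental_summary(d)
  lam <- inc$delta_cost / inc$delta_effect
  expect_gt(lam, 0)
  prob <- prob_ce_parametric(fit_nb(d, lam))
  expect_equal(prob, 0.5, tolerance = 1e-6)
})

test_that("a dominated estimate keeps the CEAC below one half at every WTP", {
  ds <- generate_ce_trial(co17_like_preset(seed = 17))
  mut <- subset_ce_for_test(ds, "MUT")
  inc <- incremental_summary(mut)
  ceac <- ceac_parametric(mut, default_wtp_grid())
  if (inc$delta_effect < 0 && inc$delta_cost > 0) {
    # every INB point estimate is negative, so every probability is < 0.5
    expect_true(all(ceac$prob_ce < 0.5))
  }
  # a clearly less-effective, costlier treatment: never near cost-effective
  cfg <- bvn_config(n_per_arm = 400, delta_cost = 15000, delta_effect = -0.1,
                    effect_sd = 0.2, sd_cost_cv = 0.6, seed = 18)
  d <- generate_ce_trial(cfg)
  ceac2 <- ceac_parametric(d, default_wtp_grid())
  expect_lt(max(ceac2$prob_ce), 0.05)
})

test_that("seeded bootstrap is bit-reproducible and seed-sensitive", {
  d <- random_ds(30, seed = 1)
  r1 <- bootstrap_replicates(d, 50, seed = 42)
  r2 <- bootstrap_replicates(d, 50, seed = 42)
  r3 <- bootstrap_replicates(d, 50, seed = 43)
  expect_identical(r1$delta_cost_reps, r2$delta_cost_reps)
  expect_identical(r1$delta_effect_reps, r2$delta_effect_reps)
  expect_false(identical(r1$delta_cost_reps, r3$delta_cost_reps))
  expect_error(bootstrap_replicates(d, 50), "seed")
})

test_that("resampling two identical patients per arm reproduces point estimates", {
  d <- ce_dataset(tx = c(0, 0, 1, 1), cost = c(100, 100, 300, 300),
                  effect = c(0.2, 0.2, 0.5, 0.5))
  r <- bootstrap_replicates(d, 1, seed = 7)
  expect_equal(r$delta_cost_reps, 200)
  expect_equal(r$delta_effect_reps, 0.3)
  expect_true(r$degenerate)
})

test_that("bootstrap spread matches the analytic SE on Gaussian data", {
  d <- generate_ce_trial(bvn_config(n_per_arm = 300, seed = 9))
  inc <- incremental_summary(d)
  r <- bootstrap_replicates(d, 2000, seed = 11)
  expect_lt(abs(stats::sd(r$delta_cost_reps) - inc$se_cost) / inc$se_cost, 0.15)
  expect_lt(abs(stats::sd(r$delta_effect_reps) - inc$se_effect) / inc$se_effect,
            0.15)
})

test_that("bootstrap CEAC counts positive-INB replicates with half-ties", {
  reps <- structure(list(B = 4, seed = 1L,
                         delta_cost_reps = c(-10, -10, 10, 0),
                         delta_effect_reps = c(0, 0, 0, 0),
                         degenerate = rep(FALSE, 4),
                         stratified = TRUE, adjusted = FALSE),
                    class = "nb_bootstrap")
  ceac <- ceac_bootstrap(reps, grid = c(0, 100))
  # INB(0) = -dC: two positive, one negative, one exact zero -> 5/8
  expect_equal(ceac$prob_ce, c(0.625, 0.625))
  # all replicates identical and positive -> probability one
  reps$delta_cost_reps <- rep(-5, 4)
  expect_equal(ceac_bootstrap(reps, 0)$prob_ce, 1)
})

test_that("bootstrap CEAC at zero WTP is the fraction of cost-saving replicates", {
  d <- random_ds(40, seed = 12)
  r <- bootstrap_replicates(d, 500, seed = 2)
  ceac <- ceac_bootstrap(r, c(0, 5e4))
  expect_equal(ceac$prob_ce[1],
               mean(r$delta_cost_reps < 0) + 0.5 * mean(r$delta_cost_reps == 0))
})

test_that("percentile intervals: degeneracy, nesting, normal-theory agreement", {
  d <- generate_ce_trial(bvn_config(n_per_arm = 500, seed = 15))
  r <- bootstrap_replicates(d, 4000, seed = 23)
  lam <- 150000
  ci95 <- bootstrap_ci_inb(r, lam, 0.95)
  ci80 <- bootstrap_ci_inb(r, lam, 0.80)
  expect_lt(ci95[["lower"]], ci80[["lower"]])
  expect_gt(ci95[["upper"]], ci80[["upper"]])
  # parametric t interval as the normal-theory oracle: endpoints within 10%
  cv <- sweep_inb(d, c(lam))
  expect_lt(abs(ci95[["lower"]] - cv$ci_low) / abs(cv$ci_low), 0.10)
  expect_lt(abs(ci95[["upper"]] - cv$ci_high) / abs(cv$ci_high), 0.10)
  # degenerate replicates give a zero-width interval
  r0 <- structure(list(B = 200, seed = 1L,
                       delta_cost_reps = rep(7, 200),
                       delta_effect_reps = rep(0.1, 200),
                       degenerate = rep(TRUE, 200),
                       stratified = TRUE, adjusted = FALSE),
                  class = "nb_bootstrap")
  ci <- bootstrap_ci_inb(r0, 100)
  expect_equal(unname(ci[1]), unname(ci[2]))
  expect_warning(bootstrap_ci_inb(structure(list(B = 50, seed = 1L,
                                                 delta_cost_reps = rnorm(50),
                                                 delta_effect_reps = rnorm(50)),
                                            class = "nb_bootstrap"), 0),
                 "B = 100")
})

test_that("adjusted bootstrap refits are deterministic under a seed", {
  d <- random_ds(25, seed = 14)
  r1 <- bootstrap_replicates(d, 30, seed = 5, covariates = c("age", "grp"))
  r2 <- bootstrap_replicates(d, 30, seed = 5, covariates = c("age", "grp"))
  expect_identical(r1$delta_cost_reps, r2$delta_cost_reps)
  expect_true(r1$adjusted)
})
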