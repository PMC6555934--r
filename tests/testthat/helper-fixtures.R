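# Shared fixtures, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 4-patient toy trial: arm means cost 100/150, effect 1.0/1.5
toy_ds <- function() {
  ce_dataset(tx = c(0, 0, 1, 1),
             cost = c(50, 150, 100, 200),
             effect = c(0.5, 1.5, 1.0, 2.0))
}

toy_csv_text <- function() {
  paste("tx,cost,effect",
        "0,50,0.5", "0,150,1.5", "1,100,1.0", "1,200,2.0", sep = "\n")
}

write_toy_csv <- function(lines = toy_csv_text()) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random small dataset with a numeric and a categorical covariate
random_ds <- function(n_per_arm = 25, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_arm
    tx <- rep(c(0, 1), each = n_per_arm)
    age <- stats::rnorm(n, 60, 8)
    grp <- sample(c("a", "b"), n, replace = TRUE)
    cost <- 1000 + 400 * tx + 10 * age + 50 * (grp == "b") +
      stats::rnorm(n, 0, 200)
    effect <- 0.5 + 0.1 * tx + 0.002 * age - 0.01 * (grp == "b") +
      stats::rnorm(n, 0, 0.1)
    ce_dataset(tx = tx, cost = abs(cost), effect = effect,
               covariates = data.frame(age = age, grp = grp))
  })
}

# bivariate-normal CE trial via the package generator (normal cost family)
bvn_config <- function(n_per_arm = 500, delta_cost = 20000, delta_effect = 0.1,
                       control_cost = 30000, control_effect = 0.5,
                       sd_cost_cv = 1, effect_sd = 0.3, rho = 0.3, seed = 7) {
  synth_config(
    strata = data.frame(name = "one", n_control = n_per_arm,
                        n_treat = n_per_arm,
                        control_cost = control_cost,
                        control_effect = control_effect,
                        delta_cost = delta_cost, delta_effect = delta_effect,
                        effect_sd = effect_sd, stringsAsFactors = FALSE),
    cost_distribution = "normal", cost_cv = sd_cost_cv, rho = rho, seed = seed)
}

# closed-form Fieller interval for the ICER from the incremental summary:
# roots of (dE^2 - t^2 vE) L^2 - 2 (dE dC - t^2 c) L + (dC^2 - t^2 vC) = 0
fieller_closed_form <- function(inc, tcrit) {
  vE <- inc$se_effect^2
  vC <- inc$se_cost^2
  cc <- inc$resid_cov
  A <- inc$delta_effect^2 - tcrit^2 * vE
  B <- -2 * (inc$delta_effect * inc$delta_cost - tcrit^2 * cc)
  C <- inc$delta_cost^2 - tcrit^2 * vC
  disc <- B^2 - 4 * A * C
  if (disc < 0 || A == 0) return(NULL)
  sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
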