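make_summary <- function(ages, dmean = 1.8, dvar = 9.36,
                         b_mean = 0, b_var = 0) {
  data.frame(individual_id = sprintf("i%d", seq_along(ages)), age = ages,
             mean_burden = b_mean + dmean * ages,
             var_burden = b_var + dvar * ages,
             n_cells = 5L)
}

test_that("cohort summaries use unbiased variances and the 3-cell rule", {
  recs <- data.frame(
    individual_id = c(rep("a", 3), rep("b", 2), rep("c", 4)),
    age = c(rep(50, 3), rep(60, 2), rep(70, 4)),
    cell_id = sprintf("c%d", 1:9),
    mutation_count = c(10, 12, 14, 5, 7, 20, 22, 24, 26),
    surveyed_length_bp = 6e9
  )
  coh <- strandseg:::new_cohort(recs, "year")
  expect_warning(s <- summarize_cohort(coh), "fewer than 3 cells")
  expect_equal(nrow(s), 2)
  a <- s[s$individual_id == "a", ]
  expect_equal(a$mean_burden, 12)
  expect_equal(a$var_burden, 4)  # unbiased: sum((x - 12)^2) / 2
  expect_equal(s$n_cells, c(3L, 4L))

  # all individuals below the threshold is an error, not an empty table
  coh_small <- strandseg:::new_cohort(recs[4:5, ], "year")
  expect_warning(expect_error(summarize_cohort(coh_small), "3 cells"))
})

test_that("slope fitting is exact on linear data and permutation-invariant", {
  s <- make_summary(c(10, 20, 30, 40), b_mean = 3, b_var = 12)
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_slopes(s))
  expect_equal(fit$dmean_dt, 1.8)
  expect_equal(fit$dvar_dt, 9.36)
  expect_equal(fit$se_mean, 0, tolerance = 1e-10)
  expect_equal(fit$se_var, 0, tolerance = 1e-10)

  set.seed(3)
  s2 <- make_summary(c(10, 25, 40, 55, 70))
  s2$mean_burden <- s2$mean_burden + rnorm(5)
  s2$var_burden <- s2$var_burden + rnorm(5, sd = 4)
  f_a <- fit_slopes(s2)
  f_b <- fit_slopes(s2[sample(5), ])
  expect_equal(f_a$dmean_dt, f_b$dmean_dt)
  expect_equal(f_a$se_var, f_b$se_var)

  expect_error(fit_slopes(make_summary(c(10, 10, 10))), "distinct ages")
  expect_error(fit_slopes(make_summary(c(10, 20))), "3 individuals")
})

test_that("moment inversion reproduces the published tissue estimates", {
  colon <- infer_parameters(load_tissue_summaries("colon"), 52)
  expect_equal(round(colon$p_hat, 3), 0.973)
  expect_equal(signif(colon$mu_hat, 3), 4.37e-9)

  liver <- infer_parameters(load_tissue_summaries("liver"), 52)
  expect_equal(round(liver$p_hat, 3), 0.988)
  expect_equal(signif(liver$mu_hat, 3), 8.48e-9)

  # published brackets correspond to same-direction slope shifts
  cc <- infer_parameters(load_tissue_summaries("colon"), 52,
                         bounds = "correlated")
  expect_equal(round(cc$p_bounds, 3), c(0.971, 0.974))
  expect_equal(signif(cc$mu_bounds, 3), c(4.26e-9, 4.46e-9))

  # bounds always bracket the point estimate, under every method
  for (b in c("corners", "correlated")) {
    r <- infer_parameters(load_tissue_summaries("small_intestine"), 52,
                          bounds = b)
    expect_true(r$p_bounds[1] <= r$p_hat && r$p_hat <= r$p_bounds[2])
    expect_true(r$mu_bounds[1] <= r$mu_hat && r$mu_hat <= r$mu_bounds[2])
  }

  # Poisson-limit and invalid inputs
  s_pois <- slope_estimates(6, 0, 6, 0)
  expect_equal(infer_parameters(s_pois, 1)$p_hat, 0)
  expect_error(infer_parameters(slope_estimates(6, 0, 3, 0), 1),
               "underdispersed")
  expect_error(infer_parameters(slope_estimates(-1, 0, 9, 0), 1), "positive")
  expect_error(infer_parameters(load_tissue_summaries("colon"), 0),
               "division_rate")
})

test_that("per-division inversion is the exact inverse of the slope maps", {
  expect_equal(infer_parameters_per_division(1.8, 9.36),
               c(p = 0.7, muL = 6))
  expect_equal(infer_parameters_per_division(6, 6), c(p = 0, muL = 6))

  set.seed(99)
  for (i in 1:40) {
    p <- runif(1, 0, 0.999)
    ml <- runif(1, 1e-3, 100)
    pars <- quick_params(p_seg = p, mu_L = ml, n_cells = 1)
    est <- infer_parameters_per_division(slope_mean_per_time(pars),
                                         slope_var_per_time(pars))
    expect_equal(unname(est[["p"]]), p, tolerance = 1e-12)
    expect_equal(unname(est[["muL"]]), ml, tolerance = 1e-12)
  }
})

test_that("division-rate scans are monotone and match published ranges", {
  colon <- load_tissue_summaries("colon")
  scan <- scan_division_rate(colon, exp(seq(log(12), log(365),
                                            length.out = 40)))
  expect_true(all(diff(scan$p_hat) >= 0))
  expect_true(all(diff(scan$mu_hat) <= 0))

  # once per month ... daily brackets the published scan range for colon
  ends <- scan_division_rate(colon, c(12, 365))
  expect_equal(round(ends$p_hat, 3), c(0.892, 0.996))

  # a single rate reduces to plain inference
  one <- scan_division_rate(colon, 52)
  expect_equal(one$p_hat, infer_parameters(colon, 52)$p_hat)

  # large-rate limit: p -> 1, muL -> R - 1
  lim <- scan_division_rate(colon, 1e9)
  expect_equal(lim$p_hat, 1, tolerance = 1e-6)
  expect_equal(lim$mu_hat * 6e9, 985.5 / 37.2 - 1, tolerance = 1e-6)
})

test_that("estimates are invariant to a joint rescaling of the time unit", {
  s_year <- slope_estimates(37.2, 3.1, 985.5, 103, time_unit = "year")
  s_day <- slope_estimates(37.2 / 365, 3.1 / 365, 985.5 / 365, 103 / 365,
                           time_unit = "day")
  r_year <- infer_parameters(s_year, 52)
  r_day <- infer_parameters(s_day, 52 / 365)
  expect_equal(r_day$p_hat, r_year$p_hat)
  expect_equal(r_day$muL_hat, r_year$muL_hat)
})

test_that("parameters are recovered from synthetic cohorts", {
  # plug-in SE from the half-width of the corner bounds
  cases <- list(c(0.7, 6), c(0.9, 6), c(0.95, 60))
  ages <- round(seq(30, 330, length.out = 24))
  n_rep <- 50
  for (case in cases) {
    p_true <- case[1]; ml_true <- case[2]
    pars <- model_params(n_cells = 60, p_seg = p_true, mu_L = ml_true)
    hit <- logical(n_rep)
    for (r in seq_len(n_rep)) {
      coh <- generate_cohort(pars, ages, 8, seed = 5000 + r)
      res <- infer_parameters(fit_slopes(summarize_cohort(coh)),
                              division_rate = 1)
      se_p <- (res$p_bounds[2] - res$p_bounds[1]) / 2
      se_ml <- (res$muL_bounds[2] - res$muL_bounds[1]) / 2
      hit[r] <- abs(res$p_hat - p_true) <= 3 * se_p &&
        abs(res$muL_hat - ml_true) <= 3 * se_ml
    }
    expect_gte(mean(hit), 0.95)
  }
})

test_that("unmodelled background mutations depress the segregation estimate", {
  bias <- background_bias_table(backgrounds = c(0, 0.5, 1, 2),
                                p_true = 0.95, mu_L_true = 6,
                                n_cells = 1000, n_steps = 150, seed = 13)
  expect_true(all(diff(bias$p_hat) < 0))
  expect_true(all(bias$p_hat[-1] < 0.95))
  expect_equal(bias$p_hat[1], 0.95, tolerance = 0.05)
})
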