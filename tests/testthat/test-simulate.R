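test_that("runs are reproducible and the pool size is conserved", {
  pars <- quick_params(n_cells = 200)
  r1 <- run_simulation(pars, 30, snapshot_every = 5, seed = 11,
                       keep_burdens = TRUE)
  r2 <- run_simulation(pars, 30, snapshot_every = 5, seed = 11,
                       keep_burdens = TRUE)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$final_burdens, r2$final_burdens)
  expect_length(r1$final_burdens, 200)

  r3 <- run_simulation(pars, 30, snapshot_every = 5, seed = 12)
  expect_false(identical(r1$snapshots, r3$snapshots))

  # n_steps = 0 yields only the initial all-zero snapshot
  r0 <- run_simulation(pars, 0, seed = 1)
  expect_equal(nrow(r0$snapshots), 1)
  expect_equal(r0$snapshots$mean_burden, 0)

  # pool size after every step, in every mode
  set.seed(5)
  st <- new_population(100L)
  pm <- quick_params(n_cells = 100, p_seg = 1, symmetric_fraction = 0.3)
  for (i in 1:20) {
    st <- step_symmetric_mix(st, pm)
    expect_length(st$burdens, 100)
  }
  st2 <- new_population(100L)
  for (i in 1:20) {
    st2 <- step_asymmetric(st2, quick_params(n_cells = 100))
    expect_length(st2$burdens, 100)
  }
})

test_that("asymmetric kernel has the analytic burden moments", {
  # perfect segregation: no stem-cell mutations ever
  rp1 <- run_simulation(quick_params(p_seg = 1, n_cells = 500), 50, 10,
                        seed = 2, keep_burdens = TRUE)
  expect_true(all(rp1$final_burdens == 0))
  expect_true(all(rp1$snapshots$var_burden == 0))

  # p = 0: one division adds Poisson(muL) to every cell
  rp0 <- run_simulation(quick_params(p_seg = 0, n_cells = 20000), 1,
                        seed = 3, keep_burdens = TRUE)
  x <- rp0$final_burdens
  expect_lt(abs(mean(x) - 6), 4 * sd(x) / sqrt(length(x)))
  expect_lt(abs(var(x) - 6), 4 * se_of_sample_var(x))

  # empirical moments track the closed forms at several division counts
  pars <- quick_params(p_seg = 0.7, mu_L = 6, n_cells = 20000)
  run <- run_simulation(pars, 500, snapshot_every = 1, seed = 17,
                        keep_burdens = TRUE)
  for (n in c(10, 100, 500)) {
    sn <- run$snapshots[run$snapshots$step == n, ]
    se_mean <- sqrt(expected_var_burden(pars, n) / pars$n_cells)
    expect_lt(abs(sn$mean_burden - expected_mean_burden(pars, n)),
              4 * se_mean)
  }
  x <- run$final_burdens
  expect_lt(abs(var(x) - expected_var_burden(pars, 500)),
            4 * se_of_sample_var(x))
})

test_that("single-lineage burden distribution matches the compound law", {
  # exact small-instance check: N = 1, two divisions, chi-square against the
  # closed-form compound Binomial-Poisson pmf
  for (p in c(0, 0.5)) {
    pars <- quick_params(p_seg = p, mu_L = 2, n_cells = 1)
    x <- replicate_single_cell(2e4, 2, pars, seed = 100 + 10 * p)
    support <- 0:max(15, max(x))
    probs <- burden_pmf_oracle(support, n = 2, p = p, muL = 2)
    # pool the upper tail so expected counts stay above 5
    cut <- min(which(cumsum(probs) > 1 - 5 / length(x)))
    obs <- tabulate(pmin(x, cut) + 1L, nbins = cut + 1L)
    pr <- c(probs[1:cut], 1 - sum(probs[1:cut]))
    gof <- suppressWarnings(chisq.test(obs, p = pr))
    expect_gt(gof$p.value, 0.01)
  }
  # p = 1 collapses to a point mass at zero
  pars1 <- quick_params(p_seg = 1, mu_L = 2, n_cells = 1)
  expect_true(all(replicate_single_cell(200, 2, pars1, seed = 9) == 0))
})

test_that("symmetric-mix kernel restores homeostasis and matches moments", {
  # symmetric_fraction = 0 behaves like the asymmetric kernel in distribution
  pars0 <- quick_params(p_seg = 0.8, n_cells = 5000, symmetric_fraction = 0)
  set.seed(21)
  st <- new_population(5000L)
  for (i in 1:30) st <- step_symmetric_mix(st, pars0)
  m_expect <- expected_mean_burden(pars0, 30)
  expect_lt(abs(mean(st$burdens) - m_expect),
            4 * sd(st$burdens) / sqrt(5000))

  # with p = 1 and a symmetric fraction s, only self-renewal daughters gain
  # mutations: the mean accrues s * muL per round
  pars_s <- quick_params(p_seg = 1, mu_L = 6, n_cells = 5000,
                         symmetric_fraction = 0.1)
  run <- run_simulation(pars_s, 100, snapshot_every = 10, seed = 22,
                        keep_burdens = TRUE)
  expect_lt(abs(mean(run$final_burdens) - 0.1 * 6 * 100),
            4 * sd(run$final_burdens) / sqrt(5000))

  # degenerate pools are refused
  set.seed(1)
  expect_error(
    step_symmetric_mix(new_population(1L),
                       quick_params(n_cells = 1, symmetric_fraction = 1)),
    "degenerate")
})

test_that("background mutations shift mean and variance equally", {
  pars <- quick_params(n_cells = 50000, mu_background = 3)
  set.seed(31)
  st <- new_population(50000L)
  st <- apply_background_mutations(st, pars, dt = 2)
  x <- st$burdens
  expect_lt(abs(mean(x) - 6), 4 * sd(x) / sqrt(length(x)))
  expect_lt(abs(var(x) - 6), 4 * se_of_sample_var(x))

  # zero rate leaves the state untouched
  st0 <- new_population(10L)
  expect_identical(apply_background_mutations(st0, quick_params(), dt = 1)$burdens,
                   st0$burdens)

  # excess (beyond-Poisson) variance slope is unchanged by background noise:
  # var slope minus mean slope is the same with and without background
  base <- quick_params(p_seg = 0.7, mu_L = 6, n_cells = 10000)
  bg <- quick_params(p_seg = 0.7, mu_L = 6, n_cells = 10000,
                     mu_background = 2)
  sl <- function(run, col) coef(lm(run$snapshots[[col]] ~ run$snapshots$step))[2]
  r1 <- run_simulation(base, 150, 5, seed = 41)
  r2 <- run_simulation(bg, 150, 5, seed = 41)
  excess1 <- sl(r1, "var_burden") - sl(r1, "mean_burden")
  excess2 <- sl(r2, "var_burden") - sl(r2, "mean_burden")
  expect_equal(unname(excess2), unname(excess1), tolerance = 0.1)

  # the two stochastic modes cannot be combined in one run
  expect_error(
    run_simulation(quick_params(symmetric_fraction = 0.1, mu_background = 1),
                   10, seed = 1),
    "not supported")
})

test_that("synthetic cohorts have the declared shape and provenance", {
  pars <- quick_params(n_cells = 100)
  coh <- generate_cohort(pars, ages = c(5, 10, 20, 40, 80), 3, seed = 8)
  expect_s3_class(coh, "cohort")
  expect_equal(nrow(coh$records), 15)
  expect_equal(coh$time_unit, "year")
  expect_equal(length(unique(coh$records$individual_id)), 5)
  expect_true(all(coh$records$mutation_count >= 0))
  expect_true(all(coh$records$surveyed_length_bp == pars$genome_length))

  # reproducible under the same seed
  coh2 <- generate_cohort(pars, ages = c(5, 10, 20, 40, 80), 3, seed = 8)
  expect_identical(coh$records, coh2$records)

  # cannot sample more cells than the pool holds
  expect_error(generate_cohort(pars, ages = c(5, 10), 101, seed = 1),
               "pool")

  # all-newborn cohorts carry zero burden and cannot support a slope fit
  coh0 <- generate_cohort(pars, ages = c(0, 0, 0), 4, seed = 2)
  expect_true(all(coh0$records$mutation_count == 0))
  expect_error(fit_slopes(summarize_cohort(coh0)), "distinct ages")
})
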