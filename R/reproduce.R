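#' Per-tissue parameter estimates from the packaged slopes
#'
#' Applies [infer_parameters] to every packaged tissue at its default division
#' rate (one division per week for adult tissues, one per 48 h for
#' development).
#'
#' @param bounds Bound method passed to [infer_parameters].
#' @return Data frame: `tissue`, `lambda`, `p_hat`, `p_low`, `p_high`,
#'   `muL_hat`, `mu_hat`, `mu_low`, `mu_high`, `surveyed_length_bp`.
#' @export
tissue_inference_table <- function(bounds = "corners") {
  tab <- load_tissue_summaries()
  rows <- lapply(tab$tissue, function(tis) {
    s <- load_tissue_summaries(tis)
    r <- infer_parameters(s, s$default_lambda, bounds = bounds)
    data.frame(tissue = tis, lambda = s$default_lambda,
               p_hat = r$p_hat, p_low = r$p_bounds[1], p_high = r$p_bounds[2],
               muL_hat = r$muL_hat, mu_hat = r$mu_hat,
               mu_low = r$mu_bounds[1], mu_high = r$mu_bounds[2],
               surveyed_length_bp = r$surveyed_length)
  })
  do.call(rbind, rows)
}

#' Median segregation probability over the four adult non-brain tissues
#'
#' Median of the point estimates for colon, small intestine, liver and skin
#' at one division per week.
#'
#' @return A single probability.
#' @export
adult_median_p <- function() {
  tab <- tissue_inference_table()
  stats::median(tab$p_hat[tab$tissue %in%
                            c("colon", "small_intestine", "liver", "skin")])
}

#' Simulation-and-recovery replica of the model verification experiment
#'
#' Simulates N stem cells with asymmetric divisions at the stated parameters,
#' regresses the snapshot mean and variance on the division count (OLS, free
#' intercept), and inverts the fitted per-division slopes with
#' [infer_parameters_per_division]. At the default scale (N = 20000, p = 0.7,
#' mu*L = 6, 300 divisions) the recovered parameters land within Monte-Carlo
#' error of the truth.
#'
#' @param seed Integer seed.
#' @param n_cells,p_seg,mu_L Simulation parameters.
#' @param n_steps Number of synchronous divisions (>= 300 recommended for a
#'   stable regression).
#' @return List: `dmean_dn`, `dvar_dn` (fitted per-division slopes), `p_hat`,
#'   `muL_hat`, and the `simulation_run`.
#' @export
fig_recovery_replica <- function(seed, n_cells = 20000, p_seg = 0.7,
                                 mu_L = 6, n_steps = 300) {
  params <- model_params(n_cells = n_cells, p_seg = p_seg, mu_L = mu_L)
  run <- run_simulation(params, n_steps = n_steps, snapshot_every = 1L,
                        seed = seed)
  sn <- run$snapshots
  dmean <- stats::coef(stats::lm(mean_burden ~ step, sn))[["step"]]
  dvar <- stats::coef(stats::lm(var_burden ~ step, sn))[["step"]]
  est <- infer_parameters_per_division(dmean, dvar)
  list(dmean_dn = dmean, dvar_dn = dvar,
       p_hat = unname(est[["p"]]), muL_hat = unname(est[["muL"]]),
       run = run)
}

# variance/mean ratio trajectory of a run, after a burn-in fraction of steps
# (the ratio is undefined while the mean is near zero)
ratio_trajectory <- function(run, burn_in = 0.2) {
  sn <- run$snapshots
  keep <- sn$step > burn_in * max(sn$step)
  ratio <- ifelse(sn$mean_burden[keep] > 0,
                  sn$var_burden[keep] / sn$mean_burden[keep], NA_real_)
  data.frame(step = sn$step[keep], ratio = ratio)
}

#' Compare asymmetric and symmetric-mix division dynamics
#'
#' Runs replicate simulations of (i) purely asymmetric divisions with
#' imperfect segregation and (ii) perfect segregation with a fraction of
#' symmetric differentiation / self-renewal pairs, and summarises the
#' variance-to-mean ratio of the burden. Both processes share the mean
#' accumulation rate and the same time-averaged dispersion ratio, but the
#' across-replicate spread of the ratio grows with time only in the symmetric
#' mix -- the diagnostic that could distinguish the two mechanisms.
#'
#' @param n_replicates Replicate runs per mode.
#' @param n_cells Pool size N.
#' @param p_asym Segregation probability of the purely asymmetric mode.
#' @param symmetric_fraction Symmetric-division fraction of the mixed mode
#'   (whose `p_seg` is 1).
#' @param mu_L Per-division mutation mean.
#' @param n_steps Divisions per run.
#' @param seed Base seed; replicate r of mode m uses a derived stream.
#' @param burn_in Fraction of early steps excluded from ratio summaries.
#' @return List with `per_replicate` (mode, replicate, time-averaged ratio),
#'   `ratio_var_trend` (per mode: slope of across-replicate ratio variance vs
#'   step, with one-sided p-value for a positive trend), and `ci` (95%
#'   confidence intervals of the time-averaged ratio per mode).
#' @export
division_mode_comparison <- function(n_replicates = 30, n_cells = 5000,
                                     p_asym = 0.9, symmetric_fraction = 0.1,
                                     mu_L = 6, n_steps = 150, seed = 1,
                                     burn_in = 0.2) {
  modes <- list(
    asymmetric = model_params(n_cells = n_cells, p_seg = p_asym, mu_L = mu_L),
    symmetric_mix = model_params(n_cells = n_cells, p_seg = 1, mu_L = mu_L,
                                 symmetric_fraction = symmetric_fraction)
  )
  per_rep <- list()
  trend <- list()
  ci <- list()
  for (m in names(modes)) {
    ratios <- NULL  # replicate x step matrix
    avg <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      sd_r <- (seed + 7919 * r + 104729 * match(m, names(modes))) %%
        .Machine$integer.max
      run <- run_simulation(modes[[m]], n_steps = n_steps,
                            snapshot_every = 5L, seed = sd_r)
      tr <- ratio_trajectory(run, burn_in)
      if (is.null(ratios)) {
        ratios <- matrix(NA_real_, n_replicates, nrow(tr))
      }
      ratios[r, ] <- tr$ratio
      avg[r] <- mean(tr$ratio, na.rm = TRUE)
    }
    steps <- tr$step  # snapshot grid is shared across replicates
    v_t <- apply(ratios, 2, stats::var, na.rm = TRUE)
    fit <- stats::lm(v_t ~ steps)
    tt <- stats::coef(summary(fit))["steps", ]
    per_rep[[m]] <- data.frame(mode = m, replicate = seq_len(n_replicates),
                               mean_ratio = avg)
    trend[[m]] <- data.frame(
      mode = m, var_slope = tt[["Estimate"]], se = tt[["Std. Error"]],
      p_one_sided = stats::pt(tt[["t value"]],
                              df = fit$df.residual, lower.tail = FALSE)
    )
    ci[[m]] <- data.frame(
      mode = m, mean_ratio = mean(avg),
      ci_low = mean(avg) - stats::qt(0.975, n_replicates - 1) *
        stats::sd(avg) / sqrt(n_replicates),
      ci_high = mean(avg) + stats::qt(0.975, n_replicates - 1) *
        stats::sd(avg) / sqrt(n_replicates)
    )
  }
  list(per_replicate = do.call(rbind, per_rep),
       ratio_var_trend = do.call(rbind, trend),
       ci = do.call(rbind, ci))
}

#' Bias of the moment estimators under background mutations
#'
#' Simulates mutation accumulation with an additional division-independent
#' mutation rate hitting all cells, then infers (p, mu*L) from the time
#' slopes while (wrongly) attributing all mutations to divisions. The
#' segregation probability is systematically underestimated once the
#' background is positive, increasingly so as it grows.
#'
#' @param backgrounds Vector of background rates (mutations per surveyed
#'   region per time unit; divisions occur at `division_rate = 1`, so the
#'   unit equals one division round).
#' @param p_true,mu_L_true Generative parameters.
#' @param n_cells Pool size.
#' @param n_steps Divisions per run.
#' @param seed Integer seed.
#' @return Data frame: `background`, `p_hat`, `muL_hat`.
#' @export
background_bias_table <- function(backgrounds = c(0, 0.5, 1, 2),
                                  p_true = 0.95, mu_L_true = 6,
                                  n_cells = 2000, n_steps = 200, seed = 1) {
  rows <- lapply(seq_along(backgrounds), function(i) {
    params <- model_params(n_cells = n_cells, p_seg = p_true,
                           mu_L = mu_L_true,
                           mu_background = backgrounds[i])
    run <- run_simulation(params, n_steps = n_steps, snapshot_every = 2L,
                          seed = (seed + 7 * i) %% .Machine$integer.max)
    sn <- run$snapshots
    dmean <- stats::coef(stats::lm(mean_burden ~ step, sn))[["step"]]
    dvar <- stats::coef(stats::lm(var_burden ~ step, sn))[["step"]]
    est <- infer_parameters_per_division(dmean, dvar)
    data.frame(background = backgrounds[i],
               p_hat = unname(est[["p"]]), muL_hat = unname(est[["muL"]]))
  })
  do.call(rbind, rows)
}

#' Regenerate the package's headline analyses into a report directory
#'
#' One-shot driver that recomputes, from the packaged slope tables and seeded
#' simulations: (a) per-tissue segregation probabilities and mutation rates
#' at the default division rates, (b) the adult-tissue median segregation
#' probability, (c) the analytic per-division slopes at (p = 0.7, mu*L = 6)
#' and a seeded simulation-recovery replica, (d) division-rate sensitivity
#' scans per tissue, and (e) the division-mode and background-bias summaries.
#' All tables are written as TSV plus a human-readable `summary.txt`; the
#' report records the seed, so two runs with the same seed are identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for all stochastic sections.
#' @param quick Use reduced replicate counts for the stochastic sections
#'   (useful for smoke tests).
#' @return Invisibly, the list of generated file paths.
#' @export
reproduce_paper <- function(out_dir, seed = 1, quick = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  save_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }

  tissues <- tissue_inference_table()
  save_tsv(cbind(tissues[1], round(tissues[-1], 6)), "tissue_estimates.tsv")
  med_p <- adult_median_p()

  analytic <- model_params(n_cells = 1, p_seg = 0.7, mu_L = 6)
  rec <- fig_recovery_replica(seed, n_steps = if (quick) 100 else 300,
                              n_cells = if (quick) 2000 else 20000)
  save_tsv(data.frame(
    quantity = c("analytic_dmean_dn", "analytic_dvar_dn",
                 "sim_dmean_dn", "sim_dvar_dn", "sim_p_hat", "sim_muL_hat"),
    value = c(slope_mean_per_time(analytic), slope_var_per_time(analytic),
              rec$dmean_dn, rec$dvar_dn, rec$p_hat, rec$muL_hat)
  ), "simulation_recovery.tsv")

  lambdas <- exp(seq(log(12), log(365), length.out = 25))
  scans <- lapply(load_tissue_summaries()$tissue, function(tis) {
    s <- load_tissue_summaries(tis)
    ls <- if (s$time_unit == "day") lambdas / 365 else lambdas
    cbind(tissue = tis, scan_division_rate(s, ls))
  })
  save_tsv(do.call(rbind, scans), "lambda_scan.tsv")

  cmp <- division_mode_comparison(
    n_replicates = if (quick) 6 else 30,
    n_cells = if (quick) 1000 else 5000,
    n_steps = if (quick) 60 else 150, seed = seed)
  save_tsv(cmp$ci, "division_mode_ratio_ci.tsv")
  save_tsv(cmp$ratio_var_trend, "division_mode_ratio_var_trend.tsv")

  bias <- background_bias_table(
    n_cells = if (quick) 500 else 2000,
    n_steps = if (quick) 60 else 200, seed = seed)
  save_tsv(bias, "background_bias.tsv")

  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("strandseg report (package %s, seed %d)",
    as.character(utils::packageVersion("strandseg")), seed)
  w("")
  w("Per-tissue estimates at the default division rate:")
  for (i in seq_len(nrow(tissues))) {
    w("  %-26s p = %.3f (%.3f; %.3f)   mu = %.3g (%.3g; %.3g) per bp per division",
      tissues$tissue[i], tissues$p_hat[i], tissues$p_low[i],
      tissues$p_high[i], tissues$mu_hat[i], tissues$mu_low[i],
      tissues$mu_high[i])
  }
  w("")
  w("Median p over colon, small intestine, liver, skin: %.3f", med_p)
  w("")
  w("Simulation recovery at (p = 0.7, mu*L = 6): analytic slopes %.3f / %.3f,",
    slope_mean_per_time(analytic), slope_var_per_time(analytic))
  w("fitted slopes %.3f / %.3f, recovered p = %.3f, mu*L = %.3g",
    rec$dmean_dn, rec$dvar_dn, rec$p_hat, rec$muL_hat)
  w("")
  w("Division-mode dispersion ratio (time-averaged, 95%% CI):")
  for (i in seq_len(nrow(cmp$ci))) {
    w("  %-14s %.2f (%.2f; %.2f)", cmp$ci$mode[i], cmp$ci$mean_ratio[i],
      cmp$ci$ci_low[i], cmp$ci$ci_high[i])
  }
  w("Across-replicate ratio-variance trend (slope, one-sided p):")
  for (i in seq_len(nrow(cmp$ratio_var_trend))) {
    w("  %-14s %+0.4f (p = %.3g)", cmp$ratio_var_trend$mode[i],
      cmp$ratio_var_trend$var_slope[i], cmp$ratio_var_trend$p_one_sided[i])
  }
  w("")
  w("Background-mutation bias (true p = 0.95, mu*L = 6):")
  for (i in seq_len(nrow(bias))) {
    w("  background %.1f -> p_hat = %.3f, muL_hat = %.3g", bias$background[i],
      bias$p_hat[i], bias$muL_hat[i])
  }
  paths <- c(paths, summary_path)
  invisible(paths)
}
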