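#' Per-individual burden summaries
#'
#' Collapses a cohort to one row per individual: age, mean burden, unbiased
#' sample variance and cell count. Individuals with fewer than 3 cells cannot
#' contribute a meaningful variance and are dropped with a warning.
#'
#' @param cohort A `cohort` (see [generate_cohort], [read_cohort_tsv]).
#' @return Data frame with columns `individual_id`, `age`, `mean_burden`,
#'   `var_burden`, `n_cells`; attribute `surveyed_length` and `time_unit`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  recs <- cohort$records
  if (nrow(recs) == 0) stop("cohort has no records", call. = FALSE)
  split_recs <- split(recs, recs$individual_id)
  rows <- lapply(split_recs, function(d) {
    data.frame(individual_id = d$individual_id[1], age = d$age[1],
               mean_burden = mean(d$mutation_count),
               var_burden = stats::var(d$mutation_count),
               n_cells = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  few <- out$n_cells < 3
  if (any(few)) {
    warning(sum(few), " individual(s) dropped with fewer than 3 cells: ",
            paste(out$individual_id[few], collapse = ", "), call. = FALSE)
    out <- out[!few, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    stop("no individual has the 3 cells required for a variance estimate",
         call. = FALSE)
  }
  attr(out, "surveyed_length") <- recs$surveyed_length_bp[1]
  attr(out, "time_unit") <- cohort$time_unit
  out
}

#' Fit the age trends of burden mean and variance
#'
#' Two independent unweighted ordinary least-squares regressions with free
#' intercepts: mean burden vs age and burden variance vs age. The free
#' intercept absorbs any in-utero / developmental burden present at age 0;
#' the slopes and their standard errors are the model's observables.
#'
#' @param summary A per-individual table as returned by [summarize_cohort],
#'   or any data frame with columns `age`, `mean_burden`, `var_burden`.
#' @param time_unit,surveyed_length Metadata overrides; defaults come from
#'   the summary's attributes when present.
#' @return A [slope_estimates].
#' @examples
#' coh <- generate_cohort(model_params(n_cells = 200, p_seg = 0.7, mu_L = 6),
#'                        ages = seq(20, 200, by = 20), 10, seed = 7)
#' fit_slopes(summarize_cohort(coh))
#' @export
fit_slopes <- function(summary, time_unit = NULL, surveyed_length = NULL) {
  stopifnot(all(c("age", "mean_burden", "var_burden") %in% names(summary)))
  if (nrow(summary) < 3) {
    stop("need at least 3 individuals to fit slopes", call. = FALSE)
  }
  if (length(unique(summary$age)) < 2) {
    stop("need at least 2 distinct ages to fit an age trend (rank-deficient)",
         call. = FALSE)
  }
  if (is.null(time_unit)) {
    time_unit <- attr(summary, "time_unit") %||% "year"
  }
  if (is.null(surveyed_length)) {
    surveyed_length <- attr(summary, "surveyed_length") %||% 6e9
  }
  fm <- stats::lm(mean_burden ~ age, data = summary)
  fv <- stats::lm(var_burden ~ age, data = summary)
  cm <- stats::coef(summary(fm))
  cv <- stats::coef(summary(fv))
  slope_estimates(
    dmean_dt = cm["age", "Estimate"], se_mean = cm["age", "Std. Error"],
    dvar_dt = cv["age", "Estimate"], se_var = cv["age", "Std. Error"],
    time_unit = time_unit, surveyed_length = surveyed_length,
    n_individuals = nrow(summary)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# core moment inversion: R = dvar/dmean, m = dmean per division
invert_moments <- function(dmean, dvar, m) {
  if (dmean <= 0) stop("mean-burden slope must be positive", call. = FALSE)
  R <- dvar / dmean
  if (R < 1) {
    stop(sprintf(paste("variance slope below mean slope (ratio %.3f < 1):",
                       "data are underdispersed relative to the model"), R),
         call. = FALSE)
  }
  c(p = (R - 1) / ((R - 1) + m), muL = (R - 1) + m)
}

#' Infer strand-segregation probability and mutation rate from slopes
#'
#' Inverts the moment equations: with dispersion ratio
#' `R = dvar_dt / dmean_dt` and per-division mean increment
#' `m = dmean_dt / lambda`,
#' \deqn{\hat p = (R - 1) / ((R - 1) + m)}
#' \deqn{\widehat{\mu L} = (R - 1) + m}
#' and `mu_hat = muL_hat / surveyed_length`. A dispersion ratio below 1
#' (variance growing slower than the mean) is inconsistent with the model and
#' raises an error rather than clamping the estimate.
#'
#' Error bounds propagate the slopes' standard errors by plug-in:
#' `bounds = "corners"` evaluates the estimators at all four
#' `(dmean +/- SE) x (dvar +/- SE)` combinations and reports the min/max
#' (conservative, allows the two regression errors to act in opposite
#' directions); `"correlated"` uses only the two same-direction corners
#' (both slopes shifted down, both up), the convention behind the published
#' per-tissue brackets; `"bootstrap"` resamples individuals from
#' `boot_summary`, refits and re-inverts, and reports percentile bounds.
#' Corners that violate the model (ratio < 1 or nonpositive mean slope) are
#' skipped.
#'
#' @param slopes A [slope_estimates].
#' @param division_rate Stem-cell division rate lambda, in divisions per the
#'   slopes' time unit (one per week = 52/year for adult tissues; one per
#'   48 h = 0.5/day for development).
#' @param bounds Bound method, see above.
#' @param boot_summary Per-individual summary table (required for
#'   `bounds = "bootstrap"`).
#' @param n_boot Bootstrap replicates.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return An `inference_result` with fields `p_hat`, `p_bounds`, `muL_hat`,
#'   `muL_bounds`, `mu_hat`, `mu_bounds`, `division_rate_used`,
#'   `surveyed_length`.
#' @examples
#' colon <- load_tissue_summaries("colon")
#' infer_parameters(colon, division_rate = 52)
#' @export
infer_parameters <- function(slopes, division_rate,
                             bounds = c("corners", "correlated", "bootstrap"),
                             boot_summary = NULL, n_boot = 500,
                             boot_seed = 1L) {
  stopifnot(inherits(slopes, "slope_estimates"))
  bounds <- match.arg(bounds)
  if (division_rate <= 0) {
    stop("division_rate must be positive", call. = FALSE)
  }
  est <- invert_moments(slopes$dmean_dt, slopes$dvar_dt,
                        slopes$dmean_dt / division_rate)

  if (bounds == "bootstrap") {
    if (is.null(boot_summary)) {
      stop("bounds = 'bootstrap' needs `boot_summary` (per-individual table)",
           call. = FALSE)
    }
    bp <- bootstrap_bounds(boot_summary, division_rate, n_boot, boot_seed,
                           slopes)
  } else {
    dm <- if (bounds == "corners") {
      expand.grid(dmean = slopes$dmean_dt + c(-1, 1) * slopes$se_mean,
                  dvar = slopes$dvar_dt + c(-1, 1) * slopes$se_var)
    } else {
      data.frame(dmean = slopes$dmean_dt + c(-1, 1) * slopes$se_mean,
                 dvar = slopes$dvar_dt + c(-1, 1) * slopes$se_var)
    }
    corner_est <- apply(dm, 1, function(r) {
      tryCatch(invert_moments(r[["dmean"]], r[["dvar"]],
                              r[["dmean"]] / division_rate),
               error = function(e) c(p = NA_real_, muL = NA_real_))
    })
    pvals <- c(corner_est["p", ], est[["p"]])
    mvals <- c(corner_est["muL", ], est[["muL"]])
    bp <- list(p = range(pvals, na.rm = TRUE),
               muL = range(mvals, na.rm = TRUE))
  }

  structure(
    list(
      p_hat = unname(est[["p"]]),
      p_bounds = bp$p,
      muL_hat = unname(est[["muL"]]),
      muL_bounds = bp$muL,
      mu_hat = unname(est[["muL"]]) / slopes$surveyed_length,
      mu_bounds = bp$muL / slopes$surveyed_length,
      division_rate_used = division_rate,
      surveyed_length = slopes$surveyed_length,
      time_unit = slopes$time_unit,
      bounds_method = bounds
    ),
    class = "inference_result"
  )
}

bootstrap_bounds <- function(boot_summary, division_rate, n_boot, boot_seed,
                             slopes) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(boot_seed)
  n <- nrow(boot_summary)
  reps <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      s <- fit_slopes(boot_summary[idx, , drop = FALSE],
                      time_unit = slopes$time_unit,
                      surveyed_length = slopes$surveyed_length)
      invert_moments(s$dmean_dt, s$dvar_dt, s$dmean_dt / division_rate)
    }, error = function(e) c(p = NA_real_, muL = NA_real_))
    reps[b, ] <- res
  }
  list(p = unname(stats::quantile(reps[, 1], c(0.025, 0.975), na.rm = TRUE)),
       muL = unname(stats::quantile(reps[, 2], c(0.025, 0.975), na.rm = TRUE)))
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("p (strand segregation) = %.3f  (%.3f; %.3f)\n",
              x$p_hat, x$p_bounds[1], x$p_bounds[2]))
  cat(sprintf("mu*L per division      = %.3g  (%.3g; %.3g)\n",
              x$muL_hat, x$muL_bounds[1], x$muL_bounds[2]))
  cat(sprintf("mu per bp per division = %.3g  (%.3g; %.3g)\n",
              x$mu_hat, x$mu_bounds[1], x$mu_bounds[2]))
  cat(sprintf("[lambda = %g per %s, L = %.3g bp, %s bounds]\n",
              x$division_rate_used, x$time_unit, x$surveyed_length,
              x$bounds_method))
  invisible(x)
}

#' Moment inversion on per-division slopes
#'
#' Same algebra as [infer_parameters] with the division rate absorbed: the
#' inputs are slopes per stem-cell division rather than per time unit. This
#' is the exact inverse of ([slope_mean_per_time], [slope_var_per_time]) at
#' `lambda = 1`.
#'
#' @param d_mean_dn Mean-burden slope per division (> 0).
#' @param d_var_dn Variance slope per division (>= `d_mean_dn`).
#' @return Named vector `c(p = ..., muL = ...)`.
#' @examples
#' infer_parameters_per_division(1.8, 9.36)  # p = 0.7, muL = 6
#' @export
infer_parameters_per_division <- function(d_mean_dn, d_var_dn) {
  invert_moments(d_mean_dn, d_var_dn, d_mean_dn)
}

#' Sensitivity of the estimates to the assumed division rate
#'
#' Re-runs [infer_parameters] over a grid of division rates. As lambda grows,
#' the per-division mean increment `m = dmean_dt / lambda` shrinks, so the
#' segregation estimate rises toward 1 and the mutation-rate estimate falls
#' toward `(R - 1) / L`: p_hat is non-decreasing and mu_hat non-increasing in
#' lambda.
#'
#' @inheritParams infer_parameters
#' @param division_rates Vector of positive division rates, in divisions per
#'   the slopes' time unit.
#' @return Data frame with one row per rate: `lambda`, `p_hat`, `p_low`,
#'   `p_high`, `mu_hat`, `mu_low`, `mu_high`.
#' @examples
#' scan_division_rate(load_tissue_summaries("colon"), c(12, 52, 365))
#' @export
scan_division_rate <- function(slopes, division_rates,
                               bounds = c("corners", "correlated")) {
  stopifnot(all(division_rates > 0))
  bounds <- match.arg(bounds)
  rows <- lapply(division_rates, function(l) {
    r <- infer_parameters(slopes, l, bounds = bounds)
    data.frame(lambda = l, p_hat = r$p_hat,
               p_low = r$p_bounds[1], p_high = r$p_bounds[2],
               mu_hat = r$mu_hat,
               mu_low = r$mu_bounds[1], mu_high = r$mu_bounds[2])
  })
  do.call(rbind, rows)
}
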