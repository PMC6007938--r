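#' Initialise a stem-cell population state
#'
#' @param n_cells Pool size N.
#' @return A `population_state`: per-cell burdens (all zero), elapsed time and
#'   per-cell division count.
#' @export
new_population <- function(n_cells) {
  stopifnot(n_cells >= 1)
  structure(
    list(
      burdens = numeric(n_cells),
      time = 0,
      divisions_elapsed = 0L
    ),
    class = "population_state"
  )
}

#' One synchronous round of asymmetric stem-cell divisions
#'
#' Every stem cell divides once. With probability `p_seg` the stem cell
#' retains the ancestral strand (its burden is unchanged; replication errors
#' leave with the differentiating daughter); otherwise the duplicated strand
#' stays in the stem compartment and the burden increases by an independent
#' Poisson(mu*L) draw. Advances wall time by `1 / division_rate`.
#'
#' Uses the session RNG; seed control belongs to [run_simulation].
#'
#' @param state A `population_state`.
#' @param params A [model_params] object with `symmetric_fraction = 0`.
#' @return The updated `population_state` (same pool size).
#' @export
step_asymmetric <- function(state, params) {
  n <- length(state$burdens)
  mutated <- stats::runif(n) >= params$p_seg
  n_mut <- sum(mutated)
  if (n_mut > 0) {
    state$burdens[mutated] <- state$burdens[mutated] +
      stats::rpois(n_mut, mu_L(params))
  }
  state$divisions_elapsed <- state$divisions_elapsed + 1L
  state$time <- state$time + 1 / params$division_rate
  state
}

#' One synchronous round with a mix of symmetric and asymmetric divisions
#'
#' Each cell's division is, with probability `symmetric_fraction`, a symmetric
#' differentiation: the cell leaves the stem pool and, to restore homeostasis
#' within the same step, a uniformly chosen surviving stem cell self-renews
#' symmetrically -- its daughter enters the pool carrying the parent burden
#' plus one Poisson(mu*L) increment (the duplicated strand now resides in a
#' stem cell regardless of segregation fidelity). All other cells divide
#' asymmetrically as in [step_asymmetric] with the same `p_seg`. The pool size
#' is exactly N after every step.
#'
#' @inheritParams step_asymmetric
#' @return The updated `population_state`.
#' @export
step_symmetric_mix <- function(state, params) {
  n <- length(state$burdens)
  lost <- stats::runif(n) < params$symmetric_fraction
  n_lost <- sum(lost)
  if (n_lost == n) {
    stop("degenerate population: every stem cell differentiated in one step",
         call. = FALSE)
  }
  survivors <- state$burdens[!lost]

  # survivors divide asymmetrically
  mutated <- stats::runif(length(survivors)) >= params$p_seg
  n_mut <- sum(mutated)
  if (n_mut > 0) {
    survivors[mutated] <- survivors[mutated] +
      stats::rpois(n_mut, mu_L(params))
  }

  if (n_lost > 0) {
    if (n == 1) {
      stop("degenerate population: lost the only stem cell", call. = FALSE)
    }
    parents <- sample.int(length(survivors), n_lost, replace = TRUE)
    daughters <- survivors[parents] + stats::rpois(n_lost, mu_L(params))
    state$burdens <- c(survivors, daughters)
  } else {
    state$burdens <- survivors
  }
  state$divisions_elapsed <- state$divisions_elapsed + 1L
  state$time <- state$time + 1 / params$division_rate
  state
}

#' Division-independent (background) mutations
#'
#' Adds to every cell an independent Poisson(`mu_background * dt`) number of
#' mutations, modelling DNA damage that hits ancestral and duplicated strands
#' equally and accrues with calendar time rather than with divisions. Shifts
#' mean and variance by the same amount, so the excess (beyond-Poisson)
#' variance slope is unchanged while parameter inference that ignores the
#' background is biased (the segregation probability is underestimated).
#'
#' @inheritParams step_asymmetric
#' @param dt Positive time increment in the unit of `params$division_rate`.
#' @return The updated `population_state` (time is NOT advanced; callers pair
#'   this with a division step that advances time).
#' @export
apply_background_mutations <- function(state, params, dt) {
  stopifnot(dt > 0)
  if (params$mu_background > 0) {
    state$burdens <- state$burdens +
      stats::rpois(length(state$burdens), params$mu_background * dt)
  }
  state
}

#' Run the individual-based simulator
#'
#' Iterates the configured division kernel from an all-zero population of
#' `params$n_cells` stem cells, one synchronous division round per step (wall
#' time `1 / division_rate` per step), recording the mean and the unbiased
#' (N-1 denominator) variance of the per-cell burden at snapshot times.
#' Background mutations, when `mu_background > 0`, are applied once per step
#' over the step's time increment. Output is bit-for-bit reproducible for a
#' fixed `(params, seed)`.
#'
#' @param params A [model_params] object. `symmetric_fraction > 0` selects the
#'   symmetric-mix kernel; combining it with `mu_background > 0` is not
#'   supported.
#' @param n_steps Number of division rounds (>= 0; 0 yields only the initial
#'   snapshot).
#' @param snapshot_every Record a snapshot every this many steps (the initial
#'   zero state and the final step are always recorded).
#' @param seed Integer seed.
#' @param keep_burdens Keep the full burden vector of the final state.
#' @return A `simulation_run`: the parameters, the seed, and a data frame
#'   `snapshots` with columns `step`, `time`, `mean_burden`, `var_burden`.
#' @examples
#' run <- run_simulation(model_params(n_cells = 500, p_seg = 0.7, mu_L = 6),
#'                       n_steps = 50, snapshot_every = 5, seed = 1)
#' head(run$snapshots)
#' @export
run_simulation <- function(params, n_steps, snapshot_every = 1L, seed,
                           keep_burdens = FALSE) {
  stopifnot(inherits(params, "model_params"),
            n_steps >= 0, snapshot_every >= 1)
  if (params$symmetric_fraction > 0 && params$mu_background > 0) {
    stop(paste("combining symmetric divisions with background mutations is",
               "not supported in one run"), call. = FALSE)
  }
  kernel <- if (params$symmetric_fraction > 0) step_symmetric_mix else
    step_asymmetric
  dt <- 1 / params$division_rate

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  state <- new_population(params$n_cells)
  take <- unique(c(0L, seq_len(n_steps)[seq_len(n_steps) %% snapshot_every == 0],
                   n_steps))
  snaps <- data.frame(step = take, time = take * dt,
                      mean_burden = NA_real_, var_burden = NA_real_)
  record <- function(i) {
    snaps$mean_burden[i] <<- mean(state$burdens)
    snaps$var_burden[i] <<- if (params$n_cells > 1) stats::var(state$burdens)
      else 0
  }
  record(1L)
  row <- 2L
  for (s in seq_len(n_steps)) {
    state <- kernel(state, params)
    state <- apply_background_mutations(state, params, dt)
    if (row <= nrow(snaps) && snaps$step[row] == s) {
      record(row)
      row <- row + 1L
    }
  }

  structure(
    list(params = params, seed = seed, snapshots = snaps,
         final_burdens = if (keep_burdens) state$burdens),
    class = "simulation_run"
  )
}

#' @export
print.simulation_run <- function(x, ...) {
  cat(sprintf("simulation_run: N=%d, p=%g, mu*L=%g, %d snapshots (seed %d)\n",
              x$params$n_cells, x$params$p_seg, mu_L(x$params),
              nrow(x$snapshots), x$seed))
  invisible(x)
}

#' Write a simulation trajectory as TSV
#'
#' Columns `time`, `mean_burden`, `var_burden`, tab-separated with a header.
#'
#' @param run A `simulation_run`.
#' @param path Output file path.
#' @export
write_simulation_tsv <- function(run, path) {
  stopifnot(inherits(run, "simulation_run"))
  utils::write.table(
    run$snapshots[, c("time", "mean_burden", "var_burden")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
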