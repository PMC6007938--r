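#' Closed-form moments of single-cell mutational burden
#'
#' Under the model, a stem-cell lineage that has divided `n` times retained
#' the ancestral strand in `k ~ Binomial(n, p)` of those divisions; each of
#' the remaining `n - k` divisions added an independent `Poisson(mu*L)` number
#' of mutations. The burden is therefore compound Binomial-Poisson with
#'
#' \deqn{E[burden] = n (1 - p) \mu L}
#' \deqn{Var[burden] = n (1 - p) \mu L + n p (1 - p) (\mu L)^2}
#'
#' Both moments are linear in the division count `n`; their ratio is
#' time-independent (see [var_mean_ratio]).
#'
#' @param params A [model_params] object.
#' @param n_divisions Nonnegative number of divisions per stem cell (may be
#'   vectorised).
#' @return Expected mean (or variance) of the per-cell mutational burden, in
#'   mutations per surveyed region.
#' @seealso [slope_mean_per_time], [slope_var_per_time], [var_mean_ratio]
#' @examples
#' pars <- model_params(n_cells = 1, p_seg = 0.7, mu_L = 6)
#' expected_mean_burden(pars, 1)  # 1.8
#' expected_var_burden(pars, 1)   # 9.36
#' @export
expected_mean_burden <- function(params, n_divisions) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(n_divisions)) || any(n_divisions < 0)) {
    stop("`n_divisions` must be nonnegative", call. = FALSE)
  }
  n_divisions * (1 - params$p_seg) * mu_L(params)
}

#' @rdname expected_mean_burden
#' @export
expected_var_burden <- function(params, n_divisions) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(n_divisions)) || any(n_divisions < 0)) {
    stop("`n_divisions` must be nonnegative", call. = FALSE)
  }
  ml <- mu_L(params)
  p <- params$p_seg
  n_divisions * ((1 - p) * ml + p * (1 - p) * ml^2)
}

#' Expected time slopes of burden mean and variance
#'
#' With a constant division rate lambda, division count maps to calendar time
#' as `dn = lambda * dt`, so the mean burden grows at
#' `lambda * (1 - p) * mu * L` per time unit and the variance at
#' `lambda * [(1 - p) mu L + p (1 - p) (mu L)^2]`. These are the quantities a
#' linear regression of per-individual burden summaries against age
#' estimates.
#'
#' @inheritParams expected_mean_burden
#' @return Slope in mutations (or squared mutations) per surveyed region per
#'   time unit of `params$division_rate`.
#' @examples
#' pars <- model_params(n_cells = 1, p_seg = 0.7, mu_L = 6, division_rate = 1)
#' slope_mean_per_time(pars)  # 1.8
#' slope_var_per_time(pars)   # 9.36
#' @export
slope_mean_per_time <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$division_rate * expected_mean_burden(params, 1)
}

#' @rdname slope_mean_per_time
#' @export
slope_var_per_time <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$division_rate * expected_var_burden(params, 1)
}

#' Variance-to-mean ratio of the burden (index of dispersion)
#'
#' The ratio of the variance slope to the mean slope equals `1 + mu*L*p`,
#' independent of both time and the division rate. It is 1 in the Poisson
#' limit (p = 0, random fate assignment with every division mutating) and
#' grows with both the segregation probability and the per-division mutation
#' mean; overdispersion beyond Poisson is the model's signature of non-random
#' strand segregation.
#'
#' @inheritParams expected_mean_burden
#' @return The dispersion ratio, a number >= 1.
#' @examples
#' var_mean_ratio(model_params(n_cells = 1, p_seg = 0.7, mu_L = 6))  # 5.2
#' @export
var_mean_ratio <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$p_seg >= 1) {
    stop("variance-to-mean ratio is undefined at p_seg = 1 (both slopes are 0)",
         call. = FALSE)
  }
  1 + mu_L(params) * params$p_seg
}
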