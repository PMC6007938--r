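#' Model parameters for the strand-segregation mutation model
#'
#' Bundles the generative parameters of the stochastic model: a constant pool
#' of `n_cells` stem cells divides at rate `division_rate`; at each division
#' the cell carrying the ancestral DNA strand keeps stem-cell fate with
#' probability `p_seg` (0.5 = random segregation, 1 = perfect retention of the
#' ancestral strand); divisions in which the duplicated strand stays in the
#' stem compartment add a Poisson number of new mutations with mean
#' `mu_per_bp * genome_length`.
#'
#' The per-division mutation mean can be given either via `mu_per_bp` (rate
#' per base pair per division) together with `genome_length`, or directly as
#' `mu_L` (mutations per surveyed region per division), in which case
#' `mu_per_bp` is derived as `mu_L / genome_length`.
#'
#' Time units are carried by the caller: `division_rate`, ages and
#' `mu_background` must share one time unit (per year for adult tissues, per
#' day for development); the model functions themselves are unit-agnostic.
#'
#' @param n_cells Positive integer, stem-cell pool size N.
#' @param p_seg Probability in `[0, 1]` of non-random strand segregation.
#' @param mu_per_bp Nonnegative mutation rate per base pair per division.
#' @param genome_length Positive integer, surveyed genome length L in bp.
#'   Defaults to the human whole genome, 6e9 bp.
#' @param division_rate Positive stem-cell division rate lambda per time unit.
#' @param mu_L Optional nonnegative per-division mutation mean (mu * L);
#'   alternative to `mu_per_bp`.
#' @param mu_background Nonnegative division-independent mutation rate, in
#'   mutations per surveyed region per time unit, hitting ancestral and
#'   duplicated strands equally. Default 0.
#' @param symmetric_fraction Probability in `[0, 1]` that a division is a
#'   symmetric differentiation compensated by a symmetric self-renewal
#'   elsewhere in the pool. Default 0 (purely asymmetric divisions).
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(n_cells = 20000, p_seg = 0.7, mu_L = 6)
#' model_params(n_cells = 100, p_seg = 0.973, mu_per_bp = 4.37e-9,
#'              genome_length = 6e9, division_rate = 52)
#' @export
model_params <- function(n_cells,
                         p_seg,
                         mu_per_bp = NULL,
                         genome_length = 6e9,
                         division_rate = 1,
                         mu_L = NULL,
                         mu_background = 0,
                         symmetric_fraction = 0) {
  if (is.null(mu_per_bp) && is.null(mu_L)) {
    stop("supply either `mu_per_bp` or `mu_L`", call. = FALSE)
  }
  if (!is.null(mu_per_bp) && !is.null(mu_L)) {
    if (abs(mu_per_bp * genome_length - mu_L) > 1e-8 * max(1, mu_L)) {
      stop("`mu_per_bp * genome_length` disagrees with `mu_L`", call. = FALSE)
    }
  }
  if (is.null(mu_per_bp)) mu_per_bp <- mu_L / genome_length

  stopifnot(
    length(n_cells) == 1, is.finite(n_cells), n_cells >= 1,
    n_cells == as.integer(n_cells),
    length(p_seg) == 1, is.finite(p_seg), p_seg >= 0, p_seg <= 1,
    length(mu_per_bp) == 1, is.finite(mu_per_bp), mu_per_bp >= 0,
    length(genome_length) == 1, is.finite(genome_length), genome_length >= 1,
    length(division_rate) == 1, is.finite(division_rate), division_rate > 0,
    length(mu_background) == 1, is.finite(mu_background), mu_background >= 0,
    length(symmetric_fraction) == 1, is.finite(symmetric_fraction),
    symmetric_fraction >= 0, symmetric_fraction <= 1
  )

  structure(
    list(
      n_cells = as.integer(n_cells),
      p_seg = as.numeric(p_seg),
      mu_per_bp = as.numeric(mu_per_bp),
      genome_length = as.numeric(genome_length),
      division_rate = as.numeric(division_rate),
      mu_background = as.numeric(mu_background),
      symmetric_fraction = as.numeric(symmetric_fraction)
    ),
    class = "model_params"
  )
}

#' Per-division mutation mean mu * L
#'
#' @param params A [model_params] object.
#' @return Expected number of new mutations per surveyed region per division
#'   (the Poisson mean of per-division increments), in full floating
#'   precision.
#' @export
mu_L <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$mu_per_bp * params$genome_length
}

#' @export
print.model_params <- function(x, ...) {
  cat("Strand-segregation model parameters\n")
  cat(sprintf("  N (stem cells)        : %d\n", x$n_cells))
  cat(sprintf("  p (strand segregation): %g\n", x$p_seg))
  cat(sprintf("  mu (per bp per div)   : %g\n", x$mu_per_bp))
  cat(sprintf("  L (surveyed bp)       : %g\n", x$genome_length))
  cat(sprintf("  mu*L (per division)   : %g\n", mu_L(x)))
  cat(sprintf("  lambda (div per time) : %g\n", x$division_rate))
  if (x$mu_background > 0) {
    cat(sprintf("  background rate       : %g per region per time\n",
                x$mu_background))
  }
  if (x$symmetric_fraction > 0) {
    cat(sprintf("  symmetric fraction    : %g\n", x$symmetric_fraction))
  }
  invisible(x)
}
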