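#' Construct a slope-estimates record
#'
#' Holds the fitted age trends of per-cell burden summaries: the change of the
#' mean burden with age (`dmean_dt`) and of the across-cell variance with age
#' (`dvar_dt`), each with the standard error of the fitted slope, plus the
#' metadata inference needs (time unit, surveyed genome length, number of
#' individuals behind the fit).
#'
#' @param dmean_dt Slope of mean burden vs age (mutations per surveyed region
#'   per time unit).
#' @param se_mean Standard error of `dmean_dt`.
#' @param dvar_dt Slope of burden variance vs age.
#' @param se_var Standard error of `dvar_dt`.
#' @param time_unit `"year"` or `"day"`.
#' @param surveyed_length Surveyed genome length L in bp.
#' @param n_individuals Number of individuals the regression used.
#' @return An object of class `slope_estimates`.
#' @export
slope_estimates <- function(dmean_dt, se_mean, dvar_dt, se_var,
                            time_unit = c("year", "day"),
                            surveyed_length = 6e9,
                            n_individuals = NA_integer_) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.finite(dmean_dt), is.finite(dvar_dt),
            se_mean >= 0, se_var >= 0, surveyed_length > 0)
  structure(
    list(dmean_dt = dmean_dt, se_mean = se_mean,
         dvar_dt = dvar_dt, se_var = se_var,
         time_unit = time_unit, surveyed_length = surveyed_length,
         n_individuals = n_individuals),
    class = "slope_estimates"
  )
}

#' @export
print.slope_estimates <- function(x, ...) {
  cat(sprintf("burden slopes per %s (L = %.3g bp):\n", x$time_unit,
              x$surveyed_length))
  cat(sprintf("  d(mean)/dt = %.4g +/- %.3g\n", x$dmean_dt, x$se_mean))
  cat(sprintf("  d(var)/dt  = %.4g +/- %.3g\n", x$dvar_dt, x$se_var))
  invisible(x)
}

slopes_columns <- c("tissue", "dmean_dt", "se_mean", "dvar_dt", "se_var",
                    "time_unit", "surveyed_length_bp")

#' Read or write a per-tissue slopes table
#'
#' Tab-separated with header
#' `tissue dmean_dt se_mean dvar_dt se_var time_unit surveyed_length_bp`;
#' extra columns (e.g. `default_lambda`, `source`) are preserved.
#'
#' @param path File path.
#' @param table Data frame with at least the columns above.
#' @return `read_slopes_tsv`: a data frame, one row per tissue.
#' @export
read_slopes_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(slopes_columns, names(tab))
  if (length(missing) > 0) {
    stop("slopes table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !tab$time_unit %in% c("year", "day")
  if (any(bad)) {
    stop("unknown time_unit in rows: ", paste(which(bad) + 1L, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' @rdname read_slopes_tsv
#' @export
write_slopes_tsv <- function(table, path) {
  missing <- setdiff(slopes_columns, names(table))
  if (length(missing) > 0) {
    stop("slopes table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published per-tissue burden slopes
#'
#' The per-tissue linear-regression slopes (and standard errors) of mean and
#' variance of single-cell mutational burden against age, as published for
#' healthy human colon, small intestine, liver, prefrontal-cortex neurons,
#' hippocampal dentate-gyrus neurons, skin, and neurons during early
#' development. Adult tissues are per whole genome (skin: per 0.69 Mb) per
#' year; the developmental record is per genome per day. `default_lambda` is
#' the division rate the published point estimates assume (one division per
#' week for adult tissues; one per 48 h during development), in divisions per
#' the row's time unit.
#'
#' These printed summaries are the only packaged data; the underlying per-cell
#' burdens of the original sequencing studies are not redistributed.
#'
#' @param tissue Optional tissue name to return a single [slope_estimates]
#'   (plus `default_lambda` and `tissue` fields) instead of the full table.
#' @return A data frame of all seven tissues, or a `slope_estimates` for one.
#' @examples
#' load_tissue_summaries()$tissue
#' load_tissue_summaries("colon")
#' @export
load_tissue_summaries <- function(tissue = NULL) {
  path <- system.file("extdata", "tissue_slopes.tsv", package = "strandseg",
                      mustWork = TRUE)
  tab <- read_slopes_tsv(path)
  if (is.null(tissue)) return(tab)
  row <- tab[tab$tissue == tissue, ]
  if (nrow(row) != 1) {
    stop("unknown tissue '", tissue, "'; available: ",
         paste(tab$tissue, collapse = ", "), call. = FALSE)
  }
  s <- slope_estimates(row$dmean_dt, row$se_mean, row$dvar_dt, row$se_var,
                       time_unit = row$time_unit,
                       surveyed_length = row$surveyed_length_bp)
  s$tissue <- row$tissue
  s$default_lambda <- row$default_lambda
  s
}
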