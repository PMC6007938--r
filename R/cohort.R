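#' Generate a synthetic single-cell burden cohort
#'
#' Emulates the sampling design of single-cell / organoid mutational-burden
#' studies: several individuals of different ages, a handful of sequenced
#' cells each. For every age an independent stem-cell population is simulated
#' for `round(division_rate * age)` synchronous divisions and
#' `cells_per_individual` cells are sampled uniformly without replacement.
#'
#' Each individual gets its own RNG stream derived deterministically from
#' `seed`, so individuals are exchangeable and the cohort is reproducible.
#'
#' @param params A [model_params] object; `division_rate` links age to
#'   division count and must share `time_unit` with `ages`.
#' @param ages Numeric vector of nonnegative individual ages (one individual
#'   per element), in `time_unit`.
#' @param cells_per_individual Integer >= 3 (the minimum needed downstream for
#'   a per-individual variance), and <= `params$n_cells`.
#' @param seed Integer seed.
#' @param time_unit `"year"` or `"day"`; metadata carried into the cohort.
#' @return A `cohort`: a data frame `records` with columns `individual_id`,
#'   `age`, `cell_id`, `mutation_count`, `surveyed_length_bp`, plus the
#'   `time_unit` attribute.
#' @examples
#' pars <- model_params(n_cells = 200, p_seg = 0.7, mu_L = 6)
#' coh <- generate_cohort(pars, ages = c(10, 20, 40), 5, seed = 1)
#' nrow(coh$records)  # 15
#' @export
generate_cohort <- function(params, ages, cells_per_individual, seed,
                            time_unit = c("year", "day")) {
  stopifnot(inherits(params, "model_params"),
            all(is.finite(ages)), all(ages >= 0),
            cells_per_individual >= 3)
  time_unit <- match.arg(time_unit)
  if (cells_per_individual > params$n_cells) {
    stop("cannot sample more cells than the stem-cell pool holds",
         call. = FALSE)
  }

  recs <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    child_seed <- (seed + 1000003 * i) %% .Machine$integer.max
    n_div <- round(params$division_rate * ages[i])
    run <- run_simulation(params, n_steps = n_div,
                          snapshot_every = max(1L, n_div),
                          seed = child_seed, keep_burdens = TRUE)
    idx <- sample_cells(run$final_burdens, cells_per_individual, child_seed)
    recs[[i]] <- data.frame(
      individual_id = sprintf("ind%03d", i),
      age = ages[i],
      cell_id = sprintf("ind%03d_cell%02d", i, seq_len(cells_per_individual)),
      mutation_count = run$final_burdens[idx],
      surveyed_length_bp = params$genome_length
    )
  }
  new_cohort(do.call(rbind, recs), time_unit)
}

# uniform sampling without replacement under a derived, restored RNG state
sample_cells <- function(burdens, k, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed + 1L)
  sample.int(length(burdens), k)
}

new_cohort <- function(records, time_unit) {
  structure(list(records = records, time_unit = time_unit), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d cells from %d individuals (ages in %ss)\n",
              nrow(x$records), length(unique(x$records$individual_id)),
              x$time_unit))
  invisible(x)
}

cohort_columns <- c("individual_id", "age", "cell_id", "mutation_count",
                    "surveyed_length_bp")

#' Read / write the cohort TSV format
#'
#' Tab-separated, UTF-8, '.' decimal separator; a `# time_unit=year|day`
#' comment line precedes the header row
#' `individual_id  age  cell_id  mutation_count  surveyed_length_bp`.
#' Reading validates every row and names the offending line on failure;
#' writing then reading returns an identical cohort.
#'
#' @param path File path.
#' @param cohort A `cohort` object.
#' @return `read_cohort_tsv` returns a `cohort`; `write_cohort_tsv` returns
#'   `path` invisibly.
#' @export
read_cohort_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty cohort file: ", path, call. = FALSE)
  m <- regmatches(lines[1], regexec("^#\\s*time_unit=(year|day)\\s*$", lines[1]))[[1]]
  if (length(m) < 2) {
    stop("line 1: expected a '# time_unit=year|day' comment", call. = FALSE)
  }
  time_unit <- m[2]
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (!identical(header, cohort_columns)) {
    stop("line 2: header must be: ", paste(cohort_columns, collapse = ", "),
         call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    warning("cohort file has a header but no records: ", path, call. = FALSE)
    recs <- data.frame(individual_id = character(), age = numeric(),
                       cell_id = character(), mutation_count = numeric(),
                       surveyed_length_bp = numeric())
    return(new_cohort(recs, time_unit))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    line_no <- i + 2L
    f <- fields[[i]]
    if (length(f) != 5) {
      stop(sprintf("line %d: expected 5 tab-separated fields, found %d",
                   line_no, length(f)), call. = FALSE)
    }
    age <- suppressWarnings(as.numeric(f[2]))
    cnt <- suppressWarnings(as.numeric(f[4]))
    len <- suppressWarnings(as.numeric(f[5]))
    if (is.na(age) || age < 0) {
      stop(sprintf("line %d: invalid age '%s'", line_no, f[2]), call. = FALSE)
    }
    if (is.na(cnt) || cnt < 0 || cnt != round(cnt)) {
      stop(sprintf("line %d: invalid mutation_count '%s'", line_no, f[4]),
           call. = FALSE)
    }
    if (is.na(len) || len <= 0) {
      stop(sprintf("line %d: invalid surveyed_length_bp '%s'", line_no, f[5]),
           call. = FALSE)
    }
  }
  recs <- data.frame(
    individual_id = vapply(fields, `[`, "", 1),
    age = as.numeric(vapply(fields, `[`, "", 2)),
    cell_id = vapply(fields, `[`, "", 3),
    mutation_count = as.numeric(vapply(fields, `[`, "", 4)),
    surveyed_length_bp = as.numeric(vapply(fields, `[`, "", 5))
  )
  if (length(unique(recs$surveyed_length_bp)) > 1) {
    stop("surveyed_length_bp must be identical within a cohort", call. = FALSE)
  }
  new_cohort(recs, time_unit)
}

#' @rdname read_cohort_tsv
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# time_unit=%s", cohort$time_unit), con)
  writeLines(paste(cohort_columns, collapse = "\t"), con)
  if (nrow(cohort$records) > 0) {
    writeLines(sprintf("%s\t%.10g\t%s\t%.0f\t%.0f",
                       cohort$records$individual_id, cohort$records$age,
                       cohort$records$cell_id, cohort$records$mutation_count,
                       cohort$records$surveyed_length_bp), con)
  }
  invisible(path)
}
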