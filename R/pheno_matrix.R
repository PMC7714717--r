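#' Construct a plot-by-day phenotype matrix
#'
#' Container for one trait measured daily on every plot of a trial. Rows are
#' plots (aligned with the design), columns are days (ISO dates); `NA` marks a
#' missing measurement.
#'
#' @param values numeric matrix, plots x days; rownames must equal
#'   `design$plot_id` (set from the design when absent).
#' @param design the `trial_design` the plots belong to.
#' @param days `Date` vector (or ISO-8601 strings), one per column, strictly
#'   increasing.
#' @return a `pheno_matrix` object.
#' @export
pheno_matrix <- function(values, design, days) {
  values <- as.matrix(values)
  days <- as.Date(days)
  if (nrow(values) != nrow(design)) {
    stop_pp("values has ", nrow(values), " rows but design has ",
            nrow(design), " plots")
  }
  if (ncol(values) != length(days)) {
    stop_pp("values has ", ncol(values), " columns but ", length(days),
            " days given")
  }
  if (any(diff(days) <= 0)) stop_pp("days must be strictly increasing")
  if (is.null(rownames(values))) {
    rownames(values) <- design$plot_id
  } else if (!identical(rownames(values), design$plot_id)) {
    if (!setequal(rownames(values), design$plot_id)) {
      stop_pp("row names of values do not match design plot ids")
    }
    values <- values[design$plot_id, , drop = FALSE]
  }
  colnames(values) <- format(days, "%Y-%m-%d")
  structure(list(values = values, design = design, days = days),
            class = "pheno_matrix")
}

#' Missing-value mask of a phenotype matrix
#'
#' @param pheno a `pheno_matrix`.
#' @return logical matrix, `TRUE` where the measurement is missing.
#' @export
missing_mask <- function(pheno) is.na(pheno$values)

#' @export
print.pheno_matrix <- function(x, ...) {
  cat("pheno_matrix:", nrow(x$values), "plots x", ncol(x$values), "days (",
      format(min(x$days)), "to", format(max(x$days)), "),",
      sum(is.na(x$values)), "missing cells\n")
  invisible(x)
}

#' @export
dim.pheno_matrix <- function(x) dim(x$values)

#' Convert a phenotype matrix to long format
#'
#' @param pheno a `pheno_matrix`.
#' @return data frame with columns `plot_id`, `day`, `value` (missing cells
#'   included with `NA`).
#' @export
pheno_long <- function(pheno) {
  data.frame(
    plot_id = rep(rownames(pheno$values), times = ncol(pheno$values)),
    day = rep(pheno$days, each = nrow(pheno$values)),
    value = as.vector(pheno$values),
    stringsAsFactors = FALSE
  )
}
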