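#' Read a trial layout CSV
#'
#' Expects a header `plot_id,genotype,replicate,block,row,col`. Coordinates
#' must be positive integers; duplicated (row, col) pairs are an error naming
#' the offending plots.
#'
#' @param path CSV file path.
#' @return a validated `trial_design`.
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "genotype", "replicate", "block", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_pp("layout file lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (cc in c("replicate", "block", "row", "col")) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(v != as.integer(v))) {
      stop_pp("column `", cc, "` must be integer")
    }
    df[[cc]] <- as.integer(v)
  }
  df$plot_id <- as.character(df$plot_id)
  df$genotype <- as.character(df$genotype)
  df <- df[need]
  class(df) <- c("trial_design", "data.frame")
  validate_design(df)
  df
}

#' Write a trial layout CSV
#' @param design a `trial_design`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(design, path) {
  utils::write.csv(as.data.frame(design)[, c("plot_id", "genotype",
                                             "replicate", "block", "row",
                                             "col")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide phenotype CSV
#'
#' Expects `plot_id` followed by ISO-8601 date columns (one per day); empty
#' and `NA` cells are missing. Plots are aligned to the design order and days
#' are sorted ascending regardless of column order in the file.
#'
#' @param path CSV file path.
#' @param design the `trial_design` the plots belong to.
#' @return a `pheno_matrix`.
#' @export
read_phenotypes <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"plot_id" %in% names(df)) stop_pp("phenotype file lacks `plot_id`")
  day_cols <- setdiff(names(df), "plot_id")
  days <- as.Date(day_cols, format = "%Y-%m-%d")
  if (anyNA(days)) {
    stop_pp("unparseable date column(s): ",
            paste(day_cols[is.na(days)], collapse = ", "))
  }
  unknown <- setdiff(df$plot_id, design$plot_id)
  if (length(unknown)) {
    stop_pp("plot(s) absent from the layout: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) " ..." else "")
  }
  ord <- order(days)
  vals <- as.matrix(df[, day_cols[ord], drop = FALSE])
  mode(vals) <- "double"
  rownames(vals) <- df$plot_id
  missing_plots <- setdiff(design$plot_id, df$plot_id)
  if (length(missing_plots)) {
    pad <- matrix(NA_real_, length(missing_plots), ncol(vals),
                  dimnames = list(missing_plots, colnames(vals)))
    vals <- rbind(vals, pad)
  }
  pheno_matrix(vals[design$plot_id, , drop = FALSE], design, days[ord])
}

#' Write a wide phenotype CSV
#' @param pheno a `pheno_matrix`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  df <- data.frame(plot_id = rownames(pheno$values), pheno$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write / read ground-truth records as JSON
#' @param truth a `truth_record`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Export a daily fit as CSV plus a JSON sidecar
#'
#' Writes `<prefix>_blues.csv` (genotype, blue, se; genotype-fixed fits), a
#' `<prefix>_fit.json` sidecar with the variance components, effective
#' dimensions, heritability and iteration count, and, for spatial fits,
#' `<prefix>_trend.csv` with the fitted surface on the grid.
#'
#' @param fit a `daily_fit`.
#' @param prefix output path prefix.
#' @return the paths written, invisibly.
#' @export
write_daily_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "daily_fit"))
  paths <- character(0)
  if (!is.null(fit$blues)) {
    p <- paste0(prefix, "_blues.csv")
    utils::write.csv(fit$blues, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  side <- list(varcomp = as.list(fit$varcomp), ED = as.list(fit$ED),
               ED_g = fit$ED_g, n_g = fit$n_g, l = fit$l, h2 = fit$h2,
               n_obs = fit$n_obs, converged = fit$converged,
               n_iter = fit$n_iter)
  p <- paste0(prefix, "_fit.json")
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))], p,
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  if (!is.null(fit$spatial_trend)) {
    p <- paste0(prefix, "_trend.csv")
    utils::write.csv(fit$spatial_trend, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run configuration
#'
#' Collects the pipeline defaults in one validated list; unknown keys are
#' rejected so a typo in a YAML file cannot silently fall back to a default.
#'
#' @param ... overrides of the defaults (see `run_config()` for the full
#'   list: `trait`, `strategy`, `seed`, `m`, `k`, `nseg`, `tol`, `alpha`,
#'   `min_size`, `n_perm`, `k_range`, `n_rep`, `n_fold`, `x_levels`,
#'   `scale_mult`).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    trait = "trait", strategy = "S8", seed = 1L,
    m = 5L, k = 5L,
    nseg = NULL, tol = 1e-6, max_iter = 200L,
    alpha = 0.05, min_size = 3L, n_perm = 199L,
    k_range = 2:6,
    n_rep = 10L, n_fold = 5L,
    x_levels = seq(0.1, 0.5, by = 0.1), scale_mult = 3
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop_pp("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  run_config(yaml::read_yaml(path))
}
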