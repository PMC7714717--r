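#' Boxplot fences of a vector of trait values
#'
#' Returns `(QR1 - 1.5 * IQR, QR3 + 1.5 * IQR)` where QR1 and QR3 are the 25
#' and 75 percent quantiles (linear-interpolation convention, type 7) and
#' `IQR = QR3 - QR1`. Values strictly below the lower or strictly above the
#' upper fence are considered outliers.
#'
#' @param values numeric vector; missing values ignored.
#' @return named numeric vector `c(lower, upper)`.
#' @export
boxplot_fences <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) stop_pp("all values are missing; fences undefined")
  q1 <- qr_quantile(v, 0.25)
  q3 <- qr_quantile(v, 0.75)
  iqr <- q3 - q1
  c(lower = q1 - 1.5 * iqr, upper = q3 + 1.5 * iqr)
}

#' Mask per-day outliers in a phenotype matrix
#'
#' For each day separately, the distribution of all plot values (all genotypes
#' and replicates together) is summarised by its boxplot fences and every
#' value outside them is replaced by a missing value, to be imputed
#' downstream. Already-missing cells are never unmasked.
#'
#' @param pheno a `pheno_matrix`.
#' @return a list with the masked `pheno` and an `outlier_report` data frame
#'   (`day`, `lower`, `upper`, `n_flagged`) carrying the flagged fraction of
#'   observed cells as attribute `total_fraction`.
#' @export
detect_outliers <- function(pheno) {
  vals <- pheno$values
  n_day <- ncol(vals)
  rep_df <- data.frame(day = colnames(vals), lower = NA_real_,
                       upper = NA_real_, n_flagged = 0L,
                       stringsAsFactors = FALSE)
  n_obs_total <- sum(!is.na(vals))
  for (d in seq_len(n_day)) {
    v <- vals[, d]
    if (all(is.na(v))) {
      warning("day ", colnames(vals)[d], " is entirely missing; skipped",
              call. = FALSE)
      next
    }
    f <- boxplot_fences(v)
    out <- which(!is.na(v) & (v < f["lower"] | v > f["upper"]))
    vals[out, d] <- NA_real_
    rep_df$lower[d] <- f["lower"]
    rep_df$upper[d] <- f["upper"]
    rep_df$n_flagged[d] <- length(out)
  }
  attr(rep_df, "total_fraction") <-
    if (n_obs_total > 0) sum(rep_df$n_flagged) / n_obs_total else 0
  class(rep_df) <- c("outlier_report", "data.frame")
  pheno$values <- vals
  list(pheno = pheno, report = rep_df)
}
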