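#' Impute missing values by predictive mean matching across days
#'
#' Sequentially imputes each day of the plot-by-day matrix using all other
#' days as predictors. For day `i`: (a) the other days form the predictor set;
#' (b) a linear regression of the observed values of day `i` on the predictors
#' is fitted; (c) regression coefficients are drawn from their sampling
#' distribution (residual variance from a scaled inverse chi-square, then
#' coefficients from a Gaussian centred at the estimates with covariance
#' sigma^2 (X'X)^-1); (d) the drawn coefficients predict every row; (e) each
#' missing cell is imputed by drawing one of the `k` observed values of day
#' `i` whose predictions are closest to the missing row's prediction; (f) this
#' runs for every missing cell of every day. The whole sweep is repeated `m`
#' times and the `m` completed matrices are pooled by cell-wise means (the
#' downstream mixed models need one completed matrix, not the between-
#' imputation variance). Observed cells are never altered.
#'
#' Numerical details: predictors are standardised and stabilised with a fixed
#' ridge penalty of 1e-5 so the regression is always solvable; predictor cells
#' that are themselves missing are filled with their day's observed mean for
#' the single sweep (no chained-equations iteration). Days with more than 75
#' percent missing values are refused (the matching step would rely on too few
#' donors); exclude such days before imputing.
#'
#' Reproducibility protocol: under `set.seed(seed)`, imputations are the outer
#' loop and days the inner loop (column order). A day with no missing cells
#' consumes no random numbers. For a day with missing cells the draws are, in
#' order: one `rchisq` for the residual variance, one standard normal vector
#' of length `n_predictors + 1` for the coefficients, then one `sample.int`
#' per missing cell taken in increasing row order.
#'
#' @param pheno a `pheno_matrix`.
#' @param m number of imputations pooled by cell-wise mean.
#' @param k number of donor candidates per missing cell.
#' @param seed integer seed.
#' @return a complete `pheno_matrix`.
#' @export
impute_pmm <- function(pheno, m = 5, k = 5, seed = 1) {
  stopifnot(m >= 1, k >= 1)
  V <- pheno$values
  n <- nrow(V); D <- ncol(V)
  mask <- is.na(V)
  if (!any(mask)) return(pheno)
  frac <- colMeans(mask)
  if (any(frac == 1)) {
    stop_pp("day(s) ", paste(colnames(V)[frac == 1], collapse = ", "),
            " have no observed values and cannot supply donors; ",
            "exclude them before imputation")
  }
  if (any(frac > 0.75)) {
    stop_pp("day(s) ", paste(colnames(V)[frac > 0.75], collapse = ", "),
            " exceed 75% missing values; predictive mean matching is ",
            "unreliable beyond that point -- exclude those days")
  }
  day_means <- colMeans(V, na.rm = TRUE)
  Vfill <- V
  for (d in seq_len(D)) Vfill[mask[, d], d] <- day_means[d]

  acc <- matrix(0, n, D)
  with_seed(seed, {
    for (imp in seq_len(m)) {
      completed <- V
      for (d in seq_len(D)) {
        mis <- which(mask[, d])
        if (!length(mis)) next
        obs <- which(!mask[, d])
        completed[mis, d] <- pmm_impute_day(
          y = V[, d], obs = obs, mis = mis,
          Z = Vfill[, -d, drop = FALSE], k = k)
      }
      acc <- acc + completed
    }
  })
  pheno$values <- acc / m
  pheno
}

## One PMM pass for a single day. `y` holds the day's values (NA at `mis`),
## `Z` the mean-filled predictor matrix (other days). Consumes RNG as
## documented in ?impute_pmm.
pmm_impute_day <- function(y, obs, mis, Z, k) {
  mu <- colMeans(Z)
  sdv <- apply(Z, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, mu), 2, sdv, `/`)
  X <- cbind(1, Zs)
  p <- ncol(X)
  A <- crossprod(X[obs, , drop = FALSE]) + diag(c(0, rep(1e-5, p - 1L)))
  Ainv <- solve(A)
  b <- Ainv %*% crossprod(X[obs, , drop = FALSE], y[obs])
  res <- y[obs] - drop(X[obs, , drop = FALSE] %*% b)
  df <- max(length(obs) - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  Ru <- chol((Ainv + t(Ainv)) / 2)          # Ainv = Ru'Ru
  bstar <- drop(b) + sqrt(sigma2) * drop(t(Ru) %*% stats::rnorm(p))
  pred <- drop(X %*% bstar)
  kk <- min(k, length(obs))
  out <- numeric(length(mis))
  ## nearest donors by predicted value: search a 2k window around the
  ## insertion point in the sorted observed predictions
  ord <- order(pred[obs])
  sorted_pred <- pred[obs][ord]
  sorted_obs <- obs[ord]
  n_obs <- length(obs)
  pos <- findInterval(pred[mis], sorted_pred)
  for (j in seq_along(mis)) {
    lo <- max(1L, pos[j] - kk + 1L)
    hi <- min(n_obs, pos[j] + kk)
    win <- lo:hi
    dist <- abs(sorted_pred[win] - pred[mis[j]])
    donors <- sorted_obs[win][order(dist)[seq_len(kk)]]
    out[j] <- y[donors[sample.int(kk, 1L)]]
  }
  out
}
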