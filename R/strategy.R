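#' Data-processing strategies S1-S9
#'
#' The eight two-step strategies combine outlier detection (yes/no), missing
#' value imputation (yes/no) and spatial adjustment (yes/no):
#'
#' | name | outliers | imputation | spatial |
#' |------|----------|------------|---------|
#' | S1   | no       | no         | no      |
#' | S2   | yes      | no         | no      |
#' | S3   | no       | yes        | no      |
#' | S4   | yes      | yes        | no      |
#' | S5   | no       | no         | yes     |
#' | S6   | yes      | no         | yes     |
#' | S7   | no       | yes        | yes     |
#' | S8   | yes      | yes        | yes     |
#'
#' S9 is the single-step alternative: no preprocessing, spatial model with
#' iterative Grubbs removal of residual outliers, missing values left to the
#' mixed model.
#'
#' @param name one of `"S1"` ... `"S9"`.
#' @return a `strategy` object with logical fields `outliers`, `imputation`,
#'   `spatial`, `single_step`.
#' @export
strategy <- function(name) {
  name <- toupper(as.character(name))
  tab <- list(
    S1 = c(FALSE, FALSE, FALSE), S2 = c(TRUE, FALSE, FALSE),
    S3 = c(FALSE, TRUE, FALSE),  S4 = c(TRUE, TRUE, FALSE),
    S5 = c(FALSE, FALSE, TRUE),  S6 = c(TRUE, FALSE, TRUE),
    S7 = c(FALSE, TRUE, TRUE),   S8 = c(TRUE, TRUE, TRUE)
  )
  if (name == "S9") {
    s <- list(name = "S9", outliers = FALSE, imputation = FALSE,
              spatial = TRUE, single_step = TRUE)
  } else if (name %in% names(tab)) {
    v <- tab[[name]]
    s <- list(name = name, outliers = v[1], imputation = v[2],
              spatial = v[3], single_step = FALSE)
  } else {
    stop_pp("unknown strategy '", name, "' (expected S1..S9)")
  }
  class(s) <- "strategy"
  s
}

#' @export
print.strategy <- function(x, ...) {
  cat("strategy", x$name, "-",
      if (x$single_step) "single-step spatial model with Grubbs cleaning"
      else paste0("outliers=", x$outliers, ", imputation=", x$imputation,
                  ", spatial=", x$spatial), "\n")
  invisible(x)
}

#' Run a processing strategy over a trait time series
#'
#' Applies the strategy's preprocessing (per-day outlier masking, then PMM
#' imputation across days, as flagged), then fits the daily mixed model with
#' genotype fixed to obtain the adjusted-mean (G-BLUE) series and, when
#' `h2 = TRUE`, a second genotype-random fit per day for the heritability
#' series. S9 instead cleans each day with the iterative Grubbs procedure
#' before the spatial fit, leaving missing values to the model. Days whose fit
#' fails are recorded as missing in all series rather than aborting.
#'
#' @param pheno a `pheno_matrix`.
#' @param design a `trial_design`.
#' @param strat a `strategy` or strategy name.
#' @param seed integer seed driving the stochastic stages (imputation).
#' @param days optional subset of days to fit (indices or ISO labels);
#'   preprocessing always uses the full series.
#' @param h2 also compute the daily heritability series (second fit per day)?
#' @param m,k imputation parameters passed to [impute_pmm()].
#' @param spec_args further arguments for [model_spec()] (e.g. `nseg`).
#' @param warm_init optional variance-component starting values for the first
#'   fitted day (list with `sigma2`, `sigma2_e`), e.g. the `init` field of a
#'   previous run on similar data; later days always warm-start from the
#'   previous day. Affects only the iteration path, not the REML solution.
#' @return a `gblue_series`: list with `genotypes`, `days`, `blues`
#'   (genotypes x days matrix), `h2` (per fitted day), `strategy`, and per-day
#'   fit diagnostics in `info`.
#' @export
run_strategy <- function(pheno, design, strat, seed = 1, days = NULL,
                         h2 = TRUE, m = 5, k = 5, spec_args = list(),
                         warm_init = NULL) {
  if (!inherits(strat, "strategy")) strat <- strategy(strat)
  validate_design(design)
  if (strat$outliers) pheno <- detect_outliers(pheno)$pheno
  if (strat$imputation) {
    pheno <- impute_pmm(pheno, m = m, k = k, seed = derive_seed(seed, 1))
  }
  day_labels <- colnames(pheno$values)
  if (is.null(days)) {
    sel <- seq_along(day_labels)
  } else if (is.character(days)) {
    sel <- match(days, day_labels)
    if (anyNA(sel)) stop_pp("unknown day label(s): ",
                            paste(days[is.na(sel)], collapse = ", "))
  } else {
    sel <- as.integer(days)
  }
  geno <- sort(unique(design$genotype))
  blues <- matrix(NA_real_, length(geno), length(sel),
                  dimnames = list(geno, day_labels[sel]))
  h2v <- rep(NA_real_, length(sel)); names(h2v) <- day_labels[sel]
  info <- data.frame(day = day_labels[sel], converged = NA, n_iter = NA_integer_,
                     n_removed = 0L, stringsAsFactors = FALSE)
  spec_f <- do.call(model_spec, c(list(genotype_role = "fixed",
                                       spatial = strat$spatial), spec_args))
  spec_r <- do.call(model_spec, c(list(genotype_role = "random",
                                       spatial = strat$spatial), spec_args))
  init_f <- warm_init; init_r <- NULL
  for (j in seq_along(sel)) {
    y <- pheno$values[, sel[j]]
    names(y) <- rownames(pheno$values)
    if (strat$single_step) {
      y <- grubbs_clean(y, design, spec_f)
      info$n_removed[j] <- length(attr(y, "removed"))
    }
    ft <- tryCatch(fit_day(y, design, spec_f, init = init_f),
                   error = function(e) e)
    if (inherits(ft, "error")) {
      warning("day ", day_labels[sel[j]], ": ", conditionMessage(ft),
              call. = FALSE)
      next
    }
    init_f <- list(sigma2 = ft$varcomp[setdiff(names(ft$varcomp), "sigma2_e")],
                   sigma2_e = unname(ft$varcomp["sigma2_e"]))
    blues[ft$blues$genotype, j] <- ft$blues$blue
    info$converged[j] <- ft$converged
    info$n_iter[j] <- ft$n_iter
    if (h2) {
      fr <- tryCatch(fit_day(y, design, spec_r, init = init_r),
                     error = function(e) e)
      if (!inherits(fr, "error")) {
        sig <- fr$varcomp[setdiff(names(fr$varcomp), "sigma2_e")]
        names(sig)[names(sig) == "sigma2_g"] <- "genotype"
        init_r <- list(sigma2 = sig, sigma2_e = unname(fr$varcomp["sigma2_e"]))
        h2v[j] <- fr$h2
      }
    }
  }
  structure(list(genotypes = geno, days = day_labels[sel], blues = blues,
                 h2 = h2v, strategy = strat, info = info, init = init_f),
            class = "gblue_series")
}

#' @export
print.gblue_series <- function(x, ...) {
  cat("gblue_series (", x$strategy$name, "): ", length(x$genotypes),
      " genotypes x ", length(x$days), " days; mean daily h2 ",
      if (all(is.na(x$h2))) "not computed" else round(mean(x$h2, na.rm = TRUE), 3),
      "\n", sep = "")
  invisible(x)
}

#' Fit a logistic growth curve to one genotype's adjusted-mean series
#'
#' Least-squares fit of `A / (1 + exp(-k (t - t0)))` to a day-ordered series.
#' Starting values: `A0` the series maximum, `t0` the day of half-maximum,
#' `k0` from the log-linear slope between 20 and 80 percent of `A0`;
#' optimization is bounded (`A > 0`, `k > 0`) via [minpack.lm::nlsLM()], with
#' `stats::nls(SSlogis)` as fallback. Goodness of fit is
#' `R2 = 1 - SSres / SStot`.
#'
#' @param series numeric vector of adjusted means, one per day (NA allowed);
#'   names or `times` give the day positions.
#' @param times numeric day positions; default `seq_along(series)`.
#' @return list `A`, `k`, `t0`, `R2`, `converged`; non-convergent fits carry
#'   `converged = FALSE` and `NA` parameters (exclude them from averages).
#' @export
fit_logistic <- function(series, times = NULL) {
  if (is.null(times)) times <- seq_along(series)
  ok <- !is.na(series)
  if (sum(ok) == 0) stop_pp("series is entirely missing")
  if (sum(ok) < 4) {
    return(list(A = NA_real_, k = NA_real_, t0 = NA_real_, R2 = NA_real_,
                converged = FALSE))
  }
  y <- series[ok]; t <- times[ok]
  A0 <- max(y)
  if (A0 <= 0) A0 <- max(abs(y)) + 1e-8
  t00 <- t[which.min(abs(y - A0 / 2))]
  in_band <- y > 0.2 * A0 & y < 0.8 * A0
  k0 <- if (sum(in_band) >= 2) {
    z <- log(pmax(y[in_band], 1e-8) / pmax(A0 - y[in_band], 1e-8))
    sl <- unname(stats::coef(stats::lm(z ~ t[in_band]))[2])
    if (is.finite(sl) && sl > 0) sl else 0.3
  } else 0.3
  A0 <- unname(A0); t00 <- unname(t00)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A / (1 + exp(-k * (t - t0))),
                      start = list(A = A0, k = k0, t0 = t00),
                      lower = c(A = 1e-8, k = 1e-8, t0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(stats::nls(y ~ SSlogis(t, Asym, xmid, scal)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      pars <- c(A = unname(cf["Asym"]), k = 1 / unname(cf["scal"]),
                t0 = unname(cf["xmid"]))
    }
  } else {
    pars <- stats::coef(fit)
  }
  if (is.null(fit)) {
    return(list(A = NA_real_, k = NA_real_, t0 = NA_real_, R2 = NA_real_,
                converged = FALSE))
  }
  pred <- pars["A"] / (1 + exp(-pars["k"] * (t - pars["t0"])))
  ssres <- sum((y - pred)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else NA_real_
  list(A = unname(pars["A"]), k = unname(pars["k"]), t0 = unname(pars["t0"]),
       R2 = r2, converged = TRUE)
}

#' Logistic fits for all genotypes of a series
#'
#' @param series a `gblue_series`.
#' @return data frame with one row per genotype (`A`, `k`, `t0`, `R2`,
#'   `converged`); `mean_R2` over converged fits as attribute.
#' @export
fit_logistic_all <- function(series) {
  times <- seq_along(series$days)
  res <- lapply(seq_len(nrow(series$blues)), function(i) {
    f <- tryCatch(fit_logistic(series$blues[i, ], times),
                  error = function(e) list(A = NA, k = NA, t0 = NA, R2 = NA,
                                           converged = FALSE))
    data.frame(genotype = series$genotypes[i], A = f$A, k = f$k, t0 = f$t0,
               R2 = f$R2, converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "mean_R2") <- mean(out$R2[out$converged], na.rm = TRUE)
  out
}
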