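#' Specify the daily mixed model
#'
#' Defines the per-day model
#' `y = mu + replicate + block(replicate) + row + col + f(row, col) + genotype + e`,
#' where replicate, block-within-replicate, row and column are random effects
#' with their own variances and `f(row, col)` is the PS-ANOVA two-dimensional
#' P-spline surface (fixed linear trends plus five penalised random blocks).
#' Genotype enters as a fixed effect for adjusted-mean (BLUE) computation, or
#' as a random effect for heritability estimation.
#'
#' @param genotype_role `"fixed"` (BLUEs) or `"random"` (heritability).
#' @param spatial include the P-spline surface? Without it the model reduces
#'   to the plain replicate/block/row/column mixed model.
#' @param random_terms which design factors enter as random effects; subset
#'   of `c("replicate", "block", "row", "col")`. Factors with a single level
#'   are dropped automatically.
#' @param nseg optional length-2 integer vector of B-spline segment counts
#'   (rows, columns); default `max(5, min(ceiling(n/2), 12))` per dimension.
#' @param degree,pord B-spline degree and difference-penalty order.
#' @param tol REML convergence tolerance on the maximum relative change of the
#'   variance components.
#' @param max_iter maximum Schall iterations.
#' @return a `model_spec` object.
#' @export
model_spec <- function(genotype_role = c("fixed", "random"), spatial = TRUE,
                       random_terms = c("replicate", "block", "row", "col"),
                       nseg = NULL, degree = 3, pord = 2,
                       tol = 1e-6, max_iter = 200) {
  genotype_role <- match.arg(genotype_role)
  if (length(random_terms)) {
    random_terms <- match.arg(random_terms,
                              c("replicate", "block", "row", "col"),
                              several.ok = TRUE)
  }
  if (!is.null(nseg)) {
    nseg <- rep_len(as.integer(nseg), 2L)
    if (any(nseg + degree < 3)) stop_pp("basis counts must be at least 3")
  }
  structure(list(genotype_role = genotype_role, spatial = isTRUE(spatial),
                 random_terms = random_terms,
                 nseg = nseg, degree = degree, pord = pord,
                 tol = tol, max_iter = max_iter),
            class = "model_spec")
}

## indicator matrix of a factor with fixed level set
indicator <- function(values, levels) {
  m <- matrix(0, length(values), length(levels))
  m[cbind(seq_along(values), match(values, levels))] <- 1
  colnames(m) <- as.character(levels)
  m
}

#' Fit the daily spatial mixed model
#'
#' Fits the model of [model_spec()] to one day of plot data by REML (Schall
#' iterations with effective-dimension updates). Missing responses are dropped
#' from the fit; genotypes without any observation that day receive no
#' adjusted mean. Genotype fixed effects use sum-to-zero contrasts and BLUEs
#' are reported as intercept plus effect. Negative variance estimates are
#' floored at 1e-10 and recorded in the fit notes.
#'
#' @param day_values numeric vector of plot values, named by plot id or
#'   aligned with `design`; `NA` allowed.
#' @param design a `trial_design`.
#' @param spec a `model_spec`.
#' @param init optional list of starting variance components
#'   (`sigma2` named vector, `sigma2_e`), e.g. from a previous day's fit.
#' @return a `daily_fit` with elements `blues` (genotype, blue, se; only for
#'   genotype fixed), `varcomp`, `ED`, `ED_g`, `n_g`, `l`, `h2` (only for
#'   genotype random), `spatial_trend`, `converged`, `n_iter`, and an internal
#'   `model` used by [predict_validation()].
#' @export
fit_day <- function(day_values, design, spec = model_spec(), init = NULL) {
  validate_design(design)
  if (!is.null(names(day_values))) {
    y_all <- day_values[design$plot_id]
  } else {
    if (length(day_values) != nrow(design)) {
      stop_pp("`day_values` length does not match the design")
    }
    y_all <- day_values
  }
  obs <- which(!is.na(y_all))
  if (length(obs) < 3) stop_pp("fewer than 3 observed plots")
  y <- as.numeric(y_all[obs])
  dsub <- design[obs, , drop = FALSE]

  geno_lev <- sort(unique(dsub$genotype))
  n_g <- length(geno_lev)
  dropped <- setdiff(sort(unique(design$genotype)), geno_lev)
  gi <- match(dsub$genotype, geno_lev)

  grid_rows <- max(design$row); grid_cols <- max(design$col)
  basis <- if (spec$spatial) {
    psanova_basis(grid_rows, grid_cols, spec$nseg, spec$degree, spec$pord)
  } else NULL

  X <- matrix(1, length(obs), 1, dimnames = list(NULL, "mu"))
  contr <- NULL
  if (spec$genotype_role == "fixed") {
    if (n_g < 2) stop_pp("need at least 2 observed genotypes for BLUEs")
    contr <- stats::contr.sum(n_g)
    Xg <- contr[gi, , drop = FALSE]
    colnames(Xg) <- paste0("geno", seq_len(n_g - 1))
    X <- cbind(X, Xg)
  }
  sp <- NULL
  if (spec$spatial) {
    sp <- basis$eval(dsub$row, dsub$col)
    X <- cbind(X, sp$fixed)
  }

  Zlist <- list()
  rt <- spec$random_terms %||% c("replicate", "block", "row", "col")
  rep_lev <- sort(unique(design$replicate))
  if ("replicate" %in% rt && length(rep_lev) > 1) {
    Zlist$replicate <- indicator(dsub$replicate, rep_lev)
  }
  blk_all <- sort(unique(paste(design$replicate, design$block, sep = ":")))
  if ("block" %in% rt && length(blk_all) > length(rep_lev)) {
    Zlist$block <- indicator(paste(dsub$replicate, dsub$block, sep = ":"),
                             blk_all)
  }
  row_lev <- sort(unique(design$row)); col_lev <- sort(unique(design$col))
  if ("row" %in% rt && length(row_lev) > 1) {
    Zlist$row <- indicator(dsub$row, row_lev)
  }
  if ("col" %in% rt && length(col_lev) > 1) {
    Zlist$col <- indicator(dsub$col, col_lev)
  }
  if (spec$spatial) Zlist <- c(Zlist, sp$blocks)
  if (spec$genotype_role == "random") {
    Zlist$genotype <- indicator(dsub$genotype, geno_lev)
  }

  fm <- fit_mm(y, X, Zlist, tol = spec$tol, max_iter = spec$max_iter,
               init = init)

  varcomp <- c(fm$sigma2, sigma2_e = fm$sigma2_e)
  if (spec$genotype_role == "random") {
    names(varcomp)[names(varcomp) == "genotype"] <- "sigma2_g"
  }

  fit <- list(day = NULL, genotype_role = spec$genotype_role,
              spatial = spec$spatial, genotypes = geno_lev, n_g = n_g,
              dropped_genotypes = dropped, varcomp = varcomp, ED = fm$ED,
              rss = fm$rss, n_obs = fm$n_obs, converged = fm$converged,
              n_iter = fm$n_iter, floored = fm$floored)

  if (spec$genotype_role == "fixed") {
    mu <- fm$coef[1]
    eff_free <- fm$coef[1 + seq_len(n_g - 1)]
    eff <- drop(contr %*% eff_free)
    Tm <- matrix(0, n_g, length(fm$coef))
    Tm[, 1] <- 1
    Tm[, 1 + seq_len(n_g - 1)] <- contr
    se <- sqrt(pmax(fm$sigma2_e * rowSums((Tm %*% fm$Ci) * Tm), 0))
    fit$blues <- data.frame(genotype = geno_lev, blue = mu + eff, se = se,
                            stringsAsFactors = FALSE)
  } else {
    fit$ED_g <- unname(fm$ED["genotype"])
    cnt <- tabulate(gi, n_g)
    fit$l <- count_null_dims(cnt, fm$n_obs)
    if (spec$spatial) {
      fit$h2 <- min(max(fit$ED_g / max(n_g - fit$l, 1), 0), 1)
    } else {
      s2g <- unname(varcomp["sigma2_g"])
      fit$h2 <- min(max(s2g / (s2g + fm$sigma2_e), 0), 1)
    }
  }

  if (spec$spatial) {
    grid <- unique(design[, c("row", "col")])
    gb <- basis$eval(grid$row, grid$col)
    ftrend <- drop(gb$fixed %*% fm$coef[1 + (spec$genotype_role == "fixed") *
                                          (n_g - 1) + 1:3])
    for (nm in names(gb$blocks)) {
      ftrend <- ftrend + drop(gb$blocks[[nm]] %*% fm$coef[fm$block_idx[[nm]]])
    }
    fit$spatial_trend <- data.frame(row = grid$row, col = grid$col,
                                    value = ftrend)
  }

  ## everything predict_validation needs, without the p x p covariance
  fit$model <- list(coef = fm$coef, block_idx = fm$block_idx,
                    contr = contr, geno_lev = geno_lev,
                    rep_lev = rep_lev, blk_lev = blk_all,
                    row_lev = row_lev, col_lev = col_lev,
                    basis = basis, px = fm$px, spec = spec)
  class(fit) <- "daily_fit"
  fit
}

## number of zero eigenvalues of the genotype block of the hat matrix under
## the intercept identifiability constraint: computed from the spectrum of
## diag(counts) - counts counts' / n (its null space is spanned by constants
## when every genotype is observed).
count_null_dims <- function(counts, n) {
  Mg <- diag(counts, length(counts)) - tcrossprod(counts) / n
  ev <- eigen(Mg, symmetric = TRUE, only.values = TRUE)$values
  sum(ev < max(ev) * 1e-8)
}

#' @export
print.daily_fit <- function(x, ...) {
  cat("daily_fit:", x$genotype_role, "genotype,",
      if (x$spatial) "spatial" else "non-spatial", "model;",
      x$n_obs, "obs,", x$n_g, "genotypes;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  if (!is.null(x$h2)) cat("  h2 =", round(x$h2, 3), "\n")
  invisible(x)
}

#' Broad-sense heritability from variance components
#'
#' Classical plot-level heritability
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)}.
#'
#' @param sigma2_g,sigma2_e genotypic and residual variances (>= 0).
#' @return a fraction in `[0, 1]`.
#' @export
h2_classical <- function(sigma2_g, sigma2_e) {
  if (sigma2_g < 0 || sigma2_e < 0) stop_pp("variances must be non-negative")
  if (sigma2_g + sigma2_e == 0) return(0)
  sigma2_g / (sigma2_g + sigma2_e)
}

#' Heritability of a daily fit
#'
#' For a genotype-random fit, returns the daily heritability: the classical
#' variance ratio for the non-spatial model, or the effective-dimension form
#' `ED_g / (n_g - l)` for the spatial model, where `ED_g` is the trace of the
#' genotype block of the hat matrix and `l` its number of zero eigenvalues.
#'
#' @param fit a `daily_fit` with `genotype_role = "random"`.
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "daily_fit"))
  if (fit$genotype_role != "random") {
    stop_pp("heritability requires a genotype-random fit")
  }
  fit$h2
}

#' Iterative Grubbs cleaning of a day's data (single-step strategy)
#'
#' Repeatedly fits the daily model, applies the two-sided Grubbs test
#' `G = max |r - mean(r)| / sd(r)` to the residuals, and removes the most
#' extreme observation while the test is significant at `alpha`, up to a cap
#' of 2 percent of the observations. Stops cleanly when residual variance
#' degenerates.
#'
#' @param day_values plot values (named by plot id or design-aligned).
#' @param design a `trial_design`.
#' @param spec a `model_spec` (genotype fixed for BLUE computation).
#' @param alpha Grubbs significance level.
#' @param max_removals iteration cap; default `ceiling(0.02 * n_obs)`.
#' @return the day values with removed observations set to `NA`; attributes
#'   `removed` (plot ids) and `n_tested` record the cleaning path.
#' @export
grubbs_clean <- function(day_values, design, spec = model_spec(),
                         alpha = 0.05, max_removals = NULL) {
  if (alpha <= 0 || alpha >= 1) stop_pp("`alpha` must be in (0, 1)")
  if (is.null(names(day_values))) names(day_values) <- design$plot_id
  y <- day_values[design$plot_id]
  n0 <- sum(!is.na(y))
  if (is.null(max_removals)) max_removals <- ceiling(0.02 * n0)
  removed <- character(0)
  init <- NULL
  tested <- 0L
  while (length(removed) < max_removals) {
    fit <- fit_day(y, design, spec, init = init)
    init <- list(sigma2 = fit$varcomp[setdiff(names(fit$varcomp), "sigma2_e")],
                 sigma2_e = unname(fit$varcomp["sigma2_e"]))
    r <- residuals_daily(fit, y, design)
    n <- length(r)
    if (n < 3) break
    s <- stats::sd(r)
    if (!is.finite(s) || s < 1e-12) break
    g <- abs(r - mean(r)) / s
    gmax <- max(g)
    tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    tested <- tested + 1L
    if (gmax <= gcrit) break
    worst <- names(r)[which.max(g)]
    y[worst] <- NA_real_
    removed <- c(removed, worst)
  }
  out <- y
  attr(out, "removed") <- removed
  attr(out, "n_tested") <- tested
  out
}

## residuals at observed plots, named by plot id
residuals_daily <- function(fit, day_values, design) {
  obs <- design[!is.na(day_values[design$plot_id]), , drop = FALSE]
  pred <- predict_validation(fit, obs)
  y <- day_values[obs$plot_id]
  r <- y[names(pred)] - pred
  r
}

#' Predict plot values from a fitted daily model
#'
#' Evaluates the fitted model at the design rows of a validation set: the
#' genotype estimate (fixed-effect BLUE contribution or random BLUP) plus the
#' estimated replicate, block, row and column effects and the spatial surface
#' at the plot's coordinates. Genotypes absent from the training fit are
#' excluded with a warning.
#'
#' @param fit a `daily_fit`.
#' @param newdesign data frame with columns `plot_id`, `genotype`,
#'   `replicate`, `block`, `row`, `col`.
#' @return named numeric vector of predictions (one per retained plot), with
#'   attribute `n_unseen` counting excluded rows.
#' @export
predict_validation <- function(fit, newdesign) {
  stopifnot(inherits(fit, "daily_fit"))
  m <- fit$model
  if (nrow(newdesign) == 0) {
    out <- numeric(0); attr(out, "n_unseen") <- 0L; return(out)
  }
  known <- newdesign$genotype %in% m$geno_lev
  n_unseen <- sum(!known)
  if (n_unseen > 0) {
    warning(n_unseen, " validation plot(s) with unseen genotypes excluded",
            call. = FALSE)
    newdesign <- newdesign[known, , drop = FALSE]
  }
  if (nrow(newdesign) == 0) {
    out <- numeric(0); attr(out, "n_unseen") <- n_unseen; return(out)
  }
  coef <- m$coef
  pred <- rep(coef[1], nrow(newdesign))
  gi <- match(newdesign$genotype, m$geno_lev)
  n_g <- length(m$geno_lev)
  if (fit$genotype_role == "fixed") {
    eff <- drop(m$contr %*% coef[1 + seq_len(n_g - 1)])
    pred <- pred + eff[gi]
  } else {
    pred <- pred + coef[m$block_idx$genotype][gi]
  }
  add_blup <- function(term, values, levels) {
    if (is.null(m$block_idx[[term]])) return(0)
    u <- coef[m$block_idx[[term]]]
    ii <- match(values, levels)
    ifelse(is.na(ii), 0, u[ii])
  }
  pred <- pred + add_blup("replicate", newdesign$replicate, m$rep_lev)
  pred <- pred + add_blup("block",
                          paste(newdesign$replicate, newdesign$block,
                                sep = ":"), m$blk_lev)
  pred <- pred + add_blup("row", newdesign$row, m$row_lev)
  pred <- pred + add_blup("col", newdesign$col, m$col_lev)
  if (fit$spatial) {
    gb <- m$basis$eval(newdesign$row, newdesign$col)
    off <- 1 + (fit$genotype_role == "fixed") * (n_g - 1)
    pred <- pred + drop(gb$fixed %*% coef[off + 1:3])
    for (nm in names(gb$blocks)) {
      pred <- pred + drop(gb$blocks[[nm]] %*% coef[m$block_idx[[nm]]])
    }
  }
  names(pred) <- newdesign$plot_id
  attr(pred, "n_unseen") <- n_unseen
  pred
}
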