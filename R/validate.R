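#' Cross-validate strategies on one trial
#'
#' Replicated k-fold cross validation of the daily mixed model under each
#' processing strategy. Per replication one day is drawn at random (to cover
#' the time dimension), its observed plots are partitioned into `n_fold`
#' folds, and each fold in turn is held out: preprocessing is applied with
#' the held-out cells masked, the model is fitted on the estimation portion,
#' the fold is predicted from the design and genotype information, and the
#' Pearson correlation between predictions and observations is recorded
#' together with the training heritability. All strategies see identical
#' partitions. `n_rep = 10` and `n_fold = 5` give 50 values per strategy.
#'
#' @param pheno a `pheno_matrix`.
#' @param design a `trial_design`.
#' @param strategies character vector of strategy names.
#' @param n_rep replications; @param n_fold folds.
#' @param seed integer seed.
#' @param spec_args passed to [model_spec()].
#' @return a `cv_report`: data frame (`strategy`, `rep`, `fold`, `day`,
#'   `rho`, `h2`, `n_val`) plus a `summary()`-style attribute `means` and
#'   Welch t-tests between treatment on/off groups in attribute `effects`.
#' @export
cross_validate <- function(pheno, design, strategies = paste0("S", 1:9),
                           n_rep = 10, n_fold = 5, seed = 1,
                           spec_args = list()) {
  validate_design(design)
  out <- list()
  for (r in seq_len(n_rep)) {
    sr <- derive_seed(seed, r)
    day <- with_seed(sr, sample(seq_along(pheno$days), 1))
    yday <- pheno$values[, day]
    obs_plots <- rownames(pheno$values)[!is.na(yday)]
    if (length(obs_plots) < n_fold) {
      stop_pp("day ", colnames(pheno$values)[day], " has fewer than ",
              n_fold, " observations")
    }
    folds <- cv_partition(obs_plots, n_fold, sr + 1L)
    for (s in strategies) {
      strat <- strategy(s)
      for (fo in seq_len(n_fold)) {
        val_plots <- folds[[fo]]
        ptrain <- pheno
        ptrain$values[val_plots, day] <- NA_real_
        fit <- cv_fit_one(ptrain, design, strat, day,
                          seed = derive_seed(seed, 1000L + r), spec_args)
        vd <- design[design$plot_id %in% val_plots, , drop = FALSE]
        pred <- suppressWarnings(predict_validation(fit$fixed, vd))
        yv <- yday[names(pred)]
        rho <- if (length(pred) >= 2 && stats::sd(yv) > 0 &&
                   stats::sd(pred) > 0) {
          stats::cor(pred, yv)
        } else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          strategy = s, rep = r, fold = fo,
          day = colnames(pheno$values)[day], rho = rho, h2 = fit$h2,
          n_val = length(pred),
          n_unseen = attr(pred, "n_unseen") %||% 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  rep_df <- do.call(rbind, out)
  class(rep_df) <- c("cv_report", "data.frame")
  attr(rep_df, "means") <- stats::aggregate(
    cbind(rho, h2) ~ strategy, data = rep_df, FUN = mean, na.action = stats::na.omit)
  attr(rep_df, "effects") <- cv_treatment_effects(rep_df)
  rep_df
}

#' Partition observations into cross-validation folds
#'
#' Random partition into `n_fold` folds of (near-)equal size: every element
#' appears in exactly one fold.
#'
#' @param ids identifiers to partition.
#' @param n_fold number of folds.
#' @param seed integer seed.
#' @return list of `n_fold` disjoint id vectors covering `ids`.
#' @export
cv_partition <- function(ids, n_fold, seed) {
  with_seed(seed, {
    f <- rep_len(seq_len(n_fold), length(ids))
    split(ids, sample(f))
  })
}

## one training fit for a CV fold: preprocessing on the estimation portion
## only, then the daily fixed- and random-genotype fits
cv_fit_one <- function(ptrain, design, strat, day, seed, spec_args) {
  if (strat$outliers) ptrain <- detect_outliers(ptrain)$pheno
  if (strat$imputation) {
    ptrain <- impute_pmm(ptrain, seed = seed)
  }
  y <- ptrain$values[, day]
  names(y) <- rownames(ptrain$values)
  spec_f <- do.call(model_spec, c(list("fixed", spatial = strat$spatial),
                                  spec_args))
  spec_r <- do.call(model_spec, c(list("random", spatial = strat$spatial),
                                  spec_args))
  if (strat$single_step) y <- grubbs_clean(y, design, spec_f)
  ff <- fit_day(y, design, spec_f)
  fr <- fit_day(y, design, spec_r)
  list(fixed = ff, h2 = fr$h2)
}

## marginal treatment contrasts over the S1-S8 truth table, paired by
## (rep, fold): each strategy with the treatment vs its counterpart without
cv_treatment_effects <- function(rep_df) {
  pairs <- list(
    outliers   = cbind(c("S2", "S4", "S6", "S8"), c("S1", "S3", "S5", "S7")),
    imputation = cbind(c("S3", "S4", "S7", "S8"), c("S1", "S2", "S5", "S6")),
    spatial    = cbind(c("S5", "S6", "S7", "S8"), c("S1", "S2", "S3", "S4"))
  )
  res <- lapply(names(pairs), function(tr) {
    pp <- pairs[[tr]]
    have <- pp[pp[, 1] %in% rep_df$strategy & pp[, 2] %in% rep_df$strategy, ,
               drop = FALSE]
    if (!nrow(have)) return(NULL)
    d_rho <- c(); d_h2 <- c()
    for (i in seq_len(nrow(have))) {
      a <- rep_df[rep_df$strategy == have[i, 1], ]
      b <- rep_df[rep_df$strategy == have[i, 2], ]
      key <- function(z) paste(z$rep, z$fold)
      m <- match(key(a), key(b))
      d_rho <- c(d_rho, a$rho - b$rho[m])
      d_h2 <- c(d_h2, a$h2 - b$h2[m])
    }
    tt <- function(d) {
      d <- d[is.finite(d)]
      if (length(d) < 3 || stats::sd(d) == 0) return(c(NA, NA))
      t <- stats::t.test(d)
      c(t$estimate, t$p.value)
    }
    r <- tt(d_rho); h <- tt(d_h2)
    data.frame(treatment = tr, mean_diff_rho = r[1], p_rho = r[2],
               mean_diff_h2 = h[1], p_h2 = h[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Between-experiment correlation of adjusted-mean series
#'
#' Pearson correlation of genotype adjusted means between two experiments on
#' the same panel, per matched day over the genotypes observed in both, and
#' its mean over days. Days with fewer than 3 common genotypes are skipped.
#'
#' @param seriesA,seriesB `gblue_series` objects sharing genotypes.
#' @param day_pairs two-column matrix/data frame of day indices (A, B);
#'   default pairs days positionally.
#' @return list with `per_day` data frame (`dayA`, `dayB`, `rho`, `n`) and
#'   `mean`.
#' @export
between_experiment_corr <- function(seriesA, seriesB, day_pairs = NULL) {
  common <- intersect(seriesA$genotypes, seriesB$genotypes)
  if (!length(common)) stop_pp("no shared genotypes")
  if (is.null(day_pairs)) {
    nd <- min(length(seriesA$days), length(seriesB$days))
    day_pairs <- cbind(seq_len(nd), seq_len(nd))
  }
  day_pairs <- as.matrix(day_pairs)
  res <- lapply(seq_len(nrow(day_pairs)), function(i) {
    a <- seriesA$blues[common, day_pairs[i, 1]]
    b <- seriesB$blues[common, day_pairs[i, 2]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) return(NULL)
    data.frame(dayA = seriesA$days[day_pairs[i, 1]],
               dayB = seriesB$days[day_pairs[i, 2]],
               rho = stats::cor(a[ok], b[ok]), n = sum(ok))
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  per_day <- do.call(rbind, res)
  if (skipped) message(skipped, " day pair(s) skipped (<3 common genotypes)")
  list(per_day = per_day, mean = mean(per_day$rho))
}

#' Robustness simulation against injected missing values and noise
#'
#' Emulates the contamination study: adjusted means of one clean reference
#' day are computed once with the spatial model; then, per repeat, scenario
#' and contamination level, the full series is contaminated with
#' [inject_missing()] and/or [inject_noise()], each strategy is run, and the
#' reference-day adjusted means are correlated with the reference. Missing
#' and noisy cell sets are drawn independently in the combined scenario.
#'
#' @param pheno_clean a complete (or nearly complete) `pheno_matrix`.
#' @param design a `trial_design`.
#' @param reference_day day index; must have no missing values.
#' @param strategies strategy names (typically S5-S9).
#' @param x_levels contamination fractions.
#' @param scenarios subset of `c("missing", "noise", "both")`.
#' @param n_rep repeats per cell of the grid.
#' @param scale_mult noise variance multiplier.
#' @param seed integer seed.
#' @param spec_args passed to [model_spec()].
#' @return a `sim_report` data frame (`scenario`, `x`, `strategy`,
#'   `mean_corr`, `sd_corr`, `n_rep`), with per-repeat correlations in
#'   attribute `raw`.
#' @export
robustness_simulation <- function(pheno_clean, design, reference_day,
                                  strategies = paste0("S", 5:9),
                                  x_levels = seq(0.1, 0.5, by = 0.1),
                                  scenarios = c("missing", "noise", "both"),
                                  n_rep = 10, scale_mult = 3, seed = 1,
                                  spec_args = list()) {
  validate_design(design)
  if (any(is.na(pheno_clean$values[, reference_day]))) {
    stop_pp("reference day contains missing values")
  }
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  ref_lab <- colnames(pheno_clean$values)[reference_day]
  ref_run <- run_strategy(pheno_clean, design, "S5", seed = seed,
                          days = reference_day, h2 = FALSE,
                          spec_args = spec_args)
  ref <- ref_run$blues[, 1]
  inits <- list()   # per-strategy warm starts carried across repeats
  raw <- list()
  for (sc in scenarios) {
    for (x in x_levels) {
      for (r in seq_len(n_rep)) {
        s_m <- derive_seed(seed, r * 131L + round(1000 * x))
        s_n <- derive_seed(seed, r * 137L + round(1000 * x) + 17L)
        pc <- pheno_clean
        if (sc %in% c("missing", "both") && x > 0) {
          pc <- inject_missing(pc, x, seed = s_m)
        }
        if (sc %in% c("noise", "both") && x > 0) {
          pc <- inject_noise(pc, x, scale_mult = scale_mult, seed = s_n)
        }
        for (s in strategies) {
          run <- tryCatch(
            run_strategy(pc, design, s, seed = derive_seed(seed, r),
                         days = ref_lab, h2 = FALSE,
                         spec_args = spec_args, warm_init = inits[[s]]),
            error = function(e) {
              warning(sc, " x=", x, " ", s, " rep ", r, ": ",
                      conditionMessage(e), call. = FALSE)
              NULL
            })
          bl <- if (is.null(run)) NULL else run$blues[, 1]
          if (!is.null(run)) inits[[s]] <- run$init
          cc <- if (is.null(bl)) NA_real_ else {
            ok <- is.finite(ref) & is.finite(bl)
            if (sum(ok) >= 3) stats::cor(ref[ok], bl[ok]) else NA_real_
          }
          raw[[length(raw) + 1L]] <- data.frame(
            scenario = sc, x = x, strategy = s, rep = r, corr = cc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  raw <- do.call(rbind, raw)
  agg <- stats::aggregate(corr ~ scenario + x + strategy, data = raw,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v)))
  rep_df <- data.frame(scenario = agg$scenario, x = agg$x,
                       strategy = agg$strategy,
                       mean_corr = agg$corr[, "mean"],
                       sd_corr = agg$corr[, "sd"],
                       n_rep = n_rep, stringsAsFactors = FALSE)
  attr(rep_df, "raw") <- raw
  class(rep_df) <- c("sim_report", "data.frame")
  rep_df
}
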