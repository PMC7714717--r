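#' Simulate a phenotyping trial with known ground truth
#'
#' Generates a plot-by-day trait matrix on a given layout. Each genotype
#' follows its own 3-parameter logistic growth curve; its effect on a day is
#' the curve value minus the population mean curve that day. On top of the
#' genotype signal the generator adds static replicate, block, row and column
#' effects, a smooth spatial surface (low-order polynomial plus a Gaussian
#' ridge along one wall of the grid, mimicking heat accumulation near a
#' boundary), and iid Gaussian plot error. The error standard deviation is
#' scaled per day so that the plot-level heritability
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)} equals `h2_target`
#' every day.
#'
#' @param design a `trial_design`.
#' @param n_days number of daily measurements (>= 3).
#' @param h2_target plot-level heritability in (0, 1).
#' @param spatial_amplitude standard deviation (trait units) of the spatial
#'   surface across the grid; `NULL` uses 0.3 times the genotype effect sd on
#'   the middle day; 0 removes the surface.
#' @param growth list of ranges `A`, `k`, `t0` (each `c(min, max)`) from which
#'   genotype-specific logistic parameters are drawn uniformly. Defaults give
#'   plant-height-like curves (asymptote 60--120 cm, rate 0.25--0.55 per day,
#'   inflection between days 8 and 15).
#' @param design_sds named list of standard deviations for the static
#'   `replicate`, `block`, `row`, `col` effects, expressed as multiples of the
#'   middle-day genotype effect sd.
#' @param error_sd optional fixed error sd overriding the `h2_target`
#'   calibration (required when the genotype variance is zero).
#' @param start_date first measurement date.
#' @param seed integer seed; the same seed reproduces the trial bit for bit.
#' @return a list with elements `pheno` (a complete `pheno_matrix`) and
#'   `truth` (a `truth_record` holding per-day genotype effects, the spatial
#'   surface, variance components, growth parameters and the seed).
#' @export
simulate_trial <- function(design, n_days = 22, h2_target = 0.7,
                           spatial_amplitude = NULL,
                           growth = list(A = c(60, 120), k = c(0.25, 0.55),
                                         t0 = c(8, 15)),
                           design_sds = list(replicate = 0.15, block = 0.15,
                                             row = 0.10, col = 0.10),
                           error_sd = NULL,
                           start_date = as.Date("2015-03-15"), seed = 1) {
  if (!(h2_target > 0 && h2_target < 1)) {
    stop_pp("`h2_target` must lie strictly between 0 and 1")
  }
  if (n_days < 3) stop_pp("`n_days` must be at least 3")
  validate_design(design)
  geno <- sort(unique(design$genotype))
  n_g <- length(geno)
  n_plot <- nrow(design)
  days <- seq_len(n_days)

  with_seed(seed, {
    pars <- data.frame(
      genotype = geno,
      A = stats::runif(n_g, growth$A[1], growth$A[2]),
      k = stats::runif(n_g, growth$k[1], growth$k[2]),
      t0 = stats::runif(n_g, growth$t0[1], growth$t0[2])
    )
    curves <- outer(seq_len(n_g), days, function(i, t) {
      pars$A[i] / (1 + exp(-pars$k[i] * (t - pars$t0[i])))
    })
    rownames(curves) <- geno
    geno_eff <- sweep(curves, 2, colMeans(curves))
    sg <- apply(geno_eff, 2, stats::sd)          # per-day genotype effect sd
    sg_mid <- sg[ceiling(n_days / 2)]

    ## static design effects
    rep_lev <- sort(unique(design$replicate))
    blk_lev <- sort(unique(paste(design$replicate, design$block)))
    row_lev <- sort(unique(design$row))
    col_lev <- sort(unique(design$col))
    e_rep <- stats::rnorm(length(rep_lev), 0, design_sds$replicate * sg_mid)
    e_blk <- stats::rnorm(length(blk_lev), 0, design_sds$block * sg_mid)
    e_row <- stats::rnorm(length(row_lev), 0, design_sds$row * sg_mid)
    e_col <- stats::rnorm(length(col_lev), 0, design_sds$col * sg_mid)

    ## smooth spatial surface on the grid: quadratic trend + wall ridge
    R <- max(design$row); C <- max(design$col)
    amp <- spatial_amplitude %||% (0.3 * sg_mid)
    rg <- (seq_len(R) - (R + 1) / 2) / R
    cg <- (seq_len(C) - (C + 1) / 2) / C
    a <- stats::runif(5, -1, 1)
    surf <- outer(rg, cg, function(u, v) {
      a[1] * u + a[2] * v + a[3] * u * v + a[4] * u^2 + a[5] * v^2
    })
    ridge <- outer(seq_len(R), seq_len(C), function(r, co) {
      exp(-0.5 * ((co - 1) / (0.15 * C))^2)
    })
    surf <- surf + ridge
    if (amp > 0 && stats::sd(as.vector(surf)) > 0) {
      surf <- (surf - mean(surf)) / stats::sd(as.vector(surf)) * amp
    } else {
      surf <- surf * 0
    }

    if (is.null(error_sd)) {
      if (any(sg == 0)) {
        stop_pp("genotype variance is zero on some day; supply `error_sd` ",
                "instead of calibrating to `h2_target`")
      }
      se <- sg * sqrt((1 - h2_target) / h2_target)
    } else {
      se <- rep(error_sd, n_days)
    }

    gi <- match(design$genotype, geno)
    static <- e_rep[match(design$replicate, rep_lev)] +
      e_blk[match(paste(design$replicate, design$block), blk_lev)] +
      e_row[match(design$row, row_lev)] +
      e_col[match(design$col, col_lev)] +
      surf[cbind(design$row, design$col)]

    values <- curves[gi, , drop = FALSE] +
      matrix(static, n_plot, n_days) +
      sweep(matrix(stats::rnorm(n_plot * n_days), n_plot, n_days), 2, se, `*`)
    rownames(values) <- design$plot_id

    pheno <- pheno_matrix(values, design, start_date + days - 1)
    truth <- structure(list(
      genotype_effects_per_day = geno_eff,
      population_curve = colMeans(curves),
      spatial_surface = surf,
      variance_components = list(
        sigma2_g = sg^2, sigma2_e = se^2,
        sigma2_rep = (design_sds$replicate * sg_mid)^2,
        sigma2_block = (design_sds$block * sg_mid)^2,
        sigma2_row = (design_sds$row * sg_mid)^2,
        sigma2_col = (design_sds$col * sg_mid)^2
      ),
      growth_params = pars,
      h2_target = h2_target,
      seed = seed
    ), class = "truth_record")
    list(pheno = pheno, truth = truth)
  })
}

## canonical cell order (plot_id then day label) so that injections commute
## with row reordering: the same seed always selects the same cell identities
canonical_cells <- function(pheno) {
  ids <- rownames(pheno$values)
  dl <- colnames(pheno$values)
  cells <- expand.grid(plot = ids, day = dl, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  ord <- order(cells$day, cells$plot)
  cells[ord, , drop = FALSE]
}

#' Inject missing values completely at random
#'
#' Sets exactly `round(x * n_cells)` currently observed cells to missing,
#' chosen uniformly (MCAR). Cell selection is keyed on plot id and day label,
#' so the injected pattern is equivariant under plot reordering.
#'
#' @param pheno a `pheno_matrix`.
#' @param x fraction of cells in `[0, 1)`.
#' @param seed integer seed.
#' @return the contaminated `pheno_matrix`.
#' @export
inject_missing <- function(pheno, x, seed) {
  if (x < 0 || x >= 1) stop_pp("`x` must lie in [0, 1)")
  n_cells <- length(pheno$values)
  n_miss <- round(x * n_cells)
  if (n_miss == 0) return(pheno)
  cells <- canonical_cells(pheno)
  obs <- which(!is.na(pheno$values[cbind(cells$plot, cells$day)]))
  if (n_miss > length(obs)) {
    stop_pp("cannot set ", n_miss, " cells missing: only ", length(obs),
            " observed cells")
  }
  with_seed(seed, {
    pick <- obs[sample.int(length(obs), n_miss)]
    idx <- cbind(match(cells$plot[pick], rownames(pheno$values)),
                 match(cells$day[pick], colnames(pheno$values)))
    pheno$values[idx] <- NA_real_
    pheno
  })
}

#' Inject additive noise to generate outliers
#'
#' For each day, `round(x * n_plots)` observed cells receive an additive draw
#' from \eqn{N(0, s \cdot Var)} where `Var` is the variance of that day's
#' values before contamination and `s = scale_mult` (3 emulates severe sensor
#' faults). Cell selection is keyed on plot id, so the pattern is equivariant
#' under plot reordering.
#'
#' @param pheno a `pheno_matrix`.
#' @param x fraction of plots per day in `[0, 1)`.
#' @param scale_mult positive multiplier of the day variance.
#' @param seed integer seed.
#' @return the contaminated `pheno_matrix`.
#' @export
inject_noise <- function(pheno, x, scale_mult = 3, seed = 1) {
  if (x < 0 || x >= 1) stop_pp("`x` must lie in [0, 1)")
  if (scale_mult <= 0) stop_pp("`scale_mult` must be positive")
  n_plot <- nrow(pheno$values)
  n_noise <- round(x * n_plot)
  if (n_noise == 0) return(pheno)
  ids <- sort(rownames(pheno$values))
  with_seed(seed, {
    for (d in seq_along(pheno$days)) {
      v <- pheno$values[ids, d]
      obs <- which(!is.na(v))
      if (length(obs) < 2) {
        stop_pp("day ", colnames(pheno$values)[d],
                " has fewer than 2 observed values; variance undefined")
      }
      day_var <- stats::var(v[obs])
      pick <- obs[sample.int(length(obs), min(n_noise, length(obs)))]
      noise <- stats::rnorm(length(pick), 0, sqrt(scale_mult * day_var))
      pheno$values[match(ids[pick], rownames(pheno$values)), d] <-
        v[pick] + noise
    }
    pheno
  })
}
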