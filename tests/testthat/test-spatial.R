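test_that("null data give near-zero heritability and a flat fitted surface", {
  d <- small_design()
  sim <- simulate_trial(d, n_days = 4, spatial_amplitude = 0,
                        growth = list(A = c(80, 80), k = c(0.4, 0.4),
                                      t0 = c(5, 5)),
                        design_sds = list(replicate = 0, block = 0,
                                          row = 0, col = 0),
                        error_sd = 3, seed = 21)
  f <- fit_day(sim$pheno$values[, 2], d, model_spec("random", spatial = TRUE))
  expect_lte(f$h2, 0.05)
  expect_lt(stats::sd(f$spatial_trend$value), 1)
})

test_that("a genotype-only least-squares model reproduces per-genotype means", {
  d <- make_design(12, 2, 4, 6, 4, seed = 3)
  set.seed(1); y <- rnorm(24, 50, 5); names(y) <- d$plot_id
  f <- fit_day(y, d, model_spec("fixed", spatial = FALSE,
                                random_terms = character(0)))
  mns <- tapply(y, d$genotype, mean)
  expect_equal(f$blues$blue, as.numeric(mns[f$blues$genotype]),
               tolerance = 1e-10)
})

test_that("the planted smooth surface is recovered better than by the
           non-spatial residual map", {
  d <- mid_design()
  sim <- simulate_trial(d, n_days = 5, h2_target = 0.6,
                        spatial_amplitude = 3, seed = 31)
  y <- sim$pheno$values[, 3]
  truth <- sim$truth$spatial_surface[cbind(d$row, d$col)]
  fs <- fit_day(y, d, model_spec("fixed", spatial = TRUE))
  sp <- fs$spatial_trend
  fitted_surf <- sp$value[match(paste(d$row, d$col),
                                paste(sp$row, sp$col))]
  corr_spatial <- stats::cor(fitted_surf, truth)
  fn <- fit_day(y, d, model_spec("fixed", spatial = FALSE))
  resid_map <- y - predict_validation(fn, d)[d$plot_id]
  corr_resid <- stats::cor(resid_map, truth)
  expect_gt(corr_spatial, corr_resid)
  expect_gt(corr_spatial, 0.8)
})

test_that("heritability formulas and bounds behave", {
  expect_equal(h2_classical(3, 1), 0.75)
  expect_equal(h2_classical(0, 2), 0)
  expect_error(h2_classical(-1, 1), "non-negative")
  d <- small_design()
  for (s in 1:5) {
    sim <- small_sim(d, n_days = 3, h2 = 0.5, seed = 40 + s)
    f <- fit_day(sim$pheno$values[, 2], d, model_spec("random"))
    expect_gte(f$h2, 0)
    expect_lte(f$h2, 1)
    expect_true(all(f$varcomp >= 0))
    expect_error(heritability(fit_day(sim$pheno$values[, 2], d,
                                      model_spec("fixed"))),
                 "genotype-random")
    expect_equal(heritability(f), f$h2)
  }
})

test_that("the genotype effective dimension equals the dense hat-matrix
           trace", {
  # 20 genotypes x 3 reps, genotype random + replicate random
  set.seed(7)
  n_g <- 20; n_rep <- 3
  g <- factor(rep(seq_len(n_g), n_rep))
  r <- factor(rep(seq_len(n_rep), each = n_g))
  y <- rnorm(n_g, 0, 2)[g] + rnorm(n_rep, 0, 1)[r] + rnorm(n_g * n_rep)
  X <- matrix(1, length(y), 1)
  Zg <- stats::model.matrix(~ 0 + g)
  Zr <- stats::model.matrix(~ 0 + r)
  fm <- phenopipe:::fit_mm(y, X, list(replicate = Zr, genotype = Zg))
  expect_true(fm$converged)
  # dense oracle: H_g = Z_g [C^-1 M']_(g rows); ED_g = tr(H_g)
  M <- cbind(X, Zr, Zg)
  lam <- fm$sigma2_e / pmax(fm$sigma2, 1e-10)
  C <- crossprod(M)
  ii <- fm$block_idx$replicate
  C[cbind(ii, ii)] <- C[cbind(ii, ii)] + lam["replicate"]
  jj <- fm$block_idx$genotype
  C[cbind(jj, jj)] <- C[cbind(jj, jj)] + lam["genotype"]
  S <- solve(C) %*% t(M)
  ED_oracle <- sum(diag(Zg %*% S[jj, ]))
  expect_equal(unname(fm$ED["genotype"]), ED_oracle, tolerance = 1e-8)
})

test_that("the Schall solution matches a dense generalized least squares
           solve at the converged variance components", {
  d <- make_design(15, 4, 5, 10, 6, seed = 5)      # 60 plots
  sim <- simulate_trial(d, n_days = 3, h2_target = 0.6, seed = 6)
  y <- sim$pheno$values[, 2]
  spec <- model_spec("fixed", spatial = TRUE, nseg = c(5, 5))
  f <- fit_day(y, d, spec)
  # rebuild the design matrices exactly as the fit does
  basis <- phenopipe:::psanova_basis(max(d$row), max(d$col), c(5, 5))
  sp <- basis$eval(d$row, d$col)
  n_g <- length(unique(d$genotype))
  contr <- stats::contr.sum(n_g)
  gi <- match(d$genotype, sort(unique(d$genotype)))
  X <- cbind(1, contr[gi, ], sp$fixed)
  Zl <- list(
    replicate = phenopipe:::indicator(d$replicate, sort(unique(d$replicate))),
    block = phenopipe:::indicator(paste(d$replicate, d$block, sep = ":"),
                                  sort(unique(paste(d$replicate, d$block,
                                                    sep = ":")))),
    row = phenopipe:::indicator(d$row, sort(unique(d$row))),
    col = phenopipe:::indicator(d$col, sort(unique(d$col))))
  Zl <- c(Zl, sp$blocks)
  fm <- phenopipe:::fit_mm(y, X, Zl)
  V <- fm$sigma2_e * diag(length(y))
  for (b in names(Zl)) V <- V + fm$sigma2[b] * tcrossprod(Zl[[b]])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - X %*% beta
  expect_equal(unname(fm$coef[seq_len(ncol(X))]), unname(drop(beta)),
               tolerance = 1e-6)
  for (b in names(Zl)) {
    u <- fm$sigma2[b] * t(Zl[[b]]) %*% Vi %*% resid
    expect_equal(unname(fm$coef[fm$block_idx[[b]]]), unname(drop(u)),
                 tolerance = 1e-6)
  }
})

test_that("genotype effects are recovered and the spatial term helps", {
  d <- small_design()
  rec <- numeric(10); benefit <- logical(10)
  for (s in 1:10) {
    sim <- simulate_trial(d, n_days = 3, h2_target = 0.7, seed = 50 + s)
    y <- sim$pheno$values[, 2]
    f <- fit_day(y, d, model_spec("fixed", spatial = TRUE))
    eff <- sim$truth$genotype_effects_per_day[f$blues$genotype, 2]
    rec[s] <- stats::cor(f$blues$blue, eff)
    h_sp <- fit_day(y, d, model_spec("random", spatial = TRUE))$h2
    h_ns <- fit_day(y, d, model_spec("random", spatial = FALSE))$h2
    benefit[s] <- h_sp > h_ns
  }
  expect_gte(stats::median(rec), 0.9)
  expect_gte(sum(benefit), 8)
})

test_that("genotypes unobserved on a day receive no adjusted mean", {
  d <- small_design()
  sim <- small_sim(d, n_days = 3, seed = 61)
  y <- sim$pheno$values[, 2]
  gone <- unique(d$genotype)[1:2]
  y[d$genotype %in% gone] <- NA
  f <- fit_day(y, d, model_spec("fixed"))
  expect_false(any(gone %in% f$blues$genotype))
  expect_setequal(f$dropped_genotypes, gone)
})

test_that("iterative Grubbs cleaning removes a planted extreme first and
           leaves null data alone", {
  d <- small_design()
  sim <- simulate_trial(d, n_days = 3, h2_target = 0.5, seed = 71)
  y <- sim$pheno$values[, 2]
  clean <- grubbs_clean(y, d, model_spec("fixed"), alpha = 0.05)
  expect_lte(length(attr(clean, "removed")), 2)
  y2 <- y
  y2[40] <- y2[40] + 8 * stats::sd(y2)
  clean2 <- grubbs_clean(y2, d, model_spec("fixed"), alpha = 0.05)
  expect_equal(attr(clean2, "removed")[1], d$plot_id[40])
  expect_true(is.na(clean2[d$plot_id[40]]))
  # alpha -> 0: no removals
  clean3 <- grubbs_clean(y2, d, model_spec("fixed"), alpha = 1e-12)
  expect_length(attr(clean3, "removed"), 0)
})

test_that("the Grubbs statistic agrees with the hand formula on the first
           removal", {
  d <- small_design()
  sim <- simulate_trial(d, n_days = 3, h2_target = 0.5, seed = 72)
  y <- sim$pheno$values[, 2]
  y[10] <- y[10] + 10 * stats::sd(y)
  f <- fit_day(y, d, model_spec("fixed"))
  r <- phenopipe:::residuals_daily(f, stats::setNames(y, d$plot_id), d)
  n <- length(r)
  G <- max(abs(r - mean(r)) / stats::sd(r))
  tq <- stats::qt(1 - 0.05 / (2 * n), n - 2)
  Gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  expect_gt(G, Gcrit)  # the planted point must trigger the removal
  expect_equal(names(r)[which.max(abs(r - mean(r)))], d$plot_id[10])
})

test_that("validation predictions reproduce training rows without noise and
           gain from the spatial term with it", {
  d <- small_design()
  sim <- simulate_trial(d, n_days = 3, spatial_amplitude = 2,
                        design_sds = list(replicate = 0.2, block = 0.2,
                                          row = 0.1, col = 0.1),
                        error_sd = 1e-3, seed = 81)
  y <- sim$pheno$values[, 2]
  f <- fit_day(y, d, model_spec("fixed", spatial = TRUE))
  pred <- predict_validation(f, d)
  expect_gt(stats::cor(pred[d$plot_id], y), 0.999)
  # empty validation set
  empty <- predict_validation(f, d[0, ])
  expect_length(empty, 0)
  # noisy spatially-trended data: held-out prediction better with the surface
  sim2 <- simulate_trial(d, n_days = 3, spatial_amplitude = 4,
                         h2_target = 0.6, seed = 82)
  y2 <- sim2$pheno$values[, 2]
  hold <- seq(1, 144, by = 6)
  ytr <- y2; ytr[hold] <- NA
  fs <- fit_day(ytr, d, model_spec("fixed", spatial = TRUE))
  fn <- fit_day(ytr, d, model_spec("fixed", spatial = FALSE))
  vd <- d[hold, ]
  ps <- suppressWarnings(predict_validation(fs, vd))
  pn <- suppressWarnings(predict_validation(fn, vd))
  ys <- y2[match(names(ps), d$plot_id)]
  yn <- y2[match(names(pn), d$plot_id)]
  expect_gt(stats::cor(ps, ys), stats::cor(pn, yn))
})

test_that("an unseen genotype in the validation set is excluded with a
           warning", {
  d <- small_design()
  sim <- small_sim(d, n_days = 3, seed = 91)
  y <- sim$pheno$values[, 2]
  gone <- unique(d$genotype)[1]
  y[d$genotype == gone] <- NA
  f <- fit_day(y, d, model_spec("fixed"))
  expect_warning(p <- predict_validation(f, d), "unseen")
  expect_equal(attr(p, "n_unseen"), sum(d$genotype == gone))
})
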