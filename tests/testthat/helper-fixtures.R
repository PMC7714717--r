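# Small in-code fixtures shared across test files. All randomness is seeded
# through the generator's own seed arguments.

tiny_design <- function(seed = 1) {
  # 24 genotypes x 3 reps in 8 blocks of 3 on a 9 x 8 grid
  make_design(24, 3, 8, 9, 8, seed = seed)
}

small_design <- function(seed = 1) {
  # 48 genotypes x 3 reps in 12 blocks of 4 on a 12 x 12 grid
  make_design(48, 3, 12, 12, 12, seed = seed)
}

mid_design <- function(seed = 1) {
  # 96 genotypes x 4 reps in 12 blocks of 8 on a 24 x 16 grid
  make_design(96, 4, 12, 24, 16, seed = seed)
}

small_sim <- function(design = small_design(), n_days = 10, h2 = 0.7,
                      seed = 1, ...) {
  simulate_trial(design, n_days = n_days, h2_target = h2, seed = seed, ...)
}

# deterministic pheno_matrix from an explicit value matrix
pheno_from_values <- function(values, design,
                              start = as.Date("2015-03-15")) {
  pheno_matrix(values, design, start + seq_len(ncol(values)) - 1)
}

# Independent reference implementation of the day-wise predictive mean
# matching sweep, written as plain loops against the documented random-draw
# protocol (one rchisq, one normal vector, one donor draw per missing cell in
# row order; days in column order; imputations outermost).
ref_pmm <- function(V, m, k, seed) {
  n <- nrow(V); D <- ncol(V)
  mask <- is.na(V)
  day_means <- colMeans(V, na.rm = TRUE)
  Vfill <- V
  for (d in seq_len(D)) Vfill[mask[, d], d] <- day_means[d]
  acc <- matrix(0, n, D)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  for (imp in seq_len(m)) {
    completed <- V
    for (d in seq_len(D)) {
      mis <- which(mask[, d])
      if (!length(mis)) next
      obs <- which(!mask[, d])
      Z <- Vfill[, -d, drop = FALSE]
      mu <- colMeans(Z)
      sdv <- apply(Z, 2, sd); sdv[sdv < 1e-12] <- 1
      Zs <- sweep(sweep(Z, 2, mu), 2, sdv, "/")
      X <- cbind(1, Zs)
      p <- ncol(X)
      A <- t(X[obs, , drop = FALSE]) %*% X[obs, , drop = FALSE] +
        diag(c(0, rep(1e-5, p - 1)))
      Ai <- solve(A)
      b <- Ai %*% t(X[obs, , drop = FALSE]) %*% V[obs, d]
      res <- V[obs, d] - X[obs, , drop = FALSE] %*% b
      sigma2 <- sum(res^2) / rchisq(1, max(length(obs) - p, 1))
      Ru <- chol((Ai + t(Ai)) / 2)
      bstar <- as.vector(b) + sqrt(sigma2) * as.vector(t(Ru) %*% rnorm(p))
      pred <- as.vector(X %*% bstar)
      kk <- min(k, length(obs))
      for (j in mis) {
        dist <- abs(pred[obs] - pred[j])
        donors <- obs[order(dist)[seq_len(kk)]]
        completed[j, d] <- V[donors[sample.int(kk, 1)], d]
      }
    }
    acc <- acc + completed
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  acc / m
}
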