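two_family_series <- function(n_per = 10, D = 12, gap = 30, seed = 1) {
  set.seed(seed)
  t <- seq_len(D)
  base <- 50 / (1 + exp(-0.5 * (t - 6)))
  fast <- (50 + gap) / (1 + exp(-0.5 * (t - 5)))
  X <- rbind(
    t(replicate(n_per, base + rnorm(D, 0, 1))),
    t(replicate(n_per, fast + rnorm(D, 0, 1)))
  )
  rownames(X) <- sprintf("G%03d", seq_len(2 * n_per))
  X
}

test_that("well-separated growth families are clustered exactly", {
  X <- two_family_series(seed = 5)
  cm <- kernel_kmeans(X, 2, seed = 3)
  truth <- rep(1:2, each = 10)
  agree <- max(mean(cm$assignment == truth), mean(cm$assignment == 3 - truth))
  expect_equal(agree, 1)
  expect_gt(cm$silhouette, 0.5)
})

test_that("duplicated genotypes always co-cluster", {
  X <- two_family_series(seed = 6)
  X[3, ] <- X[1, ]
  cm <- kernel_kmeans(X, 2, seed = 4)
  expect_equal(unname(cm$assignment[1]), unname(cm$assignment[3]))
})

test_that("the kernel k-means objective attains the exhaustive-partition
           minimum on a small instance", {
  set.seed(9)
  X <- matrix(rnorm(8 * 3), 8, 3)
  X[5:8, ] <- X[5:8, ] + 2
  rownames(X) <- letters[1:8]
  sigma <- 1.5
  cm <- kernel_kmeans(X, 2, bandwidth = sigma, seed = 2, n_starts = 10)
  # independent objective over all 2-partitions
  D2 <- as.matrix(dist(X))^2
  K <- exp(-D2 / (2 * sigma^2))
  obj_of <- function(assign) {
    s <- 0
    for (c in 1:2) {
      mem <- which(assign == c)
      if (!length(mem)) return(Inf)
      s <- s + sum(diag(K)[mem]) - sum(K[mem, mem]) / length(mem)
    }
    s
  }
  best <- Inf
  for (code in 1:(2^7 - 1)) {                 # fix element 1 in cluster 1
    assign <- c(1L, as.integer(intToBits(code))[1:7] + 1L)
    best <- min(best, obj_of(assign))
  }
  expect_equal(cm$objective, best, tolerance = 1e-10)
})

test_that("silhouette scores match the direct formula", {
  set.seed(11)
  X <- matrix(rnorm(10 * 2), 10, 2)
  assign <- rep(1:2, each = 5)
  D <- as.matrix(dist(X))
  s <- numeric(10)
  for (i in 1:10) {
    own <- setdiff(which(assign == assign[i]), i)
    a <- mean(D[i, own])
    b <- mean(D[i, assign != assign[i]])
    s[i] <- (b - a) / max(a, b)
  }
  expect_equal(phenopipe:::mean_silhouette(X, assign), mean(s),
               tolerance = 1e-12)
})

test_that("kernel k-means agrees with an independent implementation on
           separable data", {
  X <- two_family_series(seed = 7)
  sigma <- 20
  cm <- kernel_kmeans(X, 2, bandwidth = sigma, seed = 8)
  set.seed(9)
  kl <- kernlab::kkmeans(X, centers = 2,
                         kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * sigma^2)))
  a <- cm$assignment
  b <- kl@.Data
  agree <- max(mean(a == b), mean(a == 3 - b))
  expect_equal(agree, 1)
})

test_that("the silhouette method finds the planted number of families and
           flags structureless data", {
  set.seed(12)
  t <- 1:10
  centers <- list(10, 60, 130)
  X <- do.call(rbind, lapply(centers, function(m) {
    t(replicate(8, m + t + rnorm(10, 0, 0.8)))
  }))
  rownames(X) <- sprintf("G%02d", 1:24)
  k <- select_k(X, 2:5, seed = 13)
  expect_equal(as.integer(k), 3)
  blob <- matrix(rnorm(30 * 6), 30, 6)
  k2 <- select_k(blob, 2:4, seed = 14)
  expect_true(attr(k2, "low_confidence"))
})

test_that("cluster distances reduce to the expected arithmetic", {
  X <- two_family_series(seed = 15)
  cm <- kernel_kmeans(X, 2, seed = 16)
  cd <- clust_dist_series(cm, X)
  # k = 2: |c1 - c2| per day, computed directly
  for (day in c(1, 6, 12)) {
    c1 <- mean(X[cm$assignment == 1, day])
    c2 <- mean(X[cm$assignment == 2, day])
    expect_equal(unname(cd[day]), abs(c1 - c2), tolerance = 1e-12)
  }
  # identical clusters -> zero distance
  Xd <- rbind(X[1:10, ], X[1:10, ])
  rownames(Xd) <- sprintf("G%03d", 1:20)
  cm0 <- list(k = 2, assignment = stats::setNames(rep(1:2, each = 10),
                                                  rownames(Xd)))
  class(cm0) <- "cluster_model"
  expect_true(all(abs(clust_dist_series(cm0, Xd)) < 1e-12))
})

test_that("three-cluster distances equal the mean pairwise arithmetic", {
  X <- matrix(c(0, 0, 10, 10, 40, 40), 6, 2, byrow = FALSE)
  rownames(X) <- paste0("g", 1:6)
  cm <- list(k = 3, assignment = stats::setNames(rep(1:3, each = 2),
                                                 rownames(X)))
  class(cm) <- "cluster_model"
  cd <- clust_dist_series(cm, X)
  # centers 0/10/40 -> pairwise distances 10, 40, 30 -> mean 80/3
  expect_equal(unname(cd[1]), mean(c(10, 40, 30)), tolerance = 1e-12)
})

test_that("e-divisive finds a planted mean shift where brute force says it
           is", {
  set.seed(17)
  X <- cbind(c(rnorm(11), rnorm(11, 5)), c(rnorm(11), rnorm(11, 5)))
  res <- e_divisive(X, alpha = 0.05, min_size = 3, n_perm = 199, seed = 18)
  expect_gte(length(res$change_days), 1)
  # independent brute-force maximiser of the energy statistic (double loops)
  Z <- scale(X)
  estat <- function(A, B) {
    m <- nrow(A); n <- nrow(B)
    dxy <- 0
    for (i in 1:m) for (j in 1:n) dxy <- dxy + sqrt(sum((A[i, ] - B[j, ])^2))
    dxy <- dxy / (m * n)
    dxx <- 0
    if (m > 1) {
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        dxx <- dxx + sqrt(sum((A[i, ] - A[j, ])^2))
      }
      dxx <- dxx * 2 / (m * (m - 1))
    }
    dyy <- 0
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        dyy <- dyy + sqrt(sum((B[i, ] - B[j, ])^2))
      }
      dyy <- dyy * 2 / (n * (n - 1))
    }
    m * n / (m + n) * (2 * dxy - dxx - dyy)
  }
  qs <- vapply(3:19, function(tau) {
    estat(Z[1:tau, , drop = FALSE], Z[(tau + 1):22, , drop = FALSE])
  }, numeric(1))
  tau_star <- (3:19)[which.max(qs)]
  expect_lte(min(abs(res$change_days - tau_star)), 1)
  expect_lte(abs(tau_star - 11), 1)
})

test_that("iid series rarely produce change points and alpha is monotone", {
  set.seed(19)
  null_hits <- 0L
  for (s in 1:10) {
    X <- matrix(rnorm(44), 22, 2)
    res <- e_divisive(X, alpha = 0.05, min_size = 3, n_perm = 99,
                      seed = 100 + s)
    if (length(res$change_days) == 0) null_hits <- null_hits + 1L
  }
  expect_gte(null_hits, 9L)
  # tightening alpha cannot add change points (matched seeds)
  set.seed(20)
  X <- cbind(c(rnorm(8), rnorm(7, 3), rnorm(7, 6)),
             c(rnorm(8), rnorm(7, 2), rnorm(7, 5)))
  n05 <- length(e_divisive(X, alpha = 0.05, n_perm = 199,
                           seed = 5)$change_days)
  n01 <- length(e_divisive(X, alpha = 0.01, n_perm = 199,
                           seed = 5)$change_days)
  expect_lte(n01, n05)
})

test_that("change points are invariant to affine rescaling of either
           column", {
  set.seed(21)
  X <- cbind(c(rnorm(10), rnorm(12, 4)), c(rnorm(10, 0, 2), rnorm(12, 8, 2)))
  r1 <- e_divisive(X, n_perm = 99, seed = 22)
  X2 <- X
  X2[, 1] <- X2[, 1] * 1000 - 77
  X2[, 2] <- X2[, 2] / 500 + 3
  r2 <- e_divisive(X2, n_perm = 99, seed = 22)
  expect_identical(r1$change_days, r2$change_days)
})

test_that("a four-phase series yields several windows", {
  set.seed(23)
  h2 <- c(rnorm(6, 0.3, 0.02), rnorm(6, 0.7, 0.02), rnorm(5, 0.5, 0.02),
          rnorm(5, 0.25, 0.02))
  cd <- c(rnorm(6, 1, 0.1), rnorm(6, 6, 0.3), rnorm(5, 9, 0.3),
          rnorm(5, 9.5, 0.3))
  res <- e_divisive(cbind(h2, cd), alpha = 0.05, min_size = 3, n_perm = 199,
                    seed = 24)
  expect_gte(length(res$change_days), 2)
})

test_that("the optimal-window rule follows its stated hierarchy", {
  fake_result <- function(bounds, n) {
    structure(list(change_days = bounds, n = n,
                   windows = data.frame(
                     start = c(1L, bounds + 1L),
                     end = c(bounds, n))),
              class = "changepoint_result")
  }
  # windows with median h2 (.3,.7,.5,.2), rising diversity in all but last
  res <- fake_result(c(5L, 10L, 15L), 20L)
  h2 <- c(rep(0.3, 5), rep(0.7, 5), rep(0.5, 5), rep(0.2, 5))
  cd <- c(1:5, 6:10, 11:15, rep(16, 5) - 0:4)
  otw <- select_otw(res, h2, cd)
  expect_equal(as.integer(otw), 2L)
  # all equal -> earliest interior window
  h2e <- rep(0.5, 20); cde <- rep(1, 20)
  expect_equal(as.integer(select_otw(res, h2e, cde)), 2L)
  # two windows -> higher median h2
  res2 <- fake_result(10L, 20L)
  expect_equal(as.integer(select_otw(res2, h2, cd)), 1L)
  # single window -> warning
  res1 <- fake_result(integer(0), 20L)
  expect_warning(o1 <- select_otw(res1, h2, cd), "single window")
  expect_equal(as.integer(o1), 1L)
})

test_that("the cluster-by-window ANOVA reproduces textbook sums of squares
           on a balanced design", {
  # 3 clusters x 3 windows, 4 genotypes per cluster, additive construction
  set.seed(25)
  cl_eff <- c(-10, 0, 10)
  tw_eff <- c(5, 20, 35)
  n_per <- 4
  B <- matrix(NA_real_, 12, 9)
  rownames(B) <- sprintf("G%02d", 1:12)
  for (i in 1:12) {
    cl <- (i - 1) %/% n_per + 1
    for (w in 1:3) {
      B[i, (3 * (w - 1) + 1):(3 * w)] <- 50 + cl_eff[cl] + tw_eff[w] +
        rnorm(3, 0, 0.01)
    }
  }
  series <- structure(list(genotypes = rownames(B), days = as.character(1:9),
                           blues = B, h2 = rep(0.7, 9),
                           strategy = strategy("S8")),
                      class = "gblue_series")
  windows <- data.frame(start = c(1L, 4L, 7L), end = c(3L, 6L, 9L))
  an <- gc_tw_anova(series, windows, otw = 2, n_groups = 3, seed = 26)
  tab <- an$table
  # textbook two-way SS from the cell means (balanced, so Type I = textbook)
  y <- as.vector(an$response)
  cl <- rep(rep(1:3, each = n_per), times = 3)
  tw <- rep(1:3, each = 12)
  gm <- mean(y)
  ss_cl <- sum(tapply(y, cl, function(v) length(v) * (mean(v) - gm)^2))
  ss_tw <- sum(tapply(y, tw, function(v) length(v) * (mean(v) - gm)^2))
  cell <- tapply(y, list(cl, tw), mean)
  ss_int <- sum(vapply(1:3, function(a) {
    sum(vapply(1:3, function(b) {
      n_per * (cell[a, b] - mean(cell[a, ]) - mean(cell[, b]) + gm)^2
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(tab$SS[tab$source == "Gc"], ss_cl, tolerance = 1e-6)
  expect_equal(tab$SS[tab$source == "TW"], ss_tw, tolerance = 1e-6)
  expect_equal(tab$SS[tab$source == "Gc:TW"], ss_int, tolerance = 1e-6)
  # interaction of the additive construction is numerically nil
  expect_lt(tab$SS_pct[tab$source == "Gc:TW"], 0.1)
  # components add up to the total
  expect_equal(sum(tab$SS), sum((y - gm)^2), tolerance = 1e-8)
})

test_that("kernel clustering of separable data is invariant to genotype
           order", {
  X <- two_family_series(seed = 27)
  set.seed(28)
  perm <- sample(nrow(X))
  cm1 <- kernel_kmeans(X, 2, seed = 29)
  cm2 <- kernel_kmeans(X[perm, ], 2, seed = 30)
  a1 <- cm1$assignment[rownames(X)]
  a2 <- cm2$assignment[rownames(X)]
  agree <- max(mean(a1 == a2), mean(a1 == 3 - a2))
  expect_equal(agree, 1)
  expect_equal(cm1$objective, cm2$objective, tolerance = 1e-10)
  expect_equal(cm1$silhouette, cm2$silhouette, tolerance = 1e-10)
})
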