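#' Gaussian kernel k-means clustering of genotype growth series
#'
#' Clusters whole-series genotype vectors (one row per genotype, one column
#' per day) with kernel k-means under the Gaussian kernel
#' \eqn{K(a,b) = \exp(-\|a-b\|^2 / (2 \sigma^2))}. Assignments are updated by
#' minimising the implicit-feature-space distance to cluster means; the
#' within-cluster kernel dispersion objective is non-increasing over
#' iterations. Missing genotype-day cells are filled with the day mean and
#' flagged. Empty clusters are reseeded (at most 10 restarts).
#'
#' @param series_matrix numeric matrix, genotypes x days.
#' @param kk number of clusters (>= 2, < number of genotypes).
#' @param bandwidth kernel bandwidth `sigma` in trait-distance units, or
#'   `"auto"` for the median pairwise distance heuristic.
#' @param seed integer seed for the initial assignments.
#' @param max_iter assignment-update cap.
#' @param n_starts number of random initializations; the run with the lowest
#'   within-cluster kernel dispersion is kept.
#' @return a `cluster_model`: list with `k`, `assignment` (named integer
#'   vector), `bandwidth`, `objective`, `silhouette` (mean, Euclidean),
#'   `centers_per_day` (k x days), `filled_cells`.
#' @export
kernel_kmeans <- function(series_matrix, kk, bandwidth = "auto", seed = 1,
                          max_iter = 100, n_starts = 5) {
  X <- as.matrix(series_matrix)
  n <- nrow(X)
  if (kk < 2 || kk >= n) stop_pp("`kk` must be in [2, n_genotypes - 1]")
  filled <- which(is.na(X), arr.ind = TRUE)
  if (nrow(filled)) {
    dm <- colMeans(X, na.rm = TRUE)
    X[filled] <- dm[filled[, 2]]
  }
  D2 <- as.matrix(stats::dist(X))^2
  sigma <- if (identical(bandwidth, "auto")) {
    md <- stats::median(sqrt(D2[upper.tri(D2)]))
    if (md <= 0) 1 else md
  } else as.numeric(bandwidth)
  K <- exp(-D2 / (2 * sigma^2))

  best <- NULL
  with_seed(seed, {
    for (start in seq_len(n_starts)) {
      assign <- sample(rep_len(seq_len(kk), n))
      reseeds <- 0L
      for (it in seq_len(max_iter)) {
        ## an emptied cluster is reseeded with a random point (up to 10 times)
        for (c in seq_len(kk)) {
          if (!any(assign == c)) {
            if (reseeds >= 10L) break
            assign[sample.int(n, 1L)] <- c
            reseeds <- reseeds + 1L
          }
        }
        if (any(tabulate(assign, kk) == 0L)) break
        ## d2(i, c) = K_ii - 2 mean_{j in c} K_ij + mean_{j,l in c} K_jl
        dmat <- matrix(Inf, n, kk)
        for (c in seq_len(kk)) {
          mem <- which(assign == c)
          kc <- rowMeans(K[, mem, drop = FALSE])
          cc <- mean(K[mem, mem])
          dmat[, c] <- diag(K) - 2 * kc + cc
        }
        new_assign <- max.col(-dmat, ties.method = "first")
        changed <- !identical(new_assign, assign)
        assign <- new_assign
        if (!changed && all(tabulate(assign, kk) > 0L)) break
      }
      if (all(tabulate(assign, kk) > 0L)) {
        obj <- kernel_objective(K, assign, kk)
        if (is.null(best) || obj < best$objective) {
          best <- list(assignment = assign, objective = obj)
        }
      }
    }
  })
  if (is.null(best)) stop_pp("kernel k-means failed: persistent empty clusters")
  assign <- best$assignment
  names(assign) <- rownames(X)
  centers <- t(vapply(seq_len(kk), function(c) {
    colMeans(X[assign == c, , drop = FALSE])
  }, numeric(ncol(X))))
  structure(list(k = kk, assignment = assign, bandwidth = sigma,
                 objective = best$objective,
                 silhouette = mean_silhouette(X, assign),
                 centers_per_day = centers,
                 filled_cells = nrow(filled)),
            class = "cluster_model")
}

## within-cluster kernel dispersion: sum_c sum_{i in c} d2(i, center_c)
kernel_objective <- function(K, assign, kk) {
  obj <- 0
  for (c in seq_len(kk)) {
    mem <- which(assign == c)
    if (!length(mem)) next
    Kc <- K[mem, mem, drop = FALSE]
    obj <- obj + sum(diag(Kc)) - sum(Kc) / length(mem)
  }
  obj
}

## mean silhouette score (b - a) / max(a, b) on Euclidean distances
mean_silhouette <- function(X, assign) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  ks <- sort(unique(assign))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assign == assign[i])
    a <- if (length(own) > 1) mean(D[i, setdiff(own, i)]) else 0
    b <- min(vapply(setdiff(ks, assign[i]), function(c) {
      mean(D[i, assign == c])
    }, numeric(1)))
    s[i] <- if (length(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Choose the number of genotype clusters by the silhouette method
#'
#' Runs [kernel_kmeans()] for each candidate `k` and returns the one with the
#' highest mean silhouette score (Euclidean distances on the whole-series
#' vectors); ties resolve to the smallest `k`. A maximum below 0.25 is flagged
#' as low confidence (no real cluster structure).
#'
#' @param series_matrix genotypes x days matrix.
#' @param k_range candidate cluster counts (subset of `2:(n-1)`).
#' @param bandwidth,seed passed to [kernel_kmeans()].
#' @return integer `k`, with attributes `silhouette` (per candidate) and
#'   `low_confidence`.
#' @export
select_k <- function(series_matrix, k_range = 2:6, bandwidth = "auto",
                     seed = 1) {
  n <- nrow(series_matrix)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop_pp("empty `k_range`")
  sil <- vapply(seq_along(k_range), function(i) {
    kernel_kmeans(series_matrix, k_range[i], bandwidth,
                  seed = derive_seed(seed, i))$silhouette
  }, numeric(1))
  names(sil) <- k_range
  kbest <- k_range[which.max(sil)]   # which.max takes the first (smallest k)
  structure(kbest, silhouette = sil, low_confidence = max(sil) < 0.25)
}

#' Daily between-cluster distance series (Clust-Dist)
#'
#' For each day, cluster centers are the mean adjusted means of each cluster's
#' members that day; the genetic-diversity proxy is the mean pairwise
#' Euclidean distance among centers (for k = 2 this is `|c1 - c2|`). Days with
#' no data give a missing entry.
#'
#' @param model a `cluster_model`.
#' @param series a `gblue_series` (or genotypes x days matrix) the model was
#'   fitted on.
#' @return named numeric vector, one distance per day.
#' @export
clust_dist_series <- function(model, series) {
  B <- if (inherits(series, "gblue_series")) series$blues else as.matrix(series)
  if (!all(names(model$assignment) %in% rownames(B))) {
    stop_pp("cluster model genotypes not found in series")
  }
  B <- B[names(model$assignment), , drop = FALSE]
  vapply(seq_len(ncol(B)), function(d) {
    cen <- vapply(seq_len(model$k), function(c) {
      mean(B[model$assignment == c, d], na.rm = TRUE)
    }, numeric(1))
    if (all(is.nan(cen))) return(NA_real_)
    pw <- abs(outer(cen, cen, `-`))
    mean(pw[upper.tri(pw)])
  }, numeric(1)) |> stats::setNames(colnames(B))
}

## energy divergence between two multivariate samples (alpha = 1)
energy_stat <- function(X, Y) {
  m <- nrow(X); n <- nrow(Y)
  dxy <- mean_cross_dist(X, Y)
  dxx <- mean_within_dist(X)
  dyy <- mean_within_dist(Y)
  (m * n / (m + n)) * (2 * dxy - dxx - dyy)
}

mean_cross_dist <- function(X, Y) {
  s <- 0
  for (i in seq_len(nrow(X))) {
    s <- s + sum(sqrt(rowSums(sweep(Y, 2, X[i, ])^2)))
  }
  s / (nrow(X) * nrow(Y))
}

mean_within_dist <- function(X) {
  if (nrow(X) < 2) return(0)
  mean(stats::dist(X))
}

best_split_stat <- function(X, min_size) {
  n <- nrow(X)
  best_q <- -Inf; best_tau <- NA_integer_
  if (n < 2 * min_size) return(list(q = best_q, tau = best_tau))
  for (tau in min_size:(n - min_size)) {
    q <- energy_stat(X[seq_len(tau), , drop = FALSE],
                     X[(tau + 1):n, , drop = FALSE])
    if (q > best_q) { best_q <- q; best_tau <- tau }
  }
  list(q = best_q, tau = best_tau)
}

#' Divisive multivariate change-point detection (energy statistic)
#'
#' Hierarchical e-divisive estimation of change points in a short multivariate
#' series (here: daily heritability and Clust-Dist). Columns are standardised
#' internally (z-scores), so the output is invariant to affine rescaling of
#' either input variable. At each step the split maximising the between-
#' segment energy divergence over all current segments is tested by a
#' within-segment permutation test; splitting stops when the best candidate is
#' no longer significant at `alpha`.
#'
#' @param series2d numeric matrix, days x variables (typically 2).
#' @param alpha significance level of the permutation test.
#' @param min_size minimum segment length (default 3; the series here are
#'   only ~22 days long).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return a `changepoint_result`: `change_days` (indices of last day of each
#'   left segment), `windows` data frame (`start`, `end` inclusive),
#'   `p_values`, `alpha`, `n_perm`.
#' @export
e_divisive <- function(series2d, alpha = 0.05, min_size = 3, n_perm = 199,
                       seed = 1) {
  X <- as.matrix(series2d)
  n <- nrow(X)
  if (n < 2 * min_size) stop_pp("series too short for min_size = ", min_size)
  keep <- !apply(X, 1, anyNA)
  if (!all(keep)) stop_pp("missing rows in the change-point input")
  X <- scale(X)
  X[, apply(is.nan(X), 2, any)] <- 0   # constant column -> no information
  segments <- list(c(1L, n))
  change <- integer(0)
  pvals <- numeric(0)
  with_seed(seed, {
    repeat {
      cand <- lapply(segments, function(sg) {
        idx <- sg[1]:sg[2]
        bs <- best_split_stat(X[idx, , drop = FALSE], min_size)
        list(seg = sg, q = bs$q, tau = bs$tau)
      })
      qs <- vapply(cand, `[[`, numeric(1), "q")
      if (all(!is.finite(qs))) break
      bi <- which.max(qs)
      bc <- cand[[bi]]
      idx <- bc$seg[1]:bc$seg[2]
      Xi <- X[idx, , drop = FALSE]
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        Xp <- Xi[sample.int(nrow(Xi)), , drop = FALSE]
        if (best_split_stat(Xp, min_size)$q >= bc$q) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (n_perm + 1)
      if (p > alpha) break
      cp <- bc$seg[1] + bc$tau - 1L
      change <- sort(c(change, cp))
      pvals <- c(pvals, p)
      segments <- unname(split_segments(n, change))
    }
  })
  bounds <- c(0L, change, n)
  windows <- data.frame(start = bounds[-length(bounds)] + 1L,
                        end = bounds[-1])
  structure(list(change_days = change, windows = windows, p_values = pvals,
                 alpha = alpha, n_perm = n_perm, n = n),
            class = "changepoint_result")
}

split_segments <- function(n, change) {
  bounds <- c(0L, change, n)
  lapply(seq_len(length(bounds) - 1), function(i) {
    c(bounds[i] + 1L, bounds[i + 1])
  })
}

#' Select the optimal time window
#'
#' Codifies the selection narrative used with the change-point windows: among
#' interior windows (excluding the first lag phase and the last, often
#' canopy-closure, window) whose mean Clust-Dist slope is non-negative
#' (growing expressed diversity), pick the one with the highest median
#' heritability; when no window qualifies, fall back to the global median-h2
#' maximiser. With only two windows the higher-median-h2 window wins; ties go
#' to the earliest qualifying window.
#'
#' @param result a `changepoint_result`.
#' @param h2 daily heritability series (length `result$n`).
#' @param clust_dist daily Clust-Dist series (same length).
#' @return the selected window index, with attribute `summary` (per-window
#'   median h2 and Clust-Dist slope, selection rule used).
#' @export
select_otw <- function(result, h2, clust_dist) {
  w <- result$windows
  nw <- nrow(w)
  med_h2 <- vapply(seq_len(nw), function(i) {
    stats::median(h2[w$start[i]:w$end[i]], na.rm = TRUE)
  }, numeric(1))
  slope <- vapply(seq_len(nw), function(i) {
    idx <- w$start[i]:w$end[i]
    if (length(idx) < 2) return(0)
    unname(stats::coef(stats::lm(clust_dist[idx] ~ idx))[2])
  }, numeric(1))
  if (nw == 1) {
    warning("single window; returned as OTW", call. = FALSE)
    rule <- "single-window"
    otw <- 1L
  } else if (nw == 2) {
    rule <- "two-window fallback: higher median h2"
    otw <- which.max(med_h2)
  } else {
    interior <- 2:(nw - 1)
    ok <- interior[slope[interior] >= 0]
    if (length(ok)) {
      rule <- "interior window with non-negative Clust-Dist slope, max median h2"
      otw <- ok[which.max(med_h2[ok])]
    } else {
      rule <- "fallback: global max median h2"
      otw <- which.max(med_h2)
    }
  }
  summary <- data.frame(window = seq_len(nw), start = w$start, end = w$end,
                        median_h2 = med_h2, clust_dist_slope = slope,
                        is_otw = seq_len(nw) == otw)
  attr(summary, "rule") <- rule
  structure(as.integer(otw), summary = summary, rule = rule)
}

#' Genotype-cluster by time-window analysis of variance
#'
#' Groups genotypes into `n_groups` vigor classes ("low", "medium", "high") by
#' k-means on their mean adjusted means within the optimal time window, then
#' partitions the genotype-by-window mean adjusted means with a sequential
#' (Type I) two-way ANOVA fitted in the order cluster, window, interaction:
#' `y = mu + Gc + TW + Gc:TW + e`. A small interaction relative to the main
#' effects indicates clusters that are stable across growth phases.
#'
#' @param series a `gblue_series`.
#' @param windows data frame with `start`, `end` (day indices), e.g. from
#'   [e_divisive()].
#' @param otw index of the optimal window (genotype grouping is computed
#'   there).
#' @param n_groups number of vigor classes.
#' @param seed integer seed for the k-means start.
#' @return an `anova_gctw`: list with `table` (source, Df, SS, SS_pct, MS, F,
#'   p), `clusters` (genotype, cluster id, ordered label), `response` (the
#'   genotype x window means).
#' @export
gc_tw_anova <- function(series, windows, otw, n_groups = 3, seed = 1) {
  B <- series$blues
  nw <- nrow(windows)
  if (nw < 2) stop_pp("need at least 2 windows")
  win_means <- vapply(seq_len(nw), function(i) {
    rowMeans(B[, windows$start[i]:windows$end[i], drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(B)))
  colnames(win_means) <- paste0("TW", seq_len(nw))
  otw_mean <- win_means[, otw]
  keep <- is.finite(otw_mean) & apply(is.finite(win_means), 1, all)
  win_means <- win_means[keep, , drop = FALSE]
  otw_mean <- otw_mean[keep]
  km <- with_seed(seed, stats::kmeans(otw_mean, centers = n_groups,
                                      nstart = 10))
  ord <- order(km$centers)
  lab <- c("low", "medium", "high", paste0("g", 4:10))[seq_len(n_groups)]
  cluster_id <- match(km$cluster, ord)
  clusters <- data.frame(genotype = rownames(win_means),
                         cluster = cluster_id,
                         label = lab[cluster_id], stringsAsFactors = FALSE)
  long <- data.frame(
    y = as.vector(win_means),
    Gc = factor(rep(lab[cluster_id], times = nw), levels = lab),
    TW = factor(rep(colnames(win_means), each = nrow(win_means)))
  )
  fit <- stats::aov(y ~ Gc * TW, data = long)
  at <- stats::anova(fit)
  tab <- data.frame(source = rownames(at), Df = at$Df, SS = at$`Sum Sq`,
                    MS = at$`Mean Sq`, F = at$`F value`, p = at$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  tab$SS_pct <- 100 * tab$SS / sum(tab$SS)
  tab <- tab[, c("source", "Df", "SS", "SS_pct", "MS", "F", "p")]
  structure(list(table = tab, clusters = clusters, response = win_means,
                 total_SS = sum(tab$SS), otw = otw),
            class = "anova_gctw")
}

#' @export
print.anova_gctw <- function(x, ...) {
  cat("Genotype-cluster x time-window ANOVA (OTW = window", x$otw, ")\n")
  print(transform(x$table, SS = signif(SS, 4), SS_pct = round(SS_pct, 2),
                  MS = signif(MS, 4), F = signif(F, 4), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}
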