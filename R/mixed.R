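## Mixed-model engine: y = X beta + sum_b Z_b u_b + e, u_b ~ N(0, s2_b I),
## fitted by REML through Schall iterations with effective-dimension updates.
## Spline bases are pre-scaled (penalty absorbed) so every random block has an
## identity precision scaled by lambda_b = s2_e / s2_b.

## Cubic B-spline basis on an equally spaced knot grid covering [xl, xr].
bspline_def <- function(xl, xr, nseg, degree = 3) {
  dx <- (xr - xl) / nseg
  knots <- seq(xl - degree * dx, xr + degree * dx, by = dx)
  list(knots = knots, degree = degree, ncol = nseg + degree)
}

bspline_eval <- function(def, x) {
  splines::splineDesign(def$knots, x, ord = def$degree + 1, outer.ok = TRUE)
}

## One marginal smooth: eigen-decompose the difference penalty, keep the
## penalised subspace and rescale so the random coefficients are iid. The
## penalty null space (intercept + linear trend for pord = 2) is carried by
## the fixed part of the PS-ANOVA decomposition.
smooth_dim <- function(xl, xr, nseg, degree = 3, pord = 2) {
  def <- bspline_def(xl, xr, nseg, degree)
  D <- diff(diag(def$ncol), differences = pord)
  eg <- eigen(crossprod(D), symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  Tmat <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), sum(keep))
  list(def = def, transform = Tmat, q = sum(keep))
}

#' @title PS-ANOVA basis for a plot grid
#' @description Builds the two-dimensional penalised-spline decomposition of a
#'   smooth spatial surface over the row/column grid of a trial: fixed linear
#'   trends in rows and columns plus their interaction, and five random
#'   blocks (smooth row, smooth column, linear-by-smooth in both directions,
#'   and the smooth-by-smooth interaction), each with its own variance.
#' @param grid_rows,grid_cols grid extent (maximum row and column index).
#' @param nseg integer vector of length 2: B-spline segments along rows and
#'   columns. Default `max(5, min(ceiling(n/2), 12))` per dimension.
#' @param degree B-spline degree (cubic by default).
#' @param pord difference penalty order.
#' @return an object with an `eval(row, col)` closure returning the fixed
#'   columns and the list of random-block rows for arbitrary coordinates.
#' @keywords internal
psanova_basis <- function(grid_rows, grid_cols, nseg = NULL, degree = 3,
                          pord = 2) {
  default_nseg <- function(n) max(5L, min(ceiling(n / 2), 12L))
  if (is.null(nseg)) nseg <- c(default_nseg(grid_rows), default_nseg(grid_cols))
  if (any(nseg + degree < 3)) stop_pp("spline basis too small")
  sr <- smooth_dim(1, grid_rows, nseg[1], degree, pord)
  sc <- smooth_dim(1, grid_cols, nseg[2], degree, pord)
  r0 <- (1 + grid_rows) / 2
  c0 <- (1 + grid_cols) / 2
  evalf <- function(row, col) {
    xr <- (row - r0) / grid_rows
    xc <- (col - c0) / grid_cols
    Zr <- bspline_eval(sr$def, row) %*% sr$transform
    Zc <- bspline_eval(sc$def, col) %*% sc$transform
    q1 <- ncol(Zr); q2 <- ncol(Zc)
    Zten <- Zr[, rep(seq_len(q1), each = q2), drop = FALSE] *
      Zc[, rep(seq_len(q2), times = q1), drop = FALSE]
    list(
      fixed = cbind(lin_row = xr, lin_col = xc, lin_rowcol = xr * xc),
      blocks = list(
        smooth_row = Zr,
        smooth_col = Zc,
        lincol_by_smoothrow = Zr * xc,
        linrow_by_smoothcol = Zc * xr,
        smooth_by_smooth = Zten
      )
    )
  }
  structure(list(eval = evalf, nseg = nseg, degree = degree, pord = pord,
                 grid_rows = grid_rows, grid_cols = grid_cols),
            class = "psanova_basis")
}

## Core REML solver. X fixed (assumed full rank), Zlist named random blocks.
fit_mm <- function(y, X, Zlist, tol = 1e-6, max_iter = 200, init = NULL) {
  n <- length(y)
  px <- ncol(X)
  qb <- vapply(Zlist, ncol, integer(1))
  M <- do.call(cbind, c(list(X), unname(Zlist)))
  p <- ncol(M)
  idx <- vector("list", length(Zlist))
  off <- px
  for (b in seq_along(Zlist)) {
    idx[[b]] <- off + seq_len(qb[b])
    off <- off + qb[b]
  }
  names(idx) <- names(Zlist)

  G <- crossprod(M)
  My <- drop(crossprod(M, y))
  yy <- sum(y * y)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  ## start from a mostly-residual decomposition: an over-flexible start can
  ## push the total effective dimension to n, collapse the residual degrees
  ## of freedom and spiral into an interpolating (singular) system
  s2e <- init$sigma2_e %||% vy
  s2b <- rep(vy / (2 * max(length(Zlist), 1)), length(Zlist))
  names(s2b) <- names(Zlist)
  if (!is.null(init$sigma2)) {
    ## components at (or near) the floor in the donor fit restart from the
    ## default: a floored variance has an essentially infinite penalty and
    ## could never re-emerge, which would tie the fit to the donor's path
    common <- intersect(names(init$sigma2), names(s2b))
    usable <- init$sigma2[common] > 1e-6 * vy
    s2b[common[usable]] <- init$sigma2[common][usable]
  }
  floor_v <- 1e-10
  floored <- character(0)
  converged <- FALSE
  ED <- rep(NA_real_, length(Zlist)); names(ED) <- names(Zlist)
  coef <- NULL; Ci <- NULL; rss <- NA_real_
  it <- 0L
  dev_old <- Inf
  while (it < max_iter) {
    it <- it + 1L
    lam <- s2e / pmax(s2b, floor_v)
    C <- G
    for (b in seq_along(Zlist)) {
      C[cbind(idx[[b]], idx[[b]])] <- C[cbind(idx[[b]], idx[[b]])] + lam[b]
    }
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) {
      ## identify aliasing in the fixed part for a useful message
      qr_x <- qr(X)
      if (qr_x$rank < px) {
        bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):px]]
        stop_pp("singular design: aliased fixed term(s): ",
                paste(bad, collapse = ", "))
      }
      stop_pp("mixed-model coefficient system is singular")
    }
    coef <- backsolve(R, backsolve(R, My, transpose = TRUE))
    Ci <- chol2inv(R)
    fitted <- drop(M %*% coef)
    rss <- sum((y - fitted)^2)
    s2b_new <- s2b
    for (b in seq_along(Zlist)) {
      trb <- sum(Ci[cbind(idx[[b]], idx[[b]])])
      ED[b] <- qb[b] - lam[b] * trb
      ssb <- sum(coef[idx[[b]]]^2)
      if (ED[b] > 1e-8 && ssb > 0) {
        s2b_new[b] <- ssb / ED[b]
      } else {
        s2b_new[b] <- floor_v
        floored <- union(floored, names(Zlist)[b])
      }
      ## negligible components decay geometrically; snap them to the floor so
      ## the iteration is not spent tracking variances that are effectively 0
      if (s2b_new[b] < 1e-8 * vy) {
        s2b_new[b] <- floor_v
        floored <- union(floored, names(Zlist)[b])
      }
    }
    ed_tot <- px + sum(pmax(ED, 0))
    s2e_new <- max(rss / max(n - ed_tot, 1), 1e-10 * vy)
    rel <- max(abs(c(s2b_new, s2e_new) - c(s2b, s2e)) /
                 (c(s2b, s2e) + 1e-12))
    ## REML deviance (up to a constant); boundary components that decay
    ## geometrically stall the variance-component criterion while leaving the
    ## restricted likelihood (and the fit) unchanged, so either criterion
    ## declares convergence
    dev <- (n - px) * log(s2e_new) - sum(qb * log(lam)) +
      2 * sum(log(diag(R))) + (yy - sum(coef * My)) / s2e_new
    dev_ok <- is.finite(dev_old) &&
      abs(dev - dev_old) < 1e-7 * max(1, abs(dev))
    dev_old <- dev
    s2b <- s2b_new; s2e <- s2e_new
    if (rel < tol || dev_ok) { converged <- TRUE; break }
  }
  ## final solve at the converged components so that coefficients, precision
  ## and effective dimensions are mutually consistent with the reported
  ## variance components
  lam <- s2e / pmax(s2b, floor_v)
  C <- G
  for (b in seq_along(Zlist)) {
    C[cbind(idx[[b]], idx[[b]])] <- C[cbind(idx[[b]], idx[[b]])] + lam[b]
  }
  R <- chol(C)
  coef <- backsolve(R, backsolve(R, My, transpose = TRUE))
  Ci <- chol2inv(R)
  rss <- sum((y - drop(M %*% coef))^2)
  for (b in seq_along(Zlist)) {
    ED[b] <- qb[b] - lam[b] * sum(Ci[cbind(idx[[b]], idx[[b]])])
  }
  list(coef = coef, fixed_idx = seq_len(px), block_idx = idx,
       sigma2 = s2b, sigma2_e = s2e, ED = ED, rss = rss,
       n_obs = n, px = px, converged = converged, n_iter = it,
       floored = floored, Ci = Ci)
}
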