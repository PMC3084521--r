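#' Weighted non-negative linear amplitude solve
#'
#' Solves the per-pixel linear subproblem of gated-decay fitting: given the
#' basis matrix of per-gate component responses (plus the background-offset
#' column), find the non-negative amplitudes minimising the weighted residual
#' sum of squares.  Because the amplitudes of one pixel depend only on that
#' pixel's counts, the global linear problem partitions into these small
#' independent solves — the property exploited by variable projection.
#'
#' @param bases numeric matrix, gates x columns (decay components and,
#'   conventionally last, the offset column of ones); must have full column
#'   rank.
#' @param counts observed per-gate counts (length `nrow(bases)`).
#' @param weights per-gate weights (1/variance), same length.
#' @return A list with `coef` (non-negative amplitudes), `fitted`,
#'   `residuals` (weighted, i.e. \eqn{\sqrt{w}(y - \hat y)}) and `chi2`.
#' @examples
#' B <- cbind(c(1, 0), c(0, 1))
#' solve_linear_amplitudes(B, c(3, 4), c(1, 1))$coef
#' @export
solve_linear_amplitudes <- function(bases, counts, weights) {
  bases <- as.matrix(bases)
  stopifnot(nrow(bases) == length(counts), length(weights) == length(counts),
            all(weights > 0))
  if (qr(bases)$rank < ncol(bases))
    stop("degenerate basis: columns are linearly dependent ",
         "(duplicate lifetimes?)")
  sw <- sqrt(weights)
  A <- bases * sw
  b <- counts * sw
  x <- qr.coef(qr(A), b)
  if (any(x < 0)) x <- pracma::lsqnonneg(A, b)$x
  fitted <- drop(bases %*% x)
  r <- (counts - fitted) * sw
  list(coef = as.numeric(x), fitted = fitted, residuals = r,
       chi2 = sum(r^2))
}

## ---- batched per-pixel weighted least squares ------------------------------
##
## B: gates x k shared basis; Y, W: gates x P.  Closed-form normal-equation
## solves for k <= 3, generic loop otherwise; pixels with negative
## coefficients are re-solved with an active-set NNLS.

batched_wls <- function(B, Y, W, nonneg = TRUE) {
  B <- as.matrix(B); Y <- as.matrix(Y); W <- as.matrix(W)
  k <- ncol(B); P <- ncol(Y)
  if (qr(B)$rank < k)
    stop("degenerate basis: columns are linearly dependent ",
         "(duplicate lifetimes?)")
  X <- matrix(0, k, P)
  if (k == 1L) {
    X[1L, ] <- colSums(B[, 1L] * W * Y) / colSums(B[, 1L]^2 * W)
  } else if (k == 2L) {
    m11 <- colSums(B[, 1L]^2 * W); m12 <- colSums(B[, 1L] * B[, 2L] * W)
    m22 <- colSums(B[, 2L]^2 * W)
    r1 <- colSums(B[, 1L] * W * Y); r2 <- colSums(B[, 2L] * W * Y)
    det <- m11 * m22 - m12^2
    X[1L, ] <- (m22 * r1 - m12 * r2) / det
    X[2L, ] <- (m11 * r2 - m12 * r1) / det
  } else if (k == 3L) {
    m11 <- colSums(B[, 1L]^2 * W); m22 <- colSums(B[, 2L]^2 * W)
    m33 <- colSums(B[, 3L]^2 * W)
    m12 <- colSums(B[, 1L] * B[, 2L] * W)
    m13 <- colSums(B[, 1L] * B[, 3L] * W)
    m23 <- colSums(B[, 2L] * B[, 3L] * W)
    r1 <- colSums(B[, 1L] * W * Y); r2 <- colSums(B[, 2L] * W * Y)
    r3 <- colSums(B[, 3L] * W * Y)
    c11 <- m22 * m33 - m23^2;  c12 <- m13 * m23 - m12 * m33
    c13 <- m12 * m23 - m13 * m22
    c22 <- m11 * m33 - m13^2;  c23 <- m12 * m13 - m11 * m23
    c33 <- m11 * m22 - m12^2
    det <- m11 * c11 + m12 * c12 + m13 * c13
    X[1L, ] <- (c11 * r1 + c12 * r2 + c13 * r3) / det
    X[2L, ] <- (c12 * r1 + c22 * r2 + c23 * r3) / det
    X[3L, ] <- (c13 * r1 + c23 * r2 + c33 * r3) / det
  } else {
    for (p in seq_len(P)) {
      sw <- sqrt(W[, p])
      X[, p] <- qr.coef(qr(B * sw), Y[, p] * sw)
    }
  }
  if (nonneg) {
    bad <- which(colSums(X < -1e-12) > 0)
    if (length(bad)) {
      if (k <= 3L) {
        X[, bad] <- nnls_small_batch(B, Y[, bad, drop = FALSE],
                                     W[, bad, drop = FALSE])
      } else {
        for (p in bad) {
          sw <- sqrt(W[, p])
          X[, p] <- pracma::lsqnonneg(B * sw, Y[, p] * sw)$x
        }
      }
    }
    X[X < 0] <- 0
  }
  R <- Y - B %*% X
  list(coef = X, chi2 = colSums(W * R^2), residuals = sqrt(W) * R)
}

## exact batched NNLS for k <= 3 columns by enumeration of active sets:
## the optimum is the primal-feasible candidate of smallest chi2 among all
## support subsets, each of which has a closed-form weighted solve.
nnls_small_batch <- function(B, Y, W) {
  k <- ncol(B); P <- ncol(Y)
  M <- array(0, c(k, k, P))
  r <- matrix(0, k, P)
  for (i in seq_len(k)) {
    r[i, ] <- colSums(B[, i] * W * Y)
    for (j in i:k)
      M[i, j, ] <- M[j, i, ] <- colSums(B[, i] * B[, j] * W)
  }
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  bestX <- matrix(0, k, P)
  bestval <- rep(0, P)  # chi2 - yWy of the all-zero solution is 0
  for (S in subsets) {
    m <- length(S)
    x <- matrix(0, k, P)
    if (m == 1L) {
      x[S, ] <- r[S, ] / M[S, S, ]
    } else if (m == 2L) {
      i <- S[1L]; j <- S[2L]
      det <- M[i, i, ] * M[j, j, ] - M[i, j, ]^2
      x[i, ] <- (M[j, j, ] * r[i, ] - M[i, j, ] * r[j, ]) / det
      x[j, ] <- (M[i, i, ] * r[j, ] - M[i, j, ] * r[i, ]) / det
    } else {
      a <- M[1, 1, ]; b <- M[1, 2, ]; cc <- M[1, 3, ]
      d <- M[2, 2, ]; e <- M[2, 3, ]; f <- M[3, 3, ]
      c11 <- d * f - e^2; c12 <- cc * e - b * f; c13 <- b * e - cc * d
      c22 <- a * f - cc^2; c23 <- b * cc - a * e; c33 <- a * d - b^2
      det <- a * c11 + b * c12 + cc * c13
      x[1, ] <- (c11 * r[1, ] + c12 * r[2, ] + c13 * r[3, ]) / det
      x[2, ] <- (c12 * r[1, ] + c22 * r[2, ] + c23 * r[3, ]) / det
      x[3, ] <- (c13 * r[1, ] + c23 * r[2, ] + c33 * r[3, ]) / det
    }
    feas <- colSums(x < 0) == 0 & colSums(!is.finite(x)) == 0
    ## chi2 - yWy = -x' r  at the stationary point of each support
    val <- -colSums(x * r)
    upd <- feas & val < bestval - 1e-12
    if (any(upd)) { bestX[, upd] <- x[, upd]; bestval[upd] <- val[upd] }
  }
  bestX
}

## mono-exponential profile solve where the basis differs per pixel:
## Bm gates x P per-pixel basis column, plus a shared offset column of ones.
## Returns chi2 per pixel and the (amplitude, Z) coefficients, both >= 0.
mono_profile_solve <- function(Bm, Y, W, with_offset = TRUE) {
  m11 <- colSums(Bm^2 * W)
  r1 <- colSums(Bm * W * Y)
  if (!with_offset) {
    a <- pmax(r1 / m11, 0)
    R <- Y - Bm * rep(a, each = nrow(Y))
    return(list(a = a, z = rep(0, length(a)), chi2 = colSums(W * R^2)))
  }
  m12 <- colSums(Bm * W); m22 <- colSums(W)
  r2 <- colSums(W * Y)
  det <- m11 * m22 - m12^2
  a <- (m22 * r1 - m12 * r2) / det
  z <- (m11 * r2 - m12 * r1) / det
  ## non-negativity by case enumeration (2-parameter NNLS)
  neg <- which(a < 0 | z < 0)
  if (length(neg)) {
    a0 <- pmax(r1[neg] / m11[neg], 0)          # z pinned at 0
    z0 <- pmax(r2[neg] / m22[neg], 0)          # a pinned at 0
    chi_a <- -2 * a0 * r1[neg] + a0^2 * m11[neg]
    chi_z <- -2 * z0 * r2[neg] + z0^2 * m22[neg]
    use_a <- chi_a <= chi_z
    a[neg] <- ifelse(use_a, a0, 0)
    z[neg] <- ifelse(use_a, 0, z0)
  }
  R <- Y - Bm * rep(a, each = nrow(Y)) - rep(z, each = nrow(Y))
  list(a = a, z = z, chi2 = colSums(W * R^2))
}
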