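# Weighted asymmetric-L1 (pinball) linear regression solved as a linear
# program by a primal-dual interior-point method, plus a vertex-polish step
# that recovers an exact basic solution.
#
# Problem:  minimize over beta   sum_i  wpos_i * (r_i)^+  +  wneg_i * (r_i)^-
#           with r = y - X beta.
# Quantile regression at level tau is wpos = tau, wneg = 1 - tau. One-sided
# rows (wneg = 0, y = 0) act as exact-penalty inequality constraints
# x_i' beta >= 0, which is how monotonicity of growth curves is imposed.
#
# The LP dual is  max y'a  s.t.  X'a = 0,  -wneg <= a <= wpos.  With the
# shift b = a + wneg this is a box-constrained LP in standard form; the
# multiplier on X'b = X'wneg is beta. Each Newton step costs one p x p
# solve (p = ncol(X)), so fits with thousands of rows are fast.

pinball_objective <- function(r, wpos, wneg) {
  sum(wpos * pmax(r, 0)) + sum(wneg * pmax(-r, 0))
}

# interior-point core; returns list(beta, converged, iter, gap)
.pinball_ip <- function(X, y, wpos, wneg, maxit = 200, rtol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  W <- wpos + wneg
  if (any(W <= 0)) stop("each row needs wpos + wneg > 0")
  g <- drop(crossprod(X, wneg))
  scale_y <- max(1, mean(abs(y)))

  # infeasible interior start
  beta <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(0, p))
  beta[is.na(beta)] <- 0
  r <- y - drop(X %*% beta)
  d0 <- 0.1 * scale_y + 1e-3
  q <- pmax(r, 0) + d0        # dual slack for the upper box face
  z <- pmax(-r, 0) + d0       # dual slack for the lower box face
  b <- 0.5 * W
  s <- W - b

  gap0 <- sum(b * z) + sum(s * q)
  for (iter in seq_len(maxit)) {
    r1 <- g - drop(crossprod(X, b))          # primal feasibility (of dual LP)
    r3 <- y - drop(X %*% beta) - q + z       # dual feasibility
    gap <- sum(b * z) + sum(s * q)

    if (gap < rtol * (1 + gap0) &&
        max(abs(r1)) < 1e-8 * (1 + max(abs(g))) &&
        max(abs(r3)) < 1e-8 * scale_y)
      return(list(beta = beta, converged = TRUE, iter = iter, gap = gap))

    dvec <- 1 / (q / s + z / b)
    solve_step <- function(mu, cor_bz, cor_sq) {
      rhs <- r3 - (mu - cor_sq) / s + q + (mu - cor_bz) / b - z
      XtDX <- crossprod(X, X * dvec)
      rhs_beta <- drop(crossprod(X, dvec * rhs)) - r1
      dbeta <- tryCatch(solve(XtDX, rhs_beta), error = function(e) {
        solve(XtDX + diag(1e-10 * max(diag(XtDX)), p), rhs_beta)
      })
      db <- dvec * (rhs - drop(X %*% dbeta))
      ds <- -db
      dz <- (mu - b * z - cor_bz - z * db) / b
      dq <- (mu - s * q - cor_sq + q * db) / s
      list(beta = dbeta, b = db, s = ds, z = dz, q = dq)
    }
    step_len <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) return(1)
      min(1, 0.9995 * min(-v[neg] / dv[neg]))
    }

    # predictor (affine scaling)
    aff <- solve_step(0, 0, 0)
    ap <- min(step_len(b, aff$b), step_len(s, aff$s))
    ad <- min(step_len(z, aff$z), step_len(q, aff$q))
    gap_aff <- sum((b + ap * aff$b) * (z + ad * aff$z)) +
      sum((s + ap * aff$s) * (q + ad * aff$q))
    sigma <- min(1, max(0, gap_aff / gap))^3
    mu <- sigma * gap / (2 * n)

    # corrector with Mehrotra second-order terms
    stp <- solve_step(mu, aff$b * aff$z, aff$s * aff$q)
    ap <- min(step_len(b, stp$b), step_len(s, stp$s))
    ad <- min(step_len(z, stp$z), step_len(q, stp$q))

    b <- b + ap * stp$b
    s <- s + ap * stp$s
    beta <- beta + ad * stp$beta
    z <- z + ad * stp$z
    q <- q + ad * stp$q
  }
  list(beta = beta, converged = FALSE, iter = maxit, gap = gap)
}

# exact basic solution: interpolate the p rows with the smallest residuals
# (greedy, rank-checked); accept only if it does not worsen the objective
.pinball_polish <- function(X, y, wpos, wneg, beta) {
  n <- nrow(X); p <- ncol(X)
  if (n < p) return(beta)
  r <- y - drop(X %*% beta)
  ord <- order(abs(r))
  rows <- integer(0)
  qr_cur <- NULL
  for (i in ord) {
    cand <- c(rows, i)
    qr_try <- qr(X[cand, , drop = FALSE])
    if (qr_try$rank == length(cand)) {
      rows <- cand
      qr_cur <- qr_try
      if (length(rows) == p) break
    }
  }
  if (length(rows) < p) return(beta)
  beta_v <- tryCatch(qr.coef(qr_cur, y[rows]), error = function(e) NULL)
  if (is.null(beta_v) || anyNA(beta_v)) return(beta)
  obj0 <- pinball_objective(y - drop(X %*% beta), wpos, wneg)
  obj1 <- pinball_objective(y - drop(X %*% beta_v), wpos, wneg)
  if (obj1 <= obj0 + 1e-9 * (1 + abs(obj0))) beta_v else beta
}

#' Weighted pinball-loss linear fit (LP interior point)
#'
#' Minimizes `sum_i wpos_i (r_i)^+ + wneg_i (r_i)^-` over coefficients
#' `beta`, with `r = y - X beta`. Quantile regression at level `tau` uses
#' `wpos = tau`, `wneg = 1 - tau` on every row. Rows with `wneg = 0` and
#' `y = 0` act as one-sided penalties `x' beta >= 0` and are how the growth
#' charts impose monotonicity. The solution is computed by a primal-dual
#' interior-point method and then polished to an exact vertex of the LP
#' (so e.g. an intercept-only fit returns an order statistic exactly).
#'
#' @param X numeric design matrix (n x p, n >= p).
#' @param y numeric response, length n.
#' @param wpos,wneg nonnegative per-row weights on positive/negative
#'   residuals; scalars are recycled.
#' @return List with `beta`, `converged`, `iter`, `objective`.
#' @examples
#' y <- c(3, 1, 4, 1, 5, 9, 2, 6)
#' f <- pinball_fit(matrix(1, 8, 1), y, wpos = 0.5, wneg = 0.5)
#' f$beta  # a median of y
#' @export
pinball_fit <- function(X, y, wpos, wneg) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  wpos <- rep_len(wpos, n); wneg <- rep_len(wneg, n)
  if (any(wpos < 0) || any(wneg < 0)) stop("weights must be nonnegative")
  if (n < p) stop("fewer rows (", n, ") than parameters (", p, ")")
  ip <- .pinball_ip(X, y, wpos, wneg)
  beta <- .pinball_polish(X, y, wpos, wneg, ip$beta)
  list(beta = as.numeric(beta), converged = ip$converged, iter = ip$iter,
       objective = pinball_objective(y - drop(X %*% beta), wpos, wneg))
}
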