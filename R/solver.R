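#' Simplex-constrained least squares
#'
#' Solves
#' \deqn{\min_p \|Ap - b\|^2 + \lambda \|p\|^2
#'       \quad s.t. \quad p \ge 0,\; \sum_i p_i = 1,}
#' the deconvolution problem at the heart of the burden inversion. With many
#' more unknowns than rows of `A` the unregularised problem has a whole face
#' of minimisers; the tiny Tikhonov term (`lambda_reg`, default 1e-8) makes
#' the minimiser unique (essentially the minimum-norm point of that face) and
#' therefore solver-independent and reproducible.
#'
#' The solver is a two-stage method tailored to the low row rank of `A`:
#' an accelerated projected-gradient (FISTA) phase with exact Euclidean
#' projection onto the simplex locates the active face; an active-set polish
#' then solves the reduced strictly convex quadratic programme on the support
#' exactly (equality-constrained KKT systems with non-negativity handled by a
#' Lawson-Hanson style inner loop) and verifies the Karush-Kuhn-Tucker
#' conditions over all coordinates, re-solving with any violating coordinates
#' added until none remain — so the returned point is the exact global
#' minimiser up to the stated tolerances. With `lambda_reg = 0` uniqueness is
#' lost; the polish is skipped and the FISTA iterate (an approximately
#' minimum-norm minimiser, from the uniform start) is returned.
#'
#' Because any fixed ridge weight biases the solution away from the optimal
#' face (it trades a little fit for a smaller norm), the default runs a short
#' Tikhonov continuation: after solving at `lambda_reg` the polish is re-run
#' warm-started at weights decreasing by factors of 100 down to `lambda_min`,
#' so the returned point approaches the exact minimum-norm minimiser of the
#' fit alone. Set `continuation = FALSE` to solve the single summed objective
#' at `lambda_reg` instead.
#'
#' @param A numeric matrix (m x n), typically m << n.
#' @param b numeric vector of length m.
#' @param lambda_reg ridge weight; non-negative.
#' @param max_iter maximum FISTA iterations.
#' @param kkt_tol relative tolerance on the stationarity residual used to
#'   detect violating coordinates.
#' @param support_tol coordinates above this value after the gradient phase
#'   seed the active set.
#' @param continuation drive the ridge weight towards `lambda_min` after the
#'   first solve (default TRUE).
#' @param lambda_min terminal ridge weight of the continuation.
#' @return list with elements `p` (the solution), `objective`
#'   (fit + ridge at the terminal weight), `fit_objective` (`||Ap-b||^2`
#'   alone), `iterations`, `kkt_residual` and `converged`.
#' @export
simplex_ls <- function(A, b, lambda_reg = 1e-8, max_iter = 800L,
                       kkt_tol = 1e-9, support_tol = 1e-12,
                       continuation = TRUE, lambda_min = 1e-12) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, lambda_reg >= 0)
  if (n == 1L) {
    p <- 1
    return(list(p = p, objective = sum((A %*% p - b)^2) + lambda_reg,
                fit_objective = sum((A %*% p - b)^2), iterations = 0L,
                kkt_residual = 0, converged = TRUE))
  }
  # Lipschitz constant of the gradient: 2 (sigma_max(A)^2 + lambda)
  smax <- svd(A, nu = 0, nv = 0)$d[1]
  L <- 2 * (smax^2 + lambda_reg)
  p <- rep.int(1 / n, n)
  y <- p
  t_prev <- 1
  obj <- function(p) {
    r <- as.numeric(A %*% p) - b
    sum(r^2) + lambda_reg * sum(p^2)
  }
  last <- obj(p)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- as.numeric(A %*% y) - b
    g <- 2 * (as.numeric(crossprod(A, r)) + lambda_reg * y)
    p_new <- project_simplex(y - g / L)
    t_new <- (1 + sqrt(1 + 4 * t_prev^2)) / 2
    y <- p_new + ((t_prev - 1) / t_new) * (p_new - p)
    p <- p_new
    t_prev <- t_new
    if (it %% 200L == 0L) {
      cur <- obj(p)
      if (last - cur < 1e-16 * max(1, cur)) break
      last <- cur
    }
  }
  if (lambda_reg == 0) {
    r <- as.numeric(A %*% p) - b
    return(list(p = p, objective = sum(r^2), fit_objective = sum(r^2),
                iterations = it, kkt_residual = NA_real_, converged = TRUE))
  }
  lam <- lambda_reg
  polished <- polish_active_set(A, b, lam, p,
                                kkt_tol = kkt_tol, support_tol = support_tol)
  fit_of <- function(p) sum((as.numeric(A %*% p) - b)^2)
  if (continuation) {
    fit_cur <- fit_of(polished$p)
    while (lam > lambda_min * 1.0001) {
      lam <- max(lam / 100, lambda_min)
      # fail fast here: a continuation stage that cannot be solved cleanly
      # (numerical breakdown of the tiny-ridge KKT systems) is abandoned and
      # the last reliable weight kept
      nxt <- tryCatch(
        polish_active_set(A, b, lam, polished$p,
                          kkt_tol = kkt_tol, support_tol = support_tol,
                          max_pivots = 400L),
        error = function(e) NULL
      )
      if (is.null(nxt) || !nxt$converged) break  # keep last reliable weight
      fit_nxt <- fit_of(nxt$p)
      # along the exact Tikhonov path the fit decreases as lambda shrinks;
      # an increase flags numerical breakdown of the small-ridge solve
      if (fit_nxt > fit_cur * 1.5 + 1e-13) break
      polished <- nxt
      fit_cur <- fit_nxt
    }
  }
  r <- as.numeric(A %*% polished$p) - b
  list(p = polished$p,
       objective = sum(r^2) + lam * sum(polished$p^2),
       fit_objective = sum(r^2),
       iterations = it,
       kkt_residual = polished$kkt_residual,
       converged = polished$converged)
}

# Euclidean projection onto the probability simplex (sort-based algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Solve the QP restricted to support S exactly, then expand S with KKT
# violators until the point is globally optimal over all n coordinates.
polish_active_set <- function(A, b, lambda_reg, p0, kkt_tol, support_tol,
                              max_rounds = 60L, max_pivots = 10000L) {
  n <- ncol(A)
  # seed from the clearly-active coordinates; the violator loop below pulls
  # in anything the gradient phase underestimated
  S <- which(p0 > max(support_tol, 0.001 / n))
  if (length(S) == 0L) S <- which.max(p0)
  p <- p0
  converged <- FALSE
  kkt_res <- NA_real_
  for (round in seq_len(max_rounds)) {
    start <- p[S]
    if (sum(start) <= 0) start <- rep.int(1 / length(S), length(S))
    sub <- active_set_qp(A[, S, drop = FALSE], b, lambda_reg,
                         start / sum(start), max_pivots = max_pivots)
    p <- numeric(n)
    p[S] <- sub$w
    # KKT over all coordinates: g_i + nu = 0 where p_i > 0, >= 0 elsewhere
    g <- 2 * (as.numeric(crossprod(A, as.numeric(A %*% p) - b)) +
                lambda_reg * p)
    slack <- g + sub$nu
    off <- which(p <= support_tol)
    kkt_res <- if (length(off)) max(0, -min(slack[off])) else 0
    viol <- setdiff(which(slack < -kkt_tol * max(1, max(abs(g)))), S)
    if (length(viol) == 0L) {
      converged <- TRUE
      break
    }
    S <- sort(union(S, viol))
  }
  list(p = p, kkt_residual = kkt_res, converged = converged)
}

# Solve min ||A w - b||^2 + lambda ||w||^2 s.t. sum(w) = 1, w >= 0
# (strictly convex) by principal pivoting on the coordinate partition
# free/clamped. Block phase swaps every primal-infeasible free coordinate
# and every dual-infeasible clamped coordinate at once and usually finishes
# in a handful of KKT solves; if the violation count stalls, the method
# degrades to least-index single swaps (Murty's rule), which terminates
# finitely. Returns w and the equality multiplier nu.
active_set_qp <- function(A, b, lambda_reg, w0, tol = 1e-12,
                          max_pivots = 10000L) {
  k <- ncol(A)
  clamped <- w0 <= tol
  if (all(clamped)) clamped[which.max(w0)] <- FALSE
  best_viol <- Inf
  stalls <- 0L
  single_mode <- FALSE
  for (iter in seq_len(max_pivots)) {
    free <- !clamped
    sol <- eq_kkt_solve(A, b, lambda_reg, free)
    w <- numeric(k)
    w[free] <- sol$w
    g <- 2 * (as.numeric(crossprod(A, as.numeric(A %*% w) - b)) +
                lambda_reg * w)
    slack <- g + sol$nu
    primal_bad <- which(free & w < -tol)
    dual_bad <- which(clamped & slack < -1e-9 * max(1, max(abs(g))))
    n_viol <- length(primal_bad) + length(dual_bad)
    if (n_viol == 0L) {
      w <- pmax(w, 0)
      return(list(w = w / sum(w), nu = sol$nu))
    }
    if (n_viol < best_viol) {
      best_viol <- n_viol
      stalls <- 0L
      single_mode <- FALSE  # progress: back to block swaps
    } else {
      stalls <- stalls + 1L
      if (stalls >= 3L) single_mode <- TRUE
    }
    if (single_mode) {
      j <- min(c(primal_bad, dual_bad))  # least-index rule: finite
      clamped[j] <- !clamped[j]
    } else {
      clamped[primal_bad] <- TRUE
      clamped[dual_bad] <- FALSE
    }
    if (all(clamped)) clamped[which.max(w0)] <- FALSE
  }
  stop("principal pivoting did not converge")
}

# Solve min ||A_F w - b||^2 + lambda ||w||^2 s.t. sum(w) = 1 over the free
# coordinates F. The Hessian is a rank-m update of the ridge, so the KKT
# system is solved in O(m^2 |F|) through the Woodbury identity:
# (Af'Af + lambda I)^{-1} y = (y - Af' G^{-1} Af y) / lambda,
# with G = lambda I_m + Af Af' only m x m.
eq_kkt_solve <- function(A, b, lambda_reg, free) {
  Af <- A[, free, drop = FALSE]
  m <- nrow(Af)
  G <- tcrossprod(Af)
  diag(G) <- diag(G) + lambda_reg
  Gc <- chol(G)
  ridge_inv <- function(y) {
    Ay <- as.numeric(Af %*% y)
    (y - as.numeric(crossprod(Af, backsolve(Gc, forwardsolve(t(Gc), Ay))))) /
      lambda_reg
  }
  # D = 2(Af'Af + lambda I); w = D^{-1}(d - nu 1) with nu from sum(w) = 1
  x1 <- ridge_inv(as.numeric(crossprod(Af, b)))   # = D^{-1} d
  x2 <- ridge_inv(rep.int(1, ncol(Af))) / 2       # = D^{-1} 1
  nu <- (sum(x1) - 1) / sum(x2)
  w <- x1 - nu * x2
  # iterative refinement on the full KKT system claws back the precision
  # lost to the lambda division in the Woodbury form
  for (step in 1:2) {
    res_d <- as.numeric(crossprod(Af, b - as.numeric(Af %*% w))) * 2 -
      2 * lambda_reg * w - nu
    res_s <- 1 - sum(w)
    c1 <- ridge_inv(res_d / 2)
    dnu <- -(res_s - sum(c1)) / sum(x2)
    w <- w + c1 - dnu * x2
    nu <- nu + dnu
  }
  list(w = w, nu = nu)
}
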