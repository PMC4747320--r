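#' Frequency dynamics of the stage distribution
#'
#' Right-hand side of the replicator-like frequency equation
#' `dp/dt = (I - p 1') A(p) p`, whose equilibria are the stable stage
#' distributions of the nonlinear projection matrix `A(p)`. The entries of
#' the returned vector sum to zero, so the simplex is invariant.
#'
#' @param model a `sexratio_model`.
#' @param s1 resident primary sex ratio.
#' @param p stage frequency vector on the simplex.
#' @return the time derivative `dp/dt` (same length as `p`).
#' @export
frequency_dynamics <- function(model, s1, p) {
  if (any(p < -1e-12)) stop("stage frequencies must be non-negative",
                            call. = FALSE)
  A <- model$A_res(s1, p)
  Ap <- A %*% p
  as.numeric(Ap) - sum(Ap) * p
}

# --- Dormand-Prince RK5(4) with adaptive step -------------------------------
# Small self-contained integrator (no ODE suite is available offline).
# f(y) is autonomous; integrates from t = 0 to t = tmax.
.dp45 <- local({
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  )
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  function(f, y0, tmax, rtol = 1e-10, atol = 1e-12, h0 = NULL) {
    y <- y0
    t <- 0
    h <- if (is.null(h0)) min(0.1, tmax) else h0
    k1 <- f(y)
    nstep <- 0L
    while (t < tmax) {
      if (nstep > 100000L) stop("ODE integrator exceeded step budget")
      h <- min(h, tmax - t)
      k <- vector("list", 7L)
      k[[1]] <- k1
      for (i in 1:6) {
        yi <- y
        for (j in seq_len(i)) yi <- yi + h * a[[i]][j] * k[[j]]
        k[[i + 1]] <- f(yi)
      }
      y5 <- y
      y4 <- y
      for (j in 1:7) {
        y5 <- y5 + h * b5[j] * k[[j]]
        y4 <- y4 + h * b4[j] * k[[j]]
      }
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (is.na(err)) stop("ODE integrator produced NaN")
      if (err <= 1) {
        t <- t + h
        y <- y5
        k1 <- k[[7]] # FSAL
        nstep <- nstep + 1L
      }
      fac <- if (err > 0) 0.9 * err^(-0.2) else 5
      h <- h * min(5, max(0.2, fac))
    }
    y
  }
})

# Max real part of the frequency-dynamics Jacobian restricted to the
# simplex tangent space {x : sum(x) = 0}. Negative at the attractor;
# positive at saddle equilibria (e.g. single-sex boundary states), which
# warm-started Newton must not silently accept.
.tangent_growth <- function(model, s1, p) {
  s <- length(p)
  h <- 1e-7
  J <- matrix(0, s, s)
  for (j in seq_len(s)) {
    e1 <- p; e1[j] <- e1[j] + h
    e2 <- p; e2[j] <- max(e2[j] - h, 0)
    J[, j] <- (frequency_dynamics(model, s1, e1) -
                 frequency_dynamics(model, s1, e2)) / (e1[j] - e2[j])
  }
  Q <- qr.Q(qr(matrix(1, s, 1)), complete = TRUE)[, -1, drop = FALSE]
  max(Re(eigen(crossprod(Q, J %*% Q), only.values = TRUE)$values))
}

# Newton polish of the frequency equilibrium: solve F(p) = 0 with the last
# equation replaced by the simplex constraint sum(p) = 1.
.newton_equilibrium <- function(model, s1, p, tol, max_iter = 40L) {
  s <- length(p)
  Ffun <- function(q) frequency_dynamics(model, s1, pmax(q, 0))
  for (it in seq_len(max_iter)) {
    Fp <- Ffun(p)
    res <- max(abs(Fp))
    if (res < tol) {
      return(list(p = p, residual = res, converged = TRUE, iterations = it - 1L))
    }
    J <- matrix(0, s, s)
    h <- 1e-7
    for (j in seq_len(s)) {
      e1 <- p; e1[j] <- e1[j] + h
      e2 <- p; e2[j] <- e2[j] - h
      J[, j] <- (Ffun(e1) - Ffun(e2)) / (2 * h)
    }
    J[s, ] <- 1
    rhs <- Fp
    rhs[s] <- sum(p) - 1
    step <- tryCatch(solve(J, rhs), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(p = p, residual = res, converged = FALSE, iterations = it))
    }
    p_new <- p - step
    if (min(p_new) < -1e-6) { # left the simplex; caller falls back to ODE
      return(list(p = p, residual = res, converged = FALSE, iterations = it))
    }
    # projected step: boundary and near-boundary equilibria are legitimate
    p <- pmax(p_new, 0)
    p <- p / sum(p)
  }
  Fp <- Ffun(p)
  list(p = p, residual = max(abs(Fp)), converged = max(abs(Fp)) < tol,
       iterations = max_iter)
}

#' Solve for the equilibrium stage distribution
#'
#' Integrates the frequency dynamics `dp/dt = (I - p 1') A(p) p` from an
#' interior start in windows of fixed duration until consecutive window
#' ends agree, then polishes the root with a damped Newton step on
#' `F(p) = A(p) p - (1' A(p) p) p` subject to `sum(p) = 1`. Because the
#' dynamics contract onto the (unique, stable) equilibrium for this model
#' class, the ODE stage guarantees the right basin and Newton supplies
#' near-machine-precision residuals cheaply. Repeated calls at nearby `s1`
#' warm-start Newton from the previous solution and skip the ODE stage when
#' the polish succeeds.
#'
#' @param model a `sexratio_model`.
#' @param s1 resident primary sex ratio in `[0, 1]`.
#' @param p0 optional starting frequency vector (defaults to uniform).
#' @param tol convergence tolerance on the max-norm of the residual
#'   `F(p_hat)`.
#' @param window duration of one integration window.
#' @param max_time maximum total integration horizon before giving up.
#' @param use_cache reuse/populate the model's per-`s1` equilibrium cache.
#' @return an object of class `equilibrium`: list with `p` (the equilibrium
#'   stage distribution), `lambda` (dominant eigenvalue of `A(p_hat)`),
#'   `A` (the projection matrix at equilibrium), `residual`, `iterations`.
#' @export
solve_equilibrium <- function(model, s1, p0 = NULL, tol = 1e-10,
                              window = 50, max_time = 20000,
                              use_cache = TRUE) {
  if (s1 < 0 || s1 > 1) stop("s1 must lie in [0, 1]", call. = FALSE)
  key <- sprintf("eq_%.17g_%.3g", s1, tol)
  if (use_cache && !is.null(model$cache[[key]])) return(model$cache[[key]])

  s <- model$s
  f <- function(p) frequency_dynamics(model, s1, pmax(p, 0))

  start <- if (is.null(p0)) rep(1 / s, s) else {
    if (length(p0) != s || any(p0 < 0) || sum(p0) <= 0) {
      stop("p0 must be a non-negative vector of length ", s, call. = FALSE)
    }
    p0 / sum(p0)
  }

  # warm start: try Newton directly from the most recent equilibrium;
  # accept only a nearby, dynamically stable root (Newton happily converges
  # to saddle equilibria such as single-sex boundary states)
  if (use_cache && is.null(p0) && !is.null(model$cache$last_p) &&
      length(model$cache$last_p) == s) {
    nw <- .newton_equilibrium(model, s1, model$cache$last_p, tol)
    if (nw$converged &&
        max(abs(nw$p - model$cache$last_p)) < 0.2 &&
        .tangent_growth(model, s1, nw$p) < 1e-7) {
      out <- .finish_equilibrium(model, s1, nw, tol, key, use_cache)
      return(out)
    }
  }

  p <- start
  t_total <- 0
  prev_end <- NULL
  converged <- FALSE
  n_win <- 0L
  while (t_total < max_time) {
    p <- .dp45(f, p, window)
    p <- pmax(p, 0)
    p <- p / sum(p)
    t_total <- t_total + window
    n_win <- n_win + 1L
    if (!is.null(prev_end) && max(abs(p - prev_end)) < 1e-4) {
      nw <- .newton_equilibrium(model, s1, p, tol)
      # accept only the attractor the trajectory is heading to, never a
      # nearby saddle Newton may have jumped onto
      if (nw$converged && .tangent_growth(model, s1, nw$p) < 1e-7) {
        nw$iterations <- nw$iterations + n_win
        return(.finish_equilibrium(model, s1, nw, tol, key, use_cache))
      }
    }
    prev_end <- p
    if (max(abs(f(p))) < tol) {
      converged <- TRUE
      break
    }
  }
  res <- max(abs(f(p)))
  if (!converged && res >= tol) {
    stop(sprintf(
      "equilibrium not reached within horizon %g (residual %.3e, s1 = %g)",
      max_time, res, s1), call. = FALSE)
  }
  .finish_equilibrium(model, s1,
                      list(p = p, residual = res, iterations = n_win),
                      tol, key, use_cache)
}

.finish_equilibrium <- function(model, s1, nw, tol, key, use_cache) {
  A <- model$A_res(s1, nw$p)
  lam <- sum(A %*% nw$p) # 1' A p = lambda at equilibrium
  out <- structure(
    list(p = stats::setNames(nw$p, model$stage_labels), lambda = lam, A = A,
         s1 = s1, residual = nw$residual, iterations = nw$iterations),
    class = "equilibrium"
  )
  if (use_cache) {
    model$cache[[key]] <- out
    model$cache$last_p <- nw$p
  }
  out
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium stage distribution (s1 = %g)\n", x$s1))
  print(round(x$p, 6))
  cat(sprintf("  lambda = %.8f, residual = %.2e\n", x$lambda, x$residual))
  invisible(x)
}

#' Dominant eigenvalue and eigenvectors of a projection matrix
#'
#' Extracts the dominant (maximal real part) eigenvalue `lambda` of a real
#' projection/generator matrix together with its right eigenvector `w`
#' (stable stage structure, scaled to sum to one) and left eigenvector `v`
#' (stage-specific reproductive values, scaled so that `v'w = 1`). The
#' model class produces essentially non-negative (Metzler) matrices, whose
#' dominant eigenvalue is real and simple; a complex or (numerically) tied
#' dominant eigenvalue signals a model violation and raises an error.
#'
#' @param A a real square matrix.
#' @param tol tolerance for the reality/simplicity checks.
#' @return an object of class `eigen_triple`: list with `lambda`, `w`, `v`.
#' @examples
#' et <- eigen_triple(diag(c(2, 1)))
#' et$lambda # 2
#' @export
eigen_triple <- function(A, tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !is.numeric(A)) {
    stop("A must be a real square matrix", call. = FALSE)
  }
  eA <- eigen(A)
  re <- Re(eA$values)
  k <- which.max(re)
  lam <- eA$values[k]
  if (abs(Im(lam)) > tol * (1 + abs(lam))) {
    stop("dominant eigenvalue is complex; model assumptions violated",
         call. = FALSE)
  }
  gap <- if (length(re) > 1) Re(lam) - max(re[-k]) else Inf
  if (gap < 1e-12 * (1 + abs(Re(lam)))) {
    stop("dominant eigenvalue is not simple", call. = FALSE)
  }
  w <- Re(eA$vectors[, k])
  if (sum(w) == 0) stop("degenerate right eigenvector", call. = FALSE)
  w <- w / sum(w)
  if (min(w) < -1e-8) {
    stop("dominant right eigenvector has negative entries", call. = FALSE)
  }
  eL <- eigen(t(A))
  kL <- which.max(Re(eL$values))
  v <- Re(eL$vectors[, kL])
  nv <- sum(v * w)
  if (abs(nv) < 1e-14) stop("left/right eigenvectors nearly orthogonal",
                            call. = FALSE)
  v <- v / nv
  structure(list(lambda = Re(lam), w = w, v = v), class = "eigen_triple")
}

#' @export
print.eigen_triple <- function(x, ...) {
  cat(sprintf("lambda = %.8f\n", x$lambda))
  cat("w (stable structure):", paste(sprintf("%.6f", x$w), collapse = " "), "\n")
  cat("v (reproductive values):", paste(sprintf("%.6f", x$v), collapse = " "), "\n")
  invisible(x)
}

# dominant eigenvalue only (cheap path used by invasion fitness)
dominant_eigenvalue <- function(A, tol = 1e-8) {
  ev <- eigen(A, only.values = TRUE)$values
  k <- which.max(Re(ev))
  lam <- ev[k]
  if (abs(Im(lam)) > tol * (1 + abs(lam))) {
    stop("dominant eigenvalue is complex", call. = FALSE)
  }
  Re(lam)
}
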