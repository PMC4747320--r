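#' vec operator and its inverse
#'
#' `vec()` stacks the columns of a matrix into a vector; `unvec()` restores
#' an `m x n` matrix from an `mn`-vector. `unvec(vec(X), m, n)` is the
#' identity.
#'
#' @param X a matrix.
#' @param x a numeric vector of length `m * n`.
#' @param m,n target dimensions for `unvec`.
#' @return `vec`: a numeric vector; `unvec`: an `m x n` matrix.
#' @examples
#' vec(matrix(1:4, 2)) # 1 2 3 4
#' @export
vec <- function(X) {
  if (!is.matrix(X)) stop("vec expects a matrix", call. = FALSE)
  dim(X) <- NULL
  X
}

#' @rdname vec
#' @export
unvec <- function(x, m, n = m) {
  if (length(x) != m * n) {
    stop(sprintf("length(x) = %d is not m*n = %d", length(x), m * n),
         call. = FALSE)
  }
  matrix(x, m, n)
}

#' Commutation matrix
#'
#' The `mn x mn` permutation matrix `K_{m,n}` with
#' `K_{m,n} %*% vec(X) = vec(t(X))` for every `m x n` matrix `X`.
#'
#' @param m,n matrix dimensions (positive integers).
#' @return a 0/1 permutation matrix of dimension `mn x mn`.
#' @examples
#' K <- commutation_matrix(2, 3)
#' X <- matrix(rnorm(6), 2, 3)
#' all.equal(as.numeric(K %*% vec(X)), vec(t(X)))
#' @export
commutation_matrix <- function(m, n) {
  m <- as.integer(m)
  n <- as.integer(n)
  if (m < 1L || n < 1L) stop("m, n must be >= 1", call. = FALSE)
  mn <- m * n
  K <- matrix(0, mn, mn)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      # entry (i, j) of X sits at (j-1)*m + i in vec(X) and becomes entry
      # (j, i) of t(X), i.e. position (i-1)*n + j in vec(t(X))
      K[(i - 1L) * n + j, (j - 1L) * m + i] <- 1
    }
  }
  K
}

#' Sensitivity context for eigen-derivative calculations
#'
#' Packages a (mutant) projection matrix with its dominant eigen-triple,
#' checked against the normalisations the derivative formulas assume
#' (`sum(w) = 1`, `v'w = 1`).
#'
#' @param A a real square matrix with a simple real dominant eigenvalue.
#' @param triple optionally a precomputed [eigen_triple()] of `A`.
#' @return list with `A`, `triple`, `s` (dimension), class
#'   `sensitivity_context`.
#' @export
sensitivity_context <- function(A, triple = NULL) {
  if (is.null(triple)) triple <- eigen_triple(A)
  s <- nrow(A)
  if (abs(sum(triple$w) - 1) > 1e-8 ||
      abs(sum(triple$v * triple$w) - 1) > 1e-8) {
    stop("eigenvector normalisation violated (need sum(w)=1, v'w=1)",
         call. = FALSE)
  }
  structure(list(A = A, triple = triple, s = s),
            class = "sensitivity_context")
}

#' Gradient of the dominant eigenvalue along a matrix perturbation
#'
#' For a matrix `A'` with dominant triple `(lambda', w', v')` normalised so
#' that `v''w' = 1`, the derivative of `lambda'` along a perturbation
#' direction `dvecA` of its entries is `(w'' %x% v'') %*% dvecA`, i.e.
#' `v'' (dA) w'` in matrix form.
#'
#' @param ctx a [sensitivity_context()].
#' @param dvecA_ds numeric vector of length `s^2`: the direction
#'   `d vec A' / d theta`.
#' @return the scalar derivative `d lambda' / d theta`.
#' @export
eigenvalue_gradient <- function(ctx, dvecA_ds) {
  stopifnot(inherits(ctx, "sensitivity_context"),
            length(dvecA_ds) == ctx$s^2)
  tr <- ctx$triple
  as.numeric(crossprod(kronecker(tr$w, tr$v), dvecA_ds))
}

#' Derivatives of the dominant eigenvectors with respect to matrix entries
#'
#' Jacobians of the right eigenvector `w'` (normalised to sum to one) and
#' the left eigenvector `v'` (normalised so `v''w' = 1`) with respect to
#' `vec A'`:
#' \deqn{dw'/dvec'A' = (\lambda' I - A' + w' e' A')^{-1}
#'                     (w'' \otimes (I - w' e'))}
#' \deqn{dv'/dvec'A' = (\lambda' I - A'' + \lambda' v' w'')^{-1}
#'   [((I - v' w'') \otimes v'') - \lambda' (v' v'') \, dw'/dvec'A']}
#' where `e'` is the all-ones row. Both resolvent-like matrices are
#' singular at a repeated dominant eigenvalue; ill-conditioning (condition
#' number above 1e10) triggers a warning naming the failing solve.
#'
#' @param ctx a [sensitivity_context()].
#' @return list with `dw_dvecA` and `dv_dvecA`, both `s x s^2`.
#' @export
eigenvector_derivatives <- function(ctx) {
  stopifnot(inherits(ctx, "sensitivity_context"))
  A <- ctx$A
  s <- ctx$s
  tr <- ctx$triple
  lam <- tr$lambda
  w <- tr$w
  v <- tr$v
  I <- diag(s)
  e <- rep(1, s)

  M1 <- lam * I - A + (w %o% e) %*% A
  if (kappa(M1, exact = FALSE) > 1e10) {
    warning("ill-conditioned solve in dw'/dvecA' (condition > 1e10)")
  }
  dw <- tryCatch(
    solve(M1, kronecker(t(w), I - w %o% e)),
    error = function(err) stop("singular resolvent in dw'/dvecA': ",
                               conditionMessage(err), call. = FALSE)
  )

  M2 <- lam * I - t(A) + lam * (v %o% w)
  if (kappa(M2, exact = FALSE) > 1e10) {
    warning("ill-conditioned solve in dv'/dvecA' (condition > 1e10)")
  }
  rhs <- kronecker(I - v %o% w, t(v)) - lam * (v %o% v) %*% dw
  dv <- tryCatch(
    solve(M2, rhs),
    error = function(err) stop("singular resolvent in dv'/dvecA': ",
                               conditionMessage(err), call. = FALSE)
  )
  list(dw_dvecA = dw, dv_dvecA = dv)
}

#' Hessian of the dominant eigenvalue with respect to matrix entries
#'
#' The `s^2 x s^2` symmetric matrix of second derivatives of `lambda'` with
#' respect to the entries of `A'`:
#' `H = (H1 + H1')/2` with
#' `H1 = (I %x% v') dw'/dvec'A' + (w' %x% I) dv'/dvec'A'`.
#'
#' @param ctx a [sensitivity_context()].
#' @param evd optionally precomputed [eigenvector_derivatives()].
#' @return a symmetric `s^2 x s^2` matrix.
#' @export
lambda_hessian_wrt_A <- function(ctx, evd = NULL) {
  stopifnot(inherits(ctx, "sensitivity_context"))
  if (is.null(evd)) evd <- eigenvector_derivatives(ctx)
  s <- ctx$s
  tr <- ctx$triple
  I <- diag(s)
  H1 <- kronecker(I, matrix(tr$v, ncol = 1)) %*% evd$dw_dvecA +
    kronecker(matrix(tr$w, ncol = 1), I) %*% evd$dv_dvecA
  (H1 + t(H1)) / 2
}

#' Pure second derivative of invasion fitness in the mutant trait
#'
#' `d2 lambda' / d s1'^2` via the chain rule through the matrix entries:
#' the curvature of `A'` in the mutant sex ratio contracted against
#' `w' %x% v'`, plus the quadratic form of the eigenvalue Hessian in the
#' first derivative direction:
#' `(w'' %x% v'') H[vecA'; s1'] + C' H[lambda'; vecA'] C` with
#' `C = d vec A' / d s1'`.
#'
#' @param ctx a [sensitivity_context()] for the mutant matrix at
#'   `s1' = s1`.
#' @param C first derivative of `vec A'` in the mutant trait (length
#'   `s^2`).
#' @param H_vecA second derivative of `vec A'` in the mutant trait (length
#'   `s^2`); zero when `A'` is linear in `s1'`.
#' @param H_lambda optionally a precomputed [lambda_hessian_wrt_A()].
#' @return the scalar second derivative.
#' @export
d2lambda_mutant <- function(ctx, C, H_vecA, H_lambda = NULL) {
  stopifnot(inherits(ctx, "sensitivity_context"),
            length(C) == ctx$s^2, length(H_vecA) == ctx$s^2)
  if (is.null(H_lambda)) H_lambda <- lambda_hessian_wrt_A(ctx)
  tr <- ctx$triple
  term1 <- as.numeric(crossprod(kronecker(tr$w, tr$v), H_vecA))
  term2 <- as.numeric(crossprod(C, H_lambda %*% C))
  term1 + term2
}

#' Mixed second derivative of invasion fitness (mutant x resident)
#'
#' `d2 lambda' / d s1 d s1'` at a singular strategy. Differentiating the
#' selection gradient `(w'' %x% v'') C` with respect to the resident trait
#' (which acts through the equilibrium structure `p_hat(s1)`) gives
#' \deqn{(w'' \otimes v'') \frac{dC}{ds_1}
#'  + C' [ (I \otimes v') \frac{dw'}{ds_1} + (w' \otimes I)
#'    \frac{dv'}{ds_1} ]}
#' where `dC/ds1` vanishes whenever the derivative matrix `C` does not
#' depend on the resident structure (Cases 0-3), and `dw'/ds1`, `dv'/ds1`
#' follow by the chain rule through `dvecA'/ds1`.
#'
#' @param ctx a [sensitivity_context()] for the mutant matrix at the
#'   singular strategy.
#' @param C first derivative of `vec A'` in the mutant trait.
#' @param dvecA_ds1 derivative of `vec A'` in the *resident* trait (through
#'   `p_hat`), length `s^2`.
#' @param dC_ds1 derivative of `C` in the resident trait (length `s^2`);
#'   pass zeros when `C` is structurally constant in `p_hat`.
#' @param evd optionally precomputed [eigenvector_derivatives()].
#' @return the scalar mixed second derivative.
#' @export
d2lambda_mixed <- function(ctx, C, dvecA_ds1, dC_ds1 = NULL, evd = NULL) {
  stopifnot(inherits(ctx, "sensitivity_context"),
            length(C) == ctx$s^2, length(dvecA_ds1) == ctx$s^2)
  if (is.null(evd)) evd <- eigenvector_derivatives(ctx)
  s <- ctx$s
  tr <- ctx$triple
  I <- diag(s)
  dw_ds1 <- as.numeric(evd$dw_dvecA %*% dvecA_ds1)
  dv_ds1 <- as.numeric(evd$dv_dvecA %*% dvecA_ds1)
  term2 <- as.numeric(crossprod(
    C,
    kronecker(I, matrix(tr$v, ncol = 1)) %*% dw_ds1 +
      kronecker(matrix(tr$w, ncol = 1), I) %*% dv_ds1
  ))
  term1 <- if (is.null(dC_ds1)) 0 else
    as.numeric(crossprod(kronecker(tr$w, tr$v), dC_ds1))
  term1 + term2
}

#' Resident curvature from the singular-strategy identity
#'
#' At a singular strategy the three second derivatives of invasion fitness
#' satisfy `d2_mutant + 2*d2_mixed + d2_resident = 0`, so the resident
#' curvature `d2(lambda' - lambda)/d s1^2` follows from the other two
#' without differentiating the frequency-dependent resident eigenvalue
#' directly. Only valid where the selection gradient vanishes; the caller
#' must check that first.
#'
#' @param d2_mutant pure mutant second derivative.
#' @param d2_mixed mixed second derivative.
#' @return `-(d2_mutant + 2 * d2_mixed)`.
#' @export
resident_curvature_from_identity <- function(d2_mutant, d2_mixed) {
  -(d2_mutant + 2 * d2_mixed)
}
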