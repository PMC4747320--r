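test_that("vec, unvec and the commutation matrix interlock", {
  expect_equal(vec(matrix(c(1, 2, 3, 4), 2)), c(1, 2, 3, 4))
  set.seed(3)
  X <- matrix(rnorm(25), 5)
  expect_equal(unvec(vec(X), 5), X)
  expect_error(unvec(1:5, 2, 3), "m\\*n")

  expect_equal(commutation_matrix(1, 1), matrix(1, 1, 1))
  K22 <- commutation_matrix(2, 2)
  expect_equal(as.numeric(K22 %*% c(1, 2, 3, 4)), c(1, 3, 2, 4))
  for (dims in list(c(2, 3), c(3, 5))) {
    m <- dims[1]
    n <- dims[2]
    K <- commutation_matrix(m, n)
    # permutation matrix: single 1 per row and column
    expect_true(all(rowSums(K) == 1) && all(colSums(K) == 1))
    expect_true(all(K %in% c(0, 1)))
    expect_equal(t(K), commutation_matrix(n, m))
    Y <- matrix(rnorm(m * n), m, n)
    expect_equal(as.numeric(K %*% vec(Y)), vec(t(Y)))
  }
})

test_that("eigenvalue gradient matches structure and finite differences", {
  ctx <- sensitivity_context(diag(c(2, 1)))
  expect_equal(eigenvalue_gradient(ctx, rep(0, 4)), 0)
  # lambda = a11 locally: unit perturbation of entry (1,1) has gradient 1
  expect_equal(eigenvalue_gradient(ctx, c(1, 0, 0, 0)), 1)

  set.seed(5)
  for (i in 1:5) {
    mod <- fixture_model(100 + i)
    eq <- solve_equilibrium(mod, 0.5)
    ctx <- sensitivity_context(mod$A_mut(0.5, eq$p))
    C <- mod$dvecA_mut(0.5, eq$p)
    g_an <- eigenvalue_gradient(ctx, C)
    g_fd <- fd_gradient(mod, 0.5, eq)
    expect_lt(rel_err(g_an, g_fd, floor = 1e-6), 1e-5)
  }
})

test_that("eigenvector derivatives respect their normalisation constraints", {
  mod <- poor_case1(0.6, 0.4)
  eq <- solve_equilibrium(mod, 0.45)
  ctx <- sensitivity_context(mod$A_mut(0.45, eq$p))
  evd <- eigenvector_derivatives(ctx)
  s <- ctx$s
  # 1' dw = 0 columnwise (w stays on the simplex)
  expect_lt(max(abs(colSums(evd$dw_dvecA))), 1e-8)
  # d(v'w) = 0: v' dw + w' dv = 0
  expect_lt(max(abs(as.numeric(crossprod(ctx$triple$v, evd$dw_dvecA)) +
                      as.numeric(crossprod(ctx$triple$w, evd$dv_dvecA)))),
            1e-8)
})

test_that("eigenvector derivatives match entrywise finite differences", {
  mod <- poor_case1(0.6, 0.4)
  eq <- solve_equilibrium(mod, 0.45)
  A <- mod$A_mut(0.45, eq$p)
  ctx <- sensitivity_context(A)
  evd <- eigenvector_derivatives(ctx)
  s <- nrow(A)
  h <- 1e-6
  trip_of <- function(M) {
    e <- eigen(M)
    k <- which.max(Re(e$values))
    w <- Re(e$vectors[, k])
    w <- w / sum(w)
    eL <- eigen(t(M))
    kL <- which.max(Re(eL$values))
    v <- Re(eL$vectors[, kL])
    list(w = w, v = v / sum(v * w))
  }
  for (lin in c(7L, 10L, 22L, 25L)) { # a sample of matrix entries
    i <- (lin - 1L) %% s + 1L
    j <- (lin - 1L) %/% s + 1L
    Ap <- A
    Am <- A
    Ap[i, j] <- Ap[i, j] + h
    Am[i, j] <- Am[i, j] - h
    tp <- trip_of(Ap)
    tm <- trip_of(Am)
    dw_fd <- (tp$w - tm$w) / (2 * h)
    dv_fd <- (tp$v - tm$v) / (2 * h)
    expect_lt(max(abs(dw_fd - evd$dw_dvecA[, lin])), 1e-4 * (1 + max(abs(dw_fd))))
    expect_lt(max(abs(dv_fd - evd$dv_dvecA[, lin])), 1e-4 * (1 + max(abs(dv_fd))))
  }
})

test_that("the eigenvalue Hessian is symmetric and matches second differences", {
  # diagonal matrix: lambda = a11 is locally linear, so H[(1,1),(1,1)] = 0
  ctx0 <- sensitivity_context(diag(c(2, 1)))
  H0 <- lambda_hessian_wrt_A(ctx0)
  expect_equal(H0[1, 1], 0)

  mod <- productive_case1(0.6, 0.4)
  eq <- solve_equilibrium(mod, 0.55)
  A <- mod$A_mut(0.55, eq$p)
  ctx <- sensitivity_context(A)
  H <- lambda_hessian_wrt_A(ctx)
  expect_lt(max(abs(H - t(H))), 1e-10)

  s <- nrow(A)
  lam_of <- function(M) sexratioAD:::dominant_eigenvalue(M)
  h <- 1e-4
  # second difference along a random direction D: D' H D
  set.seed(9)
  for (rep in 1:3) {
    D <- matrix(stats::rnorm(s * s), s)
    D <- D / max(abs(D))
    quad_fd <- (lam_of(A + h * D) - 2 * lam_of(A) + lam_of(A - h * D)) / h^2
    quad_an <- as.numeric(crossprod(vec(D), H %*% vec(D)))
    expect_lt(abs(quad_fd - quad_an), 1e-4 * (1 + abs(quad_an)))
  }
})

test_that("analytic second derivatives match finite-difference oracles", {
  scenarios <- list(
    productive_case1(0.5, 0.5),
    poor_case1(0.65, 0.35),
    build_case_model(life_cycle_params("poor", mu_m2 = 0.7, mu_f2 = 0.3),
                     cost_model(3)),
    build_case_model(life_cycle_params("poor"),
                     cost_model(4, Dm = 0.7, Df = 0.3, c = 0.1)),
    four_stage_model(life_cycle_params("productive", mu_m1 = 0.8,
                                       mu_f1 = 0.2))
  )
  for (mod in scenarios) {
    s1 <- 0.45
    eq <- solve_equilibrium(mod, s1)
    ctx <- sensitivity_context(mod$A_mut(s1, eq$p))
    d2m <- d2lambda_mutant(ctx, mod$dvecA_mut(s1, eq$p),
                           mod$hvecA_mut(s1, eq$p))
    expect_lt(rel_err(d2m, fd_d2_mutant(mod, s1, eq), floor = 1e-3), 1e-4)
    sc <- stability_conditions(mod, s1)
    expect_lt(rel_err(sc$mixed_value, fd_d2_mixed(mod, s1), floor = 1e-3),
              1e-4)
  }
})

test_that("Case 3 mutant matrices are linear in the mutant trait", {
  mod <- build_case_model(life_cycle_params("poor", mu_m1 = 0.6, mu_f1 = 0.4),
                          cost_model(3))
  eq <- solve_equilibrium(mod, 0.5)
  expect_equal(mod$hvecA_mut(0.5, eq$p), rep(0, 25))
  # and so is Case 4 (the Case-4 trait enters T' linearly as well)
  mod4 <- build_case_model(life_cycle_params("poor"),
                           cost_model(4, Dm = 0.6, Df = 0.4, c = 0.1))
  expect_equal(mod4$hvecA_mut(0.5, eq$p), rep(0, 25))
})

test_that("the singular-strategy identity closes against an all-FD resident curvature", {
  mod <- poor_case1(0.65, 0.35)
  ss <- find_singular_strategy(mod, classify_ss = FALSE)
  sc <- stability_conditions(mod, ss$s1_star)
  d2res_fd <- fd_resident_curvature(mod, ss$s1_star)
  expect_lt(abs(sc$es_value + 2 * sc$mixed_value + d2res_fd), 1e-6)
  expect_equal(resident_curvature_from_identity(sc$es_value, sc$mixed_value),
               d2res_fd, tolerance = 1e-5)
  expect_equal(resident_curvature_from_identity(0, 0), 0)
  expect_equal(resident_curvature_from_identity(0, -0.46), 0.92)
})

test_that("derivatives scale linearly with an overall rescaling of A", {
  mod <- poor_case1(0.6, 0.4)
  s1 <- 0.48
  eq <- solve_equilibrium(mod, s1)
  base_ctx <- sensitivity_context(mod$A_mut(s1, eq$p))
  C <- mod$dvecA_mut(s1, eq$p)
  Hs <- mod$hvecA_mut(s1, eq$p)
  g0 <- eigenvalue_gradient(base_ctx, C)
  d0 <- d2lambda_mutant(base_ctx, C, Hs)
  for (k in c(0.5, 2)) {
    ctx_k <- sensitivity_context(k * mod$A_mut(s1, eq$p))
    expect_equal(eigenvalue_gradient(ctx_k, k * C), k * g0,
                 tolerance = 1e-10)
    expect_equal(d2lambda_mutant(ctx_k, k * C, k * Hs), k * d0,
                 tolerance = 1e-8)
  }
})
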