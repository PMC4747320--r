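# Shared fixtures and independent finite-difference oracles.
# The oracles deliberately avoid the analytic derivative code paths: they
# difference dominant eigenvalues (and equilibria) directly.

rel_err <- function(a, b, floor = 1) abs(a - b) / max(floor, abs(a), abs(b))

mutant_lambda <- function(model, y, p) {
  sexratioAD:::dominant_eigenvalue(model$A_mut(y, p))
}

# d lambda' / d s1' at fixed resident structure (central difference)
fd_gradient <- function(model, s1, eq = NULL, h = 1e-6) {
  if (is.null(eq)) eq <- solve_equilibrium(model, s1)
  (mutant_lambda(model, s1 + h, eq$p) -
      mutant_lambda(model, s1 - h, eq$p)) / (2 * h)
}

# d2 lambda' / d s1'^2 at fixed resident structure
fd_d2_mutant <- function(model, s1, eq = NULL, h = 1e-4) {
  if (is.null(eq)) eq <- solve_equilibrium(model, s1)
  (mutant_lambda(model, s1 + h, eq$p) - 2 * mutant_lambda(model, s1, eq$p) +
      mutant_lambda(model, s1 - h, eq$p)) / h^2
}

# d2 lambda' / d s1 d s1': difference the FD gradient (mutant trait frozen
# at s1) over the resident trait, through re-solved equilibria
fd_d2_mixed <- function(model, s1, h = 1e-4, hg = 1e-6) {
  G <- function(x) {
    e <- solve_equilibrium(model, x, tol = 1e-13)
    (mutant_lambda(model, s1 + hg, e$p) -
        mutant_lambda(model, s1 - hg, e$p)) / (2 * hg)
  }
  (G(s1 + h) - G(s1 - h)) / (2 * h)
}

# d2 (lambda' - lambda) / d s1^2 at fixed mutant trait s1, five-point
# stencil over high-accuracy equilibria
fd_resident_curvature <- function(model, s1, h = 5e-3) {
  sfun <- function(x) {
    e <- solve_equilibrium(model, x, tol = 1e-13)
    mutant_lambda(model, s1, e$p) - e$lambda
  }
  (-sfun(s1 + 2 * h) + 16 * sfun(s1 + h) - 30 * sfun(s1) +
      16 * sfun(s1 - h) - sfun(s1 - 2 * h)) / (12 * h^2)
}

# random interior model fixture for property tests
fixture_model <- function(seed, case = NULL) {
  config_to_model(generate_fixture(seed, case = case))
}

# reference models used across files
productive_case1 <- function(Cm = 0.5, Cf = 0.5) {
  build_case_model(life_cycle_params("productive"),
                   cost_model(1, Cm = Cm, Cf = Cf))
}
poor_case1 <- function(Cm = 0.5, Cf = 0.5) {
  build_case_model(life_cycle_params("poor"),
                   cost_model(1, Cm = Cm, Cf = Cf))
}

# independent trajectory oracle: integrate the abundance dynamics
# dn/dt = A(n) n directly and normalise
integrate_abundances <- function(model, s1, n0, tmax) {
  f <- function(n) {
    p <- n / sum(n)
    as.numeric(model$A_res(s1, p) %*% n)
  }
  sexratioAD:::.dp45(f, n0, tmax, rtol = 1e-10, atol = 1e-12)
}

integrate_frequencies <- function(model, s1, p0, tmax) {
  f <- function(p) frequency_dynamics(model, s1, pmax(p, 0))
  sexratioAD:::.dp45(f, p0, tmax, rtol = 1e-10, atol = 1e-12)
}
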