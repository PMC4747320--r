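test_that("closed-form cost baselines evaluate as printed", {
  expect_equal(average_cost(0, 0.7, 0.3), 0.3)
  expect_equal(average_cost(1, 0.7, 0.3), 0.7)
  expect_equal(average_cost(0.5, 0.7, 0.3), 0.5)

  expect_equal(equal_investment_ss(1, 1), 0.5)
  expect_equal(equal_investment_ss(2, 1), 1 / 3)
  expect_equal(equal_investment_ss(0.7, 0.3), 0.3) # Cm + Cf = 1 gives Cf
  expect_error(equal_investment_ss(0, 0))

  expect_equal(expected_investment_cost(1, 0, 0.5), 2) # mu -> 0 limit I/alpha
  expect_equal(expected_investment_cost(1, 1, 0.5), 1 - exp(-2))
  # declines with mortality: dying offspring consume less investment
  grid <- seq(0.05, 2, length.out = 20)
  costs <- expected_investment_cost(1, grid, 0.5)
  expect_true(all(diff(costs) < 0))
  expect_error(expected_investment_cost(1, 0.5, 0), "alpha")
})

test_that("parental reproduction costs and mated mortality follow Case 4", {
  pc <- parental_costs(1.2, 0.8, 10, 0.3, 0.5, 0.5)
  expect_equal(pc$Em, 1.2 * 10 * 0.5) # Dm = Df: mix independent of s1
  expect_equal(pc$Ef, 0.8 * 10 * 0.5)
  expect_equal(parental_costs(1.2, 0.8, 10, 1, 0.7, 0.1)$Em, 1.2 * 10 * 0.7)
  mm <- mated_mortality(0.1, 0.2, 0, 3, 4)
  expect_equal(c(mm$mu_m2c, mm$mu_f2c), c(0.1, 0.2)) # c = 0: no cost
  mm <- mated_mortality(0.1, 0.2, 0.5, 3, 4)
  expect_equal(c(mm$mu_m2c, mm$mu_f2c), c(1.6, 2.2))
})

test_that("case models reduce to one another at their boundaries", {
  params <- life_cycle_params("poor")
  p <- c(0.3, 0.15, 0.25, 0.2, 0.1)
  # Case 0 is Case 1 with equal costs
  A0 <- build_case_model(params, cost_model(0))$A_res(0.4, p)
  A1 <- build_case_model(params, cost_model(1, Cm = 1, Cf = 1))$A_res(0.4, p)
  expect_equal(A0, A1)
  # Case 3 has Ca = 1: birth entries R*s1 and R*(1-s1)
  m3 <- build_rate_matrices(params, cost_model(3), 0.3, p)
  expect_equal(m3$B["m1", "u"], 10 * 0.3)
  expect_equal(m3$B["f1", "u"], 10 * 0.7)
  # Case 4 with c = 0 reproduces the Case 3 matrices exactly
  A3 <- build_case_model(params, cost_model(3))$A_res(0.4, p)
  A4 <- build_case_model(params,
                         cost_model(4, Dm = 0.9, Df = 0.1, c = 0))$A_res(0.4, p)
  expect_equal(A3, A4)
})

test_that("resource-cost identity v_m1/v_f1 = Cm/Cf holds at the SS (Cases 1-2)", {
  # Case 1 over a (Cm, Cf) grid, both presets
  for (preset in c("productive", "poor")) {
    for (Cm in c(0.25, 0.4, 0.5, 0.6, 0.75)) {
      mod <- build_case_model(life_cycle_params(preset),
                              cost_model(1, Cm = Cm, Cf = 1 - Cm))
      ss <- find_singular_strategy(mod, classify_ss = FALSE)
      rv <- rv_ratio_at_ss(mod, ss$s1_star)
      expect_lt(rv$identity_residual, 1e-5)
      expect_equal(rv$ratio, Cm / (1 - Cm), tolerance = 1e-5)
    }
  }
  # Case 2: costs from the investment-mortality integral
  for (mu_m1 in c(0.3, 0.5, 0.7)) {
    params <- life_cycle_params("poor", mu_m1 = mu_m1, mu_f1 = 1 - mu_m1)
    mod <- build_case_model(params, cost_model(2, I = 1))
    ss <- find_singular_strategy(mod, classify_ss = FALSE)
    rv <- rv_ratio_at_ss(mod, ss$s1_star)
    cc <- sexratioAD:::resolve_costs(params, mod$cost)
    expect_lt(rv$identity_residual, 1e-5)
    expect_equal(rv$ratio, cc$Cm / cc$Cf, tolerance = 1e-5)
  }
})

test_that("after-investment mortality leaves the RV ratio at one half (Case 3)", {
  splits <- c(0.2, 0.35, 0.65, 0.8)
  for (x in splits) {
    for (which_stage in c("juvenile", "adult")) {
      params <- if (which_stage == "juvenile") {
        life_cycle_params("poor", mu_m1 = x, mu_f1 = 1 - x)
      } else {
        life_cycle_params("poor", mu_m2 = x, mu_f2 = 1 - x)
      }
      mod <- build_case_model(params, cost_model(3))
      ss <- find_singular_strategy(mod, classify_ss = FALSE)
      rv <- rv_ratio_at_ss(mod, ss$s1_star)
      expect_lt(rv$identity_residual / (1 + rv$ratio), 1e-5)
      expect_equal(rv$normalized, 0.5, tolerance = 1e-5)
    }
  }
})

test_that("the Case 4 reproductive-value relation holds and collapses as c -> 0", {
  defects <- vapply(c(0.2, 0.1, 0.05, 0.01), function(cc) {
    mod <- build_case_model(life_cycle_params("poor"),
                            cost_model(4, Dm = 0.7, Df = 0.3, c = cc))
    ss <- find_singular_strategy(mod, classify_ss = FALSE)
    rv <- rv_ratio_at_ss(mod, ss$s1_star)
    expect_lt(rv$identity_residual, 1e-5)
    # deviation of the ratio from 1 shrinks with c
    abs(rv$ratio - 1)
  }, numeric(1))
  expect_true(all(diff(defects) < 0))
})

test_that("the 4-stage no-union model conserves births and restores s1* = 0.5", {
  params <- life_cycle_params("productive", mu_m1 = 0.8, mu_f1 = 0.2)
  mod <- four_stage_model(params)
  p <- c(0.3, 0.25, 0.25, 0.2)
  A <- mod$A_res(0.4, p)
  # total birth rate Fm*m2 + Ff*f2 = R*M(p)
  births <- 3 * (A[1, 2] + A[3, 2]) * p[2] + 3 * (A[1, 4] + A[3, 4]) * p[4]
  expect_equal(births, params$R * mating_rates(p)$M)
  # symmetric adults: equal per-capita fertilities
  psym <- c(0.3, 0.22, 0.26, 0.22)
  Asym <- mod$A_res(0.5, psym)
  expect_equal(Asym[1, 2] + Asym[3, 2], Asym[1, 4] + Asym[3, 4])

  for (biased in list(c("mu_m1", "mu_f1"), c("mu_m2", "mu_f2"))) {
    args <- stats::setNames(list(0.8, 0.2), biased)
    pr <- do.call(life_cycle_params, c(list(preset = "productive"), args))
    ss <- find_singular_strategy(four_stage_model(pr))
    expect_lt(abs(ss$s1_star - 0.5), 1e-6)
    expect_lt(ss$convergence_value, 0)
  }
})

test_that("Case 1 sweeps are monotone and poor unions overshoot the baseline", {
  grid <- seq(0.1, 0.9, by = 0.1)
  tab <- sweep_case(1, grid, params = life_cycle_params("poor"))
  expect_true(all(tab$converged))
  expect_true(all(diff(tab$s1_star) < 0)) # dearer males, fewer sons
  expect_equal(tab$baseline_equal_investment, 1 - grid)
  # deviations lie on the cheaper-sex side of the equal-investment value
  dev <- tab$s1_star - tab$baseline_equal_investment
  expect_true(all(dev[grid > 0.5] < 1e-9)) # males dear: even fewer sons
  expect_true(all(dev[grid < 0.5] > -1e-9)) # females dear: even more sons
  expect_lt(abs(tab$s1_star[grid == 0.5] - 0.5), 1e-6)
  # es ~ 0, convergence < 0 everywhere (neutral attractors)
  expect_true(all(abs(tab$es_value) < 1e-6))
  expect_true(all(tab$convergence_value < 0))
})

test_that("Case 2: primary favours the high-mortality sex, secondary less biased", {
  tab <- sweep_case(2, c(0.6, 0.7, 0.8), params = life_cycle_params("poor"))
  expect_true(all(tab$converged))
  expect_true(all(tab$s1_star > 0.5)) # pricier daughters, more sons born
  expect_true(all(tab$s2_star < tab$s1_star)) # sons die before maturity
  expect_true(all(abs(tab$s2_star - 0.5) < abs(tab$s1_star - 0.5)))
})

test_that("Case 3 adult mortality favours the rarer dying sex; s2 the survivor", {
  tab <- sweep_case(3, c(0.6, 0.7, 0.8), params = life_cycle_params("poor"),
                    swept = "mu_m2")
  expect_true(all(tab$converged))
  expect_true(all(tab$s1_star > 0.5)) # widowed females re-mate: sons pay off
  expect_true(all(tab$s2_star < 0.5)) # but adult males still die faster
  expect_true(all(abs(tab$es_value) < 1e-6))
  expect_true(all(tab$convergence_value < 0))
})

test_that("Case 4 favours the sex that spares its parents", {
  tab <- sweep_case(4, c(0.3, 0.5, 0.7), params = life_cycle_params("poor"))
  expect_true(all(tab$converged))
  expect_lt(tab$s1_star[3], 0.5) # sons costly to parents: fewer sons
  expect_gt(tab$s1_star[1], 0.5)
  expect_lt(abs(tab$s1_star[2] - 0.5), 1e-6)
  expect_true(all(tab$convergence_value < 0))
})
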