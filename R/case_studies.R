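#' Primary reproductive-value ratio and its case identity at a singular
#' strategy
#'
#' At a singular strategy the vanishing selection gradient pins down a
#' relationship between the juvenile male and female reproductive values
#' `v_m1`, `v_f1` (entries of the dominant left eigenvector of the resident
#' projection matrix at equilibrium):
#'
#' * Cases 1-2 (resource costs, with Case 2 costs from
#'   [expected_investment_cost()]): `v_m1 / v_f1 = Cm / Cf`.
#' * Case 3 (mortality after investment): `v_m1 = v_f1`, i.e. the
#'   normalised ratio `v_m1 / (v_m1 + v_f1)` is 0.5 regardless of the
#'   mortality bias.
#' * Case 4 (parental mortality): `v_m1 = v_f1 + c (Df - Dm) *
#'   (Uf v_m2 + Um v_f2 - (Um + Uf) v_u)`, collapsing to Case 3 as
#'   `c -> 0`.
#'
#' The function computes the ratio and the absolute defect of the
#' applicable identity, a strong internal consistency check on the whole
#' pipeline (equilibrium, eigenvectors, and the singular strategy itself).
#'
#' @param model a 5-stage `sexratio_model`.
#' @param s1_star the singular strategy (from [find_singular_strategy()]).
#' @return list with `ratio` (`v_m1 / v_f1`), `normalized`
#'   (`v_m1 / (v_m1 + v_f1)`), and `identity_residual`.
#' @export
rv_ratio_at_ss <- function(model, s1_star) {
  if (model$s != 5L) stop("reproductive-value identities apply to the 5-stage model",
                          call. = FALSE)
  eq <- solve_equilibrium(model, s1_star)
  trip <- eigen_triple(eq$A)
  v <- trip$v
  if (v[3] == 0) stop("v_f1 = 0: ratio undefined", call. = FALSE)
  ratio <- v[1] / v[3]
  case <- model$cost$case_id
  cc <- resolve_costs(model$params, model$cost)
  residual <- if (case %in% c(0L, 1L, 2L)) {
    abs(ratio - cc$Cm / cc$Cf)
  } else if (case == 3L) {
    abs(v[1] - v[3])
  } else { # case 4
    mr <- mating_rates(eq$p)
    rhs <- v[3] + model$cost$c * (model$cost$Df - model$cost$Dm) *
      (mr$Uf * v[2] + mr$Um * v[4] - (mr$Um + mr$Uf) * v[5])
    abs(v[1] - rhs)
  }
  list(ratio = ratio, normalized = v[1] / (v[1] + v[3]),
       identity_residual = residual)
}

# complement constraint used by the published sweeps: the swept parameter x
# and its opposite-sex partner satisfy partner = 1 - x
.sweep_build <- function(case_id, swept, value, params, four_stage = FALSE) {
  stopifnot(value >= 0, value <= 1)
  fields <- c("mu_m1", "mu_f1", "mu_m2", "mu_f2",
              "alpha_m", "alpha_f", "d", "R")
  p <- unclass(params)[fields]
  preset <- attr(params, "preset")
  mk_params <- function(...) {
    ov <- list(...)
    for (nm in names(ov)) p[[nm]] <- ov[[nm]]
    do.call(life_cycle_params, c(list(preset = NULL), p))
  }
  if (four_stage) {
    pr <- switch(swept,
                 mu_m1 = mk_params(mu_m1 = value, mu_f1 = 1 - value),
                 mu_m2 = mk_params(mu_m2 = value, mu_f2 = 1 - value),
                 stop("four-stage sweeps vary mu_m1 or mu_m2", call. = FALSE))
    attr(pr, "preset") <- preset
    return(four_stage_model(pr))
  }
  switch(as.character(case_id),
         "1" = build_case_model(params, cost_model(1, Cm = value,
                                                   Cf = 1 - value)),
         "2" = {
           pr <- mk_params(mu_m1 = value, mu_f1 = 1 - value)
           attr(pr, "preset") <- preset
           build_case_model(pr, cost_model(2, I = 1))
         },
         "3" = {
           pr <- if (swept == "mu_m2") mk_params(mu_m2 = value,
                                                 mu_f2 = 1 - value)
           else mk_params(mu_m1 = value, mu_f1 = 1 - value)
           attr(pr, "preset") <- preset
           build_case_model(pr, cost_model(3))
         },
         "4" = build_case_model(params, cost_model(4, Dm = value,
                                                   Df = 1 - value,
                                                   c = if (is.null(params$c4)) 0.1 else params$c4)),
         stop("sweeps are defined for cases 1-4", call. = FALSE))
}

#' Sweep a cost parameter and track the singular strategy
#'
#' Rebuilds the model across a grid of the swept parameter, applying the
#' complement constraint used in the published analyses (the opposite-sex
#' value is one minus the swept value: `Cf = 1 - Cm`, `mu_f1 = 1 - mu_m1`,
#' `mu_f2 = 1 - mu_m2`, `Df = 1 - Dm`), and records the singular strategy
#' with its stability values, secondary sex ratio, reproductive-value
#' ratio, and the equal-investment baseline. Per-point failures are
#' flagged, not fatal.
#'
#' @param case_id cost case in `1:4`.
#' @param values grid of the swept parameter (each in `[0, 1]`).
#' @param params baseline [life_cycle_params()].
#' @param swept which parameter varies: `"Cm"` (Case 1), `"mu_m1"`
#'   (Cases 2-3), `"mu_m2"` (Case 3 adult), `"Dm"` (Case 4).
#' @param four_stage sweep the 4-stage no-union model instead (only
#'   mortality sweeps apply).
#' @param c4 Case 4 mortality scaling constant.
#' @return a data.frame with one row per grid point: `case`, `preset`,
#'   `swept_param`, `value`, `s1_star`, `s2_star`, `rv_ratio`, `es_value`,
#'   `convergence_value`, `baseline_equal_investment`, `converged`.
#' @export
sweep_case <- function(case_id, values, params = life_cycle_params("poor"),
                       swept = NULL, four_stage = FALSE, c4 = 0.1) {
  if (is.null(swept)) {
    swept <- switch(as.character(case_id),
                    "1" = "Cm", "2" = "mu_m1", "3" = "mu_m1", "4" = "Dm")
  }
  params$c4 <- c4
  rows <- lapply(values, function(x) {
    row <- data.frame(
      case = if (four_stage) "four-stage" else as.character(case_id),
      preset = if (is.null(attr(params, "preset"))) NA_character_
      else attr(params, "preset"),
      swept_param = swept, value = x, s1_star = NA_real_,
      s2_star = NA_real_, rv_ratio = NA_real_, es_value = NA_real_,
      convergence_value = NA_real_,
      baseline_equal_investment = NA_real_, converged = FALSE,
      stringsAsFactors = FALSE
    )
    mod <- tryCatch(
      .sweep_build(case_id, swept, x, params, four_stage),
      error = function(e) NULL
    )
    if (is.null(mod)) return(row)
    row$baseline_equal_investment <- .sweep_baseline(case_id, swept, x, mod)
    ss <- tryCatch(find_singular_strategy(mod), error = function(e) NULL)
    if (is.null(ss) || !inherits(ss, "ss_report")) return(row)
    row$s1_star <- ss$s1_star
    row$s2_star <- ss$s2_star
    row$rv_ratio <- ss$rv_ratio
    row$es_value <- ss$es_value
    row$convergence_value <- ss$convergence_value
    row$converged <- TRUE
    row
  })
  do.call(rbind, rows)
}

.sweep_baseline <- function(case_id, swept, x, mod) {
  if (case_id == 1) return(equal_investment_ss(x, 1 - x))
  if (case_id == 2) {
    cc <- resolve_costs(mod$params, mod$cost)
    return(equal_investment_ss(cc$Cm, cc$Cf))
  }
  if (case_id == 4 && swept == "Dm") return(equal_investment_ss(x, 1 - x))
  0.5 # unit resource costs
}
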