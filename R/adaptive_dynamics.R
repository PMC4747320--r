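#' Invasion fitness of a mutant sex ratio
#'
#' The long-term growth advantage `s_x(y) = lambda'(p_hat) - lambda` of a
#' rare mutant playing sex ratio `y = s1_mut` in the equilibrium
#' environment set by a resident playing `x = s1_res`: the mutant
#' projection matrix freezes the mating rates (and, in Case 4, the
#' per-capita mating rates entering the parental costs) at the resident
#' equilibrium stage distribution, while its birth allocation (and Case 4
#' mated mortalities) use the mutant sex ratio. Identical traits give zero
#' fitness.
#'
#' @param model a `sexratio_model`.
#' @param s1_res resident primary sex ratio.
#' @param s1_mut mutant primary sex ratio.
#' @param eq optionally a precomputed resident [solve_equilibrium()].
#' @return the scalar invasion fitness.
#' @export
invasion_fitness <- function(model, s1_res, s1_mut, eq = NULL) {
  if (s1_mut < 0 || s1_mut > 1) stop("s1_mut must lie in [0, 1]",
                                     call. = FALSE)
  if (is.null(eq)) eq <- solve_equilibrium(model, s1_res)
  Amut <- model$A_mut(s1_mut, eq$p)
  dominant_eigenvalue(Amut) - eq$lambda
}

#' Selection gradient on the primary sex ratio
#'
#' The derivative of invasion fitness in the mutant trait, evaluated at the
#' resident (`d lambda'/d s1'` at `s1' = s1`), computed analytically via
#' eigenvalue perturbation: `(w'' %x% v'') dvecA'/ds1'` at the resident
#' equilibrium. Its zeros are the singular strategies.
#'
#' @param model a `sexratio_model`.
#' @param s1 resident primary sex ratio (interior of `[0, 1]`).
#' @param eq optionally a precomputed resident equilibrium.
#' @return the scalar selection gradient.
#' @export
selection_gradient <- function(model, s1, eq = NULL) {
  if (is.null(eq)) eq <- solve_equilibrium(model, s1)
  Amut <- model$A_mut(s1, eq$p) # equals the resident matrix at s1' = s1
  ctx <- sensitivity_context(Amut)
  eigenvalue_gradient(ctx, model$dvecA_mut(s1, eq$p))
}

#' Second-derivative stability conditions at a singular strategy
#'
#' Evaluates, at a singular strategy `s1*`, the pure mutant second
#' derivative of invasion fitness (the evolutionary-stability quantity),
#' the mixed mutant-resident second derivative, the convergence-stability
#' quantity (their sum: negative means the strategy attracts), and the
#' resident curvature recovered from the singular-strategy identity.
#' The resident-structure sensitivity `d p_hat / d s1` is obtained by
#' central finite differences of [solve_equilibrium()] with step `h`; all
#' other ingredients are analytic.
#'
#' @param model a `sexratio_model`.
#' @param s1_star the singular strategy.
#' @param h finite-difference step for the resident-equilibrium
#'   sensitivity.
#' @return list with `es_value` (pure mutant), `mixed_value`,
#'   `convergence_value` (`es_value + mixed_value`), `resident_value`
#'   (from the identity), and the underlying `eq` and `triple`.
#' @export
stability_conditions <- function(model, s1_star, h = 1e-5) {
  eq <- solve_equilibrium(model, s1_star)
  Amut <- model$A_mut(s1_star, eq$p)
  ctx <- sensitivity_context(Amut)
  evd <- eigenvector_derivatives(ctx)
  H_lambda <- lambda_hessian_wrt_A(ctx, evd)
  C <- model$dvecA_mut(s1_star, eq$p)
  Hs <- model$hvecA_mut(s1_star, eq$p)
  d2_mut <- d2lambda_mutant(ctx, C, Hs, H_lambda)

  # resident-trait dependence enters only through p_hat(s1); the +/- h
  # equilibria are solved to near machine precision so that the O(tol/h)
  # differencing error stays well below the identity tolerances
  hh <- min(h, s1_star / 2, (1 - s1_star) / 2)
  eq_p <- solve_equilibrium(model, s1_star + hh, tol = 1e-13)
  eq_m <- solve_equilibrium(model, s1_star - hh, tol = 1e-13)
  dvecA_ds1 <- (vec(model$A_mut(s1_star, eq_p$p)) -
                  vec(model$A_mut(s1_star, eq_m$p))) / (2 * hh)
  dC_ds1 <- if (model$C_const_in_p) NULL else
    (model$dvecA_mut(s1_star, eq_p$p) -
       model$dvecA_mut(s1_star, eq_m$p)) / (2 * hh)
  d2_mix <- d2lambda_mixed(ctx, C, dvecA_ds1, dC_ds1, evd)

  list(es_value = d2_mut,
       mixed_value = d2_mix,
       convergence_value = d2_mut + d2_mix,
       resident_value = resident_curvature_from_identity(d2_mut, d2_mix),
       eq = eq, triple = ctx$triple)
}

.stability_labels <- function(es_value, convergence_value,
                              neutral_tol = 1e-4) {
  band <- neutral_tol * (1 + abs(convergence_value))
  es_label <- if (es_value < -band) "ESS"
  else if (es_value > band) "branching-point"
  else "weak-form-ESS (selectively neutral)"
  convergence_label <- if (convergence_value < 0) "attractor" else "repeller"
  list(es_label = es_label, convergence_label = convergence_label)
}

#' Classify a singular strategy
#'
#' Labels a verified singular strategy by evolutionary stability (sign of
#' the pure mutant second derivative, with a neutrality band
#' `|es| < 1e-4 * (1 + |convergence|)` for the selectively neutral
#' weak-form ESS that this model class typically produces) and by
#' convergence stability (sign of the convergence quantity: negative is an
#' attractor, positive a repeller). Refuses to classify a point where the
#' selection gradient does not vanish.
#'
#' @param model a `sexratio_model`.
#' @param s1_star candidate singular strategy.
#' @param gradient_tol tolerance on `|selection gradient|` at `s1_star`.
#' @param neutral_tol relative half-width of the neutrality band.
#' @return list with `es_value`, `convergence_value`, `es_label`,
#'   `convergence_label`, `mixed_value`, `resident_value`.
#' @export
classify <- function(model, s1_star, gradient_tol = 1e-6,
                     neutral_tol = 1e-4) {
  g <- selection_gradient(model, s1_star)
  if (abs(g) > gradient_tol) {
    stop(sprintf(
      "selection gradient at s1 = %.8f is %.3e (> %.1e): not singular",
      s1_star, g, gradient_tol), call. = FALSE)
  }
  sc <- stability_conditions(model, s1_star)
  lab <- .stability_labels(sc$es_value, sc$convergence_value, neutral_tol)
  c(sc[c("es_value", "mixed_value", "convergence_value", "resident_value")],
    lab)
}

#' Locate the singular primary sex ratio
#'
#' Scans the analytic selection gradient on a grid over `bracket`, brackets
#' sign changes, and bisects each to a root with `stats::uniroot`. Returns
#' a report containing the singular strategy, its stability classification,
#' the secondary sex ratio and the primary reproductive-value ratio at the
#' singular point. If the gradient never changes sign on the bracket, a
#' `no_interior_ss` result describing the boundary behaviour is returned
#' rather than a fabricated root.
#'
#' @param model a `sexratio_model`.
#' @param bracket search interval, default `c(0.01, 0.99)`.
#' @param n_scan number of grid points for the initial scan.
#' @param gradient_tol required `|gradient|` at the reported root.
#' @param classify_ss also evaluate the second-derivative conditions.
#' @return an object of class `ss_report` (fields `s1_star`,
#'   `gradient_residual`, `es_value`, `convergence_value`, `es_label`,
#'   `convergence_label`, `s2_star`, `rv_ratio`, `lambda`, `all_roots`), or
#'   of class `no_interior_ss`.
#' @export
find_singular_strategy <- function(model, bracket = c(0.01, 0.99),
                                   n_scan = 25, gradient_tol = 1e-8,
                                   classify_ss = TRUE) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2],
            bracket[1] >= 0, bracket[2] <= 1)
  grid <- seq(bracket[1], bracket[2], length.out = n_scan)
  g <- numeric(n_scan)
  active <- logical(n_scan) # equilibrium actually reproduces?
  for (i in seq_len(n_scan)) {
    eq <- tryCatch(solve_equilibrium(model, grid[i]),
                   error = function(e) NULL)
    if (is.null(eq)) next # scan point unusable (e.g. glacial convergence)
    g[i] <- selection_gradient(model, grid[i], eq = eq)
    # at a collapsed (single-sex) equilibrium no matings occur and the
    # gradient is trivially zero; such points are not singular strategies
    active[i] <- mating_rates(eq$p)$M > 1e-10
  }

  roots <- numeric(0)
  for (i in seq_len(n_scan - 1L)) {
    if (!active[i] || !active[i + 1L]) next
    gi <- g[i]
    gj <- g[i + 1L]
    if (abs(gi) < 1e-13) {
      roots <- c(roots, grid[i])
    } else if (gi * gj < 0) {
      r <- stats::uniroot(function(x) selection_gradient(model, x),
                          lower = grid[i], upper = grid[i + 1L],
                          f.lower = gi, f.upper = gj, tol = 1e-12)
      roots <- c(roots, r$root)
    }
  }
  if (active[n_scan] && abs(g[n_scan]) < 1e-13) roots <- c(roots, grid[n_scan])
  roots <- unique(roots)

  if (length(roots) == 0L) {
    return(structure(
      list(bracket = bracket,
           gradient_sign = sign(g[1]),
           monotone = all(sign(g) == sign(g[1])),
           boundary = if (g[1] < 0) "selection pushes s1 toward the lower boundary"
           else "selection pushes s1 toward the upper boundary",
           grid = grid, gradient = g),
      class = "no_interior_ss"
    ))
  }

  s1_star <- roots[1]
  g_res <- selection_gradient(model, s1_star)
  if (abs(g_res) > gradient_tol) {
    # polish by bisection on a shrinking interval around the root
    lo <- max(bracket[1], s1_star - 1e-6)
    hi <- min(bracket[2], s1_star + 1e-6)
    glo <- selection_gradient(model, lo)
    ghi <- selection_gradient(model, hi)
    if (glo * ghi < 0) {
      r <- stats::uniroot(function(x) selection_gradient(model, x),
                          lower = lo, upper = hi, f.lower = glo,
                          f.upper = ghi, tol = .Machine$double.eps)
      s1_star <- r$root
      g_res <- selection_gradient(model, s1_star)
    }
  }

  eq <- solve_equilibrium(model, s1_star)
  trip <- eigen_triple(eq$A)
  rv <- trip$v[1] / trip$v[3] # v_m1 / v_f1

  out <- list(s1_star = s1_star, gradient_residual = g_res,
              es_value = NA_real_, convergence_value = NA_real_,
              mixed_value = NA_real_, resident_value = NA_real_,
              es_label = NA_character_, convergence_label = NA_character_,
              s2_star = secondary_sex_ratio(eq$p), rv_ratio = rv,
              lambda = eq$lambda, all_roots = roots, model_label = model$label)
  if (classify_ss) {
    sc <- stability_conditions(model, s1_star)
    lab <- .stability_labels(sc$es_value, sc$convergence_value)
    out$es_value <- sc$es_value
    out$mixed_value <- sc$mixed_value
    out$convergence_value <- sc$convergence_value
    out$resident_value <- sc$resident_value
    out$es_label <- lab$es_label
    out$convergence_label <- lab$convergence_label
  }
  structure(out, class = "ss_report")
}

#' @export
print.ss_report <- function(x, ...) {
  cat("Singular strategy report — ", x$model_label, "\n", sep = "")
  cat(sprintf("  s1* = %.8f  (|gradient| = %.2e)\n",
              x$s1_star, abs(x$gradient_residual)))
  if (!is.na(x$es_value)) {
    cat(sprintf("  evolutionary stability value  = %+.6f  [%s]\n",
                x$es_value, x$es_label))
    cat(sprintf("  convergence stability value   = %+.6f  [%s]\n",
                x$convergence_value, x$convergence_label))
  }
  cat(sprintf("  s2* = %.6f,  v_m1/v_f1 = %.6f,  lambda = %.6f\n",
              x$s2_star, x$rv_ratio, x$lambda))
  invisible(x)
}

#' @export
print.no_interior_ss <- function(x, ...) {
  cat("No interior singular strategy on [",
      x$bracket[1], ", ", x$bracket[2], "]\n", sep = "")
  cat("  ", x$boundary, "\n", sep = "")
  invisible(x)
}

#' Pairwise invasion plot grid
#'
#' Evaluates invasion fitness on a resident x mutant grid. The resident
#' equilibrium is computed once per resident value and reused along the
#' mutant axis (a rare mutant does not perturb the resident equilibrium).
#' The sign matrix applies a zero band `|fitness| < zero_tol`. Cells whose
#' resident equilibrium fails are recorded as `NA`, not fatal.
#'
#' @param model a `sexratio_model`.
#' @param n_grid number of grid points per axis (at least 11).
#' @param grid_range range of both axes inside `[0, 1]`.
#' @param zero_tol half-width of the sign zero band.
#' @return an object of class `pip_grid`: list with `resident_values`,
#'   `mutant_values`, `fitness` (mutants in rows, residents in columns) and
#'   `sign`.
#' @export
pairwise_invasion_plot <- function(model, n_grid = 21,
                                   grid_range = c(0.01, 0.99),
                                   zero_tol = 1e-8) {
  if (n_grid < 11) stop("n_grid must be at least 11", call. = FALSE)
  res_vals <- seq(grid_range[1], grid_range[2], length.out = n_grid)
  mut_vals <- res_vals
  fit <- matrix(NA_real_, n_grid, n_grid,
                dimnames = list(mutant = sprintf("%.4f", mut_vals),
                                resident = sprintf("%.4f", res_vals)))
  for (j in seq_len(n_grid)) {
    eq <- tryCatch(solve_equilibrium(model, res_vals[j]),
                   error = function(e) NULL)
    if (is.null(eq)) next
    for (i in seq_len(n_grid)) {
      fit[i, j] <- invasion_fitness(model, res_vals[j], mut_vals[i], eq = eq)
    }
  }
  sg <- matrix(0L, n_grid, n_grid, dimnames = dimnames(fit))
  sg[fit > zero_tol] <- 1L
  sg[fit < -zero_tol] <- -1L
  sg[is.na(fit)] <- NA_integer_
  structure(list(resident_values = res_vals, mutant_values = mut_vals,
                 fitness = fit, sign = sg, zero_tol = zero_tol),
            class = "pip_grid")
}

#' @export
print.pip_grid <- function(x, ...) {
  cat(sprintf("Pairwise invasion plot grid: %d x %d on [%.3f, %.3f]\n",
              length(x$mutant_values), length(x$resident_values),
              min(x$resident_values), max(x$resident_values)))
  cat(sprintf("  %d cells positive, %d negative, %d neutral, %d missing\n",
              sum(x$sign == 1L, na.rm = TRUE),
              sum(x$sign == -1L, na.rm = TRUE),
              sum(x$sign == 0L, na.rm = TRUE),
              sum(is.na(x$sign))))
  invisible(x)
}

#' Convert a PIP grid to long format
#'
#' @param pip a `pip_grid`.
#' @return a data.frame with columns `resident`, `mutant`, `fitness`,
#'   `sign`.
#' @export
pip_as_data_frame <- function(pip) {
  stopifnot(inherits(pip, "pip_grid"))
  data.frame(
    resident = rep(pip$resident_values, each = length(pip$mutant_values)),
    mutant = rep(pip$mutant_values, times = length(pip$resident_values)),
    fitness = as.numeric(pip$fitness),
    sign = as.integer(pip$sign)
  )
}
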