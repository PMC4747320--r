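#' Life-cycle parameters for the two-sex model
#'
#' Bundles the demographic rates of the 5-stage (or 4-stage) life cycle:
#' sex-specific juvenile and adult mortality rates, maturation rates, the
#' union divorce rate, and the total resource investment rate. All rates are
#' per unit time and must be non-negative and finite.
#'
#' Two named presets are available. `"productive"` unions are persistent
#' (divorce rate `d = 0`) and invest heavily in offspring (`R = 20`);
#' `"poor"` unions are transient (`d = 1`) with `R = 10`. Both use
#' mortalities of 0.1 and maturation rates of 0.5 for each sex. Individual
#' fields can be overridden on top of a preset.
#'
#' @param preset optional preset name, `"productive"` or `"poor"`.
#' @param mu_m1,mu_f1 juvenile male / female mortality rates.
#' @param mu_m2,mu_f2 adult male / female mortality rates.
#' @param alpha_m,alpha_f male / female maturation rates.
#' @param d union divorce rate (dissolution rate of a pair bond).
#' @param R total resource investment rate (resources per unit time a union
#'   commits to offspring production).
#'
#' @return an object of class `life_cycle_params` (a named list with the
#'   eight rate fields and a `preset` attribute).
#' @examples
#' life_cycle_params("productive")
#' life_cycle_params("poor", mu_m1 = 0.7, mu_f1 = 0.3)
#' @export
life_cycle_params <- function(preset = NULL,
                              mu_m1 = NULL, mu_f1 = NULL,
                              mu_m2 = NULL, mu_f2 = NULL,
                              alpha_m = NULL, alpha_f = NULL,
                              d = NULL, R = NULL) {
  base <- list(mu_m1 = 0.1, mu_f1 = 0.1, mu_m2 = 0.1, mu_f2 = 0.1,
               alpha_m = 0.5, alpha_f = 0.5, d = 0, R = 20)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("productive", "poor"))
    if (preset == "poor") {
      base$R <- 10
      base$d <- 1
    }
  }
  override <- list(mu_m1 = mu_m1, mu_f1 = mu_f1, mu_m2 = mu_m2,
                   mu_f2 = mu_f2, alpha_m = alpha_m, alpha_f = alpha_f,
                   d = d, R = R)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) base[[nm]] <- override[[nm]]
  }
  validate_life_cycle_params(base)
  structure(base, preset = preset, class = "life_cycle_params")
}

validate_life_cycle_params <- function(x) {
  fields <- c("mu_m1", "mu_f1", "mu_m2", "mu_f2",
              "alpha_m", "alpha_f", "d", "R")
  if (!all(fields %in% names(x))) {
    stop("missing life-cycle parameter(s): ",
         paste(setdiff(fields, names(x)), collapse = ", "), call. = FALSE)
  }
  vals <- unlist(x[fields])
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("life-cycle parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("life-cycle parameters must be non-negative", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.life_cycle_params <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("Life-cycle parameters",
      if (!is.null(preset)) sprintf(" (preset: %s)", preset), "\n", sep = "")
  cat(sprintf("  juvenile mortality  mu_m1 = %g, mu_f1 = %g\n", x$mu_m1, x$mu_f1))
  cat(sprintf("  adult mortality     mu_m2 = %g, mu_f2 = %g\n", x$mu_m2, x$mu_f2))
  cat(sprintf("  maturation          alpha_m = %g, alpha_f = %g\n",
              x$alpha_m, x$alpha_f))
  cat(sprintf("  divorce rate        d = %g\n", x$d))
  cat(sprintf("  resource rate       R = %g\n", x$R))
  invisible(x)
}

#' Swap the sexes in a parameter set
#'
#' Exchanges all male and female rates. Used by symmetry tests: relabelling
#' the sexes and replacing the sex ratio s1 by 1 - s1 must leave the model
#' invariant.
#'
#' @param params a [life_cycle_params()] object.
#' @return a `life_cycle_params` object with male/female rates exchanged.
#' @export
swap_sexes <- function(params) {
  life_cycle_params(
    mu_m1 = params$mu_f1, mu_f1 = params$mu_m1,
    mu_m2 = params$mu_f2, mu_f2 = params$mu_m2,
    alpha_m = params$alpha_f, alpha_f = params$alpha_m,
    d = params$d, R = params$R
  )
}

#' Offspring-cost model
#'
#' Selects one of five interpretations of sex-biased offspring costs and
#' stores its parameters:
#'
#' * Case 0 — identical sexes: no cost asymmetry (unit costs).
#' * Case 1 — offspring resource costs: producing a son costs `Cm` resource
#'   units per birth and a daughter `Cf`; the average cost per birth is
#'   `Ca(s1) = s1*Cm + (1-s1)*Cf`.
#' * Case 2 — offspring mortality during parental investment: parents invest
#'   at rate `I` until the age of independence `1/alpha`; sex-specific
#'   juvenile mortality during that window sets the expected cost per birth
#'   (see [expected_investment_cost()]), which is then used as in Case 1.
#' * Case 3 — offspring mortality after parental investment: unit costs
#'   (`Cm = Cf = Ca = 1`); the asymmetry lives in the transition rates.
#' * Case 4 — parental mortality costs: each son (daughter) raises the
#'   mortality of both its mated parents in proportion to `Dm` (`Df`),
#'   scaled by `c`; unit resource costs as in Case 3.
#'
#' @param case integer case id in `0:4`.
#' @param Cm,Cf male/female offspring resource costs per birth (Case 1).
#' @param I parental investment rate during the dependent period (Case 2).
#' @param Dm,Df parental mortality cost per son / per daughter (Case 4).
#' @param c non-negative scaling from reproduction cost to extra mated-adult
#'   mortality (Case 4).
#' @return an object of class `cost_model`.
#' @examples
#' cost_model(1, Cm = 0.6, Cf = 0.4)
#' cost_model(4, Dm = 0.7, Df = 0.3, c = 0.1)
#' @export
cost_model <- function(case, Cm = NULL, Cf = NULL, I = NULL,
                       Dm = NULL, Df = NULL, c = NULL) {
  if (!case %in% 0:4) stop("case must be one of 0,1,2,3,4", call. = FALSE)
  out <- list(case_id = as.integer(case))
  chk <- function(x, nm, strict_pos = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < 0 || (strict_pos && x == 0)) {
      stop(sprintf("cost parameter %s must be a %s finite number", nm,
                   if (strict_pos) "positive" else "non-negative"),
           call. = FALSE)
    }
    x
  }
  if (case == 0) {
    out$Cm <- out$Cf <- 1
  } else if (case == 1) {
    if (is.null(Cm) || is.null(Cf)) stop("Case 1 needs Cm and Cf", call. = FALSE)
    out$Cm <- chk(Cm, "Cm")
    out$Cf <- chk(Cf, "Cf")
    if (out$Cm + out$Cf <= 0) stop("Cm + Cf must be positive", call. = FALSE)
  } else if (case == 2) {
    if (is.null(I)) stop("Case 2 needs the investment rate I", call. = FALSE)
    out$I <- chk(I, "I", strict_pos = TRUE)
  } else if (case == 3) {
    out$Cm <- out$Cf <- 1
  } else { # case 4
    if (is.null(Dm) || is.null(Df) || is.null(c)) {
      stop("Case 4 needs Dm, Df and c", call. = FALSE)
    }
    out$Cm <- out$Cf <- 1
    out$Dm <- chk(Dm, "Dm")
    out$Df <- chk(Df, "Df")
    out$c <- chk(c, "c")
  }
  structure(out, class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  lab <- c("0 (identical sexes)",
           "1 (offspring resource costs)",
           "2 (offspring mortality during investment)",
           "3 (offspring mortality after investment)",
           "4 (parental mortality costs)")[x$case_id + 1L]
  cat("Offspring-cost model, Case ", lab, "\n", sep = "")
  extra <- setdiff(names(x), "case_id")
  if (length(extra)) {
    cat("  ", paste(sprintf("%s = %g", extra, unlist(x[extra])),
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
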