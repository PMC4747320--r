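#' Average offspring resource cost per birth
#'
#' `Ca(s1) = s1 * Cm + (1 - s1) * Cf`: the mean resource cost of a birth
#' when a fraction `s1` of offspring are male. The union reproductive rate
#' is `R / Ca` offspring per unit time. The mutant birth matrix evaluates
#' `Ca` at the mutant sex ratio.
#'
#' @param s1 primary sex ratio in `[0, 1]`.
#' @param Cm,Cf male / female offspring resource costs per birth.
#' @return the average cost, a scalar (vectorised over `s1`).
#' @export
average_cost <- function(s1, Cm, Cf) {
  stopifnot(all(s1 >= 0 & s1 <= 1))
  s1 * Cm + (1 - s1) * Cf
}

#' Equal-investment (Fisherian) singular sex ratio
#'
#' The classic structureless prediction `s1* = Cf / (Cm + Cf)`: the primary
#' sex ratio that equalises total expenditure on sons and daughters. Used as
#' a baseline against which the demographic singular strategies are
#' compared. Under the trade-off `Cm + Cf = 1` it reduces to `Cf`.
#'
#' @param Cm,Cf male / female offspring costs (any common units);
#'   `Cm + Cf` must be positive.
#' @return the baseline singular sex ratio in `[0, 1]`.
#' @examples
#' equal_investment_ss(2, 1) # 1/3
#' @export
equal_investment_ss <- function(Cm, Cf) {
  if (any(Cm < 0) || any(Cf < 0) || any(Cm + Cf <= 0)) {
    stop("need Cm, Cf >= 0 with Cm + Cf > 0", call. = FALSE)
  }
  Cf / (Cm + Cf)
}

#' Expected cumulative parental investment per offspring born
#'
#' With a constant investment rate `I` up to the age of independence
#' `a = 1/alpha`, and a constant mortality rate `mu` during that window, the
#' expected cumulative investment in an offspring (its expected resource
#' cost per birth) is `(I / mu) * (1 - exp(-mu / alpha))`. The continuous
#' extension at `mu = 0` is `I / alpha` (every offspring survives to
#' independence and consumes the full investment). The cost declines as
#' `mu` grows: offspring that die early free resources for their siblings.
#'
#' @param I parental investment rate (resources per unit time), `>= 0`.
#' @param mu mortality rate during the investment period, `>= 0`.
#' @param alpha maturation rate; the age of independence is `1/alpha`.
#' @return expected cost per birth (vectorised over `mu`).
#' @examples
#' expected_investment_cost(1, 1, 0.5) # 1 - exp(-2)
#' @export
expected_investment_cost <- function(I, mu, alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  if (any(I < 0) || any(mu < 0)) stop("I and mu must be >= 0", call. = FALSE)
  # -expm1(-mu/alpha)/mu is numerically stable; patch the mu = 0 limit
  out <- ifelse(mu > 0, I * (-expm1(-mu / alpha)) / mu, I / alpha)
  as.numeric(out)
}

#' Parental costs of reproduction and mated-adult mortality (Case 4)
#'
#' A mated adult's expected cost of reproduction is the product of its
#' per-capita mating rate, the resource investment rate, and the mean
#' parental mortality cost per offspring:
#' `Em = Um * R * (s1*Dm + (1-s1)*Df)` for males and the analogue with `Uf`
#' for females. Mated-adult mortality is then raised linearly:
#' `mu_m2c = mu_m2 + c * Em`, `mu_f2c = mu_f2 + c * Ef`. Unmated adults are
#' unaffected. For a mutant, the sex ratio in the bracket is the mutant's,
#' while `Um`, `Uf` stay frozen at the resident equilibrium.
#'
#' @param Um,Uf per-capita male / female mating rates at the (resident)
#'   stage distribution.
#' @param R resource investment rate.
#' @param s1 primary sex ratio used for the offspring mix.
#' @param Dm,Df parental mortality cost per son / per daughter.
#' @return `parental_costs()`: list with `Em` and `Ef`.
#' @export
parental_costs <- function(Um, Uf, R, s1, Dm, Df) {
  if (any(c(Um, Uf, R, Dm, Df) < 0) || s1 < 0 || s1 > 1) {
    stop("parental_costs: inputs must be non-negative, s1 in [0,1]",
         call. = FALSE)
  }
  mix <- s1 * Dm + (1 - s1) * Df
  list(Em = Um * R * mix, Ef = Uf * R * mix)
}

#' @rdname parental_costs
#' @param mu_m2,mu_f2 baseline (unmated) adult mortality rates.
#' @param c scaling from reproduction cost to extra mortality.
#' @param Em,Ef expected costs of reproduction from `parental_costs()`.
#' @return `mated_mortality()`: list with `mu_m2c` and `mu_f2c`.
#' @export
mated_mortality <- function(mu_m2, mu_f2, c, Em, Ef) {
  if (any(c(mu_m2, mu_f2, c, Em, Ef) < 0)) {
    stop("mated_mortality: inputs must be non-negative", call. = FALSE)
  }
  list(mu_m2c = mu_m2 + c * Em, mu_f2c = mu_f2 + c * Ef)
}

# Resolve the per-birth resource costs (Cm, Cf) implied by a cost model.
# Case 2 derives them from the investment rate and the juvenile mortality /
# maturation rates; the other cases carry them explicitly.
resolve_costs <- function(params, cost) {
  if (cost$case_id == 2L) {
    list(Cm = expected_investment_cost(cost$I, params$mu_m1, params$alpha_m),
         Cf = expected_investment_cost(cost$I, params$mu_f1, params$alpha_f))
  } else {
    list(Cm = cost$Cm, Cf = cost$Cf)
  }
}
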