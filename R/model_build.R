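# Stage order conventions. The 5-stage life cycle is (m1, m2, f1, f2, u):
# juvenile males, adult (single) males, juvenile females, adult (single)
# females, reproducing unions. The 4-stage no-union life cycle drops u.
STAGES5 <- c("m1", "m2", "f1", "f2", "u")
STAGES4 <- c("m1", "m2", "f1", "f2")

# column-major linear index of entry (i, j) of an s x s matrix
.mx_idx <- function(i, j, s) (j - 1L) * s + i

#' Harmonic-mean mating rates
#'
#' Total union formation rate `M = 2*m2*f2/(m2+f2)` (harmonic mean of the
#' single adult male and female frequencies) and the per-capita mating
#' rates `Um = M/m2 = 2*f2/(m2+f2)`, `Uf = M/f2 = 2*m2/(m2+f2)`. The
#' function is homogeneous of degree one in abundances, so per-capita rates
#' depend only on stage frequencies. When either sex is absent (or both),
#' all three rates are defined to be 0, the continuous limit.
#'
#' @param p stage frequency (or abundance) vector; stage order
#'   `(m1, m2, f1, f2, u)` or `(m1, m2, f1, f2)`.
#' @param i_m,i_f positions of the single adult male and female stages.
#' @return list with `M`, `Um`, `Uf`.
#' @examples
#' mating_rates(c(0.25, 0.25, 0.25, 0.25, 0)) # M = 0.25, Um = Uf = 1
#' @export
mating_rates <- function(p, i_m = 2L, i_f = 4L) {
  if (any(p < 0)) stop("stage frequencies must be non-negative", call. = FALSE)
  m2 <- p[[i_m]]
  f2 <- p[[i_f]]
  if (m2 <= 0 || f2 <= 0) {
    return(list(M = 0, Um = 0, Uf = 0))
  }
  M <- 2 * m2 * f2 / (m2 + f2)
  list(M = M, Um = M / m2, Uf = M / f2)
}

#' Build the resident rate matrices U, B, T (5-stage model)
#'
#' Constructs the union-formation matrix `U(p)`, the birth matrix `B(s1)`
#' and the transition matrix `T` for the 5-stage two-sex life cycle.
#'
#' `U` moves single adults into the union stage at the harmonic-mean mating
#' rates: `-Um` and `-Uf` on the adult diagonals and `Um/2`, `Uf/2` inflows
#' into the union row (each union consumes one adult of each sex). `B`
#' contains the birth rates `R*s1/Ca` (sons) and `R*(1-s1)/Ca` (daughters)
#' out of the union stage. `T` carries mortality, maturation, and union
#' dissolution: a union dissolves by divorce (`d`) or by the death of one
#' partner, returning the widowed survivor to the singles pool. Under the
#' Case 4 cost model the mated-adult mortalities are inflated to
#' `mu_m2c`, `mu_f2c` (see [mated_mortality()]) wherever the union stage is
#' involved.
#'
#' @param params a [life_cycle_params()] object.
#' @param cost a [cost_model()] object.
#' @param s1 primary sex ratio in `[0, 1]`.
#' @param p stage frequency vector (length 5).
#' @return list with matrices `U`, `B`, `T` (5 x 5).
#' @export
build_rate_matrices <- function(params, cost, s1, p) {
  stopifnot(length(p) == 5L)
  if (s1 < 0 || s1 > 1) stop("s1 must lie in [0, 1]", call. = FALSE)
  mr <- mating_rates(p)
  U <- matrix(0, 5, 5, dimnames = list(STAGES5, STAGES5))
  U[2, 2] <- -mr$Um
  U[4, 4] <- -mr$Uf
  U[5, 2] <- mr$Um / 2
  U[5, 4] <- mr$Uf / 2

  cc <- resolve_costs(params, cost)
  Ca <- average_cost(s1, cc$Cm, cc$Cf)
  if (Ca == 0) {
    stop("average offspring cost Ca is zero; birth rates R*s1/Ca undefined",
         call. = FALSE)
  }
  B <- matrix(0, 5, 5, dimnames = list(STAGES5, STAGES5))
  B[1, 5] <- params$R * s1 / Ca
  B[3, 5] <- params$R * (1 - s1) / Ca

  TT <- transition_matrix5(params, cost, s1, mr)
  list(U = U, B = B, T = TT)
}

# 5-stage transition matrix; Case 4 substitutes mated-adult mortalities in
# the union column.
transition_matrix5 <- function(params, cost, s1, mr) {
  mu_m2u <- params$mu_m2 # mortality experienced while in a union
  mu_f2u <- params$mu_f2
  if (cost$case_id == 4L) {
    E <- parental_costs(mr$Um, mr$Uf, params$R, s1, cost$Dm, cost$Df)
    mm <- mated_mortality(params$mu_m2, params$mu_f2, cost$c, E$Em, E$Ef)
    mu_m2u <- mm$mu_m2c
    mu_f2u <- mm$mu_f2c
  }
  TT <- matrix(0, 5, 5, dimnames = list(STAGES5, STAGES5))
  TT[1, 1] <- -(params$mu_m1 + params$alpha_m)
  TT[2, 1] <- params$alpha_m
  TT[2, 2] <- -params$mu_m2
  TT[2, 5] <- mu_f2u + params$d   # widower: partner death or divorce
  TT[3, 3] <- -(params$mu_f1 + params$alpha_f)
  TT[4, 3] <- params$alpha_f
  TT[4, 4] <- -params$mu_f2
  TT[4, 5] <- mu_m2u + params$d   # widow
  TT[5, 5] <- -(mu_m2u + mu_f2u + params$d)
  TT
}

#' Assemble the projection matrix
#'
#' The continuous-time projection matrix is the average of the three rate
#' matrices, `A = (T + B + U) / 3`. The 1/3 factor rescales time (and the
#' growth rate) but does not move equilibria or change the signs of the
#' stability conditions; it is retained so that reported derivative values
#' are on the same scale as the model's published analyses.
#'
#' @param U,B,T square rate matrices of a common dimension.
#' @return the projection matrix `A`.
#' @export
assemble_A <- function(U, B, T) {
  d <- dim(U)
  if (is.null(d) || d[1] != d[2] ||
      !identical(d, dim(B)) || !identical(d, dim(T))) {
    stop("U, B, T must be square matrices of the same dimension",
         call. = FALSE)
  }
  (T + B + U) / 3
}

# ---------------------------------------------------------------------------
# Model objects: a sexratio_model packages the resident projection-matrix
# builder A(s1, p), the mutant builder A'(s1', p_hat) (mating rates frozen
# at the resident equilibrium), and the analytic first/second derivatives of
# vec A' with respect to the mutant sex ratio.

new_sexratio_model <- function(s, stage_labels, params, cost,
                               A_res, A_mut, dvecA_mut, hvecA_mut,
                               C_const_in_p, label) {
  structure(
    list(s = s, stage_labels = stage_labels, params = params, cost = cost,
         A_res = A_res, A_mut = A_mut,
         dvecA_mut = dvecA_mut, hvecA_mut = hvecA_mut,
         C_const_in_p = C_const_in_p, label = label,
         cache = new.env(parent = emptyenv())),
    class = "sexratio_model"
  )
}

#' @export
print.sexratio_model <- function(x, ...) {
  cat("Two-sex matrix model: ", x$label, "\n", sep = "")
  cat("  stages: ", paste(x$stage_labels, collapse = ", "), "\n", sep = "")
  print(x$params)
  print(x$cost)
  invisible(x)
}

#' Build a 5-stage model for a given offspring-cost case
#'
#' Pairs a life-cycle parameter set with an offspring-cost interpretation
#' and returns a model object holding the resident projection matrix
#' builder `A(s1, p)`, the mutant builder `A'(s1', p_hat)` (in which the
#' mating rates, and for Case 4 the per-capita mating rates entering the
#' parental-cost terms, are frozen at the resident equilibrium), and the
#' analytic first and second derivatives of `vec A'` with respect to the
#' mutant sex ratio, as used by the selection gradient and the stability
#' conditions.
#'
#' Case 0 is Case 1 with equal unit costs; Case 2 converts the investment
#' rate and juvenile mortality/maturation rates into per-birth costs via
#' [expected_investment_cost()] and then proceeds as Case 1; Cases 3 and 4
#' have unit resource costs (`Ca = 1`).
#'
#' @param params a [life_cycle_params()] object.
#' @param cost a [cost_model()] object.
#' @return an object of class `sexratio_model`.
#' @examples
#' mod <- build_case_model(life_cycle_params("productive"),
#'                         cost_model(1, Cm = 0.6, Cf = 0.4))
#' @export
build_case_model <- function(params, cost) {
  validate_life_cycle_params(params)
  if (!inherits(cost, "cost_model")) stop("cost must be a cost_model")
  cc <- resolve_costs(params, cost)
  Cm <- cc$Cm
  Cf <- cc$Cf
  R <- params$R
  case <- cost$case_id
  s <- 5L

  A_of <- function(s1, p_rates, s1_T = s1) {
    # p_rates supplies the mating rates; s1_T the sex ratio entering T
    # (resident: same as s1; mutant: the mutant's).
    mr <- mating_rates(p_rates)
    U <- matrix(0, s, s)
    U[2, 2] <- -mr$Um
    U[4, 4] <- -mr$Uf
    U[5, 2] <- mr$Um / 2
    U[5, 4] <- mr$Uf / 2
    Ca <- average_cost(s1, Cm, Cf)
    B <- matrix(0, s, s)
    B[1, 5] <- R * s1 / Ca
    B[3, 5] <- R * (1 - s1) / Ca
    TT <- transition_matrix5(params, cost, s1_T, mr)
    (TT + B + U) / 3
  }

  A_res <- function(s1, p) A_of(s1, p)
  A_mut <- function(s1p, p_hat) A_of(s1p, p_hat)

  dvecA_mut <- function(s1p, p_hat) {
    d <- numeric(s * s)
    Ca <- average_cost(s1p, Cm, Cf)
    d[.mx_idx(1L, 5L, s)] <- R * Cf / Ca^2 / 3
    d[.mx_idx(3L, 5L, s)] <- -R * Cm / Ca^2 / 3
    if (case == 4L) {
      mr <- mating_rates(p_hat)
      k <- cost$c * R * (cost$Dm - cost$Df)
      d[.mx_idx(2L, 5L, s)] <- k * mr$Uf / 3
      d[.mx_idx(4L, 5L, s)] <- k * mr$Um / 3
      d[.mx_idx(5L, 5L, s)] <- -k * (mr$Um + mr$Uf) / 3
    }
    d
  }

  hvecA_mut <- function(s1p, p_hat) {
    h <- numeric(s * s)
    if (case %in% c(1L, 2L)) {
      Ca <- average_cost(s1p, Cm, Cf)
      h[.mx_idx(1L, 5L, s)] <- -2 * R * Cf * (Cm - Cf) / Ca^3 / 3
      h[.mx_idx(3L, 5L, s)] <- 2 * R * Cm * (Cm - Cf) / Ca^3 / 3
    }
    # Cases 0, 3, 4: A' is linear in the mutant sex ratio
    h
  }

  lab <- sprintf("5-stage, Case %d%s", case,
                 if (!is.null(attr(params, "preset")))
                   paste0(", ", attr(params, "preset"), " preset") else "")
  new_sexratio_model(s, STAGES5, params, cost,
                     A_res, A_mut, dvecA_mut, hvecA_mut,
                     C_const_in_p = case != 4L, label = lab)
}

#' Build the 4-stage no-union contrast model
#'
#' A two-sex model in which adults reproduce directly, without a union
#' stage. The total birth rate is `R * M(p)` with the same harmonic-mean
#' mating function; it is split between adult males and females through the
#' per-capita fertilities `Fm = R*M/(2*m2)` and `Ff = R*M/(2*f2)` (the
#' factor 1/2 prevents double-counting offspring through both parents), and
#' between the sexes of the newborns by `s1`. Offspring resource costs are
#' unit (`Ca = 1`), as in Case 3. The mating matrix is zero and the
#' transition matrix carries only mortality and maturation. Mutant adults
#' reproduce at the resident per-capita fertilities (their rarity means the
#' resident sets the mating environment).
#'
#' @param params a [life_cycle_params()] object (the divorce rate `d` is
#'   ignored: there are no unions).
#' @return an object of class `sexratio_model` with 4 stages
#'   `(m1, m2, f1, f2)`.
#' @export
four_stage_model <- function(params) {
  validate_life_cycle_params(params)
  R <- params$R
  s <- 4L

  fertilities <- function(p) {
    mr <- mating_rates(p, i_m = 2L, i_f = 4L)
    # Fm = R*M/(2 m2) = R*Um/2, Ff = R*M/(2 f2) = R*Uf/2
    list(Fm = R * mr$Um / 2, Ff = R * mr$Uf / 2)
  }

  Tmat <- matrix(0, s, s, dimnames = list(STAGES4, STAGES4))
  Tmat[1, 1] <- -(params$mu_m1 + params$alpha_m)
  Tmat[2, 1] <- params$alpha_m
  Tmat[2, 2] <- -params$mu_m2
  Tmat[3, 3] <- -(params$mu_f1 + params$alpha_f)
  Tmat[4, 3] <- params$alpha_f
  Tmat[4, 4] <- -params$mu_f2

  A_of <- function(s1, p_rates) {
    fe <- fertilities(p_rates)
    B <- matrix(0, s, s)
    B[1, 2] <- s1 * fe$Fm
    B[1, 4] <- s1 * fe$Ff
    B[3, 2] <- (1 - s1) * fe$Fm
    B[3, 4] <- (1 - s1) * fe$Ff
    (Tmat + B) / 3
  }

  dvecA_mut <- function(s1p, p_hat) {
    fe <- fertilities(p_hat)
    d <- numeric(s * s)
    d[.mx_idx(1L, 2L, s)] <- fe$Fm / 3
    d[.mx_idx(3L, 2L, s)] <- -fe$Fm / 3
    d[.mx_idx(1L, 4L, s)] <- fe$Ff / 3
    d[.mx_idx(3L, 4L, s)] <- -fe$Ff / 3
    d
  }

  lab <- sprintf("4-stage (no unions)%s",
                 if (!is.null(attr(params, "preset")))
                   paste0(", ", attr(params, "preset"), " preset") else "")
  new_sexratio_model(
    s, STAGES4, params, cost_model(3),
    A_res = function(s1, p) A_of(s1, p),
    A_mut = function(s1p, p_hat) A_of(s1p, p_hat),
    dvecA_mut = dvecA_mut,
    hvecA_mut = function(s1p, p_hat) numeric(s * s),
    C_const_in_p = FALSE, # fertilities depend on the resident structure
    label = lab
  )
}

#' Secondary sex ratio at a stage distribution
#'
#' The proportion of adults that are male. In the 5-stage model each union
#' holds exactly one adult of each sex, so union members are counted:
#' `s2 = (m2 + u) / (m2 + f2 + 2u)`. In the 4-stage model
#' `s2 = m2 / (m2 + f2)`.
#'
#' @param p_hat stage frequency vector (length 4 or 5).
#' @return the secondary sex ratio, a scalar in `[0, 1]`.
#' @examples
#' secondary_sex_ratio(c(0.25, 0.2, 0.25, 0.3, 0)) # 0.4
#' @export
secondary_sex_ratio <- function(p_hat) {
  if (length(p_hat) == 5L) {
    tot <- p_hat[[2]] + p_hat[[4]] + 2 * p_hat[[5]]
    if (tot <= 0) stop("no adults: secondary sex ratio undefined", call. = FALSE)
    (p_hat[[2]] + p_hat[[5]]) / tot
  } else if (length(p_hat) == 4L) {
    tot <- p_hat[[2]] + p_hat[[4]]
    if (tot <= 0) stop("no adults: secondary sex ratio undefined", call. = FALSE)
    p_hat[[2]] / tot
  } else {
    stop("expected a stage distribution of length 4 or 5", call. = FALSE)
  }
}
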