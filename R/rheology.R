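#' Generalized Cross model parameters
#'
#' Shear-thinning viscosity law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty) /
#'       (1 + (\lambda \dot\gamma)^b)^a,}
#' interpolating between the zero-shear viscosity `mu0` and the infinite-shear
#' viscosity `mu_inf`.  Defaults are the standard whole-blood fit used
#' throughout this package.
#'
#' @param mu0 zero-shear viscosity (Pa s).
#' @param mu_inf infinite-shear viscosity (Pa s).
#' @param lam time constant (s).
#' @param a,b dimensionless exponents (> 0).
#' @return object of class `cross_params`.
#' @export
cross_params <- function(mu0 = 0.16, mu_inf = 0.0036, lam = 8.2,
                         a = 1.23, b = 0.64) {
  if (!(mu0 >= mu_inf && mu_inf > 0)) stop("need mu0 >= mu_inf > 0")
  if (!(lam > 0 && a > 0 && b > 0)) stop("need lam, a, b > 0")
  structure(list(mu0 = mu0, mu_inf = mu_inf, lam = lam, a = a, b = b),
            class = "cross_params")
}

#' Oldroyd-B parameters
#'
#' Solvent/polymer viscosity split `mu = mu_n + mu_v` with relaxation time
#' `lam_x` and retardation time `lam_d`.  The retardation time is always
#' derived from the enforced invariant `lam_d / lam_x = mu_n / (mu_n + mu_v)`.
#'
#' @param mu_n Newtonian (solvent) viscosity (Pa s).
#' @param mu_v viscoelastic (polymer) viscosity (Pa s).
#' @param lam_x relaxation time (s).
#' @return object of class `oldroyd_params` with derived `lam_d`.
#' @export
oldroyd_params <- function(mu_n = 0.0036, mu_v = 0.0036, lam_x = 0.07) {
  if (mu_n < 0 || mu_v < 0) stop("viscosities must be non-negative")
  if (lam_x < 0) stop("lam_x must be non-negative")
  mu <- mu_n + mu_v
  lam_d <- if (mu > 0) lam_x * mu_n / mu else 0
  structure(list(mu_n = mu_n, mu_v = mu_v, lam_x = lam_x, lam_d = lam_d,
                 mu = mu), class = "oldroyd_params")
}

#' Constitutive case configuration
#'
#' Selects one of the four constitutive cases:
#' \describe{
#'   \item{newtonian}{`mu_n = mu_inf`, no extra stress.}
#'   \item{gen_newtonian}{`mu_n = mu(gamma_dot)` (Cross), no extra stress.}
#'   \item{oldroyd_b}{`mu_n = mu_inf` plus transported extra stress `sigma_v`.}
#'   \item{gen_oldroyd_b}{`mu_n = mu(gamma_dot)` plus extra stress.}
#' }
#'
#' @param case one of `"newtonian"`, `"gen_newtonian"`, `"oldroyd_b"`,
#'   `"gen_oldroyd_b"` (aliases `"n"`, `"gn"`, `"od"`, `"gd"`).
#' @param cross a [cross_params()].
#' @param oldroyd an [oldroyd_params()]; its `mu_n` is forced to `cross$mu_inf`
#'   so that the viscosity split stays consistent with the Cross plateau.
#' @return object of class `case_config`.
#' @export
case_config <- function(case = c("newtonian", "gen_newtonian", "oldroyd_b",
                                 "gen_oldroyd_b", "n", "gn", "od", "gd"),
                        cross = cross_params(), oldroyd = oldroyd_params()) {
  case <- match.arg(case)
  alias <- c(n = "newtonian", gn = "gen_newtonian", od = "oldroyd_b",
             gd = "gen_oldroyd_b")
  if (case %in% names(alias)) case <- alias[[case]]
  stopifnot(inherits(cross, "cross_params"), inherits(oldroyd, "oldroyd_params"))
  elastic <- case %in% c("oldroyd_b", "gen_oldroyd_b")
  shear_thinning <- case %in% c("gen_newtonian", "gen_oldroyd_b")
  mu_v <- if (elastic) oldroyd$mu_v else 0
  oldroyd <- oldroyd_params(mu_n = cross$mu_inf, mu_v = mu_v,
                            lam_x = oldroyd$lam_x)
  structure(list(case = case, elastic = elastic,
                 shear_thinning = shear_thinning,
                 cross = cross, oldroyd = oldroyd),
            class = "case_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strain-rate tensor
#'
#' `V = (grad u + grad u^T) / 2` for a 2x2 velocity gradient.
#'
#' @param grad 2x2 matrix with `grad[i, j] = d u_i / d x_j`.
#' @return symmetric 2x2 strain-rate tensor.
#' @export
strain_rate_tensor <- function(grad) {
  stopifnot(is.matrix(grad), all(dim(grad) == c(2, 2)), all(is.finite(grad)))
  (grad + t(grad)) / 2
}

#' Scalar shear rate
#'
#' `gamma_dot = sqrt(2 V:V)`, the standard second-invariant shear rate, which
#' reduces to `|du/dy|` in simple shear.
#'
#' @param V symmetric 2x2 strain-rate tensor.
#' @return non-negative scalar shear rate.
#' @export
shear_rate <- function(V) {
  stopifnot(is.matrix(V), all(dim(V) == c(2, 2)))
  if (max(abs(V - t(V))) > 1e-12 * max(1, max(abs(V))))
    stop("V must be symmetric")
  sqrt(2 * sum(V * V))
}

#' Cross viscosity
#'
#' Evaluates the generalized Cross law (vectorized in `gamma_dot`).
#'
#' @param gamma_dot non-negative shear rate(s) (1/s).
#' @param p a [cross_params()].
#' @return viscosity in `[mu_inf, mu0]` (Pa s).
#' @export
cross_viscosity <- function(gamma_dot, p = cross_params()) {
  stopifnot(inherits(p, "cross_params"))
  if (any(gamma_dot < 0)) stop("gamma_dot must be non-negative")
  p$mu_inf + (p$mu0 - p$mu_inf) / (1 + (p$lam * gamma_dot)^p$b)^p$a
}

## derivative d mu / d gamma_dot of the Cross law (vectorized; gamma_dot > 0)
cross_viscosity_deriv <- function(gamma_dot, p = cross_params()) {
  g <- pmax(gamma_dot, 1e-300)
  lg <- (p$lam * g)^p$b
  -(p$mu0 - p$mu_inf) * p$a * p$b * lg / g / (1 + lg)^(p$a + 1)
}

#' Viscosity split for a constitutive case
#'
#' Returns the (dimensional) solvent viscosity entering the momentum
#' Laplacian, the polymer viscosity feeding the Oldroyd-B transport equation,
#' and the momentum coefficient `beta = mu_n / (mu_n + mu_v)`.
#'
#' @param case a [case_config()].
#' @param gamma_dot shear rate at which shear-thinning cases evaluate the
#'   Cross law.
#' @return list with `mu_n`, `mu_v`, `beta`.
#' @export
viscosity_split <- function(case, gamma_dot = 0) {
  stopifnot(inherits(case, "case_config"))
  mu_n <- if (case$shear_thinning) cross_viscosity(gamma_dot, case$cross)
          else case$cross$mu_inf
  mu_v <- if (case$elastic) case$oldroyd$mu_v else 0
  list(mu_n = mu_n, mu_v = mu_v, beta = mu_n / (mu_n + mu_v))
}

#' Dimensionless groups of a run
#'
#' Converts the dimensional rheology of a [case_config()] into the
#' coefficients of the dimensionless system at a given Reynolds number.
#' The characteristic length is the dimensional inlet height `L_dim`, the
#' characteristic velocity follows from `Re = rho U L / mu_ref` with
#' `mu_ref = mu_inf + mu_v` (the infinite-shear total viscosity of the case),
#' and stresses and pressure are scaled by `mu_ref U / L`.  The returned
#' closure `beta_fun(gd)` gives the dimensionless solvent viscosity
#' `mu_n(gamma_dot) / mu_ref` as a function of the dimensionless shear rate,
#' together with its derivative, and `mu_v_star` is the constant dimensionless
#' polymer viscosity.
#'
#' @param case a [case_config()].
#' @param Re Reynolds number (`0 < Re <= 3000`).
#' @param rho blood density (kg/m^3).
#' @param L_dim dimensional channel height (m); the geometry's unit length is
#'   `L_dim / 2` (the healthy half-height).
#' @param velocity_unit dimensional value (m/s) of one unit of the
#'   dimensionless velocity fields.  The simulated velocity magnitudes are
#'   read as physical arterial speeds on this scale, and the Cross law is
#'   evaluated at the resulting physical shear rates (tens of 1/s in the
#'   lesion models), which places blood in its shear-thinned regime as in a
#'   real artery.
#' @return list with `mu_ref`, `U_char`, `rate_scale` (dimensional shear per
#'   unit dimensionless shear), `lam_nd`, `mu_v_star`, `beta_fun`,
#'   `dbeta_fun`.
#' @export
dimensionless_groups <- function(case, Re, rho = 1050, L_dim = 0.02,
                                 velocity_unit = 1) {
  stopifnot(inherits(case, "case_config"), Re > 0)
  mu_v <- if (case$elastic) case$oldroyd$mu_v else 0
  mu_ref <- case$cross$mu_inf + mu_v
  U_char <- Re * mu_ref / (rho * L_dim)
  rate_scale <- velocity_unit / (L_dim / 2)
  lam_nd <- case$cross$lam * rate_scale
  mu_v_star <- mu_v / mu_ref
  if (case$shear_thinning) {
    cp <- case$cross
    ## tiny C1 regularization: the Cross law has an unbounded slope at zero
    ## shear for b < 1; evaluating at sqrt(gd^2 + g0^2) bounds the Newton
    ## linearization while perturbing the viscosity only on a vanishing
    ## neighbourhood of gd = 0.
    g0 <- 1e-5
    beta_fun <- function(gd) {
      ge <- sqrt(gd^2 + g0^2)
      cross_viscosity(ge * rate_scale, cp) / mu_ref
    }
    dbeta_fun <- function(gd) {
      ge <- sqrt(gd^2 + g0^2)
      cross_viscosity_deriv(ge * rate_scale, cp) * rate_scale / mu_ref *
        (gd / ge)
    }
  } else {
    bconst <- case$cross$mu_inf / mu_ref
    beta_fun <- function(gd) rep(bconst, length(gd))
    dbeta_fun <- function(gd) rep(0, length(gd))
  }
  list(mu_ref = mu_ref, U_char = U_char, rate_scale = rate_scale,
       lam_nd = lam_nd, mu_v_star = mu_v_star,
       beta_fun = beta_fun, dbeta_fun = dbeta_fun)
}
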