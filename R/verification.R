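#' Analytic Poiseuille fixture
#'
#' Fully developed plane channel flow: parabolic velocity
#' `u = 1.5 Ui (1 - (y/w0)^2)`, zero transverse velocity, linear pressure,
#' with the analytic wall shear stress and flux attached.  This is the exact
#' steady solution of the Newtonian system (and, with the matching
#' fully developed stresses, of the Oldroyd-B system) in a straight channel,
#' so the solver must reproduce it to solver precision.
#'
#' @param Ui mean inlet velocity (the profile peak is `1.5 Ui`).
#' @param height full channel height (half-height `w0 = height/2`).
#' @param viscosity total dimensionless viscosity.
#' @param L channel length (pressure datum `p(L) = 0`).
#' @return list of exact-field closures plus `wss`, `flux`, `dpdx`.
#' @export
poiseuille_fixture <- function(Ui = 0.046, height = 2, viscosity = 1, L = 15) {
  w0 <- height / 2
  list(u = function(x, y) 1.5 * Ui * (1 - (y / w0)^2),
       v = function(x, y) rep(0, length(x)),
       p = function(x, y) 3 * Ui * viscosity * (L - x) / w0^2,
       dudy = function(y) -3 * Ui * y / w0^2,
       wss = 3 * Ui * viscosity / w0,
       flux = Ui * height,
       dpdx = -3 * Ui * viscosity / w0^2,
       Ui = Ui, height = height, viscosity = viscosity, L = L)
}

#' Steady homogeneous-shear Oldroyd-B stresses
#'
#' The exact steady extra-stress state in simple shear with rate
#' `gamma_dot`: `s11 = 2 mu_v Wi gamma_dot^2`, `s12 = mu_v gamma_dot`,
#' `s22 = 0` (dimensionless).  The solver must reproduce this triple in
#' fully developed channel regions.
#'
#' @param gamma_dot shear rate.
#' @param mu_v dimensionless polymer viscosity.
#' @param Wi Weissenberg number.
#' @return named numeric vector `c(s11, s12, s22)`.
#' @export
shear_fixture <- function(gamma_dot, mu_v, Wi) {
  c(s11 = 2 * mu_v * Wi * gamma_dot^2, s12 = mu_v * gamma_dot, s22 = 0)
}

#' Manufactured solution for the Newtonian momentum/continuity system
#'
#' A divergence-free trigonometric velocity field with an analytic pressure
#' and the body force that makes the triple satisfy the steady dimensionless
#' momentum equation exactly.  Lives on the straight channel
#' `[0, Lx] x [-1, 1]` with velocity Dirichlet data on the whole boundary.
#'
#' @param Re Reynolds number of the manufactured problem.
#' @param beta constant solvent coefficient.
#' @param Lx channel length.
#' @return list of exact fields `u`, `v`, `p`, forcing `force(x, y)`, and
#'   `geom` (the rectangle geometry).
#' @export
manufactured_case <- function(Re = 1, beta = 1, Lx = 2) {
  u <- function(x, y) sin(pi * x) * cos(pi * y)
  v <- function(x, y) -cos(pi * x) * sin(pi * y)
  p <- function(x, y) cos(pi * x) * sin(pi * y)
  force <- function(x, y) {
    sx <- sin(pi * x); cx <- cos(pi * x)
    sy <- sin(pi * y); cy <- cos(pi * y)
    ue <- sx * cy; ve <- -cx * sy
    ux <- pi * cx * cy; uy <- -pi * sx * sy
    vx <- pi * sx * sy; vy <- -pi * cx * cy
    px <- -pi * sx * sy; py <- pi * cx * cy
    lap_u <- -2 * pi^2 * ue; lap_v <- -2 * pi^2 * ve
    list(fx = Re * (ue * ux + ve * uy) + px - beta * lap_u,
         fy = Re * (ue * vx + ve * vy) + py - beta * lap_v)
  }
  geom <- build_channel(stenosis_spec(D = 2, eps = 0, centers = numeric(0),
                                      domain_length = Lx), n_samples = 50)
  list(u = u, v = v, p = p, force = force, geom = geom, Re = Re, beta = beta,
       Lx = Lx)
}

## L2 errors of a state against exact fields, by element quadrature
state_l2_errors <- function(state, mesh, exact) {
  cache <- mesh_fe_cache(mesh)
  ref <- cache$ref
  tri <- mesh$tri
  nel <- mesh$n_elem
  uel <- matrix(state$u[tri], nel, 6)
  vel <- matrix(state$v[tri], nel, 6)
  pel <- matrix(state$p[tri[, 1:3]], nel, 3)
  eu <- ep <- 0
  for (q in seq_along(ref$w)) {
    wdet <- ref$w[q] * cache$det
    xq <- drop(cache$xq[[q]]); yq <- drop(cache$yq[[q]])
    du <- drop(uel %*% ref$N[, q]) - exact$u(xq, yq)
    dv <- drop(vel %*% ref$N[, q]) - exact$v(xq, yq)
    dp <- drop(pel %*% ref$H[, q]) - exact$p(xq, yq)
    eu <- eu + sum(wdet * (du^2 + dv^2))
    ep <- ep + sum(wdet * dp^2)
  }
  c(u = sqrt(eu), p = sqrt(ep))
}

#' Grid-convergence study on a manufactured solution
#'
#' Solves the manufactured problem on a sequence of uniformly refined meshes,
#' records the L2 velocity and pressure errors, and fits observed convergence
#' orders by least squares on the log-log error curve.  Quadratic velocity
#' elements should deliver an observed velocity order of at least 1.8 and the
#' linear pressure at least 0.9.
#'
#' @param case a [manufactured_case()].
#' @param h vector of at least 3 target mesh sizes (descending).
#' @return list with `h`, `err_u`, `err_p`, `order_u`, `order_p`.
#' @export
convergence_study <- function(case = manufactured_case(),
                              h = c(0.4, 0.2, 0.1)) {
  if (length(h) < 3) stop("need at least 3 mesh sizes")
  err_u <- err_p <- numeric(length(h))
  for (k in seq_along(h)) {
    ny <- max(4L, as.integer(round(2 / h[k])))
    mesh <- mesh_channel(case$geom, h_far = h[k], h_lesion = h[k], ny = ny)
    cc <- case_config("newtonian")
    cfg <- solver_config(Re = case$Re, Wi = 0, case = cc, tol = 1e-8,
                         stabilize = "off", force = case$force,
                         bc = "dirichlet", exact = case, max_newton = 20)
    dof <- dof_map(mesh, elastic = FALSE)
    st <- newton_solve(mesh, dof, cfg)
    e <- state_l2_errors(st, mesh, case)
    err_u[k] <- e["u"]; err_p[k] <- e["p"]
  }
  fit <- function(e) unname(stats::coef(stats::lm(log(e) ~ log(h)))[2])
  list(h = h, err_u = err_u, err_p = err_p,
       order_u = fit(err_u), order_p = fit(err_p))
}
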