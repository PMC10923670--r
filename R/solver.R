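#' Degree-of-freedom map for the mixed discretization
#'
#' Velocity components and extra-stress components carry unknowns on all six
#' nodes of every triangle; pressure is associated with corner nodes only.
#' Index vectors are dense and disjoint across fields.
#'
#' @param mesh a [mesh_channel()] mesh.
#' @param elastic logical; whether the extra-stress fields (s11, s12, s22)
#'   carry unknowns (Oldroyd-B cases).
#' @return object of class `dof_map` with per-field global index vectors and
#'   the total unknown count `ndof`.
#' @export
dof_map <- function(mesh, elastic = TRUE) {
  nn <- mesh$n_nodes; nc <- mesh$n_corner
  off <- 0L
  u <- off + seq_len(nn); off <- off + nn
  v <- off + seq_len(nn); off <- off + nn
  p <- off + seq_len(nc); off <- off + nc
  if (elastic) {
    s11 <- off + seq_len(nn); off <- off + nn
    s12 <- off + seq_len(nn); off <- off + nn
    s22 <- off + seq_len(nn); off <- off + nn
  } else s11 <- s12 <- s22 <- NULL
  structure(list(u = u, v = v, p = p, s11 = s11, s12 = s12, s22 = s22,
                 elastic = elastic, n_nodes = nn, n_corner = nc, ndof = off),
            class = "dof_map")
}

#' Solver configuration
#'
#' Collects the operating point and numerical controls of a steady solve of
#' the dimensionless system: continuity, momentum with Reynolds number `Re`
#' and solvent coefficient `beta`, and (for elastic cases) Oldroyd-B stress
#' transport with Weissenberg number `Wi`.
#'
#' @param Re Reynolds number, `0 < Re <= 3000`.
#' @param Wi Weissenberg number, `0 <= Wi <= 1`.
#' @param case a [case_config()].
#' @param Ui dimensionless inlet mean velocity (inlet peak is `1.5 Ui`).
#' @param tol nodal-increment convergence tolerance: the Newton loop stops
#'   when the summed absolute nodal change of every field (velocity,
#'   pressure, stress) drops below `tol`.
#' @param rtol safety relative-residual criterion guarding the absolute
#'   increment sum.
#' @param max_newton Newton iteration cap.
#' @param relaxation Newton under-relaxation factor in (0, 1].
#' @param stabilize `"auto"` (on for `Re >= 500`), `"on"` or `"off"`;
#'   streamline (SUPG-type) stabilization of stress transport and momentum
#'   convection.
#' @param force optional body force: function `(x, y) -> list(fx, fy)`.
#' @param rho blood density (kg/m^3), used only to form dimensionless groups.
#' @param L_dim dimensional channel height (m) behind the Reynolds scaling.
#' @param continuation Reynolds continuation levels used by [solve_case()].
#' @param bc `"channel"` (parabolic inlet, no-slip walls, natural outflow) or
#'   `"dirichlet"` (velocity fixed on the whole boundary from `exact`, with
#'   one pinned pressure node; used by manufactured-solution verification).
#' @param exact optional list of exact-field functions for `bc = "dirichlet"`.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(Re, Wi = 0, case = case_config("newtonian"),
                          Ui = 0.046, tol = 1e-5, rtol = 1e-8,
                          max_newton = 60L, relaxation = 1,
                          stabilize = c("auto", "on", "off"), force = NULL,
                          rho = 1050, L_dim = 0.02,
                          continuation = c(100, 300, 1000, 2000),
                          bc = c("channel", "dirichlet"), exact = NULL) {
  stabilize <- match.arg(stabilize)
  bc <- match.arg(bc)
  if (!(Re > 0 && Re <= 3000)) stop("Re must satisfy 0 < Re <= 3000")
  if (Wi < 0 || Wi > 1) stop("Wi must satisfy 0 <= Wi <= 1")
  if (tol <= 0) stop("tol must be positive")
  stopifnot(inherits(case, "case_config"))
  groups <- dimensionless_groups(case, Re, rho = rho, L_dim = L_dim)
  structure(list(Re = Re, Wi = Wi, case = case, Ui = Ui, tol = tol,
                 rtol = rtol, max_newton = as.integer(max_newton),
                 relaxation = relaxation, stabilize = stabilize,
                 force = force, rho = rho, L_dim = L_dim,
                 continuation = continuation, bc = bc, exact = exact,
                 groups = groups),
            class = "solver_config")
}

stabilize_on <- function(cfg) {
  switch(cfg$stabilize, on = TRUE, off = FALSE, auto = cfg$Re >= 500)
}

## ---- state packing ------------------------------------------------------

new_flow_state <- function(dof, x = NULL) {
  if (is.null(x)) x <- numeric(dof$ndof)
  st <- list(u = x[dof$u], v = x[dof$v], p = x[dof$p])
  if (dof$elastic) {
    st$s11 <- x[dof$s11]; st$s12 <- x[dof$s12]; st$s22 <- x[dof$s22]
  }
  structure(st, class = "flow_state")
}

pack_state <- function(state, dof) {
  x <- numeric(dof$ndof)
  x[dof$u] <- state$u; x[dof$v] <- state$v; x[dof$p] <- state$p
  if (dof$elastic) {
    x[dof$s11] <- state$s11 %||% 0
    x[dof$s12] <- state$s12 %||% 0
    x[dof$s22] <- state$s22 %||% 0
  }
  x
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state: %d velocity nodes, %d pressure nodes%s%s>\n",
              length(x$u), length(x$p),
              if (!is.null(x$s11)) ", extra stress" else "",
              if (isTRUE(attr(x, "converged"))) ", converged" else ""))
  invisible(x)
}

## ---- geometric cache ----------------------------------------------------

mesh_fe_cache <- function(mesh, ref = tri6_ref_data()) {
  tri <- mesh$tri
  p1 <- mesh$coords[tri[, 1], , drop = FALSE]
  p2 <- mesh$coords[tri[, 2], , drop = FALSE]
  p3 <- mesh$coords[tri[, 3], , drop = FALSE]
  J11 <- p2[, 1] - p1[, 1]; J12 <- p3[, 1] - p1[, 1]
  J21 <- p2[, 2] - p1[, 2]; J22 <- p3[, 2] - p1[, 2]
  det <- J11 * J22 - J12 * J21
  if (any(det <= 0)) stop("element with non-positive Jacobian: ",
                          which(det <= 0)[1])
  i11 <- J22 / det; i12 <- -J12 / det; i21 <- -J21 / det; i22 <- J11 / det
  nq <- length(ref$w)
  Gx <- vector("list", nq); Gy <- vector("list", nq)
  for (q in seq_len(nq)) {
    Gx[[q]] <- outer(i11, ref$Dxi[, q]) + outer(i21, ref$Deta[, q])
    Gy[[q]] <- outer(i12, ref$Dxi[, q]) + outer(i22, ref$Deta[, q])
  }
  ## quadrature-point physical coordinates (affine map -> corner H basis)
  xc <- cbind(p1[, 1], p2[, 1], p3[, 1])
  yc <- cbind(p1[, 2], p2[, 2], p3[, 2])
  xq <- lapply(seq_len(nq), function(q) xc %*% ref$H[, q])
  yq <- lapply(seq_len(nq), function(q) yc %*% ref$H[, q])
  ## per-element constants: P1 (corner) basis gradients and P2 Laplacians
  Hx <- cbind((p2[, 2] - p3[, 2]) / det, (p3[, 2] - p1[, 2]) / det,
              (p1[, 2] - p2[, 2]) / det)
  Hy <- cbind((p3[, 1] - p2[, 1]) / det, (p1[, 1] - p3[, 1]) / det,
              (p2[, 1] - p1[, 1]) / det)
  ## reference second derivatives of the P2 basis (constant)
  Hxx_r <- c(4, 4, 0, -8, 0, 0)
  Hxe_r <- c(4, 0, 0, -4, 4, -4)
  Hee_r <- c(4, 0, 4, 0, 0, -8)
  lap <- outer(i11^2 + i12^2, Hxx_r) +
    outer(2 * (i11 * i21 + i12 * i22), Hxe_r) +
    outer(i21^2 + i22^2, Hee_r)
  list(ref = ref, det = det, Gx = Gx, Gy = Gy, xq = xq, yq = yq,
       h = sqrt(det), Hx = Hx, Hy = Hy, lap = lap)
}

## ---- assembly -----------------------------------------------------------

#' Assemble residual and Jacobian of the steady dimensionless system
#'
#' Evaluates the Galerkin weighted residuals of continuity, momentum (with
#' convection `Re (U.grad)U`, pressure gradient, the `beta`-weighted
#' Laplacian and the extra-stress divergence) and, for elastic cases, the
#' Oldroyd-B transport equation with its upper-convected terms
#' `(grad U) sigma + sigma (grad U)^T`, using a 7-point degree-5 quadrature.
#' The Jacobian is the analytic linearization of those residuals, including
#' the Cross-viscosity derivative for shear-thinning cases; when streamline
#' stabilization is active, its weight is frozen at the current state.
#'
#' @param mesh a [mesh_channel()] mesh.
#' @param dofmap a [dof_map()].
#' @param state a `flow_state` (or packed numeric vector).
#' @param cfg a [solver_config()].
#' @param jacobian assemble the Jacobian (set `FALSE` for residual-only).
#' @param cache optional precomputed geometric cache (internal reuse).
#' @return list with `r` (residual vector), `J` (`dgCMatrix` or `NULL`).
#' @export
assemble <- function(mesh, dofmap, state, cfg, jacobian = TRUE, cache = NULL) {
  if (inherits(state, "flow_state")) state <- pack_state(state, dofmap)
  if (!all(is.finite(state))) stop("state contains non-finite values")
  if (is.null(cache)) cache <- mesh_fe_cache(mesh)
  ref <- cache$ref
  nel <- mesh$n_elem
  tri <- mesh$tri
  elastic <- dofmap$elastic
  Re <- cfg$Re; Wi <- cfg$Wi
  mu_v <- if (elastic) cfg$groups$mu_v_star else 0
  beta_fun <- cfg$groups$beta_fun
  dbeta_fun <- cfg$groups$dbeta_fun
  stab <- stabilize_on(cfg)

  IU <- matrix(dofmap$u[tri], nel, 6)
  IV <- matrix(dofmap$v[tri], nel, 6)
  IP <- matrix(dofmap$p[tri[, 1:3]], nel, 3)
  uel <- matrix(state[IU], nel, 6)
  vel <- matrix(state[IV], nel, 6)
  pel <- matrix(state[IP], nel, 3)
  if (elastic) {
    IS1 <- matrix(dofmap$s11[tri], nel, 6)
    IS2 <- matrix(dofmap$s12[tri], nel, 6)
    IS3 <- matrix(dofmap$s22[tri], nel, 6)
    s1el <- matrix(state[IS1], nel, 6)
    s2el <- matrix(state[IS2], nel, 6)
    s3el <- matrix(state[IS3], nel, 6)
  }

  ru <- matrix(0, nel, 6); rv <- matrix(0, nel, 6); rp <- matrix(0, nel, 3)
  if (elastic) { rs1 <- rs2 <- rs3 <- matrix(0, nel, 6) }
  if (stab) { # element-constant strong-form pieces for SUPG
    lap_u <- rowSums(uel * cache$lap); lap_v <- rowSums(vel * cache$lap)
    px_e <- rowSums(pel * cache$Hx); py_e <- rowSums(pel * cache$Hy)
  }

  blocks <- list()
  addblk <- function(name, rows, cols, nt, ntr) {
    if (is.null(blocks[[name]]))
      blocks[[name]] <<- list(rows = rows, cols = cols, nt = nt, ntr = ntr,
                              acc = matrix(0, nel, nt * ntr))
    invisible(NULL)
  }
  acc_AB <- function(name, A, B) { # A: nel x nt, B: nel x ntr
    b <- blocks[[name]]
    Ik <- rep(seq_len(b$nt), times = b$ntr)
    Jk <- rep(seq_len(b$ntr), each = b$nt)
    blocks[[name]]$acc <<- b$acc + A[, Ik, drop = FALSE] * B[, Jk, drop = FALSE]
    invisible(NULL)
  }
  if (jacobian) {
    addblk("uu", IU, IU, 6, 6); addblk("uv", IU, IV, 6, 6)
    addblk("up", IU, IP, 6, 3)
    addblk("vu", IV, IU, 6, 6); addblk("vv", IV, IV, 6, 6)
    addblk("vp", IV, IP, 6, 3)
    addblk("pu", IP, IU, 3, 6); addblk("pv", IP, IV, 3, 6)
    if (elastic) {
      addblk("us1", IU, IS1, 6, 6); addblk("us2", IU, IS2, 6, 6)
      addblk("vs2", IV, IS2, 6, 6); addblk("vs3", IV, IS3, 6, 6)
      addblk("s1u", IS1, IU, 6, 6); addblk("s1v", IS1, IV, 6, 6)
      addblk("s1s1", IS1, IS1, 6, 6); addblk("s1s2", IS1, IS2, 6, 6)
      addblk("s2u", IS2, IU, 6, 6); addblk("s2v", IS2, IV, 6, 6)
      addblk("s2s1", IS2, IS1, 6, 6); addblk("s2s2", IS2, IS2, 6, 6)
      addblk("s2s3", IS2, IS3, 6, 6)
      addblk("s3u", IS3, IU, 6, 6); addblk("s3v", IS3, IV, 6, 6)
      addblk("s3s2", IS3, IS2, 6, 6); addblk("s3s3", IS3, IS3, 6, 6)
    }
  }

  tau_s <- NULL; tau_m <- NULL
  nq <- length(ref$w)
  for (q in seq_len(nq)) {
    N <- ref$N[, q]; H <- ref$H[, q]
    Gx <- cache$Gx[[q]]; Gy <- cache$Gy[[q]]
    wdet <- ref$w[q] * cache$det
    Nmat <- matrix(N, nel, 6, byrow = TRUE)
    Hmat <- matrix(H, nel, 3, byrow = TRUE)

    u <- drop(uel %*% N); v <- drop(vel %*% N)
    ux <- rowSums(uel * Gx); uy <- rowSums(uel * Gy)
    vx <- rowSums(vel * Gx); vy <- rowSums(vel * Gy)
    p <- drop(pel %*% H)
    gam <- sqrt(2 * (ux^2 + vy^2) + (uy + vx)^2)
    gg <- pmax(gam, 1e-10)
    beta <- beta_fun(gam)
    dbeta <- if (jacobian) dbeta_fun(gam) else NULL

    if (q == 1L) { # centroid: freeze stabilization weights for this assembly
      if (stab) {
        spd <- sqrt(u^2 + v^2)
        h <- cache$h
        tau_s <- h / (2 * Wi * spd + h)           # stress advection-reaction
        tau_m <- 1 / sqrt((2 * Re * spd / h)^2 + (12 * beta / h^2)^2)
      } else {
        tau_s <- rep(0, nel); tau_m <- rep(0, nel)
      }
    }

    if (elastic) {
      s11 <- drop(s1el %*% N); s12 <- drop(s2el %*% N); s22 <- drop(s3el %*% N)
      s11x <- rowSums(s1el * Gx); s11y <- rowSums(s1el * Gy)
      s12x <- rowSums(s2el * Gx); s12y <- rowSums(s2el * Gy)
      s22x <- rowSums(s3el * Gx); s22y <- rowSums(s3el * Gy)
      div_sx <- s11x + s12y
      div_sy <- s12x + s22y
    } else div_sx <- div_sy <- 0

    fx <- 0; fy <- 0
    if (!is.null(cfg$force)) {
      fv <- cfg$force(drop(cache$xq[[q]]), drop(cache$yq[[q]]))
      fx <- fv[[1]]; fy <- fv[[2]]
    }

    ## ---- momentum residuals
    convx <- u * ux + v * uy
    convy <- u * vx + v * vy
    ru <- ru + (wdet * (Re * convx - div_sx - fx)) * Nmat +
      (wdet * (beta * ux - p)) * Gx + (wdet * beta * uy) * Gy
    rv <- rv + (wdet * (Re * convy - div_sy - fy)) * Nmat +
      (wdet * beta * vx) * Gx + (wdet * (beta * vy - p)) * Gy
    ## ---- continuity residual
    rp <- rp + (wdet * (ux + vy)) * Hmat

    if (stab) { # residual-based SUPG on momentum
      Wm <- (tau_m * Re * u) * Gx + (tau_m * Re * v) * Gy
      Rmx <- Re * convx + px_e - beta * lap_u - div_sx - fx
      Rmy <- Re * convy + py_e - beta * lap_v - div_sy - fy
      ru <- ru + (wdet * Rmx) * Wm
      rv <- rv + (wdet * Rmy) * Wm
    }

    if (elastic) {
      Wt <- Nmat + (tau_s * Wi * u) * Gx + (tau_s * Wi * v) * Gy
      A11 <- Wi * (u * s11x + v * s11y) + s11 - 2 * mu_v * ux -
        2 * Wi * (ux * s11 + uy * s12)
      A12 <- Wi * (u * s12x + v * s12y) + s12 - mu_v * (uy + vx) -
        Wi * (ux * s12 + uy * s22 + vx * s11 + vy * s12)
      A22 <- Wi * (u * s22x + v * s22y) + s22 - 2 * mu_v * vy -
        2 * Wi * (vx * s12 + vy * s22)
      rs1 <- rs1 + (wdet * A11) * Wt
      rs2 <- rs2 + (wdet * A12) * Wt
      rs3 <- rs3 + (wdet * A22) * Wt
    }

    if (jacobian) {
      gu <- (2 * ux * Gx + (uy + vx) * Gy) / gg   # d gamma / d u_j
      gv <- (2 * vy * Gy + (uy + vx) * Gx) / gg
      wN <- wdet * Nmat

      ## momentum-x
      acc_AB("uu", (wdet * Re) * Nmat, ux * Nmat + u * Gx + v * Gy)
      acc_AB("uu", (wdet * beta) * Gx, Gx)
      acc_AB("uu", (wdet * beta) * Gy, Gy)
      if (cfg$case$shear_thinning) {
        visc_u <- ux * Gx + uy * Gy
        acc_AB("uu", (wdet * dbeta) * visc_u, gu)
        acc_AB("uv", (wdet * dbeta) * visc_u, gv)
      }
      acc_AB("uv", (wdet * Re) * Nmat, uy * Nmat)
      acc_AB("up", -wdet * Gx, Hmat)
      ## momentum-y
      acc_AB("vv", (wdet * Re) * Nmat, vy * Nmat + u * Gx + v * Gy)
      acc_AB("vv", (wdet * beta) * Gx, Gx)
      acc_AB("vv", (wdet * beta) * Gy, Gy)
      if (cfg$case$shear_thinning) {
        visc_v <- vx * Gx + vy * Gy
        acc_AB("vu", (wdet * dbeta) * visc_v, gu)
        acc_AB("vv", (wdet * dbeta) * visc_v, gv)
      }
      acc_AB("vu", (wdet * Re) * Nmat, vx * Nmat)
      acc_AB("vp", -wdet * Gy, Hmat)
      ## continuity
      acc_AB("pu", wdet * Hmat, Gx)
      acc_AB("pv", wdet * Hmat, Gy)
      if (stab) {
        Wm <- (tau_m * Re * u) * Gx + (tau_m * Re * v) * Gy
        wWm <- wdet * Wm
        acc_AB("uu", wWm, Re * (ux * Nmat + u * Gx + v * Gy) -
                 beta * cache$lap)
        acc_AB("uv", wWm, (Re * uy) * Nmat)
        acc_AB("vu", wWm, (Re * vx) * Nmat)
        acc_AB("vv", wWm, Re * (vy * Nmat + u * Gx + v * Gy) -
                 beta * cache$lap)
        if (cfg$case$shear_thinning) { # d(beta)/dU inside the strong residual
          acc_AB("uu", (-dbeta * lap_u) * wWm, gu)
          acc_AB("uv", (-dbeta * lap_u) * wWm, gv)
          acc_AB("vu", (-dbeta * lap_v) * wWm, gu)
          acc_AB("vv", (-dbeta * lap_v) * wWm, gv)
        }
        acc_AB("up", wWm, cache$Hx)
        acc_AB("vp", wWm, cache$Hy)
        if (elastic) {
          acc_AB("us1", -wWm, Gx)
          acc_AB("us2", -wWm, Gy)
          acc_AB("vs2", -wWm, Gx)
          acc_AB("vs3", -wWm, Gy)
        }
      }

      if (elastic) {
        Wt <- Nmat + (tau_s * Wi * u) * Gx + (tau_s * Wi * v) * Gy
        wW <- wdet * Wt
        ## momentum coupling to stress divergence (not integrated by parts)
        acc_AB("us1", -wN, Gx)
        acc_AB("us2", -wN, Gy)
        acc_AB("vs2", -wN, Gx)
        acc_AB("vs3", -wN, Gy)
        ## s11 row
        acc_AB("s1u", wW, Wi * s11x * Nmat - 2 * mu_v * Gx -
                 2 * Wi * (s11 * Gx + s12 * Gy))
        acc_AB("s1v", wW, Wi * s11y * Nmat)
        acc_AB("s1s1", wW, Wi * (u * Gx + v * Gy) + (1 - 2 * Wi * ux) * Nmat)
        acc_AB("s1s2", wW, (-2 * Wi * uy) * Nmat)
        ## s12 row
        acc_AB("s2u", wW, Wi * s12x * Nmat - mu_v * Gy -
                 Wi * (s12 * Gx + s22 * Gy))
        acc_AB("s2v", wW, Wi * s12y * Nmat - mu_v * Gx -
                 Wi * (s11 * Gx + s12 * Gy))
        acc_AB("s2s1", wW, (-Wi * vx) * Nmat)
        acc_AB("s2s2", wW, Wi * (u * Gx + v * Gy) +
                 (1 - Wi * (ux + vy)) * Nmat)
        acc_AB("s2s3", wW, (-Wi * uy) * Nmat)
        ## s22 row
        acc_AB("s3u", wW, Wi * s22x * Nmat)
        acc_AB("s3v", wW, Wi * s22y * Nmat - 2 * mu_v * Gy -
                 2 * Wi * (s12 * Gx + s22 * Gy))
        acc_AB("s3s2", wW, (-2 * Wi * vx) * Nmat)
        acc_AB("s3s3", wW, Wi * (u * Gx + v * Gy) + (1 - 2 * Wi * vy) * Nmat)
      }
    }
  }

  ## scatter residuals
  ndof <- dofmap$ndof
  ivec <- c(as.vector(IU), as.vector(IV), as.vector(IP))
  rvec <- c(as.vector(ru), as.vector(rv), as.vector(rp))
  if (elastic) {
    ivec <- c(ivec, as.vector(IS1), as.vector(IS2), as.vector(IS3))
    rvec <- c(rvec, as.vector(rs1), as.vector(rs2), as.vector(rs3))
  }
  r <- as.vector(Matrix::sparseMatrix(i = ivec, j = rep(1L, length(ivec)),
                                      x = rvec, dims = c(ndof, 1L)))

  J <- NULL
  if (jacobian) {
    ti <- tj <- tx <- vector("list", length(blocks))
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      Ik <- rep(seq_len(b$nt), times = b$ntr)
      Jk <- rep(seq_len(b$ntr), each = b$nt)
      ti[[k]] <- as.vector(b$rows[, Ik])
      tj[[k]] <- as.vector(b$cols[, Jk])
      tx[[k]] <- as.vector(b$acc)
    }
    J <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                              dims = c(ndof, ndof))
  }
  list(r = r, J = J, ndof = ndof)
}

## ---- boundary conditions ------------------------------------------------

inlet_profile <- function(y, Ui, w0 = 1) 1.5 * Ui * (1 - (y / w0)^2)
inlet_profile_dy <- function(y, Ui, w0 = 1) -3 * Ui * y / w0^2

#' Dirichlet data for a configuration
#'
#' For channel runs: parabolic inlet velocity `U = 1.5 Ui (1 - (y/w0)^2)`
#' with the matching fully developed Oldroyd-B inlet stresses
#' `s11 = 2 mu_v Wi (dU/dy)^2`, `s12 = mu_v dU/dy`, `s22 = 0`; no-slip walls;
#' natural (uniform-pressure, zero normal extra stress) outflow, which needs
#' no Dirichlet rows.  For `bc = "dirichlet"` verification runs: velocity
#' fixed on the whole boundary from `cfg$exact`, plus one pinned pressure
#' node.
#'
#' @param mesh,dofmap,cfg as in [assemble()].
#' @return list with integer `idx` and numeric `val`.
#' @export
bc_data <- function(mesh, dofmap, cfg) {
  b <- mesh$boundary
  if (any(is.na(b$tag))) stop("untagged boundary edge")
  node_of <- function(tags) sort(unique(c(b$n1[b$tag %in% tags],
                                          b$n2[b$tag %in% tags],
                                          b$mid[b$tag %in% tags])))
  idx <- integer(0); val <- numeric(0)
  add <- function(i, g) { idx <<- c(idx, i); val <<- c(val, g) }
  if (cfg$bc == "dirichlet") {
    bn <- node_of(c("inlet", "outlet", "wall"))
    xy <- mesh$coords[bn, , drop = FALSE]
    add(dofmap$u[bn], cfg$exact$u(xy[, 1], xy[, 2]))
    add(dofmap$v[bn], cfg$exact$v(xy[, 1], xy[, 2]))
    pin <- 1L
    pexact <- if (!is.null(cfg$exact$p))
      cfg$exact$p(mesh$coords[pin, 1], mesh$coords[pin, 2]) else 0
    add(dofmap$p[pin], pexact)
    o <- !duplicated(idx)
    return(list(idx = idx[o], val = val[o]))
  }
  wall <- node_of("wall")
  inlet <- setdiff(node_of("inlet"), wall)
  w0 <- max(abs(mesh$coords[node_of("inlet"), 2]))
  yin <- mesh$coords[inlet, 2]
  add(dofmap$u[wall], rep(0, length(wall)))
  add(dofmap$v[wall], rep(0, length(wall)))
  add(dofmap$u[inlet], inlet_profile(yin, cfg$Ui, w0))
  add(dofmap$v[inlet], rep(0, length(inlet)))
  if (dofmap$elastic) {
    inlet_all <- node_of("inlet")
    ya <- mesh$coords[inlet_all, 2]
    dudy <- inlet_profile_dy(ya, cfg$Ui, w0)
    mu_v <- cfg$groups$mu_v_star
    add(dofmap$s11[inlet_all], 2 * mu_v * cfg$Wi * dudy^2)
    add(dofmap$s12[inlet_all], mu_v * dudy)
    add(dofmap$s22[inlet_all], rep(0, length(inlet_all)))
  }
  list(idx = idx, val = val)
}

#' Constrain an assembled system with Dirichlet data
#'
#' Replaces each constrained residual entry by `x_d - g_d` and the
#' corresponding Jacobian row by the identity row.
#'
#' @param sys result of [assemble()].
#' @param bc result of [bc_data()].
#' @param state current packed state vector (or `flow_state`).
#' @param dofmap the [dof_map()] (needed to pack a `flow_state`).
#' @return the constrained system (same shape as `sys`).
#' @export
apply_bcs <- function(sys, bc, state, dofmap = NULL) {
  if (inherits(state, "flow_state")) state <- pack_state(state, dofmap)
  r <- sys$r
  r[bc$idx] <- state[bc$idx] - bc$val
  J <- sys$J
  if (!is.null(J)) {
    mask <- rep(1, sys$ndof); mask[bc$idx] <- 0
    J <- Matrix::Diagonal(x = mask) %*% J +
      Matrix::sparseMatrix(i = bc$idx, j = bc$idx, x = rep(1, length(bc$idx)),
                           dims = c(sys$ndof, sys$ndof))
  }
  list(r = r, J = J, ndof = sys$ndof)
}

## ---- Newton solve -------------------------------------------------------

#' Steady Newton solve
#'
#' Newton iteration with analytic Jacobian and sparse direct linear solves.
#' Convergence requires the summed absolute nodal increment of every field
#' (velocity, pressure, stress) to drop below `cfg$tol`, guarded by a
#' relative-residual safety criterion (`cfg$rtol`, or increment stationarity
#' over two consecutive iterations).
#'
#' @param mesh a [mesh_channel()] mesh.
#' @param dofmap a [dof_map()]; must match `cfg$case$elastic`.
#' @param cfg a [solver_config()].
#' @param initial_state optional `flow_state` used as the starting iterate.
#' @return a `flow_state` with attributes `converged`, `iterations`, and a
#'   `history` data frame (residual norm and per-field increment sums).
#' @export
newton_solve <- function(mesh, dofmap, cfg, initial_state = NULL) {
  stopifnot(identical(dofmap$elastic, cfg$case$elastic))
  cache <- mesh_fe_cache(mesh)
  bc <- bc_data(mesh, dofmap, cfg)
  x <- if (is.null(initial_state)) numeric(dofmap$ndof)
       else pack_state(initial_state, dofmap)
  hist <- list()
  r0norm <- NA_real_
  converged <- FALSE
  eq23_prev <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_newton)) {
    sys <- assemble(mesh, dofmap, x, cfg, jacobian = TRUE, cache = cache)
    sys <- apply_bcs(sys, bc, x)
    rn <- sqrt(sum(sys$r^2))
    if (!is.finite(rn)) stop("residual diverged (non-finite) at iteration ", it)
    if (it == 1L) r0norm <- max(rn, 1e-300)
    if (rn > 1e6 * max(1, r0norm))
      stop("Newton divergence: residual grew by > 1e6")
    dx <- tryCatch(as.vector(Matrix::solve(sys$J, -sys$r)),
                   error = function(e) stop("linear solve failed: ",
                                            conditionMessage(e)))
    ## backtracking line search on the residual norm
    alpha <- cfg$relaxation
    repeat {
      xt <- x + alpha * dx
      rt <- apply_bcs(assemble(mesh, dofmap, xt, cfg, jacobian = FALSE,
                               cache = cache), bc, xt)$r
      rtn <- sqrt(sum(rt^2))
      if (is.finite(rtn) && (rtn <= rn || alpha <= cfg$relaxation / 16)) break
      alpha <- alpha / 2
    }
    x <- xt
    dscaled <- abs(alpha * dx)
    inc_u <- sum(dscaled[dofmap$u]) + sum(dscaled[dofmap$v])
    inc_p <- sum(dscaled[dofmap$p])
    inc_s <- if (dofmap$elastic)
      sum(dscaled[dofmap$s11]) + sum(dscaled[dofmap$s12]) +
      sum(dscaled[dofmap$s22]) else 0
    hist[[it]] <- data.frame(iter = it, resid = rn, inc_u = inc_u,
                             inc_p = inc_p, inc_s = inc_s)
    eq23 <- max(inc_u, inc_p, inc_s) <= cfg$tol
    if (eq23 && (rn / r0norm <= cfg$rtol || rn <= 1e-10 || eq23_prev)) {
      converged <- TRUE
      break
    }
    eq23_prev <- eq23
  }
  st <- new_flow_state(dofmap, x)
  attr(st, "converged") <- converged
  attr(st, "iterations") <- it
  attr(st, "history") <- do.call(rbind, hist)
  attr(st, "Re") <- cfg$Re; attr(st, "Wi") <- cfg$Wi
  attr(st, "case") <- cfg$case$case
  attr(st, "cfg") <- cfg
  st
}

#' Solve one operating point with Reynolds continuation
#'
#' Builds (or reuses) the channel geometry and mesh for the requested model,
#' then marches the Reynolds number through `cfg$continuation` up to the
#' target, reusing each converged state to initialize the next solve.
#'
#' @param model `"stenosis"` or `"aneurysm"` (ignored when `geom` is given).
#' @param case a case tag accepted by [case_config()] or a `case_config`.
#' @param Re,Wi target operating point.
#' @param geom optional [build_channel()] geometry (defaults to the standard
#'   two-lesion model of the given type).
#' @param mesh optional mesh; built from `h_far`/`h_lesion` otherwise.
#' @param h_far,h_lesion,ny mesh controls when `mesh` is `NULL`.
#' @param keep_Re optional vector of intermediate Reynolds numbers whose
#'   converged states should be returned as well.
#' @param ... further arguments passed to [solver_config()].
#' @return a `flow_state` (the target solve) with attributes `geom`, `mesh`;
#'   if `keep_Re` is non-empty, attribute `kept` holds a named list of the
#'   intermediate states.
#' @export
solve_case <- function(model = c("stenosis", "aneurysm"), case = "newtonian",
                       Re = 1000, Wi = 0.6, geom = NULL, mesh = NULL,
                       h_far = 0.35, h_lesion = 0.15, ny = NULL,
                       keep_Re = NULL, ...) {
  if (is.null(geom)) {
    model <- match.arg(model)
    spec <- if (model == "stenosis") stenosis_spec() else aneurysm_spec()
    geom <- build_channel(spec)
  }
  if (is.null(mesh)) mesh <- mesh_channel(geom, h_far = h_far,
                                          h_lesion = h_lesion, ny = ny)
  if (!inherits(case, "case_config")) case <- case_config(case)
  cfg <- solver_config(Re = Re, Wi = Wi, case = case, ...)
  dof <- dof_map(mesh, elastic = case$elastic)
  sched <- sort(unique(c(cfg$continuation[cfg$continuation < Re], Re)))
  kept <- list()
  st <- NULL
  for (re_k in sched) {
    cfg_k <- solver_config(Re = re_k, Wi = cfg$Wi, case = case, Ui = cfg$Ui,
                           tol = cfg$tol, rtol = cfg$rtol,
                           max_newton = cfg$max_newton,
                           relaxation = cfg$relaxation,
                           stabilize = cfg$stabilize, force = cfg$force,
                           rho = cfg$rho, L_dim = cfg$L_dim,
                           continuation = cfg$continuation, bc = cfg$bc,
                           exact = cfg$exact)
    st <- newton_solve(mesh, dof, cfg_k, initial_state = st)
    if (!isTRUE(attr(st, "converged")) && re_k < Re)
      warning(sprintf("continuation step Re = %g did not fully converge", re_k))
    if (re_k %in% keep_Re) kept[[as.character(re_k)]] <- st
  }
  attr(st, "geom") <- geom
  attr(st, "mesh") <- mesh
  if (length(kept)) attr(st, "kept") <- kept
  st
}

## ---- flux ---------------------------------------------------------------

#' Volumetric flux through a cross-section
#'
#' `method = "conservative"` evaluates the discretely conservative flux
#' functional: the axial velocity is weighted by the gradient of a linear
#' ramp interpolated on the pressure (corner) basis, which makes the result
#' exactly consistent with the discrete continuity equation (fluxes at any
#' two stations agree to solver precision on a converged state).
#' `method = "line"` integrates the quadratic velocity along the vertical
#' line at `x0` exactly, element by element.
#'
#' @param state a `flow_state`.
#' @param mesh the mesh the state lives on.
#' @param x0 axial station.
#' @param method `"conservative"` or `"line"`.
#' @param width ramp half-width for the conservative functional.
#' @return scalar flux.
#' @export
flux <- function(state, mesh, x0, method = c("conservative", "line"),
                 width = NULL) {
  method <- match.arg(method)
  g <- mesh$grid
  L <- max(mesh$coords[, 1])
  if (x0 < 0 || x0 > L) stop("station outside domain")
  if (method == "line") return(flux_line(state, mesh, x0))
  if (is.null(width)) width <- max(2.5 * stats::median(diff(g$xcols)), 1e-3)
  lo <- max(0, x0 - width); hi <- min(L, x0 + width)
  wn <- pmin(1, pmax(0, (hi - mesh$coords[seq_len(mesh$n_corner), 1]) /
                       (hi - lo)))
  cache <- mesh_fe_cache(mesh)
  ref <- cache$ref
  tri <- mesh$tri
  nel <- mesh$n_elem
  wel <- matrix(wn[tri[, 1:3]], nel, 3)
  ## P1 gradient of the ramp is constant per element; use the P2 machinery's
  ## corner rows (first derivatives of H equal those of the corner L's)
  p1 <- mesh$coords[tri[, 1], , drop = FALSE]
  p2 <- mesh$coords[tri[, 2], , drop = FALSE]
  p3 <- mesh$coords[tri[, 3], , drop = FALSE]
  det <- cache$det
  b1 <- (p2[, 2] - p3[, 2]) / det; b2 <- (p3[, 2] - p1[, 2]) / det
  b3 <- (p1[, 2] - p2[, 2]) / det
  c1 <- (p3[, 1] - p2[, 1]) / det; c2 <- (p1[, 1] - p3[, 1]) / det
  c3 <- (p2[, 1] - p1[, 1]) / det
  wx <- wel[, 1] * b1 + wel[, 2] * b2 + wel[, 3] * b3
  wy <- wel[, 1] * c1 + wel[, 2] * c2 + wel[, 3] * c3
  uel <- matrix(state$u[tri], nel, 6)
  vel <- matrix(state$v[tri], nel, 6)
  total <- 0
  for (q in seq_along(ref$w)) {
    u <- drop(uel %*% ref$N[, q]); v <- drop(vel %*% ref$N[, q])
    total <- total + sum(ref$w[q] * det * (-u * wx - v * wy))
  }
  total
}

flux_line <- function(state, mesh, x0) {
  tri <- mesh$tri
  p1 <- mesh$coords[tri[, 1], , drop = FALSE]
  p2 <- mesh$coords[tri[, 2], , drop = FALSE]
  p3 <- mesh$coords[tri[, 3], , drop = FALSE]
  xmin <- pmin(p1[, 1], p2[, 1], p3[, 1])
  xmax <- pmax(p1[, 1], p2[, 1], p3[, 1])
  ## half-open test so a station on a shared mesh line is counted once
  if (x0 >= max(xmax)) cand <- which(xmax >= x0 & x0 > xmin)
  else cand <- which(xmin <= x0 & x0 < xmax)
  total <- 0
  for (e in cand) {
    P <- rbind(p1[e, ], p2[e, ], p3[e, ])
    ys <- numeric(0)
    for (k in 1:3) {
      a <- P[k, ]; b <- P[k %% 3 + 1, ]
      if ((a[1] - x0) * (b[1] - x0) <= 0 && a[1] != b[1]) {
        t <- (x0 - a[1]) / (b[1] - a[1])
        ys <- c(ys, a[2] + t * (b[2] - a[2]))
      }
    }
    if (length(ys) < 2) next
    ylo <- min(ys); yhi <- max(ys)
    if (yhi - ylo < 1e-14) next
    ## Simpson is exact for the quadratic trace along the line
    ym <- (ylo + yhi) / 2
    det <- (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
      (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])
    val <- vapply(c(ylo, ym, yhi), function(yv) {
      l2 <- ((x0 - P[1, 1]) * (P[3, 2] - P[1, 2]) -
               (yv - P[1, 2]) * (P[3, 1] - P[1, 1])) / det
      l3 <- ((yv - P[1, 2]) * (P[2, 1] - P[1, 1]) -
               (x0 - P[1, 1]) * (P[2, 2] - P[1, 2])) / det
      sum(tri6_shape(l2, l3) * state$u[tri[e, ]])
    }, 0)
    total <- total + (yhi - ylo) / 6 * (val[1] + 4 * val[2] + val[3])
  }
  total
}
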